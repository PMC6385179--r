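# Beta diversity: pairwise dissimilarities (Bray-Curtis, binary Jaccard,
# Morisita-Horn), principal coordinates analysis, and one-factor permutation
# PERMANOVA on a distance matrix.

#' Log-transform a count table
#'
#' Elementwise `ln(1 + x)`, the transform applied to counts before computing
#' Bray-Curtis and Jaccard dissimilarities.
#'
#' @param table numeric matrix or vector of non-negative counts.
#' @return transformed object of the same shape.
#' @export
log_transform_counts <- function(table) {
  if (any(table < 0)) bld_abort("counts must be non-negative", "invalid_counts")
  log1p(table)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    bld_abort("abundance vectors must have equal length", "invalid_parameter")
  }
  if (any(x < 0) || any(y < 0)) {
    bld_abort("abundances must be non-negative", "invalid_counts")
  }
  if (sum(x) == 0 && sum(y) == 0) {
    bld_abort("dissimilarity undefined for two all-zero vectors",
              "undefined_distance")
  }
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`.
#'
#' @param x,y equal-length non-negative abundance vectors, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Jaccard dissimilarity between two samples
#'
#' Binary (default): `1 - |A intersect B| / |A union B|` over the presence
#' sets. The quantitative variant (`binary = FALSE`) is vegan's
#' abundance-based Jaccard, `2B / (1 + B)` with `B` the Bray-Curtis
#' dissimilarity.
#'
#' @inheritParams bray_curtis
#' @param binary use presence/absence sets.
#' @return dissimilarity in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(x, y, binary = TRUE) {
  check_pair(x, y)
  if (binary) {
    1 - sum(x > 0 & y > 0) / sum(x > 0 | y > 0)
  } else {
    b <- bray_curtis(x, y)
    2 * b / (1 + b)
  }
}

#' Morisita-Horn dissimilarity between two abundance vectors
#'
#' `1 - 2 sum(x_i y_i) / ((d_x + d_y) N_x N_y)` with `d_x = sum(x_i^2)/N_x^2`;
#' invariant to the total abundance of each sample.
#'
#' @inheritParams bray_curtis
#' @return dissimilarity in `[0, 1]`.
#' @export
morisita_horn <- function(x, y) {
  check_pair(x, y)
  nx <- sum(x)
  ny <- sum(y)
  if (nx == 0 || ny == 0) {
    bld_abort("Morisita-Horn undefined when a sample total is zero",
              "undefined_distance")
  }
  dx <- sum(x^2) / nx^2
  dy <- sum(y^2) / ny^2
  1 - 2 * sum(x * y) / ((dx + dy) * nx * ny)
}

#' Dissimilarity matrix for a count table
#'
#' Computes all pairwise dissimilarities of a samples-by-taxa table with
#' `vegan::vegdist`. Bray-Curtis and Jaccard are computed on log(1+x) counts
#' by default, Morisita-Horn on raw counts (its scale invariance makes the
#' transform unnecessary).
#'
#' @param table samples-by-taxa count matrix with sample ids as row names.
#' @param metric `"bray"`, `"jaccard"` or `"morisita_horn"`.
#' @param log_transform apply `log1p` first; defaults to TRUE for Bray and
#'   Jaccard, FALSE for Morisita-Horn.
#' @param binary for Jaccard: presence/absence (default TRUE).
#' @return a `dist` object with sample labels.
#' @export
beta_dissimilarity <- function(table,
                               metric = c("bray", "jaccard", "morisita_horn"),
                               log_transform = NULL, binary = TRUE) {
  metric <- match.arg(metric)
  table <- as.matrix(table)
  if (is.null(log_transform)) log_transform <- metric != "morisita_horn"
  if (log_transform) table <- log_transform_counts(table)
  switch(metric,
         bray = vegan::vegdist(table, method = "bray"),
         jaccard = vegan::vegdist(table, method = "jaccard", binary = binary),
         morisita_horn = vegan::vegdist(table, method = "horn"))
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition. Axes
#' with positive eigenvalues are retained; non-Euclidean matrices (e.g.
#' Bray-Curtis) can produce negative eigenvalues, which are reported rather
#' than hidden, together with the residual error of reconstructing the input
#' distances from the retained axes.
#'
#' @param d a `dist` object or symmetric dissimilarity matrix (n >= 3).
#' @return object of class `pcoa_ordination`: `coordinates` (samples x
#'   retained axes, scaled so Euclidean inter-point distances approximate
#'   `d`), `eigenvalues` (all n, non-increasing), `proportion_explained`
#'   (share of positive inertia per retained axis) and
#'   `reconstruction_rmse`.
#' @export
pcoa_ordination <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) bld_abort("PCoA needs at least 3 samples", "too_few_samples")
  if (any(abs(dm - t(dm)) > 1e-12)) {
    bld_abort("dissimilarity matrix must be symmetric", "invalid_parameter")
  }
  b <- -0.5 * dm^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))   # second sweep re-adds the grand mean
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  recon <- as.matrix(stats::dist(coords))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = e$values[pos] / sum(e$values[pos]),
                 reconstruction_rmse = sqrt(mean((recon - dm)^2))),
            class = "pcoa_ordination")
}

# SS_within for each column of a label matrix L (n x B, integer group codes),
# from the squared-distance matrix. Vectorized over permutations.
ss_within_cols <- function(d2, labs) {
  n_lev <- max(labs)
  out <- numeric(ncol(labs))
  for (lev in seq_len(n_lev)) {
    e <- (labs == lev) * 1
    ng <- sum(e[, 1])
    out <- out + colSums(e * (d2 %*% e)) / (2 * ng)
  }
  out
}

# all permutations of 1..n (n small) as an n! x n matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' One-factor permutation PERMANOVA
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components (the `adonis` decomposition) and assesses the
#' pseudo-F statistic by permuting group labels. The reported p-value uses the
#' +1 correction `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, so its
#' minimum attainable value is `1 / (n_permutations + 1)`. With
#' `exact = TRUE` all `n!` relabelings are enumerated instead and
#' `p = #{F >= F_obs} / n!` (the observed labeling included). A grouping with
#' zero within-group sum of squares yields an infinite pseudo-F, which is
#' treated as exceeding every finite permuted statistic.
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param labels group labels aligned with the rows of `d` (>= 2 groups).
#' @param n_permutations number of random permutations (ignored when
#'   `exact = TRUE`).
#' @param seed optional integer seed for the permutations.
#' @param strata optional cluster ids; permutations are then restricted to
#'   shuffle labels only within each stratum.
#' @param exact enumerate all relabelings (requires n <= 8 and no strata).
#' @return object of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `seed`, `ss_between`, `ss_within`, `df`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL,
                      strata = NULL, exact = FALSE) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  labels <- factor(labels)
  if (length(labels) != n) {
    bld_abort("labels must align with the dissimilarity matrix",
              "invalid_parameter")
  }
  g <- nlevels(labels)
  if (g < 2 || any(table(labels) < 1)) {
    bld_abort("need at least two non-empty groups", "invalid_parameter")
  }
  codes <- as.integer(labels)
  ss_total <- sum(d2) / (2 * n)
  f_stat <- function(ssw) {
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  ssw_obs <- ss_within_cols(d2, matrix(codes, ncol = 1))
  f_obs <- f_stat(ssw_obs)
  if (exact) {
    if (!is.null(strata)) {
      bld_abort("exact enumeration does not support strata", "invalid_parameter")
    }
    if (n > 8) bld_abort("exact enumeration limited to n <= 8", "invalid_parameter")
    perms <- all_permutations(n)
    labs <- matrix(codes[t(perms)], nrow = n)   # n x n! label matrix
    f_all <- f_stat(ss_within_cols(d2, labs))
    p <- mean(f_all >= f_obs)
    n_perm_used <- nrow(perms)
  } else {
    perm_indices <- function() {
      if (is.null(strata)) return(sample.int(n))
      idx <- seq_len(n)
      for (s in split(seq_len(n), strata)) idx[s] <- s[sample.int(length(s))]
      idx
    }
    labs <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) codes[perm_indices()],
             integer(n))
    })
    f_perm <- f_stat(ss_within_cols(d2, labs))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
    n_perm_used <- n_permutations
  }
  structure(list(pseudo_F = f_obs,
                 R2 = (ss_total - ssw_obs) / ss_total,
                 p_value = p,
                 n_permutations = n_perm_used,
                 seed = seed,
                 ss_between = ss_total - ssw_obs,
                 ss_within = ssw_obs,
                 df = c(between = g - 1, within = n - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$df[["between"]], x$df[["within"]], x$R2, x$p_value,
    x$n_permutations))
  invisible(x)
}
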