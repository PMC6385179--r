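# Longitudinal comparisons: paired encounter deltas, Gaussian GEE with
# exchangeable working correlation and sandwich variance, group comparison of
# deltas, and a permutation differential-abundance test with BH adjustment.

ENCOUNTER_LEVELS <- c("B", "E", "T", "R")
ENCOUNTER_PAIRS <- list(c("B", "T"), c("B", "R"), c("E", "T"), c("E", "R"))

#' Build paired encounter deltas per exacerbation
#'
#' For every exacerbation, emits the change (later minus earlier) in each
#' alpha-diversity index across the four encounter pairs B-T, B-R, E-T and
#' E-R, whenever both member samples exist, were sequenced, and are not on the
#' exclusion list. When an exacerbation after the first has no baseline of its
#' own, the previous exacerbation's post-recovery (R) sample serves as its
#' baseline (one physical sample, two encounter roles); the provenance columns
#' record which sample filled each role.
#'
#' @param metadata data frame with columns `patient_id`,
#'   `exacerbation_number`, `encounter` (B/E/T/R) and `sample_id` (NA when no
#'   sample was collected). Keys `(patient_id, exacerbation_number,
#'   encounter)` must be unique.
#' @param alpha per-sample index table, e.g. from [alpha_diversity()]: a
#'   `sample_id` column plus one numeric column per index.
#' @param indices index columns of `alpha` to difference (default: all
#'   numeric columns except the bookkeeping ones).
#' @param excluded_samples character vector of sample ids to drop (sensitivity
#'   filter).
#' @return data frame of deltas: `patient_id`, `exacerbation_number`, `pair`,
#'   `index_name`, `delta`, `sample_id_from`, `sample_id_to`.
#' @export
pair_encounters <- function(metadata, alpha, indices = NULL,
                            excluded_samples = character()) {
  req <- c("patient_id", "exacerbation_number", "encounter", "sample_id")
  if (!all(req %in% names(metadata))) {
    bld_abort(paste("metadata must contain columns:",
                    paste(req, collapse = ", ")), "schema")
  }
  key <- paste(metadata$patient_id, metadata$exacerbation_number,
               metadata$encounter)
  if (anyDuplicated(key)) {
    bld_abort("duplicate (patient, exacerbation, encounter) keys",
              "data_integrity")
  }
  if (is.null(indices)) {
    indices <- setdiff(names(alpha)[vapply(alpha, is.numeric, logical(1))],
                       c("rarefaction_depth", "n_iterations"))
  }
  # look up a usable sample id for one encounter role, honoring exclusions
  # and the R-becomes-next-B chain
  find_sample <- function(pid, exac, enc) {
    hit <- metadata$sample_id[metadata$patient_id == pid &
                                metadata$exacerbation_number == exac &
                                metadata$encounter == enc]
    if (length(hit) == 1 && !is.na(hit) && !(hit %in% excluded_samples) &&
        hit %in% alpha$sample_id) {
      return(hit)
    }
    if (enc == "B" && length(hit) == 0) {
      # fall back to the previous exacerbation's post-recovery sample
      prev <- metadata$exacerbation_number[metadata$patient_id == pid &
                                             metadata$exacerbation_number < exac]
      if (length(prev) > 0) return(find_sample(pid, max(prev), "R"))
    }
    NA_character_
  }
  exacs <- unique(metadata[, c("patient_id", "exacerbation_number")])
  out <- list()
  for (i in seq_len(nrow(exacs))) {
    pid <- exacs$patient_id[i]
    exac <- exacs$exacerbation_number[i]
    ids <- vapply(ENCOUNTER_LEVELS, function(e) find_sample(pid, exac, e),
                  character(1))
    for (pr in ENCOUNTER_PAIRS) {
      from <- ids[[pr[1]]]
      to <- ids[[pr[2]]]
      if (is.na(from) || is.na(to)) next
      a_from <- alpha[alpha$sample_id == from, indices, drop = FALSE]
      a_to <- alpha[alpha$sample_id == to, indices, drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        patient_id = pid, exacerbation_number = exac,
        pair = paste(pr, collapse = "-"), index_name = indices,
        delta = as.numeric(a_to[1, ]) - as.numeric(a_from[1, ]),
        sample_id_from = from, sample_id_to = to,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(), exacerbation_number = numeric(),
                      pair = character(), index_name = character(),
                      delta = numeric(), sample_id_from = character(),
                      sample_id_to = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Gaussian GEE with exchangeable working correlation and sandwich variance
#'
#' Iterated estimating equations for a marginal linear model on clustered
#' data: identity link, Gaussian variance, exchangeable working correlation
#' with a moment estimator of the common within-cluster correlation, and the
#' robust (sandwich) covariance estimator for the coefficients. With singleton
#' clusters the estimates coincide exactly with ordinary least squares.
#'
#' @param response numeric response vector.
#' @param design model matrix (full column rank), same number of rows.
#' @param cluster_ids cluster membership (e.g. patient id) per row.
#' @param max_iter,tol iteration cap and convergence tolerance on
#'   `max |delta beta|`.
#' @return object of class `gee_result`: `coefficients`, `robust_se`,
#'   `z_scores`, `p_values`, `working_correlation_alpha`, `dispersion`,
#'   `n_clusters`, `converged`, `vcov`.
#' @export
gee_gaussian_exchangeable <- function(response, design, cluster_ids,
                                      max_iter = 100, tol = 1e-8) {
  y <- as.numeric(response)
  x <- as.matrix(design)
  n <- length(y)
  p <- ncol(x)
  if (nrow(x) != n || length(cluster_ids) != n) {
    bld_abort("response, design and cluster_ids must align", "invalid_parameter")
  }
  if (qr(x)$rank < p) bld_abort("design matrix is rank deficient",
                                "singular_design")
  if (n <= p) {
    bld_abort("need more observations than coefficients", "invalid_parameter")
  }
  clusters <- split(seq_len(n), factor(cluster_ids,
                                       levels = unique(cluster_ids)))
  n_pairs <- sum(vapply(clusters, function(i) length(i) * (length(i) - 1) / 2,
                        numeric(1)))
  n_max <- max(lengths(clusters))
  beta <- qr.solve(x, y)
  alpha <- 0
  phi <- 1
  converged <- FALSE
  weighted_cross <- function(beta, alpha, phi) {
    a <- matrix(0, p, p)
    b <- numeric(p)
    for (i in clusters) {
      ni <- length(i)
      xi <- x[i, , drop = FALSE]
      c1 <- 1 / (phi * (1 - alpha))
      c2 <- alpha / (1 + (ni - 1) * alpha)
      # t(Xi) V^{-1} for V = phi [(1-alpha) I + alpha J]
      xtv <- c1 * (t(xi) - c2 * tcrossprod(colSums(xi), rep(1, ni)))
      a <- a + xtv %*% xi
      b <- b + xtv %*% y[i]
    }
    list(a = a, b = b)
  }
  for (iter in seq_len(max_iter)) {
    r <- y - x %*% beta
    phi <- sum(r^2) / (n - p)
    if (n_pairs > p) {
      s <- sum(vapply(clusters, function(i) {
        ri <- r[i]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, numeric(1)))
      alpha <- s / phi / (n_pairs - p)
      lower <- if (n_max > 1) -1 / (n_max - 1) + 1e-6 else 0
      alpha <- min(max(alpha, lower), 1 - 1e-6)
    } else {
      alpha <- 0
    }
    wc <- weighted_cross(beta, alpha, phi)
    beta_new <- solve(wc$a, wc$b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  r <- as.numeric(y - x %*% beta)
  wc <- weighted_cross(beta, alpha, phi)
  a_inv <- solve(wc$a)
  meat <- matrix(0, p, p)
  for (i in clusters) {
    ni <- length(i)
    xi <- x[i, , drop = FALSE]
    c1 <- 1 / (phi * (1 - alpha))
    c2 <- alpha / (1 + (ni - 1) * alpha)
    xtv <- c1 * (t(xi) - c2 * tcrossprod(colSums(xi), rep(1, ni)))
    u <- xtv %*% r[i]
    meat <- meat + tcrossprod(u)
  }
  vc <- a_inv %*% meat %*% a_inv
  se <- sqrt(diag(vc))
  z <- as.numeric(beta) / se
  cf <- as.numeric(beta)
  names(cf) <- colnames(x) %||% paste0("b", seq_len(p))
  structure(list(coefficients = cf, robust_se = se, z_scores = z,
                 p_values = 2 * stats::pnorm(-abs(z)),
                 working_correlation_alpha = alpha, dispersion = phi,
                 n_clusters = length(clusters), converged = converged,
                 vcov = vc),
            class = "gee_result")
}

#' @export
print.gee_result <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$z_scores, p = x$p_values)
  print(round(tab, 5))
  cat(sprintf("exchangeable alpha = %.4f, clusters = %d, converged = %s\n",
              x$working_correlation_alpha, x$n_clusters, x$converged))
  invisible(x)
}

#' Compare encounter deltas between exposure groups
#'
#' For every (encounter pair, diversity index) cell, regresses the paired
#' delta on a therapeutic-group indicator with the patient as cluster, using
#' [gee_gaussian_exchangeable()]. The group coefficient is therapeutic minus
#' subtherapeutic, so a diversity decline specific to the therapeutic group
#' appears as a negative estimate. Cells where either group has no deltas are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param deltas output of [pair_encounters()].
#' @param classification data frame with `patient_id`, `exacerbation_number`
#'   and `category` (`"therapeutic"` / `"subtherapeutic"`).
#' @return data frame with one row per tested cell: group means/SDs and
#'   sizes, GEE estimate of the group effect, robust SE and p-value.
#' @export
compare_group_deltas <- function(deltas, classification) {
  req <- c("patient_id", "exacerbation_number", "category")
  if (!all(req %in% names(classification))) {
    bld_abort("classification needs patient_id, exacerbation_number, category",
              "schema")
  }
  m <- merge(deltas, classification[, req],
             by = c("patient_id", "exacerbation_number"))
  out <- list()
  skipped <- character()
  for (pr in unique(m$pair)) {
    for (idx in unique(m$index_name)) {
      cell <- m[m$pair == pr & m$index_name == idx, ]
      ther <- cell$delta[cell$category == "therapeutic"]
      sub <- cell$delta[cell$category == "subtherapeutic"]
      if (length(ther) < 2 || length(sub) < 2) {
        skipped <- c(skipped,
                     sprintf("%s/%s: fewer than 2 deltas in a group", pr, idx))
        next
      }
      x <- cbind(`(Intercept)` = 1,
                 group_therapeutic = as.numeric(cell$category == "therapeutic"))
      fit <- gee_gaussian_exchangeable(cell$delta, x, cell$patient_id)
      out[[length(out) + 1]] <- data.frame(
        pair = pr, index_name = idx,
        n_therapeutic = length(ther), n_subtherapeutic = length(sub),
        mean_therapeutic = mean(ther), sd_therapeutic = stats::sd(ther),
        mean_subtherapeutic = mean(sub), sd_subtherapeutic = stats::sd(sub),
        estimate = fit$coefficients[["group_therapeutic"]],
        robust_se = fit$robust_se[2], p_value = fit$p_values[2],
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else data.frame()
  attr(res, "skipped") <- skipped
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps `stats::p.adjust`), with
#' input validation.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    bld_abort("p-values must lie in [0, 1]", "validation")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation test of differential relative abundance
#'
#' A deliberately simple two-group differential-abundance test: per taxon, the
#' log2 fold change of mean relative abundance (pseudocount 0.5 added to every
#' count) between groups, with a two-sided p-value from permuting group labels
#' and Benjamini-Hochberg adjustment across taxa. This is not a
#' negative-binomial model; its fold changes are descriptive.
#'
#' @param table samples-by-taxa count matrix.
#' @param group_labels two-level factor aligned with the rows; the fold change
#'   is first level relative to second.
#' @param n_permutations label permutations for the null distribution.
#' @param seed optional integer seed.
#' @return data frame: `taxon`, `log2_fold_change`, `p_value`, `adjusted_p`,
#'   ordered as in the input. Taxa absent from every sample are excluded.
#' @export
differential_abundance <- function(table, group_labels, n_permutations = 999,
                                   seed = NULL) {
  table <- as.matrix(table)
  group_labels <- factor(group_labels)
  if (nlevels(group_labels) != 2) {
    bld_abort("group_labels must have exactly two levels", "invalid_parameter")
  }
  if (any(table(group_labels) < 2)) {
    bld_abort("need at least two samples per group", "invalid_parameter")
  }
  present <- colSums(table) > 0
  if (any(!present)) {
    message(sprintf("differential_abundance: excluding %d all-zero taxa",
                    sum(!present)))
  }
  table <- table[, present, drop = FALSE]
  ra <- (table + 0.5) / rowSums(table + 0.5)
  in_a <- group_labels == levels(group_labels)[1]
  stat <- function(sel) {
    log2(colMeans(ra[sel, , drop = FALSE]) /
           colMeans(ra[!sel, , drop = FALSE]))
  }
  obs <- stat(in_a)
  n_a <- sum(in_a)
  n <- nrow(ra)
  exceed <- with_seed(seed, {
    hits <- numeric(ncol(ra))
    for (b in seq_len(n_permutations)) {
      sel <- seq_len(n) %in% sample.int(n, n_a)
      hits <- hits + (abs(stat(sel)) >= abs(obs))
    }
    hits
  })
  p <- (1 + exceed) / (1 + n_permutations)
  data.frame(taxon = colnames(table) %||% paste0("taxon", seq_along(obs)),
             log2_fold_change = unname(obs), p_value = unname(p),
             adjusted_p = bh_adjust(unname(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}
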