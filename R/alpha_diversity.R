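# Alpha diversity across the Hill-number gradient: rarefaction to a common
# depth, observed richness, Chao and ACE richness estimators (q = 0), Shannon
# (q = 1) and inverse Simpson (q = 2).

#' Rarefy a count vector to a common depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric draw) so
#' that every sample is represented by the same number of sequences, removing
#' library-size bias before diversity estimation. Draws are generated by
#' sequential conditional hypergeometric sampling, which is exact and fast for
#' long count vectors.
#'
#' @param counts non-negative integer vector (optionally named by taxon).
#' @param depth target depth; must not exceed `sum(counts)`.
#' @param n_iterations number of independent subsamples to draw.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return list of `n_iterations` count vectors, each summing exactly to
#'   `depth`.
#' @examples
#' rarefy(c(a = 50, b = 30, c = 20), depth = 25, n_iterations = 2, seed = 1)
#' @export
rarefy <- function(counts, depth, n_iterations = 1, seed = NULL) {
  counts <- check_counts(counts)
  n_total <- sum(counts)
  if (!is_number(depth) || depth <= 0 || depth != round(depth)) {
    bld_abort("depth must be a positive integer", "invalid_parameter")
  }
  if (depth > n_total) {
    bld_abort(sprintf("depth %s exceeds sample total %s", depth, n_total),
              "insufficient_depth")
  }
  if (!is_number(n_iterations) || n_iterations < 1) {
    bld_abort("n_iterations must be >= 1", "invalid_parameter")
  }
  nm <- names(counts)
  k <- length(counts)
  draw_one <- function() {
    out <- numeric(k)
    remaining <- n_total
    need <- depth
    for (i in seq_len(k)) {
      if (need == 0) break
      remaining <- remaining - counts[i]
      if (remaining <= 0) {        # everything left must come from the tail
        out[i] <- need
        need <- 0
        break
      }
      x <- stats::rhyper(1, counts[i], remaining, need)
      out[i] <- x
      need <- need - x
    }
    names(out) <- nm
    out
  }
  with_seed(seed, replicate(n_iterations, draw_one(), simplify = FALSE))
}

#' Observed richness (number of taxa detected)
#'
#' @param counts non-negative integer count vector with positive total.
#' @return number of taxa with count > 0.
#' @export
observed_richness <- function(counts) {
  counts <- check_counts(counts)
  sum(counts > 0)
}

#' Chao richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` or the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1`/`F2` are the singleton and
#' doubleton counts. The classic form substitutes `F1 (F1 - 1) / 2` when no
#' doubletons are present.
#'
#' @inheritParams observed_richness
#' @param bias_corrected use the bias-corrected form (default, the mothur
#'   convention).
#' @return estimated richness, always >= observed richness.
#' @export
chao_estimate <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' ACE (abundance-based coverage) richness estimator
#'
#' Splits taxa into rare (`count <= rare_threshold`) and abundant groups and
#' estimates unseen richness from the rare group's sample coverage:
#' `S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2` with
#' `C_ace = 1 - F1 / N_rare` and the squared coefficient of variation
#' `gamma^2` truncated at zero. When all rare taxa are singletons the coverage
#' is zero and the bias-corrected Chao estimate is returned instead.
#'
#' @inheritParams observed_richness
#' @param rare_threshold maximum count for the rare group (default 10).
#' @return estimated richness.
#' @export
ace_estimate <- function(counts, rare_threshold = 10) {
  counts <- check_counts(counts)
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao_estimate(counts, bias_corrected = TRUE))
  fi <- tabulate(rare, nbins = rare_threshold)
  i <- seq_len(rare_threshold)
  gamma2 <- max(s_rare * sum(i * (i - 1) * fi) /
                  (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` with `p_i = n_i / N`; natural log by default
#' (mothur convention), zero-count taxa skipped.
#'
#' @inheritParams observed_richness
#' @param base logarithm base.
#' @return Shannon index (nats for the default base).
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Inverse Simpson index
#'
#' Naive form `1 / sum(p_i^2)` (the Hill number of order 2), or the unbiased
#' finite-sample form `N (N - 1) / sum(n_i (n_i - 1))` (mothur's
#' `invsimpson`, the default).
#'
#' @inheritParams observed_richness
#' @param unbiased use the unbiased estimator.
#' @return inverse Simpson index, >= 1 when defined.
#' @export
inverse_simpson <- function(counts, unbiased = TRUE) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (unbiased) {
    if (n < 2) bld_abort("unbiased inverse Simpson needs N >= 2",
                         "invalid_parameter")
    denom <- sum(counts * (counts - 1))
    if (denom == 0) {
      bld_abort("all taxa are singletons: unbiased inverse Simpson undefined",
                "estimator_undefined")
    }
    n * (n - 1) / denom
  } else {
    p <- counts / n
    1 / sum(p^2)
  }
}

# the five per-sample indices on a single (already rarefied) vector
alpha_indices_one <- function(counts) {
  c(n_genus = observed_richness(counts),
    ace = ace_estimate(counts),
    chao = chao_estimate(counts),
    shannon = shannon_index(counts),
    inverse_simpson = inverse_simpson(counts, unbiased = TRUE))
}

#' Per-sample alpha diversity table with rarefaction
#'
#' Rarefies every sample of a samples-by-taxa count matrix to a common depth
#' and reports the five standard indices (observed genera, ACE, Chao, Shannon,
#' inverse Simpson), averaged over rarefaction iterations. Samples whose total
#' falls below the depth are dropped with a warning, mirroring the exclusion
#' of under-sequenced samples.
#'
#' @param table numeric matrix, samples in rows, taxa in columns, with sample
#'   ids as row names.
#' @param depth rarefaction depth, or `"auto"` to use the smallest sample
#'   total.
#' @param n_iterations rarefaction iterations to average over (default 100;
#'   use 1 for a single-subsample analysis).
#' @param seed optional integer seed for reproducible subsampling.
#' @return data frame with one row per retained sample: `sample_id`,
#'   `n_genus`, `ace`, `chao`, `shannon`, `inverse_simpson`,
#'   `rarefaction_depth`, `n_iterations`.
#' @export
alpha_diversity <- function(table, depth = "auto", n_iterations = 100,
                            seed = NULL) {
  table <- as.matrix(table)
  if (is.null(rownames(table))) {
    bld_abort("count table must have sample ids as row names",
              "invalid_parameter")
  }
  totals <- rowSums(table)
  if (identical(depth, "auto")) depth <- min(totals)
  keep <- totals >= depth
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) below rarefaction depth %s: %s",
                    sum(!keep), depth,
                    paste(rownames(table)[!keep], collapse = ", ")))
  }
  table <- table[keep, , drop = FALSE]
  if (nrow(table) == 0) bld_abort("no samples at or above depth",
                                  "insufficient_depth")
  with_seed(seed, {
    rows <- lapply(rownames(table), function(s) {
      draws <- rarefy(table[s, ], depth = depth, n_iterations = n_iterations)
      vals <- rowMeans(vapply(draws, alpha_indices_one, numeric(5)))
      data.frame(sample_id = s, t(vals), rarefaction_depth = depth,
                 n_iterations = n_iterations, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
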