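# End-to-end orchestration: simulate -> classify -> alpha diversity ->
# encounter deltas + GEE -> beta diversity + PCoA + PERMANOVA ->
# differential abundance, with a JSON manifest for reproduction.

#' Run the full exposure-diversity pipeline on a synthetic cohort
#'
#' Generates (or accepts) a synthetic cohort, classifies every antibiotic
#' course as therapeutic or subtherapeutic from its dosing, plasma samples and
#' cultures, computes rarefied alpha diversity per sample, builds paired
#' encounter deltas and compares them between exposure groups with a
#' cluster-robust GEE, computes Bray-Curtis/Jaccard (log counts) and
#' Morisita-Horn dissimilarities with PCoA and PERMANOVA over exposure group
#' and encounter, and runs the permutation differential-abundance test on
#' baseline samples. All randomness derives from `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed recorded in the manifest.
#' @param cohort optionally, an existing `cf_cohort` (then `config` is
#'   ignored).
#' @param out_dir optional directory; when given, every artifact is written
#'   (TSVs + JSON manifest).
#' @param rarefaction_iterations rarefaction iterations per sample.
#' @param n_permutations permutations for PERMANOVA and differential
#'   abundance.
#' @param use_map classify from MAP-estimated PK (TRUE) or true PK.
#' @param excluded_samples sample ids excluded by the sensitivity filter.
#' @return object of class `pipeline_result`: list with `cohort`,
#'   `classification`, `per_drug`, `alpha`, `deltas`, `delta_comparisons`,
#'   `beta` (per metric: `dist`, `pcoa`, `permanova_group`,
#'   `permanova_encounter`), `differential_abundance`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, cohort = NULL,
                         out_dir = NULL, rarefaction_iterations = 100,
                         n_permutations = 999, use_map = TRUE,
                         excluded_samples = character()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bld_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "stage_failure")
    })
  }
  if (is.null(cohort)) {
    cohort <- stage("simulate", generate_cohort(config, seed = seed))
  }
  config <- cohort$config
  cls <- stage("classify", classify_cohort(cohort, use_map = use_map))
  alpha <- stage("alpha", alpha_diversity(cohort$counts, depth = "auto",
                                          n_iterations = rarefaction_iterations,
                                          seed = seed + 1L))
  deltas <- stage("pair", pair_encounters(cohort$metadata, alpha,
                                          indices = c("n_genus", "ace", "chao",
                                                      "shannon",
                                                      "inverse_simpson"),
                                          excluded_samples = excluded_samples))
  comparisons <- stage("compare",
                       compare_group_deltas(deltas, cls$classification))
  # sample-level labels for ordination and PERMANOVA
  md <- cohort$metadata[!is.na(cohort$metadata$sample_id), ]
  md <- md[!(md$sample_id %in% excluded_samples), ]
  counts <- cohort$counts[md$sample_id, , drop = FALSE]
  beta <- stage("beta", {
    lapply(stats::setNames(c("bray", "jaccard", "morisita_horn"),
                           c("bray", "jaccard", "morisita_horn")),
           function(metric) {
             d <- beta_dissimilarity(counts, metric = metric)
             list(dist = d,
                  pcoa = pcoa_ordination(d),
                  permanova_group = permanova(
                    d, md$group, n_permutations = n_permutations,
                    seed = seed + 2L),
                  permanova_encounter = permanova(
                    d, md$encounter, n_permutations = n_permutations,
                    seed = seed + 3L))
           })
  })
  da <- stage("differential_abundance", {
    base_md <- md[md$encounter == "B", ]
    if (length(unique(base_md$group)) == 2 &&
        all(table(base_md$group) >= 2)) {
      differential_abundance(counts[base_md$sample_id, , drop = FALSE],
                             factor(base_md$group,
                                    levels = c("therapeutic",
                                               "subtherapeutic")),
                             n_permutations = n_permutations,
                             seed = seed + 4L)
    } else {
      NULL
    }
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("betalactamdiv")),
    seed = seed,
    derived_seeds = list(alpha = seed + 1L, permanova_group = seed + 2L,
                         permanova_encounter = seed + 3L,
                         differential_abundance = seed + 4L),
    rarefaction_iterations = rarefaction_iterations,
    rarefaction_depth = alpha$rarefaction_depth[1],
    n_permutations = n_permutations,
    use_map = use_map,
    excluded_samples = excluded_samples,
    n_courses = nrow(cls$classification),
    fraction_therapeutic =
      mean(cls$classification$category == "therapeutic"),
    config = unclass(config))
  result <- structure(list(cohort = cohort, classification = cls$classification,
                           per_drug = cls$per_drug, alpha = alpha,
                           deltas = deltas, delta_comparisons = comparisons,
                           beta = beta, differential_abundance = da,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write every pipeline artifact to a directory
#'
#' Emits the classification table, per-drug exposure table, per-sample alpha
#' indices, encounter deltas, delta comparisons, distance matrices, PCoA
#' coordinates, PERMANOVA summaries, the differential-abundance table, the
#' count and metadata tables, and a JSON manifest.
#'
#' @param result a `pipeline_result`.
#' @param out_dir destination directory (created if needed).
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(result$classification, p("classification.tsv"))
  write_tsv(result$per_drug, p("exposure_per_drug.tsv"))
  write_tsv(result$alpha, p("alpha_diversity.tsv"))
  write_tsv(result$deltas, p("encounter_deltas.tsv"))
  write_tsv(result$delta_comparisons, p("delta_comparisons.tsv"))
  write_count_table(result$cohort$counts, p("counts.tsv"))
  write_tsv(result$cohort$metadata, p("metadata.tsv"))
  perm_rows <- list()
  for (metric in names(result$beta)) {
    b <- result$beta[[metric]]
    dm <- as.matrix(b$dist)
    write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
              p(sprintf("distance_%s.tsv", metric)))
    co <- b$pcoa$coordinates
    write_tsv(data.frame(sample_id = rownames(co), co, check.names = FALSE),
              p(sprintf("pcoa_%s.tsv", metric)))
    for (fac in c("group", "encounter")) {
      pr <- b[[paste0("permanova_", fac)]]
      perm_rows[[length(perm_rows) + 1]] <- data.frame(
        metric = metric, factor = fac, pseudo_F = pr$pseudo_F, R2 = pr$R2,
        p_value = pr$p_value, n_permutations = pr$n_permutations)
    }
  }
  write_tsv(do.call(rbind, perm_rows), p("permanova.tsv"))
  if (!is.null(result$differential_abundance)) {
    write_tsv(result$differential_abundance,
              p("differential_abundance_baseline.tsv"))
  }
  jsonlite::write_json(result$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Exposure-diversity pipeline (seed %d)\n", x$manifest$seed))
  cat(sprintf(" courses: %d (%.0f%% therapeutic)\n", x$manifest$n_courses,
              100 * x$manifest$fraction_therapeutic))
  cat(sprintf(" samples analyzed: %d (rarefied to %d reads, %d iterations)\n",
              nrow(x$alpha), as.integer(x$manifest$rarefaction_depth),
              x$manifest$rarefaction_iterations))
  bt <- x$delta_comparisons[x$delta_comparisons$pair == "B-T" &
                              x$delta_comparisons$index_name == "shannon", ]
  if (nrow(bt) == 1) {
    cat(sprintf(
      " B-T Shannon delta: therapeutic %.2f vs subtherapeutic %.2f (GEE p = %.3g)\n",
      bt$mean_therapeutic, bt$mean_subtherapeutic, bt$p_value))
  }
  pg <- x$beta$bray$permanova_group
  cat(sprintf(" PERMANOVA (Bray, group): pseudo-F = %.2f, p = %.3g\n",
              pg$pseudo_F, pg$p_value))
  invisible(x)
}
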