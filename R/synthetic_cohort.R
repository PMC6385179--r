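# Synthetic study-cohort generator: patients with repeated exacerbations,
# intermittent IV beta-lactam regimens with lognormal population PK, sparse
# noisy plasma sampling, culture panels with MICs (including normal-flora-only
# and MRSA cases), and four-encounter Dirichlet-multinomial count tables with
# programmed group-by-encounter diversity dynamics.

default_drug_menu <- function() {
  list(
    list(drug_name = "ceftazidime", drug_class = "cephalosporin",
         dose = 2000, infusion_duration = 0.5, interval_tau = 8, weight = 0.50),
    list(drug_name = "meropenem", drug_class = "carbapenem",
         dose = 1000, infusion_duration = 0.5, interval_tau = 8, weight = 0.30),
    list(drug_name = "piperacillin-tazobactam", drug_class = "penicillin",
         dose = 4000, infusion_duration = 0.5, interval_tau = 6, weight = 0.20)
  )
}

default_taxa <- function(n_taxa) {
  core <- c("Streptococcus", "Prevotella", "Veillonella", "Pseudomonas",
            "Haemophilus", "Rothia", "Gemella", "Neisseria", "Staphylococcus",
            "Fusobacterium", "Enterobacteriaceae_unclassified",
            "Porphyromonas", "Granulicatella", "Actinomyces", "Leptotrichia",
            "Capnocytophaga", "Oribacterium", "Atopobium", "Campylobacter",
            "Selenomonas")
  if (n_taxa <= length(core)) return(core[seq_len(n_taxa)])
  c(core, sprintf("Genus_%02d", seq_len(n_taxa - length(core))))
}

#' Configuration of the synthetic cohort
#'
#' Bundles every knob of the generator with defaults that emulate a small
#' pediatric CF cohort followed over four encounters (baseline B, exacerbation
#' onset E, end of treatment T, post-recovery R): about twenty patients with a
#' skewed number of repeat exacerbations, intermittent IV beta-lactam regimens
#' drawn from a three-drug menu, CF-range lognormal population PK, a log2 MIC
#' grid, sparse noisy plasma sampling, and a Dirichlet-multinomial community
#' model whose concentration (evenness) and focal-taxon dominance parameters
#' differ by exposure group and encounter. The therapeutic group is programmed
#' with a diversity drop at end of treatment and partial non-recovery; the
#' subtherapeutic group starts lower (with an Enterobacteriaceae-like dominant
#' taxon) and stays flat to slightly increasing.
#'
#' @param n_patients number of patients.
#' @param exacerbation_probs named probabilities of the per-patient number of
#'   exacerbations (names are the counts).
#' @param fraction_therapeutic target fraction of courses engineered to meet
#'   their pharmacodynamic target.
#' @param drug_menu list of regimen templates (name, class, dose mg, infusion
#'   duration h, interval h, sampling weight).
#' @param n_beta_lactam_probs named probabilities for the number of
#'   beta-lactams per course.
#' @param pk_population lognormal population means/SDs for clearance (L/h) and
#'   volume (L).
#' @param residual_sd residual concentration error SD (mg/L) used both to
#'   perturb observations and as the MAP prior's error model.
#' @param mic_grid permissible MIC values (mg/L), a log2 grid by default.
#' @param target_margin minimum distance of the engineered fT>MIC from the
#'   class target, so classifications are not razor-edge.
#' @param culture probabilities of the culture panel composition (normal flora
#'   only, dominant organism, MRSA, measured MSSA MIC, anti-MRSA therapy).
#' @param literature_mssa_mic named literature MICs (mg/L) for MSSA per drug.
#' @param pa_fallback_mic named fallback MICs used as the cohort median when
#'   no patient grew *P. aeruginosa*.
#' @param obs sparse plasma sampling design: samples per drug, times as
#'   fractions of the dosing interval, lognormal noise SD.
#' @param missingness probability that an encounter's respiratory sample is
#'   missing (not collected or failed sequencing).
#' @param sample_type_probs probabilities of sputum / OP swab / BAL per
#'   patient.
#' @param community Dirichlet-multinomial community model: number of taxa,
#'   geometric base-composition decay, per-patient lognormal perturbation SD,
#'   focal taxa, per group-by-encounter concentration `theta` and focal-taxon
#'   `boost`, and the sequencing-depth lognormal (with a hard minimum).
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 20,
                          exacerbation_probs = c(`1` = 13, `2` = 5, `3` = 1,
                                                 `5` = 1) / 20,
                          fraction_therapeutic = 0.45,
                          drug_menu = default_drug_menu(),
                          n_beta_lactam_probs = c(`1` = 25, `2` = 5, `3` = 1) / 31,
                          pk_population = list(mean_log_clearance = log(9),
                                               sd_log_clearance = 0.30,
                                               mean_log_volume = log(18),
                                               sd_log_volume = 0.25),
                          residual_sd = 1,
                          mic_grid = 2^seq(-2, 6),
                          target_margin = 0.02,
                          culture = list(p_normal_flora_only = 0.25,
                                         p_pseudomonas = 0.35,
                                         p_staph = 0.40,
                                         p_mrsa_given_staph = 0.45,
                                         p_mssa_mic_measured = 0.5,
                                         p_anti_mrsa = 0.6),
                          literature_mssa_mic = c(ceftazidime = 8,
                                                  meropenem = 0.25,
                                                  `piperacillin-tazobactam` = 2),
                          pa_fallback_mic = c(ceftazidime = 8, meropenem = 1,
                                              `piperacillin-tazobactam` = 8),
                          obs = list(n_per_drug = 3,
                                     times_frac = c(0.2, 0.5, 0.85),
                                     noise_sd = 0.10),
                          missingness = 0.08,
                          sample_type_probs = c(sputum = 0.55, op_swab = 0.40,
                                                bal = 0.05),
                          community = list(
                            n_taxa = 40,
                            base_decay = 0.82,
                            patient_sd = 0.40,
                            focal_therapeutic = "Pseudomonas",
                            focal_subtherapeutic = "Enterobacteriaceae_unclassified",
                            theta = list(
                              therapeutic = c(B = 40, E = 40, T = 14.5, R = 22),
                              subtherapeutic = c(B = 20, E = 20, T = 23, R = 21)),
                            boost = list(
                              therapeutic = c(B = 1, E = 1, T = 6.75, R = 3),
                              subtherapeutic = c(B = 25, E = 25, T = 16, R = 22)),
                            depth_meanlog = log(8000),
                            depth_sdlog = 0.40,
                            depth_min = 2239)) {
  if (!is_number(n_patients) || n_patients < 1) {
    bld_abort("n_patients must be >= 1", "validation")
  }
  for (pr in list(exacerbation_probs, n_beta_lactam_probs)) {
    if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
      bld_abort("probability vectors must be non-negative and sum to 1",
                "validation")
    }
  }
  if (fraction_therapeutic < 0 || fraction_therapeutic > 1) {
    bld_abort("fraction_therapeutic must lie in [0, 1]", "validation")
  }
  if (any(mic_grid <= 0)) bld_abort("MICs must be positive", "validation")
  structure(list(n_patients = n_patients,
                 exacerbation_probs = exacerbation_probs,
                 fraction_therapeutic = fraction_therapeutic,
                 drug_menu = drug_menu,
                 n_beta_lactam_probs = n_beta_lactam_probs,
                 pk_population = pk_population,
                 residual_sd = residual_sd,
                 mic_grid = mic_grid,
                 target_margin = target_margin,
                 culture = culture,
                 literature_mssa_mic = literature_mssa_mic,
                 pa_fallback_mic = pa_fallback_mic,
                 obs = obs,
                 missingness = missingness,
                 sample_type_probs = sample_type_probs,
                 community = community),
            class = "cohort_config")
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate noisy steady-state plasma concentration observations
#'
#' Evaluates the true steady-state profile at the requested times and applies
#' multiplicative lognormal noise.
#'
#' @param regimen a [drug_regimen()].
#' @param true_pk the true [pk_parameters()].
#' @param sampling_times times (h) after the start of a steady-state dose;
#'   must lie within one dosing interval.
#' @param noise_sd_fraction SD of the lognormal noise on the log scale
#'   (approximately the coefficient of variation); 0 returns the exact curve.
#' @param seed optional integer seed.
#' @return data frame with columns `time` and `concentration`.
#' @export
generate_observed_concentrations <- function(regimen, true_pk, sampling_times,
                                             noise_sd_fraction = 0.1,
                                             seed = NULL) {
  if (!is_number(noise_sd_fraction) || noise_sd_fraction < 0) {
    bld_abort("noise_sd_fraction must be >= 0", "validation")
  }
  if (any(sampling_times < 0) || any(sampling_times > regimen$interval_tau)) {
    bld_abort("sampling times must lie within the dosing interval",
              "validation")
  }
  truth <- conc_steady_state(sampling_times, regimen, true_pk)
  conc <- with_seed(seed, {
    truth * exp(stats::rnorm(length(truth), 0, noise_sd_fraction))
  })
  data.frame(time = sampling_times, concentration = conc)
}

# Engineer the MIC assigned to a course's dominant isolate so that the
# intended exposure category is feasible under the true PK. MIC values are
# drawn from a lognormal weighting over the log2 grid (mode a few mg/L, the
# usual clinical range) restricted to the feasible set, so that engineered
# cohorts keep a realistic MIC distribution and a realistic cohort median.
# Returns a named vector of MICs per drug.
engineer_mics <- function(regimens, pks, intended_therapeutic, config) {
  grid <- config$mic_grid
  margin <- config$target_margin
  wts <- stats::dlnorm(grid, meanlog = log(2), sdlog = 1.4)
  pick_mic <- function(values) {
    if (length(values) == 1) return(values)
    w <- wts[match(values, grid)]
    values[sample.int(length(values), 1, prob = w)]
  }
  mics <- stats::setNames(rep(NA_real_, length(regimens)),
                          vapply(regimens, `[[`, character(1), "drug_name"))
  feas <- lapply(seq_along(regimens), function(i) {
    f <- vapply(grid, function(m) {
      fraction_time_above_mic(regimens[[i]], pks[[i]], m)
    }, numeric(1))
    tgt <- pd_target(regimens[[i]]$drug_class)
    list(ok = grid[f >= tgt + margin], fail = grid[f <= tgt - margin])
  })
  if (intended_therapeutic) {
    achiever <- which(vapply(feas, function(z) length(z$ok) > 0, logical(1)))
    if (length(achiever) == 0) intended_therapeutic <- FALSE
  }
  for (i in seq_along(regimens)) {
    z <- feas[[i]]
    if (intended_therapeutic && i == min(achiever)) {
      mics[i] <- pick_mic(z$ok)
    } else if (length(z$fail) > 0) {
      mics[i] <- pick_mic(z$fail)
    } else {
      mics[i] <- max(grid)
    }
  }
  mics
}

#' Generate a complete synthetic cohort
#'
#' Draws patients, exacerbations, dosing courses with true PK, engineered
#' culture/MIC panels, sparse noisy plasma observations, four-encounter sample
#' metadata (with missingness and recovery-baseline chaining) and the
#' Dirichlet-multinomial count table. The stored truth (true PK, true fT>MIC,
#' true exposure category) is internally consistent: re-running the
#' classification rules on the noise-free inputs reproduces it.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param include_counts also simulate the count table (default TRUE).
#' @return object of class `cf_cohort`: list with `metadata` (sample table),
#'   `counts` (samples x taxa), `courses` (per-exacerbation dosing, cultures,
#'   observations and truth), `cohort_median_pa_mic`, `truth` (per-sample
#'   community parameters and per-course categories) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            include_counts = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    menu <- config$drug_menu
    menu_w <- vapply(menu, `[[`, numeric(1), "weight")
    pk_pop <- config$pk_population
    cul <- config$culture
    patients <- sprintf("P%02d", seq_len(config$n_patients))
    n_exac <- sample(as.integer(names(config$exacerbation_probs)),
                     config$n_patients, replace = TRUE,
                     prob = config$exacerbation_probs)
    courses <- list()
    for (ip in seq_along(patients)) {
      for (k in seq_len(n_exac[ip])) {
        pid <- patients[ip]
        intended <- stats::runif(1) < config$fraction_therapeutic
        n_bl <- min(sample(as.integer(names(config$n_beta_lactam_probs)), 1,
                           prob = config$n_beta_lactam_probs), length(menu))
        picks <- sample(seq_along(menu), n_bl, prob = menu_w)
        regimens <- lapply(menu[picks], function(m) {
          drug_regimen(m$drug_name, m$drug_class, m$dose, m$infusion_duration,
                       m$interval_tau)
        })
        draw_pks <- function() {
          lapply(regimens, function(r) {
            pk_parameters(stats::rlnorm(1, pk_pop$mean_log_clearance,
                                        pk_pop$sd_log_clearance),
                          stats::rlnorm(1, pk_pop$mean_log_volume,
                                        pk_pop$sd_log_volume))
          })
        }
        pks <- draw_pks()
        # culture panel
        flora_only <- stats::runif(1) < cul$p_normal_flora_only
        mrsa <- FALSE
        isolates <- list()
        mics <- NULL
        fallback_mics <- NULL    # set when the MIC comes from a fallback rule
        if (flora_only) {
          isolates <- list(culture_isolate("normal respiratory flora",
                                           is_normal_flora_only = TRUE))
          fallback_mics <- config$pa_fallback_mic
        } else {
          pick <- sample(c("pa", "sa", "other"), 1,
                         prob = c(cul$p_pseudomonas, cul$p_staph,
                                  1 - cul$p_pseudomonas - cul$p_staph))
          if (pick == "sa") {
            mrsa <- stats::runif(1) < cul$p_mrsa_given_staph
          }
          measured <- pick != "sa" || mrsa ||
            stats::runif(1) < cul$p_mssa_mic_measured
          if (measured) {
            mics <- engineer_mics(regimens, pks, intended, config)
          } else {
            fallback_mics <- config$literature_mssa_mic
          }
          isolates <- switch(pick,
            pa = list(culture_isolate("Pseudomonas aeruginosa",
                                      mic_by_drug = mics)),
            sa = list(culture_isolate(
              "Staphylococcus aureus",
              methicillin_status = if (mrsa) "mrsa" else "mssa",
              mic_by_drug = if (measured) mics else numeric())),
            other = list(culture_isolate("Achromobacter xylosoxidans",
                                         mic_by_drug = mics)))
        }
        anti_mrsa <- mrsa && stats::runif(1) < cul$p_anti_mrsa
        courses[[length(courses) + 1]] <- list(
          patient_id = pid, exacerbation_number = k,
          exacerbation_id = sprintf("%s_ex%d", pid, k),
          regimens = regimens, true_pk = pks,
          isolates = isolates, intended_therapeutic = intended,
          uses_fallback_mic = !is.null(fallback_mics),
          mrsa_grown = mrsa, anti_mrsa_given = anti_mrsa)
      }
    }
    # cohort median P. aeruginosa MIC per drug (the normal-flora fallback)
    drug_names <- vapply(menu, `[[`, character(1), "drug_name")
    med_pa <- config$pa_fallback_mic[drug_names]
    names(med_pa) <- drug_names
    for (dn in drug_names) {
      vals <- unlist(lapply(courses, function(co) {
        pa <- vapply(co$isolates, function(iso) {
          !iso$is_normal_flora_only && grepl("Pseudomonas", iso$organism)
        }, logical(1))
        unlist(lapply(co$isolates[pa], function(iso) {
          unname(iso$mic_by_drug[dn])
        }))
      }))
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) med_pa[dn] <- stats::median(vals)
    }
    # Courses whose MIC comes from a fallback rule (normal flora -> cohort
    # median, unmeasured MSSA -> literature value) cannot be steered through
    # the MIC, so honor the intended category through the PK draw instead
    # (truncated rejection sampling against the same MIC the rules will use).
    for (i in seq_along(courses)) {
      co <- courses[[i]]
      if (!co$uses_fallback_mic) next
      flora <- co$isolates[[1]]$is_normal_flora_only
      ref_mic <- if (flora) med_pa else config$literature_mssa_mic
      course_met <- function(pk_list) {
        any(vapply(seq_along(co$regimens), function(j) {
          reg <- co$regimens[[j]]
          fraction_time_above_mic(reg, pk_list[[j]],
                                  ref_mic[[reg$drug_name]]) >=
            pd_target(reg$drug_class)
        }, logical(1)))
      }
      pks <- co$true_pk
      for (try in seq_len(50)) {
        if (course_met(pks) == co$intended_therapeutic) break
        pks <- lapply(co$regimens, function(r) {
          pk_parameters(stats::rlnorm(1, pk_pop$mean_log_clearance,
                                      pk_pop$sd_log_clearance),
                        stats::rlnorm(1, pk_pop$mean_log_volume,
                                      pk_pop$sd_log_volume))
        })
      }
      courses[[i]]$true_pk <- pks
    }
    # sparse plasma sampling from the final true PK
    for (i in seq_along(courses)) {
      co <- courses[[i]]
      observations <- lapply(seq_along(co$regimens), function(j) {
        generate_observed_concentrations(
          co$regimens[[j]], co$true_pk[[j]],
          sampling_times = config$obs$times_frac *
            co$regimens[[j]]$interval_tau,
          noise_sd_fraction = config$obs$noise_sd)
      })
      names(observations) <- vapply(co$regimens, `[[`, character(1),
                                    "drug_name")
      courses[[i]]$observations <- observations
    }
    # true classification from the rules + true PK
    for (i in seq_along(courses)) {
      co <- courses[[i]]
      assessments <- do.call(rbind, lapply(seq_along(co$regimens), function(j) {
        reg <- co$regimens[[j]]
        sel <- select_mic(co$isolates, reg$drug_name,
                          cohort_median_pa_mic = med_pa[[reg$drug_name]],
                          literature_mssa_mic =
                            config$literature_mssa_mic[[reg$drug_name]])
        assess_exposure(reg, co$true_pk[[j]], sel$mic, sel$mic_source)
      }))
      cls <- classify_course(co$exacerbation_id, assessments,
                             mrsa_grown = co$mrsa_grown,
                             anti_mrsa_given = co$anti_mrsa_given)
      courses[[i]]$true_assessments <- assessments
      courses[[i]]$true_category <- cls$category
    }
    # encounter/sample metadata; later exacerbations have no separate baseline
    # (the prior post-recovery sample fills that role)
    meta <- list()
    sample_counter <- 0
    sample_type_by_patient <- stats::setNames(
      sample(names(config$sample_type_probs), config$n_patients,
             replace = TRUE, prob = config$sample_type_probs), patients)
    for (co in courses) {
      encs <- if (co$exacerbation_number == 1) c("B", "E", "T", "R")
              else c("E", "T", "R")
      for (e in encs) {
        missing <- stats::runif(1) < config$missingness
        sid <- if (missing) NA_character_ else {
          sample_counter <- sample_counter + 1
          sprintf("S%03d", sample_counter)
        }
        meta[[length(meta) + 1]] <- data.frame(
          sample_id = sid, patient_id = co$patient_id,
          exacerbation_number = co$exacerbation_number, encounter = e,
          sample_type = sample_type_by_patient[[co$patient_id]],
          group = co$true_category, stringsAsFactors = FALSE)
      }
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    truth <- list(
      categories = data.frame(
        patient_id = vapply(courses, `[[`, character(1), "patient_id"),
        exacerbation_number = vapply(courses, `[[`, numeric(1),
                                     "exacerbation_number"),
        category = vapply(courses, `[[`, character(1), "true_category"),
        stringsAsFactors = FALSE),
      cohort_median_pa_mic = med_pa)
    cohort <- structure(list(metadata = metadata, counts = NULL,
                             courses = courses,
                             cohort_median_pa_mic = med_pa, truth = truth,
                             config = config, seed = seed),
                        class = "cf_cohort")
    if (include_counts) cohort$counts <- generate_otu_timeline(cohort)
    cohort
  })
}

#' Simulate the four-encounter count table of a cohort
#'
#' Per sample, the community composition is drawn from a Dirichlet
#' distribution whose mean is a geometric base composition (perturbed once per
#' patient) with the group-specific focal taxon multiplied by the
#' group-by-encounter dominance boost, and whose concentration parameter is
#' the group-by-encounter `theta` (lower theta and higher boost both lower the
#' expected diversity). Counts are multinomial at a lognormal sequencing depth
#' with a hard minimum. Called by [generate_cohort()]; exposed so that
#' alternative community settings can be re-simulated on a fixed cohort
#' design. Uses the current RNG stream.
#'
#' @param cohort a `cf_cohort` (metadata and truth must be present).
#' @return samples-by-taxa integer matrix with sample ids as row names.
#' @export
generate_otu_timeline <- function(cohort) {
  config <- cohort$config
  cm <- config$community
  taxa <- default_taxa(cm$n_taxa)
  base <- cm$base_decay^(seq_len(cm$n_taxa) - 1)
  base <- base / sum(base)
  patients <- unique(cohort$metadata$patient_id)
  perturb <- lapply(stats::setNames(patients, patients), function(p) {
    exp(stats::rnorm(cm$n_taxa, 0, cm$patient_sd))
  })
  focal <- c(therapeutic = match(cm$focal_therapeutic, taxa),
             subtherapeutic = match(cm$focal_subtherapeutic, taxa))
  if (any(is.na(focal))) bld_abort("focal taxa must be among the taxa names",
                                   "validation")
  md <- cohort$metadata[!is.na(cohort$metadata$sample_id), ]
  counts <- matrix(0L, nrow(md), cm$n_taxa,
                   dimnames = list(md$sample_id, taxa))
  for (i in seq_len(nrow(md))) {
    grp <- md$group[i]
    enc <- md$encounter[i]
    w <- base * perturb[[md$patient_id[i]]]
    w[focal[[grp]]] <- w[focal[[grp]]] * cm$boost[[grp]][[enc]]
    w <- w / sum(w)
    p <- rdirichlet1(cm$theta[[grp]][[enc]] * w)
    depth <- max(cm$depth_min,
                 round(stats::rlnorm(1, cm$depth_meanlog, cm$depth_sdlog)))
    counts[i, ] <- stats::rmultinom(1, depth, p)[, 1]
  }
  counts
}

#' Classify every course of a cohort from its generated inputs
#'
#' Runs the full exposure workflow on a cohort's dosing, plasma observations
#' and culture panels: per drug, clearance and volume are estimated by
#' [map_estimate_pk()] (population prior from the cohort configuration) or
#' taken as the stored truth, the MIC is selected by the highest-MIC /
#' normal-flora / MSSA rules, fT>MIC is computed and the course classified.
#'
#' @param cohort a `cf_cohort`.
#' @param use_map estimate PK from the plasma observations (TRUE, default) or
#'   use the stored true parameters.
#' @return list with `classification` (one row per course: category, drugs,
#'   MRSA flags) and `per_drug` (per drug: MIC used and its source, fT>MIC,
#'   target, target_met).
#' @export
classify_cohort <- function(cohort, use_map = TRUE) {
  stopifnot(inherits(cohort, "cf_cohort"))
  config <- cohort$config
  prior <- pk_prior(config$pk_population$mean_log_clearance,
                    config$pk_population$sd_log_clearance,
                    config$pk_population$mean_log_volume,
                    config$pk_population$sd_log_volume,
                    config$residual_sd)
  med_pa <- cohort$cohort_median_pa_mic
  rows <- list()
  per_drug <- list()
  for (co in cohort$courses) {
    assessments <- do.call(rbind, lapply(seq_along(co$regimens), function(j) {
      reg <- co$regimens[[j]]
      pk <- if (use_map) {
        map_estimate_pk(co$observations[[j]], reg, prior)
      } else {
        co$true_pk[[j]]
      }
      sel <- select_mic(co$isolates, reg$drug_name,
                        cohort_median_pa_mic = med_pa[[reg$drug_name]],
                        literature_mssa_mic =
                          config$literature_mssa_mic[[reg$drug_name]])
      assess_exposure(reg, pk, sel$mic, sel$mic_source)
    }))
    cls <- classify_course(co$exacerbation_id, assessments,
                           mrsa_grown = co$mrsa_grown,
                           anti_mrsa_given = co$anti_mrsa_given)
    rows[[length(rows) + 1]] <- data.frame(
      exacerbation_id = co$exacerbation_id, patient_id = co$patient_id,
      exacerbation_number = co$exacerbation_number, category = cls$category,
      drugs = paste(assessments$drug_name, collapse = ";"),
      mrsa_grown = co$mrsa_grown, anti_mrsa_given = co$anti_mrsa_given,
      mrsa_rule_applied = cls$mrsa_rule_applied, stringsAsFactors = FALSE)
    per_drug[[length(per_drug) + 1]] <-
      cbind(exacerbation_id = co$exacerbation_id, assessments)
  }
  list(classification = do.call(rbind, rows),
       per_drug = do.call(rbind, per_drug))
}

#' @export
print.cf_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients, %d courses (%d therapeutic), %d samples\n",
    length(unique(x$metadata$patient_id)), length(x$courses),
    sum(x$truth$categories$category == "therapeutic"),
    sum(!is.na(x$metadata$sample_id))))
  invisible(x)
}
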