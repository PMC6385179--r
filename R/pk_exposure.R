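# Beta-lactam exposure: one-compartment intermittent-infusion PK at steady
# state, fraction of the dosing interval above MIC, MAP parameter estimation
# from sparse plasma samples, MIC selection rules and the therapeutic /
# subtherapeutic course classification.

#' Intravenous beta-lactam dosing regimen
#'
#' Describes one intermittently infused drug: dose, infusion duration and
#' dosing interval. Bolus administration is approximated by a short infusion.
#'
#' @param drug_name drug label, e.g. `"ceftazidime"`.
#' @param drug_class one of `"carbapenem"`, `"penicillin"`, `"cephalosporin"`;
#'   determines the pharmacodynamic fT>MIC target.
#' @param dose dose per administration (mg), > 0.
#' @param infusion_duration infusion length (h), in `(0, interval_tau]`.
#' @param interval_tau dosing interval (h), > 0.
#' @return an object of class `drug_regimen`.
#' @examples
#' drug_regimen("ceftazidime", "cephalosporin", dose = 2000,
#'              infusion_duration = 0.5, interval_tau = 8)
#' @export
drug_regimen <- function(drug_name, drug_class, dose, infusion_duration,
                         interval_tau) {
  drug_class <- match.arg(drug_class,
                          c("carbapenem", "penicillin", "cephalosporin"))
  check_positive(dose, "dose")
  check_positive(infusion_duration, "infusion_duration")
  check_positive(interval_tau, "interval_tau")
  if (infusion_duration > interval_tau) {
    bld_abort("infusion_duration must not exceed interval_tau",
              "invalid_parameter")
  }
  structure(list(drug_name = as.character(drug_name), drug_class = drug_class,
                 dose = dose, infusion_duration = infusion_duration,
                 interval_tau = interval_tau),
            class = "drug_regimen")
}

#' One-compartment pharmacokinetic parameters
#'
#' @param clearance drug clearance (L/h), > 0.
#' @param volume volume of distribution (L), > 0.
#' @return object of class `pk_parameters` with derived elimination rate
#'   constant `k_elim = clearance / volume` (1/h).
#' @export
pk_parameters <- function(clearance, volume) {
  check_positive(clearance, "clearance")
  check_positive(volume, "volume")
  structure(list(clearance = clearance, volume = volume,
                 k_elim = clearance / volume),
            class = "pk_parameters")
}

#' Lognormal population prior for MAP estimation
#'
#' Population prior over clearance and volume (lognormal in each) together
#' with the residual (assay + model) error standard deviation used in the
#' Gaussian observation likelihood.
#'
#' @param mean_log_clearance,sd_log_clearance mean and sd of log clearance.
#' @param mean_log_volume,sd_log_volume mean and sd of log volume.
#' @param residual_sd residual concentration error sd (mg/L), > 0.
#' @return object of class `pk_prior`.
#' @export
pk_prior <- function(mean_log_clearance, sd_log_clearance,
                     mean_log_volume, sd_log_volume, residual_sd) {
  for (x in c(sd_log_clearance, sd_log_volume, residual_sd)) {
    check_positive(x, "prior standard deviation")
  }
  if (!is_number(mean_log_clearance) || !is_number(mean_log_volume)) {
    bld_abort("prior means must be finite numbers", "invalid_parameter")
  }
  structure(list(mean_log_clearance = mean_log_clearance,
                 sd_log_clearance = sd_log_clearance,
                 mean_log_volume = mean_log_volume,
                 sd_log_volume = sd_log_volume,
                 residual_sd = residual_sd),
            class = "pk_prior")
}

# Closed-form steady-state concentration of an intermittent infusion in a
# one-compartment model with first-order elimination, by superposition of all
# prior doses (geometric-series accumulation). `t` is time after the start of
# a steady-state dose, recycled modulo tau; vectorized over t.
conc_steady_state <- function(t, regimen, pk) {
  k <- pk$k_elim
  tau <- regimen$interval_tau
  tinf <- regimen$infusion_duration
  r0 <- regimen$dose / tinf
  base <- r0 / (k * pk$volume)
  tm <- t %% tau
  # dose of the current interval
  cur <- base * (1 - exp(-k * pmin(tm, tinf))) * exp(-k * pmax(0, tm - tinf))
  # all earlier doses, fully infused: geometric accumulation
  acc <- exp(-k * tau) / (1 - exp(-k * tau))
  prev <- base * (1 - exp(-k * tinf)) * exp(-k * (tm - tinf)) * acc
  cur + prev
}

#' Steady-state concentration profile over one dosing interval
#'
#' Evaluates the closed-form one-compartment, first-order-elimination
#' superposition solution for an intermittent infusion at steady state, on a
#' regular grid covering one dosing interval. Total (not free) drug
#' concentration is modeled.
#'
#' @param regimen a [drug_regimen()].
#' @param pk a [pk_parameters()] object.
#' @param dt grid step (h); must be positive and no coarser than
#'   `interval_tau / 100`.
#' @return object of class `concentration_profile`: list with `times` (h,
#'   from 0 to `interval_tau`) and `concentrations` (mg/L).
#' @export
steady_state_profile <- function(regimen, pk, dt = regimen$interval_tau / 1000) {
  stopifnot(inherits(regimen, "drug_regimen"))
  if (!inherits(pk, "pk_parameters")) {
    bld_abort("pk must be a pk_parameters object", "invalid_parameter")
  }
  check_positive(dt, "dt")
  if (dt > regimen$interval_tau / 100) {
    bld_abort("dt must be <= interval_tau / 100", "invalid_parameter")
  }
  times <- seq(0, regimen$interval_tau, by = dt)
  if (times[length(times)] < regimen$interval_tau) {
    times <- c(times, regimen$interval_tau)
  }
  structure(list(times = times,
                 concentrations = conc_steady_state(times, regimen, pk),
                 regimen = regimen, pk = pk),
            class = "concentration_profile")
}

#' Fraction of the dosing interval above MIC (fT>MIC)
#'
#' Fraction of one steady-state dosing interval during which the predicted
#' concentration strictly exceeds `mic`. The steady-state profile rises
#' monotonically during the infusion and decays monotonically afterwards, so
#' the crossing times are located by root finding on the closed form.
#'
#' @inheritParams steady_state_profile
#' @param mic minimum inhibitory concentration (mg/L), >= 0.
#' @return fraction in `[0, 1]`.
#' @examples
#' reg <- drug_regimen("ceftazidime", "cephalosporin", 2000, 0.5, 8)
#' fraction_time_above_mic(reg, pk_parameters(10, 20), mic = 8)
#' @export
fraction_time_above_mic <- function(regimen, pk, mic) {
  stopifnot(inherits(regimen, "drug_regimen"))
  if (!inherits(pk, "pk_parameters")) {
    bld_abort("pk must be a pk_parameters object", "invalid_parameter")
  }
  if (!is_number(mic) || mic < 0) {
    bld_abort("mic must be a single non-negative number", "invalid_parameter")
  }
  if (mic == 0) return(1)
  tau <- regimen$interval_tau
  tinf <- regimen$infusion_duration
  cmax <- conc_steady_state(tinf, regimen, pk)
  ctrough <- conc_steady_state(0, regimen, pk)
  if (mic >= cmax) return(0)
  if (mic <= ctrough) return(1)
  f <- function(t) conc_steady_state(t, regimen, pk) - mic
  t_up <- stats::uniroot(f, c(0, tinf), tol = 1e-12)$root
  t_down <- stats::uniroot(f, c(tinf, tau), tol = 1e-12)$root
  (t_down - t_up) / tau
}

#' MAP estimate of clearance and volume from sparse plasma samples
#'
#' Maximum a posteriori estimate of one-compartment clearance and volume,
#' optimized in (log CL, log V) space: Gaussian residual likelihood (sd from
#' the prior's `residual_sd`) around the steady-state profile, plus the
#' lognormal population prior. A quasi-Newton search starts at the prior mode;
#' with no observations the prior mode is returned unchanged.
#'
#' @param observations data frame with columns `time` (h after the start of a
#'   steady-state dose) and `concentration` (mg/L); may have zero rows.
#' @param regimen the [drug_regimen()] under which samples were drawn.
#' @param prior a [pk_prior()].
#' @return a [pk_parameters()] object with attributes `log_posterior_grad`
#'   (gradient norm at the optimum) and `n_obs`.
#' @export
map_estimate_pk <- function(observations, regimen, prior) {
  stopifnot(inherits(regimen, "drug_regimen"), inherits(prior, "pk_prior"))
  if (is.null(observations) || nrow(observations) == 0) {
    est <- pk_parameters(exp(prior$mean_log_clearance),
                         exp(prior$mean_log_volume))
    attr(est, "n_obs") <- 0L
    return(est)
  }
  if (!all(c("time", "concentration") %in% names(observations))) {
    bld_abort("observations need columns 'time' and 'concentration'",
              "invalid_parameter")
  }
  if (any(observations$time < 0) || any(observations$concentration < 0)) {
    bld_abort("observation times and concentrations must be non-negative",
              "invalid_parameter")
  }
  tt <- observations$time
  cc <- observations$concentration
  nlp <- function(theta) {
    pk <- list(clearance = exp(theta[1]), volume = exp(theta[2]),
               k_elim = exp(theta[1] - theta[2]))
    pred <- conc_steady_state(tt, regimen, pk)
    sum((cc - pred)^2) / (2 * prior$residual_sd^2) +
      (theta[1] - prior$mean_log_clearance)^2 / (2 * prior$sd_log_clearance^2) +
      (theta[2] - prior$mean_log_volume)^2 / (2 * prior$sd_log_volume^2)
  }
  start <- c(prior$mean_log_clearance, prior$mean_log_volume)
  fit1 <- stats::optim(start, nlp, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  # restart from the optimum: a converged fit must be a fixed point
  fit <- stats::optim(fit1$par, nlp, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  drift <- max(abs(fit$par - fit1$par) / (1 + abs(fit1$par)))
  if (fit$convergence != 0 || fit1$convergence != 0 || drift > 1e-6) {
    bld_abort(sprintf(
      "MAP estimation failed to converge (codes %d/%d, restart drift %.3g)",
      fit1$convergence, fit$convergence, drift), "estimation_failure")
  }
  est <- pk_parameters(exp(fit$par[1]), exp(fit$par[2]))
  attr(est, "restart_drift") <- drift
  attr(est, "n_obs") <- nrow(observations)
  est
}

#' Culture isolate with susceptibility results
#'
#' @param organism organism label.
#' @param is_normal_flora_only logical; normal respiratory flora carries no
#'   MICs.
#' @param methicillin_status `"na"`, `"mssa"` or `"mrsa"` (for
#'   *S. aureus* isolates).
#' @param mic_by_drug named numeric vector of MICs (mg/L) keyed by drug name;
#'   may be empty.
#' @return object of class `culture_isolate`.
#' @export
culture_isolate <- function(organism, is_normal_flora_only = FALSE,
                            methicillin_status = c("na", "mssa", "mrsa"),
                            mic_by_drug = numeric()) {
  methicillin_status <- match.arg(methicillin_status)
  if (length(mic_by_drug) > 0) {
    if (is.null(names(mic_by_drug)) || any(mic_by_drug <= 0)) {
      bld_abort("mic_by_drug must be a named vector of positive MICs",
                "invalid_parameter")
    }
    if (is_normal_flora_only) {
      bld_abort("normal-flora-only isolates carry no MICs", "invalid_parameter")
    }
  }
  structure(list(organism = as.character(organism),
                 is_normal_flora_only = isTRUE(is_normal_flora_only),
                 methicillin_status = methicillin_status,
                 mic_by_drug = mic_by_drug),
            class = "culture_isolate")
}

#' Select the MIC used for fT>MIC evaluation of one drug
#'
#' The highest MIC measured for the drug across the exacerbation's isolates is
#' used. Two fallbacks mirror standard practice when no isolate-level MIC is
#' available: a culture growing only normal respiratory flora is assigned the
#' cohort median *P. aeruginosa* MIC, and an MSSA isolate without a measured
#' MIC is assigned a literature MIC.
#'
#' @param isolates list of [culture_isolate()] objects.
#' @param drug_name drug to look up.
#' @param cohort_median_pa_mic cohort median *P. aeruginosa* MIC (mg/L) for
#'   this drug, used when only normal flora grew.
#' @param literature_mssa_mic literature MIC (mg/L) for MSSA and this drug.
#' @return list with `mic` (mg/L) and `mic_source` (one of
#'   `"isolate_highest"`, `"cohort_median_pa"`, `"literature_mssa"`).
#' @export
select_mic <- function(isolates, drug_name, cohort_median_pa_mic = NULL,
                       literature_mssa_mic = NULL) {
  if (length(isolates) == 0) bld_abort("no isolates supplied", "missing_mic")
  stopifnot(all(vapply(isolates, inherits, logical(1), "culture_isolate")))
  measured <- unlist(lapply(isolates, function(iso) {
    unname(iso$mic_by_drug[drug_name])
  }))
  measured <- measured[!is.na(measured)]
  if (length(measured) > 0) {
    return(list(mic = max(measured), mic_source = "isolate_highest"))
  }
  if (all(vapply(isolates, function(i) i$is_normal_flora_only, logical(1)))) {
    if (is.null(cohort_median_pa_mic)) {
      bld_abort("normal flora only but no cohort median MIC supplied",
                "missing_mic")
    }
    return(list(mic = cohort_median_pa_mic, mic_source = "cohort_median_pa"))
  }
  has_mssa <- any(vapply(isolates, function(i) i$methicillin_status == "mssa",
                         logical(1)))
  if (has_mssa && !is.null(literature_mssa_mic)) {
    return(list(mic = literature_mssa_mic, mic_source = "literature_mssa"))
  }
  bld_abort(sprintf("no MIC available for drug '%s' and no fallback applies",
                    drug_name), "missing_mic")
}

#' Class-specific pharmacodynamic fT>MIC target
#'
#' Beta-lactam efficacy targets by class: 40% of the dosing interval above MIC
#' for carbapenems, 50% for penicillins, 60% for cephalosporins.
#'
#' @param drug_class `"carbapenem"`, `"penicillin"` or `"cephalosporin"`.
#' @return target fraction.
#' @export
pd_target <- function(drug_class) {
  targets <- c(carbapenem = 0.40, penicillin = 0.50, cephalosporin = 0.60)
  if (length(drug_class) != 1 || !drug_class %in% names(targets)) {
    bld_abort(sprintf("unknown drug class '%s'", paste(drug_class)),
              "configuration")
  }
  unname(targets[drug_class])
}

#' Assess one drug's exposure against its pharmacodynamic target
#'
#' @inheritParams fraction_time_above_mic
#' @param mic MIC used (mg/L).
#' @param mic_source provenance of the MIC (see [select_mic()]).
#' @return one-row data frame: `drug_name`, `drug_class`, `mic_used`,
#'   `mic_source`, `f_t_above_mic`, `pd_target`, `target_met`. Meeting the
#'   target exactly counts as met.
#' @export
assess_exposure <- function(regimen, pk, mic, mic_source = "isolate_highest") {
  f <- fraction_time_above_mic(regimen, pk, mic)
  tgt <- pd_target(regimen$drug_class)
  data.frame(drug_name = regimen$drug_name, drug_class = regimen$drug_class,
             mic_used = mic, mic_source = mic_source, f_t_above_mic = f,
             pd_target = tgt, target_met = f >= tgt,
             stringsAsFactors = FALSE)
}

#' Classify an antibiotic course as therapeutic or subtherapeutic
#'
#' A course is therapeutic when at least one beta-lactam met its fT>MIC
#' target; a patient who grew MRSA must additionally have received directed
#' anti-MRSA therapy. Everything else is subtherapeutic.
#'
#' @param exacerbation_id identifier of the patient-exacerbation.
#' @param assessments data frame of per-drug rows from [assess_exposure()]
#'   (at least one row, with a logical `target_met` column).
#' @param mrsa_grown logical; did the exacerbation culture grow MRSA.
#' @param anti_mrsa_given logical; was directed anti-MRSA therapy given.
#' @return object of class `course_classification`: list with
#'   `exacerbation_id`, `category`, `per_drug`, `mrsa_rule_applied`.
#' @export
classify_course <- function(exacerbation_id, assessments, mrsa_grown = FALSE,
                            anti_mrsa_given = FALSE) {
  if (is.null(assessments) || nrow(assessments) < 1 ||
      !"target_met" %in% names(assessments)) {
    bld_abort("at least one exposure assessment is required",
              "invalid_parameter")
  }
  any_met <- any(assessments$target_met)
  mrsa_rule_applied <- isTRUE(mrsa_grown) && any_met
  therapeutic <- any_met && (!isTRUE(mrsa_grown) || isTRUE(anti_mrsa_given))
  structure(list(exacerbation_id = exacerbation_id,
                 category = if (therapeutic) "therapeutic" else "subtherapeutic",
                 per_drug = assessments,
                 mrsa_rule_applied = mrsa_rule_applied),
            class = "course_classification")
}
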