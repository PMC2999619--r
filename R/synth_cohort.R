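# Synthetic patient cohorts with known statistical structure: binary
# clinicopathological covariates drawn to target marginals, correlated
# lognormal (nuclear, cytoplasmic) autoscores, duplicate cores with
# multiplicative noise, and proportional-hazards survival with a true
# CNR changepoint, competing other-cause mortality and administrative
# censoring.

#' Configuration for the cohort simulator
#'
#' @param n_patients number of patients (at least 2).
#' @param covariate_marginals named numeric vector giving the target
#'   frequency of the *second* (risk) level of each binary covariate:
#'   `age_high` (> 65 y), `size_large` (> 20 mm), `nodal_pos` (N1+),
#'   `grade_III`, `er_neg` (< 10%), `pr_neg`, `ki67_high` (>= 10%),
#'   `her2_pos` (3+). A length-2 per-covariate frequency pair may be
#'   supplied instead and must sum to 1.
#' @param score_distribution list with `mu_nuclear`, `mu_cytoplasmic`
#'   (log-scale locations), `sd_nuclear`, `sd_cytoplasmic` and
#'   `correlation` of the bivariate normal behind the lognormal
#'   (nuclear, cytoplasmic) autoscores. Defaults are calibrated so the
#'   aggregated cohort reproduces the reference fractions above the
#'   4.26 nuclear-autoscore and 5 CNR cut points (~44-46% high) and a
#'   measured nuclear-vs-cytoplasmic Spearman correlation near 0.75.
#' @param duplicate_noise_sd log-scale SD of the multiplicative
#'   replicate-core noise per measure.
#' @param duplicate_noise_share fraction of the replicate-noise
#'   variance that is core-wide (shared by the nuclear and cytoplasmic
#'   measures of the same core, as staining strength varies jointly).
#' @param log_hr named numeric of log hazard ratios on breast-cancer
#'   death; recognized names: `cnr_high` (indicator of true CNR above
#'   `true_threshold`), `snas` and `cytoplasmic` (per score unit).
#' @param true_threshold CNR changepoint used by the hazard.
#' @param baseline_hazard breast-cancer death rate per month at
#'   baseline.
#' @param other_cause_rate other-cause death rate per month (doubled
#'   above age 65).
#' @param admin_censor_month administrative censoring time (months).
#' @param covariate_assoc named numeric of log-odds shifts applied to a
#'   covariate's risk level in high-CNR patients (centred so marginals
#'   stay on target); plants Table-1-style associations.
#' @param treatment_probs probabilities for
#'   `c(tamoxifen, chemotherapy, none, unknown)`; must sum to 1.
#' @param seed RNG seed used by [generate_cohort()].
#' @return validated `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_patients = 512L,
    covariate_marginals = c(age_high = 0.513, size_large = 0.284,
                            nodal_pos = 0.364, grade_III = 0.338,
                            er_neg = 0.229, pr_neg = 0.427,
                            ki67_high = 0.622, her2_pos = 0.195),
    score_distribution = list(mu_nuclear = 1.169,
                              mu_cytoplasmic = 2.748,
                              sd_nuclear = 0.4, sd_cytoplasmic = 0.4,
                              correlation = 0.82),
    duplicate_noise_sd = 0.4,
    duplicate_noise_share = 0.8,
    log_hr = c(cnr_high = 0),
    true_threshold = 5,
    baseline_hazard = 0.0045,
    other_cause_rate = 0.003,
    admin_censor_month = 207,
    covariate_assoc = NULL,
    treatment_probs = c(tamoxifen = 0.3125, chemotherapy = 0.045,
                        none = 0.39, unknown = 0.2525),
    seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop("`n_patients` must be at least 2", call. = FALSE)
  }
  marg <- lapply(seq_along(covariate_marginals), function(i) {
    v <- if (is.list(covariate_marginals)) covariate_marginals[[i]]
         else covariate_marginals[i]
    if (length(v) == 2L) {
      if (abs(sum(v) - 1) > 1e-8) {
        stop(sprintf("marginal frequencies for `%s` do not sum to 1",
                     names(covariate_marginals)[i]), call. = FALSE)
      }
      v <- v[2L]
    }
    v <- unname(v)
    stopifnot_scalar_prop(v, names(covariate_marginals)[i])
    v
  })
  names(marg) <- names(covariate_marginals)
  covariate_marginals <- unlist(marg)
  sdist <- score_distribution
  for (nm in c("mu_nuclear", "mu_cytoplasmic")) stopifnot(is.numeric(sdist[[nm]]))
  stopifnot_nonneg(sdist$sd_nuclear, "sd_nuclear")
  stopifnot_nonneg(sdist$sd_cytoplasmic, "sd_cytoplasmic")
  if (abs(sdist$correlation) > 1) {
    stop("score correlation must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot_nonneg(duplicate_noise_sd, "duplicate_noise_sd")
  stopifnot_scalar_prop(duplicate_noise_share, "duplicate_noise_share")
  stopifnot_nonneg(baseline_hazard, "baseline_hazard")
  stopifnot_nonneg(other_cause_rate, "other_cause_rate")
  stopifnot_nonneg(true_threshold, "true_threshold")
  if (admin_censor_month <= 0) {
    stop("`admin_censor_month` must be positive", call. = FALSE)
  }
  if (!is.numeric(log_hr) || is.null(names(log_hr)) ||
      !all(names(log_hr) %in% c("cnr_high", "snas", "cytoplasmic"))) {
    stop("`log_hr` must be a named numeric over cnr_high/snas/cytoplasmic",
         call. = FALSE)
  }
  if (abs(sum(treatment_probs) - 1) > 1e-8) {
    stop("`treatment_probs` must sum to 1", call. = FALSE)
  }
  structure(list(
    n_patients = n_patients,
    covariate_marginals = covariate_marginals,
    score_distribution = sdist,
    duplicate_noise_sd = duplicate_noise_sd,
    duplicate_noise_share = duplicate_noise_share,
    log_hr = log_hr,
    true_threshold = true_threshold,
    baseline_hazard = baseline_hazard,
    other_cause_rate = other_cause_rate,
    admin_censor_month = admin_censor_month,
    covariate_assoc = covariate_assoc,
    treatment_probs = treatment_probs,
    seed = seed
  ), class = "cohort_sim_config")
}

COVARIATE_LEVELS <- list(
  age_high   = c("<=65", ">65"),
  size_large = c("<=20mm", ">20mm"),
  nodal_pos  = c("N0", "N1+"),
  grade_III  = c("I&II", "III"),
  er_neg     = c(">=10%", "<10%"),
  pr_neg     = c(">=10%", "<10%"),
  ki67_high  = c("<10%", ">=10%"),
  her2_pos   = c("0-2+", "3+")
)

COVARIATE_COLUMN <- c(
  age_high = "age_group", size_large = "size_group", nodal_pos = "nodal",
  grade_III = "grade", er_neg = "er", pr_neg = "pr", ki67_high = "ki67",
  her2_pos = "her2"
)

#' Simulate a patient cohort with duplicate autoscore records
#'
#' Draws covariates at the configured marginals (optionally tilted by
#' CNR group), correlated lognormal true (nuclear, cytoplasmic)
#' autoscores, two replicate core records per patient with
#' multiplicative noise, and survival: breast-cancer-specific death
#' from a proportional-hazards exponential model on the configured
#' predictors, an independent exponential other-cause death (rate
#' doubled above 65), and administrative censoring. A breast-cancer
#' death is always also an overall-survival death at the same time.
#'
#' @param config a [cohort_sim_config()].
#' @return list of class `cohort_sim` with `patients` (one row per
#'   patient: covariates, treatment, true scores and groups, measured
#'   aggregated scores, OS/BCSS outcomes) and `cores` (two replicate
#'   autoscore records per patient).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config")) {
    stop("`config` must be created by cohort_sim_config()", call. = FALSE)
  }
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  sd_ <- cfg$score_distribution

  # true autoscores: bivariate normal on the log scale
  z1 <- rnorm(n)
  z2 <- sd_$correlation * z1 + sqrt(1 - sd_$correlation^2) * rnorm(n)
  log_nuc <- sd_$mu_nuclear + sd_$sd_nuclear * z1
  log_cyt <- sd_$mu_cytoplasmic + sd_$sd_cytoplasmic * z2
  true_snas <- exp(log_nuc)
  true_cyt <- exp(log_cyt)
  true_cnr <- true_cyt / true_snas
  cnr_high <- true_cnr > cfg$true_threshold

  # covariates; optional planted dependence on CNR group, centred so
  # the configured marginal is preserved
  p_high <- mean(cnr_high)
  cov_df <- data.frame(row.names = seq_len(n))
  for (nm in names(cfg$covariate_marginals)) {
    p0 <- cfg$covariate_marginals[[nm]]
    shift <- if (!is.null(cfg$covariate_assoc) &&
                 nm %in% names(cfg$covariate_assoc)) {
      cfg$covariate_assoc[[nm]]
    } else 0
    eta <- stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6)) +
      shift * (as.numeric(cnr_high) - p_high)
    draw <- runif(n) < stats::plogis(eta)
    lv <- COVARIATE_LEVELS[[nm]]
    cov_df[[COVARIATE_COLUMN[[nm]]]] <-
      factor(ifelse(draw, lv[2L], lv[1L]), levels = lv)
  }
  age_high <- cov_df$age_group == ">65"
  age <- ifelse(age_high, runif(n, 66, 96), runif(n, 27, 65))

  treatment <- factor(
    sample(names(cfg$treatment_probs), n, replace = TRUE,
           prob = cfg$treatment_probs),
    levels = names(cfg$treatment_probs))

  # proportional-hazards linear predictor
  lp <- rep(0, n)
  if ("cnr_high" %in% names(cfg$log_hr)) {
    lp <- lp + cfg$log_hr[["cnr_high"]] * as.numeric(cnr_high)
  }
  if ("snas" %in% names(cfg$log_hr)) {
    lp <- lp + cfg$log_hr[["snas"]] * true_snas
  }
  if ("cytoplasmic" %in% names(cfg$log_hr)) {
    lp <- lp + cfg$log_hr[["cytoplasmic"]] * true_cyt
  }
  bc_rate <- cfg$baseline_hazard * exp(lp)
  t_bc <- if (cfg$baseline_hazard > 0) rexp(n, bc_rate) else rep(Inf, n)
  oc_rate <- cfg$other_cause_rate * ifelse(age_high, 2, 1)
  t_oc <- ifelse(oc_rate > 0, rexp(n, pmax(oc_rate, 1e-12)), Inf)
  t_admin <- cfg$admin_censor_month
  t_obs <- pmin(t_bc, t_oc, t_admin)
  bcss_event <- as.integer(t_bc <= pmin(t_oc, t_admin))
  os_event <- as.integer(pmin(t_bc, t_oc) <= t_admin)

  # duplicate cores with multiplicative log-normal noise; part of the
  # noise is core-wide (shared by both measures of the same core)
  sh_sd <- sqrt(cfg$duplicate_noise_share) * cfg$duplicate_noise_sd
  sp_sd <- sqrt(1 - cfg$duplicate_noise_share) * cfg$duplicate_noise_sd
  shared <- rnorm(2L * n, 0, sh_sd)
  core_nuc <- rep(true_snas, each = 2L) *
    exp(shared + rnorm(2L * n, 0, sp_sd))
  core_cyt <- rep(true_cyt, each = 2L) *
    exp(shared + rnorm(2L * n, 0, sp_sd))
  cores <- data.frame(
    patient_id = rep(seq_len(n), each = 2L),
    replicate = rep(1:2, times = n),
    nuclear_autoscore = core_nuc,
    cyt_autoscore = core_cyt,
    cnr = compute_cnr(core_cyt, core_nuc),
    evaluable = TRUE
  )

  # measured patient-level scores: per-measure maximum over replicates
  meas_nuc <- pmax(core_nuc[c(TRUE, FALSE)], core_nuc[c(FALSE, TRUE)])
  meas_cyt <- pmax(core_cyt[c(TRUE, FALSE)], core_cyt[c(FALSE, TRUE)])
  meas_cnr <- compute_cnr(meas_cyt, meas_nuc)
  thr <- threshold_config(cnr_threshold = cfg$true_threshold)

  patients <- cbind(
    data.frame(patient_id = seq_len(n), age = round(age, 1)),
    cov_df,
    data.frame(
      treatment = treatment,
      true_snas = true_snas,
      true_cytoplasmic = true_cyt,
      true_cnr = true_cnr,
      cnr_high = cnr_high,
      snas = meas_nuc,
      cytoplasmic_autoscore = meas_cyt,
      cnr = meas_cnr,
      snas_group = dichotomize(meas_nuc, thr$snas_threshold),
      cnr_group = dichotomize(meas_cnr, thr$cnr_threshold),
      os_time = t_obs, os_event = os_event,
      bcss_time = t_obs, bcss_event = bcss_event
    )
  )
  structure(list(patients = patients, cores = cores, config = cfg),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$patients), "patients,",
      nrow(x$cores), "cores;",
      sum(x$patients$bcss_event), "BCSS events,",
      sum(x$patients$os_event), "OS events\n")
  invisible(x)
}
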