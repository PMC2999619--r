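# Composite scoring: nuclear/cytoplasmic autoscores, the nuclear
# autoscore (SNAS) at patient level, the cytoplasmic-to-nuclear ratio
# (CNR), duplicate-core handling, evaluability and dichotomization.
#
# The autoscore combines the fraction of positive pixels with the mean
# positive intensity: score = 100 * fraction * intensity, so it lives
# on [0, 100].  Intensity is mean positive DAB OD normalized by od_max.
# CNR is scale-free: the normalization constant cancels.

#' Dichotomization thresholds for the composite scores
#'
#' @param snas_threshold cut point on the nuclear autoscore
#'   (default 4.26).
#' @param cnr_threshold cut point on the cytoplasmic-to-nuclear ratio
#'   (default 5).
#' @param prior_snas_threshold historical nuclear-autoscore cut point
#'   (default 8) kept for cross-cohort comparison.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(snas_threshold = 4.26, cnr_threshold = 5,
                             prior_snas_threshold = 8) {
  for (nm in c("snas_threshold", "cnr_threshold", "prior_snas_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  structure(list(snas_threshold = snas_threshold,
                 cnr_threshold = cnr_threshold,
                 prior_snas_threshold = prior_snas_threshold),
            class = "threshold_config")
}

#' Combined percentage-and-intensity autoscore
#'
#' `100 * positive_fraction * mean_intensity`, on `[0, 100]`.
#'
#' @param positive_fraction fraction of compartment pixels that are
#'   DAB-positive, in `[0, 1]`. Vectorized.
#' @param mean_intensity mean positive DAB OD normalized to `[0, 1]`.
#' @return numeric score(s) in `[0, 100]`.
#' @export
compute_autoscore <- function(positive_fraction, mean_intensity) {
  if (any(!is.finite(positive_fraction)) || any(!is.finite(mean_intensity))) {
    stop("autoscore arguments must be finite", call. = FALSE)
  }
  if (any(positive_fraction < 0 | positive_fraction > 1)) {
    stop("`positive_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (any(mean_intensity < 0 | mean_intensity > 1)) {
    stop("`mean_intensity` must lie in [0, 1]", call. = FALSE)
  }
  100 * positive_fraction * mean_intensity
}

#' Cytoplasmic-to-nuclear ratio
#'
#' Ratio of the cytoplasmic to the nuclear autoscore; undefined (`NA`)
#' when the nuclear autoscore is zero — such records are excluded as
#' non-evaluable rather than assigned an infinite ratio.
#'
#' @param cytoplasmic_autoscore,nuclear_autoscore non-negative scores.
#'   Vectorized.
#' @return numeric ratio(s), `NA` where undefined.
#' @export
compute_cnr <- function(cytoplasmic_autoscore, nuclear_autoscore) {
  if (any(cytoplasmic_autoscore < 0, na.rm = TRUE) ||
      any(nuclear_autoscore < 0, na.rm = TRUE)) {
    stop("autoscores must be non-negative", call. = FALSE)
  }
  ifelse(!is.na(nuclear_autoscore) & nuclear_autoscore > 0,
         cytoplasmic_autoscore / nuclear_autoscore, NA_real_)
}

#' Evaluability of a quantified core
#'
#' A core is evaluable when it carries at least `min_tumour_px` tumour
#' pixels and a nuclear compartment in which an autoscore can be
#' computed (nuclear area > 0).
#'
#' @param quant a `compartment_quant`.
#' @param min_tumour_px inclusive tumour-area floor.
#' @return logical flag.
#' @export
assess_evaluability <- function(quant, min_tumour_px = 2000L) {
  quant$tumour_px >= min_tumour_px && quant$nuclear$total_px > 0L
}

#' Per-core autoscore record from a quantification
#'
#' @param quant a `compartment_quant`.
#' @param patient_id,replicate identifiers carried through.
#' @param thresholds a [positivity_config()] providing `od_max`.
#' @return one-row data.frame: patient_id, replicate, nuclear_pct,
#'   nuclear_intensity, cyt_pct, cyt_intensity, nuclear_autoscore,
#'   cyt_autoscore, cnr, evaluable.
#' @export
autoscore_record <- function(quant, patient_id, replicate = 1L,
                             thresholds = positivity_config()) {
  comp <- function(cp) {
    frac <- if (cp$total_px > 0L) cp$positive_px / cp$total_px else 0
    int <- min(cp$mean_positive_od / thresholds$od_max, 1)
    c(frac, int)
  }
  n <- comp(quant$nuclear); cy <- comp(quant$cytoplasmic)
  nuc_as <- compute_autoscore(n[1], n[2])
  cyt_as <- compute_autoscore(cy[1], cy[2])
  data.frame(
    patient_id = patient_id, replicate = as.integer(replicate),
    nuclear_pct = 100 * n[1], nuclear_intensity = n[2],
    cyt_pct = 100 * cy[1], cyt_intensity = cy[2],
    nuclear_autoscore = nuc_as, cyt_autoscore = cyt_as,
    cnr = compute_cnr(cyt_as, nuc_as),
    evaluable = isTRUE(quant$evaluable)
  )
}

#' Aggregate duplicate cores to one patient-level record
#'
#' Tumours arrayed in duplicate are summarized by the per-measure
#' maximum over evaluable replicates; the patient-level CNR is then
#' recomputed from the aggregated autoscores (ratio of maxima, not the
#' maximum of per-core ratios). A patient with no evaluable replicate
#' is returned flagged non-evaluable with `NA` scores.
#'
#' @param records data.frame of per-core rows as produced by
#'   [autoscore_record()] for one patient.
#' @return one-row patient-level data.frame (replicate dropped).
#' @export
aggregate_duplicates <- function(records) {
  if (nrow(records) < 1L || nrow(records) > 2L) {
    stop("expected 1 or 2 replicate records per patient", call. = FALSE)
  }
  if (length(unique(records$patient_id)) != 1L) {
    stop("records belong to different patients", call. = FALSE)
  }
  ev <- records[isTRUE_vec(records$evaluable), , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(
      patient_id = records$patient_id[1], nuclear_pct = NA_real_,
      nuclear_intensity = NA_real_, cyt_pct = NA_real_,
      cyt_intensity = NA_real_, nuclear_autoscore = NA_real_,
      cyt_autoscore = NA_real_, cnr = NA_real_, evaluable = FALSE
    ))
  }
  nuc <- max(ev$nuclear_autoscore)
  cyt <- max(ev$cyt_autoscore)
  data.frame(
    patient_id = ev$patient_id[1],
    nuclear_pct = max(ev$nuclear_pct),
    nuclear_intensity = max(ev$nuclear_intensity),
    cyt_pct = max(ev$cyt_pct),
    cyt_intensity = max(ev$cyt_intensity),
    nuclear_autoscore = nuc,
    cyt_autoscore = cyt,
    cnr = compute_cnr(cyt, nuc),
    evaluable = TRUE
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Aggregate a whole cohort of core records to patient level
#'
#' @param records per-core data.frame (any number of patients).
#' @return patient-level data.frame, one row per patient, in order of
#'   first appearance.
#' @export
aggregate_cohort <- function(records) {
  ids <- unique(records$patient_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    aggregate_duplicates(records[records$patient_id == id, , drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}

#' Duplicate-core concordance
#'
#' Spearman rank correlation between replicate 1 and replicate 2
#' across patients with both replicates evaluable, for each of the four
#' component measures.
#'
#' @param records per-core data.frame with `replicate` in `{1, 2}`.
#' @return data.frame with measure, rho, p and n.
#' @export
duplicate_concordance <- function(records) {
  r1 <- records[records$replicate == 1L & isTRUE_vec(records$evaluable), ]
  r2 <- records[records$replicate == 2L & isTRUE_vec(records$evaluable), ]
  common <- intersect(r1$patient_id, r2$patient_id)
  if (length(common) < 10L) {
    stop("need at least 10 patients with both replicates evaluable",
         call. = FALSE)
  }
  r1 <- r1[match(common, r1$patient_id), ]
  r2 <- r2[match(common, r2$patient_id), ]
  measures <- c("nuclear_pct", "nuclear_intensity",
                "cyt_pct", "cyt_intensity")
  out <- lapply(measures, function(m) {
    res <- spearman_rho(r1[[m]], r2[[m]])
    data.frame(measure = m, rho = res$rho, p = res$p, n = res$n)
  })
  do.call(rbind, out)
}

#' Dichotomize a score at a threshold
#'
#' High means strictly greater than the threshold; a score exactly at
#' the threshold is low. Undefined scores return `NA` (excluded, not
#' grouped).
#'
#' @param score numeric vector.
#' @param threshold single positive cut point.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(score, threshold) {
  stopifnot_nonneg(threshold, "threshold")
  factor(ifelse(is.na(score), NA_character_,
                ifelse(score > threshold, "high", "low")),
         levels = c("low", "high"))
}
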