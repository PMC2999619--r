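# Cohort-level statistics: chi-square association tables,
# Kaplan-Meier / log-rank, Cox proportional hazards (Efron ties) and
# Spearman rank correlation.  The survival machinery is delegated to
# the survival package; association and reporting conventions
# (Pearson chi-square without continuity correction, p to three
# decimals with "<0.001" below resolution) are fixed here.

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction; df = 1; p from the upper tail.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `counts`, `chi_square`, `df`, `p` and
#'   `expected`.
#' @export
contingency_test <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(!is.finite(m))) {
    stop("`table` must be a 2x2 matrix of non-negative counts",
         call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  list(counts = m, chi_square = stat, df = 1L,
       p = pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = expected)
}

#' Format a p-value in the reporting convention
#'
#' Three decimals, `"<0.001"` below that resolution.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.0005, "<0.001", sprintf("%.3f", round(p, 3))))
}

#' Association table of covariates against a score stratifier
#'
#' For each binary covariate: counts and within-stratum percentages by
#' stratifier group, the chi-square p-value, and the number of
#' patients excluded as unknown for that covariate.
#'
#' @param cohort patient-level data.frame.
#' @param stratifier column name of a two-level factor (e.g.
#'   `snas_group`, `cnr_group`) or `known_vs_unknown` built from the
#'   `evaluable` column.
#' @param covariates covariate column names (default the eight
#'   standard ones present in `cohort`).
#' @return data.frame: covariate, level, count and percent per
#'   stratum, chi_square, p (one row per covariate level).
#' @export
build_table1 <- function(cohort, stratifier = "cnr_group",
                         covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(unname(COVARIATE_COLUMN), names(cohort))
  }
  if (identical(stratifier, "known_vs_unknown")) {
    strat <- factor(ifelse(isTRUE_vec(cohort$evaluable), "known",
                           "unknown"), levels = c("known", "unknown"))
  } else {
    strat <- cohort[[stratifier]]
  }
  if (is.null(strat)) stop("stratifier column not found", call. = FALSE)
  strat <- droplevels(factor(strat))
  keep <- !is.na(strat)
  if (nlevels(strat) != 2L || !all(table(strat[keep]) > 0L)) {
    stop("stratifier must define two non-empty groups", call. = FALSE)
  }
  out <- lapply(covariates, function(cv) {
    v <- factor(cohort[[cv]])[keep]
    s <- strat[keep]
    ok <- !is.na(v)
    tab <- table(v[ok], s[ok])
    ct <- contingency_test(tab)
    pct <- sweep(tab, 2L, colSums(tab), "/") * 100
    data.frame(
      covariate = cv,
      level = rownames(tab),
      count_1 = as.integer(tab[, 1L]), pct_1 = round(pct[, 1L], 1),
      count_2 = as.integer(tab[, 2L]), pct_2 = round(pct[, 2L], 1),
      unknown = sum(!ok),
      chi_square = ct$chi_square,
      p = ct$p,
      p_formatted = format_pvalue(ct$p),
      row.names = NULL
    )
  })
  res <- do.call(rbind, out)
  attr(res, "strata") <- levels(strat)
  attr(res, "n") <- as.integer(table(strat[keep]))
  res
}

#' Kaplan-Meier survivor curves per group
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time.
#'
#' @param times follow-up times (months, non-negative).
#' @param events event flags.
#' @param groups optional grouping; a single curve when omitted.
#' @return data.frame with group, time, n_risk, n_event, survival.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("negative times", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", length(times))
  g <- factor(groups)
  if (any(table(g) < 1L)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ g)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(g)[1L], length(sm$time))
         else sub("^g=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, survival = sm$surv)
}

#' Two-group log-rank test
#'
#' @param times,events survival outcome.
#' @param groups two-level grouping.
#' @return list with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) != 2L) {
    stop("log-rank test requires exactly two groups", call. = FALSE)
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chi_square = sd_$chisq, df = 1L,
       p = pchisq(sd_$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fits with Wald intervals
#'
#' Univariate (one fit per covariate) or multivariate (one joint fit),
#' Efron tie handling, optional subgroup filter (the ER-positive and
#' tamoxifen-treated analyses are row filters, not interaction
#' models).
#'
#' @param cohort patient-level data.frame.
#' @param covariates covariate column names entering the model.
#' @param outcome `"BCSS"` or `"OS"` (expects `<prefix>_time` /
#'   `<prefix>_event` columns in lower case).
#' @param type `"univariate"` or `"multivariate"`.
#' @param subgroup optional logical vector or filtering expression
#'   result selecting the analysis subset.
#' @param min_events minimum events required (default 10).
#' @return data.frame: term, hazard_ratio, ci_low, ci_high, p, n,
#'   n_events, loglik, converged.
#' @export
cox_fit <- function(cohort, covariates, outcome = c("BCSS", "OS"),
                    type = c("univariate", "multivariate"),
                    subgroup = NULL, min_events = 10L) {
  outcome <- match.arg(outcome)
  type <- match.arg(type)
  pre <- tolower(outcome)
  dat <- cohort
  if (!is.null(subgroup)) dat <- dat[which(subgroup), , drop = FALSE]
  time <- dat[[paste0(pre, "_time")]]
  event <- dat[[paste0(pre, "_event")]]
  if (is.null(time) || is.null(event)) {
    stop("outcome columns not found", call. = FALSE)
  }
  one_fit <- function(cols) {
    sub <- dat[, cols, drop = FALSE]
    cc <- complete.cases(sub) & !is.na(time) & !is.na(event)
    for (cl in cols) {
      v <- sub[[cl]][cc]
      if (length(unique(v[!is.na(v)])) < 2L) {
        stop(sprintf("covariate `%s` is constant in the analysis set", cl),
             call. = FALSE)
      }
    }
    if (sum(event[cc]) < min_events) {
      stop(sprintf("fewer than %d events in the analysis set", min_events),
           call. = FALSE)
    }
    df <- cbind(data.frame(.time = time[cc], .event = event[cc]),
                droplevels(sub[cc, , drop = FALSE]))
    f <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", cols), collapse = " + ")))
    fit <- survival::coxph(f, data = df, ties = "efron")
    s <- summary(fit)
    conv <- all(is.finite(stats::coef(fit)))
    data.frame(
      term = rownames(s$coefficients),
      hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
      ci_low = unname(s$conf.int[, "lower .95"]),
      ci_high = unname(s$conf.int[, "upper .95"]),
      p = unname(s$coefficients[, "Pr(>|z|)"]),
      n = s$n, n_events = s$nevent,
      loglik = fit$loglik[2L],
      converged = conv,
      row.names = NULL
    )
  }
  if (type == "univariate") {
    do.call(rbind, lapply(covariates, function(cv) one_fit(cv)))
  } else {
    one_fit(covariates)
  }
}

#' Spearman rank correlation
#'
#' Average ranks for ties, large-sample p-value.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list with `rho`, `p`, `n` and `defined` (FALSE when either
#'   input is constant).
#' @export
spearman_rho <- function(x, y) {
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 5L) {
    stop("need at least 5 complete pairs", call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}
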