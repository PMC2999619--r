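test_that("a perfectly separating predictor forces the midpoint threshold", {
  x <- data.frame(snas = c(rep(3, 10), rep(4, 10)))
  times <- c(seq(1, 5.5, by = 0.5), rep(100, 10))
  events <- c(rep(1L, 10), rep(0L, 10))
  fit <- fit_survival_tree(x, times, events, max_depth = 1L,
                           min_node_size = 5L)
  expect_equal(fit$root_threshold, 3.5)
  expect_identical(fit$root_predictor, "snas")
})

test_that("a constant predictor yields a single terminal node", {
  x <- data.frame(snas = rep(2, 40))
  fit <- fit_survival_tree(x, times = rexp(40) + 1,
                           events = rep(1L, 40), min_node_size = 5L)
  expect_true(fit$nodes[[1]]$terminal)
  expect_true(is.na(fit$root_threshold))
  expect_equal(unname(variable_importance(fit)), 0)
})

test_that("the chosen split matches exhaustive survdiff enumeration", {
  set.seed(5)
  n <- 12L
  d <- data.frame(snas = runif(n, 0, 10), cnr = runif(n, 0, 10))
  times <- rexp(n, 0.1); events <- rbinom(n, 1, 0.8)
  # brute-force oracle: every predictor, every midpoint, survdiff chisq
  best <- list(stat = -1)
  for (p in c("snas", "cnr")) {
    ux <- sort(unique(d[[p]]))
    for (thr in (ux[-1] + ux[-length(ux)]) / 2) {
      grp <- d[[p]] <= thr
      if (sum(grp) < 2 || sum(!grp) < 2) next
      st <- survival::survdiff(
        survival::Surv(times, events) ~ grp)$chisq
      if (st > best$stat + 1e-12) best <- list(stat = st, p = p, thr = thr)
    }
  }
  fit <- fit_survival_tree(d, times, events, max_depth = 1L,
                           min_node_size = 2L)
  expect_identical(fit$root_predictor, best$p)
  expect_equal(fit$root_threshold, best$thr, tolerance = 1e-9)
  expect_equal(fit$nodes[[1]]$stat, best$stat, tolerance = 1e-8)
})

test_that("fitting requires events and enough patients", {
  x <- data.frame(snas = runif(50))
  expect_error(fit_survival_tree(x, rep(1, 50), rep(0L, 50)),
               "no events")
  expect_error(fit_survival_tree(x[1:10, , drop = FALSE], rep(1, 10),
                                 rep(1L, 10), min_node_size = 20L),
               "min_node_size")
})

test_that("duplicating every patient leaves the root split unchanged", {
  d <- generate_cohort(cohort_sim_config(
    n_patients = 150, log_hr = c(cnr_high = log(0.4)), seed = 9))$patients
  X <- data.frame(snas = d$true_snas, cytoplasmic = d$true_cytoplasmic,
                  cnr = d$true_cnr)
  f1 <- fit_survival_tree(X, d$bcss_time, d$bcss_event, max_depth = 1L)
  f2 <- fit_survival_tree(rbind(X, X), rep(d$bcss_time, 2),
                          rep(d$bcss_event, 2), max_depth = 1L)
  expect_identical(f1$root_predictor, f2$root_predictor)
  expect_equal(f1$root_threshold, f2$root_threshold, tolerance = 1e-9)
})

test_that("cross-validation folds partition the cohort evenly and reproducibly", {
  d <- generate_cohort(cohort_sim_config(
    n_patients = 120, log_hr = c(cnr_high = log(0.4)), seed = 21))$patients
  dd <- data.frame(snas = d$true_snas, cytoplasmic = d$true_cytoplasmic,
                   cnr = d$true_cnr, bcss_time = d$bcss_time,
                   bcss_event = d$bcss_event)
  cv1 <- select_model_cv(dd, seed = 13, min_node_size = 10L)
  cv2 <- select_model_cv(dd, seed = 13, min_node_size = 10L)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$selected, cv2$selected)
  expect_equal(cv1$root_threshold, cv2$root_threshold)
  sizes <- table(cv1$folds)
  expect_identical(length(sizes), 10L)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(sum(sizes), nrow(dd))
  expect_equal(cv1$accuracy[cv1$selected], max(cv1$accuracy, na.rm = TRUE))
})

test_that("importance normalizes to 1 at the top and 0 for unused predictors", {
  x <- data.frame(snas = c(rep(1, 15), rep(9, 15)),
                  cnr = rep(4, 30), cytoplasmic = rep(2, 30))
  times <- c(seq(0.5, 7.5, by = 0.5), rep(60, 15))
  events <- c(rep(1L, 15), rep(0L, 15))
  fit <- fit_survival_tree(x, times, events, min_node_size = 5L)
  imp <- variable_importance(fit)
  expect_equal(unname(imp["snas"]), 1)
  expect_equal(unname(imp["cnr"]), 0)
  expect_equal(unname(imp["cytoplasmic"]), 0)
  expect_true(all(imp >= 0 & imp <= 1))
  expect_error(variable_importance(list()), "survival_tree")
})

test_that("an SNAS-only hazard ranks SNAS as the most important predictor", {
  d <- generate_cohort(cohort_sim_config(
    n_patients = 400, log_hr = c(snas = 0.25), seed = 17))$patients
  X <- data.frame(snas = d$true_snas, cytoplasmic = d$true_cytoplasmic,
                  cnr = d$true_cnr)
  fit <- fit_survival_tree(X, d$bcss_time, d$bcss_event)
  imp <- variable_importance(fit)
  expect_identical(names(which.max(imp)), "snas")
  expect_equal(max(imp), 1)
})

test_that("null data yields chance-level held-out concordance", {
  # events permuted against predictors; the selected tree is evaluated
  # on an independent permuted test set
  cc <- vapply(1:50, function(s) {
    d <- generate_cohort(cohort_sim_config(
      n_patients = 180, log_hr = c(cnr_high = 0), seed = 300 + s))$patients
    dd <- data.frame(snas = d$true_snas, cytoplasmic = d$true_cytoplasmic,
                     cnr = d$true_cnr, bcss_time = d$bcss_time,
                     bcss_event = d$bcss_event)
    perm <- with_seed_test(s, sample.int(nrow(dd)))
    dd[, c("bcss_time", "bcss_event")] <-
      dd[perm, c("bcss_time", "bcss_event")]
    tr <- seq_len(120); te <- 121:180
    cv <- tryCatch(
      select_model_cv(dd[tr, ], seed = s, min_node_size = 10L, k = 5L),
      error = function(e) NULL)
    if (is.null(cv) || is.na(cv$root_threshold)) return(0.5)
    pr <- predict(cv$selected_model, dd[te, c("snas", "cytoplasmic", "cnr")])
    if (length(unique(pr$risk)) < 2L) return(0.5)
    survival::concordance(
      survival::Surv(dd$bcss_time[te], dd$bcss_event[te]) ~ pr$risk,
      reverse = TRUE)$concordance
  }, numeric(1))
  expect_equal(mean(cc), 0.5, tolerance = 0.05 / 0.5)
})

test_that("threshold reporting exposes integer rounding explicitly", {
  expect_equal(report_threshold(4.87), 4.87)
  expect_equal(report_threshold(4.87, "integer"), 5)
})
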