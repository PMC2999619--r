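test_that("chi-square association tables reproduce printed cohort p-values", {
  # 2x2 counts from the published evaluated-cohort association tables
  # (rows: covariate levels; columns: low/high score group)
  cases <- list(
    list(tab = matrix(c(53, 143, 28, 130), 2), p3 = 0.038),  # ER x CNR
    list(tab = matrix(c(119, 79, 118, 42), 2), p3 = 0.007),  # grade x CNR
    list(tab = matrix(c(149, 47, 136, 22), 2), p3 = 0.018),  # Her2 x CNR
    list(tab = matrix(c(82, 105, 46, 106), 2), p3 = 0.010),  # Ki-67 x SNAS
    list(tab = matrix(c(145, 55, 92, 66), 2), p3 = 0.005)    # grade x SNAS
  )
  for (cs in cases) {
    res <- contingency_test(cs$tab)
    expect_equal(round(res$p, 3), cs$p3)
    expect_identical(res$df, 1L)
  }
  # Ki-67 x CNR prints below the reporting resolution
  res6 <- contingency_test(matrix(c(55, 133, 73, 78), 2))
  expect_identical(format_pvalue(res6$p), "<0.001")
})

test_that("chi-square degeneracies are handled", {
  # identical row proportions: statistic 0, p = 1
  res <- contingency_test(matrix(c(10, 30, 20, 60), 2))
  expect_equal(res$chi_square, 0)
  expect_equal(res$p, 1)
  expect_error(contingency_test(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(contingency_test(matrix(1:6, 2)), "2x2")
})

test_that("association table accounting and percentages are exact", {
  d <- generate_cohort(cohort_sim_config(
    n_patients = 400, covariate_assoc = list(er_neg = -1.3),
    seed = 19))$patients
  d$er[1:7] <- NA # unknowns are excluded per covariate
  t1 <- build_table1(d, stratifier = "cnr_group")
  er <- t1[t1$covariate == "er", ]
  expect_identical(unique(er$unknown), 7L)
  expect_identical(sum(er$count_1) + sum(er$count_2) + 7L, nrow(d))
  expect_equal(er$pct_1, round(100 * er$count_1 / sum(er$count_1), 1))
  # planted dependence is recovered
  expect_lt(er$p[1], 0.05)
  # percentages recompute: 53/196 prints as 27.0
  expect_equal(round(100 * 53 / 196, 1), 27.0)
  expect_error(build_table1(d, stratifier = "nope"), "not found")
})

test_that("Kaplan-Meier matches the hand product on toy data", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  # S(1) = 3/4; S(2) = 3/4 * 2/3 = 1/2; censored at 3; S(4) = 0
  s <- km$survival[km$time %in% c(1, 2, 4)]
  expect_equal(s, c(3 / 4, 1 / 2, 0))
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_lte(km$survival[1], 1)
  # no censoring: empirical survivor fraction
  km2 <- km_estimate(c(2, 4, 6, 8), rep(1, 4))
  expect_equal(km2$survival, c(3, 2, 1, 0) / 4)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches the hand-computed O-E sums on a toy example", {
  toy <- fixture_toy_surv()
  res <- logrank_test(toy$time, toy$event, toy$group)
  # independent O-E / V accumulation over pooled event times
  et <- sort(unique(toy$time[toy$event == 1]))
  O1 <- E1 <- V <- 0
  for (t_ in et) {
    at <- toy$time >= t_
    d <- sum(toy$time == t_ & toy$event == 1)
    d1 <- sum(toy$time == t_ & toy$event == 1 & toy$group == "a")
    n <- sum(at); n1 <- sum(at & toy$group == "a")
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chi_square, (O1 - E1)^2 / V, tolerance = 1e-9)
  expect_equal(res$p, pchisq((O1 - E1)^2 / V, 1, lower.tail = FALSE))
  # symmetry and degeneracy
  swapped <- logrank_test(toy$time, toy$event,
                          factor(toy$group, levels = c("b", "a")))
  expect_equal(res$chi_square, swapped$chi_square)
  same <- logrank_test(rep(toy$time, 2), rep(toy$event, 2),
                       rep(c("a", "b"), each = 8))
  expect_error(logrank_test(toy$time, toy$event, rep("a", 8)),
               "two groups")
  # identical groups: statistic 0, p = 1
  expect_lt(same$chi_square, 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-6)
})

test_that("the internal splitting statistic agrees with survdiff", {
  set.seed(3)
  time <- rexp(40, 0.1); event <- rbinom(40, 1, 0.7)
  x <- runif(40)
  sc <- cnrquant:::logrank_scan(x, time, event, min_node_size = 5L)
  i <- sample(nrow(sc), 1)
  ref <- survival::survdiff(
    survival::Surv(time, event) ~ (x <= sc$threshold[i]))$chisq
  expect_equal(sc$stat[i], ref, tolerance = 1e-9)
})

test_that("Cox estimation matches a brute-force partial-likelihood grid", {
  # two groups, no ties
  time <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.4, 7.8, 9.2, 10.5, 12.0)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  grp <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1)
  d <- data.frame(os_time = time, os_event = event, g = grp)
  res <- cox_fit(d, "g", outcome = "OS", min_events = 5L)
  # grid oracle: written partial likelihood (no ties -> exact)
  pl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      ll <- ll + beta * grp[i] - log(sum(exp(beta * grp[rs])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-3)
  beta_hat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_lt(abs(log(res$hazard_ratio) - beta_hat), 1e-3) # grid half-step
  expect_true(res$ci_low < res$hazard_ratio &
                res$hazard_ratio < res$ci_high)
  expect_true(res$converged)
})

test_that("Cox contracts: constant covariates and event floors", {
  d <- generate_cohort(cohort_sim_config(n_patients = 100, seed = 23))$patients
  d$flat <- 1
  expect_error(cox_fit(d, "flat", outcome = "BCSS"), "constant")
  expect_error(cox_fit(d, "cnr_high", outcome = "BCSS",
                       subgroup = seq_len(nrow(d)) <= 8), "events")
  # univariate vs multivariate shape
  uni <- cox_fit(d, c("cnr_high", "grade"), outcome = "BCSS")
  mult <- cox_fit(d, c("cnr_high", "grade"), outcome = "BCSS",
                  type = "multivariate")
  expect_identical(nrow(uni), 2L)
  expect_identical(nrow(mult), 2L)
  expect_identical(length(unique(uni$loglik)), 2L)
  expect_identical(length(unique(mult$loglik)), 1L)
})

test_that("Cox sign agrees with the KM ordering on strong-effect data", {
  d <- generate_cohort(cohort_sim_config(
    n_patients = 300, log_hr = c(cnr_high = log(0.4)), seed = 29))$patients
  res <- cox_fit(d, "cnr_high", outcome = "BCSS")
  km <- km_estimate(d$bcss_time, d$bcss_event,
                    ifelse(d$cnr_high, "high", "low"))
  # high-CNR protective: HR < 1 and the high curve sits above at 100 mo
  s_at <- function(g) {
    k <- km[km$group == g & km$time <= 100, ]
    k$survival[nrow(k)]
  }
  expect_lt(res$hazard_ratio, 1)
  expect_gt(s_at("high"), s_at("low"))
})

test_that("subgroup filters reduce the analysis set", {
  d <- generate_cohort(cohort_sim_config(
    n_patients = 400, log_hr = c(cnr_high = log(0.5)), seed = 31))$patients
  er_pos <- d$er == ">=10%"
  res_all <- cox_fit(d, "cnr_high", outcome = "BCSS")
  res_sub <- cox_fit(d, "cnr_high", outcome = "BCSS", subgroup = er_pos)
  expect_lt(res_sub$n, res_all$n)
  expect_identical(res_sub$n, sum(er_pos))
})

test_that("Spearman matches the rank formula on seven untied pairs", {
  x <- c(2.2, 8.1, 4.4, 9.9, 1.1, 6.6, 5.5)
  y <- c(3.0, 7.2, 5.1, 8.8, 2.4, 4.0, 6.9)
  res <- spearman_rho(x, y)
  d <- rank(x) - rank(y)
  expect_equal(res$rho, 1 - 6 * sum(d^2) / (7 * 48), tolerance = 1e-12)
  expect_true(res$defined)
  # perfectly monotone
  expect_equal(spearman_rho(1:6, c(2, 4, 8, 16, 32, 64))$rho, 1)
  # constant input flagged, short input errors
  expect_false(spearman_rho(rep(1, 6), 1:6)$defined)
  expect_error(spearman_rho(1:4, 1:4), "at least 5")
})

test_that("p-value formatting follows the three-decimal convention", {
  expect_identical(format_pvalue(c(0.0379868, 0.0004, 0.2504)),
                   c("0.038", "<0.001", "0.250"))
})
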