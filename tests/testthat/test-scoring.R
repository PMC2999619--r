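test_that("autoscore arithmetic and bounds", {
  expect_equal(compute_autoscore(0, 0.7), 0)
  expect_equal(compute_autoscore(1, 1), 100)
  expect_equal(compute_autoscore(0.5, 0.4), 20)
  expect_error(compute_autoscore(1.2, 0.5), "\\[0, 1\\]")
  expect_error(compute_autoscore(0.5, -0.1), "\\[0, 1\\]")
  # strictly increasing in each argument on (0, 1]^2
  fr <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(compute_autoscore(fr, 0.5)) > 0))
  expect_true(all(diff(compute_autoscore(0.5, fr)) > 0))
})

test_that("autoscore equals an independent per-pixel recomputation", {
  p <- stain_params(noise_sd = 0)
  g <- generate_core_image(p, 160, 160, seed = 41)
  q <- quantify_compartments(g$image, g$truth$class_mask)
  rec <- autoscore_record(q, "pt1")
  # pixel-loop oracle on the estimated masks and an independent unmix
  un <- oracle_unmix(g$image)
  masks <- attr(q, "masks")
  for (cp in c("nuclear", "cytoplasm")) {
    vals <- un$d[masks[[cp]]]
    pos <- vals > 0.15
    oracle <- 100 * (sum(pos) / length(vals)) *
      min(mean(vals[pos]) / 2.0, 1)
    got <- if (cp == "nuclear") rec$nuclear_autoscore else rec$cyt_autoscore
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("CNR definition, scale invariance and undefined flagging", {
  expect_equal(compute_cnr(10, 2), 5)
  expect_equal(compute_cnr(3 * 7, 3 * 2), compute_cnr(7, 2))
  expect_true(is.na(compute_cnr(7, 0)))
  expect_error(compute_cnr(-1, 2), "non-negative")
  # invariance to the OD normalization constant
  q <- quantify_compartments(
    fixture_core(seed = 43)$image, fixture_core(seed = 43)$truth$class_mask)
  r1 <- autoscore_record(q, "a", thresholds = positivity_config(od_max = 1))
  r2 <- autoscore_record(q, "a", thresholds = positivity_config(od_max = 2))
  expect_equal(r1$cnr, r2$cnr, tolerance = 1e-12)
})

test_that("duplicate aggregation takes per-measure maxima then the ratio", {
  mk <- function(id, rep, nuc, cyt) data.frame(
    patient_id = id, replicate = rep, nuclear_pct = nuc,
    nuclear_intensity = 0.5, cyt_pct = cyt, cyt_intensity = 0.5,
    nuclear_autoscore = nuc, cyt_autoscore = cyt,
    cnr = compute_cnr(cyt, nuc), evaluable = TRUE)
  # the constructed counterexample: per-core CNRs 10 and 1.2, but the
  # aggregate is 10/5 = 2
  rec <- rbind(mk("p", 1, 1, 10), mk("p", 2, 5, 6))
  agg <- aggregate_duplicates(rec)
  expect_equal(agg$nuclear_autoscore, 5)
  expect_equal(agg$cyt_autoscore, 10)
  expect_equal(agg$cnr, 2)
  # simple maximum and identity
  expect_equal(aggregate_duplicates(
    rbind(mk("p", 1, 3, 1), mk("p", 2, 7, 1)))$nuclear_autoscore, 7)
  single <- mk("p", 1, 4, 8)
  agg1 <- aggregate_duplicates(single)
  expect_equal(agg1$nuclear_autoscore, 4)
  expect_equal(agg1$cnr, 2)
  # order invariance and idempotence
  fwd <- aggregate_duplicates(rec)
  rev_ <- aggregate_duplicates(rec[2:1, ])
  expect_equal(fwd, rev_)
  fwd2 <- fwd; fwd2$replicate <- 1L
  again <- aggregate_duplicates(fwd2)
  expect_equal(again$cnr, fwd$cnr)
  expect_equal(again$nuclear_autoscore, fwd$nuclear_autoscore)
  # zero evaluable replicates: survivin unknown
  bad <- mk("p", 1, 3, 3); bad$evaluable <- FALSE
  unk <- aggregate_duplicates(bad)
  expect_false(unk$evaluable)
  expect_true(is.na(unk$cnr))
})

test_that("duplicate concordance matches the rank formula on toy pairs", {
  x <- c(3.1, 1.2, 5.6, 4.4, 2.0, 6.3)
  y <- c(2.9, 1.5, 6.1, 3.9, 2.2, 7.0) # same ranks: rho = 1
  mkrec <- function(v1, v2) {
    rbind(
      data.frame(patient_id = sprintf("p%02d", seq_along(v1)),
                 replicate = 1L, nuclear_pct = v1, nuclear_intensity = v1,
                 cyt_pct = v1, cyt_intensity = v1, evaluable = TRUE),
      data.frame(patient_id = sprintf("p%02d", seq_along(v2)),
                 replicate = 2L, nuclear_pct = v2, nuclear_intensity = v2,
                 cyt_pct = v2, cyt_intensity = v2, evaluable = TRUE))
  }
  expect_error(duplicate_concordance(mkrec(x, y)), "at least 10")
  x10 <- c(x, 7.7, 8.8, 9.9, 0.4); y10 <- c(y, 8.0, 9.0, 10.5, 0.1)
  conc <- duplicate_concordance(mkrec(x10, y10))
  # no ties: rho = 1 - 6 sum d^2 / (n (n^2 - 1))
  d <- rank(x10) - rank(y10)
  rho_hand <- 1 - 6 * sum(d^2) / (10 * (100 - 1))
  expect_equal(conc$rho[conc$measure == "nuclear_pct"], rho_hand,
               tolerance = 1e-12)
  # reversed ranks
  concr <- duplicate_concordance(mkrec(x10, -y10))
  expect_equal(concr$rho[1], -rho_hand, tolerance = 1e-12)
})

test_that("dichotomization uses a strict greater-than at the threshold", {
  expect_identical(as.character(dichotomize(5.0, 5)), "low")
  expect_identical(as.character(dichotomize(5.1, 5)), "high")
  expect_identical(as.character(dichotomize(4.26, 4.26)), "low")
  expect_true(is.na(dichotomize(NA_real_, 5)))
})

test_that("evaluability boundary is inclusive and tissue-poor cores drop out", {
  q0 <- cnrquant:::new_compartment_quant(
    nuclear = list(total_px = 10L, positive_px = 1L,
                   bins = c(weak = 1L, medium = 0L, strong = 0L),
                   mean_positive_od = 0.3),
    cytoplasmic = list(total_px = 10L, positive_px = 0L,
                       bins = c(weak = 0L, medium = 0L, strong = 0L),
                       mean_positive_od = 0),
    tumour_px = 0L)
  expect_false(assess_evaluability(q0, 1L))
  q1 <- q0; q1$tumour_px <- 2000L
  expect_true(assess_evaluability(q1, 2000L))  # inclusive bound
  expect_false(assess_evaluability(q1, 2001L))

  # a cohort with 30% tissue-poor cores is ~70% evaluable
  poor <- rep(c(TRUE, FALSE), c(30, 70))
  eval_flags <- vapply(seq_len(100), function(i) {
    taf <- if (poor[i]) 0 else 0.45 # tissue-poor: no invasive tumour hit
    g <- generate_core_image(
      stain_params(tumour_area_fraction = taf,
                   lymphocyte_area_fraction = 0.05),
      96, 96, seed = 1000 + i)
    g$truth$true_quant$evaluable
  }, logical(1))
  expect_equal(mean(eval_flags), 0.7, tolerance = 0.05 / 0.7)
})
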