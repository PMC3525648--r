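test_that("pairwise concordance is C/(C+D) with domain checks", {
  expect_equal(pairwise_concordance(twin_counts(9, 31)), 0.225)
  expect_equal(pairwise_concordance(twin_counts(22, 66)), 0.25)
  expect_equal(pairwise_concordance(twin_counts(0, 10)), 0)
  expect_error(pairwise_concordance(twin_counts(0, 0)), "at least one")
  expect_error(twin_counts(-1, 5), "non-negative")
})

test_that("ascertainment calibration solves the inflation factor and round-trips", {
  fac <- calibrate_ascertainment(twin_counts(20, 73), 0.297)
  expect_equal(fac$ascertainment_inflation, 0.297 * 73 / (20 * 0.703),
               tolerance = 1e-12)
  expect_equal(fac$ascertainment_inflation, 1.542, tolerance = 1e-3)
  ## round-trip to the calibration rate
  expect_equal(probandwise_concordance(twin_counts(20, 73), fac), 0.297,
               tolerance = 1e-12)
  ## boundary cases: full double ascertainment and none
  full <- 2 * 24 / (2 * 24 + 109)
  expect_equal(calibrate_ascertainment(twin_counts(24, 109), full)$ascertainment_inflation,
               2, tolerance = 1e-12)
  expect_equal(calibrate_ascertainment(twin_counts(24, 109), 24 / 133)$ascertainment_inflation,
               1, tolerance = 1e-12)
  ## rates implying f outside [1, 2] are rejected with a diagnostic
  expect_error(calibrate_ascertainment(twin_counts(20, 73), 0.1), "no ascertainment solution")
  expect_error(calibrate_ascertainment(twin_counts(20, 73), 0.5), "no ascertainment solution")
})

test_that("proband-wise concordance reproduces the published subgroup rates", {
  fac <- calibrate_ascertainment(twin_counts(20, 73), 0.297)
  expect_equal(round(probandwise_concordance(twin_counts(9, 31), fac), 3), 0.309)
  ## published 0.287 used a truncated factor; full precision is within one ulp
  expect_lt(abs(probandwise_concordance(twin_counts(11, 42), fac) - 0.287), 1e-3)
  expect_equal(probandwise_concordance(twin_counts(9, 31), 1),
               pairwise_concordance(twin_counts(9, 31)))
})

test_that("proband-wise rate is increasing in f and exceeds pairwise for f > 1", {
  set.seed(42)
  for (i in 1:25) {
    C <- sample(1:50, 1); D <- sample(1:200, 1)
    tc <- twin_counts(C, D)
    fs <- sort(runif(5, 1, 2))
    rates <- vapply(fs, function(f) probandwise_concordance(tc, f), numeric(1))
    expect_true(all(diff(rates) > 0))
    expect_true(all(rates > pairwise_concordance(tc)))
  }
})

test_that("the pooled sibling/DZ ratio is the factor consistent with all published adjusted values", {
  obs <- ms_observables()
  fac <- iu_adjustment_factor(obs)
  expect_equal(fac$iu_ch_factor, 0.029 / 0.054, tolerance = 1e-12)
  ## the one multiplier that reproduces all four printed adjusted rates
  printed <- rbind(c(0.25, 0.134), c(0.34, 0.183), c(0.067, 0.036),
                   c(0.309, 0.166))
  for (i in seq_len(nrow(printed)))
    expect_equal(round(adjust_concordance(printed[i, 1], fac), 3), printed[i, 2])
  ## per-gender ratios (0.039/0.051, 0.019/0.057) would NOT reproduce them
  expect_false(round(0.34 * 0.039 / 0.051, 3) == 0.183)
  ## no IU excess means no adjustment
  expect_equal(iu_adjustment_factor(
    epi_observables(0.001, 0.2, 0.05, 0.05))$iu_ch_factor, 1)
  degenerate <- suppressWarnings(epi_observables(0.001, 0.2, 0, 0.01))
  expect_error(iu_adjustment_factor(degenerate), "DZ concordance")
})

test_that("adjustment preserves zero and subgroup ordering", {
  expect_equal(adjust_concordance(0, 0.54), 0)
  set.seed(7)
  for (i in 1:20) {
    t0 <- runif(1); s0 <- runif(1, 0, t0); fac <- runif(1, 0.1, 1)
    expect_gt(adjust_concordance(t0, fac), adjust_concordance(s0, fac))
  }
})

test_that("subgroup renormalization enforces the mixture constraint exactly", {
  ## default: renormalize against the subgroup mixture itself
  r0 <- renormalize_subgroups(0.166, 0.154, 0.57, 0.134)
  expect_equal(0.57 * r0$t + 0.43 * r0$s, 0.134, tolerance = 1e-15)
  ## against the table's own pooled adjusted rate (0.160), as the published
  ## subgroup penetrances were formed
  r <- renormalize_subgroups(0.166, 0.154, 0.57, 0.134, b_subgroup = 0.160)
  expect_equal(round(r$t, 3), 0.139)
  expect_equal(round(r$s, 3), 0.129)
  ## identity when already consistent
  mix <- 0.6 * 0.2 + 0.4 * 0.1
  r2 <- renormalize_subgroups(0.2, 0.1, 0.6, mix)
  expect_equal(r2$t, 0.2); expect_equal(r2$s, 0.1); expect_equal(r2$factor, 1)
  ## mixture consistency over random partitions, to machine precision
  set.seed(11)
  for (i in 1:30) {
    t0 <- runif(1); s0 <- runif(1); w <- runif(1); b <- runif(1, 0.01, 1)
    r3 <- renormalize_subgroups(t0, s0, w, b)
    expect_equal(w * r3$t + (1 - w) * r3$s, b, tolerance = 1e-12)
  }
  expect_error(renormalize_subgroups(0, 0, 0.5, 0.1), "zero")
})

test_that("the gender mixture is consistent with the overall adjusted concordance", {
  ## 0.68 x 0.183 + 0.32 x 0.036 = 0.136, within printed rounding of 0.134
  mix <- 0.68 * 0.183 + 0.32 * 0.036
  expect_lt(abs(mix - 0.134), 0.003)
  r <- renormalize_subgroups(0.183, 0.036, 0.68, 0.134)
  expect_equal(r$factor, 0.134 / mix, tolerance = 1e-12)
  expect_lt(abs(r$factor - 1), 0.02)
})

test_that("the full adjustment chain reproduces every published adjusted value", {
  fit <- fit_susceptibility(ms_observables())
  expect_equal(round(fit$b, 3), 0.134)
  hla <- fit$tables$hla
  expect_equal(round(unname(hla$adjusted["t"]), 3), 0.166)
  expect_equal(round(unname(hla$adjusted["s"]), 3), 0.154)
  expect_equal(round(unname(hla$adjusted["b"]), 3), 0.160)
  expect_equal(round(unname(hla$renormalized["t"]), 3), 0.139)
  expect_equal(round(unname(hla$renormalized["s"]), 3), 0.129)
  gen <- fit$tables$gender
  expect_equal(round(unname(gen$renormalized["t"]), 3), 0.183)
  expect_equal(round(unname(gen$renormalized["s"]), 3), 0.036)
})
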