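test_that("identical seeds yield identical cohorts", {
  cfg <- sim_config(n_pairs = 2000, p_g = 0.05,
                    penetrance = list(type = "two_point",
                                      values = c(0.1, 0.5), probs = c(0.5, 0.5)),
                    seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mz, b$mz)
  expect_identical(a$dz, b$dz)
  expect_identical(a$sibling, b$sibling)
  expect_identical(a$double_ascertained, b$double_ascertained)
  c2 <- simulate_cohort(sim_config(n_pairs = 2000, p_g = 0.05,
                                   penetrance = cfg$penetrance, seed = 100))
  expect_false(identical(a$mz, c2$mz))
})

test_that("constant penetrance makes proband-wise MZ concordance converge to it", {
  z0 <- 0.3
  sim <- simulate_cohort(sim_config(n_pairs = 50000, p_g = 1,
                                    penetrance = list(type = "point", value = z0),
                                    iu_effect = 1, ascertainment_pi = 1,
                                    seed = 21))
  pw <- probandwise_concordance(sim$mz, 2)
  ## binomial CI: ~50k informative pairs
  expect_lt(abs(pw - z0), 0.01)
})

test_that("size-biased sampling drives concordance to E[z^2]/E[z], not E[z]", {
  vals <- c(0.1, 0.5); probs <- c(0.5, 0.5)
  oracle <- size_biased_mean(vals, probs)     # 0.4333
  sim <- simulate_cohort(sim_config(
    n_pairs = 60000, p_g = 1,
    penetrance = list(type = "two_point", values = vals, probs = probs),
    iu_effect = 1, ascertainment_pi = 1, seed = 33))
  pw <- probandwise_concordance(sim$mz, 2)
  expect_lt(abs(pw / oracle - 1), 0.03)
  ## and it clearly exceeds the plain mean
  expect_gt(pw, 0.38)
  expect_equal(sim$truth$b_prime, oracle, tolerance = 1e-12)
})

test_that("twin carrier frequency matches the population frequency (representativeness)", {
  maf <- 0.25
  sim <- simulate_cohort(sim_config(
    n_pairs = 40000, p_g = 0.02, carrier = list(maf = maf), seed = 55))
  cf <- 1 - (1 - maf)^2
  n_carrier <- sim$mz_by_carrier$plus$concordant + sim$mz_by_carrier$plus$discordant
  n_total <- with(sim$mz_by_carrier,
                  plus$concordant + plus$discordant +
                  minus$concordant + minus$discordant)
  ## carrier fraction among ascertained pairs: carriers and non-carriers share
  ## identical penetrance here, so ascertainment does not distort the ratio
  se <- sqrt(cf * (1 - cf) / n_total)
  expect_lt(abs(n_carrier / n_total - cf), 4 * se)
})

test_that("shared intra-uterine effect inflates b unless the correction is applied", {
  cfg <- function(seed) sim_config(
    n_pairs = 60000, p_g = 0.05,
    penetrance = list(type = "point", value = 0.25),
    iu_effect = 1.8, ascertainment_pi = 1, seed = seed)
  est_corr <- numeric(5); est_raw <- numeric(5)
  for (i in 1:5) {
    sim <- simulate_cohort(cfg(i))
    est_corr[i] <- recover_parameters(sim, g = 1)$b
    est_raw[i] <- recover_parameters(sim, g = 1, apply_iu_adjustment = FALSE)$b
  }
  ## without correction the estimate is biased upward relative to with it
  expect_gt(mean(est_raw), mean(est_corr))
  expect_gt(mean(est_raw) / 0.25, 1.3)   # raw reflects the inflated concordance
})

test_that("simulated cohorts round-trip through the twin-table CSV schema", {
  sim <- simulate_cohort(sim_config(n_pairs = 3000, p_g = 0.05,
                                    carrier = list(maf = 0.2), seed = 8))
  path <- file.path(tempdir(), "sim_twins.csv")
  write_twin_table(sim, path)
  back <- read_twin_table(path)
  expect_equal(back[["MZ:all"]]$concordant, sim$mz$concordant)
  expect_equal(back[["DZ:all"]]$discordant, sim$dz$discordant)
  expect_equal(back[["MZ:carrier"]]$concordant,
               sim$mz_by_carrier$plus$concordant)
  expect_equal(back[["sibling:all"]]$concordant, sim$sibling$concordant)
})

test_that("recovered parameter chain brackets the truth on a model-satisfying cohort", {
  sim <- simulate_cohort(sim_config(
    n_pairs = 150000, p_g = 0.01,
    penetrance = list(type = "two_point", values = c(0.1, 0.5),
                      probs = c(0.5, 0.5)),
    iu_effect = 1, ascertainment_pi = 0.5, seed = 77))
  est <- recover_parameters(sim, g = 1, apply_iu_adjustment = FALSE)
  expect_lt(est$p_g_lower, 0.01)
  expect_gt(est$p_g_upper, 0.01)
  ## zero-variance identity: with a point distribution b ~ z
  sim0 <- simulate_cohort(sim_config(
    n_pairs = 150000, p_g = 0.05,
    penetrance = list(type = "point", value = 0.3),
    iu_effect = 1, ascertainment_pi = 1, seed = 78))
  est0 <- recover_parameters(sim0, g = 1, apply_iu_adjustment = FALSE)
  ## ~7500 susceptible pairs: 4 binomial standard errors is ~0.035
  expect_lt(abs(est0$b - 0.3), 0.035)
})

test_that("invalid penetrance configurations are rejected", {
  expect_error(simulate_cohort(sim_config(
    n_pairs = 10, p_g = 1, penetrance = list(type = "nope"))),
    "unknown penetrance")
  expect_error(simulate_cohort(sim_config(
    n_pairs = 10, p_g = 1,
    penetrance = list(type = "point", value = 1.4))), "support")
})
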