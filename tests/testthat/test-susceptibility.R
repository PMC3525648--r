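test_that("P(G) upper bound reproduces the headline and regional values", {
  expect_equal(round(100 * prob_g_upper(0.0015, 0.134), 1), 2.2)
  expect_equal(round(100 * prob_g_upper(0.00152, 0.222 * 29 / 54), 1), 2.5)
  expect_equal(prob_g_upper(0.001, 1), 0.002)   # maximal-penetrance limit
  expect_error(prob_g_upper(0.001, 0), "positive")
})

test_that("P(G) lower bound reproduces the regional values", {
  expect_equal(round(100 * prob_g_lower(0.00144, 0.94, 0.1192), 1), 1.1)
  expect_equal(round(100 * prob_g_lower(0.00052, 0.94, 0.2481), 1), 0.2)
  expect_equal(prob_g_lower(0.001, 0, 0.5), 0)
  expect_error(prob_g_lower(0.001, 0.9, 0), "positive")
})

test_that("bound ordering p_g_lower <= p_g_upper holds over random observables", {
  set.seed(3)
  for (i in 1:50) {
    prev <- runif(1, 1e-4, 0.02); b <- runif(1, 0.05, 0.9); g <- runif(1)
    expect_lte(prob_g_lower(prev, g, b), prob_g_upper(prev, b))
  }
})

test_that("joint partition feasibility locates g near 0.94 for the reference inputs", {
  fit <- fit_susceptibility(ms_observables())
  est <- fit$g_estimate
  ## HLA partition identifies g sharply; gender partition is consistent
  expect_gte(est$g_lower, 0.93)
  expect_lte(est$g_upper, 0.96)
  expect_gte(est$g_lower, 0.94 - 0.01)
  expect_lt(est$intervals$gender[1], 0.5)
  expect_equal(est$intervals$gender[2], 1, tolerance = 1e-6)
})

test_that("a partition with no signal is uninformative beyond generic penetrance limits", {
  p <- partition_analysis(A0 = 0.3, A = 0.3, t = 0.05, s = 0.05, b = 0.05)
  est <- estimate_g(p)
  expect_lte(est$g_lower, 0.06)   # only b' <= 1 and t' <= 1 bind
  expect_equal(est$g_upper, 1, tolerance = 1e-6)
})

test_that("contradictory partitions produce an infeasibility report", {
  ## forced allele-frequency-only classification with a grossly unequal t/s
  p <- partition_analysis(A0 = 0.5, A = 0.68, t = 0.183, s = 0.036,
                          b = 0.134, mechanism1 = TRUE, label = "forced")
  expect_error(estimate_g(p), "per-partition intervals")
})

test_that("penetrance range obeys conservation and the size-bias identity", {
  pr <- penetrance_range(0.0015, 0.94, c(0.0105, 0.0224), b = 0.134)
  ## conservation z * P(G) = g * P(D) at both endpoints
  expect_equal(unname(pr$z * pr$p_g), rep(0.94 * 0.0015, 2), tolerance = 1e-12)
  expect_true(all(diff(unname(pr$z)) >= 0))
  expect_true(all(pr$sigma2 >= 0))
  ## zero-variance limit: when z equals b' the variance vanishes
  pr0 <- penetrance_range(0.003, 1, c(0.01, 0.01), b = 0.3)
  expect_equal(unname(pr0$z), c(0.3, 0.3))
  expect_equal(unname(pr0$sigma2), c(0, 0), tolerance = 1e-12)
})

test_that("two-point penetrance moments are recovered from the size-biased rate", {
  ## distribution z in {0.1, 0.5} with equal mass: mean 0.3, variance 0.04,
  ## size-biased mean E[z^2]/E[z] = 0.13/0.3
  b_prime <- size_biased_mean(c(0.1, 0.5), c(0.5, 0.5))
  expect_equal(b_prime, 0.13 / 0.3, tolerance = 1e-12)
  pr <- penetrance_range(0.003, 1, c(0.01, 0.01), b = b_prime)
  expect_equal(unname(pr$z[1]), 0.3, tolerance = 1e-12)
  expect_equal(unname(pr$sigma2[1]), 0.04, tolerance = 1e-12)
})

test_that("incoherent penetrance constraint sets are reported", {
  expect_error(penetrance_range(0.0015, 0.94, c(0.01, 0.02), b = 0.134,
                                z_constraint = c(0.5, 0.9)),
               "incoherent")
})

test_that("the near-unity penetrance mass bound matches brute-force search", {
  ## boundary behaviour
  expect_equal(purely_genetic_bound(1, 0, 0.9), 1)
  expect_lt(purely_genetic_bound(0.1, 0.005, 0.99), 0.01)
  set.seed(19)
  for (i in 1:10) {
    z <- runif(1, 0.05, 0.5)
    s2 <- runif(1, 5e-4, 0.05)
    thr <- runif(1, 0.8, 1)
    bound <- purely_genetic_bound(z, s2, thr)
    brute <- brute_force_tail_mass(z, s2, thr)
    expect_lte(brute, bound + 1e-9)
    expect_lt(bound - brute, 0.02)
  }
})

test_that("sensitivity sweep applies the named scenarios and monotonicity holds", {
  obs <- ms_observables()
  sw <- sensitivity_sweep(obs)
  base <- sw[sw$prevalence == 0.0015 & sw$mz_raw == 0.25 & sw$sib_raw == 0.029, ]
  expect_equal(round(base$b, 3), 0.134)
  doubled <- sw[sw$prevalence == 0.003 & sw$mz_raw == 0.25 & sw$sib_raw == 0.029, ]
  expect_equal(doubled$p_g_upper, 2 * 0.003 / doubled$b, tolerance = 1e-12)
  expect_lt(abs(doubled$p_g_upper - 0.0448), 2e-4)
  sib35 <- sw[sw$prevalence == 0.0015 & sw$mz_raw == 0.25 & sw$sib_raw == 0.035, ]
  expect_equal(round(sib35$b, 3), 0.162)
  expect_equal(round(sib35$p_g_upper, 4), 0.0185, tolerance = 1e-4)
  ## no overrides beyond base reproduce base estimates
  same <- sensitivity_sweep(obs, list(prevalence = 0.0015))
  expect_equal(same$p_g_upper, prob_g_upper(0.0015, same$b), tolerance = 1e-12)
  expect_error(sensitivity_sweep(obs, list(nonsense = 1)), "unknown observable")
  ## p_g_upper increasing in prevalence, decreasing in b
  expect_true(all(sw$p_g_upper[sw$prevalence == 0.003 & sw$mz_raw == 0.25] >
                  sw$p_g_upper[sw$prevalence == 0.0015 & sw$mz_raw == 0.25]))
})

test_that("regional and cross-disease tables reproduce the published bounds", {
  rt <- region_table(ms_region_registry(), iu_factor = 0.029 / 0.054, g = 0.94)
  sard <- rt[rt$region == "Sardinia", ]
  expect_equal(round(100 * sard$p_g_lower, 1), 1.1)
  expect_equal(round(100 * sard$p_g_upper, 1), 2.5)
  dt <- region_table(ms_disease_registry(), mode = "unadjusted")
  sle <- dt[dt$disease == "Systemic lupus erythematosus", ]
  expect_equal(round(100 * sle$p_g_lower, 2), 0.13)
  expect_equal(round(100 * sle$p_g_upper, 2), 0.13)
  ## lower <= upper even with a degenerate prevalence range (g <= 2)
  one <- region_table(data.frame(region = "x", prevalence_low = 0.001,
                                 prevalence_high = 0.001, probandwise_mz = 0.3),
                      mode = "iu_adjusted", iu_factor = 1, g = 0.94)
  expect_lte(one$p_g_lower, one$p_g_upper)
  expect_warning(region_table(ms_region_registry()[0, ], iu_factor = 0.5),
                 "empty registry")
})
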