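test_that("enrichment mechanism classification follows the s/b ratio", {
  hla <- enrichment_mechanism(0.129, 0.134)
  expect_equal(round(hla$ratio, 2), 0.96)
  expect_equal(hla$mechanism, "allele_frequency_only")
  gen <- enrichment_mechanism(0.036, 0.134)
  expect_equal(round(gen$ratio, 2), 0.27)
  expect_equal(gen$mechanism, "both")
  expect_equal(enrichment_mechanism(0.2, 0.2)$ratio, 1)
  expect_equal(enrichment_mechanism(0.2, 0.2)$mechanism, "allele_frequency_only")
})

test_that("Hardy-Weinberg triples reproduce the published predictions", {
  expect_equal(round(hwe_expected(0.07), 2),
               c(freq_2copy = 0.07, freq_1copy = 0.39, freq_0copy = 0.54))
  p <- hwe_expected(0.24, "carrier_freq")
  expect_equal(round(unname(p), 3), c(0.016, 0.224, 0.760))
  ## boundary degeneracies
  expect_equal(unname(hwe_expected(1)), c(1, 0, 0))
  expect_equal(unname(hwe_expected(0)), c(0, 0, 1))
})

test_that("Hardy-Weinberg triples sum to one and re-anchoring is idempotent", {
  set.seed(5)
  for (i in 1:25) {
    v <- runif(1, 0.01, 0.99)
    anchor <- sample(c("two_copy_freq", "carrier_freq", "zero_copy_freq"), 1)
    h <- hwe_expected(v, anchor)
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_equal(hwe_expected(h[["freq_2copy"]], "two_copy_freq"), h,
                 tolerance = 1e-12)
    expect_equal(hwe_expected(h[["freq_0copy"]], "zero_copy_freq"), h,
                 tolerance = 1e-12)
    expect_equal(hwe_expected(1 - h[["freq_0copy"]], "carrier_freq"), h,
                 tolerance = 1e-12)
  }
})

test_that("genotype odds ratios reproduce published carrier ORs", {
  ## carrier/non-carrier cohorts folded into the one-copy class
  expect_equal(round(genotype_odds_ratios(c(0, 0.55, 0.45),
                                          c(0, 0.24, 0.76))[["or_carrier"]], 1),
               3.9)
  expect_equal(round(genotype_odds_ratios(c(0, 0.56, 0.44),
                                          c(0, 0.24, 0.76))[["or_carrier"]], 1),
               4.0)
  same <- genotype_odds_ratios(c(0.07, 0.39, 0.54), c(0.07, 0.39, 0.54))
  expect_equal(unname(same), c(1, 1, 1))
  expect_error(genotype_odds_ratios(c(0.5, 0.5, 0), c(0.2, 0.2, 0.6)),
               "reference frequency")
})

test_that("odds ratios are invariant under rescaling before renormalization", {
  set.seed(23)
  for (i in 1:20) {
    ca <- runif(3, 0.05, 1); ca <- ca / sum(ca)
    co <- runif(3, 0.05, 1); co <- co / sum(co)
    base <- genotype_odds_ratios(ca, co)
    expect_equal(genotype_odds_ratios(ca * runif(1, 0.1, 10), co), base,
                 tolerance = 1e-9)
  }
})

test_that("allele-dose selection weights are classified geometric for the published ORs", {
  a <- geometric_selection_test(3.1, 9.3)
  expect_equal(round(a$geometric_deviation, 3), 0.032)
  expect_equal(a$classification, "geometric")
  b <- geometric_selection_test(3.6, 10.4)
  expect_equal(round(b$geometric_deviation, 2), 0.20)
  expect_equal(b$classification, "geometric")
  exact <- geometric_selection_test(3, 9)
  expect_equal(exact$geometric_deviation, 0)
})

test_that("carrier susceptibility follows total probability for allele-frequency partitions", {
  expect_equal(round(carrier_susceptibility(0.55, 0.24, 0.022), 3), 0.050)
  expect_equal(round(carrier_susceptibility(0.46, 0.20, 0.022), 3), 0.051)
  expect_equal(carrier_susceptibility(0.3, 0.3, 0.01), 0.01)  # no enrichment
  set.seed(31)
  for (i in 1:20) {
    A0 <- runif(1, 0.1, 0.9); A <- runif(1, A0, 1); pg <- runif(1, 0.001, 0.05)
    g_plus <- carrier_susceptibility(A, A0, pg)
    g_minus <- (1 - A) * pg / (1 - A0)
    expect_equal(g_plus * A0 + g_minus * (1 - A0), pg, tolerance = 1e-12)
  }
})

test_that("allele contribution fraction matches the published ~41% and is monotone", {
  expect_equal(round(allele_contribution_fraction(0.55, 0.24), 3), 0.408)
  expect_equal(allele_contribution_fraction(0.3, 0.3), 0)
  expect_equal(allele_contribution_fraction(1, 0.24), 1)
  expect_warning(x <- allele_contribution_fraction(0.2, 0.3), "protective")
  expect_equal(x, 0)
  set.seed(13)
  for (i in 1:20) {
    A0 <- runif(1, 0.05, 0.8)
    As <- sort(runif(3, A0, 1))
    fr <- vapply(As, allele_contribution_fraction, numeric(1), A0 = A0)
    expect_true(all(fr >= 0 & fr <= 1))
    expect_true(all(diff(fr) >= 0))
    expect_gte(allele_contribution_fraction(As[1], A0 * 0.5),
               allele_contribution_fraction(As[1], A0))
  }
})

test_that("risk-allele carrier ceiling reproduces the worked example", {
  expect_equal(round(100 * max_susceptible_carriers(0.022, 0.40), 1), 3.4)
  ## 2.2/16 = 13.75, published as 13.8
  expect_lt(abs(100 * max_susceptible_carriers(0.022, 0.40, "homozygote") - 13.8),
            0.051)
  expect_equal(max_susceptible_carriers(0.01, 1), 0.01)
  expect_equal(max_susceptible_carriers(0.01, 1, "homozygote"), 0.01)
})

test_that("stepwise enrichment distinguishes the two mechanisms", {
  hla <- continued_enrichment_check(0.24, 0.55, 0.57)
  expect_true(hla$second_step_flat)
  expect_equal(hla$mechanism, "allele_frequency_only")
  gen <- continued_enrichment_check(0.50, 0.68, 0.92)
  expect_false(gen$second_step_flat)
  expect_equal(gen$mechanism, "penetrance_present")
  flat <- continued_enrichment_check(0.4, 0.4, 0.4)
  expect_equal(flat$step1, 1); expect_equal(flat$step2, 1)
})
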