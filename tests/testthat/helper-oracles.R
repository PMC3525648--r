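# Independent oracles and small fixture builders used across the test files.

# Brute-force search over two-point penetrance distributions on a grid:
# the largest mass any distribution with mean z and variance <= sigma2 can
# place at or above `threshold`.  Independent of the closed-form bound.
brute_force_tail_mass <- function(z, sigma2, threshold, step = 0.005) {
  v1s <- seq(0, z, by = step)
  v2s <- seq(threshold, 1, by = step)
  best <- 0
  for (v2 in v2s) {
    m <- (z - v1s) / (v2 - v1s)
    ok <- m >= 0 & m <= 1 & m * (1 - m) * (v2 - v1s)^2 <= sigma2 + 1e-12
    if (any(ok)) best <- max(best, max(m[ok]))
  }
  best
}

# Exact size-biased concordance E[z^2]/E[z] for a discrete penetrance
# distribution (the expected proband-wise MZ concordance among susceptible
# probands under full double ascertainment).
size_biased_mean <- function(values, probs) {
  probs <- probs / sum(probs)
  sum(probs * values^2) / sum(probs * values)
}

# Write a small twin-table CSV fixture and return its path.
write_twin_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, "twin_fixture.csv")
  df <- data.frame(
    zygosity = c("MZ", "MZ", "MZ", "DZ", "sibling"),
    subgroup = c("carrier", "non-carrier", "", "", ""),
    concordant = c(9, 11, 20, 5, 3),
    discordant = c(31, 42, 73, 88, 97))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal analysis-config YAML fixture mirroring the bundled reference inputs.
write_config_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, "analysis_config.yaml")
  writeLines(c(
    "observables:",
    "  prevalence: 0.0015",
    "  mz_raw: 0.25",
    "  dz_raw: 0.054",
    "  sib_raw: 0.029",
    "  female_fraction_cases: 0.68",
    "  carrier_fraction_cases: 0.55",
    "  carrier_fraction_population: 0.24",
    "twin_tables:",
    "  hla:",
    "    plus: [9, 31]",
    "    minus: [11, 42]",
    "    pooled: [20, 73]",
    "    pooled_probandwise: 0.297",
    "    probandwise_plus: 0.309",
    "    probandwise_minus: 0.287",
    "    case_fraction_plus: 0.57",
    "  gender:",
    "    plus: [22, 66]",
    "    minus: [2, 43]",
    "    pooled: [24, 109]",
    "    pooled_probandwise: 0.25",
    "    probandwise_plus: 0.34",
    "    probandwise_minus: 0.067",
    "    case_fraction_plus: 0.68"), path)
  path
}
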