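#' Simulation configuration for synthetic twin cohorts
#'
#' Describes a generative population in which every individual carries an
#' individual-specific susceptibility genotype with a genotype-specific
#' penetrance.  Twin cohorts drawn from it obey the model assumptions by
#' construction (twins are genetically representative of the population), so
#' every estimator in the package can be checked against known truth.
#'
#' @param n_pairs twin pairs per zygosity.
#' @param p_g marginal susceptible population fraction.
#' @param penetrance penetrance distribution over the susceptible set: a list
#'   with \code{type} one of \code{"point"} (field \code{value}),
#'   \code{"two_point"} (\code{values}, \code{probs}), or \code{"beta"}
#'   (\code{shape1}, \code{shape2}), support within \[0, 1\].
#' @param penetrance_nonsusceptible P(D|G-), default 0.
#' @param carrier optional risk-marker model: list with \code{maf} (allele
#'   frequency; carrier frequency is 1 - (1-maf)^2),
#'   \code{susceptibility_multiplier} (carriers more likely susceptible;
#'   allele-frequency mechanism) and \code{penetrance_multiplier}
#'   (susceptible carriers more penetrant; penetrance mechanism), both
#'   defaulting to 1.  The marginal susceptible fraction is held at
#'   \code{p_g} by rescaling the per-stratum susceptibility probabilities.
#' @param sib_share_susceptibility probability that a DZ twin or sibling of a
#'   susceptible proband is susceptible (default 0.5); non-sharing co-twins
#'   are redrawn from the population.
#' @param iu_effect multiplicative inflation of the joint affection
#'   probability for co-gestated pairs (MZ and DZ, not siblings); 1 = no
#'   shared intra-uterine effect.
#' @param ascertainment_pi probability that a concordant pair is
#'   independently ascertained twice (contributing two probands).
#' @param seed integer RNG seed.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_pairs = 10000, p_g = 0.01,
                       penetrance = list(type = "point", value = 0.2),
                       penetrance_nonsusceptible = 0,
                       carrier = NULL,
                       sib_share_susceptibility = 0.5,
                       iu_effect = 1,
                       ascertainment_pi = 0.5,
                       seed = 1L) {
  stopifnot(n_pairs >= 1, p_g >= 0, p_g <= 1,
            penetrance_nonsusceptible >= 0, penetrance_nonsusceptible <= 1,
            sib_share_susceptibility >= 0, sib_share_susceptibility <= 1,
            iu_effect >= 0, ascertainment_pi >= 0, ascertainment_pi <= 1)
  if (!is.null(carrier)) {
    carrier$maf <- carrier$maf %||% 0.2
    carrier$susceptibility_multiplier <- carrier$susceptibility_multiplier %||% 1
    carrier$penetrance_multiplier <- carrier$penetrance_multiplier %||% 1
    stopifnot(carrier$maf > 0, carrier$maf < 1,
              carrier$susceptibility_multiplier > 0,
              carrier$penetrance_multiplier > 0)
  }
  structure(list(n_pairs = as.integer(n_pairs), p_g = p_g,
                 penetrance = penetrance,
                 penetrance_nonsusceptible = penetrance_nonsusceptible,
                 carrier = carrier,
                 sib_share_susceptibility = sib_share_susceptibility,
                 iu_effect = iu_effect, ascertainment_pi = ascertainment_pi,
                 seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_penetrance <- function(n, dist) {
  z <- switch(dist$type,
              point = rep(dist$value, n),
              two_point = sample(dist$values, n, replace = TRUE,
                                 prob = dist$probs),
              beta = stats::rbeta(n, dist$shape1, dist$shape2),
              stop("unknown penetrance distribution type: ", dist$type))
  if (any(z < 0 | z > 1)) stop("penetrance support must lie within [0, 1]")
  z
}

penetrance_moments <- function(dist) {
  switch(dist$type,
         point = c(mean = dist$value, m2 = dist$value^2),
         two_point = {
           p <- dist$probs / sum(dist$probs)
           c(mean = sum(p * dist$values), m2 = sum(p * dist$values^2))
         },
         beta = {
           m <- dist$shape1 / (dist$shape1 + dist$shape2)
           v <- dist$shape1 * dist$shape2 /
             ((dist$shape1 + dist$shape2)^2 * (dist$shape1 + dist$shape2 + 1))
           c(mean = m, m2 = v + m^2)
         })
}

## symmetric joint affection draw for a pair with penetrances (z1, z2) and a
## shared-environment inflation of the concordant cell
draw_pair_disease <- function(z1, z2, iu) {
  p11 <- pmin(iu * z1 * z2, pmin(z1, z2))
  p10 <- z1 - p11
  p01 <- z2 - p11
  p00 <- pmax(1 - p10 - p01 - p11, 0)
  tot <- p11 + p10 + p01 + p00
  u <- stats::runif(length(z1)) * tot
  cell <- 1L + (u > p11) + (u > p11 + p10) + (u > p11 + p10 + p01)
  ## cell: 1 = both, 2 = only twin1, 3 = only twin2, 4 = neither
  cbind(d1 = cell %in% c(1L, 2L), d2 = cell %in% c(1L, 3L))
}

#' Simulate a synthetic twin cohort
#'
#' Draws MZ, DZ, and sibling pair cohorts from the generative configuration.
#' MZ co-twins share their full genotype (susceptibility, carrier status, and
#' penetrance value); DZ twins and siblings share susceptibility status with
#' probability \code{sib_share_susceptibility} and are otherwise redrawn, and
#' when susceptible draw their own penetrance value.  Disease is drawn per
#' genotype penetrance, with the concordant cell of co-gestated pairs
#' inflated by \code{iu_effect}.  Pairs with at least one affected member are
#' ascertained; concordant pairs are counted from both probands with
#' probability \code{ascertainment_pi}.  The draw order (genotype, carrier,
#' disease, ascertainment) consumes a single stream seeded from
#' \code{config$seed}, so identical configurations yield identical cohorts.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{"sim_cohort"}: per-zygosity
#'   \code{\link{twin_counts}}, per-carrier-subgroup MZ counts (when a
#'   carrier model is present), population affection tallies, the observed
#'   double-ascertainment rate, and an immutable \code{truth} record
#'   (p_g, mean penetrance z, sigma2, the size-biased concordance
#'   E\[z^2\]/E\[z\], the realized susceptible-case fraction g, and carrier
#'   frequencies).
#' @examples
#' sim <- simulate_cohort(sim_config(n_pairs = 2000, p_g = 0.05, seed = 7))
#' sim$mz
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  cf <- if (is.null(config$carrier)) 0 else 1 - (1 - config$carrier$maf)^2
  smult <- if (is.null(config$carrier)) 1 else config$carrier$susceptibility_multiplier
  pmult <- if (is.null(config$carrier)) 1 else config$carrier$penetrance_multiplier
  ## per-stratum susceptibility probabilities with marginal held at p_g
  p0 <- config$p_g / ((1 - cf) + smult * cf)
  p_susc_carrier <- min(p0 * smult, 1)
  p_susc_noncar <- min(p0, 1)

  draw_individuals <- function(m) {
    carrier <- stats::runif(m) < cf
    susc <- stats::runif(m) < ifelse(carrier, p_susc_carrier, p_susc_noncar)
    z <- rep(config$penetrance_nonsusceptible, m)
    if (any(susc)) {
      zi <- draw_penetrance(sum(susc), config$penetrance)
      zi <- ifelse(carrier[susc], pmin(zi * pmult, 1), zi)
      z[susc] <- zi
    }
    list(carrier = carrier, susc = susc, z = z)
  }

  tally <- function(d, subgroup = NULL, zyg = "MZ") {
    both <- d[, 1] & d[, 2]
    one <- xor(d[, 1], d[, 2])
    twin_counts(sum(both), sum(one), zygosity = zyg, subgroup = subgroup)
  }

  ## --- MZ pairs: identical genotypes -------------------------------------
  mz <- draw_individuals(n)
  iu <- config$iu_effect
  d_mz <- draw_pair_disease(mz$z, mz$z, iu)
  mz_counts <- tally(d_mz)
  mz_by_carrier <- NULL
  if (!is.null(config$carrier)) {
    mz_by_carrier <- list(
      plus = tally(d_mz[mz$carrier, , drop = FALSE], "carrier"),
      minus = tally(d_mz[!mz$carrier, , drop = FALSE], "non-carrier"))
  }

  ## --- DZ pairs and siblings: partial sharing ----------------------------
  draw_pairs_partial <- function(m, iu_pair) {
    t1 <- draw_individuals(m)
    share <- stats::runif(m) < config$sib_share_susceptibility
    t2_susc <- ifelse(share, t1$susc,
                      stats::runif(m) < ifelse(stats::runif(m) < cf,
                                               p_susc_carrier, p_susc_noncar))
    z2 <- rep(config$penetrance_nonsusceptible, m)
    if (any(t2_susc)) z2[t2_susc] <- draw_penetrance(sum(t2_susc), config$penetrance)
    list(d = draw_pair_disease(t1$z, z2, iu_pair), susc1 = t1$susc)
  }
  dz <- draw_pairs_partial(n, iu)
  sib <- draw_pairs_partial(n, 1)

  ## --- ascertainment ------------------------------------------------------
  both_mz <- sum(d_mz[, 1] & d_mz[, 2])
  double <- stats::rbinom(1, both_mz, config$ascertainment_pi)
  pi_hat <- if (both_mz > 0) double / both_mz else 0

  affected <- sum(d_mz) + sum(dz$d) + sum(sib$d)
  individuals <- 6 * n

  m2 <- penetrance_moments(config$penetrance)
  z_mean <- unname(m2["mean"])
  sigma2 <- unname(m2["m2"] - m2["mean"]^2)
  susc_affected <- sum(d_mz[mz$susc, ]) + sum(dz$d[, 1][dz$susc1])
  prob_affected <- sum(d_mz) + sum(dz$d[, 1])

  structure(list(
    mz = mz_counts, dz = tally(dz$d, zyg = "DZ"),
    sibling = tally(sib$d, zyg = "sibling"),
    mz_by_carrier = mz_by_carrier,
    n_pairs = n,
    affected = affected, individuals = individuals,
    double_ascertained = double, pi_hat = pi_hat,
    config = config,
    truth = list(p_g = config$p_g, z = z_mean, sigma2 = sigma2,
                 b_prime = unname(m2["m2"] / m2["mean"]),
                 g = if (prob_affected > 0) susc_affected / prob_affected else NA_real_,
                 carrier_freq = cf)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated twin cohort: %d pairs/zygosity (seed %d)\n",
              x$n_pairs, x$config$seed))
  print(x$mz); print(x$dz); print(x$sibling)
  cat(sprintf("  truth: P(G) = %g, z = %.3f, sigma2 = %.4f, E[z^2]/E[z] = %.3f\n",
              x$truth$p_g, x$truth$z, x$truth$sigma2, x$truth$b_prime))
  invisible(x)
}

#' Recover susceptibility estimates from a simulated cohort
#'
#' Runs the observational estimation chain on a synthetic cohort: prevalence
#' from the simulated individuals, proband-wise MZ concordance using the
#' realized double-ascertainment factor, the sibling/DZ shared-environment
#' adjustment (optionally disabled), and the P(G) bounds.  Returns estimates
#' alongside the cohort truth for assertion in validation tests.
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @param g susceptible-case fraction used for the lower bound; defaults to
#'   the cohort's realized value.
#' @param apply_iu_adjustment logical; apply the sibling/DZ factor
#'   (default TRUE).
#' @return A list with \code{prevalence}, \code{probandwise_mz}, \code{b},
#'   \code{p_g_lower}, \code{p_g_upper}, and the cohort \code{truth}.
#' @export
recover_parameters <- function(cohort, g = NULL,
                               apply_iu_adjustment = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(g)) g <- cohort$truth$g
  prev <- cohort$affected / cohort$individuals
  f <- 1 + cohort$pi_hat
  pw <- probandwise_concordance(cohort$mz, f)
  iu_fac <- 1
  if (apply_iu_adjustment) {
    dz <- pairwise_concordance(cohort$dz)
    sb <- pairwise_concordance(cohort$sibling)
    if (dz > 0 && sb <= dz) iu_fac <- sb / dz
  }
  b <- pw * iu_fac
  list(prevalence = prev, probandwise_mz = pw, b = b,
       p_g_lower = prob_g_lower(prev, g, b),
       p_g_upper = prob_g_upper(prev, b),
       g = g, truth = cohort$truth)
}
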