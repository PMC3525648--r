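#' Upper bound on the genetically susceptible population fraction
#'
#' The simultaneous-constraint argument on the high- and low-penetrance
#' halves of the susceptible set yields the bound P(G) <= 2 P(D) / b, where b
#' is the adjusted MZ-twin concordance (the penetrance of the shared-genotype
#' trait).  Whichever half of the susceptible set holds at least half of its
#' probability mass, its mean penetrance is at least b/2, and the disease
#' cases it alone produces cannot exceed the population prevalence.
#'
#' @param prevalence lifetime disease probability P(D).
#' @param b adjusted MZ-twin concordance, > 0.
#' @return The upper bound on P(G).
#' @examples
#' prob_g_upper(0.0015, 0.134)  # ~0.022: at most 2.2% susceptible
#' @export
prob_g_upper <- function(prevalence, b) {
  if (any(b <= 0)) stop("adjusted concordance b must be positive")
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence must lie in [0, 1]")
  2 * prevalence / b
}

#' Lower bound on the genetically susceptible population fraction
#'
#' Conservation of genetic cases gives P(G) = g P(D) / z, where g is the
#' fraction of cases occurring in susceptible individuals and z the mean
#' penetrance of the susceptible set.  Replacing z by any admissible upper
#' bound z_upper yields a lower bound on P(G).  The regional-registry
#' convention takes z_upper = b (the adjusted MZ concordance, which
#' overestimates z because co-twin concordance is size-biased towards
#' high-penetrance genotypes); a tighter, distribution-specific z_max may be
#' supplied instead.
#'
#' @param prevalence lifetime disease probability P(D).
#' @param g fraction of cases that are genetically susceptible, in \[0, 1\].
#' @param z_upper admissible upper bound on the susceptible-set mean
#'   penetrance, > 0.
#' @return The lower bound on P(G).
#' @examples
#' prob_g_lower(0.00144, 0.94, 0.1192)  # Sardinia: ~1.1%
#' @export
prob_g_lower <- function(prevalence, g, z_upper) {
  if (any(z_upper <= 0)) stop("`z_upper` must be positive")
  if (any(g < 0 | g > 1)) stop("`g` must lie in [0, 1]")
  g * prevalence / z_upper
}

#' Estimate the susceptible-case fraction g from two-way partitions
#'
#' Estimates g = P(G|D), the fraction of cases occurring in genetically
#' susceptible individuals, by joint feasibility over one or more two-way
#' genetic partitions of the case population (e.g. risk-allele carrier
#' status, gender).
#'
#' For a partition with population marker frequency A0, case marker frequency
#' A, and adjusted subgroup concordances t (marker-positive) and s
#' (marker-negative), the non-genetic cases carry the marker at the
#' population frequency A0 (the marker is susceptibility-related, and the
#' susceptible set is a tiny population fraction), which forces
#' \deqn{g_1 = [A - (1-g)A_0]/A, \quad g_2 = [(1-A) - (1-g)(1-A_0)]/(1-A)}
#' where g1, g2 are the susceptible fractions of the two case subgroups.
#' Feasibility of a value of g requires g1, g2 in \[0, 1\] and the
#' susceptible-only concordances t' = t/g1, s' = s/g2 and b' = b/g to be
#' valid probabilities.  For a partition whose enrichment operates through
#' allele frequency alone (s/b within \code{mech_tol} of 1), carrier status
#' does not alter penetrance among susceptibles, so additionally t' = s' = b'
#' within \code{ratio_tol}; this equality is what identifies g sharply: the
#' small excess of t over s is then explained only by the non-genetic cases
#' diluting the marker-negative subgroup.
#'
#' The admissible set is located by a deterministic grid search with interval
#' refinement.
#'
#' @param partitions a list of \code{\link{partition_analysis}} objects (a
#'   single one may be passed bare).
#' @param b overall adjusted MZ concordance; defaults to the \code{b} carried
#'   by the first partition.
#' @param mech_tol tolerance on |s/b - 1| used to classify a partition as
#'   allele-frequency-only (default 0.10).
#' @param ratio_tol tolerance on the susceptible-only concordance equality
#'   |t'/b' - 1| and |s'/b' - 1| for such partitions (default 0.01: published
#'   three-decimal concordance rates carry up to ~0.35\% combined rounding
#'   error, and the equality itself is a modelling idealization).
#' @param grid_step initial grid step over g (default 1e-4).
#' @return An object of class \code{"g_estimate"}: a list with \code{g_lower},
#'   \code{g_upper}, the per-partition admissible \code{intervals}, and the
#'   settings used.
#' @examples
#' hla <- partition_analysis(A0 = 0.24, A = 0.55, t = 0.139, s = 0.129,
#'                           b = 0.134, label = "carrier")
#' estimate_g(hla)  # g >= ~0.94
#' @export
estimate_g <- function(partitions, b = NULL, mech_tol = 0.10,
                       ratio_tol = 0.01, grid_step = 1e-4) {
  if (inherits(partitions, "partition_analysis")) partitions <- list(partitions)
  if (length(partitions) == 0) stop("at least one partition is required")
  if (is.null(b)) b <- partitions[[1]]$b
  if (is.null(b) || is.na(b) || b <= 0)
    stop("an overall adjusted concordance b is required")

  feasible_one <- function(p, g) {
    bp <- b / g
    if (bp > 1) return(FALSE)
    g1 <- (p$A - (1 - g) * p$A0) / p$A
    g2 <- ((1 - p$A) - (1 - g) * (1 - p$A0)) / (1 - p$A)
    if (g1 < 0 || g1 > 1 || g2 < 0 || g2 > 1) return(FALSE)
    if (p$t > g1 || p$s > g2) return(FALSE)       # t', s' <= 1
    if (isTRUE(p$mechanism1)) {
      tp <- p$t / g1
      sp <- p$s / g2
      if (abs(tp / bp - 1) > ratio_tol) return(FALSE)
      if (abs(sp / bp - 1) > ratio_tol) return(FALSE)
    }
    TRUE
  }

  interval_for <- function(p) {
    gs <- seq(grid_step, 1, by = grid_step)
    ok <- vapply(gs, function(g) feasible_one(p, g), logical(1))
    if (!any(ok)) return(c(NA_real_, NA_real_))
    lo <- gs[which(ok)[1]]
    hi <- gs[rev(which(ok))[1]]
    ## refine the endpoints by bisection on the feasibility indicator
    refine <- function(a, bnd, increasing) {
      for (i in 1:40) {
        mid <- (a + bnd) / 2
        if (feasible_one(p, mid) == increasing) bnd <- mid else a <- mid
      }
      bnd
    }
    if (lo > grid_step) lo <- refine(lo - grid_step, lo, TRUE)
    if (hi < 1) hi <- refine(hi + grid_step, hi, TRUE)
    c(lo, hi)
  }

  partitions <- lapply(partitions, function(p) {
    if (is.null(p$mechanism1) || is.na(p$mechanism1))
      p$mechanism1 <- abs(p$s / b - 1) <= mech_tol
    p
  })
  ivs <- lapply(partitions, interval_for)
  labels <- vapply(seq_along(partitions), function(i) {
    lb <- partitions[[i]]$label
    if (is.null(lb)) paste0("partition", i) else lb
  }, character(1))
  names(ivs) <- labels

  lo <- max(vapply(ivs, `[`, numeric(1), 1))
  hi <- min(vapply(ivs, `[`, numeric(1), 2))
  if (is.na(lo) || is.na(hi) || lo > hi) {
    msg <- paste(vapply(labels, function(l)
      sprintf("  %s: [%s, %s]", l,
              format(ivs[[l]][1], digits = 4), format(ivs[[l]][2], digits = 4)),
      character(1)), collapse = "\n")
    stop("no jointly admissible value of g; per-partition intervals:\n", msg)
  }
  structure(list(g_lower = lo, g_upper = hi, intervals = ivs, b = b,
                 mech_tol = mech_tol, ratio_tol = ratio_tol),
            class = "g_estimate")
}

#' @export
print.g_estimate <- function(x, ...) {
  cat(sprintf("Susceptible-case fraction g: admissible interval [%.4f, %.4f]\n",
              x$g_lower, x$g_upper))
  for (nm in names(x$intervals))
    cat(sprintf("  %s: [%.4f, %.4f]\n", nm,
                x$intervals[[nm]][1], x$intervals[[nm]][2]))
  invisible(x)
}

#' Penetrance decomposition of the susceptible set
#'
#' Converts the susceptibility estimates into a range for the expected
#' penetrance z of the susceptible set via the conservation identity
#' z P(G) = g P(D), and recovers the within-set penetrance variance from the
#' size-biased concordance identity b' = z + sigma^2 / z (the co-twin of an
#' affected proband samples genotypes proportionally to their penetrance, so
#' the adjusted susceptible-only concordance is the size-biased mean
#' E\[z_i^2\]/E\[z_i\]).
#'
#' A second constraint interval for z (for example, derived from subgroup
#' penetrances) may be supplied; the returned range is the coherent
#' intersection, with a disjoint pair reported as an error.  Boundaries whose
#' constraint set cannot identify them (the subgroup-derived lower boundary
#' is not identified without distributional assumptions) are minimally
#' modified to the conservation bound.
#'
#' @param prevalence lifetime disease probability P(D).
#' @param g susceptible-case fraction.
#' @param p_g_bounds numeric length-2: lower and upper bounds on P(G).
#' @param b adjusted MZ concordance (b' = b/g is the susceptible-only rate).
#' @param z_constraint optional numeric length-2 secondary interval for z.
#' @return A list of class \code{"penetrance_range"} with the z range, the
#'   implied P(G) at each endpoint, b', and the sigma^2 range.
#' @examples
#' penetrance_range(0.0015, 0.94, c(0.0094, 0.0224), b = 0.134)
#' @export
penetrance_range <- function(prevalence, g, p_g_bounds, b,
                             z_constraint = NULL) {
  if (length(p_g_bounds) != 2 || any(p_g_bounds <= 0) ||
      p_g_bounds[1] > p_g_bounds[2])
    stop("`p_g_bounds` must be an increasing positive pair")
  z_lo <- g * prevalence / p_g_bounds[2]
  z_hi <- g * prevalence / p_g_bounds[1]
  if (!is.null(z_constraint)) {
    zc <- sort(as.numeric(z_constraint))
    lo2 <- max(z_lo, zc[1])
    hi2 <- min(z_hi, zc[2])
    if (lo2 > hi2)
      stop(sprintf(paste0("incoherent penetrance constraints: conservation range ",
                          "[%.4g, %.4g] does not intersect [%.4g, %.4g]"),
                   z_lo, z_hi, zc[1], zc[2]))
    z_lo <- lo2; z_hi <- hi2
  }
  b_prime <- b / g
  if (b_prime > 1) stop("b/g exceeds 1; g is too small for the supplied b")
  if (z_hi > b_prime) z_hi <- b_prime      # size-biased mean dominates the mean
  z <- c(lower = z_lo, upper = z_hi)
  sigma2 <- pmax((b_prime - z) * z, 0)
  names(sigma2) <- c("at_z_lower", "at_z_upper")
  structure(list(z = z,
                 p_g = g * prevalence / z,
                 b_prime = b_prime,
                 sigma2 = sigma2,
                 g = g, prevalence = prevalence),
            class = "penetrance_range")
}

#' @export
print.penetrance_range <- function(x, ...) {
  cat(sprintf("Susceptible-set penetrance z in [%.4f, %.4f] (b' = %.4f)\n",
              x$z[1], x$z[2], x$b_prime))
  cat(sprintf("  implied P(G) in [%.4g, %.4g]; sigma^2 in [%.4g, %.4g]\n",
              min(x$p_g), max(x$p_g), min(x$sigma2), max(x$sigma2)))
  invisible(x)
}

#' Upper bound on the mass of near-unity-penetrance genotypes
#'
#' "Purely genetic" cases arise from susceptible genotypes whose penetrance
#' is near one (they do not depend on environmental events).  Given the first
#' two moments (z, sigma^2) of the penetrance distribution within the
#' susceptible set, the largest probability mass that any distribution can
#' place at or above a penetrance threshold is attained by an extremal
#' two-point distribution and equals sigma^2 / (sigma^2 + (threshold - z)^2)
#' for threshold > z (the one-sided Chebyshev bound), and 1 otherwise.
#'
#' @param z expected penetrance of the susceptible set.
#' @param sigma2 penetrance variance within the set.
#' @param threshold the near-unity penetrance defining "purely genetic"
#'   genotypes, in (0.5, 1\].
#' @return Upper bound on the susceptible-set fraction with penetrance at or
#'   above the threshold.
#' @examples
#' purely_genetic_bound(0.1, 0.01, 0.9)   # small
#' purely_genetic_bound(1, 0, 0.9)        # all mass at penetrance 1
#' @export
purely_genetic_bound <- function(z, sigma2, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1)
    stop("`threshold` must lie in (0.5, 1]")
  if (sigma2 < 0) stop("`sigma2` must be non-negative")
  if (threshold <= z) return(1)
  unname(pmin(1, sigma2 / (sigma2 + (threshold - z)^2)))
}

#' Sensitivity sweep over the observable inputs
#'
#' Recomputes the adjusted concordance and susceptibility bounds for each
#' combination of overridden observables.  Called without overrides it runs
#' the standard named scenarios: prevalence doubled to 0.003 (the 45-55-year
#' age-bracket refinement), MZ proband-wise concordance 0.35, and sibling
#' concordance 0.035, plus their combination.
#'
#' @param base an \code{\link{epi_observables}} object.
#' @param overrides named list of value vectors over any of
#'   \code{prevalence}, \code{mz_raw}, \code{dz_raw}, \code{sib_raw};
#'   combinations are expanded on a full grid.
#' @param g susceptible-case fraction used for the lower bounds
#'   (default 0.94).
#' @return A data frame with one row per scenario: the overridden inputs,
#'   b, and the P(G) bounds.
#' @examples
#' sensitivity_sweep(ms_observables(), list(prevalence = c(0.0015, 0.003)))
#' @export
sensitivity_sweep <- function(base, overrides = NULL, g = 0.94) {
  fields <- c("prevalence", "mz_raw", "dz_raw", "sib_raw")
  if (is.null(overrides)) {
    overrides <- list(prevalence = c(base$prevalence, 0.003),
                      mz_raw = c(base$mz_raw, 0.35),
                      sib_raw = c(base$sib_raw, 0.035))
  }
  bad <- setdiff(names(overrides), fields)
  if (length(bad))
    stop("unknown observable field(s): ", paste(bad, collapse = ", "))
  grid <- do.call(expand.grid, c(overrides, KEEP.OUT.ATTRS = FALSE))
  for (f in setdiff(fields, names(grid))) grid[[f]] <- base[[f]]
  grid <- grid[fields]
  grid$iu_factor <- grid$sib_raw / grid$dz_raw
  grid$b <- grid$mz_raw * grid$iu_factor
  grid$p_g_upper <- prob_g_upper(grid$prevalence, grid$b)
  grid$p_g_lower <- prob_g_lower(grid$prevalence, g, grid$b)
  grid
}

#' Regional / cross-disease susceptibility table
#'
#' Applies the P(G) bounds to a registry of regions (or diseases), each with
#' a prevalence range and a proband-wise MZ concordance.  In
#' \code{"iu_adjusted"} mode the concordance is first multiplied by the
#' shared-environment factor and the lower bound uses the susceptible-case
#' fraction g with z_upper = b; in \code{"unadjusted"} mode (used for
#' registries without sibling/DZ data, where the intra-uterine environment is
#' assumed to have no impact) the factor is 1 and both ends use the
#' upper-bound formula.
#'
#' @param registry data frame with a name column and either
#'   \code{prevalence_low_per1e5}/\code{prevalence_high_per1e5} (per 100,000)
#'   or \code{prevalence_low}/\code{prevalence_high} (decimals), plus
#'   \code{probandwise_mz} (decimal).
#' @param mode \code{"iu_adjusted"} or \code{"unadjusted"}.
#' @param iu_factor shared-environment factor for \code{"iu_adjusted"} mode.
#' @param g susceptible-case fraction for the lower bounds (default 0.94).
#' @return The registry augmented with \code{b}, \code{p_g_lower},
#'   \code{p_g_upper} (decimals).
#' @examples
#' region_table(ms_region_registry(), iu_factor = 0.029 / 0.054)
#' @export
region_table <- function(registry, mode = c("iu_adjusted", "unadjusted"),
                         iu_factor = 1, g = 0.94) {
  mode <- match.arg(mode)
  if (nrow(registry) == 0) {
    warning("empty registry; returning empty table")
    registry$b <- registry$p_g_lower <- registry$p_g_upper <- numeric(0)
    return(registry)
  }
  if (all(c("prevalence_low_per1e5", "prevalence_high_per1e5") %in%
          names(registry))) {
    plo <- registry$prevalence_low_per1e5 / 1e5
    phi <- registry$prevalence_high_per1e5 / 1e5
  } else if (all(c("prevalence_low", "prevalence_high") %in% names(registry))) {
    plo <- registry$prevalence_low
    phi <- registry$prevalence_high
  } else stop("registry must carry prevalence_low/high columns (decimal or per1e5)")
  if (!"probandwise_mz" %in% names(registry))
    stop("registry must carry a `probandwise_mz` column")
  fac <- if (mode == "iu_adjusted") iu_factor else 1
  b <- registry$probandwise_mz * fac
  registry$b <- b
  registry$p_g_lower <- if (mode == "iu_adjusted")
    prob_g_lower(plo, g, b) else prob_g_upper(plo, b)
  registry$p_g_upper <- prob_g_upper(phi, b)
  registry
}
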