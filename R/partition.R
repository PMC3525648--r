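#' Two-way genetic partition of a case population
#'
#' Bundles the observables describing a two-way partition of cases and
#' population by a genetic characteristic (risk-allele carrier status,
#' gender): the population marker frequency A0 = P(Gx+), the case marker
#' frequency A = P(Gx+|D), and the adjusted subgroup concordances t
#' (marker-positive probands) and s (marker-negative probands).
#'
#' @param A0 marker frequency in the population.
#' @param A marker frequency among cases.
#' @param t adjusted MZ concordance for marker-positive probands.
#' @param s adjusted MZ concordance for marker-negative probands.
#' @param b overall adjusted MZ concordance for the same study (optional but
#'   required by most downstream analyses).
#' @param label partition name used in reports.
#' @param mechanism1 logical; force the allele-frequency-only classification
#'   instead of deriving it from s/b.  Leave \code{NA} to auto-classify.
#' @return An object of class \code{"partition_analysis"}.
#' @examples
#' partition_analysis(A0 = 0.24, A = 0.55, t = 0.139, s = 0.129, b = 0.134,
#'                    label = "carrier")
#' @export
partition_analysis <- function(A0, A, t, s, b = NULL, label = NULL,
                               mechanism1 = NA) {
  for (v in c(A0 = A0, A = A, t = t, s = s))
    if (is.na(v) || v < 0 || v > 1) stop("all partition inputs must lie in [0, 1]")
  if (A0 %in% c(0, 1)) stop("degenerate partition: A0 must lie strictly in (0, 1)")
  structure(list(A0 = A0, A = A, t = t, s = s, b = b, label = label,
                 mechanism1 = mechanism1),
            class = "partition_analysis")
}

#' @export
print.partition_analysis <- function(x, ...) {
  cat(sprintf("Partition%s: A0 = %g, A = %g, t = %g, s = %g%s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$A0, x$A, x$t, x$s,
              if (is.null(x$b)) "" else sprintf(", b = %g", x$b)))
  invisible(x)
}

#' Classify the enrichment mechanism of a partition
#'
#' A genetic marker can be enriched among cases either because carriers are
#' more likely to be susceptible (an allele-frequency mechanism) or because
#' susceptible carriers have higher penetrance (a penetrance mechanism).  The
#' ratio of the marker-negative adjusted concordance to the overall adjusted
#' concordance, s/b, proxies the susceptible-only ratio s'/b' when nearly all
#' cases are genetic (g close to 1): a ratio near 1 means penetrance is
#' unchanged in the marker-negative subgroup, so the enrichment must operate
#' through allele frequency alone.
#'
#' @param s_adj adjusted concordance of the marker-negative subgroup.
#' @param b_adj overall adjusted concordance, > 0.
#' @param tolerance classification tolerance on |s/b - 1| (default 0.10).
#' @return A list with \code{ratio} and \code{mechanism}, one of
#'   \code{"allele_frequency_only"}, \code{"both"},
#'   \code{"penetrance_reduced_in_carriers"}.
#' @examples
#' enrichment_mechanism(0.129, 0.134)  # allele frequency only
#' enrichment_mechanism(0.036, 0.134)  # both mechanisms
#' @export
enrichment_mechanism <- function(s_adj, b_adj, tolerance = 0.10) {
  if (b_adj <= 0) stop("`b_adj` must be positive")
  ratio <- s_adj / b_adj
  mech <- if (abs(ratio - 1) <= tolerance) "allele_frequency_only"
          else if (ratio < 1) "both"
          else "penetrance_reduced_in_carriers"
  list(ratio = ratio, mechanism = mech)
}

#' Hardy-Weinberg expected genotype-dose frequencies
#'
#' Derives the allele frequency q from a single anchor frequency and returns
#' the Hardy-Weinberg genotype triple (q^2, 2q(1-q), (1-q)^2) for two, one,
#' and zero copies of the allele.
#'
#' @param value the anchor frequency, in (0, 1) (boundary values 0 and 1
#'   return the degenerate triples).
#' @param anchor which frequency is supplied: the two-copy (homozygote)
#'   frequency, the carrier frequency 1 - (1-q)^2, or the zero-copy
#'   frequency.
#' @return Named numeric vector \code{c(freq_2copy, freq_1copy, freq_0copy)}.
#' @examples
#' hwe_expected(0.07)                      # (0.07, 0.39, 0.54)
#' hwe_expected(0.24, "carrier_freq")      # (0.016, 0.224, 0.76)
#' @export
hwe_expected <- function(value, anchor = c("two_copy_freq", "carrier_freq",
                                           "zero_copy_freq")) {
  anchor <- match.arg(anchor)
  if (is.na(value) || value < 0 || value > 1)
    stop("anchor frequency must lie in [0, 1]")
  q <- switch(anchor,
              two_copy_freq = sqrt(value),
              carrier_freq = 1 - sqrt(1 - value),
              zero_copy_freq = 1 - sqrt(value))
  c(freq_2copy = q^2, freq_1copy = 2 * q * (1 - q), freq_0copy = (1 - q)^2)
}

#' Genotype-dose odds ratios, cases versus controls
#'
#' Odds of each genotype class in cases divided by the odds of the same class
#' in controls, with the zero-copy class as reference; the carrier odds ratio
#' pools the one- and two-copy classes.
#'
#' @param cases,controls numeric vectors or one-row data frames with
#'   \code{freq_2copy}, \code{freq_1copy}, \code{freq_0copy} (each triple
#'   summing to 1).
#' @return Named numeric vector \code{c(or_2copy, or_1copy, or_carrier)}.
#' @examples
#' genotype_odds_ratios(c(0.07, 0.39, 0.54), c(0.012, 0.186, 0.80))
#' @export
genotype_odds_ratios <- function(cases, controls) {
  get3 <- function(x) {
    if (is.data.frame(x)) x <- unlist(x[c("freq_2copy", "freq_1copy", "freq_0copy")])
    x <- as.numeric(x)
    if (length(x) != 3 || any(x < 0)) stop("genotype triple must be 3 non-negative frequencies")
    if (abs(sum(x) - 1) > 1e-6) x <- x / sum(x)
    x
  }
  ca <- get3(cases); co <- get3(controls)
  if (ca[3] <= 0 || co[3] <= 0)
    stop("zero-copy reference frequency must be positive in both groups")
  c(or_2copy = (ca[1] / ca[3]) / (co[1] / co[3]),
    or_1copy = (ca[2] / ca[3]) / (co[2] / co[3]),
    or_carrier = ((ca[1] + ca[2]) / ca[3]) / ((co[1] + co[2]) / co[3]))
}

#' Test for geometric (independent) allele-dose selection
#'
#' Compares the observed one- and two-copy odds ratios against the geometric
#' weighting (1, w, w^2) in which each risk-allele copy is selected
#' independently, and the dominant (1, w, w) and recessive (1, 1, w)
#' alternatives.  Each scheme is scored by the relative deviation of the
#' observed two-copy enrichment from its prediction; ties break toward
#' geometric.
#'
#' @param or_1copy one-copy odds ratio (> 0), the weight w.
#' @param or_2copy two-copy odds ratio (> 0).
#' @param tolerance maximum relative deviation for the geometric call
#'   (default 0.25).
#' @return A list with \code{w}, \code{w2}, \code{geometric_deviation},
#'   per-scheme \code{deviations}, and the \code{classification}.
#' @examples
#' geometric_selection_test(3.1, 9.3)   # deviation ~3%: geometric
#' @export
geometric_selection_test <- function(or_1copy, or_2copy, tolerance = 0.25) {
  if (or_1copy <= 0 || or_2copy <= 0) stop("odds ratios must be positive")
  w <- or_1copy
  dev <- c(geometric = abs(or_2copy - w^2) / w^2,
           dominant = abs(or_2copy - w) / w,
           recessive = abs(or_1copy - 1) / 1)
  best <- names(dev)[which.min(dev)]   # which.min keeps the first (geometric) on ties
  cls <- if (dev[["geometric"]] <= tolerance) "geometric" else best
  if (cls == "geometric" && best != "geometric")
    warning(sprintf("geometric within tolerance but %s deviates less", best))
  list(w = w, w2 = or_2copy, geometric_deviation = unname(dev[["geometric"]]),
       deviations = dev, classification = cls)
}

#' Susceptible fraction among marker carriers
#'
#' For a partition whose enrichment operates through allele frequency alone,
#' carriers are over-represented among susceptibles to the same degree as
#' among cases, so P(G|Gx+) = A P(G) / A0.
#'
#' @param A marker frequency among cases.
#' @param A0 marker frequency in the population, > 0.
#' @param p_g susceptible population fraction P(G) (use the upper bound for
#'   an upper bound on the result).
#' @return P(G|Gx+), the susceptible fraction among carriers.
#' @examples
#' carrier_susceptibility(0.55, 0.24, 0.022)  # ~0.050: under 5% of carriers
#' @export
carrier_susceptibility <- function(A, A0, p_g) {
  if (A0 <= 0) stop("`A0` must be positive")
  A * p_g / A0
}

#' Fraction of susceptible cases whose susceptibility depends on the allele
#'
#' Assumes susceptible cases split into those whose susceptibility depends on
#' the allele (all of whom carry it) and the rest, who carry it at the
#' population frequency A0.  Solving x + (1 - x) A0 = A gives
#' x = (A - A0) / (1 - A0).
#'
#' @param A marker frequency among cases.
#' @param A0 marker frequency in the population, < 1.
#' @return The dependence fraction in \[0, 1\]; a protective direction
#'   (A < A0) returns 0 with a warning.
#' @examples
#' allele_contribution_fraction(0.55, 0.24)  # ~0.41
#' @export
allele_contribution_fraction <- function(A, A0) {
  if (A0 >= 1) stop("`A0` must be below 1")
  if (A < A0) {
    warning("marker is depleted among cases (protective direction); returning 0")
    return(0)
  }
  (A - A0) / (1 - A0)
}

#' Maximum susceptible fraction among risk-allele carriers
#'
#' Even if every susceptible individual carried the risk allele, the fraction
#' of carriers who are susceptible cannot exceed P(G) divided by the carrier
#' frequency: p_g / (1 - (1 - maf)^2) in carrier mode, or p_g / maf^2 when
#' the risk is assumed to be confined to homozygotes.
#'
#' @param p_g_upper upper bound on the susceptible population fraction.
#' @param maf risk-allele frequency in (0, 1\].
#' @param mode \code{"carrier"} or \code{"homozygote"}.
#' @return The maximum susceptible carrier (or homozygote) fraction.
#' @examples
#' max_susceptible_carriers(0.022, 0.40)                # ~0.034
#' max_susceptible_carriers(0.022, 0.40, "homozygote")  # ~0.138
#' @export
max_susceptible_carriers <- function(p_g_upper, maf,
                                     mode = c("carrier", "homozygote")) {
  mode <- match.arg(mode)
  if (maf <= 0 || maf > 1) stop("`maf` must lie in (0, 1]")
  denom <- if (mode == "carrier") 1 - (1 - maf)^2 else maf^2
  if (denom <= 0) stop("carrier frequency is zero")
  p_g_upper / denom
}

#' Stepwise enrichment check across population, cases, concordant cases
#'
#' Reports the enrichment of a marker in moving from the general population
#' to the case population (first step) and from cases to the co-twins of
#' affected probands who themselves develop the disease (second step).  An
#' allele-frequency mechanism produces a first-step enrichment only; a
#' penetrance mechanism keeps enriching at the second step.
#'
#' @param freq_population marker frequency in the population.
#' @param freq_cases marker frequency among cases.
#' @param freq_concordant_cases marker frequency among affected co-twins of
#'   affected probands.
#' @param flat_tol ratio tolerance for calling a step flat (default 0.10).
#' @return A list with the two step ratios and a \code{mechanism} flag.
#' @examples
#' continued_enrichment_check(0.24, 0.55, 0.57)  # flat second step
#' continued_enrichment_check(0.50, 0.68, 0.92)  # continued enrichment
#' @export
continued_enrichment_check <- function(freq_population, freq_cases,
                                       freq_concordant_cases,
                                       flat_tol = 0.10) {
  f <- c(freq_population, freq_cases, freq_concordant_cases)
  if (any(is.na(f) | f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  step1 <- if (freq_population > 0) freq_cases / freq_population else NA_real_
  step2 <- if (freq_cases > 0) freq_concordant_cases / freq_cases else NA_real_
  second_flat <- !is.na(step2) && abs(step2 - 1) <= flat_tol
  list(step1 = step1, step2 = step2,
       second_step_flat = second_flat,
       mechanism = if (second_flat) "allele_frequency_only" else "penetrance_present")
}
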