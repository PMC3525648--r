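#' Epidemiological observables
#'
#' The directly observable inputs of the model: lifetime prevalence, raw
#' proband-wise MZ concordance, DZ and sibling concordance, the female
#' fraction of cases, and the risk-marker carrier fraction among cases and in
#' the population.  All values are probabilities in \[0, 1\].
#'
#' A warning (not an error) is issued when the expected ordering
#' MZ >= DZ >= sibling does not hold, since real registries occasionally
#' violate it.
#'
#' @param prevalence lifetime disease probability P(D) in the population.
#' @param mz_raw raw proband-wise MZ-twin concordance.
#' @param dz_raw raw DZ-twin concordance.
#' @param sib_raw raw sibling concordance.
#' @param female_fraction_cases P(F|D), optional.
#' @param carrier_fraction_cases P(marker+|D) (the quantity A), optional.
#' @param carrier_fraction_population P(marker+) (the quantity A0), optional.
#' @param by_gender optional named list of per-gender variants (each itself a
#'   list with any of the fields above), kept for reporting; the pooled values
#'   drive all adjustments.
#' @return An object of class \code{"epi_observables"}.
#' @examples
#' obs <- epi_observables(prevalence = 0.0015, mz_raw = 0.25,
#'                        dz_raw = 0.054, sib_raw = 0.029)
#' iu_adjustment_factor(obs)
#' @export
epi_observables <- function(prevalence, mz_raw, dz_raw, sib_raw,
                            female_fraction_cases = NA_real_,
                            carrier_fraction_cases = NA_real_,
                            carrier_fraction_population = NA_real_,
                            by_gender = NULL) {
  fields <- list(prevalence = prevalence, mz_raw = mz_raw, dz_raw = dz_raw,
                 sib_raw = sib_raw,
                 female_fraction_cases = female_fraction_cases,
                 carrier_fraction_cases = carrier_fraction_cases,
                 carrier_fraction_population = carrier_fraction_population)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.na(v) && (v < 0 || v > 1))
      stop(sprintf("`%s` must be a probability in [0, 1]", nm))
  }
  if (!any(is.na(c(mz_raw, dz_raw, sib_raw))) &&
      !(mz_raw >= dz_raw && dz_raw >= sib_raw))
    warning("expected concordance ordering MZ >= DZ >= sibling does not hold")
  structure(c(fields, list(by_gender = by_gender)), class = "epi_observables")
}

#' @export
print.epi_observables <- function(x, ...) {
  cat("Epidemiological observables:\n")
  cat(sprintf("  prevalence P(D)          : %g\n", x$prevalence))
  cat(sprintf("  MZ / DZ / sib concordance: %g / %g / %g\n",
              x$mz_raw, x$dz_raw, x$sib_raw))
  if (!is.na(x$female_fraction_cases))
    cat(sprintf("  P(F|D)                   : %g\n", x$female_fraction_cases))
  if (!is.na(x$carrier_fraction_cases))
    cat(sprintf("  carrier freq cases/pop   : %g / %g\n",
                x$carrier_fraction_cases, x$carrier_fraction_population))
  invisible(x)
}

#' Shared intra-uterine environment adjustment factor
#'
#' MZ twins share both their genotype and an intra-uterine (IU) / childhood
#' environment; DZ twins share the IU environment but only half their genes,
#' while ordinary siblings share genes to the same degree as DZ twins but not
#' the IU environment.  The sibling/DZ concordance ratio therefore isolates
#' the IU excess, and multiplying the MZ concordance by it leaves only the
#' effect of sharing an identical genotype.
#'
#' The factor is computed from the pooled sibling and DZ rates and applied
#' uniformly to all subgroups: only the pooled factor reproduces the published
#' subgroup-adjusted penetrances, and per-gender sibling/DZ ratios are far
#' noisier (tiny male sibling counts).  Per-subgroup factors can still be
#' formed by calling this function on subgroup observables explicitly.
#'
#' @param obs an \code{\link{epi_observables}} object.
#' @param mode \code{"apply_iu_adjustment"} (default) or \code{"none"}.
#' @return An \code{\link{adjustment_factors}} object with the IU/CH factor
#'   set to sib_raw / dz_raw (or 1 in mode \code{"none"}).
#' @examples
#' iu_adjustment_factor(epi_observables(0.0015, 0.25, 0.054, 0.029))
#' @export
iu_adjustment_factor <- function(obs, mode = c("apply_iu_adjustment", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(adjustment_factors(mode = "none"))
  if (is.na(obs$dz_raw) || obs$dz_raw <= 0)
    stop("DZ concordance must be positive to form the sibling/DZ ratio")
  fac <- obs$sib_raw / obs$dz_raw
  if (fac > 1) {
    warning("sibling concordance exceeds DZ concordance; no IU excess, factor set to 1")
    fac <- 1
  }
  adjustment_factors(iu_ch_factor = fac)
}

#' Apply the shared-environment adjustment to a concordance rate
#'
#' Multiplies a (proband-wise) concordance rate by the IU/CH factor, yielding
#' the genotype-sharing penetrance b (or its subgroup analogues t and s).
#'
#' @param raw_probandwise proband-wise concordance rate.
#' @param factors an \code{\link{adjustment_factors}} object or bare factor.
#' @return The adjusted concordance.
#' @examples
#' adjust_concordance(0.25, 0.029 / 0.054)  # ~0.134
#' @export
adjust_concordance <- function(raw_probandwise, factors) {
  fac <- if (inherits(factors, "adjustment_factors"))
    factors$iu_ch_factor else as.numeric(factors)
  if (any(raw_probandwise < 0 | raw_probandwise > 1))
    stop("concordance rates must lie in [0, 1]")
  raw_probandwise * fac
}

#' Renormalize subgroup penetrances to a target mixture
#'
#' Subgroup-adjusted concordances (t for the marker-positive, s for the
#' marker-negative subgroup) inherit rounding and sampling error from the
#' subgroup tables, so their case-weighted mixture need not equal the overall
#' adjusted concordance b estimated from the pooled table.  This rescales t
#' and s by a common factor so the mixture constraint
#' \code{weight_plus * t + (1 - weight_plus) * s = b_target} holds exactly.
#'
#' When the pooled adjusted rate for the same table is available it should be
#' passed as \code{b_subgroup}: rescaling against the pooled rate (rather than
#' the re-mixed subgroup values) is what keeps the subgroup table internally
#' consistent with its own totals row.
#'
#' @param t adjusted concordance of the marker-positive subgroup.
#' @param s adjusted concordance of the marker-negative subgroup.
#' @param weight_plus case fraction of the marker-positive subgroup.
#' @param b_target the overall adjusted concordance the mixture must equal.
#' @param b_subgroup optional: the subgroup table's own pooled adjusted rate;
#'   defaults to the mixture \code{weight_plus * t + (1 - weight_plus) * s}.
#' @return A list with elements \code{t}, \code{s}, \code{factor}, and
#'   \code{b} (the achieved mixture, equal to \code{b_target} up to machine
#'   precision when the default \code{b_subgroup} is used).
#' @examples
#' renormalize_subgroups(0.166, 0.154, 0.57, 0.134)
#' @export
renormalize_subgroups <- function(t, s, weight_plus, b_target,
                                  b_subgroup = NULL) {
  if (weight_plus < 0 || weight_plus > 1)
    stop("`weight_plus` must lie in [0, 1]")
  mixture <- weight_plus * t + (1 - weight_plus) * s
  if (is.null(b_subgroup)) b_subgroup <- mixture
  if (b_subgroup <= 0)
    stop("subgroup mixture is zero; nothing to renormalize")
  fac <- b_target / b_subgroup
  list(t = t * fac, s = s * fac, factor = fac,
       b = mixture * fac)
}
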