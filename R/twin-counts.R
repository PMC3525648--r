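#' Twin-pair concordance counts
#'
#' Container for raw twin (or sibling) pair tallies: the number of pairs in
#' which both members are affected (concordant, C) and in which exactly one is
#' affected (discordant, D).  Counts may be tagged with a zygosity and an
#' optional subgroup label (e.g. a carrier status or the proband's gender).
#'
#' @param concordant non-negative integer count of doubly-affected pairs.
#' @param discordant non-negative integer count of singly-affected pairs.
#' @param zygosity one of \code{"MZ"}, \code{"DZ"}, \code{"sibling"}.
#' @param subgroup optional character label for the proband subgroup.
#' @return An object of class \code{"twin_counts"}.
#' @examples
#' twin_counts(9, 31, subgroup = "carrier")
#' @export
twin_counts <- function(concordant, discordant, zygosity = "MZ",
                        subgroup = NULL) {
  if (length(concordant) != 1L || length(discordant) != 1L)
    stop("`concordant` and `discordant` must be scalars")
  if (is.na(concordant) || is.na(discordant) ||
      concordant < 0 || discordant < 0)
    stop("pair counts must be non-negative")
  zygosity <- match.arg(zygosity, c("MZ", "DZ", "sibling"))
  structure(
    list(concordant = as.numeric(concordant),
         discordant = as.numeric(discordant),
         zygosity = zygosity,
         subgroup = subgroup),
    class = "twin_counts")
}

#' @export
print.twin_counts <- function(x, ...) {
  lbl <- if (is.null(x$subgroup)) "" else paste0(" [", x$subgroup, "]")
  cat(sprintf("Twin-pair counts (%s%s): C = %g, D = %g, pairs = %g\n",
              x$zygosity, lbl, x$concordant, x$discordant,
              x$concordant + x$discordant))
  invisible(x)
}

as_twin_counts <- function(x) {
  if (inherits(x, "twin_counts")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(twin_counts(x[[1]], x[[2]]))
  stop("cannot interpret input as twin-pair counts")
}

#' Pair-wise concordance rate
#'
#' The fraction of ascertained twin pairs in which both twins are affected,
#' C / (C + D).
#'
#' @param counts a \code{\link{twin_counts}} object (or a length-2 numeric
#'   vector \code{c(C, D)}).
#' @return The pair-wise concordance rate in \[0, 1\].
#' @examples
#' pairwise_concordance(twin_counts(9, 31))  # 0.225
#' @export
pairwise_concordance <- function(counts) {
  counts <- as_twin_counts(counts)
  n <- counts$concordant + counts$discordant
  if (n < 1) stop("at least one ascertained pair is required")
  counts$concordant / n
}

#' Proband-wise concordance rate
#'
#' Probability that the co-twin of an ascertained affected proband is also
#' affected.  Concordant pairs in which both twins were independently
#' ascertained contribute two probands, so the concordant count is inflated by
#' a study-wide factor f in \[1, 2\] (f = 1 + pi, where pi is the probability
#' of double ascertainment): rate = f*C / (f*C + D).
#'
#' @param counts a \code{\link{twin_counts}} object.
#' @param factors an \code{\link{adjustment_factors}} object, or a bare
#'   numeric inflation factor in \[1, 2\].
#' @return The proband-wise concordance rate.
#' @seealso \code{\link{calibrate_ascertainment}}
#' @examples
#' probandwise_concordance(twin_counts(9, 31), 1.542)  # ~0.309
#' @export
probandwise_concordance <- function(counts, factors = 1) {
  counts <- as_twin_counts(counts)
  f <- if (inherits(factors, "adjustment_factors"))
    factors$ascertainment_inflation else as.numeric(factors)
  if (length(f) != 1L || is.na(f) || f < 1 || f > 2)
    stop("ascertainment inflation factor must lie in [1, 2]")
  fc <- f * counts$concordant
  if (fc + counts$discordant == 0) stop("at least one ascertained pair is required")
  fc / (fc + counts$discordant)
}

#' Calibrate the double-ascertainment inflation factor
#'
#' Solves f*C / (f*C + D) = observed proband-wise rate for the study-wide
#' inflation factor f applied to concordant-pair proband counts.  Twin
#' registries typically publish proband-wise rates without the underlying
#' double-ascertainment probability; calibrating f on the pooled table lets
#' the same factor be applied to subgroup tables from the same study.
#'
#' @param counts pooled \code{\link{twin_counts}} for the study.
#' @param observed_probandwise the published proband-wise concordance rate,
#'   strictly between 0 and 1.
#' @return An \code{\link{adjustment_factors}} object carrying the calibrated
#'   inflation factor.
#' @examples
#' calibrate_ascertainment(twin_counts(20, 73), 0.297)  # f ~ 1.542
#' @export
calibrate_ascertainment <- function(counts, observed_probandwise) {
  counts <- as_twin_counts(counts)
  r <- observed_probandwise
  if (length(r) != 1L || is.na(r) || r <= 0 || r >= 1)
    stop("observed proband-wise rate must lie strictly within (0, 1)")
  if (counts$concordant <= 0)
    stop("calibration requires at least one concordant pair")
  ## f*C*(1 - r) = r*D  =>  f = r*D / (C*(1 - r))
  f <- r * counts$discordant / (counts$concordant * (1 - r))
  if (f < 1 - 1e-9 || f > 2 + 1e-9)
    stop(sprintf(paste0("no ascertainment solution in [1, 2]: implied f = %.4f ",
                        "(pair-wise rate %.4f, full double-ascertainment rate %.4f)"),
                 f, pairwise_concordance(counts),
                 probandwise_concordance(counts, 2)))
  adjustment_factors(ascertainment_inflation = min(max(f, 1), 2))
}

#' Concordance adjustment factors
#'
#' Bundles the two corrections applied to raw twin concordance: the
#' double-ascertainment inflation factor (applied to concordant-pair proband
#' counts) and the multiplicative shared-environment factor that removes the
#' excess concordance attributable to twins sharing an intra-uterine (and
#' early childhood) environment, estimated as the sibling/DZ concordance
#' ratio.
#'
#' @param ascertainment_inflation multiplier (1 + pi) in \[1, 2\].
#' @param iu_ch_factor shared-environment correction in (0, 1\].
#' @param mode \code{"apply_iu_adjustment"} or \code{"none"}; in mode
#'   \code{"none"} the environment factor is forced to 1 (used e.g. when a
#'   disease registry is analysed without any intra-uterine adjustment).
#' @return An object of class \code{"adjustment_factors"}.
#' @export
adjustment_factors <- function(ascertainment_inflation = 1,
                               iu_ch_factor = 1,
                               mode = c("apply_iu_adjustment", "none")) {
  mode <- match.arg(mode)
  if (ascertainment_inflation < 1 || ascertainment_inflation > 2)
    stop("ascertainment inflation must lie in [1, 2]")
  if (iu_ch_factor <= 0 || iu_ch_factor > 1)
    stop("shared-environment factor must lie in (0, 1]")
  if (mode == "none") iu_ch_factor <- 1
  structure(list(ascertainment_inflation = ascertainment_inflation,
                 iu_ch_factor = iu_ch_factor,
                 mode = mode),
            class = "adjustment_factors")
}

#' @export
print.adjustment_factors <- function(x, ...) {
  cat(sprintf("Adjustment factors: ascertainment f = %.4f, IU/CH factor = %.4f (%s)\n",
              x$ascertainment_inflation, x$iu_ch_factor, x$mode))
  invisible(x)
}
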