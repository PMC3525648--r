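#' Response-curve parameters
#'
#' Parameters of the saturating exposure-response curve for a gender (or any
#' stratum): disease probability among susceptibles rises from zero beyond an
#' exposure threshold and saturates at a plateau.  The exposure coordinate x
#' is dimensionless ("environmental units"), monotone in the likelihood of a
#' sufficient exposure but carrying no time semantics.
#'
#' @param plateau_c asymptotic probability at saturating exposure, in
#'   \[0, 1\].
#' @param hazard_scale rate constant of the response, > 0.
#' @param hazard_ratio stratum-specific multiplier on the hazard scale
#'   (default 1); the proportional-hazard ratio between strata is the ratio
#'   of their multipliers.
#' @param lambda exposure threshold at which the response begins.
#' @return An object of class \code{"response_params"}.
#' @export
response_params <- function(plateau_c, hazard_scale = 1, hazard_ratio = 1,
                            lambda = 0) {
  if (plateau_c < 0 || plateau_c > 1) stop("`plateau_c` must lie in [0, 1]")
  if (hazard_scale <= 0 || hazard_ratio <= 0) stop("hazard parameters must be positive")
  if (!is.finite(lambda)) stop("`lambda` must be finite")
  structure(list(plateau_c = plateau_c, hazard_scale = hazard_scale,
                 hazard_ratio = hazard_ratio, lambda = lambda),
            class = "response_params")
}

#' Exposure-response curve
#'
#' Constant-hazard saturating response: zero up to the threshold, then
#' \code{plateau_c * (1 - exp(-hazard_scale * hazard_ratio * (x - lambda)))}.
#' The curve is continuous at the threshold, strictly increasing beyond it,
#' and approaches the plateau as exposure grows.  The exponential form is the
#' minimal model with a constant hazard beyond a threshold consistent with a
#' proportional-hazard comparison between strata.
#'
#' @param x exposure coordinate(s), dimensionless.
#' @param params a \code{\link{response_params}} object.
#' @return Disease probability (same length as \code{x}).
#' @examples
#' response_curve(1, response_params(0.5))  # 0.5 * (1 - exp(-1)) ~ 0.316
#' @export
response_curve <- function(x, params) {
  stopifnot(inherits(params, "response_params"))
  dx <- pmax(x - params$lambda, 0)
  params$plateau_c * (1 - exp(-params$hazard_scale * params$hazard_ratio * dx))
}

#' Fit gender-specific response curves to current-epoch penetrances
#'
#' Solves for the male-female threshold offset and/or hazard ratio such that
#' the two response curves pass through the observed susceptible-only
#' penetrances (z_f, z_m) at the calibration epoch.  The female curve is the
#' reference (lambda_F = 0, hazard multiplier 1) and the calibration epoch is
#' placed where the female curve attains z_f.
#'
#' Constraint modes: \code{"threshold"} keeps a common hazard (r = 1) and
#' solves for the male threshold; \code{"hazard"} keeps common thresholds and
#' solves for the male hazard multiplier; \code{"both"} solves for the male
#' threshold at a supplied hazard ratio \code{r}.  When the male saturation
#' fraction z_m/plateau_m exceeds the female fraction, the solution
#' necessarily has a lower male threshold or a greater male hazard (or both):
#' men then sit closer to their plateau than women at the same exposure.
#'
#' @param z_f,z_m current adjusted penetrances for susceptible women and men.
#' @param plateau_f,plateau_m gender plateaus (defaults 0.28 and 0.06).
#' @param constraint_mode \code{"threshold"}, \code{"hazard"}, or
#'   \code{"both"}.
#' @param r hazard ratio women:men used in mode \code{"both"} (default 1).
#' @param hazard_scale common rate constant (default 1).
#' @return A list of class \code{"gender_curves"} with \code{female} and
#'   \code{male} \code{\link{response_params}}, the calibration epoch
#'   \code{x0}, the threshold offset \code{lambda_offset} (male minus
#'   female), the hazard ratio, and a \code{degenerate} flag set when both
#'   strata are at saturation (any threshold/hazard pair then fits).
#' @examples
#' fit_gender_curves(0.183, 0.036)
#' @export
fit_gender_curves <- function(z_f, z_m, plateau_f = 0.28, plateau_m = 0.06,
                              constraint_mode = c("threshold", "hazard", "both"),
                              r = 1, hazard_scale = 1) {
  constraint_mode <- match.arg(constraint_mode)
  if (z_f > plateau_f + 1e-12 || z_m > plateau_m + 1e-12)
    stop("penetrance targets exceed their plateaus; infeasible")
  sat_f <- z_f / plateau_f
  sat_m <- z_m / plateau_m
  if (sat_f >= 1 && sat_m >= 1) {
    return(structure(list(
      female = response_params(plateau_f, hazard_scale),
      male = response_params(plateau_m, hazard_scale),
      x0 = Inf, lambda_offset = 0, hazard_ratio = 1, degenerate = TRUE),
      class = "gender_curves"))
  }
  if (sat_f >= 1 || sat_m >= 1)
    stop("one stratum is exactly at saturation; threshold/hazard not identifiable")
  x0 <- -log(1 - sat_f) / hazard_scale          # female curve: lambda_F = 0
  need_m <- -log(1 - sat_m)                      # required hazard*(x0 - lambda_M)
  if (constraint_mode == "hazard") {
    rm_mult <- need_m / (hazard_scale * x0)
    male <- response_params(plateau_m, hazard_scale, hazard_ratio = rm_mult)
    lambda_off <- 0
    hr <- 1 / rm_mult
  } else {
    rm_mult <- if (constraint_mode == "both") 1 / r else 1
    lambda_off <- x0 - need_m / (hazard_scale * rm_mult)
    male <- response_params(plateau_m, hazard_scale, hazard_ratio = rm_mult,
                            lambda = lambda_off)
    hr <- 1 / rm_mult
  }
  if (sat_m > sat_f && !(lambda_off <= 0 || hr <= 1))
    stop("internal inconsistency: male saturation exceeds female but fitted curve lags")
  structure(list(female = response_params(plateau_f, hazard_scale),
                 male = male, x0 = x0, lambda_offset = lambda_off,
                 hazard_ratio = hr, degenerate = FALSE),
            class = "gender_curves")
}

#' @export
print.gender_curves <- function(x, ...) {
  if (x$degenerate) {
    cat("Gender response curves: both strata at saturation (degenerate fit)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("Gender response curves: calibration epoch x0 = %.3f, ",
                     "male threshold offset = %.3f, hazard ratio (F:M) = %.3f\n"),
              x$x0, x$lambda_offset, x$hazard_ratio))
  invisible(x)
}

#' Exposure-sufficiency summary
#'
#' Under a monotone response bounded by the plateau, the current saturation
#' fraction z/plateau is a lower bound on the probability that a susceptible
#' individual's lifetime environmental experience is sufficient to produce
#' disease.  The minimum number of required environmental events is a
#' configured input (default 3), not derived here.
#'
#' @param z_gender current adjusted penetrance for the stratum.
#' @param plateau_gender the stratum plateau, > 0.
#' @param n_events_min configured minimum number of environmental events.
#' @return A list with \code{p_e_lower} and \code{n_events_min}.
#' @examples
#' exposure_sufficiency(0.183, 0.28)  # ~0.65
#' @export
exposure_sufficiency <- function(z_gender, plateau_gender, n_events_min = 3L) {
  if (plateau_gender <= 0) stop("`plateau_gender` must be positive")
  if (z_gender < 0 || z_gender > plateau_gender + 1e-12)
    stop("`z_gender` must lie in [0, plateau]")
  list(p_e_lower = min(z_gender / plateau_gender, 1),
       n_events_min = as.integer(n_events_min))
}
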