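#' Fit the twin-study susceptibility model
#'
#' The central entry point: converts epidemiological observables and
#' subgroup twin tables into the model's non-observable estimates.  The
#' chain is
#' \enumerate{
#'   \item shared-environment adjustment: the sibling/DZ concordance ratio
#'     multiplies the raw proband-wise MZ concordance, leaving the
#'     genotype-sharing penetrance b;
#'   \item per-table ascertainment calibration: the double-ascertainment
#'     inflation factor is solved from each table's pooled counts and pooled
#'     proband-wise rate, subgroup proband-wise rates are adjusted and
#'     renormalized against the table's own pooled adjusted rate so their
#'     case-weighted mixture equals b;
#'   \item partition-based estimation of the susceptible-case fraction
#'     g = P(G|D) by joint feasibility over the supplied partitions
#'     (\code{\link{estimate_g}});
#'   \item population susceptibility bounds P(G) in
#'     \[g P(D)/b, 2 P(D)/b\] and the penetrance decomposition
#'     (z range, sigma^2, b' = b/g);
#'   \item per-partition mechanism classification and carrier-susceptibility
#'     quantities; gender environmental-response summaries.
#' }
#'
#' @param observables an \code{\link{epi_observables}} object.
#' @param twin_tables named list of subgroup twin tables in the
#'   \code{\link{ms_twin_table}} layout; defaults to the bundled MS carrier
#'   and gender tables when the bundled observables are used.
#' @param population_fraction named numeric giving the population frequency
#'   A0 of the "positive" subgroup for each twin table; defaults to the
#'   observables' carrier fraction for a table named \code{"hla"} and 0.5
#'   for a table named \code{"gender"}.
#' @param g optionally fix the susceptible-case fraction instead of
#'   estimating it.
#' @param plateaus length-2 named numeric \code{c(female =, male =)} response
#'   plateaus (defaults 0.28 and 0.06).
#' @param mech_tol,ratio_tol,grid_step passed to \code{\link{estimate_g}}.
#' @param use_published_probandwise logical; when a table carries published
#'   (rounded) subgroup proband-wise rates, use them as the inputs of the
#'   adjustment chain (default TRUE, matching registry reporting practice);
#'   otherwise recompute them from the counts and the calibrated factor.
#' @return An object of class \code{"susceptibility_fit"}.
#' @examples
#' fit <- fit_susceptibility(ms_observables())
#' fit
#' coef(fit)
#' @export
fit_susceptibility <- function(observables,
                               twin_tables = NULL,
                               population_fraction = NULL,
                               g = NULL,
                               plateaus = c(female = 0.28, male = 0.06),
                               mech_tol = 0.10, ratio_tol = 0.01,
                               grid_step = 1e-4,
                               use_published_probandwise = TRUE) {
  stopifnot(inherits(observables, "epi_observables"))
  if (is.null(twin_tables))
    twin_tables <- list(hla = ms_twin_table("hla"),
                        gender = ms_twin_table("gender"))

  iu <- iu_adjustment_factor(observables)
  b <- adjust_concordance(observables$mz_raw, iu)
  ## In published mode the subgroup tables are constrained to reproduce the
  ## overall adjusted concordance at its reported precision (the constraint a
  ## registry actually states); the full-precision chain uses b itself.
  b_used <- if (use_published_probandwise) round(b, 3) else b

  default_a0 <- function(nm) {
    if (nm == "gender") return(0.5)
    if (!is.na(observables$carrier_fraction_population))
      return(observables$carrier_fraction_population)
    stop("no population fraction available for table '", nm, "'")
  }

  tables <- list()
  partitions <- list()
  for (nm in names(twin_tables)) {
    tab <- twin_tables[[nm]]
    asc <- calibrate_ascertainment(tab$pooled, tab$pooled_probandwise)
    pw_plus <- if (use_published_probandwise && !is.null(tab$probandwise_plus))
      tab$probandwise_plus else probandwise_concordance(tab$plus, asc)
    pw_minus <- if (use_published_probandwise && !is.null(tab$probandwise_minus))
      tab$probandwise_minus else probandwise_concordance(tab$minus, asc)
    t_adj <- adjust_concordance(pw_plus, iu)
    s_adj <- adjust_concordance(pw_minus, iu)
    b_pooled <- adjust_concordance(tab$pooled_probandwise, iu)
    ## renormalize only when the table's own pooled adjusted rate disagrees
    ## with the target at the working precision (a table that already pools
    ## to the full cohort needs no rescaling)
    b_tab <- if (use_published_probandwise && round(b_pooled, 3) == b_used)
      b_pooled else b_used
    ren <- renormalize_subgroups(t_adj, s_adj, tab$case_fraction_plus,
                                 b_target = b_tab, b_subgroup = b_pooled)
    a0 <- if (!is.null(population_fraction) && nm %in% names(population_fraction))
      population_fraction[[nm]] else default_a0(nm)
    a <- if (nm == "gender") {
      if (is.na(observables$female_fraction_cases)) tab$case_fraction_plus
      else observables$female_fraction_cases
    } else {
      if (is.na(observables$carrier_fraction_cases)) tab$case_fraction_plus
      else observables$carrier_fraction_cases
    }
    tables[[nm]] <- list(ascertainment = asc,
                         probandwise = c(plus = pw_plus, minus = pw_minus,
                                         pooled = tab$pooled_probandwise),
                         adjusted = c(t = t_adj, s = s_adj, b = b_pooled),
                         renormalized = c(t = ren$t, s = ren$s),
                         renorm_factor = ren$factor)
    partitions[[nm]] <- partition_analysis(A0 = a0, A = a, t = ren$t,
                                           s = ren$s, b = b_used, label = nm)
  }

  g_est <- NULL
  if (is.null(g)) {
    g_est <- estimate_g(partitions, b = b_used, mech_tol = mech_tol,
                        ratio_tol = ratio_tol, grid_step = grid_step)
    g <- g_est$g_lower
  }

  p_g_upper <- prob_g_upper(observables$prevalence, b_used)
  p_g_lower <- prob_g_lower(observables$prevalence, g, b_used)
  pen <- penetrance_range(observables$prevalence, g,
                          c(p_g_lower, p_g_upper), b_used)

  mech <- lapply(partitions, function(p)
    enrichment_mechanism(p$s, b_used, tolerance = mech_tol))
  carrier <- NULL
  if ("hla" %in% names(partitions)) {
    p <- partitions$hla
    carrier <- list(
      susceptible_fraction_upper = carrier_susceptibility(p$A, p$A0, p_g_upper),
      contribution_fraction = allele_contribution_fraction(p$A, p$A0))
  }

  env <- NULL
  if ("gender" %in% names(tables)) {
    zf <- tables$gender$renormalized[["t"]]
    zm <- tables$gender$renormalized[["s"]]
    env <- list(
      female = exposure_sufficiency(zf, plateaus[["female"]]),
      male = exposure_sufficiency(zm, plateaus[["male"]]),
      curves = fit_gender_curves(zf, zm, plateaus[["female"]],
                                 plateaus[["male"]]))
  }

  structure(list(observables = observables, iu = iu, b = b_used,
                 b_full = b,
                 tables = tables, partitions = partitions,
                 g = g, g_estimate = g_est,
                 p_g_lower = p_g_lower, p_g_upper = p_g_upper,
                 penetrance = pen, mechanisms = mech,
                 carrier = carrier, environment = env,
                 plateaus = plateaus),
            class = "susceptibility_fit")
}

#' @export
print.susceptibility_fit <- function(x, digits = 3, ...) {
  cat("Twin-study genetic susceptibility model\n")
  cat(sprintf("  adjusted MZ concordance b        : %.*f\n", digits, x$b))
  cat(sprintf("  susceptible-case fraction g      : >= %.*f\n", digits, x$g))
  cat(sprintf("  susceptible population P(G)      : %.2f%% - %.2f%%\n",
              100 * x$p_g_lower, 100 * x$p_g_upper))
  cat(sprintf("  susceptible-set penetrance z     : %.*f - %.*f (b' = %.*f)\n",
              digits, x$penetrance$z[1], digits, x$penetrance$z[2],
              digits, x$penetrance$b_prime))
  invisible(x)
}

#' @export
summary.susceptibility_fit <- function(object, digits = 3, ...) {
  x <- object
  print(x, digits = digits)
  cat("\nPer-table adjustment chain:\n")
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    cat(sprintf("  %s: f = %.3f; proband-wise %.3f/%.3f; adjusted %.3f/%.3f; renormalized t = %.3f, s = %.3f\n",
                nm, tb$ascertainment$ascertainment_inflation,
                tb$probandwise[["plus"]], tb$probandwise[["minus"]],
                tb$adjusted[["t"]], tb$adjusted[["s"]],
                tb$renormalized[["t"]], tb$renormalized[["s"]]))
    cat(sprintf("      mechanism: s/b = %.2f -> %s\n",
                x$mechanisms[[nm]]$ratio, x$mechanisms[[nm]]$mechanism))
  }
  if (!is.null(x$g_estimate)) {
    cat("\n"); print(x$g_estimate)
  }
  if (!is.null(x$carrier))
    cat(sprintf("\nCarrier analysis: susceptible carriers <= %.1f%%; allele contributes for %.0f%% of cases\n",
                100 * x$carrier$susceptible_fraction_upper,
                100 * x$carrier$contribution_fraction))
  if (!is.null(x$environment))
    cat(sprintf("Environment: P(E|G) >= %.2f (women), %.2f (men); plateaus %.2f / %.2f\n",
                x$environment$female$p_e_lower, x$environment$male$p_e_lower,
                x$plateaus[["female"]], x$plateaus[["male"]]))
  invisible(x)
}

#' @export
coef.susceptibility_fit <- function(object, ...) {
  out <- c(b = object$b, b_prime = object$penetrance$b_prime,
           g = object$g,
           p_g_lower = object$p_g_lower, p_g_upper = object$p_g_upper,
           z_lower = unname(object$penetrance$z[1]),
           z_upper = unname(object$penetrance$z[2]),
           sigma2_upper = max(object$penetrance$sigma2))
  if (!is.null(object$carrier))
    out <- c(out,
             carrier_susceptible_upper = object$carrier$susceptible_fraction_upper,
             allele_contribution = object$carrier$contribution_fraction)
  out
}

#' Predict susceptibility bounds for new regions or diseases
#'
#' Applies the fitted shared-environment factor and susceptible-case
#' fraction to a registry of prevalence/concordance rows (see
#' \code{\link{region_table}}).
#'
#' @param object a \code{\link{fit_susceptibility}} result.
#' @param newdata a registry data frame.
#' @param mode \code{"iu_adjusted"} (regional registries) or
#'   \code{"unadjusted"} (registries without sibling/DZ data).
#' @param ... unused.
#' @return The registry augmented with \code{b}, \code{p_g_lower},
#'   \code{p_g_upper}.
#' @examples
#' fit <- fit_susceptibility(ms_observables())
#' predict(fit, ms_region_registry())
#' @export
predict.susceptibility_fit <- function(object, newdata,
                                       mode = c("iu_adjusted", "unadjusted"),
                                       ...) {
  mode <- match.arg(mode)
  region_table(newdata, mode = mode, iu_factor = object$iu$iu_ch_factor,
               g = object$g)
}

#' Simulate a twin cohort from a fitted model
#'
#' Draws synthetic twin cohorts whose generative parameters match the fitted
#' estimates: susceptible fraction at the fitted P(G) upper bound, a
#' two-point penetrance distribution matching the fitted (z, sigma^2) at the
#' upper-z end of the range, and the fitted double-ascertainment factor.
#'
#' @param object a \code{\link{fit_susceptibility}} result.
#' @param nsim number of cohorts.
#' @param seed integer seed; cohort i uses \code{seed + i - 1}.
#' @param n_pairs pairs per zygosity per cohort.
#' @param ... unused.
#' @return A list of \code{\link{simulate_cohort}} results (a single cohort
#'   is returned bare when \code{nsim = 1}).
#' @export
simulate.susceptibility_fit <- function(object, nsim = 1, seed = 1L,
                                        n_pairs = 10000, ...) {
  z <- unname(object$penetrance$z[2])
  s2 <- unname(object$penetrance$sigma2[["at_z_upper"]])
  pen <- if (s2 > 1e-12) {
    d <- sqrt(s2)
    list(type = "two_point", values = c(max(z - d, 0), min(z + d, 1)),
         probs = c(0.5, 0.5))
  } else list(type = "point", value = z)
  f <- object$tables[[1]]$ascertainment$ascertainment_inflation
  cohorts <- lapply(seq_len(nsim), function(i)
    simulate_cohort(sim_config(
      n_pairs = n_pairs, p_g = object$p_g_upper, penetrance = pen,
      iu_effect = 1, ascertainment_pi = f - 1, seed = seed + i - 1L)))
  if (nsim == 1) cohorts[[1]] else cohorts
}

#' Plot fitted gender response curves
#'
#' Draws the exposure-response curves for susceptible women and men with
#' their plateaus and the calibration epoch.
#'
#' @param x a \code{\link{fit_susceptibility}} result (with a gender table).
#' @param xmax right edge of the exposure axis (environmental units).
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.susceptibility_fit <- function(x, xmax = NULL, ...) {
  if (is.null(x$environment)) stop("fit carries no gender environment analysis")
  cv <- x$environment$curves
  if (is.null(xmax)) xmax <- max(3, 2 * cv$x0)
  xs <- seq(0, xmax, length.out = 200)
  yf <- response_curve(xs, cv$female)
  ym <- response_curve(xs, cv$male)
  graphics::plot(xs, yf, type = "l", col = "firebrick", lwd = 2,
                 xlab = "environmental exposure (x)",
                 ylab = "P(D, E | G)", ylim = c(0, max(x$plateaus) * 1.05), ...)
  graphics::lines(xs, ym, col = "steelblue", lwd = 2)
  graphics::abline(h = x$plateaus, lty = 3, col = c("firebrick", "steelblue"))
  graphics::abline(v = cv$x0, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = c("women", "men"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}
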