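#' Bundled multiple sclerosis reference observables
#'
#' Published Canadian epidemiological observables for multiple sclerosis:
#' lifetime prevalence 0.0015 (women 0.00204, men 0.00096), raw proband-wise
#' MZ concordance 0.25, DZ concordance 0.054, sibling concordance 0.029,
#' female case fraction 0.68, and DRB1*1501 carrier fractions 0.55 (cases) /
#' 0.24 (controls).
#'
#' @return An \code{\link{epi_observables}} object.
#' @examples
#' ms_observables()
#' @export
ms_observables <- function() {
  epi_observables(
    prevalence = 0.0015, mz_raw = 0.25, dz_raw = 0.054, sib_raw = 0.029,
    female_fraction_cases = 0.68,
    carrier_fraction_cases = 0.55,
    carrier_fraction_population = 0.24,
    by_gender = list(
      female = list(prevalence = 0.00204, mz_raw = 0.34,
                    dz_raw = 0.051, sib_raw = 0.039),
      male = list(prevalence = 0.00096, mz_raw = 0.067,
                  dz_raw = 0.057, sib_raw = 0.019)))
}

#' Bundled MZ-twin tables for the MS reference analysis
#'
#' Concordant/discordant MZ twin-pair tallies for probands stratified by
#' DRB1*1501 carrier status (carrier: 9/31, non-carrier: 11/42) and by gender
#' (female: 22/66, male: 2/43), together with each table's published pooled
#' proband-wise rate used to calibrate the double-ascertainment factor and
#' the adjusted case fraction of the "positive" subgroup.
#'
#' @param which \code{"hla"} or \code{"gender"}.
#' @return A list with components \code{plus}, \code{minus}, \code{pooled}
#'   (\code{\link{twin_counts}} objects), \code{pooled_probandwise}, and
#'   \code{case_fraction_plus}.
#' @examples
#' ms_twin_table("hla")$pooled
#' @export
ms_twin_table <- function(which = c("hla", "gender")) {
  which <- match.arg(which)
  if (which == "hla") {
    list(plus = twin_counts(9, 31, subgroup = "carrier"),
         minus = twin_counts(11, 42, subgroup = "non-carrier"),
         pooled = twin_counts(20, 73),
         pooled_probandwise = 0.297,
         ## published proband-wise subgroup rates (3 d.p.), the inputs to the
         ## reproduction chain
         probandwise_plus = 0.309, probandwise_minus = 0.287,
         case_fraction_plus = 0.57)
  } else {
    list(plus = twin_counts(22, 66, subgroup = "female"),
         minus = twin_counts(2, 43, subgroup = "male"),
         pooled = twin_counts(24, 109),
         pooled_probandwise = 0.25,
         probandwise_plus = 0.34, probandwise_minus = 0.067,
         case_fraction_plus = 0.68)
  }
}

#' Bundled genotype-dose frequency tables for DRB1*1501
#'
#' Published three-class genotype frequencies (two copies, one copy, zero
#' copies of the risk allele) in MS cases and controls for three cohorts.
#' The Canadian cohort reports only carrier/non-carrier totals.
#'
#' @return A data frame with columns \code{cohort}, \code{group},
#'   \code{freq_2copy}, \code{freq_1copy}, \code{freq_0copy}.
#' @examples
#' ms_genotype_tables()
#' @export
ms_genotype_tables <- function() {
  data.frame(
    cohort = c("UCSF1", "UCSF2", "UCSF2"),
    group = c("case", "case", "control"),
    freq_2copy = c(0.10, 0.07, 0.012),
    freq_1copy = c(0.46, 0.39, 0.186),
    freq_0copy = c(0.44, 0.54, 0.80),
    stringsAsFactors = FALSE)
}

#' Bundled regional MS registry
#'
#' Published per-region MS prevalence ranges (per 100,000) and proband-wise
#' MZ-twin concordance for nine North American and European regions.
#'
#' @return A data frame with columns \code{region},
#'   \code{prevalence_low_per1e5}, \code{prevalence_high_per1e5},
#'   \code{probandwise_mz}.
#' @examples
#' ms_region_registry()
#' @export
ms_region_registry <- function() {
  data.frame(
    region = c("Canada", "Northern US", "Southern US", "Finland", "Denmark",
               "British Isles", "France", "Sardinia", "Italy"),
    prevalence_low_per1e5 = c(68, 100, 22, 52, 110, 74, 32, 144, 38),
    prevalence_high_per1e5 = c(248, 160, 112, 93, 110, 193, 65, 152, 90),
    probandwise_mz = c(0.253, 0.314, 0.174, 0.462, 0.24, 0.40, 0.111,
                       0.222, 0.145),
    stringsAsFactors = FALSE)
}

#' Bundled cross-disease registry
#'
#' Published prevalence and proband-wise MZ concordance for three other
#' complex autoimmune diseases, analysed without any intra-uterine
#' adjustment (no sibling/DZ data are available for these registries, and the
#' published estimates assume no IU impact).
#'
#' @return A data frame with columns \code{disease},
#'   \code{prevalence_low}, \code{prevalence_high} (decimals), and
#'   \code{probandwise_mz}.
#' @examples
#' ms_disease_registry()
#' @export
ms_disease_registry <- function() {
  data.frame(
    disease = c("Rheumatoid arthritis", "Ankylosing spondylitis",
                "Systemic lupus erythematosus"),
    prevalence_low = c(0.01, 0.004, 0.00025),
    prevalence_high = c(0.02, 0.04, 0.00025),
    probandwise_mz = c(0.35, 0.53, 0.39),
    stringsAsFactors = FALSE)
}
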