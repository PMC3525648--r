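Package: twinsus
Title: Genetic and Environmental Susceptibility Estimation from Twin-Study Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts directly observable epidemiology -- disease prevalence,
    monozygotic/dizygotic twin and sibling concordance, and subgroup carrier
    frequencies -- into estimates of quantities that cannot be observed
    directly: the fraction of the population genetically susceptible to a
    complex disease, the fraction of cases requiring susceptibility,
    genotype-subset penetrances and their variance, enrichment mechanisms for
    risk alleles, and gender-specific environmental response curves.  Includes
    proband-wise ascertainment calibration, shared intra-uterine environment
    adjustment, Hardy-Weinberg genotype-dose analysis, a forward twin-cohort
    simulator providing ground-truth oracles for every estimator, and a
    bundled multiple sclerosis reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
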