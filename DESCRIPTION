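Package: rvfbat
Title: Family-Based Association Tests for Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Collapsed, weighted and fixed-threshold family-based association
    test (FBAT) statistics for rare sequence variants in nuclear families
    (affected trios and discordant sibpairs), together with the FBAT
    multimarker chi-square test, population-based comparator tests (a burden
    score test and a modified Madsen-Browning weighted-sum test), a
    population-genetic simulator (Wright's equilibrium frequency
    distribution, Balding-Nichols stratification, relative-risk disease
    model with family ascertainment), and a replication harness for type-I
    error, power, prevalence and population-attributable-risk studies.
    Pedigree genotype data are read and written in PLINK text PED/MAP
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
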