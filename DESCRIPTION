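Package: dpcrscreen
Title: Chip-Based Digital PCR Screening for Fetal Aneuploidies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid fetal aneuploidy screening from chip-based digital PCR
    partition counts. Converts per-channel positive/negative well tallies
    from 20,000-well duplex TaqMan chips into copies-per-partition and
    copies/uL by Poisson statistics, computes within-reaction chromosomal
    ratios, and integrates three duplex reactions (13/21, X/18, X/Y) into
    sample-level karyotype calls covering the common autosomal trisomies,
    sex-chromosome aneuploidies, male triploidy and mosaics. Includes a
    stochastic chip simulator for arbitrary karyotype states, and cohort
    validation utilities (confusion matrices, binomial proportion
    confidence intervals, Mann-Whitney U comparison of ratio
    distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
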