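# dpcrscreen

Rapid fetal aneuploidy screening from chip-based digital PCR partition
counts.

Invasive prenatal diagnosis by karyotyping takes about two weeks of cell
culture; molecular rapid tests deliver a same-day answer for the common
aneuploidies while the karyotype is pending. `dpcrscreen` implements the
computational half of a chip-based digital PCR (dPCR) screen: a DNA
sample is partitioned into ~20,000 wells, three duplex TaqMan reactions
measure chromosomes 13/21, X/18 and X/Y (one target per dye channel,
FAM or VIC), and chromosome dosage is read out as a ratio of absolute
concentrations — no external reference assay, no polymorphic markers.
The package is for laboratories and methods developers who have
per-reaction positive/negative well tallies (from any thresholding
software) and want calls, QC and validation statistics; a partition-level
chip simulator makes the whole pipeline testable without instrument data.

## The statistics underneath

**Poisson quantification.** With `n_neg` of `n` valid wells negative in a
channel, the mean occupancy (copies per partition) is

    lambda = -ln(n_neg / n)

with delta-method standard error `se = sqrt((1 - p_neg) / (n * p_neg))`,
`p_neg = n_neg / n`, and 95% CI `lambda ± 1.96 se`. Concentration is
`lambda / v` for well volume `v` (default 0.755 nL), times any dilution.

**Chromosomal ratios.** For two targets in the *same* duplex reaction,
`r = lambda_target / lambda_reference`; volume and loading cancel.
Expected values are copy-number ratios: `r ≈ 1.5` for a trisomy against a
disomic reference, `≈ 0.5` for monosomy X against chromosome 18,
`18/X ≈ 2` in euploid males (one X), `X/Y ≈ 2` in XXY, and so on. A
decision table over the three reactions calls euploid male/female, T13,
T18, T21, monosomy X, XXX, XXY, XYY, XXXY, male triploidy, and flags
intermediate ratios as mosaics with estimated aberrant-cell fraction
`f = 2(r - 1)` (trisomy) or `f = 2(1 - r)` (X0 on the X/18 scale).
Chromosome 18 needs two interval pairs because euploid fetuses carry one
or two X copies depending on sex. Female triploidy (69,XXX) leaves every
ratio at 1 and is a documented blind spot.

**Validation.** Sensitivity/specificity with binomial confidence
intervals (Clopper–Pearson, Wilson, Jeffreys, Agresti–Coull) and
Mann–Whitney U comparison of ratio distributions (exact enumeration for
small groups, tie-corrected normal approximation otherwise).

## Worked example

```r
library(dpcrscreen)

sim   <- simulate_cohort(c("46,XY" = 2, "47,XX,+21" = 1, "45,X" = 1),
                         sim_params(seed = 42))
calls <- call_samples(sim$counts)
merge(calls[, c("sample_id", "call_class", "sex", "r21", "r18X", "rX18")],
      sim$truth)
#>   sample_id   call_class    sex   r21   r18X   rX18 true_karyotype
#> 1     S0001 EUPLOID_MALE   male 1.002 1.9843 0.5040          46,XY
#> 2     S0002 EUPLOID_MALE   male 1.002 2.0575 0.4860          46,XY
#> 3     S0003          T21 female 1.497 0.9843 1.0160      47,XX,+21
#> 4     S0004           X0 female 1.017 2.0315 0.4923           45,X
```

The trisomy-21 sample shows the 21/13 ratio at ~1.5; the euploid males
show 18/X near 2 (one X copy) and the X0 sample shows X/18 near 0.5 with
no Y signal. Quantification of a single channel:

```r
q <- estimate_lambda(n_positive = 10873, n_valid = 19804)
#> lambda = 0.7964 copies/partition, 95% CI [0.7810, 0.8117]
#> concentration = 1054.8 copies/uL, precision 1.93%
```

and the exact confidence interval for a fully concordant cohort of 505:

```r
binomial_ci(505, 505, "clopper_pearson")
#> sens 100% (95% CI 99.27-100%)
```

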