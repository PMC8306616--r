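---
title: "Methods: digital PCR aneuploidy screening with dpcrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital PCR aneuploidy screening with dpcrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrscreen)
```

## The measurement model

Chip-based digital PCR partitions a DNA sample into ~20,000 wells and
scores each well positive or negative per dye channel after endpoint
amplification. Under random partitioning, the number of target molecules
per well is Poisson with mean occupancy $\lambda$, so the fraction of
negative wells estimates $e^{-\lambda}$ and

$$\hat\lambda = -\ln\left(\frac{n_\mathrm{neg}}{n}\right), \qquad
\mathrm{se}(\hat\lambda) = \sqrt{\frac{1 - p_\mathrm{neg}}{n\,p_\mathrm{neg}}},$$

the standard error being the delta-method transform of the binomial
variance of $p_\mathrm{neg} = n_\mathrm{neg}/n$. `estimate_lambda()`
implements this with a symmetric 95% interval
$\hat\lambda \pm 1.96\,\mathrm{se}$ (lower bound clamped at 0); an
exact alternative obtained by inverting a Clopper–Pearson interval for
$p_\mathrm{neg}$ is available via `ci = "exact"`. At $n = 20{,}000$ the
two differ by well under 1% of the interval width, which is why the
delta method is the default — it is also what dPCR practice reports.

Each duplex reaction measures two chromosomes, one per channel (FAM,
VIC). A well positive in both channels counts for both targets: the two
occupancies are estimated independently from their own negative-well
fractions. The assumptions that matter are (i) random, well-mixed
partitioning, (ii) endpoint detection good enough that a well with at
least one template molecule scores positive, and (iii) no cross-talk
between channels. Departures from (ii) act as a per-channel efficiency
factor; see the simulator section.

## The ratio statistic and the decision table

Chromosome dosage is read from within-reaction concentration ratios
$r = \hat\lambda_t/\hat\lambda_r$ — partition volume, dilution and
loading cancel, so $r$ estimates the chromosomal copy-number ratio
directly. The five standard definitions are `r13 = 13/21`,
`r21 = 21/13`, `r18X = 18/X`, `rX18 = X/18` and `rXY = X/Y`. Both
directions of the 13/21 duplex are first-class because a trisomy of
either chromosome shows up as 1.5 in one direction (and 2/3 in the
other); for the sex chromosomes, 18/X detects trisomy 18 and X/18
detects monosomy X — the observed euploid-female X/18 values sit near 1
and monosomy X near 0.5, which fixes the direction convention. The
ratio CI is a delta-method interval on $\log r$ assuming channel
independence; the (negative) covariance contributed by shared
double-positive wells is ignored, which is slightly conservative at the
occupancies used here ($\lambda \le 1.5$).

Sex is called first, from the X/Y duplex: male iff
$\hat\lambda_Y/\hat\lambda_X$ exceeds `y_presence_min` (default 0.1).
The floor exists because a handful of false-positive wells in the Y
channel of a female sample would otherwise imply a tiny but nonzero
$\hat\lambda_Y$; a true single Y copy sits near ratio 0.5, far above
0.1. Sex must precede the chromosome-18 verdict because euploid females
(two X) expect 18/X ≈ 1 while euploid males (one X) expect 18/X ≈ 2 —
the "two intervals, two thresholds" feature of this axis. Y-absence is
also what separates monosomy X (18/X ≈ 2, no Y) from the euploid male
(18/X ≈ 2, Y present).

The integrated call is a lookup over band memberships:

| state | r13 | 18/X | X/Y | call |
|---|---|---|---|---|
| 46,XX | 1 | 1 | — | EUPLOID_FEMALE |
| 46,XY | 1 | 2 | 1 | EUPLOID_MALE |
| 47,+13 | 1.5 | per sex | per sex | T13 |
| 47,+21 | 2/3 | per sex | per sex | T21 |
| 47,XX,+18 | 1 | 1.5 | — | T18 |
| 47,XY,+18 | 1 | 3 | 1 | T18 |
| 45,X | 1 | 2 | — | X0 |
| 47,XXX | 1 | 2/3 | — | XXX |
| 47,XXY | 1 | 1 | 2 | XXY |
| 47,XYY | 1 | 2 | 0.5 | XYY |
| 48,XXXY | 1 | 2/3 | 3 | XXXY |
| 69,XXY | 1 | 1.5 | 2 | TRIPLOID_MALE |
| 69,XYY | 1 | 3 | 0.5 | TRIPLOID_MALE |

69,XXX leaves every ratio at its euploid value and is called
EUPLOID_FEMALE: female triploidy is undetectable by any pure
dosage-ratio design, and the package makes that blind spot explicit
(`expected_call("69,XXX")`). Conflicting abnormal evidence across
reactions, or QC failure on a required reaction, yields INDETERMINATE.

## Thresholds

The clinical publication behind this design prints observed group ranges
but not its cut-offs, so the defaults bracket those ranges with midpoint
gaps: trisomy-type ratios use euploid [0.80, 1.25] and aneuploid
[1.35, 1.70]; male 18/X uses [1.65, 2.48] and [2.52, 3.30]; the
monosomy-X band on X/18 is [0.45, 0.60]; X/Y bands sit at ~1
[0.75, 1.35], ~2 [1.6, 2.4], ~3 [2.6, 3.4] and ~0.5 [0.4, 0.65]. All of
them are plain numbers in the config (`load_thresholds()`), because a
laboratory validating its own assay lot should derive its own bands.
Two small interval interactions are resolved deliberately: the male
18/X euploid band overlaps the 1.5-copy band on (1.65, 1.70), and male
samples check the 2-copy band first; and in females the zone between
the euploid and trisomic 18/X bands is reported as an X0-type mosaic
(see below).

## Mosaics

A mosaic sample mixes euploid and aneuploid cell populations at
fraction $f$, shifting the expected ratio linearly:
$r = (2+f)/2$ for a trisomy, $r = (2-f)/2$ for monosomy X on the X/18
scale. `mosaic_fraction()` inverts these exactly; ratios falling in the
inter-band gap produce a MOSAIC call with the estimated $f$ under the
default policy (`"flag"`), or INDETERMINATE under `"reject"`. Two
honest caveats. First, only part of the $f$ range is visible: with the
default bands a trisomy mosaic flags for $f$ roughly in (0.5, 0.7);
below that it is indistinguishable from euploid, above it from full
trisomy. Second, in females an intermediate 18/X admits two
explanations — a chromosome-18-gain mosaic or an X-loss mosaic — that
produce identical observables in that reaction; the package reports the
zone as an X0-type mosaic (the class observed clinically on this axis)
and the call text should always be read as "confirm by karyotype",
which is also how mosaics are handled clinically.

## The chip simulator

`simulate_chip()` emulates the instrument output for an arbitrary
karyotype state: valid wells are `n_partitions` minus a binomial number
of quality failures (`invalid_fraction`, default 1%); each channel's
per-well positive probability is
$1 - e^{-\lambda d}(1 - \mathrm{fp})$ where
$\lambda = \lambda_\mathrm{base}\cdot c/2 \cdot \mathrm{efficiency}$
for copy number $c$, $d$ is the per-molecule detection probability
(default 0.98) and fp the per-well false-positive rate (default 1e-4);
the four well categories are drawn from the implied multinomial with
independent channels. `lambda_base` (default 0.8 copies/partition per
two-copy autosome, a mid-dynamic-range loading for a 20,000-well chip)
scales with true copy count, so one X in males loads at 0.4. Mosaic
components mix at the concentration level (cell-fraction weighting),
matching how a blended DNA extract behaves. Detection dropout and false
positives scale both channels of a duplex almost identically, so they
cancel in ratios to first order — which is exactly why the clinical
method is robust to them.

What the simulator does *not* emulate: inter-sample variation in
loading and per-assay efficiency, pipetting variance, maternal-cell
contamination, chip-to-chip thresholding differences, and channel
cross-talk. One visible consequence: simulated euploid ratio SDs at the
default settings are ≈0.015, tighter than the ≈0.05 observed clinically,
because the clinical spread includes those biological and technical
components. Passing the simulated-separation tests therefore
demonstrates that the estimator and decision logic are correct under
partition statistics, not that any particular laboratory will see
perfectly separated clinical ratio clouds; the configurable thresholds
and per-assay efficiency calibration exist for that reason. The euploid
ratio means observed clinically (0.975–1.018 on trisomy-type axes,
1.965 on male 18/X) deviate slightly from the ideal 1.0/2.0, consistent
with unmodelled per-assay efficiency; the simulator targets the ideal
values at efficiency 1 and lets config override per-assay factors.

## Validation statistics

Sensitivity and specificity come from binary confusion matrices per
abnormality; MOSAIC calls count toward their base class by default, and
INDETERMINATE counts as negative (configurable to exclusion). Four
binomial interval constructions are provided. The default is
Clopper–Pearson with the *all-observations* denominator convention (CI
computed on the full cohort size): for a fully concordant cohort of
505 this gives a lower bound of $0.025^{1/505} = 99.27\%$ for every
abnormality — matching the single printed interval pattern of the
clinical validation this package models, which reported one 99.26–100%
interval across abnormalities (the 0.01-point difference from 99.27 is
a rounding/method detail that cannot be resolved from the printed
text). Methodologically, Wilson or Jeffreys intervals have better
average coverage and remain selectable; the "standard" per-denominator
convention is also available and is what a fresh study should report.

The Mann–Whitney U comparison of euploid versus aneuploid ratio
distributions uses an exact p-value from the full null distribution of
U (computed by dynamic programming over the Gaussian-binomial
recurrence) whenever there are no ties and $n_a n_b \le 400$, and the
tie-corrected, continuity-corrected normal approximation otherwise.
Cohort percentages round half-up to two decimals, matching how such
tables are conventionally printed.

## Numerical and QC choices

- **Saturation guard**: besides the undefined $\hat\lambda$ at zero
  negatives, any channel with fewer than 20 negative wells is flagged
  SATURATED because the estimator variance explodes as
  $p_\mathrm{neg} \to 0$; saturated channels never enter ratios.
- **Low chip quality**: fewer than 10,000 valid wells flags LOW_QC and
  forces INDETERMINATE — a stand-in for the vendor's opaque chip-quality
  score, with the threshold exposed in the QC config block.
- **NTC contamination**: a no-template control with more than 5 positive
  wells in either channel is CONTAMINATED; the pipeline aborts in strict
  mode.
- **Partition volume** (0.755 nL) only affects reported copies/µL; every
  classification quantity is a ratio in which it cancels.
- **Determinism**: cohort simulation derives per-sample seeds from one
  master seed, so identical inputs give byte-identical CSV/TSV outputs;
  the pipeline records the seed and config digest in a run manifest.

## Problem sizes used by the test suite

The suite verifies estimator recovery over 500 chips per occupancy
level, CI coverage over 2,000 simulated chips per level at
$\lambda \in \{0.2, 0.7, 1.5\}$, perfect separation on a simulated
501-sample cohort (380 euploid, 65 T21, 30 T18, 14 T13, 12 X0), ratio
recovery over 150–200 replicate chips, and mosaic linearity over a
9-point fraction grid — sizes chosen so Monte-Carlo error is well below
the tolerances being asserted while the full suite runs in seconds.

## Known limitations

Structural aberrations (balanced translocations, marker chromosomes),
segmental CNVs and female triploidy are invisible to chromosome-dosage
ratios by construction. Mosaic visibility is band-limited as described.
The caller assumes exactly the five-chromosome, three-duplex panel
geometry (configurable pairings, but ratios never cross reactions), and
raw fluorescence thresholding is upstream of this package — it consumes
well counts, not intensities.
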