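---
title: "Quantifying tubular-cell polyploidy: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tubular-cell polyploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyscope)
```

After acute kidney injury (AKI), many surviving tubular epithelial cells
(TC) do not divide but endoreplicate, acquiring 4C or 8C DNA content.
`ploidyscope` implements the four quantification routes used to measure
this phenomenon — FUCCI2aR flow cytometry, the Confetti multicolour
reporter, per-nucleus PicoGreen densitometry, and transcutaneous GFR /
ChIP-qPCR closed forms — together with seeded generators that produce
every input with known ground truth. This vignette explains the models,
the defaults, and the choices made where the design was genuinely open.

## 1. FUCCI2aR gating model

The FUCCI2aR reporter expresses mCherry-hCdt1 in G1 nuclei and
mVenus-hGem in S/G2/M nuclei; both are present at the G1/S boundary.
Combining reporter state with DNA content gives a total classification
map, applied by `classify_events()` after two preprocessing gates:

1. **Doublet exclusion.** Events wider than `doublet_width_max` are
   removed. With `"auto"` the cutoff is the 99.5th percentile of a
   singlet calibration population (events narrower than 1.5x the median
   width — the median is robust to doublet contamination below 50%).
   This abstains on ~0.5% of genuine singlets; because excluded events
   also leave the denominator, the reported fractions stay unbiased.
2. **Induction.** Events below both reporter thresholds are non-induced
   and leave the denominator, matching the convention of normalizing
   per-sample counts on the induction percentage. `"auto"` thresholds are
   5x the channel background median, with background taken from events at
   or below the channel's lower quartile. This assumes under three
   quarters of events are positive per channel; for sorted or uniformly
   positive populations, pass numeric thresholds.

DNA intensities are binned on the log2 axis. The 2C anchor comes from
`calibrate_dna_axis()` — the density mode of mCherry-only (G1) events —
and the 4C and 8C peaks sit at exactly +1 and +2 log2 units. Each event
goes to the nearest peak; events below the 2C window's lower edge
(`anchor * 2^-bin_tolerance`, default tolerance 0.25 log2 units) are
sub-2C. The classification map is then:

| reporter state | sub-2C | 2C | 4C | >= 8C |
|---|---|---|---|---|
| mCherry only | dead | diploid G1 | polyploid, non-cycling | polyploid, non-cycling |
| mCherry + mVenus | dead | cycling | polyploid, cycling | polyploid, cycling |
| mVenus only | dead | cycling | cycling | polyploid, cycling |

The mVenus-only 4C cell is deliberately called *cycling*, not polyploid:
a diploid cell in G2/M and a tetraploid cell in G1 are indistinguishable
there, and only at >= 8C is an mVenus-only event unambiguously polyploid.
This asymmetry is the reason snapshot reporters under-count polyploidy
and motivates the Confetti model below.

### Why dead cells are generated below 1.65C

Dying cells are reporter-positive events with degraded, sub-2C DNA. The
generator draws their DNA content uniformly on `(0.5, 1.65)` C-units.
The upper bound sits below the 2C window's lower edge (1.68C at the
default tolerance) on purpose: it makes ground truth recoverable in the
noise-free limit, so oracle-equivalence tests can demand exact
agreement, while still exercising the sub-2C gate across its whole
range. Real debris distributions extend closer to 2C; the range is a
config field (`dead_dna_range`) for users who want the harder overlap.

### Redistribution accounting

Cells cycling at day 2 are, by day 3, still cycling, dead, or polyploid.
`redistribute_cycling(c2, p3_new, d3)` expresses the three fates as
shares of the day-2 cycling pool, clipping at zero and renormalizing.
Two conventions were open:

* **Baseline handling.** `p3_new` should be the *newly* polyploid
  fraction — day-3 polyploidy minus the pre-injury baseline — because
  pre-existing polyploid cells were never part of the day-2 cycling
  pool. The subtraction is left to the caller so both conventions are
  available.
* **Averaging order.** Applying the formula to group means gives shares
  (for 39.8% cycling, 17% newly polyploid, 19.6% dead) of 42.7% / 49.2%
  / 8.0%; averaging per-animal shares first gives different numbers.
  The function computes one call at a time, so either order can be
  assembled; neither is asserted as canonical.

## 2. The Confetti combinatorial model

The Confetti cassette fixes one of four fluorochromes per recombination
event. A diploid cell recombines once; a 4C cell recombines twice,
independently. With three equiprobable countable colours (RFP, YFP,
CFP; GFP is rare and excluded from all counts), two independent draws
differ with probability

$$P(\text{bi-coloured} \mid \text{4C}) = \frac{n-1}{n} = \frac{2}{3},$$

so one third of polyploid cells duplicate a colour and hide among
mono-coloured diploids. `estimate_polyploid_fraction()` inverts this:
$\hat p = \tfrac{3}{2}\, b_{\text{obs}}$, clipped to [0, 1], where
$b_{\text{obs}}$ is the bi-coloured fraction of coloured cells. Cells
with more than two recombinations (>= 8C) are not modelled; the
correction addresses 4C cells only, so $\hat p$ is conservative when 8C
cells are present.

Two readouts are reported side by side and labelled distinctly, because
they answer different questions:

* `b_corrected_pct` — the observed bi-coloured percentage divided by the
  recombination efficiency (coloured / total TC), e.g.
  `correct_for_efficiency(13.3, 0.847)` = 15.7%. This reproduces the
  field's efficiency-normalization arithmetic verbatim.
* `p_hat` — the model-based polyploid fraction $\tfrac32 b_{\text{obs}}$,
  which additionally accounts for the invisible same-colour duplicates.

Uncertainty comes from a percentile bootstrap over cells (default 2,000
resamples). Resampling `n_coloured` binary outcomes with replacement is
distributionally identical to a binomial draw, which is how it is
implemented; the seed is explicit. An optional plug-in mode replaces the
equiprobability assumption with observed single-colour frequencies via
$1/\left(1 - \sum_i c_i^2\right)$.

`expected_tally()` provides the exact multinomial expectations
(partitioned into disjoint outcomes that sum to one) and is the
closed-form oracle against which the simulator is tested. The default
GFP recombination probability is 0.01 — "rare" without a published
number — and is excluded from numerator and denominator exactly as in
the counting protocol.

## 3. PicoGreen densitometry

PicoGreen fluorescence is proportional to dsDNA over a local background,
so per-nucleus DNA content in C-units is linear in background-subtracted
intensity. `calibrate_diploid_reference()` averages the designated
diploid internal-control nuclei (>= 20 required; an optional trimmed
mean guards against contaminating non-diploid nuclei without asserting
that trimming was the original protocol), and `ploidy_fold()` reports
each nucleus as fold-over-diploid (2C = 1.0; a C-value scale is an
output option). Background is subtracted per nucleus from the supplied
local average; the generator records the true local background, so the
subtraction is exact up to intensity noise. Negative folds are clipped
to zero and counted. Group comparisons (e.g. YAP1-positive versus
YAP1-negative tubular nuclei) use the two-sided Mann-Whitney test via
`stats::wilcox.test()`, the standard choice for these skewed,
small-sample fold distributions.

## 4. GFR and ChIP closed forms

Transcutaneous FITC-sinistrin kinetics follow a two-compartment model:
a fast distribution phase and a slow renal elimination phase. The GFR
conversion is

$$\mathrm{GFR}\ [\mu l/\min] = \frac{14616.8\ [\mu l]}{t_{1/2}\ [\min]}
  \times \frac{bw\ [g]}{100\ [g]},$$

with the empirical constant treated as a configurable fixed input.
`fit_halflife()` isolates the elimination phase by discarding an initial
window (default 10 min, several distribution half-lives) and fitting
log-fluorescence by least squares — simple, transparent, and accurate to
well under 5% at the default noise level; a full bi-exponential
Levenberg-Marquardt fit (`method = "biexp"`) is available when the
distribution phase cannot be discarded. The generator's two-compartment
defaults (distribution half-life 2 min, weight 0.25, 75 min of 1-min
samples, additive noise SD 2 on an amplitude of 1000) are this package's
choices of typical small-rodent values; no published parameterization
exists for them. Longitudinal series are normalized per animal to
baseline and then to the sham-group *mean* ratio per time point (mean
rather than median: an explicit choice, as sham cohorts are small and
symmetric).

ChIP-qPCR enrichment uses
$\Delta C_t = C_t(\text{bound}) - \left[C_t(\text{input}) -
\log_2(\text{dilution})\right]$ and
$FR = 2^{-\left[\Delta C_t(\text{ab}) - \Delta C_t(\text{IgG})\right]}$.
Matching dilution factors cancel exactly, which is property-tested.

## 5. What the generators do and do not emulate

The simulators reproduce the *statistical structure* the analysis
assumes: mixtures of 2C/4C/8C cells across cycle phases with
multiplicative lognormal stain noise (CV 0.06, a typical DAPI width),
sub-2C dead events, width-doubled doublets, stochastic two-draw
recombination with incomplete induction, background-plus-linear-signal
nuclear intensities, bi-exponential decay, and Ct noise. They do not
emulate spectral spillover or compensation, instrument drift,
segmentation error, autofluorescence, or S3-segment spatial structure —
so green tests demonstrate that the estimators are correct *under the
stated model*, not that the model captures every property of real
cytometry or imaging data. Composition presets (`fucci_preset()`) encode
a published-scale time course — 39.8% cycling at day 2 collapsing to
8.8% with 17% polyploid at day 3 — as population structure for
recovery experiments, not as mouse-level reproductions.

Default problem sizes — 10^4 events for gating recovery, 3 x 10^4 cells
for the combinatorial check, 5 x 10^4 cells for estimator recovery, 100
bootstrap-coverage replicates — were chosen so every Monte Carlo
tolerance is several standard errors wide at desk scale.

## 6. Numerical and degenerate-input conventions

* All generators are bitwise deterministic given `seed`; the pipeline
  fans a global seed out as `seed + stage index` so stages are
  independently reproducible.
* `rlnorm_cv1(cv = 0)` returns exactly 1, so noise-free configurations
  are exact, not merely tight.
* DNA-axis calibration with a zero-variance G1 population returns the
  single value directly (a kernel density cannot be formed); with
  variance it uses the density mode on the log2 axis, which is robust to
  the 4C shoulder of mCherry-only polyploid G1 cells.
* Ambiguous DNA values between windows go to the nearest peak; exact
  midpoints resolve by round-half-even, deterministically.
* Estimator edge cases: zero bi-coloured cells give $\hat p = 0$ with a
  CI floored at 0; $b_{\text{obs}} \ge 2/3$ clips to $\hat p = 1$.
* Redistribution shares are clipped at zero and renormalized; a zero
  cycling pool is an error, not NaN.
* Typed conditions separate configuration errors
  (`ploidyscope_config_error`) from data errors
  (`ploidyscope_data_error`); the shell wrapper maps them to exit codes
  2 and 3.

## 7. Known limitations

* The 3/2 inversion is exact only for 4C polyploids with equiprobable
  colours; 8C cells and colour-probability skew bias $\hat p$ downward
  and upward respectively (the plug-in mode addresses the latter).
* The efficiency-normalized percentage `b/e` divides a within-coloured
  fraction by a coloured-over-total efficiency; it mirrors the published
  arithmetic and is reported as such, without a model-based
  justification.
* Auto reporter thresholds require a mixed positive/negative population.
* The log-linear half-life fit assumes the distribution phase is
  negligible after the discard window; for very low GFR (long
  elimination phase) prefer the bi-exponential mode.
* Snapshot gating cannot distinguish diploid G2/M from tetraploid G1 at
  4C mVenus-only; this is a property of the reporter, faithfully
  retained, not a defect of the implementation.
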