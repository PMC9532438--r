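# ploidyscope

Quantification machinery for tubular-cell polyploidy after acute kidney
injury (AKI). After ischemic injury, most kidney tubular epithelial
cells (TC) that enter the cell cycle either die or endoreplicate —
acquiring 4C or 8C DNA content without dividing. Measuring that process
takes four complementary readouts, and this package implements the
analysis behind each of them, plus seeded synthetic-data generators with
known ground truth so the whole pipeline is testable without any
external data:

* **FUCCI2aR flow cytometry** (`classify_events`, `summarize_sample`,
  `redistribute_cycling`): mCherry-hCdt1 marks G1, mVenus-hGem marks
  S/G2/M; combined with DNA content this classifies every event as
  dead (reporter-positive, sub-2C), diploid G1, cycling, or polyploid
  (cycling / non-cycling), with DNA-axis self-calibration and
  pulse-width doublet exclusion.
* **Confetti multicolour reporter** (`p_bicoloured`,
  `estimate_polyploid_fraction`, `correct_for_efficiency`): a 4C cell
  recombines the reporter twice, so with three equiprobable colours
  P(bi-coloured | polyploid) = (n−1)/n = 2/3 and the polyploid fraction
  is estimated as p̂ = (3/2)·b_obs with a percentile-bootstrap CI;
  observed percentages are also normalized for recombination
  efficiency.
* **PicoGreen densitometry** (`calibrate_diploid_reference`,
  `ploidy_fold`, `compare_marker_groups`): per-nucleus DNA content as
  fold over a diploid internal control, compared between marker groups
  (e.g. YAP1⁺ vs YAP1⁻) by two-sided Mann-Whitney.
* **Physiology closed forms** (`fit_halflife`, `gfr_from_halflife`,
  `normalize_gfr`, `chip_fold_enrichment`): transcutaneous GFR from the
  FITC-sinistrin half-life, GFR [µl/min] = 14616.8/t½ × bw/100, with
  baseline/sham normalization; and ChIP-qPCR fold enrichment
  FR = 2^−(ΔCt_ab − ΔCt_IgG) with dilution-corrected ΔCt.

`run_pipeline()` ties the stages into a reproducible, manifest-checked
run; `inst/scripts/ploidyscope` is a thin shell wrapper over it.

## Worked example

```r
library(ploidyscope)

# 10,000 events with the day-2 post-injury composition preset
ev    <- simulate_fucci_events(fucci_sim_config(10000, seed = 11))
calls <- classify_events(ev)
round(summarize_sample(calls), 3)
#>    dead diploid_G1 cycling polyploid_noncycling polyploid_cycling
#> 1 0.076      0.443   0.399                 0.05             0.033
#>   polyploid_total n_events
#> 1           0.083     8026
```

Fractions are over induced singlet events (8,026 of 10,000 here:
doublets and non-induced events leave the denominator). The preset
encodes 39.8% true cycling; gating recovers 39.9%.

```r
# Confetti: 30,000 cells, 30% truly polyploid, 84.7% recombination efficiency
cells <- simulate_confetti(confetti_sim_config(
  30000, polyploid_fraction = 0.3, induction_efficiency = 0.847, seed = 2))
estimate_polyploid_fraction(tally_confetti(cells), seed = 2)
#> Confetti polyploidy estimate (sim, n = 25005 coloured cells)
#>   bi-coloured:            19.7%
#>   recombination efficiency: 83.4%
#>   efficiency-normalized:  23.6%
#>   polyploid fraction (3/2 x bi-coloured): 29.5% [28.8, 30.3]
```

The bi-coloured count alone (19.7%) under-reports polyploidy because a
third of polyploid cells recombine the same colour twice; the 3/2
inversion recovers the true 30% within its interval.

```r
# GFR from a noisy bi-exponential decay (true GFR 250 µl/min, 25 g mouse)
curve  <- simulate_decay(decay_sim_config(gfr_true = 250, body_weight = 25, seed = 3))
t_half <- fit_halflife(curve)
sprintf("t1/2 = %.2f min -> GFR = %.1f ul/min", t_half, gfr_from_halflife(t_half, 25))
#> "t1/2 = 14.69 min -> GFR = 248.8 ul/min"
```

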