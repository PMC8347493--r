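# hbdisc

Colorimetric haemoglobin mapping of the optic nerve head, cup morphology,
the composite GDF index, companion perimetric indices, and z-score/ROC
fusion machinery for glaucoma assessment — with seeded synthetic phantoms,
visual fields and cohorts so the whole pipeline runs and is tested without
clinical data.

## Who this is for

Researchers working on structure–function analysis of glaucoma who need a
transparent, scriptable implementation of vessel-referenced disc
colorimetry (the Laguna-ONhE family of indices), the perimetric indices it
is fused with, and the evaluation statistics used to compare diagnostic
indices on the same eyes.

## The methods, briefly

* **Haemoglobin map.** Haemoglobin absorbs green and reflects red, so each
  pixel's ratio `(R − G)/R` indexes its haemoglobin content. The retinal
  vessels — essentially pure blood — anchor the scale: tissue is reported
  as `100 · ratio / median(vessel ratios)`, a percentage of the vessel
  reference. The ratio is exactly invariant to a common channel gain.
* **Cup and sectors.** The cup is the low mode of the disc Hb histogram:
  Otsu split, contrast gate, closing across vessel shadows, largest
  component, moment-ellipse regularisation; vertical and area cup/disc
  ratios follow. Angular sectors (default 24) summarise the Hb
  distribution; features are placed on a normal cohort via midrank
  percentiles.
* **GDF.** `GDF = −[0.45·z_classifier + 0.55·mean(z_components)]` over
  z-scores normalised against the normal cohort and sign-aligned so larger
  means more glaucomatous; lower GDF = more glaucomatous. The classifier is
  a pluggable contract (a closed-form linear discriminant ships as the
  deterministic reference).
* **Perimetric indices.** MD (mean pointwise deviation from age-expected
  thresholds, negative in loss; Octopus-style values are sign-inverted on
  ingest), PSD (sample SD of the deviations), the rectified
  `PSDr = PSD + (|MD| − 16.33)/0.84` for `|MD| > 16.33` dB, and
  `TCV = 100·SD/mean` of the thresholds at 16 symmetric positions — an
  age-independent harmony index, with absolute scotomas excluded from both
  numerator and denominator.
* **Evaluation.** Midrank Mann–Whitney AUC (exact tie handling), DeLong
  comparison of correlated AUCs, sensitivity at 95%/99% specificity by the
  conservative empirical threshold, Steiger's test for dependent
  overlapping correlations, and the three-way confirmed / suspect / normal
  case classification (field and structural percentiles < 5, IOP and
  corneal-thickness suspicion rules).

See the methods vignette (`vignettes/hbdisc-methods.Rmd`) for the full
model descriptions, parameter defaults and design rationale.

## Worked example

Render a phantom with a known cup (half the disc radius), analyse it with
its ground-truth masks, and evaluate fused indices on a synthetic cohort:

```r
library(hbdisc)

ph <- make_disc_phantom(phantom_spec(cup_fraction = 0.5, seed = 42))
an <- analyze_fundus(ph$image, masks = ph$masks)
an
#> <onhe_analysis>
#> <hb_map> 3668 tissue px, reference ratio 0.7498, Hb% median 64.8 [27.9, 67.5]
#> <cup_estimate> vertical C/D 0.457, area C/D 0.243 (threshold 47.6 Hb%, 1219 px)
#> # A tibble: 1 × 4
#>   mean_hb vertical_cd area_cd inferotemporal_hb
#>     <dbl>       <dbl>   <dbl>             <dbl>
#> 1    58.5       0.457   0.243              56.2
```

The vessel reference ratio comes back at 0.7498 (the phantom renders its
vessels at 0.75), the rim sits near its rendered 65% haemoglobin level,
and the estimated vertical cup/disc ratio 0.457 recovers the rasterised
truth of 0.506 within the estimator's 0.05 tolerance despite vessels
crossing the cup.

```r
co  <- make_cohort(cohort_spec(500, 500, d = 1, rho = 0,
                               indices = c("TCV", "PSDr"), seed = 1))
roc <- cohort_roc(co, c("TCV", "PSDr"),
                  combinations = list(`TCV+PSDr` = c("TCV", "PSDr")))
tidy(roc)
#> # A tibble: 3 × 11
#>   index      auc     se ci_lo ci_hi sens95 sens99 thr95 thr99 n_cases n_controls
#>   <chr>    <dbl>  <dbl> <dbl> <dbl>  <dbl>  <dbl> <dbl> <dbl>   <int>      <int>
#> 1 TCV      0.743 0.0154 0.713 0.773  0.228  0.108  1.65  2.27     500        500
#> 2 PSDr     0.753 0.0151 0.724 0.783  0.268  0.092  1.65  2.30     500        500
#> 3 TCV+PSDr 0.824 0.0129 0.799 0.849  0.352  0.126  1.19  1.79     500        500
```

Each index was generated with a one-SD case shift, so the analytic
single-index AUC is Φ(1/√2) ≈ 0.76; fusing the two independent indices by
z-mean lifts the AUC to ≈ 0.82 (analytic Φ(1) ≈ 0.84) and raises the
sensitivity at 95% specificity from ~0.23–0.27 to 0.35. `autoplot(roc)`
draws the empirical ROC curves.

Perimetric indices on a generated advanced-defect field:

```r
vf_indices(make_vf("advanced", depth = 22, noise_sd = 0, seed = 1)$vf)
#> # A tibble: 1 × 5
#>      md   psd  psdr   tcv tcv_n_used
#>   <dbl> <dbl> <dbl> <dbl>      <int>
#> 1   -22     0  6.75  5.21         16
```

A uniform 22 dB depression has MD = −22 and PSD = 0 — the collapse the
rectification exists to undo: PSDr = (22 − 16.33)/0.84 = 6.75 restores a
value that keeps growing with the defect.

## Command line

A thin wrapper ships at `inst/cli/hbdisc.R`:

```sh
Rscript inst/cli/hbdisc.R simulate --what phantom --seed 7 --out-dir fixtures/
Rscript inst/cli/hbdisc.R analyze-image --image fixtures/phantom.png \
    --disc-mask fixtures/disc_mask.png --vessel-mask fixtures/vessel_mask.png \
    --out-dir results/
Rscript inst/cli/hbdisc.R vf-indices --vf field.csv --out vfi.json
Rscript inst/cli/hbdisc.R cohort-roc --cohort cohort.csv \
    --indices GDF,TCV --combine GDF+TCV --out roc.json
```

Subcommands: `analyze-image`, `vf-indices`, `cohort-roc`, `compare-auc`,
`classify`, `simulate`, `fit-reference`. All honour `--seed` and
`--config` (YAML), log to stderr, and produce byte-identical outputs on
identical invocations; every JSON embeds the package version, a config
hash and input checksums.

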