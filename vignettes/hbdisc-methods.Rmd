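---
title: "Colorimetric optic-nerve-head analysis and perimetric index fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric optic-nerve-head analysis and perimetric index fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdisc)
```

## The problem

Glaucoma damages the optic nerve head (ONH): the central cup enlarges, the
neuroretinal rim thins, and perfusion of the remaining tissue falls. All
three changes alter the *colour* of the disc on an ordinary fundus
photograph, because the visible redness of perfused tissue comes from
haemoglobin, which absorbs green light and reflects red. `hbdisc`
implements a colorimetric analysis of the ONH in the style of the
Laguna-ONhE family of methods — a haemoglobin proxy map referenced to the
retinal vessels, cup morphology estimated from that map, and a composite
Globin Distribution Function (GDF) index — together with the perimetric
indices it is designed to be fused with (MD, PSD, a rectified PSD, and the
threshold coefficient of variation, TCV), and the ROC machinery used to
evaluate single and fused indices.

Everything is testable without clinical data: seeded generators produce
disc phantoms with known cup geometry, visual fields with template defects,
and binormal cohorts with known effect sizes.

## The haemoglobin proxy map

For a pixel with red and green intensities $R$ and $G$, the haemoglobin
ratio is

$$h = \frac{R - G}{R},$$

undefined at $R = 0$. Since the central retinal vessels are essentially
pure blood columns, their colour anchors the scale: the map reports, for
every disc tissue pixel,

$$\mathrm{Hb}\% = 100 \cdot \frac{h_{\text{pixel}}}{h_{\text{vessels}}},$$

where $h_{\text{vessels}}$ is the **median** ratio over vessel pixels
inside the disc (dilated by a 2 px margin). The median was chosen over the
mean because specular highlights along vessel centrelines produce low-ratio
outliers; the statistic is configurable. Values are not clipped — tissue
redder than the vessels legitimately exceeds 100% — and pixels with
$R = 0$ are missing, never zero-filled. The ratio is invariant to a common
positive gain on both channels, which is what makes the map robust to
exposure differences; residual inter-camera differences are handled by an
affine per-channel calibration table (identity by default), which is the
package's extension point for camera harmonisation. Intensities are treated
as linear sensor values; no gamma model is applied.

## Cup estimation and sector morphology

The cup is pale: its Hb% forms the low mode of the disc histogram. The
estimator is deliberately simple and fully disclosed:

1. threshold at the Otsu split of the disc Hb values (the centre of the
   argmax plateau, so well-separated modes give the midpoint);
2. a **contrast gate**: if the disc Hb range is below 15 Hb points the cup
   is declared empty — a near-uniform disc has no detectable cup and a
   histogram split of pure noise would be arbitrary;
3. morphological closing (radius 5 px) to bridge vessel shadows;
4. largest connected component;
5. union with the component's moment ellipse (semi-axes $2\sqrt{\lambda}$
   of the pixel covariance — exact for a filled ellipse), clipped to the
   disc. This step exists because vessels crossing the cup's vertical poles
   leave notches no closing can restore, which would bias the vertical
   cup/disc ratio low; the union only ever adds pixels that the elliptical
   cup model implies. `regularize = "none"` disables it.

The vertical cup/disc ratio is measured on the single column through the
disc centroid (the maximum over columns is available via
`vertical_rule = "max_column"`); the area ratio is a pixel count ratio. On
noise-free phantoms with cup fractions 0.3–0.7 the pipeline recovers both
ratios within about 0.03 (tested to a 0.05 tolerance).

Sectors are pure angular wedges (default 24) about the disc centroid.
Sector 1 is centred on the temporal horizontal; angles advance
counterclockwise as viewed — inferior at 90°, nasal at 180°, superior at
270° — for right eyes, and left eyes are mirrored so that the same sector
index is the same anatomical sector in both eyes. We adopted wedges (rather
than rim/cup subdivisions) because they need no cup segmentation to be
well-defined and the hemifield contrasts the GDF components use are
captured either way. Sector areas always sum to 100% of the disc by
construction; a sector with no defined Hb pixel reports a missing mean, not
zero. Normative placement of any feature uses midrank empirical
percentiles, $100\,(\#\{x < v\} + \tfrac12\#\{x = v\})/n$, with a warning
for reference cohorts under 20 eyes.

## Fixture-grade segmentation

Clinical deployments of colorimetric ONH analysis use learned segmentation
models; those are out of scope here and their interfaces are the package's
boundary: users supply disc and vessel masks for real photographs. So that
the *pipeline* is still exercisable end-to-end, `hbdisc` ships deterministic
classical routines adequate for its phantoms: the disc is the largest
compact component above the 90th luminance percentile (opening to shave
protruding vessel segments, closing to bridge gaps, then a moment-ellipse
fill), and vessels are the high mode of the haemoglobin ratio under an
adaptive two-stage Otsu cut. Two guards matter: if the first Otsu split
leaves more than 35% of the region above the cut, the "vessel" class still
contains rim tissue and is split again; and if the resulting classes touch
(gap below 0.05 in ratio units) the split merely bisected one noisy mode
and the image is declared vessel-free. All parameters were chosen on
phantoms, and both routines are exactly gain-invariant because they only
use luminance quantiles and the ratio. Laterality and image quality are
accepted as metadata — a basic exposure/contrast sanity gate is provided,
but quality grading proper is upstream of this package.

## The GDF composite

All fusion happens in z-space: every index is normalised against the
normal cohort, $(x - \mu_{\text{normal}})/\sigma_{\text{normal}}$, then
sign-aligned so that larger z always means more glaucomatous (indices where
health is the larger raw value — MD, rim area, RNFLT, haemoglobin
percentages, GDF itself — are negated). The GDF mixes a classifier score
with morphology/perfusion components:

$$\mathrm{GDF} = -\left[\,w\, z_{\text{clf}} + (1-w)\,\overline{z}_{\text{comp}}\,\right],
\qquad w = 0.45,$$

negated so that lower GDF indicates glaucoma, the sign convention of the
published index. The component set is configurable; the shipped default is
mean disc Hb%, vertical Hb-C/D, area C/D and inferotemporal-sector Hb%,
aggregated as an unweighted mean of z-scores — the published work does not
enumerate its exact component set or internal weights, so these are this
package's own choices, stated here once and fixed. The classifier slot is a
*contract*: any external scorer can be plugged in. The shipped reference
classifier is a closed-form pooled-covariance linear discriminant (optional
ridge on the diagonal when the covariance is singular) so the pipeline is
deterministic and testable end-to-end; it stands where a learned
normal-vs-glaucoma model would go in production.

## Perimetric indices

Let $t_i$ be measured thresholds (dB) and $e_i$ age-expected values.
`MD` $= \overline{t_i - e_i}$ (internally always negative-in-loss; Octopus
mean-defect values, which are positive in loss, are sign-inverted on
ingest via `harmonize_md()`), and `PSD` is the sample SD of the pointwise
deviations (commercial per-location weighting is out of scope). PSD
collapses in advanced loss as more points reach 0 dB, so it is rectified:

$$\mathrm{PSDr} = \begin{cases} \mathrm{PSD} & |MD| \le 16.33\\
\mathrm{PSD} + (|MD| - 16.33)/0.84 & |MD| > 16.33\end{cases}$$

The correction term appears in the source literature with typography that
collapses the operator; we read it as a division by 0.84 because that
restores growth on the scale of MD (roughly 1.19 dB of PSDr per dB of MD),
which is the stated purpose of the rectification; the multiplicative
reading remains selectable (`op = "multiply"`). The transform is continuous
at the knee and monotone in $|MD|$.

`TCV` $= 100\,\mathrm{SD}/\mathrm{mean}$ of the thresholds at 16 symmetric
field positions — a pure harmony index: no normative surface, no age term,
invariant to a uniform scaling of sensitivity. The 16 positions are not
enumerated in the source literature; we ship the innermost sixteen
locations of the 24-2-like grid ($|x|, |y| \in \{3, 9\}°$), symmetric in
fours about both meridians, as an editable CSV
(`inst/extdata/tcv_positions.csv`). When absolute scotomas (0 dB) are
present both numerator and denominator must be adjusted; the default
excludes 0 dB points from both and records `n_used`, and a proportional
inflation by $16/n_{\text{used}}$ is selectable. Fields from left eyes are
mirrored about the vertical midline on ingest so one position set serves
both eyes.

## ROC, DeLong, and fixed-specificity sensitivity

AUCs are midrank Mann–Whitney statistics (ties get half credit), exactly
equal to the trapezoidal area of the empirical ROC; the test suite asserts
exact agreement with an exhaustive pairwise oracle. Correlated AUCs on the
same eyes are compared with the DeLong structural-components estimator
(cross-checked against an independent implementation and against a paired
bootstrap); confidence intervals are normal-approximation intervals on the
DeLong SE, clipped to [0, 1]. Sensitivity at 95%/99% specificity uses the
most permissive threshold whose empirical specificity reaches the target,
with no interpolation — conservative and exactly reproducible. Dependent
overlapping correlations (does index A track MD better than index B?) use
Steiger's Fisher-z test, with a permutation fallback, since the source
literature names no method. Eyes are the unit of analysis; inter-eye
correlation within subjects is recorded in the cohort table but not
modelled, matching the evaluation design this package mirrors, and flagged
here as a known limitation.

Case classification: *confirmed* glaucoma requires a visual-field sign (PSD
or MD percentile < 5 in the normal population) **and** a structural sign
(GDF or rim-area percentile < 5); otherwise *suspect* if any suspicion
criterion holds (IOP > 25 mmHg; IOP 21–25 mmHg with corneal thickness
< 500 µm; IOP > 21 mmHg with a family-history / dubious-disc /
borderline-field flag — the prose list is implemented as a disjunction,
each criterion independently testable); otherwise *normal*. A case that is
not confirmed, has no measured IOP and no risk flags raises a classified
"insufficient data" error rather than guessing; risk flags without a
measurable IOP do not, on their own, raise suspicion (every suspicion
criterion is anchored on pressure).

## Synthetic data: what it does and does not show

The phantom renders a bright disc (radius 40 px in a 256 px frame) with a
concentric paler cup, rim tissue at 65% and cup tissue at 30% of the
vessel haemoglobin signal, quadratic-Bézier vessel strokes crossing the
disc vertically, and Gaussian sensor noise (SD 1 on the 8-bit scale). The
visual-field generator subtracts template defects (arcuate, nasal step,
advanced) from a hill-of-vision normative surface (33 dB apex, 0.15 dB/deg
eccentricity fall-off, 0.6 dB/decade age decline — mid-range values for
white-on-white perimetry in normal adults) and floors at 0 dB; the
advanced template with depth ≥ 17 dB drives $|MD|$ past the 16.33 dB knee
so the rectification branch is exercised. Cohorts are multivariate normal:
normals at $N(0, \Sigma)$, cases shifted by $d$ SDs per index in each
index's disease direction, with exchangeable correlation 0.5 by default
(about what related structural/functional glaucoma indices show); the
analytic single-index AUC is $\Phi(d/\sqrt2)$, which the generator
reproduces empirically.

Passing tests on these generators shows that the *computations* are
correct and the pipeline recovers known ground truth under its stated
geometry; it says nothing about performance on real retinographies —
phantoms have none of the peripapillary atrophy, media opacity,
illumination gradients or anatomical variation that make real segmentation
hard, which is exactly why real-image users supply their own masks.

## Numerical choices and degenerate inputs

Seeds are mandatory for every generator (no hidden global state). Otsu
thresholds take the centre of the argmax plateau. Ties in percentiles use
midranks. `roc_auc` is computed via average ranks, so tie handling is
exact. A DeLong comparison of two score vectors inducing identical
rankings returns difference 0 and p = 1 by construction rather than 0/0.
Empty vessel masks, non-positive vessel references, single-class inputs,
mismatched field locations and non-PSD correlation matrices are all hard
errors with diagnostic messages. CLI outputs print numbers at 6
significant digits with fixed key order and no timestamps, so identical
invocations are byte-identical; every output embeds the package version, a
config hash and input checksums.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use cohorts of 300–500
eyes per group, 100-replicate fusion experiments, 200-simulation null
calibrations with a 2000-replicate bootstrap, and 256 px phantoms — sizes
at which the Monte-Carlo error is comfortably below the asserted
tolerances while the whole suite runs in well under a minute.
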