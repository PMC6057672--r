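---
title: "Coccolith morphometry, calcification varieties and their ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coccolith morphometry, calcification varieties and their ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccolithr)
```

## The measurement problem

*Emiliania huxleyi* sheds micron-scale calcite plates (coccoliths) whose
mass varies with both size and degree of calcification. Under crossed
polarizers, calcite up to about 1.55 µm thick maps grey level linearly to
thickness, so a calibrated micrograph turns into a thickness map and a
segmented coccolith into a mass:

$$ m = \sum_{\text{pixels}} \frac{g - g_0}{\gamma}\, \Delta^2\, \rho_c $$

with grey $g$, background $g_0$, gain $\gamma$ (grey per µm thickness),
pixel size $\Delta$ (µm) and $\rho_c = 2.7$ pg µm⁻³. Two complications
drive this package's design:

1. **The shield-dimness bias.** The coccolith's optically bright part is
   the central tube ring; the thin distal-shield rim falls below any
   sensible segmentation threshold. The segmented extent — the *apparent
   length* — therefore underestimates the true distal-shield length (DSL),
   and the bias must be corrected by regressing electron-microscope
   reference lengths on apparent lengths.
2. **Mass–size confounding.** A sample's mean coccolith mass $M_s$ rises
   with coccolith size even at constant calcification. The calcification
   index divides that out:
   $$ C_i = \frac{M_s}{M_n}, \qquad M_n = k_s\, L_c^3\, \rho_c $$
   where $L_c$ is the mean corrected length and $k_s = 0.02$ the Type A
   shape constant: $M_n$ is the mass a normally calcified coccolith of
   that length would carry, so $C_i$ is a size-normalized calcification
   degree. On the worked province averages,
   `calcification_index(4.76, 3.45)` gives
   `r round(calcification_index(4.76, 3.45), 3)` and
   `calcification_index(3.77, 3.25)` gives
   `r round(calcification_index(3.77, 3.25), 3)`.

Within morphotype Type A, coccoliths fall into calcification varieties
read off SEM measurements of the distal shield: the radial slit length
(SL) outside the tube and the radial tube width (TW). A1 (lightly
calcified) has SL > TW, A2 (intermediate) SL ≈ TW, A3b (heavy) SL < TW,
and A3a is marked by a nearly-or-completely closed central area, which
takes precedence because its SL/TW ratio is erratic. "≈" is inherently
qualitative; `classification_policy()` operationalizes it as a relative
band `|SL − TW| ≤ ε·TW` with ε = 0.10 by default, band edges resolving to
A2, and a closure cut of 0.75 for "nearly closed". Both are free
parameters surfaced in the API, because no quantitative boundary exists in
the morphological literature.

## The synthetic generator

Field datasets of this kind are rarely deposited per sample, so the
package treats simulation as a first-class module rather than a test
fixture. A ground-truth coccolith is three concentric elliptical zones
sharing the shield outline (semi-axes $a = \mathrm{DSL}/2$,
$b = a\,e$ with ellipticity $e = 0.8$): a thin shield rim of radial width
SL, a thick tube ring of width TW, and a central area of which a fraction
`central_area_closure` is covered by a plate. Its true mass is the exact
integral of thickness × area × $\rho_c$ over the zones, which gives every
downstream mass estimate an analytic oracle (the renderer is checked to
conserve it within 1%, the fine-grid numeric integral to 0.5%).

Per-variety distributions (`variety_params()`) encode the defining
contrasts — A1 draws satisfy SL > TW(1+margin), A3b SL < TW(1−margin), A2
stays within half the margin of equality, A3a draws its closure above the
cut — with a generation margin of 0.15 so the classes are separable by
construction, and A3b drawn larger and thicker-tubed than A1 so the
field's size–calcification covariance emerges. Tube width is allometric
(a fraction of DSL, ~0.10 for A1 up to ~0.16 for A3a/A3b) so slit loss
scales with size; this is what makes the regression of apparent length on
DSL come out with slope < 1, the signature of the shield-dimness bias.
Absolute sizes and thicknesses (DSL means 2.6–3.8 µm, tube thickness
0.25–0.65 µm, shield 0.06 µm) are free parameters chosen to give
per-coccolith masses of roughly 1.5–7 pg and sample means in the 2–6 pg
range typical of subtropical field populations; they are not claimed to
match any particular sea's populations.

The optics model (`plm_optics()`) is linear grey–thickness with
saturation at 1.55 µm (the first-order birefringence plateau of calcite),
additive Gaussian read noise (σ = 50 grey by default), and 16-bit
quantization at 0.05 µm/px — a plausible ×1000 setup; the gain default
(38 000 grey/µm) keeps all generated thicknesses in the linear range.
There is no attempt at full interference-colour physics, point-spread
blur, or 3-D coccosphere rendering; consequently, passing tests show the
measurement chain is unbiased *under this optics model*, not that a real
microscope is calibrated.

The virtual transect (`transect_config()`, `generate_transect()`) spans
20 stations from 6.6° W to 31° E by default. Environmental profiles are
smooth functions of longitude — eastward the water warms (15.5→21 °C),
gets saltier (36.3→39.4), more alkaline (2330→2620 µmol kg⁻¹) and
nutrient-poorer — with small Gaussian station scatter (15% of each
variable's spread) so ranks are not degenerate, and light decays
exponentially with depth. Variety abundances follow Gaussian niche
responses on standardized variables (the standard unimodal
community-ecology model): A1 prefers fresher western water, A3b saltier
eastern water, A3a colder, nutrient-richer water, A2 is broadly tolerant
and B/C tracks the cool inflow. Counts per sample (default 300, the usual
counting effort) are multinomial in the niche weights. Everything is
deterministic given a seed.

## Numerical and procedural choices

* **Segmentation** is thresholded connected-component labelling
  (8-connectivity) — deliberately simple and deterministic, replacing
  neural-network coccolith recognition while preserving its outputs (mass
  and length per coccolith). The default threshold is Otsu's method on the
  non-background histogram (pixels above the modal grey plus three Poisson
  standard deviations); a fixed threshold is available for strict
  reproducibility. Enclosed holes are filled before labelling so a tube
  ring and its central plate count as one coccolith.
* **Intact/isolated filtering**: components touching the frame border or
  under 20 px are excluded; disjoint components whose convex hulls
  intersect (separating-axis test) are flagged not-isolated and excluded,
  the per-mask analogue of rejecting overlapping coccoliths.
* **Mass halo**: because the shield rim is below threshold by design, the
  mass integral runs over the mask dilated by 0.8 µm (background-
  subtracted, so the extra pixels only add zero-mean noise); the apparent
  length always comes from the undilated mask. Without the halo the
  shield's ~5% of calcite would be systematically lost.
* **Apparent length** is the maximum Feret diameter of the mask (largest
  hull-vertex distance plus one pixel), robust to slit-induced concavity,
  rather than a fitted-ellipse major axis.
* **Length correction** is ordinary least squares of reference length on
  apparent length. The shipped fallback coefficients are slope 0.585 and
  intercept 0.4537 µm; `fit_length_correction()` refits per dataset, which
  is the default in the pipeline. Note the shipped line *shortens* lengths
  above 1.09 µm — the package applies it exactly as given and leaves the
  orientation to the user, since either regression direction can be fitted
  from the same pairs.
* **Averaging order for $C_i$**: per sample, from the mean mass and the
  cube of the corrected mean length (the correction is linear, so the
  corrected mean equals the mean of corrected lengths). A per-coccolith
  variant (mean of individual $m/M_n$ ratios) is available via
  `summarize_samples(method = "per_coccolith")`; the two differ by a
  Jensen-type term that grows with the length spread.
* **Spearman correlations** are Pearson correlations of midranks (average
  ranks on ties), with a two-sided t-approximation for n > 9 and exact
  enumeration of all n! permutations for n ≤ 9; significance at p ≤ 0.05,
  stars `**` at 0.01. No multiple-testing correction is applied across a
  battery by default (a Benjamini–Hochberg option exists), matching common
  practice in this literature.
* **CCA** is delegated to `vegan::cca()` behind `cca_ordination()`, with
  axis shares reported relative to the *constrained* inertia (summing to
  100) and relative to total inertia alongside, weighted-average site
  scores by default (linear-combination scores by flag), scaling-2 species
  scores, and intraset env–axis correlations computed as row-mass-weighted
  correlations of each variable with the LC scores. Exactly collinear or
  constant predictors are dropped with a warning. The test suite checks
  the eigenvalues against an explicit chi-square-residual/weighted-
  projection construction to 1e-10.

## Problem sizes and what the tests show

The suite runs at desk scale: geometry and classification properties on a
few hundred random draws, mass recovery on a 500-coccolith render (ten
1250-px frames), oracle comparisons on ≤ 6×5 tables, and the end-to-end
sign-recovery experiment on a 20-station, 300-coccolith-per-sample
transect — about half a minute in total. Passing them demonstrates
internal consistency against analytic ground truth and configured signs;
it does not validate the generator's free parameters against any real
population, and magnitudes of the synthetic correlations are not
comparable to field tables.

## Known limitations

Type B/C enters only as a labelled fraction (no geometric model and no
image-based morphotype discrimination); $k_s$ is the Type A constant only;
the optics model ignores diffraction and interference colours; coccoliths
are rendered flat-lying and non-overlapping unless placements say
otherwise; and SEM measurement is table-driven (no SEM image processing).
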