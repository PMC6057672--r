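# coccolithr

Coccolith morphometry and its ecological interpretation, from simulated
cross-polarized-light microscopy to constrained ordination.

Coccolithophores — above all *Emiliania huxleyi*, the dominant calcifying
phytoplankton of the modern ocean — build shells of calcite plates
(coccoliths) whose mass responds to the environment. A standard way to study
this in field samples is birefringence mass estimation: below ~1.55 µm of
calcite, the grey level of a coccolith photographed between crossed
polarizers is proportional to its calcite thickness, so integrating grey
over a segmented coccolith yields its mass in picograms. Because the thin
outer distal shield is too faint to segment, the apparent length
underestimates the true distal-shield length (DSL) and must be corrected
against electron-microscope reference measurements. The mean mass of a
sample, `M_s`, confounds size and calcification degree; the **calcification
index** separates them:

```
C_i = M_s / M_n,     M_n = k_s · L_c³ · ρ_c
```

with `L_c` the mean corrected length (µm), `k_s = 0.02` the Type A shape
constant and `ρ_c = 2.7 pg µm⁻³` the density of calcite. Within morphotype
Type A, individual coccoliths are further assigned to **calcification
varieties** from SEM measurements: a nearly/completely closed central area
marks A3a; otherwise slit length (SL) vs tube width (TW) decides — SL > TW
is the lightly calcified A1, SL ≈ TW the intermediate A2, SL < TW the heavy
A3b. Variety percentages (summing to 100 over Type A) can then be related
to environmental gradients with Spearman rank correlations and canonical
correspondence analysis (CCA).

`coccolithr` implements this whole chain and, because per-sample field data
of this kind are rarely deposited, ships a first-class synthetic generator:
parametric ground-truth coccoliths with exact analytic masses, a
linear-plus-saturation optics model that renders them into 16-bit
polarized-light rasters, and a virtual west–east transect whose variety
abundances follow configurable Gaussian niche responses to smooth
environmental gradients. Every stage is therefore testable against known
truth. It is a package for biological oceanographers and
micropaleontologists who want a reproducible, scriptable version of this
workflow, and for method developers who need a ground-truthed benchmark.

## Worked example

```r
library(coccolithr)

# the two worked province averages: mean mass (pg) and corrected length (um)
calcification_index(4.76, 3.45)   # south-eastern province
#> [1] 2.146624
calcification_index(3.77, 3.25)   # Atlantic-Gibraltar province
#> [1] 2.03375

# simulate a micrograph and measure it back
set.seed(1)
img <- render_plm(sample_shapes(5, "A2"), width = 600, height = 600)
m   <- match_ground_truth(measure_plm(img), img)
m[, c("mass_pg", "true_mass", "apparent_length_um", "distal_shield_length")]
#> # A tibble: 5 × 4
#>   mass_pg true_mass apparent_length_um distal_shield_length
#>     <dbl>     <dbl>              <dbl>                <dbl>
#> 1    3.17      3.16               2.37                 3.11
#> 2    3.70      3.71               2.61                 3.40
#> 3    3.32      3.32               2.51                 3.36
#> 4    3.05      3.03               2.20                 3.05
#> 5    5.15      5.18               2.83                 3.78
```

Measured masses land within ~1% of ground truth; apparent lengths fall
short of the true DSL because the dim shield rim sits below the
segmentation threshold — exactly the bias the length calibration corrects.

A full virtual campaign, from simulation to ecology statistics:

```r
run <- run_transect_pipeline(
  transect_config(n_stations = 20, coccoliths_per_sample = 300), seed = 7)
run
#> Transect run: 20 sample(s)
#>   M_s 3.02-5.36 pg, L_c 3.07-3.52 um, C_i 1.88-2.28
#>   64 of 72 Spearman correlations significant at p <= 0.05
dplyr::filter(run$correlations, left == "A3b_pct", right == "salinity")
#> # A tibble: 1 × 7
#>   left    right      rho  p_value     n significant stars
#>   <chr>   <chr>    <dbl>    <dbl> <int> <lgl>       <chr>
#> 1 A3b_pct salinity 0.991 3.64e-17    20 TRUE        **
tidy(run$cca)        # constrained-axis eigenvalues and % inertia
autoplot(run$cca)    # CCA triplot
```

The heavy A3b variety tracks the configured salinity gradient with the
positive rank correlation the generator imposed — the sign-recovery check
the test suite automates.

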