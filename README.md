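# lvmass

Left-ventricular mass (LVM) quantification from traced 2D echocardiographic
contours, with the full method-agreement protocol used for anatomical
(necropsy) validation and a synthetic LV phantom generator with analytic
ground truth.

Increased LVM is a powerful predictor of adverse cardiovascular events, but
the guideline linear (1D) methods are too inaccurate for individual use.
This package implements five end-diastolic quantification methods side by
side — so they can be compared on the same subjects — together with the
statistics needed to judge them against a reference mass, and a simulator
that makes the whole chain testable without any image data. It is aimed at
researchers validating echocardiographic LVM methods (against necropsy, CMR
or phantoms) and at method developers who need reproducible synthetic
cohorts.

## The methods

All methods convert a myocardial volume to mass with the myocardial density
ρ = 1.05 g/ml (configurable):

| method | inputs | formula core |
|---|---|---|
| Devereux (1D) | IVSd, LVIDd, PWTd | `0.8·1.04·[(IVSd+LVIDd+PWTd)³ − LVIDd³] + 0.6` |
| Area-Length (2D) | PSAX areas A₁, A₂; AP4CH length L | `ρ·(5/6)·[A₁(L+t) − A₂L]` |
| Truncated Ellipsoid (2D) | A₁, A₂; AP4CH split a, d | prolate-spheroid shell with wall t |
| Biplane endo/epi (2D) | 4 apical contours | `ρ·(V_epi − V_endo)`, biplane disks |
| Wall-addition (2D) | 2 apical endo contours + PSAX | t added to each disk of the endocardial stack |

with the mean wall thickness `t = √(A₁/π) − √(A₂/π)` from the parasternal
short-axis areas (epicardial A₁, endocardial A₂), and the biplane method of
disks `V = (π/4)·Σ aᵢbᵢ·h` over N = 20 disks. The wall-addition method
reconstructs the epicardial volume from the endocardial tracing alone —
each disk widened by 2t, the axis extended by t at the apex — so the
hard-to-trace apical epicardial border is never needed.

The agreement protocol treats the reference as truth: bias and 95% limits
of agreement (±1.96 SD of the differences), CV (difference SD relative to
the reference mean), SEE (residual SD of method-on-reference regression),
Pearson r, paired t-test, proportional-bias regression, per-subject
most/least-accurate ranking, and intra-/inter-reader variability.

## A worked example

Simulate a calibrated 34-subject cohort (true mass 132 ± 11 g, LVIDd
4.8 ± 0.3 cm, wall 0.97 ± 0.08 cm, default tracing noise) and validate all
five methods against the analytic ground truth:

```r
library(lvmass)
cohort <- simulate_cohort(n = 34, seed = 1)
pl <- run_pipeline(cohort, quiet = TRUE)
pl$agreement[, c("method", "n", "bias_g", "loa_g", "cv_pct", "see_g", "r")]
#>                method  n bias_g loa_g cv_pct see_g     r
#> 1            devereux 34  27.23  50.6  19.06  24.8 0.130
#> 2         area_length 34  21.27  20.8   7.83  10.6 0.791
#> 3 truncated_ellipsoid 34  -2.51  20.1   7.57  10.4 0.743
#> 4    biplane_endo_epi 34   2.24  61.7  23.26  31.3 0.158
#> 5               novel 34  -1.89  19.9   7.50  10.1 0.809
```

Read: the cube formula (`devereux`) overestimates mass by ~27 g with ±51 g
limits of agreement and a 19% CV; the wall-addition method (`novel`) is
near-unbiased (−1.9 g) with the narrowest limits (±19.9 g), the smallest
CV (7.5%) and the best correlation with truth (r = 0.81). The per-subject
ranking tells the same story — the wall-addition method is most accurate
for 29% of subjects and least accurate for none:

```r
pl$ranking
#>                method most_n most_pct least_n least_pct
#> 1         area_length      3     8.82       7     20.59
#> 2    biplane_endo_epi      8    23.53      12     35.29
#> 3            devereux      4    11.76      13     38.24
#> 4               novel     10    29.41       0      0.00
#> 5 truncated_ellipsoid      9    26.47       2      5.88
```

On a *noiseless* phantom the oracle ladder is visible directly — the
Truncated Ellipsoid is exact on this geometry (132.24 g true mass), the
biplane tracing is within disk-quadrature error, the wall-addition method
sits in its documented −5%…+3% geometric band, and the 1D cube formula
overestimates:

```r
shell <- shell_spec(b_endo = 2.4, a_apex = 7, d_base = 1.19, t_wall = 0.97)
lvm_quantify(simulate_study(shell, noiseless()))
#>   study_id              method mass_g   t_cm edv_endo_ml edv_epi_ml feasible
#>  synthetic            devereux  163.3     NA          NA         NA     TRUE
#>  synthetic         area_length  156.3 0.9699          NA         NA     TRUE
#>  synthetic truncated_ellipsoid  132.2 0.9699          NA         NA     TRUE
#>  synthetic    biplane_endo_epi  132.3     NA       105.8      231.8     TRUE
#>  synthetic               novel  131.3 0.9699       105.8      230.8     TRUE
```

Studies round-trip through a versioned JSON contour format
(`write_study()` / `read_study()`; CSV point lists via
`read_contours_csv()`), and `inst/cli/lvmass.R` wraps the
`compute` / `simulate` / `agree` steps for shell use.

See the vignette (`vignettes/lvm-quantification.Rmd`) for the geometry
conventions, the disk-expansion rule and its pre-computed error band, the
noise-model calibration, and what phantom validation can and cannot show.

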