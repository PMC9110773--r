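---
title: "Quantifying left-ventricular mass from traced echocardiographic contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular mass from traced echocardiographic contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmass)
```

## The problem

Left-ventricular mass (LVM) is one of the strongest echocardiographic
predictors of adverse cardiovascular events, yet the recommended linear
(1D) quantification methods are too inaccurate for individual patient
decisions. `lvmass` implements, side by side, five methods that estimate
LVM at end-diastole from traced 2D contours and calliper measures, plus the
full method-agreement protocol used to validate them against an anatomical
reference mass (a weighed necropsy ventricle or an equivalent gold
standard), and a synthetic phantom generator so that every method and every
statistic can be verified against analytic ground truth without any image
data.

All methods share the same convention: the myocardial volume $V_{myo}$ (ml)
is converted to mass with the myocardial density $\rho = 1.05$ g/ml,

$$\mathrm{LVM} = \rho \, V_{myo}.$$

The density is configurable (`method_config(density = )`) because infarct
edema and fibrosis can change it.

## The five methods

**Devereux cube formula (1D).** From the septal thickness IVSd, internal
diameter LVIDd and posterior wall thickness PWTd (cm), using the
guideline-corrected formula

$$\mathrm{LVM} = 0.8 \cdot 1.04\left[(\mathrm{IVSd}+\mathrm{LVIDd}+
\mathrm{PWTd})^3 - \mathrm{LVIDd}^3\right] + 0.6 \; \mathrm{g}.$$

The 1.04 g/ml density and the $0.8 x + 0.6$ regression correction are part
of the formula, so the configurable density does not enter here, and the
formula is homogeneous of degree 3 only up to its additive constant.

**Mean wall thickness from PSAX.** The two short-axis areas — epicardial
$A_1$ and endocardial $A_2$ — define the mean wall thickness as the
difference of the equivalent-circle radii,

$$t = \sqrt{A_1/\pi} - \sqrt{A_2/\pi},$$

which is exactly the anatomical thickness for concentric circular borders.
Whether clinical analysis software derives $t$ this way or by averaging
direct thickness measurements is generally not documented; the
equivalent-circle form is adopted here because it uses the same traced
areas as the 2D methods and is exact in the concentric limit.

**Area-Length (2D).** With the apical long-axis length $L$:
$\mathrm{LVM} = \rho \tfrac{5}{6}\left[A_1 (L + t) - A_2 L\right]$.

**Truncated Ellipsoid (2D).** Models the cavity as a prolate spheroid with
minor radius $b = \sqrt{A_2/\pi}$, apical semi-axis $a$, truncated by the
mitral plane at distance $d$ below the widest minor axis, with a uniform
wall $t$:

$$\mathrm{LVM} = \rho\,\pi \left\{ (b+t)^2 \left[\tfrac{2}{3}(a+t) + d -
\tfrac{d^3}{3(a+t)^2}\right] - b^2\left[\tfrac{2}{3}a + d -
\tfrac{d^3}{3a^2}\right]\right\}.$$

$a$, $d$ and $L$ are measured on the AP4CH tracing: the widest chord
perpendicular to the long axis splits the axis into $a$ (to the apex) and
$d$ (to the base). The widest plane is located on a midpoint scan refined
by a parabolic fit of the squared chord — exact for ellipse profiles, where
the squared chord is globally quadratic in the axial coordinate. Whether
clinical software uses the AP4CH length or the longer of both apical views
for these methods is unstated; the AP4CH is used because the method is
defined on that single view.

**Biplane endo-/epicardial tracing (2D).** Both borders traced in both
apical views; $V_{myo} = V_{epi} - V_{endo}$, each volume by the biplane
method of disks below.

**Wall-addition method (2D).** The newest method: trace only the
*endocardium* in the two apical views (epicardial apical borders are the
hardest to trace), take $t$ from PSAX, and reconstruct the epicardial
volume by adding the wall to each disk of the endocardial stack:

$$V_{myo} = \mathrm{EDV}_{EPI} - \mathrm{EDV}_{ENDO}, \qquad
\mathrm{LVM} = \rho\,V_{myo}.$$

## The biplane method of disks

An apical contour's long axis runs from the midpoint of the base (mitral
annulus) segment to the vertex farthest from it; distance ties — which only
occur for synthetic circular arcs — break toward the vertex farthest from
the base line. The cavity is cut into $N$ slabs of equal height and the
chord width perpendicular to the axis is evaluated at each slab *midpoint*
(whether clinical software samples midpoints or edges is not documented;
the midpoint rule was chosen and its quadrature error is characterised
below). A chord is the total in-segment length of the slicing line (even–odd
rule), so mildly non-convex tracings are handled. With diameters $a_i$,
$b_i$ from the two views,

$$V = \frac{\pi}{4} \sum_{i=1}^{N} a_i b_i \, h , \qquad h = L / N .$$

When the two views disagree on axis length, the common disk height uses the
longer $L$ and each view's chords are sampled at the common slab fractions
of its own length — the standard biplane convention. $N = 20$ by default
(the guideline-standard count), configurable.

On a half-spheroid the midpoint rule's relative error is exactly
$1/(8N^2)$: 0.125% at $N = 10$, 0.031% at $N = 20$, confirming second-order
convergence. This is the only numerical error of the endo-/epicardial
tracing method on smooth phantoms.

## The disk-expansion rule of the wall-addition method

"Adding the wall to each disk" admits more than one geometry, and the
choice matters. Two rules are implemented behind
`method_config(expansion = )`:

* **`extend_apex` (default).** The epicardial stack has $N$ disks over the
  extended axis $L + t$ (the apex gains a wall cap; the base plane, the
  mitral annulus, gains none). Each disk's diameters are the endocardial
  chords resampled at the disk's *absolute* axial position, plus $2t$
  (wall on both margins); disks beyond the endocardial apex are pure wall
  of diameter $2t$.
* **`stretch`.** The endocardial fraction-sampled chords are reused
  unchanged with the taller disks of the extended axis, i.e. the profile is
  stretched axially before widening.

The difference was quantified *before* the implementation with an
independent analytic-chord oracle over a calibrated grid of 125
truncated-spheroid shells ($a$ 6–8 cm, $b$ 2.2–2.6 cm, $t$ 0.8–1.2 cm,
$d = 0.17a$ — end-diastolic left ventricles of large-animal/human size):

| rule | relative mass error vs analytic shell |
|---|---|
| `extend_apex` | −5.2% … +2.6% (mean −1.0%) |
| `stretch` | +17% … +20% |

The stretch rule double-counts wall (it widens chords that were *also*
displaced apically), grossly overestimating mass, which contradicts the
near-zero bias this method achieves in vivo; `extend_apex` is therefore
the default, and the package's implementation is required (in the test
suite) to match the oracle reconstruction to 0.1%.

The documented `extend_apex` band applies to *elongated* LV-like shells.
For the degenerate hemispherical shell ($a = b = 2.4$, $t = 0.8$) the
reconstruction under-estimates the shell mass by 26%, because the flat
disk stack cannot represent the dome-shaped apex cap that dominates a
shell with $a/b = 1$ and $t/b = 1/3$. Real end-diastolic ventricles have
$a/b \approx 3$, where the apex cap is a small correction.

## The agreement protocol

Validation treats the reference (necropsy) mass as *truth*, not as a second
method. With per-subject differences $d_i = \hat{m}_i - m_i$ (positive =
overestimation by echocardiography):

* **Bias and LOA**: $\bar{d} \pm 1.96\,\mathrm{SD}(d)$. The multiplier is
  exactly 1.96 (95% limits), configurable.
* **CV**: $100\,\mathrm{SD}(d) / \bar{m}_{ref}$ — the difference SD
  adjusted to the mean reference mass.
* **SEE**: residual SD of the OLS regression of the *method* on the
  *reference* (the reference is the independent variable),
  $\sqrt{\sum r_i^2 / (n-2)}$.
* **Pearson r** with its two-sided $t$-based p-value; **paired t-test** on
  the differences (zero-variance differences: p = 1 when the common
  difference is zero, p = 0 in the constant-offset limit).
* **Proportional bias**: OLS of $d_i$ on $m_i$; "no proportional bias" is
  declared at $p \ge 0.05$ (two-sided, no multiplicity adjustment).
  Numerically constant differences short-circuit to slope 0, p = 1.
* **Per-subject accuracy ranking**: smallest / largest $|d_i| / m_i$ per
  subject; ties split the credit equally ($1/k$ for a $k$-way tie) so
  counts always total $n$.
* **Reader variability**: differences are repeat − baseline, the CV
  denominator is the baseline mean, and the SEE regresses the repeat on
  the baseline reading.

Every statistic is checked against an explicit brute-force summation
implementation to $10^{-12}$ on randomised fixtures.

## The synthetic phantom

The phantom family is a truncated prolate-spheroid shell with uniform wall
(`shell_spec`): endocardial semi-axes $a$ (apical) and $b_x, b_y$
(short; equal for a solid of revolution), truncated at $d$ below the
equator, wall $t$. Its myocardial volume has the closed form used by the
Truncated Ellipsoid method, so

* ground truth is analytic (`true_myocardial_volume`, checked against 1D
  numerical quadrature to $10^{-6}$), and
* the TE method is an *exact oracle* on noiseless phantoms — a deliberate
  property that anchors the whole oracle ladder: TE exact $\le$ biplane
  endo/epi (disk quadrature only) $\le$ wall-addition (documented
  geometric band).

`render_contours` produces the polygons a perfect reader would trace
(AP4CH in the $x$–$z$ plane, AP2CH orthogonal, PSAX at the equator), with
the apex an exact vertex and base landmarks on the truncation plane.

**Cohort calibration** (`simulate_cohort` defaults). Shells are drawn from
truncated normals (at ±3 SD, preventing non-physical shapes) calibrated to
an end-diastolic porcine-like cohort: true mass 132 ± 11 g, LVIDd
4.8 ± 0.3 cm ($b = \mathrm{LVIDd}/2$), wall 0.97 ± 0.08 cm. For each
subject the apical semi-axis is *solved* (monotone root-finding, with
$d = 0.17a$) so the shell's analytic mass equals its drawn target exactly;
the resulting shells have $a \approx 7$ cm, cavity EDV $\approx 105$ ml —
realistic end-diastolic dimensions for a 50-kg pig or an adult human. The
0.17 truncation fraction reproduces those proportions and is held fixed.

**Tracing noise** (`tracing_noise` defaults). Manual tracing error is
modelled as a smooth multiplicative radial field (a random 5-harmonic
series about the contour centroid), normalised so the enclosed area is
unbiased in expectation; the star-shaped construction keeps every noised
polygon simple. Defaults, chosen once against reported intra-/inter-reader
reproducibility levels (CVs near 9–10% for all methods) and then frozen:

| parameter | default | what it models |
|---|---|---|
| `point_jitter_sd` | 0.05 (fraction of local radius) | border placement |
| `epi_apical_mult` | 2 | epicardial apical borders are the hardest to see |
| `border_corr` | 0.7 | endo/epi borders traced on one image share error |
| `landmark_jitter_sd` | 0.08 cm | mitral-annulus landmark placement |
| `linear_sd` | 0.05 cm | calliper noise on IVSd/LVIDd/PWTd |
| `thickness_bias` | 0 | optional systematic outward epicardial placement |

Under these defaults the simulated intra-reader CV of the wall-addition
method lands near 9%, and a full simulated cohort reproduces the
*qualitative* accuracy pattern seen in vivo: the cube formula and
Area-Length overestimate mass by ~20 g with the widest limits of
agreement, the endo-/epicardial tracing method is unbiased but noisy (four
hard borders, and the myocardial volume is a small difference of two large
volumes), and the wall-addition method is near-unbiased with the
narrowest-or-near-narrowest limits.

**What the phantom does *not* emulate.** Real ventricles are not truncated
spheroids: regional shape variation, apical tapering, wall-thickness
non-uniformity and papillary/trabecular irregularity are absent (contours
are assumed traced excluding papillary muscles). This matters for
interpreting the validation: on these phantoms the Truncated Ellipsoid
method is exact *by construction*, so its phantom performance is an upper
bound that real ventricles — where its spheroid assumption fails — do not
reach. Consequently the phantom reproduces the in-vivo *direction* of the
method differences (cube-formula overestimation, the wall-addition
method's near-zero bias and low CV) but cannot reproduce the wall-addition
method's empirical *dominance over TE*: in replicate simulated cohorts the
wall-addition, TE and endo/epi methods race as three near-unbiased
estimators and no single one wins a large majority of replicates. Showing
that dominance requires phantoms with realistic shape mismatch, which is
out of scope here.

## Numerical choices and degenerate inputs

* Units are cm / cm² / ml / g everywhere, enforced at type boundaries.
* Mass methods accept the zero-wall limit $A_1 = A_2$ (returning 0 g) and
  reject inverted tracings ($A_1 < A_2$); the contour-level
  `mean_wall_thickness_psax` is strict (errors at $t \le 0$).
* Contours are validated as simple polygons at construction; the tracing
  noise preserves simplicity by construction (star-shaped fields) and
  retries landmark draws that break it (5 attempts, then an error).
* Operations act on whatever cardiac phase a contour is labelled with;
  frame selection is upstream of this package.
* All simulation is driven by one seeded RNG stream per cohort, so equal
  seeds give byte-identical pipelines end to end.

## Problem sizes used in the validation suite

The shipped tests validate on: a 5×5×5 calibrated shape grid (exact-oracle
and error-band checks), disk counts $N \in \{10, 20, 40, 80\}$
(convergence order), 100 random fixtures of $n$ = 5–50 (statistics
oracles), and 100 replicate cohorts of $n = 34$ subjects (accuracy
ordering under the default noise). Rendered test contours use 129–513
vertices; at 257 vertices polygonisation contributes relative errors below
$10^{-4}$, an order of magnitude under the quadrature error at $N = 20$.

## A worked example

```{r example}
set.seed(1)
cohort <- simulate_cohort(n = 34, seed = 1)
pl <- run_pipeline(cohort, quiet = TRUE)
pl$agreement[, c("method", "bias_g", "loa_g", "cv_pct", "see_g", "r")]
pl$ranking
```

```{r plot, fig.width = 6, fig.height = 5}
truth <- cohort_truth(cohort)
novel <- subset(pl$results, method == "novel" & feasible)
ag <- lvm_agreement(novel$mass_g,
                    truth$true_mass_g[match(novel$study_id, truth$study_id)])
summary(ag)
plot(ag, main = "Wall-addition method vs ground truth")
```
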