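---
title: "Methods: multislice spin-lock T1rho mapping and the tumour-to-brain delta-T1rho biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multislice spin-lock T1rho mapping and the tumour-to-brain delta-T1rho biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1rhomap)
```

## The problem

T1rho — the spin–lattice relaxation time in the rotating frame — is measured
by applying a spin-lock radio-frequency pulse of amplitude FSL (Hz) for a
duration TSL (ms) and observing the resulting signal decay. Because the lock
amplitude sets the motional frequency window being probed (kHz-scale, where
chemical exchange between water and macromolecules lives), T1rho is sensitive
to the tumour microenvironment and works at clinical field strengths where
CEST does not. In gliomas, IDH1-mutant tumours tend to show elevated T1rho
relative to healthy brain while IDH1-wild-type tumours do not, making the
*tumour-to-brain normalised difference*

$$\Delta T_{1\rho} = \frac{T_{1\rho}(\text{tumour}) - T_{1\rho}(\text{brain})}
  {T_{1\rho}(\text{brain})} \times 100\%$$

a candidate non-invasive marker of IDH1 status. This package implements the
full quantitative chain for a preclinical (mouse) multislice spin-lock study
of that question — simulation of cohorts with known ground truth, the
multislice saturation correction, voxelwise mapping, ROI metrics, and the
rank-based group statistics — so that every step can be validated against
known truth.

## Signal model and the multislice saturation correction

The voxel signal follows a monoexponential in TSL,

$$S(\mathrm{TSL}) = S_0 \, e^{-\mathrm{TSL}/T_{1\rho}},$$

with $S_0$ and $T_{1\rho}$ free parameters. In a *multislice* acquisition
with per-slice recovery delay $\tau$ comparable to $T_1$ (here $\tau$ = 2000
ms against brain $T_1 \approx$ 670–880 ms), longitudinal magnetisation does
not fully recover between excitations; at steady state the available
magnetisation is reduced by

$$\frac{M_z}{M_0} = \frac{M_{\mathrm{sat}}\,(1 - e^{-\tau/T_1})}
  {1 - M_{\mathrm{sat}}\,e^{-\tau/T_1}}, \qquad
  M_{\mathrm{sat}} = e^{-\mathrm{TSL}/T_{2\rho,\mathrm{eff}}}, \qquad
  \frac{1}{T_{2\rho,\mathrm{eff}}} = \frac{1}{2}\Big(\frac{1}{T_1} +
  \frac{1}{T_2}\Big).$$

Measured signals are divided by $M_z/M_0$ (per TSL) before fitting
(`saturation_factor()`, `correct_series()`). Because per-session $T_1$/$T_2$
maps are rarely available, the correction uses *group-average* $T_1$/$T_2$
per tissue class (`study_tissue_t1t2()`); a per-voxel mode would be a
straightforward extension but is deliberately not the default, mirroring
practice. `fit_t1rho_map(..., correction = FALSE)` provides the uncorrected
analysis path for sensitivity checks.

The factor is monotone decreasing in TSL: ignoring it mixes extra decay into
the fit and biases $T_{1\rho}$ low, which the tests verify by simulation.

## Fitting

`t1rho_fit()` (one curve) and `fit_t1rho_map()` (all in-mask voxels at once)
fit the monoexponential by bounded nonlinear least squares. $S_0$ enters the
model linearly and is profiled out in closed form (variable projection);
$T_{1\rho}$ is updated by a damped Gauss–Newton iteration with projection
onto its bounds. The closed-form log-linear regression of $\log S$ on TSL
initialises the search.

Numerical choices, all configurable:

* bounds $T_{1\rho} \in [1, 2000]$ ms and $S_0 \in (0, 10\times\max S]$ —
  wide enough never to bind for physiological tissue, tight enough to pin
  down degenerate voxels;
* convergence at relative step $< 10^{-8}$, at most 200 iterations;
  non-convergence is reported in diagnostics, never thrown;
* degenerate inputs (no decay, e.g. a constant series) legitimately drive
  $T_{1\rho}$ to the upper bound; such voxels carry `at_bound = TRUE` and an
  undefined $R^2$, and are removed by quality control;
* quality control excludes voxels with $R^2 < 0.5$ or failed convergence
  from ROI summaries (the threshold is exposed; ROI summaries count
  exclusions). Some exclusion rule is unavoidable for noisy magnitude data;
  0.5 is deliberately permissive so that at the study's noise level
  essentially only degenerate voxels are removed.

Plain (unweighted) least squares on magnitudes is used — no Rician bias
correction in the estimator — matching how such data are analysed in
practice; the Rician floor is a property of the simulator. On noiseless data
the whole chain (forward simulation with the steady-state factor →
correction → fit) is exact to better than $10^{-6}$ relative error, which
the acceptance suite checks at all four lock amplitudes and both tissue
classes.

At the study's noise level the information limit is worth stating: for the
8-point TSL schedule at SNR 50 the Cramér–Rao bound gives
$\mathrm{sd}(\hat T_{1\rho})/T_{1\rho} \approx 3.5\text{–}4.2\%$ for brain
and tumour values, i.e. a median voxelwise |relative error| of ~2.4% even
for an ideal unbiased estimator, and ~3.4% in practice once the correction's
noise amplification at long TSL is included. Voxelwise maps at this SNR are
therefore noisy by construction; the ROI means that all study metrics build
on average over hundreds of voxels and are far more precise.

## The synthetic cohort

`generate_cohort()` emulates the study design: three groups of five mice
(naive controls, IDH1-wild-type and IDH1-mutant tumour-bearing), imaged
weekly; TSL = {1, 15, 30, 45, 60, 75, 90, 105} ms; FSL = {100, 500, 1000,
2000} Hz; $\tau$ = 2000 ms; ten 1-mm slices with 0.2-mm gaps; a 60×60
anatomical grid and a 34×34 T1rho grid sharing a 15.94-mm field of view.
The default weekly schedule (`default_schedule()`) reproduces the study's
pooled Weeks 2–4 sample sizes exactly — 0/15, 9/14 and 7/12 tumour/brain
measurements for the three groups — with the narrative features: earliest
visible tumour at Week 2 in the mutant group, most visible by Week 3, one
mutant-group mouse tumour-free, tumour-bearing mice gone after Week 4,
controls imaged through Week 6.

Each mouse-week measurement is a digital phantom: a whole-brain ellipsoid
(semi-axes 4.5 × 3.5 × 4.0 mm), a contralateral brain-ROI ellipse sized to
the study's reported ~18 mm² ROIs, and a spherical tumour right of midline
(the implantation side) whose central-slice area is drawn from the reported
13 ± 10 mm² range, truncated to [4, 15] mm² so the sphere stays inside the
brain. Labels are rasterised by the voxel-centre rule. Rician noise applies
independent Gaussian noise to both quadrature channels; SNR is defined as
$S_0/\sigma_{\text{channel}}$ with $S_0 = 100$, so the study condition
SNR 50 means $\sigma = 2$.

**Parameterisation of the measurement-level draws.** The study tables report
three statistics per group and amplitude: brain T1rho (mean ± SD), tumour
T1rho (mean ± SD), and the *per-measurement* delta-T1rho (mean ± SD). These
three are mutually inconsistent with drawing brain and tumour independently
(or bivariately) from their marginals: the wild-type delta column averages
~3% while the ratio of the printed tumour/brain means implies ~5–7%, because
delta is computed per measurement and brain and tumour values of one mouse
are strongly coupled. Since delta-T1rho is the endpoint the study is about,
the generator draws **(brain, delta)** per measurement from the printed
distributions and derives tumour = brain · (1 + delta/100). This reproduces
the brain and delta columns exactly in expectation, keeps the implied tumour
means within their printed SDs, and induces the (unreported) within-mouse
brain–tumour correlation naturally. The draws for the four lock amplitudes
within one measurement share a latent factor with correlation 0.8 — a
deliberate, configurable choice reflecting that one session measures the
same tissue four times; it affects joint significance patterns but no group
mean.

What the simulator does *not* emulate: anatomically realistic atlases,
partial-volume mixing at class boundaries, $B_0/B_1$ inhomogeneity, EPI
distortion, motion, within-mouse longitudinal trends (the study found no
significant week effects, so weekly draws are exchangeable within group).
Passing tests therefore demonstrate correctness of the *pipeline* under the
stated generative model, not robustness to those real-data effects.

## ROI transfer and metrics

ROIs are drawn on the anatomical grid and transferred to the T1rho grid.
The exact interpolation used in practice is tool-dependent; here
`resample_mask()` uses deterministic area-overlap resampling: a target voxel
takes a label iff at least 50% (inclusive) of its area is covered by that
label, with exact ties resolved in favour of the tumour label. This rule has
an exhaustive brute-force oracle, which the tests exercise, and conserves
labels (no label appears that is absent from the source).

`roi_mean()` averages QC-passed voxels and counts exclusions. Per
measurement and amplitude, `delta_t1rho()` forms the percent difference of
the tumour and brain ROI means — per measurement first, then averaged within
group, never as a ratio of group means. `dispersion_ratios()` quantifies
T1rho dispersion as $(T_{1\rho}(\mathrm{FSL}_{high}) -
T_{1\rho}(\mathrm{FSL}_{low}))/T_{1\rho}(\mathrm{FSL}_{low})$ for every
ordered pair — six ratios from four amplitudes.

## Statistics

Weeks 2–4 are pooled (`merge_weeks()`) and groups compared with two-sided
Mann–Whitney U tests (`mann_whitney()`): exact null distribution when the
combined sample size is ≤ 20 without ties (which covers every comparison at
the study's sample sizes), otherwise the midrank normal approximation with
tie and continuity corrections; the mode used is recorded, since the choice
is invisible in most software defaults. Benjamini–Hochberg control at
FDR 5% (`bh_adjust()`) is applied *within* each four-amplitude comparison
family, not across families. The six dispersion-ratio comparisons share
amplitudes and so violate BH's independence-type condition; they are judged
against the Bonferroni threshold 0.05/6 ≈ 0.0083
(`bonferroni_threshold()`). Control-group age trends use per-mouse OLS of
brain T1rho on week with a t test of zero slope (`age_trend_test()`), BH
over the four amplitudes within each mouse; a zero-residual fit returns
p = 0 (collinear) or p = 1 (constant) by documented convention.

## Worked example

A small cohort (two mice per group, two weeks) end to end:

```{r example, eval = FALSE}
design <- cohort_design(schedule = subset(default_schedule(),
                                          mouse <= 2 & week %in% 2:3))
cfg <- study_config(design = design, seed = 1)
res <- run_pipeline(cfg)
res$summary                      # group means, study-table layout
res$comparisons$delta            # delta-T1rho: wild type vs mutant
```

At the full default design (66 measurements, four amplitudes each) a
complete simulate → correct → fit → metrics → statistics run takes on the
order of ten seconds; the acceptance script pools sixteen replicate cohorts,
and the replicate-pattern check in the test suite runs fifty, sizes chosen
so the Monte-Carlo error on the recovered group means (~1.4 percentage
points for the mutant group) is small against the tolerances being checked.

## Known limitations

* Group-average $T_1/T_2$ correction ignores individual and temporal
  variation — by design, as in the study; the uncorrected path quantifies
  the sensitivity.
* The simulator's uniform per-class values make ROI SDs at the voxel level
  purely noise-driven; real tumours are heterogeneous.
* Voxelwise precision at SNR 50 is bounded at ~2.4% median relative error
  by information content (see above); conclusions should rest on ROI
  summaries.
* With the printed between-measurement spreads and n = 9 vs 7, single-cohort
  group means of delta-T1rho carry standard errors of ~4 percentage points;
  recovering the printed values to a point or two requires pooling replicate
  cohorts, which is what the acceptance machinery does.
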