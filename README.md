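# t1rhomap

Quantitative T1ρ (spin–lattice relaxation in the rotating frame) analysis for
multislice spin-lock MRI of a glioma mouse model, built around one question:
does the tumour-to-brain normalised T1ρ difference separate IDH1-mutant from
IDH1-wild-type glioma?

T1ρ is measured by applying a spin-lock pulse of amplitude FSL (Hz) for a
duration TSL (ms); the voxel signal decays as

    S(TSL) = S0 · exp(−TSL / T1ρ)

In a multislice acquisition whose per-slice recovery delay τ is on the order
of T1, residual saturation suppresses the available longitudinal
magnetisation at steady state by

    Mz/M0 = Msat · (1 − e^(−τ/T1)) / (1 − Msat · e^(−τ/T1)),
    Msat  = exp(−TSL / T2ρ,eff),   1/T2ρ,eff = (1/T1 + 1/T2) / 2

so measured signals are divided by Mz/M0 (using group-average tissue T1/T2)
before voxelwise bounded nonlinear least-squares fitting of S0 and T1ρ. From
the fitted maps the package extracts ROI means, the per-measurement
biomarker

    ΔT1ρ = 100% · (T1ρ(tumour) − T1ρ(brain)) / T1ρ(brain)

and spin-lock dispersion ratios (T1ρ(FSL_high) − T1ρ(FSL_low)) / T1ρ(FSL_low)
for all six amplitude pairs, then runs the study's statistics: Weeks 2–4
pooling, two-sided Mann–Whitney U tests (exact where the sample sizes allow),
Benjamini–Hochberg control at FDR 5% within each four-amplitude family, the
Bonferroni threshold 0.05/6 ≈ 0.0083 for the six dispersion comparisons, and
per-mouse age-trend regressions for the controls.

Because no raw data are deposited for such studies, the package includes a
first-class synthetic-cohort generator: digital mouse-brain phantoms
(brain ellipsoid, ~18 mm² contralateral brain ROI, implanted-side spherical
tumour), the full acquisition protocol (TSL = 1–105 ms, FSL = 100–2000 Hz,
τ = 2 s, 10 slices, 60×60 anatomical / 34×34 T1ρ grids on a shared 15.94-mm
FOV), measurement-level draws from the published group tissue tables, and
Rician noise at SNR 50 — with ground truth retained so every stage is
testable. Volumes travel as NIfTI-1 with JSON sidecars; results as CSV.

## Worked example

```r
library(t1rhomap)

# a small synthetic cohort: two mice per group, weeks 2-3
design <- cohort_design(schedule = subset(default_schedule(),
                                          mouse <= 2 & week %in% 2:3))
res <- run_pipeline(study_config(design = design, seed = 1))
subset(res$summary, metric == "delta")
#>   group fsl_hz    roi metric      mean         sd n
#> 1     2    100 tumour  delta 15.131448  2.9636774 2
#> 3     2    500 tumour  delta 15.743324 11.5105490 2
#> 5     2   1000 tumour  delta 13.175667  2.0449358 2
#> 7     2   2000 tumour  delta  9.744628  0.8517205 2
#> 2     3    100 tumour  delta 32.742315 17.2984284 3
#> 4     3    500 tumour  delta 31.051457 14.2758112 3
#> 6     3   1000 tumour  delta 28.233272  2.3438585 3
#> 8     3   2000 tumour  delta 28.044488 13.6670513 3
```

The `delta` rows are group means of the per-measurement ΔT1ρ (%): the
simulated IDH1-mutant group (group 3) sits near +30% while wild type
(group 2) lies well below it (with only 2–3 tumour measurements per cell,
individual group means scatter by several points around their population
values — the full design uses 9 and 7). A
single voxel decay can be fitted directly with the classic model interface:

```r
tsl <- c(1, 15, 30, 45, 60, 75, 90, 105)
fit <- t1rho_fit(tsl, signal = 100 * exp(-tsl / 100))
coef(fit)
#>       s0 t1rho_ms
#>      100      100
```

A thin command-line driver is installed as `exec/t1rho`
(`t1rho run-all --config cfg.yaml --seed 7 --out results/`).

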