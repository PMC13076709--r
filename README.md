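# adcphantom

A synthetic test bench for studying how reconstruction-stage denoising
affects apparent diffusion coefficient (ADC) quantification and
histogram-based (first-order radiomic) ADC metrics in diffusion-weighted
MRI (DWI).

It is written for medical physicists and quantitative-imaging researchers
who want to exercise an entire phantom QA analysis — accuracy,
repeatability, histogram shape, distributional distances, paired
nonparametric tests — end to end, deterministically, and without any
scanner data.

## What it does

The package simulates a calibrated multi-vial diffusion phantom: thirteen
20 mL vials of polyvinylpyrrolidone (PVP) solutions at six concentrations
(0–50% w/w), nominal ADC from 2.0 down to 0.3 × 10⁻³ mm²/s at 20 °C,
arranged in central/inner/outer rings in a water bath. Two acquisition
protocols are modelled (full-FOV: 0.86 mm pixels, 2 averages per b;
reduced-FOV: 0.70 mm pixels, extra averages, 11 of 13 vials visible), each
with five b-values (0, 500, 1000, 1500, 2000 s/mm²).

Every voxel follows the mono-exponential model

    S(b) = S0 · exp(−b · ADC)

with Rician magnitude noise and NEX averaging. Reconstruction strengths
OFF / LOW / MEDIUM / HIGH are emulated by in-plane Gaussian smoothing
(σ = 0 / 0.4 / 0.8 / 1.2 mm) of the same raw realization, so comparisons
across levels are genuinely paired. Downstream, the package provides:

* voxelwise ADC fitting by log-linear OLS over all b-values;
* cylindrical VOIs (25 / 22 mm diameter, 3 slices) reused identically
  across levels;
* fixed-bin ADC histograms (bin width 5 × 10⁻⁶ mm²/s on a shared bin
  vector) and the eleven first-order features: mean, SD, median, IQR,
  P10/P25/P75/P90, kurtosis (non-excess, normal → 3), skewness, entropy
  (bits);
* Wasserstein distances between cumulative relative histograms (bin-index
  units, Σ|C₁−C₂|), voxel-paired Friedman tests across levels, paired
  two-sided Wilcoxon signed-rank tests (exact up to n = 25) per feature;
* accuracy vs temperature-dependent nominal references
  (100·(measured−nominal)/nominal on repeat-averaged VOI medians),
  intra-session CV (100·σ/μ), extreme deviations from the first repeat,
  and metric-specific cross-session pooling;
* minimal NIfTI-1 I/O plus JSON sidecars, so real per-b magnitude volumes
  or precomputed ADC maps can enter at the fitting or extraction stage.

See `vignettes/adcphantom-methods.Rmd` for the model, every convention and
default, and the limitations of the linear-smoothing stand-in (notably:
it cannot reproduce the kurtosis increase that edge-preserving DL
denoising shows on real data — explained there).

## Worked example

A small two-session full-FOV study (3 repeats, 96×96×3 grid for speed):

```r
library(adcphantom)
cfg <- default_config(sequences = "fFOV", seed = 42,
  protocol = list(matrix = 96L, n_slices = 3L, pixel_mm = 1.6),
  design = list(n_repeats = 3L,
                sessions = data.frame(session = c("S1", "S2"),
                                      temperature_c = c(22.9, 20.8))))
res <- run_study(cfg)

subset(res$accuracy, vial == "PVP0_C")[, c("session", "level",
       "measured_median", "nominal", "deviation_percent")]
#>  session  level measured_median  nominal deviation_percent
#>       S1    OFF        0.002100 0.002116           -0.7389
#>       S1   HIGH        0.002099 0.002116           -0.7832
#>       S2    OFF        0.002020 0.002032           -0.6094
#>       S2   HIGH        0.002019 0.002032           -0.6475
#>  ...
```

Median ADC of the water vial is accurate to well under 1% at every
denoising level — denoising does not bias the median. The distribution
shape is another story:

```r
subset(res$pooled$percent_diff_pooled, feature %in% c("entropy", "iqr", "median"))
#>  feature  level mean_percent_diff sd_percent_diff
#>  entropy    LOW         -0.065           0.074
#>  entropy MEDIUM        -21.8             9.35
#>  entropy   HIGH        -42.6            18.8
#>      iqr    LOW         -0.140           0.032
#>      iqr MEDIUM        -36.2             1.18
#>      iqr   HIGH        -62.1             1.23
#>   median    LOW          0.0001          0.0004
#>   median MEDIUM         -0.0048          0.023
#>   median   HIGH         -0.0033          0.025
```

Entropy and IQR collapse progressively with denoising strength while the
median moves by thousandths of a percent. And the effect concentrates in
the high-ADC (water) vials, visible in the session-averaged OFF–HIGH
Wasserstein distances:

```r
head(res$pooled$wasserstein_pooled[order(-res$pooled$wasserstein_pooled$wasserstein), ])
#>     vial wasserstein   (level == "HIGH")
#>   PVP0_C        7.17
#>   PVP0_O        6.96
#>   PVP0_I        6.80
#>  PVP10_I        2.02
#>  PVP10_O        2.00
```

`run_study(cfg, out_dir = "out")` writes every table as CSV
(`accuracy.csv`, `repeatability.csv`, `wasserstein.csv`, `friedman.csv`,
`features.csv`, `percent_diff.csv`, `wilcoxon.csv`, `pooled_*.csv`) plus a
JSON run manifest and a data dictionary; `render_report()` adds trend
tables, a Wilcoxon significance matrix, and a plain-text summary.
Re-running with the same config is byte-identical.

## Command line

```sh
Rscript inst/cli/adcphantom --config my_study.json --out out --seed 7 \
        --sequence both --verbose
```

The JSON config mirrors `default_config()`: protocol overrides, study
design (levels, repeats, sessions with temperatures), layout overrides,
histogram bin width, seed. Unknown keys are rejected before any stage runs.

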