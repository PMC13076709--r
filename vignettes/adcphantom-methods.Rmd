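---
title: "Methods: simulating denoising effects on ADC quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating denoising effects on ADC quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reconstruction-stage denoising is now built into clinical MRI systems. It
improves the appearance of diffusion-weighted images (DWI), but the apparent
diffusion coefficient (ADC) maps computed from those images are quantitative
biomarkers: their voxel-value *distributions* — summarized by first-order
radiomic features such as entropy, interquartile range, kurtosis and
percentiles — carry information about tissue heterogeneity. A denoiser that
leaves the median ADC untouched can still reshape the distribution.

`adcphantom` provides a fully synthetic, seeded test bench for this
question. It simulates a calibrated multi-vial diffusion phantom (thirteen
20 mL vials of polyvinylpyrrolidone, PVP, at 0–50% w/w, nominal ADC from
about 2.0 to 0.3 × 10⁻³ mm²/s at 20 °C, arranged in central/inner/outer
rings in a water bath), applies graded denoising, fits ADC maps, and runs
the full accuracy / repeatability / histogram / distance / test battery so
that every stage of such an analysis is exercised without any scanner data.

## Signal model

Each voxel follows the mono-exponential decay

$$S(b) = S_0 \exp(-b \cdot ADC),$$

with $b \in \{0, 500, 1000, 1500, 2000\}$ s/mm² and the voxel's true ADC
taken from its vial (the bath elsewhere, zero outside the phantom). Noise
is Rician: each stored b-value image is the arithmetic mean of
`averages_per_b` independent magnitude realizations
$\sqrt{(S + n_1)^2 + n_2^2}$ with $n_1, n_2 \sim N(0, \sigma^2)$. Averaging
is done in the magnitude domain, as scanners average NEX, so the Rician
floor is *preserved* — this matters, because the noise floor at $b = 2000$
in the water vial is exactly where denoising has its largest distributional
effect.

The full-FOV protocol uses 2 averages at every b on a 0.86 mm grid; the
reduced-FOV protocol uses 0.70 mm pixels with 2 averages at $b=0$ and 4 at
the diffusion-weighted b-values, and sees only 11 of the 13 vials.

### Nominal (reference) ADC model

Phantom vendors characterize each PVP concentration by a quadratic
$ADC(T) = a_0 + a_1 T + a_2 T^2$ over 15–24 °C. Those coefficient tables
are shipped documents, not public data, so the default model here is
synthetic but anchored: 2.0 × 10⁻³ mm²/s for 0% PVP and 0.3 × 10⁻³ mm²/s
for 50% at 20 °C (the phantom's printed range), log-linear interpolation in
concentration between the endpoints (which guarantees strict monotonicity
in PVP fraction), and a linear +2%/°C relative temperature slope, a
realistic magnitude for aqueous diffusivity near room temperature. Any
user-supplied coefficient table (`adc_model()`) overrides the default. The
same model generates the simulation and serves as the accuracy reference,
so accuracy deviations measure the *pipeline*, not the model.

### Denoising emulation

The vendor network is proprietary, so reconstruction strengths OFF / LOW /
MEDIUM / HIGH are emulated by in-plane Gaussian smoothing of the magnitude
b-images before fitting, with kernel standard deviations 0 / 0.4 / 0.8 /
1.2 mm. OFF is exactly the identity. Smoothing reproduces the leading
signature of reconstruction-stage denoising — unchanged local means (hence
stable median ADC), monotonically shrinking dispersion, effects largest
where SNR is lowest — and its strength ordering is what the monotonicity
properties test.

One raw acquisition is simulated per (session, repeat) and all four levels
are derived from that same realization, mirroring multiple reconstructions
of one scan. This is what makes voxel-paired Friedman tests and paired
Wilcoxon tests meaningful, and it is a modelling decision: the alternative
(independent acquisitions per level) would break pairing.

**Known limitation.** A *linear* smoother cannot reproduce the kurtosis
increase reported for DL reconstruction. For any linear filter with weights
$w$ applied to approximately independent voxel noise, excess kurtosis
scales by $\sum w_i^4 / (\sum w_i^2)^2 < 1$: kurtosis contracts toward 3.
In real data the rise in kurtosis comes from edge-preserving networks
shrinking the noise core while retaining structured tails (Gibbs ringing,
bias fields, vial-wall voxels) — structure a uniform-vial phantom
simulation does not contain. The corresponding acceptance check is left
failing deliberately rather than patching the generator to chase it; a
green result there would say nothing true about linear smoothing.

## Geometry

Vials are axis-aligned cylinders replicated across slices; the bath is a
disc of free-water ADC (2.0 × 10⁻³ mm²/s). The default vial radius is
16 mm. This is deliberately larger than a literal 20 mL vial cross-section:
the analysis VOIs are 25 mm (full-FOV) / 22 mm (reduced-FOV) diameter
cylinders on three consecutive slices, and they must sit fully interior to
the vial with a margin exceeding the diagonal reach of the strongest
smoothing kernel (≈ 3.5 mm at σ = 1.2 mm), otherwise VOI statistics mix
vial and bath material. Ring radii (33 mm inner, 59 mm outer, outer ring
rotated 30°) are chosen so no two vials overlap and the full layout fits a
220 mm field of view. The reduced-FOV layout marks the two outer-ring vials
that fall outside the rotated FOV (20% and 50%) invisible, leaving 11.

VOI masks use a voxel-center-in-circle rule (no partial-volume weighting),
are built once per sequence, and are reused bit-identically across all
levels and repeats, so segmentation never contributes variability.

## Histograms and features

All histograms of one VOI group share a fixed bin grid: width
5 × 10⁻⁶ mm²/s, range equal to the pooled min/max over *all levels and
repeats* of that VOI within a session, aligned outward to bin-width
multiples. Bins are half-open (last bin closed). Mean histograms average
bin counts across repeats.

The eleven first-order features are computed from the raw voxel values
except entropy, which is defined on the fixed-bin histogram
($-\sum p_k \log_2 p_k$, bits). Conventions, fixed once:

* sample SD with $n-1$;
* percentiles by linear interpolation (type 7);
* skewness $m_3 / m_2^{3/2}$ and *non-excess* kurtosis $m_4 / m_2^2$
  (normal → 3) with $1/n$ central moments — the non-excess form keeps
  denominators away from zero in percent-difference tables;
* a constant sample yields SD = IQR = 0 and undefined (NA) skewness and
  kurtosis, flagged rather than thrown.

## Statistics

* **Accuracy**: per vial/session/level, the VOI median ADC per repeat,
  averaged over repeats, compared with the nominal value as
  $100(\text{measured}-\text{nominal})/\text{nominal}$.
* **Repeatability**: intra-session CV ($100\,\sigma/\mu$ of the repeat
  medians) and the signed extreme deviations of repeats 2..n from repeat 1.
* **Wasserstein distance**: histograms normalized to relative counts,
  cumulated over bins; the distance is $\sum_k |C_1[k] - C_2[k]|$ in
  *bin-index units* — no bin-width scaling. The unitless form is what makes
  a unit mass translated by $k$ bins lie at distance exactly $k$, and it is
  the only reading compatible with distances of order 10 on these data.
* **Friedman test** across the four levels, blocks = voxels (levels of one
  repeat share a raw realization; repeats concatenated; only voxels defined
  at every level enter), mid-ranks within blocks, tie-corrected chi-square
  with 3 df. Fully tied data report p = 1 with a degenerate flag.
* **Wilcoxon signed-rank**, two-sided, per feature, level pair and session;
  pairing unit = vial × repeat. Zero differences dropped, mid-ranks on
  ties; the exact (tie-conditional) null distribution is used up to n = 25
  via dynamic programming over doubled ranks, the normal approximation with
  continuity and tie correction beyond. No multiplicity correction is
  applied, matching the raw-p reporting convention this pipeline mirrors.
* **Cross-session pooling**: CVs and Wasserstein distances averaged;
  maximum deviations keep signed extrema; accuracy deviations pool the
  per-repeat values of both sessions into median/IQR; feature percent
  differences pool vial × session cells into mean ± SD.

## Default noise level

The single-average noise scale is σ = 4 at $S_0 = 1000$ (SNR 250 at b = 0).
Chosen once, a priori, on two grounds: phantom QA acquisitions are
high-SNR, and this value places simulated intra-session CVs in the
0.1–1.2% band reported for this class of experiment while keeping the
b = 2000 water-vial signal (≈ 18) above the deep Rician floor, so
log-linear fitting remains meaningful. It was not adjusted afterwards.

## What the generator does and does not establish

The simulation contains: correct decay physics, Rician magnitude noise
with NEX averaging, resolution/averaging differences between the two
protocols, temperature-dependent references, and level-graded linear
smoothing on shared raw data. It does not contain: EPI/k-space artifacts,
eddy currents, susceptibility or gradient-nonlinearity bias fields, vial
walls, Gibbs ringing, or any nonlinear (edge-preserving) denoising. A green
monotonicity test therefore establishes that the *pipeline* correctly
measures what linear denoising does to ADC distributions — it does not
certify vendor networks, and the kurtosis caveat above marks exactly where
the linear stand-in and real DL reconstruction part ways.

## Numerical details worth knowing

* Bin alignment uses a 10⁻⁹-relative fuzz so values that are exact
  multiples of the bin width do not widen the grid through floating-point
  slop; degenerate single-point pools get one bin.
* Voxels with fewer than two positive signals are missing (NA); negative
  fitted slopes clamp ADC to 0 with a count kept on the map; voxels whose
  b = 0 signal is below 3σ are masked before any VOI statistics.
* Child seeds derive from (base seed, session index, repeat index) through
  a fixed Lehmer-style integer mix, exact in doubles and below 2³¹, so
  studies are reproducible elementwise, not just as a whole.
* `run_study()` streams one raw acquisition at a time through
  reconstruction → fitting → extraction, so memory stays flat in the study
  size; `simulate_study()` materializes all stacks and is meant for small
  grids.
* All tables are written by `write.csv` with fixed column order; two runs
  with one config are byte-identical.
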