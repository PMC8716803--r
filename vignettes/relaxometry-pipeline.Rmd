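---
title: "Indirect proton relaxometry of 17O-labelled water: models and methods"
author: "o17relax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect proton relaxometry of 17O-labelled water: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(o17relax)
```

## The problem

Water in which the oxygen is the ¹⁷O isotope (H₂¹⁷O) shortens the proton
transverse relaxation time T2 through ¹H–¹⁷O scalar coupling. A conventional
3-T proton scanner can therefore see an injected bolus of enriched water
*indirectly*, as a rise in the voxel-wise transverse relaxation rate
R2 = 1/T2, without any ¹⁷O-tuned hardware. `o17relax` implements the full
quantitative chain behind that idea:

1. voxel-wise relaxometry — T1 from a variable-flip-angle (VFA) spoiled
   gradient echo, T2 and T2* from multi-echo trains;
2. calibration — per-vial statistics on a cylindrical multi-vial phantom and
   an ordinary-least-squares line relating R2 to H₂¹⁷O concentration;
3. dynamics — baseline-normalized relative R2 change
   (R2\^post − R2\^pre)/R2\^pre through an injected-bolus time series;
4. dosimetry — the mixing model that converts a target intravascular
   concentration into an injection volume.

No scanner data ship with the package. Instead a synthetic-data module
renders phantom and rat-brain series with known ground truth, so every stage
is verified by parameter recovery.

## Signal models and unit conventions

Throughout the package relaxation **times are in ms**, **rates in s⁻¹**
(`rate = 1000 / time`), **concentrations in mole-percent** of water
molecules, and volumes in mL. The two forward models are the SPGR
steady-state signal at repetition time TR and flip angle θ,

$$ S(\theta) \;=\; M_0 \,\sin\theta\; \frac{1 - e^{-TR/T_1}}{1 - \cos\theta\, e^{-TR/T_1}}, $$

and the mono-exponential echo train at echo time TE,

$$ S(TE) \;=\; k\, e^{-TE/T}, \qquad T \in \{T_2, T_2^{*}\}. $$

Protocol presets mirror the acquisition battery: `tse_protocol()` is the
single-slice 8-echo turbo spin echo (TR 800 ms, TEs at multiples of a
configurable interval, 20 ms by default, 1.67 × 1.67 × 5 mm voxels);
`vfa_protocol()` is the 3-D SPGR at TR 14 ms with flip angles 5–45°;
`gre_t2star_protocol()` is the 12-echo gradient echo. Protocol validation
requires TR to exceed the last echo, which makes the long-interval T2*
echo set unusable at its printed TR of 13 ms; callers wanting that train
must supply a consistent TR.

## The synthetic data generator

**What it emulates.** The phantom generator rasterizes a cylindrical holder
with 13 holes (one central, an inner ring of 4, an outer ring of 8; 12-mm
vial radius) onto the acquisition grid. Nineteen H₂¹⁷O concentrations from
the 0.037 % natural abundance to 6.5 % are split over two layouts — 18
above-abundance values interleaved so each layout spans the range — and
every layout carries three plain-saline control vials in its first three
holes. Ground-truth relaxation follows a forward model that *is* the
calibration being recovered:

$$ R_2(C) = 0.405\,C + 0.3215 \ \mathrm{s^{-1}}, \qquad
   T_1 = 3000\ \mathrm{ms\ (constant)}, \qquad T_2^{*} = 0.8\,T_2 . $$

T1 and T2* are deliberately concentration-independent so that the R1/R2*
branches of the pipeline act as negative controls: their per-vial medians
must show no trend with concentration. The linear response is used over the
whole range; the low-concentration detection threshold seen on real
hardware is treated as a noise-floor phenomenon, not a kink in the physics.
The T2*/T2 ratio of 0.8 is a generic short-T2′ choice; no phantom T2′
measurement constrains it.

**Noise.** Magnitude MR noise is Rician: each voxel becomes
$\sqrt{(s+g_1)^2 + g_2^2}$ with independent zero-mean Gaussians of standard
deviation σ. The working noise level is expressed as a first-echo
signal-to-noise ratio; `snr_sigma()` sets σ so that the mean foreground
first-frame signal divided by σ equals the requested SNR (50 by default,
high enough that per-vial medians are stable and the Rician floor is a
percent-level effect). Every generator takes an explicit integer seed and
is bit-reproducible; the global RNG stream is never consumed. There is no
B1/B0 inhomogeneity field, no slice-profile or coil-sensitivity model, and
no partial-volume rendering beyond nearest-voxel assignment — passing
recovery tests therefore demonstrates correctness of the estimators, not
robustness to scanner non-idealities.

**The rat scenario.** A brain-shaped elliptical region at baseline
R2 = 13 s⁻¹ (a typical 3-T brain value) receives a bolus that lifts R2 by a
relative fraction of 0.10 at arrival (the first post series by default),
followed by mono-exponential washout with a 60-min half-life:
$R_2(t) = R_2^{base}\,\bigl(1 + p\,2^{-(t-t_{arr})/t_{1/2}}\bigr)$.
Only the schedule — a baseline series plus 82 consecutive 3-min series,
ending at 246 min — is fixed by the experimental design; peak, half-life
and baseline are documented defaults chosen once as physiologically
plausible. Series are assumed co-registered (anesthetized subject); no
motion correction is applied.

## Fitting

Both fitters run vectorized over all foreground voxels. Starting values are
deterministic closed forms: a log-linear regression of intensity on echo
time for the decay models, and the DESPOT1-style linearization (S/sin θ
regressed on S/tan θ, whose slope is $e^{-TR/T_1}$) for VFA. Refinement is
damped least squares (Levenberg–Marquardt) with a variable-projection
twist: the amplitude enters both models linearly, so it is profiled out by
linear least squares at every step and the iteration runs on the relaxation
time alone. This keeps every voxel's subproblem one-dimensional and makes
bound handling trivial (projection).

Numerical choices, all overridable through `fit_config()`:

* time bounds [1, 20000] ms; amplitude bounds (0, 10 × max signal] for the
  decay models and (0, 1000 × max signal] for VFA — at TR = 14 ms and
  saline-like T1 the SPGR signal is only a few percent of M0, so a 10×
  cap would exclude the true amplitude;
* convergence at relative parameter change < 10⁻⁸, an accepted step with no
  measurable residual decrease, or 200 iterations;
* voxels whose maximum frame intensity is below 5 % of the series maximum
  are skipped as background and marked non-converged;
* unweighted least squares over **all** echoes; no echo dropping and no
  Rician bias correction. At first-echo SNR 50 the noise floor biases the
  recovered calibration intercept upward by a small amount that the
  acceptance suite measures and that stays within its tolerance; at
  substantially lower SNR a bias correction would be required.

Degenerate voxels carry NaN sentinels with the converged mask as the
authoritative record: a strictly increasing echo train is non-physical for
a decay and is flagged; a VFA voxel whose refined T1 is pinned at a bound,
or whose best fit still misses the data by more than 15 % RMS of the mean
signal (an order of magnitude above the misfit of well-modelled voxels at
working SNR), admits no T1 within bounds — this covers the
constant-signal case. Noise-flat long-T2 voxels are *not* discarded:
censoring them would clip the low-R2 tail and bias per-vial medians upward.

On noiseless data both fitters reproduce the truth to better than 10⁻⁶
relative error, and the refined solution matches an exhaustive profiled
grid search (0.1-ms step) and an independent per-voxel optimizer; the test
suite asserts all three.

## Phantom analysis

**ROI detection** is Otsu thresholding of the central slice of the first
frame, connected-component labelling, a circularity filter
(4π·area/perimeter² > 0.7, plus a minimum area of half the ROI target), and
a disc of round(118 mm² / in-plane voxel area) voxels nearest each
component centroid — 42 voxels at 1.67 × 1.67 mm. ROIs are replicated on
the centred five slices, or all slices when the volume has fewer (the
single-slice TSE uses its one slice). When a layout hint is supplied, each
ROI is matched to the nearest hole centre; count mismatches warn and return
the partial result.

**Statistics.** Per-vial rates are pooled across repeats; medians and
interquartile ranges use linear-interpolation quartiles (`quantile`
type 7 — the IQR depends on this convention, so it is fixed and
documented). The battery is the Shapiro–Wilk normality test, the Spearman
rank correlation of median rate with concentration (average ranks for
ties, t-approximation p-value), and the Games–Howell post hoc test:
pairwise Welch standard errors, Welch–Satterthwaite degrees of freedom, and
$q = |\Delta \bar x|\sqrt{2}/SE$ referred to the studentized range with k
groups, whose tail supplies the built-in family-wise adjustment — no
further multiple-testing layer is added. Zero-variance pairs take p = 1
(equal means) or p = 0 (unequal) by convention. α = 0.05 throughout.

**Calibration.** Unweighted OLS of per-vial median R2 on concentration,
restricted to the default inclusive range [0.245, 5.5] % (the vial values
bracketing the linear regime; the 6.5 % vial is outside the default
range). Two in-range vials determine the line exactly; fewer raise an
error. Inversion `estimate_concentration()` never extrapolates silently —
estimates outside the fit range are flagged. The model stores the Spearman
rho of the full concentration set alongside the line.

## Dynamics and dosimetry

Relative change maps are voxel-wise (R2^post − R2^pre)/R2^pre with NaN
where either fit failed or the baseline rate falls below a 0.1 s⁻¹ floor
(division by a near-zero baseline is meaningless). The curve summary is the
mean over the brain mask of the voxel-wise ratios — the map definition
fixes mean-of-ratios rather than ratio-of-means; the median is available
as an option. Timepoint i is stamped i × series duration, so 82 series of
3 min end at 246 min. A timepoint whose mask empties after sentinel
exclusion is flagged, not fatal. `fit_washout()` recovers peak and
half-life from a measured curve by least squares.

The dose calculator solves the mixing balance
$(V E + BV c_{nat})/(V + BV) = C_{target}$ for the injection volume V,
with BV = weight × blood volume per kg (65 mL/kg for rats), E the
injectate enrichment (70 %), and $c_{nat}$ = 0.037 % the natural-abundance
background of blood water. Crediting the background is the package's
choice where the arithmetic is usually left implicit; the simpler
no-background variant sits behind `include_background = FALSE` and always
requires slightly more injectate. `dose_volume()` and
`intravascular_concentration()` are exact inverses, and
`natural_abundance_molality()` converts mole-percent abundance to µmol of
H₂¹⁷O per gram of water (20.56 µmol/g at natural abundance).

## Verification scale and what it shows

The test suite and `scripts/acceptance.R` run the full pipeline at the
study scale: both layouts, 30 noise repeats per layout at SNR 50 (about
30 000 pooled voxel-rates), recovering the forward slope within 2 % and
the intercept within 5 %. Module tests use smaller grids (single voxels to
100 × 100 slices, 3–10 repeats, 6–12 dynamic series) chosen so each
property is measured well above its noise floor. Null-phantom simulations
keep the Games–Howell false-positive rate at or below 5 %, and the rat
scenario recovers a 0.10 peak within [0.08, 0.12] and the washout
half-life within 20 %.

What passing does **not** show: robustness to B1/B0 inhomogeneity,
stimulated echoes in TSE trains, multi-compartment decay, motion, or the
true noise field of a physical scanner — the printed statistics of real
phantom experiments (rho, medians, IQRs) depend on those and are outside
the generator's scope.

## Command-line use

`run_command()` (and the thin wrapper installed at
`system.file("scripts/o17relax", package = "o17relax")`) wires the stages
into reproducible commands — `simulate-phantom`, `simulate-rat`,
`fit-maps`, `phantom-calibrate`, `dynamics`, `dose` — each writing its
artifacts plus a manifest recording command, config and seed. Stochastic
commands require an explicit seed; identical config and seed give
byte-identical volumes.

```{r dose-example}
params <- dose_params(subject_weight_kg = 0.292)
dose_volume(params)
intravascular_concentration(dose_volume(params), params)
```

## Known limitations

* The generator's repeats differ only by noise seed; the "reposition the
  phantom between repeats" averaging of real acquisitions has no simulated
  counterpart because there is no inhomogeneity field to average.
* No Rician bias correction: appropriate at the default SNR, not below
  SNR ≈ 20.
* The mono-exponential model ignores stimulated-echo contamination of TSE
  trains and multi-compartment water; both are out of scope.
* Dynamic frames are assumed aligned; no registration is performed.
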