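---
title: "Methods: high-resolution rs-fMRI preprocessing and laminar connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-resolution rs-fMRI preprocessing and laminar connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`laminarfc` preprocesses high-resolution resting-state fMRI of small
(rodent-scale) brains and derives atlas-based functional connectivity down
to cortical-layer granularity. The processing chain is: B0 field-map
distortion-shift computation, random-matrix-theory (RMT) PCA suppression
of thermal noise, three-stage motion estimation (per-slice phase-encode
translation, 6-DOF rigid, patch-wise non-rigid), composition of every
voxel-shift source into a single displacement field applied with exactly
one interpolation per frame, nuisance regression with band-pass
filtering, anatomical/atlas alignment chains, and seed/matrix/connectogram
connectivity analysis on a region hierarchy. A layered digital phantom
with fully known ground truth drives every validation.

# The phantom and what it does (and does not) emulate

`make_layered_phantom()` builds an ellipsoidal "brain": a cortical shell
split into concentric layer bands, a white-matter band, and two
subcortical nuclei, with a three-level hierarchy (region, subregion,
layer/nucleus). Layer band shares mirror the laminar thicknesses of the
mouse barrel field (0.12/0.25/0.20/0.27/0.32 mm of a 1.16 mm cortex).
Bands are delimited on an *equal-area* radial coordinate, so band voxel
counts are proportional to the thickness weights; a plain radial split
would bias counts by circumference (outer bands would be over-counted),
breaking the proportionality that the laminar analysis relies on.

Anatomical intensities get a laminar gradient, tissue contrast, a
deterministic ripple plus seeded smooth texture (so registration has
features to lock onto), and a Gaussian point-spread smoothing
(`psf_sigma = 0.8` voxels). The smoothing reflects that MRI images are
band-limited by acquisition; voxel-sharp edges would alias under sub-voxel
transforms and are not a feature of real data.

`simulate_bold()` plants band-limited (default 0.01-0.1 Hz, the
infra-slow band spontaneous BOLD fluctuations occupy) region time courses
with a user-specified correlation structure, mixed through a Cholesky
factor so planted region-pair Pearson correlations are attained exactly
in expectation; voxels add small independent band-limited jitter.
`apply_acquisition()` then applies, per frame, non-rigid deformation,
rigid motion, per-slice phase-encode translation and the B0 shift — in
that fixed order, mirroring the physical causes (tissue deformation, head
motion, scanner instability, static field) — composed into one pullback
mapping and applied with one interpolation, before adding i.i.d. Gaussian
thermal noise. Gaussian (rather than Rician) noise is the high-SNR
magnitude approximation; it is also what makes the denoiser's
residual-Gaussianity diagnostic a meaningful check.

Defaults (48 x 48 x 3 test grid, baseline ~60 intensity units, noise SD 6,
i.e. pre-denoising tSNR ~ 10, BOLD amplitude 2) are choices of a
plausible operating point, not claims about any particular dataset. The
phantom does not model k-space/EPI readout, physiological noise,
T2* decay, or slice-timing offsets — conclusions about those effects
cannot be drawn from passing tests.

# RMT-PCA denoising

Each in-plane patch (default 3 x 3; never spanning slices) of the series
unfolds into a Casorati matrix of P voxels x T frames. After removing
each voxel's temporal mean, the singular spectrum of pure noise follows
the Marchenko-Pastur (MP) law with aspect ratio P/(T-1); the largest
noise singular value fluctuates by Tracy-Widom (TW1). The noise edge is
either the MP bulk edge `sigma * (1 + sqrt(gamma))` or its TW-calibrated
quantile (default p = 0.95, quantile 0.9793); values at or below the edge
are classified as noise (ties are noise).

The noise level is estimated by matching the *mean* of the noise-bulk
eigenvalues to the corresponding truncated-MP mean — with no excluded
spikes this is the unbiased trace estimator — and the classification and
estimation alternate until stable, which preserves robustness to a few
signal spikes. A bulk *median* matched to the MP median was evaluated
first: at P = 9 its sampling noise inflates the null false-signal rate at
the 95% TW quantile to ~8%, whereas the trace-matched estimator holds it
near 2%; calibration, not convenience, fixed this choice.

Retained signal singular values are debiased by inverting the standard
spiked-covariance forward map
`lambda_obs = (l + sigma^2)(1 + gamma sigma^2 / l)`. This is a documented
stand-in: the shrinkage used by the method this module follows lives in
prior literature that does not print a formula, and the spiked-model
inverse is the standard, testable choice. Overlapping patch estimates are
combined by uniform averaging (stride 1 default). Conservation holds by
construction: the residual is stored as the exact floating-point
difference `input - denoised`, so `input - denoised == residual` is
bit-for-bit and the rearranged sum recovers the input to within one ulp
of the larger summand (bit-exact summation is unattainable in IEEE
arithmetic wherever the input is orders of magnitude smaller than the
denoised value).

Two caveats the laminar user should know. First, sub-edge signal is
removed: a planted fluctuation whose patch singular value
`amplitude * sqrt(P)` is below `sigma * (1 + sqrt(gamma))` cannot be
retained by any edge rule, independent of run length (both sides grow as
`sqrt(T)`). Second, patches blend adjacent voxels: thin adjacent layers
(1-3 voxels) acquire some spurious shared signal, so laminar
between-region nulls should be evaluated on spatially disjoint pairs.
Both effects are visible in, and bounded by, the phantom tests.

# Motion estimation and the one-interpolation contract

The motion module only *estimates*; it never resamples the delivered
data. Stages run in the fixed order pe2d -> rigid3d -> nonrigid, each
estimating on a working copy corrected by the previous stages; working
copies are discarded and all estimates are composed by the warp module so
the data cross exactly one interpolation (verified by an instrumentation
counter).

* Per-slice phase-encode translation: sub-voxel phase correlation
  constrained to the PE axis, refined by local matrix-multiply DFT
  upsampling (factor 100). The estimate maps the frame onto the
  reference: a slice displaced +3 voxels yields -3. The per-slice PE
  drift is scanner-specific, so the stage is optional.
* Rigid 6-DOF: Nelder-Mead on mean squared intensity difference with
  *edge-clamped* out-of-support values — zero-filling creates a cost
  cliff when the initial simplex perturbs the through-plane translation
  of a thin slab, which collapses the optimiser. Initialisation comes
  from integer 3D phase correlation; two trilinear passes locate the
  optimum and a final pass with cubic sampling removes a small rotation
  bias that trilinear interpolation couples into oblique transforms
  (without it, out-of-plane rotations recover to only ~0.5 degrees; with
  it, to ~0.05). On large volumes the metric is evaluated on a stride-2
  in-plane subgrid. Rotation convention: intrinsic x -> y -> z, degrees,
  about the volume centre.
* Non-rigid: tapered (Hann) patches (default 20 voxels, stride 4),
  phase-correlation shift per patch, two 3 x 3 median passes over the
  coarse shift grid (single-patch outliers and their halo), bilinear
  densification and Gaussian smoothing (sigma 2 voxels). Patch size
  trades per-patch shift accuracy (larger is better) against low-pass
  attenuation of genuine deformation (smaller is better); 20 voxels
  balances both on half-FOV-period fields. Signal-free or low-confidence
  patches are imputed from neighbours and counted in a `flagged`
  attribute. The taper is required: phase correlation assumes
  periodicity, and untapered patches mis-estimate sub-voxel shifts by
  several tenths of a voxel.

The reference is the temporal mean after a first PE pass by default
(`ref_strategy`), since no acquisition frame is privileged.

# One-pass warping

All shift sources — field-map shift (`Hz x effective echo spacing x n_pe
x polarity` voxels along the PE axis), per-slice PE translations, rigid
transforms and non-rigid fields — are *functionally composed* (not
summed): output voxel positions are pushed through each pullback mapping
in sequence, in the inverse order of the physical forward chain
(B0 -> pe2d -> rigid -> nonrigid). Pullback (output-driven) resampling
makes the composition exact for arbitrary mapping chains and lets an
upsampling grid change (voxel-centre aligned, default factor 2 when
requested) ride along for free. Interpolants: trilinear, Keys cubic
(default; good blur/ringing trade-off) and Lanczos-3 "sinc" for the
smoothness comparisons. Out-of-field voxels are filled with 0; sample
positions within 1e-3 voxel of the support are treated as inside, because
composed mappings carry floating-point noise and a hard boundary puts a
discontinuity exactly where rigid transforms of thin slabs evaluate.

Smoothness is quantified by the first-difference FWHM estimator: the
lag-1 spatial correlation `rho` per axis gives
`FWHM = sqrt(-2 log 2 / log rho)` voxels, the FWHM of the Gaussian kernel
that would produce that correlation. Below `rho = 0.1` the estimate
carries no information (white noise would otherwise read ~0.5) and 0 is
reported. Field inversion uses fixed-point iteration (tolerance 0.01
voxel, max 50 iterations).

# Nuisance cleaning

Regression precedes filtering, with the motion regressors themselves
band-matched first — the standard remedy for regression re-introducing
filtered frequencies. The design holds a constant, the six rigid
parameters, the mean per-slice PE shift when non-zero, and a drift basis
(default DCT cosines below 0.01 Hz, `floor(2 * duration * cutoff)`
functions; polynomial drift available). Global-signal regression is off
by default. The band-pass applies the squared-magnitude response of an
order-4 Butterworth on the DFT grid: exactly zero phase, no start-up
transients, monotone response with no pass-band ripple, and exact DC
behaviour (`lo = 0` preserves the mean; `lo > 0` removes it). A
forward-backward IIR implementation was evaluated and rejected: with a
0.01 Hz high-pass edge its transients span ~100 frames of a 310-frame
run and violate the module's own contracts.

# Alignment

Registration follows the texture-rich-to-texture-poor direction
(anatomical onto functional, atlas onto anatomical); stored transforms
are always fixed <- moving pullbacks, so chains compose directly.
Bias correction fits a low-order (default 3) polynomial to masked log
intensities. A fundamental identifiability limit applies: anatomy whose
intensity varies smoothly at the field's own spatial scale (e.g. a
radial laminar gradient in a ring geometry) is indistinguishable from
coil bias for *any* blind estimator — class-mean and robust
gradient-domain variants were evaluated and hit the same wall — so the
recovery guarantees are stated and tested on near-homogeneous tissue
(2% texture), and on structured anatomy the field should be read as
"bias plus smooth anatomical trend".

Brain masking: two-class k-means threshold (cut biased 70/30 toward the
dim class so faint tissue survives), largest 3D connected component
(a small in-package labeller; no installed package labels 3D volumes),
interior hole filling, and optional box closing (off by default — box
closing on a discrete ellipse fills staircase notches and bridges tapered
slices, so a clean phantom support would no longer be reproduced
exactly). Mutual information uses a 32-bin masked joint histogram.

Non-linear registration is a multi-resolution, diffusion-regularised
small-deformation demons (update step clamped to 1 voxel, field smoothed
with sigma 1.5 per iteration, in-plane levels 2 -> 1). A symmetric
normalisation (SyN) backend is a delegation point only; requesting it
without an installed backend raises an error naming the internal
fallback. Full SyN is prior art, not this package's contribution.
Transform chains validate space adjacency, invert analytically (linear)
or numerically (fields), and delegate their single interpolation to the
warp module; label volumes are only ever resampled nearest-neighbour.

# Connectivity

Seed time courses are unweighted voxel means; a parent region's course is
the voxel-mean over all descendant voxels (volume-weighted), not the mean
of child means. Seed maps are voxel-wise Pearson correlations Fisher
transformed with |r| clipped at 1 - 1e-7 (`z` cap ~8.4; the matrix
diagonal carries the sentinel NA). Connectogram edges keep z above
threshold (default 0.2, the conventional reporting cut for these maps),
each pair once, ordered by |z|. Seed-size scaling reports, per seed,
suprathreshold mean z and voxel count plus log-log OLS slopes; seed
voxels are excluded from the suprathreshold accounting by default to
avoid self-correlation inflation, with `include_seed = TRUE` exposing the
inclusive variant since published practice is ambiguous. Group averaging
is voxel-wise in the Fisher domain with an optional one-sample t map.

For sampling-error bands on band-limited series the tests use
`n_eff = 2 * bandwidth * duration` effective samples in the Fisher-z
variance `1/(n_eff - 3)`; full-band frame counts would overstate the
information content.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes field-map shift computation, denoising, motion
estimation, the one-shot warp, cleaning and connectivity, recording a QC
entry (tSNR, residual Gaussianity, correlation to reference/anatomy,
FWHM) after each stage and a provenance record (config echo + MD5,
versions) sufficient to re-execute the run; reruns with the same seed are
bit-identical. Denoising precedes motion estimation because RMT-PCA
assumes stationary thermal noise and registration is more accurate on
denoised frames; all spatial corrections still collapse into the single
warp, so the order does not add interpolations.

Validation sizes are chosen so the whole suite exercises every claim on
one CPU: 48 x 48 x 3-5 grids for estimation tests, 64 x 64 x 5 for atlas
chains, 96 x 48 x 9 x 310 (the acquisition geometry) in the acceptance
script, 1000-replicate nulls for the TW calibration and 5000-frame runs
for connectivity recovery. tSNR gains, correlation gains and FWHM
comparisons on the phantom are asserted *directionally*; their magnitudes
depend on the phantom's operating point and are not comparable to any
particular acquired dataset.

# Known limitations

* Non-rigid estimation and the demons registration are in-plane
  (slice-wise); through-plane deformation is not modelled, matching
  thin-slab acquisitions but not isotropic volumes.
* Patch denoising cannot retain signal below the noise edge and blends
  adjacent thin layers (see above).
* Bias-field recovery is only identifiable against anatomy without
  FOV-scale smooth intensity trends.
* The Tracy-Widom quantile table covers p in [0.90, 0.99], the range a
  detection threshold plausibly uses.
* Label resampling fidelity is quantisation-limited for structures a few
  voxels wide; Dice targets are evaluated on merged tissue classes.
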