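---
title: "Models and methods behind snarescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snarescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`snarescape` quantifies how plasma-membrane SNAREs (syntaxin-1, SNAP-25)
are organized relative to secretory vesicles, from single-molecule
localization microscopy (SMLM) coordinates and single-particle tracks.
This vignette is the package's own account of its models, parameter
choices and numerical decisions. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The synthetic membrane

No public microscopy data exist for this system, so every pipeline input is
generated with known ground truth.

**Molecular maps.** Molecules are drawn from a Thomas cluster process —
Poisson parents of intensity 2 /µm², Poisson offspring displaced by an
isotropic Gaussian of sd `sigma_c` = 50 nm — superposed on a uniform
background carrying 20% of the molecules. A Thomas process is the simplest
stationary model producing "drifts" of higher and lower density rather than
hard-edged clusters; the offspring mean is derived from the target density
so the expected count is always `density × area`. Offspring falling outside
the rectangle are wrapped periodically to keep the realized intensity
homogeneous. The default density of 55 molecules/µm² is a calibration, not
a measured value: it makes the expected count inside the 82.5 nm
interaction window ≈ 1.2, consistent with the observed order of one to two
molecules per vesicle. Real tSNARE maps add species co-dependence, membrane
topology and label non-uniformity that this model does not attempt.

**Vesicles.** Centroids are placed by rejection sampling with acceptance
weight `exp(−bias × d/d̄)`, where `d` is a Gaussian kernel density estimate
of the molecular pattern (bandwidth 100 nm, matching the 100 nm analysis
grid) and `d̄` the global mean density. `bias = 0` reduces exactly to
uniform placement; the default `bias = 2` suppresses placement at twice
the mean density by `e⁻⁴` and effectively excludes cluster cores, which is
how vesicles in low-density membrane are emulated. The biological targeting
mechanism is unknown, so the exponential form is purely phenomenological.
The vesicle radius default of 200 nm is *inferred*: inverting
`82.5² = 2·R·17.8 − 17.8²` gives R ≈ 200.1 nm. It is larger than typical
PC-12 dense-core vesicles and therefore kept as an explicit, overridable
constant.

**Localization corruption.** Each ground-truth molecule is re-localized
`k ≥ 1` times with `k − 1` geometric (mean `blink_mean`), emulating GSDIM
dye blinking; the law of real blink counts is unknown, and the geometric
distribution is the maximum-entropy choice on {1, 2, …} with a given mean.
Each localization is displaced by isotropic Gaussian noise with sd drawn
uniformly from 4–21 nm, the PALM/GSDIM precision range.

**Camera movies.** Emitters are rendered as integrated 2-D Gaussians
(error-function integrals per pixel, so photons are conserved exactly);
Poisson shot noise acts on expected photons *before* the EM gain and
Gaussian read noise is added *after*. Excess noise factor, pixel
cross-talk and dye photophysics beyond geometric blinking are not modeled,
so detection performance on these movies is an upper bound on real data.

**Fusion traces** are a step of amplitude `spike` at the fusion time
followed by exponential decay (`tau` default 0.5 s) on a noisy baseline —
the un-quenching-then-dispersal signature used to find fusion events.

## Localization and rendering

Spots are fit with `A·exp(−r²/2s²) + b` by Levenberg–Marquardt
(`minpack.lm`). Precision uses the Thompson photon-count formula
`(s² + a²/12)/N + 8π s⁴ b²/(a² N²)`. Two rejection rules flag
non-convergent fits: amplitude below 5× the residual sd, and fitted
`s < 0.6 px` — a physical PSF is never narrower than about half a pixel,
and fits that collapse to the sigma floor are single noise pixels. Pixel
size is `floor(1000 × pitch/magnification)` nm (16 µm at 150× → 106 nm,
matching the printed value; the floor convention reproduces it exactly).

Rendering draws each localization as a unit-integral Gaussian of sd equal
to its precision, so the image integral equals the localization count up
to raster clipping. Resolution convolution uses an isotropic Gaussian PSF:
diffraction-limited preset 250 nm FWHM at 106 nm pixels, STED preset 60 nm
FWHM at 30 nm pixels (the FWHMs are this package's choices; only the pixel
sizes are given). One subtlety: the claim that low resolution creates
*partial apparent overlap* between vesicle and molecule images is tested
with an overlap (cosine) coefficient, not Pearson correlation — vesicles
avoid dense regions by construction, so Pearson becomes more *negative*
as the PSF widens, while the overlap coefficient rises monotonically
(checked at 60/120/250 nm FWHM on the reference synthetic map).

Residual stage drift is quantified (never corrected): per-frame bead
centroids are fit and the report gives the smallest radius about the mean
containing 99.9% of them. For pure localization jitter of sd σ the radius
approaches the Rayleigh quantile `σ√(−2 ln 0.001) ≈ 3.72 σ`.

## Particle detection

Per frame: (1) a Haar-like centre–surround feature (mean over a
particle-sized box minus mean over an equal-area surrounding ring,
via integral images — linear and offset-invariant); (2) a *weak* threshold,
default 2× the MAD of the feature image, chosen robust and deliberately
permissive; (3) a particle-probability image — per pixel, the fraction of
its particle-size window occupied by its own 8-connected component;
(4) Gaussian refinement (σ = 1 px); (5) marker-controlled segmentation of
the original grayscale frame: markers are regional maxima of the refined
probability ≥ 0.3, the support is probability > 0.05, and support pixels
are assigned to markers by steepest ascent on intensity (a hill-climbing
watershed; pixels whose ascent ends away from a marker fall to the nearest
marker of their component; components without markers are dropped).
Centroids are intensity-weighted and sub-pixel; the background is the
frame median outside all supports. Defaults assume diffraction-limited
spots at 106 nm pixels (particle size 5 px). Connectivity is 8-connected
throughout — the labelling is written in-package because the available
image libraries label 4-connected.

## IMM tracking

Each track hypothesis carries three linear models in a common
(x, vx, ax, y, vy, ay) state: random walk (process noise matched to a
diffusion coefficient, default 0.015 µm²/s), constant velocity with white
acceleration (4×10⁷ nm²/s³) and constant acceleration with white jerk
(10¹¹ nm²/s⁵). The noise intensities were set so each model's one-frame
positional uncertainty at 50 ms is of the order of a Brownian step
(~40 nm); none are published values. Markov transition matrix: 0.8
self-transition, 0.1 cross; initial probabilities uniform. Standard IMM
mixing precedes per-model Kalman prediction; the mixed measurement
prediction gates candidates at the chi-square 99% level (2 df).
Association cost = squared Mahalanobis innovation distance plus
`|Δlog intensity| + |Δlog area|` (weights 1; topology enters the cost, not
the kinematic state). Per frame, a Jonker–Volgenant solver finds the exact
minimum-cost one-to-one assignment on an augmented matrix in which leaving
a track or detection unassigned costs the gate value; optimality is the
contract and is tested against exhaustive enumeration. Unmatched
detections become tracks immediately; tracks die after 2 consecutive
misses; covariances are symmetrized and eigenvalue-checked at every step
(a non-PSD covariance after one symmetrization retry is an error).

Fusion events in vesicle intensity traces require a one-frame rise above
5× the rolling MAD of the increments *and* a post-peak exponential fit
(nonlinear, linear-scale r² ≥ 0.8, `tau` within 0.05–5 s) — the decay
criterion rejects monotone ramps. Track excerpts are re-indexed so the
peak frame is t = 0 for pre-fusion speed averaging.

## Spatial statistics

Ripley's `K(r) = (area/n²) Σᵢ≠ⱼ 1[dᵢⱼ ≤ r]` is used *without* edge
correction, with radii capped at a quarter of the shorter domain side, and
with the identical estimator applied to the observed pattern and to every
one of the (default 1000) uniform redistributions of the same n on the
same domain — shared boundary bias cancels in the envelope comparison.
Envelopes are the pointwise min/max of the simulated L curves (the
conservative summary of plotting all curves); each radius is classified
above/within/below. Occupancy counting assigns each molecule to its
nearest vesicle centroid and counts assigned molecules within the window
radius, so a molecule in two overlapping windows is counted once, for the
nearer vesicle. Contour maps count each track at most once per 100 nm box
(from sampled points, without segment interpolation), normalize the counts
to sum exactly to 1, and report per box the mean of the mean speeds of the
tracks passing through. SEM uses the n − 1 denominator.

## Track kinematics

Step speed = step length / step time; track speed = mean of step speeds;
maximum displacement = largest pairwise distance within the track; total
length = sum of step lengths (so max displacement ≤ total length always).
Turning angles use 36 wedges of 10°, counter-clockwise positive, Θ ∈
(−180°, 180°], first positive wedge (0°, 10°]. Deviation mode measures the
signed angle of each step against the forward extension of the previous
step; absolute mode the lab-frame step direction. Zero-length steps are
skipped (no direction). Wedge color/speed is the mean speed of the
contributing steps. The reversal bias is the fraction of deviation angles
beyond ±90°: exactly 0.5 under isotropy, above 0.5 for confined ("ball in
a box") motion. Tracks need ≥ 2 points for speeds and displacement;
single-point tracks are skipped and counted. Length bins for cumulative
displacement profiles default to quartiles of the observed total length.

## The encounter simulation

Molecules are free Brownian walkers (no interactions of any kind);
vesicles follow a tethered Ornstein–Uhlenbeck process,
`dx = θ(μ − x)dt + σ dW`, with μ fixed at the initial (docked) position.
Defaults: 10 × 10 µm periodic domain, 5 s duration (the longest period a
molecule is observable under sptPALM), 50 ms sampling (20 Hz), θ = 5 s⁻¹
and σ chosen for a stationary positional sd of 50 nm per coordinate —
consistent with morphological docking and the ~50 nm pre-fusion movement
scale. Diffusion coefficients D(SNAP-25) = 0.015 and
D(syntaxin) = 0.008 µm²/s are calibrated stand-ins (none are published):
they preserve the SNAP-25 > syntaxin mobility ordering and keep 5 s
maximum displacements under the 1.6 µm ceiling. All are config fields.

Integration is Euler–Maruyama. For the OU vesicles the step is the default
`dt_fine` = 10 µs (the integrator refuses θ·dt ≥ 1). For Brownian motion
the Euler–Maruyama increment is the *exact* transition density at any step
size, so molecules take one exact step per 50 ms sample; this is
statistically indistinguishable from fine stepping and makes the default
problem size (5500 molecules × 101 samples) fast. A 10 µs path is stored
on request (`store_fine`) for selected molecules, consistent with their
sampled positions. Trajectories are stored unwrapped so kinematics see
physical displacements; wrapping happens inside the occupancy counter,
which uses minimum-image distances (exact while drift stays below half the
domain, amply true at 5 s). Convergence is verified with common random
numbers: the coarse step consumes the summed increments of the two fine
half-steps, and occupancy summaries at dt and dt/2 agree within 1%.

Subsampled tracks truncate each molecule at an exponential photobleaching
time (mean 0.5 s, a typical sptPALM track-length scale; not a published
value) capped at the duration. OU parameters are recoverable from sampled
vesicle paths by the exact AR(1) form of the discretized process
(`fit_ou`), within 10% at 50 s duration.

## Pipeline, seeds and problem sizes

Every stochastic function takes an explicit seed; there is no hidden
global state, and identical configs give bit-identical outputs.
`run_pipeline()` derives per-stage sub-seeds from one global seed
(multiplicative-congruential stepping, always below 2³¹) and writes an MD5
manifest of config and outputs; a stage failure still writes the partial
manifest. The test suite uses reduced problem sizes chosen so each suite
exercises the same code paths at comfortable Monte-Carlo margins: envelope
tests use 99 randomizations × 20 replicates, the reference detection movie
is 100 frames of 10 particles at SNR 10 on a 128-pixel field, MSD checks
use 1500–2000 molecules, and occupancy acceptance uses 5 seeds of the full
5500-molecule, 20-vesicle reference configuration.

## Known limitations

Everything is 2-D; there is no photobleaching-state kinetics beyond
geometric blinking, no merge/split or gap closing beyond two missed
frames, no SNARE-complex formation or vesicle–molecule interaction, no
drift correction (only quantification), and no edge correction in K. The
synthetic generator's passing tests demonstrate correctness of the
*algorithms*, not of any biological parameter value: where the underlying
publication prints no number (densities, diffusion coefficients, OU noise,
blink law), the defaults here are documented calibrations and should be
re-fit before applying the pipeline to real data.
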