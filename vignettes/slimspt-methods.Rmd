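---
title: "Models and methods behind slimspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slimspt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimspt)
```

`slimspt` quantifies molecular assemblies seen by two imaging modalities:
high-speed single-molecule fluorescence microscopy (Slimfield/SlimVar-style
movies of diffraction-limited foci in live nuclei) and confocal/Airyscan
3D stacks of micron-scale condensates. This vignette explains the models the
package implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was open.

## The measurement model

A tracked focus is an assembly of S copies of a fluorescently tagged
protein. Its background-corrected intensity in one frame is, in
expectation,

$$ I = S \, b \, f_{\mathrm{ill}}(x, y), $$

where $b$ is the characteristic single-molecule brightness (integrated
camera counts contributed by one fluorophore per frame) and
$f_{\mathrm{ill}}$ the illumination profile, approximately uniform inside
the analysis crop. Everything downstream rests on estimating $b$ once per
reporter and dividing initial track intensities by it.

- **Brightness calibration** (`calibrate_brightness`). During late-stage
  photobleaching an assembly loses one fluorophore at a time, so its
  intensity trace descends a staircase with unit step $b$. Traces are
  denoised with the Chung–Kennedy edge-preserving filter, downward jumps
  exceeding 3 times the local noise s.d. mark step edges, and the step
  amplitude is measured as the difference of plateau medians taken two
  samples clear of the edge (so residual filter transition cannot shrink
  the amplitude). The calibration is the mode of a Gaussian KDE over the
  pooled step sizes (Silverman bandwidth, argmax on a 0.1-count grid). For
  an mScarlet-I-class reporter the defaults centre on $b = 110$ counts with
  15 counts s.d.
- **Stoichiometry** (`stoichiometry`). A least-squares line through the
  first up to 5 intensity samples of a track, evaluated at the track's
  first observed frame, undoes within-track photobleaching; dividing by
  $b$ gives S. Extrapolation is linear (not exponential): over 5 frames at
  the default bleach rates the curvature of the exponential is far below
  the intensity noise, and a linear fit is unbiased at the first frame.
  The target is the track's own first frame, not movie frame zero —
  whole-field decay before detection is handled separately by
  `bleach_correct`, which divides the movie by a fitted monoexponential of
  the frame means.

### The Chung–Kennedy filter

`chung_kennedy` combines a forward (past-window) and a backward
(future-window) running mean with weights proportional to the inverse of
each predictor's summed squared prediction error over the analysis window,
raised to an exponent p. On a plateau both predictors are accurate and the
output is a smooth average; straddling a step, the predictor that mixes the
two levels accumulates a large error and is switched off, so the edge is
preserved. The default exponent is 4: with p = 1 the switch is soft enough
that roughly a tenth of each step leaks into the neighbouring samples,
which biases the modal step low by several percent; p = 4 makes the switch
effectively hard while remaining finite. Endpoint samples lacking one
window are returned unchanged.

### Periodicity of the stoichiometry distribution

Per nucleus, track stoichiometries are smoothed into a Gaussian KDE with a
**fixed** bandwidth of 0.6 molecules — the empirical measurement s.d. on
the single-molecule brightness scale, not a data-driven bandwidth — on a
0.05-molecule grid. Peaks are local maxima whose topographic prominence is
at least 5% of the global maximum (the prominence floor is the package's
choice and is configurable), refined by three-point parabolic
interpolation. Successive peak spacings are pooled across nuclei (weighted
by track count) and the periodicity P is the mode of the pooled interval
KDE, reported both raw and rounded to the nearest integer. Per-replicate
aggregation, where needed, reuses the same weighted pooling.

A resolution limit is worth stating plainly: with measurement noise of 0.6
molecules and a 0.6-molecule bandwidth the effective peak width is about
0.85 molecules, so ladders with a unit of 2 molecules sit at the edge of
bimodality — adjacent peaks occasionally merge and the recovered spacing
then doubles. Units of 3 molecules and above are recovered reliably at a
few hundred tracks; a 2-molecule unit is not, at any sample size. The test
suite asserts exactly this behaviour.

## Detection, localization, linking

- **Sifting** (`detect_foci`): candidates are local maxima of the frame
  smoothed with a 1.5 px Gaussian, excluding a border margin equal to the
  background-box half-width. Duplicate maxima within 2.5 px (noise splitting
  one focus) are collapsed to the brightest. Each candidate's intensity is
  measured with the aperture below and converted to an SNR — intensity per
  disc pixel over the robust s.d. of the background region; the default
  threshold is 0.4 in these units (the original tracking software's numeric
  threshold is unpublished, so this is a declared choice). Finally, any two
  surviving candidates closer than `min_separation` are *both* discarded:
  overlapping assemblies corrupt each other's stoichiometry.
- **Aperture photometry** (`measure_intensity`): the sum over a disc of
  radius 5 px minus the disc area times the mean of the rest of a 17 px
  square. Adding a constant to the frame leaves the measurement unchanged.
  Note that a disc of radius 5 px captures about 87% of a PSF with
  sigma = 2.5 px; because the calibration steps are measured with the same
  aperture, the capture fraction cancels in S = I/b.
- **Localization** (`localize_subpixel`): an iterative Gaussian-mask
  centroid (pixel-integrated mask, mask sigma = PSF sigma) run to
  convergence; each iteration contracts toward the fixed point by roughly a
  factor two, so a fixed small iteration count would leave a visible bias.
  The precision estimate uses the standard centroid-precision formula with
  shot-noise and background terms. At the fixture noise a 4-molecule focus
  localizes to ~40 nm, which is also where the information bound sits for
  these counts.
- **Linking** (`link_tracks`): per frame, an optimal assignment between
  active tracks and new foci minimizing total squared displacement
  (Jonker–Volgenant shortest augmenting path), with links longer than the
  per-frame budget forbidden, gap closing up to 1 frame with the budget
  scaled by sqrt(gap+1), and a minimum track length of 3 so the MSD has two
  lag points. Foci are processed in canonical (x, y) order, making the
  result independent of input ordering.

## Diffusion

`msd` computes the time-averaged mean-square displacement over all ordered
frame pairs of a track; `fit_diffusion` fits a weighted least-squares line
over the first 4 lags, D = slope/4. Four lags keeps the correlated-lag bias
of time-averaged MSD small for short tracks; the intercept is retained and
absorbs the localization-error offset (~4 sigma_loc^2). Negative single-track
estimates are kept (flagged) so that group means stay unbiased; clamping
them at zero would bias slow populations upward. Group summaries split at
S = 10 molecules by default.

## 3D condensate segmentation and colocalization

`blob_segment` re-implements a seeded 3D blob finder as a documented
behavioural contract (the original is a closed vendor tool):

1. the stack is smoothed with an anisotropic Gaussian,
   sigma per axis = diameter / (2 sqrt 3) / voxel size, so the physical blob
   scale is honoured on anisotropic voxels (e.g. 0.06 x 0.06 x 0.26 um);
2. seeds are 26-connected local maxima of the scale-normalized (negated)
   Laplacian of the smoothed stack whose response reaches the
   "probability threshold", expressed in percent of the maximum response —
   this makes segmentation invariant to global intensity scaling;
3. watershed basins grow from the seeds in descending smoothed-intensity
   order; when two basins meet, the first contact is their saddle. Basins
   merge when the saddle depth is at most (1 − split_sensitivity/100)
   times the lower basin height above the stack floor, so split
   sensitivity 0% merges all touching basins and 100% never merges;
4. labels are restricted to the positive-response (blob interior) support.

Object metrics follow the mesh convention: volume is voxel count times
voxel volume; surface area comes from a marching-tetrahedra triangulation
of an isosurface of the lightly smoothed (sigma 0.55 voxel) object mask,
with the iso level set to half the interior maximum so that structures
thinner than the smoothing kernel still close. Sphericity is Wadell's
pi^(1/3) (6V)^(2/3) / A; digitized spheres of radius >= 5 voxels come out
within ~5% of the analytic value and may slightly exceed 1 on coarse
grids. Filters default to a minimum volume of 0.03 um^3 and minimum
sphericity 0.6. Channel alignment uses the 3D FFT cross-correlation peak
with parabolic sub-voxel refinement (as one would calibrate with
multi-fluorescent beads), and colocalization is the voxel-wise AND of the
two label volumes: an object is co-localized iff it shares at least one
voxel with the other channel.

## The synthetic-data generator

`simulate_movie` renders Brownian assemblies (reflecting boundaries at the
ROI edge) whose S fluorophores carry independent Normal(b, cv·b)
brightnesses, bleach independently with an exponential lifetime, and are
imaged as pixel-integrated 2D Gaussians (sigma 0.130 um ~ 2.5 px, truncated
at 4 sigma) on a 53 nm pixel grid at 80 Hz. The camera model is
Poisson(signal + background) plus Gaussian read noise at unit gain.
Background 50 counts/px and read noise 5 counts are the package's fixture
choices (the imaging papers do not state camera magnitudes); they put the
localization precision of a 4-molecule focus at the typical 40 nm scale.
Illumination is flat by default or a centred Gaussian that falls to 80% of
peak at the ROI corner. `simulate_bleach_trace` produces the matching
staircase traces, and `simulate_confocal_stack` renders soft-edged
ellipsoids (half-maximum at the stated radii) into two channels with a
controllable chromatic shift and exact truth labels (analytic volumes,
voxelized pairwise overlap).

What the generator does **not** emulate: oblique-beam optics beyond the
static illumination profile, a 3D PSF for the single-plane movies,
fluorophore blinking, maturation kinetics beyond a static dark fraction,
sample drift, or autofluorescence texture. Tests passing on this generator
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to every property of real root-tissue
data.

## Statistics

`brunner_munzel` implements the nonparametric two-sample test of the
relative effect P(X<Y) + 0.5 P(X=Y) from combined-sample midranks, with
the studentized statistic referred to a t distribution with
Satterthwaite-type degrees of freedom (the standard small-sample
recommendation); a label-permutation variant is available for very small
groups. `welch_t` wraps the two-tailed Welch t-test. Degenerate inputs
(both samples constant and equal) raise an error rather than returning a
p-value.

## Problem sizes and determinism

All simulation entry points take explicit seeds; camera noise is seeded
separately from trajectories so truth is reproducible independently of
photon noise, and equal seeds give bit-identical movies. The test suite and
the acceptance script run at desk scale: 100-500 tracks or traces per
recovery check, 1,000 tracks for ensemble diffusion bias, stacks of about
64 x 48 x 14 voxels for segmentation — sizes at which each check completes
in seconds while the Monte-Carlo error stays well inside the stated
tolerances.

## Known limitations

- Apparent stoichiometries are reported: no correction for immature/dark
  fluorophores is applied.
- The blob finder matches the documented contract, not the vendor's
  proprietary "probability" computation; behavioural equivalence is claimed
  only for threshold ordering and the split/merge semantics above.
- Periodicity at a 2-molecule unit is at the bandwidth resolution limit
  (see above).
- The linker assumes random-walk mobility (no motion model); very dense
  fields of fast particles will fragment.
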