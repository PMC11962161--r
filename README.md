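# slimspt

Single-particle tracking stoichiometry, oligomer periodicity, diffusion and
3D condensate analysis for Slimfield/SlimVar-style fluorescence microscopy.

Biomolecular condensates in living tissue are built from smaller units:
individual protein assemblies that diffuse, multimerize and eventually
coalesce into micron-scale bodies. Quantifying that hierarchy in vivo takes
two kinds of measurement, and this package implements the full analysis
chain for both:

- **Single-molecule movies** (high-speed, narrow-field fluorescence): detect
  diffraction-limited foci per frame with signal-to-noise "sifting",
  localize them to sub-pixel precision (~40 nm), link them into tracks, and
  convert each track's initial intensity into a **stoichiometry**
  S = I / b, where b is the characteristic single-molecule brightness
  calibrated from the modal size of late-stage photobleaching steps
  (Chung–Kennedy filtered). Per-nucleus kernel-density distributions of S
  (fixed 0.6-molecule bandwidth) yield peaks whose most common
  nearest-neighbour spacing is the **periodicity** P — the repeating
  oligomeric unit. Mean-square displacement fits under a 2D random-walk
  model (MSD = 4 D tau + offset) give each track's diffusion coefficient D.
- **Confocal/Airyscan 3D stacks**: a seeded blob finder (scale-matched
  Laplacian-of-Gaussian seeds + 3D watershed with saddle-depth merging)
  segments condensates per channel; objects are filtered by volume
  (>= 0.03 um^3) and mesh (Wadell) sphericity (>= 0.6), aligned across
  channels with bead-calibrated FFT cross-correlation, and co-localized by
  voxel-wise intersection.

A ground-truthed synthetic-data generator (`simulate_movie`,
`simulate_bleach_trace`, `simulate_confocal_stack`) emulates the imaging
regime — Brownian assemblies with per-fluorophore exponential bleaching,
pixel-integrated Gaussian PSF on a 53 nm grid at 80 Hz, Poisson + read
camera noise, ellipsoidal two-channel phantoms — so every stage is testable
without any raw data. Group comparisons use the Brunner–Munzel
nonparametric test (plus Welch's t-test).

## Worked example

```r
library(slimspt)

## 1. calibrate single-molecule brightness from photobleaching steps
emit <- emitter_model(brightness_b = 110, brightness_cv = 15/110,
                      bleach_rate = 0.02)
traces <- lapply(1:200, function(i)
  simulate_bleach_trace(((i - 1) %% 4) + 1, emit, noise_sd = 10,
                        seed = i, n_frames = 150)$trace)
cal_b <- calibrate_brightness(traces)

## 2. track a synthetic movie and estimate stoichiometry + diffusion
cal <- movie_calibration(frame_count = 40, roi = c(128, 96))
set.seed(1)
asm <- data.frame(S = sample(c(4, 8, 12), 8, replace = TRUE), D = 0.1)
sim <- simulate_movie(cal, asm, emitter_model(bleach_rate = 0.01),
                      noise_model(), seed = 1)
foci <- do.call(rbind, lapply(1:40, function(f) {
  d <- detect_foci(sim$movie[, , f])
  if (nrow(d)) cbind(frame = f, d) else NULL
}))
tracks <- link_tracks(foci)
tab <- merge(stoichiometry_table(tracks, cal_b), diffusion_table(tracks),
             by = "track_id")

## 3. periodicity of a stoichiometry ladder (tetramer multiples + noise)
set.seed(2)
s <- sample(seq(4, 56, 4), 500, replace = TRUE) + rnorm(500, 0, 0.6)
pr <- periodicity_by_nucleus(
  data.frame(S = s, nucleus_id = rep(1:10, each = 50)),
  periodicity_config(max_s = 70))

## 4. 3D phantom: segment both channels, intersect
obj <- data.frame(x = c(0.9, 2.9), y = 1.4, z = 1.8,
                  rx = 0.175, ry = 0.175, rz = 0.175, peak = 100)
ph <- simulate_confocal_stack(phantom3d_config(shape = c(64, 48, 14),
        objects_ch1 = obj, objects_ch2 = obj[1, ]))
la <- blob_segment(ph$ch1, c(0.06, 0.06, 0.26), blob_params(preset = "mscarlet"))
lb <- blob_segment(ph$ch2, c(0.06, 0.06, 0.26), blob_params(preset = "mturquoise"))
cc <- colocalize(la, lb)

## 5. nonparametric group comparison
brunner_munzel(c(0.02, 0.05, 0.04, 0.11, 0.06),
               c(0.08, 0.14, 0.21, 0.11, 0.17))
```

Output from this exact script:

```
b_modal = 112.2 counts/molecule (85 steps, sd 26.8)
14 tracks; S range 2.5-10.2; mean D = 0.11 um^2/s
periodicity P = 4.05 molecules (rounded 4)
channel 1: 2 objects, 50% co-localized with channel 2
Brunner-Munzel test: statistic = 6.102, df = 6.97, p = 0.0004988
relative effect P(X<Y)+0.5P(X=Y) = 0.9400 (n = 5, 5)
```

Reading the numbers: the modal photobleaching step recovers the simulated
110-count single-molecule brightness within ~2%; the tracked movie yields
per-track stoichiometries spanning the simulated 4–12-molecule range
(apparent S is scaled by the aperture's PSF capture fraction unless b is
calibrated through the same aperture, which is how the real pipeline
operates); the 4-molecule ladder is recovered as a periodicity of 4; the
channel-1 sphere that was also rendered in channel 2 is flagged
co-localized while the other is not; and the Brunner–Munzel relative
effect of 0.94 says draws from the second group exceed the first 94% of
the time.

A YAML-driven runner (`run_pipeline`) chains
simulate → detect → track → stoich → mobility → periodicity, writing
stage CSVs stamped with the config hash plus a log;
`inst/scripts/spt-pipeline.R` wraps it for shell use.

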