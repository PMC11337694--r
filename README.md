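# psar

Phase-space density-map features for single-lead ECG by **periodic split
attractor reconstruction** (PSAR).

## The problem

Single-lead (lead-I) ECG is the channel wearable and portable monitors can
record, and nonlinear-dynamics features of it — attractors reconstructed by
Takens time-delay embedding — are informative inputs for automated
cardiovascular and sleep-apnea screening. A classical delay embedding

v(n) = (yₙ, yₙ₊τ, yₙ₊₂τ),   m = 3

uses one global delay τ, conventionally a third of the *mean* cycle period.
Because heart rhythm is not strictly periodic, a global τ falls out of
register as the RR interval fluctuates, and the orbit smears. PSAR instead
**splits the record by cardiac cycle** (three schemes: R-R, Q-R-S, S-TP-Q),
embeds each segment with its own delay

τᵢ = round(Tᵢ / 3)

(Tᵢ the segment's period in samples), and re-splices the per-cycle
trajectories. The trajectory is projected onto the plane orthogonal to the
x = y = z axis,

u = (x − z)/√2, v = (x − 2y + z)/√6, w = (x + y + z)/√3,

and the (u, v) points are binned into a density map — an image feature for
downstream classifiers. Constant baseline offsets move points only along w,
so the maps are exactly offset-invariant; per-cycle embedding with τ = T/3
gives the orbit an exact Z₃ (120°) symmetry for periodic cycles and makes
the projected point set invariant under time-rescaling of a cycle.

The package implements the full chain for anyone who wants these features
without a GPU pipeline: preprocessing (10-level Daubechies-6 wavelet
band-removal denoising, LOESS baseline-wander subtraction, band-limited
resampling), PQRST fiducial detection, the three split schemes, circular
and truncated per-cycle embedding, projection, density maps, PNG/CSV/JSON
artifacts, WFDB/CSV I/O, classification metrics, and a fully seeded
synthetic-signal module (ideal sinusoids, drift/noise injectors, and a
PQRST generator with exact ground truth) so every stage is testable without
any ECG archive.

## Worked example

```r
library(psar)

ecg   <- gen_synthetic_ecg(bpm = 70, rr_cv = 0.15, duration_s = 120,
                           noise = list(snr_db = 20), seed = 1)
clean <- preprocess_pipeline(ecg$signal)
fids  <- detect_fiducials(clean)
glance(fids)
#> # A tibble: 1 × 8
#>   n_beats mean_rr_s cv_rr mean_hr_bpm prop_p prop_q prop_s prop_t
#> 1     138     0.864 0.130        69.4  0.993  0.993      1      1

traj <- reconstruct_attractor(clean, fids, method = "rr")
dm   <- make_density_map(project_points(traj))
dm
#> <psar_density> 224 x 224 grid, 59193 points in, 0 clipped
#>   u range [-0.8348, 0.8348] mV, v range [-0.8348, 0.8348] mV, 6595 occupied bins

match_events(detect_r_peaks(clean), ecg$truth$r, fs = 500)
#> # A tibble: 1 × 8
#>   n_truth n_detected    tp    fp    fn sensitivity precision mean_abs_err_ms
#> 1     138        138   138     0     0           1         1           0.319
```

The 120 s record at 70 bpm with RR coefficient of variation 0.15 and 20 dB
white noise yields 138 beats; after denoising and detrending, all 138 R
peaks are recovered (sensitivity and precision 1.0, mean timing error
0.32 ms), the R-R split produces 137 cycle segments whose 59 193 embedded
points land in a 224 × 224 density map. `render_image(dm, "map.png")`
writes the map as a deterministic 8-bit grayscale PNG; `autoplot(dm)` shows
it in R.

`run_pipeline(psar_config(...), signal = ...)` wires the whole chain and
writes the artifact bundle (density PNG + CSV grid + JSON metadata +
fiducial CSV); `export_dataset()` builds per-class image trees for
classifier training; `inst/cli/psar` exposes `run`, `simulate`, `export`
and `metrics` subcommands for shell use.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end from scratch: it generates the seeded
synthetic ECG above, runs preprocessing, fiducial detection, and all three
split schemes through to density artifacts, verifies each run completes,
and writes the result summary JSON to `--out`.

## Method properties verified by the test suite

* exact wavelet round-trip and band selectivity of the denoiser;
* baseline-ramp removal (fitted residual slope < 5 × 10⁻⁶ mV/ms on a
  5 × 10⁻⁵ mV/ms ramp);
* exact offset-invariance of density maps, Z₃ symmetry, full-period orbit
  collapse, and time-rescaling invariance of the projected point set;
* R-peak sensitivity/precision ≥ 0.99 at 50 ms tolerance on noisy
  irregular synthetic records across 50 seeds;
* structural bookkeeping (segment, point and bin-mass counts) and the
  classification-metric arithmetic.

See `vignettes/psar-methods.Rmd` for the model, parameter choices, and an
analysis of a known structural limitation of drift thickening under
per-cycle embedding.
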