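# edascope

Hybrid event-driven acquisition (hybrid-EDA) for live-cell microscopy, as a
desk-scale, fully synthetic-testable R package.

## The problem

Continuous fluorescence imaging of mitochondria at 1 frame per second kills
cells within minutes, while label-free phase-contrast at the same rate is
nearly harmless (> 100-fold lower excess mortality). The events worth the
fluorescence — mitochondrion–droplet/lysosome contacts (~20 s, about one per
3.1 min) and divisions with transient pre-constrictions (~one per 3.2 min) —
are rare. Hybrid-EDA surveils in phase-contrast, runs a neural-network event
detector on every frame, and switches to correlative phase + fluorescence
only when an event score crosses a threshold:

* **Detector**: a U-Net (depth 2, 16 initial filters) regressing per-pixel
  event heatmaps — unit-peak Gaussians on the last five frames of each
  event — trained with a soft focal loss
  `L = mean(|t − p|^γ · [−t·log p − (1−t)·log(1−p)])`,
  with single-frame, channel-stacked multi-frame, and *stateful* variants
  (time-distributed encoder + convolutional LSTM memory bottleneck).
* **Selection metric**: `F_β = (1+β²)·P·R / (β²·P + R)` with β = 0.1, so
  precision dominates — a false trigger costs a phototoxic burst.
* **Controller**: a two-state machine (analyzer → interpreter with memory and
  thresholding → scheduler) with a minimum correlative burst (default
  20 frames) and one frame of actuation latency.
* **Accounting**: at one event per 3.1 min and 1 Hz, continuous fluorescence
  spends 186 frames per event; a 20-frame triggered burst is a ~9-fold
  reduction (192 frames and ten-fold at the division rate of 1/3.2 min).

The package also ships the virtual microscope it is tested against: a
simulator of phase-contrast/fluorescence time-lapses with scripted contacts,
divisions, ruffle distractors, photobleaching and a light-dose–dependent
viability model, plus the downstream analyses (survival curves with
exponential-decay fits, SYTOX/Hoechst death scoring, duty-cycle arithmetic,
DRP1 daughter-tip ratios, TMRE tracking and flicker detection).

## Worked example

Closed-loop acquisition with the ground-truth (oracle) detector on a 60-min
synthetic movie with Poisson contacts at the reference rates:

```r
library(edascope)

cfg  <- sim_config(duration = 3600, frame_rate = 1,
                   contact_rate = 1 / 3.1, contact_duration = 20,
                   division_rate = 0, seed = 1)
traj <- simulate_sample(cfg)
det  <- oracle_detector(traj$events, c(cfg$height, cfg$width))
ctrl <- controller_config(min_correlative_frames = 20,
                          correlative_channels = "ld_fluo")
log  <- run_eda(traj, det, ctrl, render = FALSE)
st   <- capture_stats(log, traj$events)

model <- duty_cycle_model(event_interval = 3.1, event_duration = 20,
                          frame_rate = 1)
cat(sprintf("events %d, captured %.0f%%, duty cycle %.3f, %.1f fluo frames/event, %.1f-fold reduction\n",
            st$n_events, 100 * st$events_captured_fraction, st$duty_cycle,
            st$fluorescence_frames_per_captured_event,
            fold_reduction(model, st$fluorescence_frames_per_captured_event)))
#> events 24, captured 100%, duty cycle 0.127, 19.0 fluo frames/event, 9.8-fold reduction
```

Every event was captured, fluorescence ran 12.7% of the time instead of
100%, and each captured event cost ~19 fluorescence frames instead of the
186 a continuous acquisition would spend — the ~nine-fold phototoxicity
reduction per event. (Averaged over seeds 1–5 the duty cycle is 0.104 and
the fold reduction 9.7.)

Training a small contact detector on synthetic 64×64 crops:

```r
movies <- make_event_movies("contact", n_events = 20, seed = 5)
ts  <- make_crop_dataset(movies, n_time_points = 3)
det <- build_detector(detector_config(n_time_points = 3, loss = "soft_focal",
                                      epochs = 6, seed = 2))
det <- train_detector(det, ts)
maps <- infer_sequence(det, movies[[1]]$movie)
```

## Command line

```sh
Rscript inst/cli/eda.R simulate --config sim.yaml --seed 1 --out out/
Rscript inst/cli/eda.R train    --config train.yaml --data out/ --runs 5 --out model/
Rscript inst/cli/eda.R evaluate --model model/model.rds --data out/ --beta 0.1 --out eval/
Rscript inst/cli/eda.R run-eda  --sim sim.yaml --model model/model.rds --seed 1 --out eda/
Rscript inst/cli/eda.R analyze  dutycycle --interval 3.1 --rate 1 --triggered 20 --out .
```

Movies are multi-page TIFF (one file per channel, TYX, ImageJ-compatible);
events are CSV (`event_id,class,polarity,t_start,t_end,x,y`, 0-based
inclusive frame spans); configs are YAML; every run writes a
`manifest.json` with seeds and a config hash.

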