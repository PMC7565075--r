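# mptrack

Multi-parametric cell tracking for fluorescence time-lapse microscopy.

`mptrack` is for quantitative biologists running live-cell chemotaxis and
growth assays: cells embedded in a 3D gel inside a microfluidic chamber,
imaged at low magnification for days (defaults: 1.34 µm/pix, one frame
every 30 min, 240 frames), one fluorescence channel per cell population.
From raw multi-page TIFF stacks it produces labeled cells, migration
tracks, and the standard chemotaxis statistics, and it ships a synthetic
time-lapse generator with ground truth so the whole pipeline is testable
without microscopy data.

## The method

**Segmentation** (per frame): morphological-opening background
subtraction → frame-wise linear intensity adjustment saturating 1% of
pixels (compensates photobleaching) → 5×5 block-mean downsampling →
Hessian eigenmap detection (bright blobs have λ₂ < 0 with |λ₁| ≤ |λ₂|) →
adaptive h-maxima peak splitting → marker-seeded region growing → full
resolution boundary refinement, stopping at 25% of each cell's peak
intensity or at sharp Canny edges.

**Parameterization**: each cell becomes the feature vector
(C_x, C_y, I_max, R, θ, S, AR) — intensity-weighted centroid, peak
intensity, equivalent radius R = √(A_cell/π), and the equivalent
ellipse's orientation θ, solidity S = A_cell/A_CH and aspect ratio
AR = R_b/R_a ∈ (0, 1].

**Tracking**: frames are linked by minimum total weighted deviation

    cost = w_xyz · ‖Δ(Cx,Cy)‖ + Σ_m w_m · |Δ_m| / s_m,

over the non-spatial features (θ wrapped with period π, scales s_m robust
per frame pair), solved as a gated Hungarian assignment with optional gap
closing — the classic nearest-neighbor criterion plus brightness and
morphology, which preserves identities where pure proximity would swap
crossing cells.

**Statistics** (µm and hours, from stack calibration): per-step
velocities (u,v); Euclidean vs accumulated distance per track; forward
migration indices FMI∥ = mean(x_end/d_acc) along the chemotaxis gradient
(negative x toward the chemoattractant; straight runs toward it give −1)
and FMI⊥; directness D = mean(d_euc/d_acc); normalized counts N_t/N₀;
velocity histograms. Condition summaries apply the protocol's selection
rule (drop tracks ≤ 10 frames, keep the 100 longest per replicate, pool —
triplicates give 300 tracks).

## Worked example

Simulate a 50-frame movie of 20 cells performing an unbiased persistent
random walk at 3 µm/h, then run the full pipeline and summarize:

```r
library(mptrack)

cfg <- simulation_config(image_size = c(384, 384), n_frames = 50,
                         n_cells_init = 20, division_rate = 0,
                         death_rate = 0, seed = 11)
truth <- simulate_truth(cfg)
stack <- render_stack(truth, cfg)
stack
#> image_stack: 50 frames of 384 x 384 [sim], 1.34 um/pix, 30 min/frame

res <- track_stack(stack, segmentation_config(),
                   tracking_config(max_link_distance = 15))
res$labels[[1]]
#> label_image: frame 0, 384 x 384, 20 cells

summ <- condition_summary(list(res$tracks), pixel_size = stack$pixel_size,
                          frame_interval = stack$frame_interval,
                          k = 20, min_frames = 10)
summ
#> condition_summary: 20 pooled tracks
#>   N/N0 final: 1.000 | mean speed: 2.99 um/h
#>   FMI par: +0.0183 | FMI perp: +0.0743 | directness: 0.263

head(summ$per_track[, c("n_frames", "mean_speed", "d_euc", "d_acc",
                        "directness_i")], 4)
#>   n_frames mean_speed  d_euc  d_acc directness_i
#> 1       50      3.010 10.551 73.754        0.143
#> 2       50      3.020  7.738 73.984        0.105
#> 3       50      3.031  5.886 74.265        0.079
#> 4       50      2.999 14.415 73.485        0.196
```

All 20 cells are found in every frame and the recovered mean speed
(2.99 µm/h) matches the configured 3 µm/h; FMI near zero and the modest
directness are what an unbiased random walk should produce. On this
stack, every frame-to-frame link agrees with the simulator's ground
truth. `render_trajectory_map(res$tracks, k = 20)` draws the wind-rose
trajectory plot; `run_pipeline()` writes tracks/metrics/summary files
plus a manifest, and `inst/cli/celltrack` exposes `simulate`, `run`,
`metrics` and `map` subcommands for shell use.

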