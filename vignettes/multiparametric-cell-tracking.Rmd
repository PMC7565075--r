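---
title: "Multi-parametric cell tracking: models, parameters and design notes"
author: "mptrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric cell tracking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptrack)
```

## What the package computes

`mptrack` quantifies the growth and migration of fluorescently labeled
cells in time-lapse microscopy, the setting of chemotaxis assays in
microfluidic chambers: cells embedded in a gel are imaged at low
magnification (defaults: 1.34 µm/pix, one frame every 30 min, 240 frames
over 5 days), each population carrying its own fluorophore so channels are
analyzed independently. The pipeline has four stages:

1. **Segmentation** of each frame into labeled cell regions.
2. **Parameterization** of each region as a feature vector
   $(C_x, C_y, I_{max}, R, \theta, S, AR)$.
3. **Tracking** by minimum weighted feature deviation between frames.
4. **Statistics**: per-track velocities and distances, and per-condition
   growth and chemotaxis summaries.

A synthetic time-lapse generator with known ground truth closes the loop:
every stage is validated against simulations whose answers are known by
construction.

## The segmentation chain

Fluorescence time-lapse frames have three nuisance properties the chain is
built around: uneven illumination, photobleaching (intensities decay over
hours of acquisition), and intracellular intensity heterogeneity.

- **Background subtraction** — grayscale morphological opening with a disc
  of radius `background_radius` (default 40 px, roughly four times the
  largest expected cell radius), subtracted and clipped at zero. The
  opening is computed on a lightly smoothed (σ = 2 px), replicate-padded
  copy. Both details matter in practice: opening a raw noisy frame tracks
  the *lower envelope* of the noise, leaving a positive residual
  proportional to the noise amplitude, and unpadded erosion underestimates
  the background near borders; either residual becomes spurious
  "cells" once later frames bleach and the intensity adjustment rescales.
- **Intensity adjustment** — a frame-wise linear map onto $[0, 1]$ that
  saturates `saturation_fraction` (default 1%) of the pixels, split
  equally between the two tails. Because the map is recomputed per frame
  it compensates photobleaching; because it is affine-invariant the rest
  of the chain sees a stable intensity scale.
- **Downsampling** — non-overlapping 5 × 5 block means. Cells are
  detected at this coarse scale so intracellular texture cannot split one
  cell into several.
- **Hessian eigenmap** — the smoothed intensity's per-pixel 2 × 2 Hessian;
  ordering eigenvalues by magnitude ($|\lambda_1| \le |\lambda_2|$, the
  vesselness convention), bright blob- and tube-like structures have
  $\lambda_2 < 0$. The sign test alone fires on half of all background
  noise pixels, so candidates must also exceed `support_threshold` on the
  adjusted scale.
- **Dynamic erosion** — within each candidate component, peaks are
  separated by an h-maxima transform with adaptive prominence
  $h = h_{frac} \cdot (\text{component max} - \text{component min})$
  (default `h_fraction` 0.1): raising a threshold until touching cells
  split at their saddle, while peaks less prominent than $h$ merge.
- **Dilation** — marker-seeded region growing over the above-background
  support (`EBImage::propagate` with a small smoothness weight), which
  places boundaries between touching cells at the intensity saddle.
- **Refinement** — coarse regions are mapped back to full resolution and
  regrown from each cell's bright core (pixels above 80% of its peak).
  Growth stops where intensity falls below
  `refine_stop_fraction` (default 25%) of the cell's peak, or at a sharp
  edge (next section); regions outside `[min_cell_area, max_cell_area]`
  are discarded. For a Gaussian-profile cell the 25% rule recovers the
  quarter-maximum level set, radius $\sqrt{2\ln 4}\,\sigma$.

### Edge-stopped growth: a calibrated design choice

Using a Canny edge map as a growth barrier poses a real conflict for
diffuse fluorescent cells: with purely quantile-based hysteresis
thresholds, the strongest gradients in a sparse field are the smooth
flanks of the cells themselves, and every cell gets carved along a ring
of its own flank. Measured on ideal profiles, a unit intensity step
produces a non-maximum-suppressed gradient magnitude of ≈ 0.32 per pixel,
while a Gaussian blob flank never exceeds ≈ 0.16 of its amplitude (σ ≥ 3
px). The refinement therefore treats an edge *chain* as a barrier for a
given cell only when the chain's peak gradient reaches
`edge_stop_fraction` (default 0.2) of that cell's peak intensity — above
everything a smooth flank can produce, below what a genuine sharp
boundary produces. The detector itself keeps its quantile thresholds
(defaults 0.80/0.95) plus a small absolute floor (`min_gradient`
0.05/px) against the sensor-noise gradient floor.

Two consequences are worth knowing. First, growth is 4-connected inside
the refinement (regions remain connected a fortiori): an 8-connected
one-pixel edge chain cannot block 8-connected growth — the two
connectivities must be dual or the barrier leaks diagonally. Second, a
strongly *saturated* cell (clipped by the 1% adjustment) can present a
flank steep enough to act as its own barrier, in which case its measured
region shrinks toward the saturated core; counts and centroids are
unaffected, but area-derived features of very bright small cells are
biased low. This is the price of the paper-style per-frame saturation,
not of the edge rule.

### Saturation and closed-form checks

The 1% saturation deliberately clips cell peaks (that is how it
normalizes bleaching), which rescales "25% of peak" relative to the
*clipped* peak and enlarges the recovered level set by a predictable
factor. Closed-form fixtures (the quarter-maximum radius check) therefore
run with a near-zero `saturation_fraction`; the default is right for real
and simulated movies, not for analytic identities.

## The feature vector

Shape terms come from the unweighted pixel set (the equivalent ellipse
with matched second moments; `Ra`, `Rb`, θ with period π wrapped to
[−π/2, π/2)); only the centroid is intensity-weighted, and `Imax` is the
region's peak intensity. Solidity uses the convex hull of pixel *corner*
points (each pixel a unit square), the convention under which a convex
pixel region has solidity exactly 1 and the plus-pentomino has hull area
7 — a hull of pixel centers would give a 1 × n bar zero hull area and
solidity above 1. Degenerate single-pixel regions get semi-axes of 0.5 px.

## Tracking

The link cost between cells $a$ (frame $t$) and $b$ (frame $t+1$) is

$$ c(a,b) = w_{xyz}\,\lVert (C_x,C_y)_a - (C_x,C_y)_b \rVert
  + \sum_m w_m \frac{|\Delta_m|}{s_m}, $$

over the five non-spatial features $(I_{max}, R, \theta, S, AR)$, with
the orientation deviation wrapped at period π (+89° vs −89° differ by
2°). The scales $s_m$ are median absolute deviations pooled over the two
frames being linked, so "one unit of deviation" is comparable across
features with different physical units; a feature with no spread gets
scale 1. Defaults weight everything equally (`w_xyz` = 1, all `w_m` = 1).
θ is treated linearly in the MAD — adequate because the scale only
equalizes units; it is not a circular-statistics estimate.

Assignment is a maximum-cardinality minimum-cost partial matching: the
Hungarian algorithm on a matrix padded with per-cell unmatched
alternatives, with pairs beyond `max_link_distance` (pixels) forbidden.
A greedy ascending-cost mode exists for comparison and is never cheaper.
Ties prefer the older (smaller-id) track, making linking invariant to the
order detections are listed. Tracks may bridge up to `max_gap_frames`
missed detections, with the spatial gate scaled by the elapsed gap;
velocities across a closed gap divide by the full elapsed time. Divisions
are not resolved: a division appears as one matched daughter plus one new
track, which is also how the simulator's lineage events present to the
tracker. The z coordinate of a single-focal-plane acquisition is constant
and the spatial term is 2D.

## Migration statistics

With calibration (µm/pix, min/frame) from stack metadata — never
hard-coded — each track yields per-step velocities, the Euclidean
distance $d_{euc}$ (net start-to-end displacement), the accumulated
distance $d_{acc} = \sum_t \sqrt{u_t^2 + v_t^2}$, and per-condition:

- $N_t/N_0$ growth curves (from all detections, before track selection);
- forward migration indices
  $FMI_{\parallel} = \frac1n \sum_i x_{i,end}/d_{i,acc}$ (x parallel to
  the chemotaxis gradient, negative x toward the chemoattractant) and
  $FMI_{\perp}$ likewise in y;
- directness $D = \frac1n \sum_i d_{i,euc}/d_{i,acc}$ (1 = straight-line
  migration);
- a velocity-magnitude histogram (0.5 µm/h bins to the 99th percentile)
  and a per-frame mean velocity series (unsmoothed by default; a centered
  moving-average window is available but off, since no smoothing
  convention is standard).

One published formula for $d_{acc}$ repeats $u_t^2$ where $v_t^2$ is
plainly intended; the implementation uses $\sqrt{u_t^2+v_t^2}$, without
which $d_{euc} \le d_{acc}$ would not hold.

Condition summaries follow the protocol's selection rule: per replicate,
drop tracks of ≤ `min_frames` (default 10) frames, keep the `k` (default
100) longest (ties: larger $d_{acc}$, then smaller id), pool replicates —
three replicates give the canonical 300 tracks. Growth curves
intentionally bypass selection, since $N_t/N_0$ is a counting statistic.
Whether the per-frame mean velocity should include non-selected tracks is
not standardized; the default uses the selected pool, and
`velocity_on_all = TRUE` switches.

## The simulator

`simulate_truth()` draws a persistent random walk per cell: fixed step
length $L$ = `motion_speed` × frame interval, headings accumulating
wrapped-normal turns with $E[\cos(\text{turn})]$ = `persistence`
(σ = $\sqrt{-2\ln p}$, uniform at $p = 0$, straight at $p = 1$).
Chemotaxis adds drift along x:
$\text{step} = (1-|b|)\,L\,(\cos\varphi, \sin\varphi) + b\,L\,\hat e_x$,
so at $b = \pm 1$ runs are exactly straight and, at zero persistence, the
mean x-step is exactly $bL$. Cells reflect at the field edges; divisions
and deaths are per-interval Bernoulli events with the configured Poisson
rates, daughters placed one radius away under a fresh id with lineage
recorded. Orientation is fixed per cell.

`render_stack()` draws each cell as an anisotropic Gaussian whose
quarter-maximum contour equals the truth ellipse — so the 25% refinement
rule should recover the truth semi-axes — then applies bleaching
$2^{-t\,\Delta t/t_{1/2}}$, a multiplicative linear illumination field
spanning `illumination_gradient` across the diagonal, and additive
Gaussian noise clipped at zero. All randomness flows through the single
config seed (the renderer uses seed + 1 so truth and rendering are
independent streams); identical config and seed reproduce stacks
bit-for-bit.

Defaults mirror the acquisition they emulate: 1024 × 1280 field at
1.34 µm/pix, 240 frames at 30 min, ~100 cells, radii 7–12 µm,
eccentricity up to 0.7, speeds around 3 µm/h (the observed 2–5 µm/h
range), division ≈ 0.005/h (a ~40% rise over 2.5 days) and death ≈
0.002/h, a 48 h bleach half-life, 20% illumination drop, and initial
spacing of at least four cell radii (sparse gel seeding). Where the
emulated protocol states no value (noise, background, bleach rate) the
choice is a plausible mid-range one, stated once here.

What the simulator does *not* emulate — and hence what passing its tests
cannot show — includes non-Gaussian cell morphologies (protrusions,
elongation during crawling), intracellular texture, out-of-focus drift,
cell–cell adhesion and contact dynamics, and optical PSF effects beyond
the Gaussian profile. Recovery rates quoted on synthetic data are upper
bounds for real microscopy.

## Numerical and scale choices

- Desk-scale validation sizes: stack-based recovery runs use a 384 × 384
  field with 20 cells and 50 frames per seed (two seeds), where
  segmentation recovers the exact true count in ≥ 99% of frames and
  ≥ 95% (in practice 100%) of ground-truth links; statistic-recovery
  sweeps use 300 truth tracks × 3 persistence levels without rendering.
  These sizes were chosen as the smallest at which the checked rates are
  stable.
- The assignment oracle (exhaustive enumeration of partial assignments)
  is checked on a thousand seeded instances up to 6 × 6.
- 16-bit TIFF quantization bounds the stack round-trip error at
  `intensity_scale`/65535; the scale lives in the YAML sidecar.
- Degenerate inputs: blank frames segment to zero labels; empty masks,
  empty marker sets and empty coarse labels propagate as empty results;
  all-zero-intensity regions fall back to geometric centroids with a
  flag; zero-$d_{acc}$ tracks are excluded from FMI/directness with a
  warning.
- Tie-breaking is deterministic everywhere (component order, label order,
  assignment ties), so the whole pipeline is reproducible byte-for-byte
  given inputs and config.

## Known limitations

- Touching cells whose saddle is shallower than the adaptive prominence
  merge into one region; the tracker then sees one detection (recorded,
  not resolved).
- Track selection by length biases toward long-lived, well-detected
  cells; this is the protocol's intent (it discounts debris and dying
  cells) but it is a selection effect, and `min_frames`/`k` should be
  reported with any result.
- MAD-based feature scales adapt per frame pair; in frames with very few
  cells the scales are noisy and the spatial term effectively dominates.
- The per-cell sequential claim of pixels during refinement (label order)
  can, for touching cells, assign the contested boundary to the
  lower-labeled cell.
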