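---
title: "Methods: single-fly arena tracking and locomotion analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-fly arena tracking and locomotion analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

flyarena analyses long (up to 24 h), 1 frame/s grayscale recordings of a
circular dish partitioned into walled sectors, one fly per sector, on a
bright IR-backlit field. This vignette is the package's account of its
models, parameters, numerical choices and limitations. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Arena model

The arena is modelled as a dish of diameter 85 mm split into `n_sectors`
equal annular wedges around the dish centre. The assay's constants are
areas, not shapes, so the inner wedge radius is solved in closed form from
the configured per-sector area $A_s$:

$$ r_\text{in} = \sqrt{r_\text{out}^2 - \frac{n \, A_s}{\pi}}, $$

with defaults $n = 8$ and $A_s = 5.5\ \mathrm{cm^2}$, giving a radial band
of roughly 20–42.5 mm. Each sector carries one circular food-patch ROI of
0.2 cm² (radius $\sqrt{20/\pi} \approx 2.52$ mm) at the wedge's area
centroid, plus an identical "virtual" patch ROI for patch-free assays. A
user-supplied integer label mask (`geometry_from_mask()`) is the escape
hatch for arenas that do not follow the wedge layout.

**Calibration.** The package takes the imaging calibration from the
stationarity convention 2 px = 0.1 mm, i.e. `pixel_scale = 0.05` mm/px.
An 85 mm dish at that calibration needs a 1700 px square, which is
therefore the default image size: it is the only default under which the
dish diameter, the sector areas and the 2 px = 0.1 mm conversion are
simultaneously consistent (an 85 mm dish imaged onto 1024 px would imply
≈0.083 mm/px instead; the two conventions cannot hold at once). Calibration
is a config field end to end — nothing downstream assumes 0.05 — and most
tests run the same geometry at coarser calibrations (e.g. 85 mm over
256 px) purely for speed, which the area logic is invariant to within
rasterisation error.

Coordinates are continuous pixels: origin at the top-left pixel centre,
x right, y down; regions are rasterised (pixel-centre-in-region, boundary
inclusive) only when a mask or an area is needed. ROI membership is
boundary-inclusive so analytic queries and mask lookups agree.

## Synthetic experiments

`simulate_trajectory()` is a two-state Markov walker at 1 s resolution
(matching the 1 Hz acquisition; speeds are therefore per-frame
displacements):

* state transitions: stop→walk with probability `p_stop_to_walk` per
  second, walk→stop with `p_walk_to_stop`; the initial state is drawn from
  the chain's stationary distribution;
* in the walk state the step length is log-normal
  (`speed_log_mean`, `speed_log_sd`, mm) along a heading equal to the
  previous heading plus a wrapped-normal turn (`turn_sd`, radians),
  optionally mixed with a unit vector toward the sector's patch weighted by
  `patch_attraction`;
* walls reflect: a step leaving the wedge is folded back by mirror
  reflection in the radial and angular coordinates, with a body-radius
  margin so the rendered disc stays inside;
* in the stop state the position is unchanged.

Detection dropout is modelled as omission of the fly from the rendered
frame (not occlusion), so injected missing rates are exact and the QC
recovery targets are analytic. Rendering draws each present fly as a dark
disc (`fly_radius`, default 1.2 mm) on the bright field with darker walls,
adds Gaussian pixel noise (`noise_sd`, grayscale units on the 0–255 scale)
and clips to the valid range.

The shipped group presets encode the direction, not the magnitude, of the
feeding-state contrast: "pre-fed" walks fast (median step 4 mm/s, so a
substantial 5–10 mm class) with no patch attraction; "pre-starved" walks
slowly (median 1.1 mm/s, mostly ≤2 mm steps), stops more, and is
patch-attracted. These magnitudes are the generator's own choices — the
fixture gives the comparison pipeline a known-direction effect, nothing
more.

**What passing tests do and do not show.** The generator emulates stop/walk
kinematics, wall confinement, dropout and sensor noise; it does not model
grooming or micro-movements, body pose, legged gait, photorealistic
appearance, circadian modulation of its parameters, or occlusion-like
failure modes. Tests passing on synthetic recordings therefore validate the
pipeline's bookkeeping and numerics, not its robustness to every artefact
of real video.

**Wall accumulation and the occupancy null.** A persistent random walk
(small `turn_sd`) in a reflecting domain does not have a uniform stationary
distribution: correlated headings pile density up against the walls and
deplete the mid-band, where the patch sits. We verified this empirically —
with the default `turn_sd = 0.6` the radial density visibly exceeds the
uniform law near both walls and patch occupancy falls ~15% below the
area ratio, while with a near-isotropic kernel (`turn_sd = 3`) the radial
density matches the uniform law and occupancy is unbiased across seeds.
The uniform-ergodicity check (patch occupancy = patch/sector area ratio
0.2/5.5 ≈ 0.036 for a `patch_attraction = 0` walker) is therefore computed
under the isotropic kernel with a negligible body margin, which is the null
model for which the area ratio is the true value. Its Monte-Carlo tolerance
uses a batch-means standard error (25 batches of 2000 steps) rather than
the iid binomial one, because successive positions are strongly
autocorrelated.

## Tracking

Identity is by sector: the walled arena admits one animal per sector, so
no frame-to-frame assignment is needed and a trajectory is simply the best
blob per sector over time.

* **Background**: per-pixel temporal median of ≥25 frames sampled evenly
  across the recording (default 51). A fly occupying a pixel in under half
  the sampled frames leaves no trace.
* **Segmentation**: absolute difference from the background, thresholded,
  8-connectivity connected components within the sector regions, area
  bounds corresponding to a 1–4 mm body diameter, one intensity-weighted
  centroid per sector from the largest surviving component. Equal-area ties
  go to the component nearer the previous valid position, else the lowest
  label — a fixed, deterministic rule.
* **Threshold default**: 5× the robust noise SD (MAD) of the difference
  image, floored at 8/255 grayscale so the rule degenerates gracefully on
  noiseless input. The threshold is estimated once, on the first frame, and
  frozen for the run; all tracking is deterministic (bit-identical on
  re-run). Using the absolute difference makes the detector polarity-
  agnostic (dark-on-bright or the inverse).
* Frames with no surviving component are marked invalid; nothing is
  interpolated, ever. Missing data propagate as undefined values through
  every downstream metric.

## Quality control

Three steps, mirroring a human-in-the-loop workflow:

1. missing-detection rate per fly; flies with a rate **strictly above** 5%
   are excluded ("more than 5%": exactly 5.0% is retained). Because the
   ambiguity between per-fly and per-recording exclusion cannot be resolved
   from the wording, both are computed: the per-fly rule drives analytics,
   and an experiment-level roll-up (mean rate over flies) is reported
   alongside.
2. walking-trace plots with a temporal colour code, one panel per sector,
   broken at invalid frames — for visual inspection;
3. long frame-to-frame jumps (default > 10 mm/frame, about four times a
   fast walk at 1 Hz; "particularly long" is not a defined quantity, so the
   threshold is a config field). Jumps are *flagged, never deleted*: a long
   apparent move may be a false-positive detection, and the decision is
   left to the analyst.

## Behavioural metrics

All metrics operate on frame-pair displacements (the velocity proxy at
1 Hz) and respect undefined pairs.

* **Stationarity floor**: displacements below 2 px (0.1 mm at the default
  calibration) are camera noise; the pair is stationary. The floor is
  inclusive on the moving side (exactly 2 px counts as movement) — a fixed
  convention, required for reproducibility.
* **Activity** is not an externally defined quantity, so the package's
  canonical definition is the fraction of moving pairs among defined pairs
  per bin (a distance-per-bin variant is available from the displacement
  series directly). Default bins: 5 min for 1 h views, 30 min for 24 h
  views. Trailing partial bins are dropped in start alignment; in clock
  alignment bins are anchored to midnight so flies started at different
  times co-bin on the clock axis.
* **Stops** are maximal runs of stationary pairs, split at undefined pairs
  (a gap never bridges a stop), floored at 2 s to match the log2 duration
  axis whose first bin is 2–3 s ($2^k$ to $2^{k+1}-1$ s). A stop's location
  is its mean position, and ROI membership is decided once per event on
  that mean — a single testable rule rather than per-frame voting.
* **Displacement classes**: short walks are moves of 0.1–2 mm, long walks
  5–10 mm, both bounds inclusive. The 0.1 mm lower bound is the
  stationarity floor: sub-floor jitter belongs to neither class even when
  a coarse calibration lets it past the 2 px floor.
* **Occupancy**: fraction of valid frames per bin inside an ROI; physical
  and virtual patches use identical machinery.

Conservation holds by construction and is property-tested: per fly, moving
time + stopped time + undefined time equals the recording's pair time
exactly, and per bin the moving and stationary fractions of defined pairs
sum to one.

## Statistics

Each time bin is compared between groups with a two-sided Mann–Whitney
U test on per-fly values, U reported as $\min(U_A, U_B)$ with midrank
ties. The p value is exact — full enumeration of the
$\binom{n_A+n_B}{n_A}$ labelings — when $n_A + n_B \le 12$ with no ties,
else a normal approximation with tie and continuity corrections (the exact
and approximate paths agree with `stats::wilcox.test` and with a
permutation oracle in the test suite; degenerate all-tied input returns
p = 1). Bins where either group has no defined values are marked
untestable. Sidedness is fixed at two-sided, and per-bin p values are
**uncorrected** by default, reproducing the per-bin testing procedure this
assay family uses; `p_adjust = "BH"` is available because many bins are
tested, and the uncorrected default should be read with that caveat.

## Problem sizes used in the checks

The validation suites choose sizes that keep each property statistically
decidable: tracker recovery uses a 500-frame, 8-fly recording at 85 mm over
256 px; the occupancy null uses a 50,000-step walker; the type-I error
check uses 500 null replicates of a 12-bin comparison with 20 flies per
group per bin; parameter-recovery checks use single 20,000-step walkers.
The full-resolution (1700 px) geometry is exercised where the printed arena
constants themselves are under test.

## Known limitations

* One animal per sector is assumed, not checked; two animals in a sector
  will be tracked as one (the larger blob).
* JPEG input is not supported (PNG/TIFF only).
* Clock co-binning is exact only when start times lie on the bin grid;
  off-grid starts are snapped to the enclosing clock bin.
* The exclusion rule, jump threshold and stationarity floor are global, not
  per-fly adaptive.
* No feeding inference: a stop on the patch is not a sip.
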