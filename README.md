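# flyarena

Tracking and locomotion analytics for multi-sector single-fly arena assays.

The assay: a circular dish (85 mm) is split by walls into eight sectors of
5.5 cm² each, one fly per sector, optionally with a 0.2 cm² food patch per
sector, imaged from below against a bright IR-backlit field at 1 frame/s
for up to 24 h. From such an image sequence the package recovers one
trajectory per fly and computes the assay's behavioural read-outs, with a
ground-truthed synthetic generator standing in for recordings wherever the
pipeline needs to be tested.

**Pipeline** (each stage is a plain function; `run_pipeline()` chains them):

1. **geometry** — annular-wedge sector model solved from the configured
   areas, patch and virtual-patch ROIs, pixel↔mm calibration
   (2 px = 0.1 mm by default).
2. **tracking** — temporal-median background, thresholded difference,
   8-connected components per sector, one intensity-weighted centroid per
   sector per frame; identity is by sector (the walls guarantee it).
3. **qc** — missing-detection rate with the "more than 5 %" exclusion rule
   (5.0 % retained, 5.1 % excluded), colour-coded trace plots, flagging of
   long frame-to-frame jumps (default > 10 mm) for inspection — never
   deletion.
4. **metrics** — frame-pair displacement as a velocity proxy with a 2 px
   stationarity floor; activity per 5-min bin; maximal stop bouts on a log2
   duration axis (2–3 s, 4–7 s, 8–15 s, ...); displacement distributions
   with short (0.1–2 mm) and long (5–10 mm) walk classes; patch/virtual
   patch occupancy; start- or clock-aligned binning.
5. **stats** — per-bin two-sided Mann–Whitney U tests between the
   pre-fed and pre-starved groups: U = min(U_A, U_B) with midrank ties,
   exact p by enumeration for n_A + n_B ≤ 12 without ties, otherwise
   normal approximation with tie and continuity corrections.

## Worked example

Simulate a two-group experiment (4 pre-fed + 4 pre-starved flies in
alternating sectors, 300 frames at 1 Hz, 85 mm dish imaged over 256 px),
render it to PNG frames, then run the full pipeline on those images:

```r
library(flyarena)

geom <- build_default_geometry(list(pixel_scale = 85/256))
exp_dir <- file.path(tempdir(), "demo")
generate_experiment(n_flies_per_group = 4, n_frames = 300, seed = 42,
                    geom = geom, out_dir = exp_dir, render = TRUE)

res <- run_pipeline(list(frames = file.path(exp_dir, "frames"),
                         geometry = file.path(exp_dir, "geometry.yaml"),
                         metadata = file.path(exp_dir, "metadata.csv"),
                         out_dir = file.path(exp_dir, "output"),
                         bin_width_s = 60, occupancy_bin_s = 60))

res$qc[, c("fly_id", "group", "missing_rate", "excluded", "n_jumps")]
#>   fly_id       group missing_rate excluded n_jumps
#> 1  fly00     pre-fed            0    FALSE       0
#> 2  fly01 pre-starved            0    FALSE       0
#> 3  fly02     pre-fed            0    FALSE       2
#> 4  fly03 pre-starved            0    FALSE       0
#> ...
```

All eight flies were detected in every frame (`missing_rate 0`, nobody
excluded); a few genuine fast runs of the pre-fed walkers exceed the 10 mm
jump threshold and are flagged for inspection, not removed.

```r
head(aggregate_bins(res$activity), 4)
#>     group bin_start      mean        sem n
#> 1 pre-fed         0 0.6416667 0.02590939 4
#> 2 pre-fed        60 0.7250000 0.04330127 4
#> 3 pre-fed       120 0.5583333 0.05114431 4
#> 4 pre-fed       180 0.6458333 0.03871489 4

res$comparisons$activity[, c("bin_start", "U", "p", "significant")]
#>   bin_start U          p significant
#> 1         0 0 0.02857143        TRUE
#> 2        60 0 0.02746864        TRUE
#> 3       120 0 0.02940105        TRUE
#> 4       180 0 0.02857143        TRUE

round(tapply(res$classes$short, res$classes$group, mean), 3)
#>     pre-fed pre-starved
#>       0.130       0.886
```

Pre-fed flies move in ~64 % of frame pairs (mean ± SEM over 4 flies per
1-min bin); every bin separates the groups (U = 0 means complete
separation of the per-fly activity values; p ≈ 0.029 is the smallest
two-sided value attainable at n = 4 + 4). Pre-starved walkers make short
(≤2 mm) moves with probability 0.89 versus 0.13 for pre-fed — the
direction the presets encode. `res$occupancy`, `res$stops` and the files
under `out_dir` (trajectory CSV, QC report, analytics and comparison
tables, figures, JSON run log of all thresholds) carry the rest.

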