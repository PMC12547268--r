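# flockmotion

Flock-level spatial-behavior analysis for laying hens housed in multi-tier
aviary systems.

Commercial aviaries house hundreds of hens per pen across three tiers and a
littered floor. Where the flock is — how often birds jump between tiers, how
many forage on the litter — is a continuous, non-invasive readout of its
state: vertical movement collapses when a predator silhouette passes
overhead, spikes under a sudden thunder clap, and litter occupancy drains
when feed is withheld. `flockmotion` implements the full analysis chain that
turns side-view and top-view camera footage into those statistics and tests
them against stress events:

1. **Vertical movement counting** (`count_movements`): greyscale frames at
   4 frames/s are Gaussian-blurred, consecutive frames differenced, motion
   blobs extracted as 8-connected components, linked into centroid tracks by
   greedy nearest-neighbour association, and every track transition between
   the 4 annotated horizontal zones (3 tiers + litter) is counted as one
   directed crossing. Hens walking the stairs between the lowest tier and the
   litter fall in an exclusion polygon and are never counted.
2. **Litter occupancy** (`count_litter`, `zone_counts`, `litter_density`):
   per-frame hen detections — either ingested from an external detector CSV
   or produced by a built-in background-subtraction reference detector — are
   assigned by bounding-box center to the system-side or wall-side litter
   zone and expressed as hens/m² over the 4 m² viewed area, with occupancy
   heatmaps.
3. **Software evaluation** (`match_events`, `count_confusion`,
   `precision_recall_f1`): confusion-matrix evaluation against reference
   observations,
   `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
   `F1 = 2PR/(P+R)`.
4. **Weekly consistency** (`weekly_descriptives`, `friedman_block_test`,
   `posthoc_pairs`): per-minute counts are mapped to named activity
   categories of the observation day (feeding, feeding sound, resting,
   predator cue, thunder, frustration stages), summarised per week, and
   described by median, Q1–Q3, IQR and the quartile coefficient of
   dispersion `QCD = 100·(Q3−Q1)/(Q3+Q1)`; differences between activities
   are tested with a week-blocked Friedman test (χ², Kendall's W) and exact
   all-pairs post hoc comparisons under Benjamini–Hochberg FDR control.
5. **Stress-phase model** (`select_windows`, `fit_nb_glmm`, `phase_report`):
   per-minute counts in before/during/after windows around a stressor onset
   are modelled as `y ~ NB2(μ, k)` with `log μ = β₀ + β_phase + b_week`,
   `b_week ~ N(0, σ²_w)` — a negative-binomial mixed model with week as
   random intercept, fitted by Laplace-approximated ML. Response-scale phase
   means, delta-method SEs and Wald contrasts against the pre-stress phase
   are reported.
6. **Synthetic flock generator** (`simulate_crossing_schedule`,
   `render_video`, `simulate_litter_scene`, `simulate_count_series`):
   seeded scenes of hen-like agents with Poisson-scheduled zone jumps,
   rendered to greyscale frames with known ground truth, and NB2 count
   series with phase-specific means and a log-normal week effect — so every
   stage above is verifiable without farm data.

A configuration-driven pipeline (`run_pipeline`, CLI script under
`inst/cli/`) chains simulate → count → evaluate → describe → friedman →
stress-fit with seeded reproducibility and per-stage manifests.

## Worked example

Simulate a noiseless aviary scene (8 agents, 60 s, 4 fps, adjacent-zone
jumps at 1/min per directed pair), count movements, and evaluate against the
ground truth:

```r
library(flockmotion)

zm <- read_zone_annotation(system.file("extdata",
        "aviary_zones_synthetic.json", package = "flockmotion"))
rates <- do.call(rbind, lapply(1:3, function(i)
  data.frame(from = c(i, i + 1L), to = c(i + 1L, i), rate = 1)))
sc <- video_scenario(zonemap = zm, n_agents = 8, duration = 60,
                     crossing_rates = rates, agent_spacing = 72, seed = 1)
truth  <- simulate_crossing_schedule(sc)
frames <- render_video(sc, truth)
res <- count_movements(frames, zm, list(max_link_distance = 70))
res$events
#>   time_s from_zone to_zone direction track_id
#> 1   4.00         3       2        up        1
#> 2  12.25         2       3      down        2
#> 3  34.50         2       1        up        3
#> 4  38.00         3       2        up        4
#> 5  40.00         3       2        up        5
#> 6  54.25         2       3      down        6

ref <- transform(truth$events,
                 direction = ifelse(to_zone < from_zone, "up", "down"))
match_events(res$events, ref)
#> TP=6 FP=0 FN=0  precision=1.00 recall=1.00 F1=1.00
```

All six scheduled crossings are recovered with their directions (`up` =
toward the top tier) within 0.5 s — on noiseless, well-separated synthetic
agents the counter is exact, which is the package's end-to-end acceptance
property.

Fit the stress model to a count series simulated at the reference
predator-response means (15.6 → 7.5 → 11.4 movements/min, week SD 0.23 on
the log scale, NB2 dispersion 10, 4 groups × 10 weeks):

```r
p <- count_sim_params(c(before = 15.6, during = 7.5, after = 11.4),
                      c(before = 5, during = 6, after = 5),
                      week_sd = 0.23, nb_dispersion = 10, seed = 1)
fit <- fit_nb_glmm(simulate_count_series(p))
fit
#> NB2 GLMM, week random intercept sd = 0.170 (k = 9.56, logLik = -1901.8)
#>    phase duration_min      mean        SE  p_vs_before  raw_mean
#> 1 before           NA 15.522166 0.9495530           NA 15.710000
#> 2 during           NA  7.597421 0.4733032 1.388426e-62  7.695833
#> 3  after           NA 11.825274 0.7330546 1.303219e-10 12.090000
```

The during-phase response-scale mean (7.60) recovers the generating value
7.5 within the week-level sampling noise of one 10-week realisation; the
before−during contrast (−7.9 movements/min) reproduces the reference
−8 movements/min predator effect.

## Pipeline

```sh
Rscript inst/cli/flockmotion.R all --out out/ --seed 1
```

writes frames (plain-text PGM + manifest), ground-truth CSVs, per-minute
count tables, the evaluation report, descriptive statistics, the Friedman
report and the stress-model fit, each stage with a manifest recording seed,
config hash and package version. Rerunning with the same seed and config is
byte-identical. See `vignettes/flockmotion-methods.Rmd` for the modelling
choices and their rationale.
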