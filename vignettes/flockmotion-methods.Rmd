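---
title: "Models and methods behind flockmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flockmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockmotion)
```

`flockmotion` analyses flock-level spatial behavior of laying hens in
multi-tier aviaries: directed vertical movements between the three tiers and
the litter, counted from side-view video by frame differencing, and litter
occupancy counted from top-view detections, followed by weekly-consistency
descriptives, week-blocked Friedman tests and a negative-binomial mixed
model of stress-phase effects. This vignette documents the models, the
tunable parameters, the synthetic-data generator that stands in for farm
video, and the design decisions taken where the problem left the design
open.

## 1. Zone geometry

A camera view is described by a `zone_map`: ordered simple polygons in pixel
coordinates (origin top-left, x rightward, y downward). Zones are indexed 1
(upmost tier) to K top-to-bottom — K = 4 for the aviary side view, K = 2
(system side, wall side) for the litter top view. The top-to-bottom indexing
direction is a package convention (the numbering direction is not dictated
by the underlying protocol); labels are free text so users may relabel.

Three deliberate geometry rules:

* **Exclusions override zones.** Polygons labelled `exclude:` (the stairs
  between the lowest tier and the litter) absorb any point they contain, so
  hens walking the stairs are never assigned a zone and never produce a
  crossing.
* **Boundary tie-break.** A point exactly on a boundary shared by two zones
  belongs to the lower zone index. This is arbitrary but deterministic and
  documented; it matters only for measure-zero inputs.
* **Interior disjointness** is validated as: no proper edge crossing between
  two zone polygons, and no vertex, edge midpoint or centroid of one
  strictly inside the other. For simple polygons that share at most boundary
  segments (the annotation style in practice) this is exact; the edge
  midpoints catch stacked rectangles whose edge intersections are all
  collinear.

Point-in-polygon uses the even-odd crossing rule with an explicit boundary
test; the test suite checks it against an independent winding-number oracle
on random convex polygons and random points.

## 2. Vertical-movement counting

The pipeline is blur → difference → blobs → tracks → crossings → per-minute
counts. Processing runs at 4 frames/s (higher-rate input is subsampled).
Parameters, with defaults and reasons:

| key | default | meaning |
|---|---|---|
| `blur_kernel` | 5 (5×5 Gaussian) | denoising before differencing; sigma defaults to the usual size-derived value |
| `diff_threshold` | 25 grey levels | motion if the signed frame difference exceeds this |
| `min_area` | π·(radius/2)² ≈ 79 px² at radius 10 | discard sub-hen-size blobs |
| `max_link_distance` | 70 px | maximum centroid displacement for track linking |
| `max_gap` | 2 frames | unmatched frames before a track closes |
| `polarity` | `"bright"` | whether hens are brighter or darker than background |

None of these four vision parameters are fixed by the underlying protocol;
the defaults follow standard motion-detection practice and are all config
keys.

**Why appearance blobs.** Differencing two frames of a moving body yields a
*double image*: one blob where the body was (grey level falls back to
background) and one where it now is. With centroid tracks and greedy
nearest-neighbour linking, the departure ghost sits at distance ≈ 0 from the
track's last observation and always wins the link, so the track never
observes a zone change. The counting pipeline therefore splits the signed
difference and tracks only **appearance** blobs (`cur − prev > threshold`
for bright-on-dark hens), which isolates the body's current position. The
plain absolute-difference mask (`|cur − prev| > threshold`) remains the
default mode of `frame_difference()` and is tested against a per-pixel
loop oracle; the appearance mode is the same comparison without the absolute
value.

**Crossings from tracks.** A crossing is one consecutive observation pair in
a track whose zones differ and are both non-missing; the event takes the
later frame's time, and direction is `up` iff the target index is smaller.
A missing zone (exclusion region) breaks the pair, so movement across the
stairs produces no event. Non-adjacent zone changes count as a single
crossing with the observed endpoints. Association is greedy in ascending
distance order with deterministic tie-breaks (lower track id, then blob
order) — a contract, not a tracker mandate; it is checked against an
exhaustive minimum-total-distance assignment on small cases.

## 3. Litter occupancy

A trained neural hen detector is deliberately out of scope (its weights are
not desk-reproducible content). The module instead offers (a) ingestion of
any external detector's boxes from CSV and (b) a background-subtraction
reference detector (`|frame − background|` thresholded, components within an
area band) that is exact on synthetic scenes. Zone membership is by box
*center* — simple, deterministic, and adequate at hen-count granularity;
centers outside both zones are dropped and counted. Density is
count / litter area with the viewed litter area defaulting to 4 m².
Per-frame counts are averaged per second (or per minute) unrounded; whether
real deployments smooth before plotting is a presentation choice, not part
of the counting contract.

## 4. Software evaluation

Event-level evaluation matches predicted to reference crossings greedily in
time order, one-to-one, requiring direction agreement and |Δt| ≤ 0.5 s (2
frames at 4 fps; the tolerance is a package decision, as the underlying
evaluation was done by human review without a stated tolerance). For 1-D
tolerance windows this greedy matching attains the maximum matching, which
the tests verify by exhaustive enumeration on lists of ≤ 6 events.
Count-level evaluation of the litter counter uses, per observation,
TP = min(n, m), FP = (n − m)₊, FN = (m − n)₊, accumulated by summation —
i.e. a surplus of detected hens is false positives, a deficit false
negatives. Precision, recall and F1 follow the usual definitions; undefined
metrics (zero denominators) are reported as `NA` with a warning, never as 0.

## 5. Weekly consistency

Per-minute counts are mapped to the named activity categories of each
observation day (the default schedules place the predator cue at
15:30–15:36, the thunder response minute at 15:30, and the four 15-min
frustration stages from 10:00; anchors and durations are config). A minute
starting exactly at a boundary belongs to the category that starts there.

Aggregation order is **groups first, then weeks**: minute values are
averaged across experimental groups, each week × activity cell is the mean
of its per-minute values (the inner statistic is switchable to median), and
the across-week summary reports median, Q1, Q3 (linear-interpolation
quantiles, type 7 — the convention matters because QCD table checks are
sensitive to it), IQR = Q3 − Q1, QCD = 100·(Q3 − Q1)/(Q3 + Q1), and the
weekly min/max. QCD is scale-free and undefined when Q1 + Q3 = 0 (flagged,
not zeroed).

The week-blocked Friedman test uses within-block mid-ranks with the standard
tie correction,
χ²_F = (k−1)·Σ(R_j − n(k+1)/2)² / (Σr² − nk(k+1)²/4), df = k−1, and
Kendall's W = χ²_F / (n(k−1)). The default p-value is asymptotic
(chi-squared); `p_method = "exact"` enumerates all (k!)ⁿ within-block
orderings for small designs, which the tests compare against an independent
enumeration built on `stats::friedman.test`. Post hoc, every treatment pair
gets a within-block rank-difference statistic whose exact null comes from
2ⁿ sign flips (swapping a pair's values within a block negates that block's
rank difference) — full enumeration up to 10 blocks, seeded Monte-Carlo
beyond — with Benjamini–Hochberg adjustment across pairs. The "exact
all-pairs" method is named but not specified in the source protocol, so the
null construction here is explicit and testable.

## 6. Stress-phase model

Counts per minute in the before/during/after windows are modelled as NB2
with log link:

y_gwm ~ NB2(μ, k), log μ = β₀ + β_phase + b_w, b_w ~ N(0, σ²_w),

with `before` as reference level, experimental groups entering as replicate
observations (no group random effect), and week as random intercept. NB2
means variance μ + μ²/k; the parameterisation is chosen to match the common
mixed-model default since the family is named but not parameterised in the
source. The mixed model is fitted by Laplace-approximated ML via
`lme4::glmer.nb` (the estimator contract is defined by the oracle and
recovery tests, so any established mixed-model machinery satisfying them is
conformant; a TMB-based fitter would be an equally valid backend but is not
available in this environment). The `week_effect = FALSE` route is an in-package direct ML fit
(IRLS for the coefficients nested in a profile search over log k), kept
independent so it can be checked against `MASS::glm.nb` as an oracle — the
tests require agreement to 1e-4 relative.

Phase windows: visual — during = 6 min from a 15:30 onset; auditory —
during = the single thunder-response minute; frustrative — during = the
first or last 5 min (short horizon) or 30 min (long) of the 60-min feed
delay; flanking windows 5 min (short) or 25/30 min (long). Reports carry
response-scale phase means exp(β₀ + β_phase), delta-method SEs, Wald
p-values for during/after vs before, raw observed means alongside
(whether the reference tables print raw or model-based means is ambiguous, so
both are emitted), and the week effect as mean ± SD of the predicted week
intercepts with the raw σ_w also available.

**Interval calibration.** With only 10 week clusters, plain 1.96-normal
intervals for the response-scale phase means undercover: measured over 100
seeded replicates of the stated design, coverage is ≈ 86–89% for phase
means while the contrasts cover 95–98%. `phase_confint()` therefore uses a
t quantile with n_weeks − 1 degrees of freedom for the mixed fit — the
standard small-cluster correction — which restores nominal coverage; SEs
themselves are unchanged.

## 7. The synthetic world

The generator emulates exactly the statistical structure the analysis
assumes, with defaults stating realistic recording conditions:

* **Aviary scene**: 640×480 px, 4 stacked 120-px zones, a stairs exclusion
  rectangle, 4 frames/s, hen-like agents as filled ellipses (horizontal
  radius 10 px) on a uniform background with optional Gaussian pixel noise.
  Zone jumps are independent homogeneous Poisson processes per directed
  zone pair; agents are assigned so no agent has two events closer than 2
  frames, and infeasible demand (an event from an empty zone) is an error
  advising more agents rather than a silently altered schedule.
* **Crossing kinematics**: an event moves the agent over exactly two
  consecutive frame steps — home → a point 0.45 of the way along the path
  (still inside the source zone) → the target home. This yields exactly two
  differing consecutive frame pairs per crossing and makes the event
  recoverable by appearance-blob tracking: the two blobs observe the source
  zone then the target zone, 0.45 and 0.55 of the zone pitch apart (54/66
  px ≤ the 70 px link distance). Agents occupy distinct 72-px-spaced
  columns, so blobs of different agents are always farther apart than the
  link distance and cross-linking is geometrically impossible.
* **Litter scene**: static agents placed uniformly in the requested zone
  with a minimum-distance overlap constraint and an areal capacity bound;
  truth counts are constant per frame.
* **Count series**: y ~ NB2(phase_mean · exp(b_w), k) per group × phase ×
  minute with b_w ~ N(0, σ_w²) — the log-normal week effect is multiplicative
  by construction, matching the model being fitted. Generating values for
  the recovery experiments are the reference short-term predator-response
  estimates (15.6/7.5/11.4 movements/min with week SD 0.23; 27.6/13.0/17.7
  hens per 4 m² with week SD 0.42); the NB2 dispersion is not reported
  anywhere, so k = 10 was chosen once as realistic overdispersion for these
  counts (variance ≈ 2.5× the mean at μ = 15) and is not tuned.

What the generator does **not** emulate — and hence what a green test does
not establish: photorealistic plumage and lighting, occlusion beyond the
placement overlap limit, real detector noise, camera distortion, or hens
dwelling on the stairs. End-to-end perfection (precision = recall = 1) is
asserted only for noiseless, well-separated scenes; the reference
farm-video scores (precision 0.95/recall 0.84 for movement; 0.99/0.90 for
litter) are reproduced arithmetically as F1 checks, not re-derived from
synthetic video.

## 8. Numerical choices and degenerate inputs

* Frames are plain-text PGM (P2) plus a JSON manifest — portable and
  diff-able; no binary image dependency.
* Blur uses replicate border padding; the blur is checked against a direct
  convolution oracle, and differencing/labelling against per-pixel loop and
  flood-fill oracles.
* `frame_difference` uses a strict inequality, so raising the threshold is
  monotonically non-increasing in motion pixels (a tested invariant).
* Empty inputs: empty masks give zero blobs; empty event lists aggregate to
  zero-filled minutes; an all-tied Friedman matrix gives χ² = 0, W = 0;
  all-zero confusion counts give `NA` metrics with a warning.
* Config files are JSON (no YAML parser is available in the target
  environment); the section structure mirrors the documented config keys.
* Pipeline determinism: every stochastic stage takes its seed from the
  config/CLI seed, and rerunning a stage with identical config and seed is
  byte-identical on all CSV outputs (tested).

## 9. Known limitations

* The track-based reading of "count movements from pixel differences" is
  one faithful realisation of an underspecified mechanism; alternative
  realisations (e.g. zone-boundary motion counting without tracking) could
  count differently on real, crowded footage.
* Greedy association can in principle mis-link agents that move
  simultaneously within the link distance; the synthetic world spaces
  agents beyond it, and real deployments should set `max_link_distance`
  below the typical inter-hen spacing.
* The Poisson zone-jump schedule can demand a crossing from a momentarily
  empty zone; the generator then stops with advice rather than bending the
  requested rates.
* Parameter-recovery experiments average over seeded replicates to separate
  estimator bias from the ±9–13% week-level sampling noise a single
  10-week realisation carries by design.
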