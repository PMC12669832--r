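---
title: "Quantifying larval local search: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval local search: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvasearch)
```

## The problem

A *Drosophila* larva that has briefly contacted a food stimulus keeps
searching around the stimulus location after the stimulus is removed. The
raw observable is a per-frame centroid track (2 frames/s) in a circular
arena of 30 mm radius, exported by a tracker as pixel coordinates with
frequent detection failures. `larvasearch` turns such tracks into per-phase
behavioral metrics and hypothesis tests. This vignette explains each stage's
model, its tunable parameters, and the design decisions taken where the
procedure was genuinely open.

## Track repair

Trackers lose larvae to reflections, wall occlusion and container blind
spots; in real recordings the missing-frame fraction averages around a
quarter of all frames. Every maximal run of missing frames is classified,
in priority order:

1. **end-hold** — no detection after the gap: the last coordinate is
   repeated (the animal is assumed stationary or hidden until the recording
   ends). This must rank first since a terminal gap has no closing flank.
2. **container contact** — both flanks within the container-proximity
   radius (default: the 8 mm center-zone radius) while the container is
   present: the larva is hidden at the container; its position is held at
   the disappearance point.
3. **arc** — both flanks beyond 21.3 mm from the center: a wall-following
   larva; the gap is filled along the *minor* circular arc about the arena
   center with the radius blended linearly between the flank radii.
4. **edge-assigned** — flanking frames carry the wall-verification flag but
   lie below the radial threshold: only edge-zone membership is known. These
   frames get the edge-zone midpoint radius (27 mm) and no x/y position;
   they contribute dwell time to the edge zone and nothing to track length.
5. **linear** — everything else: evenly spaced points on the straight
   segment.

Design notes. The minor arc is the minimal-length completion consistent
with wall-following; antipodal flanks (undefined direction) fall back to a
straight line with a warning. The radius blend matters little because wall
flanks have nearly equal radii. The 21.3 mm arc threshold is applied to
*both* flanks — a gap that starts at the wall and ends in the open field is
a straight line. Pixel coordinates are converted at 0.2673 mm/px and
re-centered on the configured arena center, so the distance to center is
`sqrt(x² + y²)`.

## Phase segmentation

The event log (container placed, first verified head contact, container
removed) cuts the recording into half-open windows: baseline
`[0, t_placed)`, pre-search `[t_placed, t_contact)`, investigation
`[t_contact, t_removed)` and the analyzed search window
`[t_removed, t_removed + 300 s)`. Only the first 5 min after removal are
analyzed, making the search window commensurate with the 5 min baseline.
Container-free control recordings are segmented with artificial event times
at the same offsets. Larvae that never contact the container, whose contact
fails frame-by-frame review, or that approach via the arena lid are
excluded with a reason code.

## Metrics

* **Distance categories and zones.** Seven half-open categories
  `[0,4), …, [20,24), ≥24` mm; zones are their pairwise unions. Half-open
  binning guarantees a partition (a larva at exactly 8 mm is in the search
  zone). Dwell is attributed per frame — each frame adds `1/frame_rate`
  seconds to its own category, without splitting steps at boundary
  crossings; at 2 frames/s the attribution error per transition is at most
  half a second.
* **Track length.** Cumulative Euclidean step length; each step attributed
  to the category of its starting frame; steps touching position-less
  (edge-assigned) frames contribute nothing.
* **Speed.** Instantaneous speed is step length × frame rate; the plotted
  trace is a 10-frame moving average; the scalar summary is the median,
  which is robust to the interpolation-flattened segments.
* **Revisits.** Inward crossings of the 8 mm center-zone border. The
  radius itself counts as inside, so a landing exactly on the border is an
  entry; one convention applied everywhere. The 8 mm radius is not free: it
  is container radius (0.35 cm) + median larval length (0.35 cm) + 0.10 cm
  slack (`center_zone_radius_cm()`).
* **Stops.** A stop starts at the first step below 0.05 mm; it ends only
  after five consecutive steps at or above threshold ("moved continuously"
  is read strictly as *every* one of the next five steps); stops separated
  by five or fewer moving frames merge. The two rules collapse into one
  grouping — sub-threshold runs separated by more than five moving steps
  are distinct stops — which the implementation exploits; the test suite
  checks it against an independent explicit state machine on random
  sequences.
* **Search score.** `(t_search − t_edge)/t_total ∈ [−1, 1]`; positive =
  search-zone preference, negative = edge preference. The score follows the
  familiar two-zone preference-index construction used across larval
  chemosensory and learning assays, which keeps it comparable between
  paradigms.

## Statistics

Only nonparametric tests, mirroring conservative practice for small
behavioral cohorts: paired Wilcoxon signed-rank (baseline vs search),
one-sample Wilcoxon (score vs 0), Mann–Whitney U (two conditions),
Kruskal–Wallis with tie correction (three or more) with post hoc pairwise
rank tests run only when the global p ≤ 0.05. Implementation rides on R's
`wilcox.test`/`kruskal.test` (exact null distributions for small tie-free
samples, tie-corrected normal approximation otherwise — the paired test is
exact up to n = 25); the test suite verifies the exact p-values against
full enumerations of sign patterns and rank assignments for n ≤ 8. Zero
differences are dropped (Wilcoxon's convention) and their count logged,
since the source procedure does not state a rule. Stars: `*` P ≤ 0.05,
`**` P ≤ 0.01, `***` P < 0.001. The post hoc family-wise correction
defaults to Holm and is switchable; no particular multi-comparison method
was mandated by the original MATLAB tooling.

## The synthetic-data generator

The simulator exists so that every pipeline stage and statistical claim is
testable end to end without recordings. Agents do run-and-turn locomotion:
per frame the heading gets wrapped-normal noise (sd
`1/sqrt(heading_persistence)`) plus a steering pull toward a target ring —
near the wall (28 mm) in baseline mode, at 12 mm (the middle of the search
zone) in search mode. The steering gain tapers linearly within 4 mm of the
target ring, so agents orbit the ring rather than pinning to it; with the
gain at 1 and no noise the orbit radius converges to the ring radius, which
the tests exploit as a deterministic limit. The wall reflects: a step
crossing the 30 mm radius is folded back and the heading mirrored about
the wall tangent.

Defaults are the study conditions: 2 frames/s; 5 min baseline; pre-search
of 436 s (the mean time to find a fermented-yeast container, 7:16 min);
1 min investigation; 300 s analyzed search; median crawl speeds 0.64 mm/s
(baseline) and 0.92 mm/s (search), matching the reported phase medians;
stop rate 1.5/min with mean duration 6 frames (a realistic handful of
pauses per phase); detection dropout 26% of frames in geometric runs of
mean 4 frames, with the start probability renewal-corrected so the realized
missing fraction matches the nominal rate. Cohort members get child seeds
`(seed + i·99991) mod (2³¹−1)`, so any larva is re-simulable in isolation.

What the generator does **not** emulate: posture and head casts, odor
gradients, burrowing, lid climbing, inter-individual variability beyond
seed noise, and systematic tracker biases other than frame loss. Passing
tests therefore validate the *pipeline arithmetic and test calibration*,
not any biological claim about real larvae.

One consequence worth stating plainly: in a fixed-baseline (control)
cohort the baseline window still contains the initial center-to-wall
transit (larvae are placed at the center), while the analyzed search
window does not, so baseline scores sit near −0.8 and search-window scores
at −1. With the generator's small inter-individual spread this systematic
offset is detectable by the paired test — unlike in real control cohorts,
where individual variability swamps it. Null calibration of the testing
layer is therefore done at the test level: 10,000 replicates of n = 15
exchangeable score pairs, where the exact signed-rank test rejects at just
under the nominal 5% (the attainable exact level at n = 15).

## Problem sizes and numerical choices

The validation suite runs cohorts of 15 larvae (the scale of the real
experiments, n = 12–20); power of the search-score contrast is estimated
over 200 replicate switching cohorts, null calibration over 10,000
test-level replicates, stop-counting equivalence over 1,000 random
600-step sequences, and conservation/bounds over 10,000 random windows.
Tolerances: geometry checks at 1e-9 mm; zone-time conservation at one
frame period; exact-test oracle agreement at 1e-12. Times-to-contact are
formatted min:s rounded to the nearest second and compared with ±1 s,
because the per-larva inputs are themselves printed rounded.

## Known limitations

* Dwell attribution is per frame, not sub-frame; at higher frame rates the
  distinction vanishes, at 2 frames/s it bounds the zone-time error by one
  frame period per boundary crossing.
* Speed from step lengths differs from tracker-internal speed estimates by
  whatever smoothing the tracker applies; the median summary limits the
  impact.
* Arc interpolation assumes wall-following during the gap; a larva that
  detached from the wall and returned within the gap is reconstructed too
  close to the wall.
* The simulator's stop episodes use a jittered sub-threshold displacement,
  not a biomechanical pause model; stop *counting* is exercised fully, stop
  *duration* distributions are nominal.
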