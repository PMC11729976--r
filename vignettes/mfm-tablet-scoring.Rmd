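---
title: "Scoring tablet traces of the MFM distal items: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tablet traces of the MFM distal items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfmtrace)
```

## The problem

Three items of the Motor Function Measure (MFM), a 0–3 ordinal scale for
neuromuscular disease, are performed on a flat support with the hand:
circumnavigating a CD with one finger (item 18), drawing loops inside a
1 × 4 cm frame with a pencil or stylus (item 19), and lift-and-place of a
finger on the 8 drawings of a diagram (item 22). On a tablet, each attempt
is a timestamped multi-pointer trace. Two analyses follow from that:

1. **Mode agreement** — whether tablet completion preserves the score a
   therapist would give on paper, quantified by weighted Cohen's kappa,
   percent agreement and agreement charts over paired 4 × 4 tables.
2. **Automatic scoring** — mapping the raw trace to the 0–3 score directly,
   with auditable geometric evidence.

This vignette documents the models behind both, the parameters that matter,
what the synthetic generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The trace model

A recording is an ordered table of touch samples
(`time_ms`, `pointer_id`, `phase` ∈ {down, move, up}, `x`, `y`) with a
device calibration and the support layout. Invariants are enforced at
construction: per-pointer time ordering and a `down → move* → up` life
cycle. Two deliberate relaxations reflect real logs: a pointer still down
when the log ends is closed and flagged rather than rejected (logs
truncate), and duplicate timestamps within a stroke are collapsed to the
last sample (devices emit bursts).

Raw coordinates are pixels with y growing downward; all scoring happens in
a y-up centimetre frame shared with the layout, via the calibration's
`px_per_cm`. The density default (103.9 px/cm) corresponds to the 264
ppi-class 9.7-inch panel of the reference tablet, but is never inferred
silently: scoring thresholds are physical lengths, so calibration must be
explicit and overridable. A quality-control pass warns (without failing)
when the support is placed within 0.5 cm of the screen border — a placement
that provoked pixel recording failures in field use — and on sampling gaps,
open pointers and empty recordings. The recording software's sampling rate
is not published; the gap threshold (500 ms) is a screening parameter, not
a claim about the hardware.

Resets during an attempt are represented as separate recordings and only
the last recording of an attempt is scored; how resets should enter scoring
is otherwise unspecified, and this convention keeps the scored unit
well-defined.

## Geometry: from rubric wording to measurable quantities

Each rubric clause maps to one primitive:

* *"goes round the edge of the CD"* → unwrapped angular sweep about the CD
  centre. Steps take the minimal rotation in (−180°, 180°]; an exact 180°
  step is ambiguous and resolved as +180° for determinism. The net sweep of
  a full circumnavigation is ±360°.
* *"may stop one or more times" / "without stopping"* → pause detection:
  maximal runs of finite-difference speed below `v_pause` lasting at least
  `pause_min`. Defaults 0.5 cm/s and 400 ms: slow enough not to flag
  cautious steady drawing (typical drawing speeds here are several cm/s),
  long enough to ignore single-sample hesitations.
* *"without touching the lines" / "inside the frame"* → contact
  classification against drawn regions. The supports are drawn with lines
  of width 0.1 cm; a point within `line_w/2 + τ_line` of the nominal
  boundary is in the *boundary band*, strictly inside is *interior*,
  otherwise *outside*. τ_line = 0.05 cm covers fingertip-scale placement
  noise without swallowing the target interiors.
* *"over the full length of the frame"* → union length of the x-projections
  of consecutive segments, as a fraction of the frame width.

## The decision trees

All thresholds live in `scoring_params()` and are recorded with every
score. Comparisons are inclusive as written: a sample exactly at
`r_large − ε_in` does **not** count as entering the disc.

**Item 18.** Score 3 requires a *single* stroke of one pointer with
|net sweep| ≥ θ (355°), minimum radius ≥ `r_large − ε_in`, maximum radius ≤
`r_large + band_out`, and no pauses. θ is set just below 360° so that
endpoint clipping of an honest full turn is not punished. The CD's outer
radius is not printed anywhere in the item description; `r_large` defaults
to 6 cm (a standard 12 cm disc) and is configurable. Failing score 3 while
the pooled strokes still accumulate a full net sweep inside the wide
annulus `[r_small + band_small, r_large + band_out]` gives score 2 — this
annulus accepts traces that wander between the small circle's surround and
1.5 cm beyond the edge, which is what stopped, fragmented, finger-changed
or disc-entering circumnavigations look like. A full sweep with median
radius ≤ `r_small + band_small` is the small-circle circumnavigation,
score 1. A finger change is observable only as a pointer-id change; true
motor compensations (trunk, whole-limb) are invisible in the trace, which
is a known source of disagreement with therapist scores and out of scope by
design.

**Item 19.** "Ink" is total path length; below `min_ink` (0.2 cm) nothing
was written — pencil grasp itself is unobservable on a tablet, so the
rubric's "cannot pick up the pencil" collapses to "no ink". A *loop* is a
completed alternation pair between the top and bottom contact bands (within
`τ_touch` = 0.1 cm of the interior edges): visits T→B→T or B→T→B count one
loop, so a train of n full sinusoid periods counts 2n − 1 loops. The rubric
says "a continuous series of loops" without a count; `min_loops_full = 3`
defines the series and is deliberately prominent and configurable. Score 3
additionally demands one stroke (continuity), ≥ 90 % frame-width coverage,
no pauses, and no sample beyond τ_line outside the frame.

**Item 22.** Strokes are *taps* when both duration ≤ 600 ms and path ≤
0.5 cm, otherwise *slides*; a lift is deemed to have occurred when there
are at least two strokes. A tap hits a target precisely when every sample
is interior; touching the boundary band makes the hit imprecise. Slides
cover a target when any sample is interior. The tree then follows the
rubric: 3 = lift plus all 8 targets precise; 2 = lift plus any tap hit;
1 = no tap hit but a slide covers a target; 0 otherwise. The 8 drawings are
pictograms in the original diagram; the default layout stands in with
discs of radius 0.8 cm on a 4.5 cm ring (disjointness is validated), and
arbitrary target regions can be supplied. A first contact outside the
start zone warns rather than changes the score.

These trees are a faithful implementation of the published rubric wording
with declared parameters; they are not presented as bit-identical to the
original recording software's internal operators, which are not published
in enough detail to replicate.

## Agreement statistics

Scores are ordinal, so agreement uses the quadratic (Fleiss–Cohen)
weighted kappa, `w_ij = 1 − (i−j)²/9` for k = 4. The variance estimator is
the large-sample Fleiss–Cohen–Everitt form around the observed kappa; the
validation study does not name its estimator, and this choice reproduces
all three of its printed 95 % intervals to within ±0.01 per bound. The
interval is truncated to [−1, 1]. Kappa is undefined when the expected
weighted agreement is 1 (all mass in one cell); that is surfaced as an
error, never as a number. Missing pairs are dropped pairwise with a logged
count, matching the varying per-item denominators of such studies.
Landis–Koch labels are assigned after rounding kappa to the two decimals
the published bins carry.

The Bangdiwala chart places, for each category, a rectangle spanned by the
cumulative row and column marginals, the exact-agreement square of side
`n_ii` inside it, and a partial band for cells within one category.
`B = Σ n_ii² / Σ (n_i+ n_+i)` is 1 for every diagonal table and below 1
whenever both raters use every observed category and any disagreement
exists. Two degenerate conventions are worth stating: when every marginal
product is zero the denominator vanishes and B is defined as 0; and the
classical statistic equals 1 for tables whose disagreements sit entirely in
categories one margin never uses (their rectangles have zero area). The
test suite asserts the exact characterisation by enumeration.

## The synthetic generator

The generator exists so that every scorer and statistic is testable with no
patient data. Each item has four archetypes whose noise-free geometry
satisfies the intended score's predicates *by construction*: e.g. the full
item 18 archetype circles at `r_large + 0.3` cm; the imperfect one adds a
1.2 s stop and a brief dip into the disc; the item 19 full archetype is a
five-period loop train whose crests sit mid-way into the contact bands; the
item 22 imperfect archetype lands one tap exactly on a target's drawn
boundary. On top of that sit three noise processes: a tremor sinusoid
(default 0.02 cm at 4 Hz), white positional jitter (0.01 cm sd), and tap
endpoint scatter (0.05 cm sd). These magnitudes were chosen once as
mild-impairment values sized against the rubric margins (the item 19 band
placement leaves ±0.05 cm of room; the item 22 precise-hit margin is about
0.7 cm), and are documented stand-ins: realistic per-diagnosis noise
magnitudes are not available in the literature this package draws on.
Cohort simulation draws archetypes from per-item marginals (defaulting to
the ability mix of the validation cohort), and generates a second scoring
mode through a row-stochastic misclassification matrix, which gives paired
scores with a known analytic kappa.

What the generator does **not** emulate: biomechanics (no limb model, no
trunk compensation), pathological tremor spectra, stroke-pressure or tilt,
and the original diagram's pictogram shapes. Passing recovery tests
therefore show that the scorers read the rubric geometry correctly under
graded noise — not that they replicate therapist judgement on real
patients, where compensations invisible to the trace are a documented
source of disagreement.

## Numerical and reproducibility choices

All randomness flows from explicit seeds through a scoped RNG (the caller's
RNG state is never touched); scoring contains no randomness at all, and the
simulate → score → agree pipeline is byte-for-byte reproducible, which the
tests assert. Trace CSVs write coordinates with up to 17 significant
digits so doubles round-trip exactly. Synthetic traces are sampled at
60 Hz (typical touch hardware, configurable) and pixel coordinates are
rounded to 3 decimals — 10⁻³ px is far below sensor resolution. Test and
validation problem sizes were chosen to exercise the statistics at
realistic scale while staying quick: 200 random tables against the
brute-force kappa oracle, an exhaustive enumeration of 3 × 3 tables with
N ≤ 6 for the B characterisation, and a 200-subject noisy cohort
(600 recordings) for score recovery, which completes in seconds.

## Known limitations

* The A-score is a geometric proxy. Postural compensation, hand support on
  the table, and finger identity are not observable; pointer-id change is
  the only correlate of a finger change.
* `min_loops_full`, the pause thresholds and the contact tolerances are
  declared operationalisations of qualitative rubric wording; sites with
  different conventions should set them explicitly and report them.
* The per-subject disagreement profile implements a per-subject reading
  (classifying each subject across their items); published summary
  percentages of this kind cannot be reconstructed from marginal tables
  alone, so the operation is validated synthetically.
* Item 19's score 0 cannot distinguish "cannot pick up the pencil" from
  "made no mark"; both are no-ink.
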