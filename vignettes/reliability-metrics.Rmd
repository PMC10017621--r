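---
title: "Measuring rater reliability of temporal surgical workflow annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rater reliability of temporal surgical workflow annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotRR)
```

## The problem

Training and validating surgical phase- and step-recognition models requires
temporal annotations of operative videos: a rater watches a recording of, say,
a laparoscopic Roux-en-Y gastric bypass (LRYGB) and marks the start and end of
each *phase* (a first-level component of the procedure, such as creation of
the gastric pouch) and each *step* (a finer action within a phase, such as
stapling). Before such annotations can anchor any downstream analysis, two
questions must be answered quantitatively: do two trained raters annotating
the same video agree (inter-rater reliability), and does one rater agree with
themself after a wash-out period (intra-rater reliability)?

`annotRR` implements the full measurement apparatus for these questions: a
machine-readable hierarchical label ontology, exact millisecond-level
agreement metrics between two annotation timelines, *application-dependent*
(AD) metrics that forgive small boundary disagreements, cohort-level
aggregation, and a synthetic two-rater simulator that makes every metric
verifiable by parameter recovery.

## The ontology

The packaged LRYGB ontology contains 12 phases and 46 steps. Each step
belongs to exactly one parent phase; phases and steps flagged *facultative*
may legitimately be absent from an individual procedure (an omentum division
is routine in some centers and rare in others). A reserved `idle` label
represents un-annotated time — before the first trocar, between phases —
so that a video timeline can always be labelled totally.

```{r}
o <- load_ontology(lrygb_ontology_path())
o
head(o$steps, 4)
```

The schema is deliberately a flat label vocabulary with parentage, not a
description-logic ontology: every metric below depends only on label
identity, so the wording of step names carries no analytic weight.

## Annotation timelines

One rater's annotation of one video at one level is an ordered set of
non-overlapping, half-open intervals `[start_ms, end_ms)` in integer
milliseconds. Half-open intervals guarantee that no millisecond is counted
twice at a boundary, and integer milliseconds make all of the interval
algebra exact — there is no floating-point time anywhere in the pipeline.
`totalize()` fills gaps with explicit `idle` intervals so that a track tiles
`[0, duration)`; whether raters annotated gap-free or not, comparison always
happens on totalized tracks. When two raters trimmed the same video
differently, both tracks are totalized onto the longer duration, which is
this package's convention for reconciling trailing un-annotated time.

## Classical time-weighted metrics

All agreement metrics weight by time. The confusion matrix cell $(a, b)$
holds the number of milliseconds during which one track (the "ground truth"
of that comparison) carries label $a$ while the other carries $b$; it is
computed by a sweep over the merged interval boundaries, which is exactly
equivalent to dense 1 ms sampling at any video length but costs only
$O(\text{segments})$. From the matrix:

* accuracy $= \mathrm{tr}(C) / \sum C$,
* per-class precision $= C_{cc}/\text{colsum}(c)$, recall
  $= C_{cc}/\text{rowsum}(c)$, F1 their harmonic mean,
* Cohen's kappa $\kappa = (p_o - p_e)/(1 - p_e)$ with
  $p_o = \mathrm{tr}(C)/\sum C$ and
  $p_e = \sum_c \text{rowsum}(c)\,\text{colsum}(c)/(\sum C)^2$, the
  chance-corrected agreement.

Comparing two *human* annotations is not a ground-truth-vs-prediction
comparison, so every metric is computed twice — each track once as ground
truth — and the two values are averaged (`symmetric_compare()`). Because the
confusion matrix transposes under the swap, swap-averaged macro precision
*equals* swap-averaged macro recall exactly; identical precision and recall
columns in a reliability table are a structural consequence of the symmetric
protocol, not a coincidence.

Three conventions required decisions the metric definitions leave open:

* **Macro averaging** is unweighted over the union of classes appearing in
  either track, with `idle` as an ordinary class (`average =
  "macro_present"`). Averaging over all 46 step labels would let videos
  lacking facultative steps score systematically differently for reasons
  unrelated to rater agreement; `macro_all` and `micro` remain available.
* **Zero denominators** (a class present in one track only) score precision
  and recall 0 rather than being dropped: hallucinated or omitted classes
  must cost something, and the convention is deterministic.
* **Degenerate kappa**: when both raters used a single identical label,
  $p_e = 1$ and kappa is undefined; `NA` is returned, and aggregation skips
  the value while reporting how many were skipped, rather than silently
  substituting 0 or 1.

## Transition metrics and delta-relaxation

A *transitional moment* is any time point where a track's label changes;
changes into and out of `idle` count, because on the totalized timeline
`idle` is a label like any other (an insertion into un-annotated time is
still a disagreement about workflow structure). Three quantities summarize
boundary behaviour:

* **Average transitional delay (ATD)**: annotated and real transitions are
  matched one-to-one and the mean delay (annotated − real) is reported in
  seconds. Matching is greedy nearest-neighbour by |delay|, first among
  pairs sharing the `(from, to)` label signature, then among the remainder,
  with deterministic tie-breaks. No time window restricts matching: observed
  ATDs can far exceed the relaxation threshold, so a windowed matching would
  discard exactly the delays the metric exists to measure. The signed mode
  is the default (a consistently late rater is `+`, an early one `-`);
  note that the swap-averaged signed ATD is identically 0, because under a
  role swap every delay changes sign — delay magnitude lives in the
  per-direction values or in `delay_mode = "absolute"`.
* **Coefficient of transitional moments (C_TM)**: the ratio of annotated to
  real transition counts, in percent. Each spurious segment spliced into a
  timeline adds exactly two transitions.
* **Noise level (NL)**: the percentage of annotated segments (maximal
  same-label runs, `idle` excluded) that have zero temporal overlap with any
  real segment of the same label. Segments are *counted*, not
  time-weighted, so a brief hallucinated segment counts as much as a long
  one; an IoU-thresholded variant was considered and rejected as a second
  tunable with no principled default.

The **application-dependent metrics** recompute the classical set after
forgiving label disagreement near boundaries: any millisecond lying in the
window $[t - \delta,\ t + \delta)$ around a ground-truth transition at $t$,
whose predicted label equals the ground-truth label immediately before or
after $t$, is credited to the diagonal (the `relax_mode` options restrict
this to the pre- or post-label only). The default $\delta$ is 5 s — a
tolerance appropriate when the application is, e.g., estimating remaining
intervention time, where being five seconds late on a phase change is
immaterial; for real-time intraoperative decision support a much smaller
$\delta$ would be appropriate, and $\delta$ is fully configurable. By
construction AD metrics equal the classical ones at $\delta = 0$, never fall
below them, and are monotone non-decreasing in $\delta$; all three laws are
enforced by tests.

## Per-video evaluation and aggregation

`evaluate_video_pair()` runs the whole protocol per video at both levels;
`aggregate_dataset()` reports the unweighted mean and sample (n−1) SD of
each metric across videos, skipping undefined values and recording
`n_defined` per metric. A multi-cohort "overall" summary pools videos rather
than averaging cohort means (the per-cohort reports remain available, so the
alternative is a one-liner). `render_table()` prints the conventional
reliability-table layout — kappa, accuracy, precision, recall, F1, ATD,
C_TM, NL, then the AD columns — with percents to one decimal.

## The synthetic cohort generator

No clinical annotations ship with the package, so correctness is
demonstrated the only way it can be: simulate raters with *known* noise and
recover the injected parameters through the metrics. The generator has two
parts.

**Ground truth.** A `cohort_profile()` lays phases out sequentially in
ontology order, draws each duration from a log-normal (positive,
right-skewed, matching the long tail of surgical durations; only means and
SDs are specified, and 35% relative SD is used as a realistic default), and
includes facultative phases by Bernoulli draws. Steps tile their parent
phase with fixed uneven weights. Two profiles ship, emulating reported
center-specific technique differences between a Strasbourg-style and a
Bern-style bariatric cohort: mean video duration 108 vs 75 min, gastric
pouch ~26 vs ~15 min, jejunojejunal anastomosis ~24 vs ~18 min, and
facultative-phase inclusion 95 vs 36% (omentum division), 98 vs 16%
(Petersen space closure), 100 vs 21% (mesenteric defect closure). Inclusion
probabilities not pinned to a specific phase were calibrated once so the
expected phase and step counts per video are 10 and 33 (Strasbourg-like) and
8 and 27 (Bern-like); the realism test checks those means at Monte-Carlo
precision.

**Rater noise.** `perturbation_config()` has four channels:

* *Boundary jitter* — each transition moves by $N(\mu, \sigma)$ ms,
  optionally clamped to a maximum magnitude. Boundaries that would invert an
  interval are clipped to preserve ≥ 1 ms durations; under extreme jitter
  this clipping slightly biases recovered means toward zero, which is why
  recovery tests use jitter well below segment durations.
* *Substitution* — a segment's label swaps with a confusable one, by default
  the adjacent label in ontology order (raters confuse neighbouring
  workflow elements, not arbitrary ones); uniform substitution is available.
* *Insertion* — spurious segments are spliced strictly inside an existing
  non-idle segment, never inside a previously inserted one. This makes the
  bookkeeping exact: $k$ insertions add exactly $2k$ transitions and $2k$
  segments of which $k$ are noise, so C_TM must equal $100\,(m+2k)/m$ for
  $m$ real transitions and NL must equal $100\,k/(n+2k)$ for $n$ real
  segments — closed forms the acceptance tests verify per video.
* *Omission* — a facultative segment is relabelled `idle`, modelling a rater
  who did not annotate that span (absorbing it into a neighbour would
  instead model a boundary disagreement, which jitter already covers).

One global seed fans out deterministically to per-video streams, so cohorts
are byte-identical on re-run and extensible without stream reuse.

## What the tests do and do not show

The oracle suite proves the interval-sweep implementations *exactly*
equivalent to brute-force 1 ms dense sampling on hundreds of randomized
tracks, and the recovery suite shows each metric measures what it claims
under a noise model whose parameters are known. The simulator emulates
duration structure, facultative-element prevalence and four rater error
modes; it does not emulate content-driven human behaviour — systematic
disagreement about the *definition* of a boundary, attention drift over a
long video, or correlated errors between levels. Passing tests therefore
certify the measurement instrument, not any claim about how reliable a
particular ontology is in clinical hands; for that, the pipeline must be run
on real double-annotated videos.

Problem sizes in the shipped tests — 200 randomized oracle tracks of up to
10 minutes, 100 random symmetry pairs, recovery cohorts of 50 videos — were
chosen so the whole suite completes in well under a minute on one core while
keeping Monte-Carlo standard errors small against the tested effect sizes.

## Known limitations

* Exactly two raters per comparison; no Fleiss kappa or other multi-rater
  generalizations, and no weighted kappa.
* No bootstrap confidence intervals on cohort summaries.
* The transition-matching procedure is a documented convention
  (signature-first greedy nearest-neighbour); an exhaustive minimum-cost
  assignment is used as a test oracle on small instances but is not the
  production path.
* NL counts segments; a time-weighted noise share is easy to compute from
  the confusion matrix but is not what this metric reports.
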