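---
title: "Multimodal surgical workflow assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal surgical workflow assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgflow)
```

## The problem

Surgical workflow analysis deconstructs a procedure into a timed sequence
of phases. For laparoscopic cholecystectomy the canonical decomposition has
seven phases, from patient preparation to gallbladder extraction
(`lc_phases()`). Automatic phase recognition usually works from the
endoscopic video alone; adding the surgeon's speech brings in the cognitive
side of the procedure — a narrating trainee verbalizes what they are doing —
and a second, largely independent, noise channel.

`surgflow` takes the *outputs* of two such classifiers — per-frame phase
posteriors from a video model and per-fragment posteriors from a speech
model — and provides everything downstream: time synchronization and late
fusion, timeline segmentation, timewise skill metrics, embedded-Markov
workflow modelling, Wasserstein comparison against a reference workflow,
and frame-wise evaluation against ground truth. Training or running the
classifiers themselves is out of scope; a seeded simulator stands in for
them so that the entire pipeline is testable end to end.

## Data model

Time is continuous, in seconds from procedure start. Video frames are
instants on a regular grid at `fps` frames/second; each frame is taken to
occupy the `1/fps` seconds starting at its timestamp (the total procedure
time is therefore exactly `n_frames/fps`; no special rule is needed for the
last frame). Speech fragments are half-open intervals `[start, end)`
obtained by cutting the audio at silences; half-openness makes
frame-to-fragment membership unambiguous. Fragments are sorted and
non-overlapping.

Speech posteriors carry one extra class, always serialized last: the
*pseudo-phase*, which absorbs off-task talk (casual conversation in the
operating room, questions to or from trainees) that belongs to no
procedural phase. Probability vectors must sum to one within `1e-9`;
vectors inside that tolerance are renormalized exactly on ingest, so CSV
round-trip jitter never propagates.

## The fusion rule

The two prediction streams are synchronized: frame `i` belongs to fragment
`f` iff `f.start <= t_i < f.end`. For each fragment the fused posterior is
the convex combination

$$\mathbf{p}_{\text{fused}} \;=\; w_a\,\mathbf{p}_{\text{speech}}
\;+\; \sum_{i=1}^{k}\frac{1-w_a}{k}\,\mathbf{p}_{\text{video},i},$$

with equal modality weight $w_a = 0.5$ by default and the video share split
equally over the $k$ covered frames. One fused distribution is computed per
fragment window and assigned to every frame in it — the modalities are
averaged for as long as the speech fragment lasts, which also smooths the
timeline. Three branches are distinguished per frame and recorded as its
*provenance*:

* `fused` — the frame lies under a fragment whose predicted class is
  procedural;
* `audio_eliminated` — the fragment's argmax is the pseudo-phase: the
  fragment is off-task talk and is eliminated from the analysis, so its
  frames fall back to the video posterior;
* `video_only` — no speech captured at that moment.

A fragment that is not eliminated but carries residual pseudo-phase mass
has that entry dropped and the procedural mass renormalized
(`strip_pseudo()`); whether to renormalize or eliminate is exposed as
`pseudo_policy` in `fusion_config()` since either convention is defensible.

Numerical conventions, chosen once and applied everywhere:

* **Ties.** Argmax ties are resolved to the lowest phase index —
  deterministic and order-stable. Ties have probability zero for
  continuous posteriors; the rule only matters for hand-built inputs such
  as an exact 0.5/0.5 split.
* **Degenerate weights.** With `audio_weight = 1` every covered frame
  takes the fragment's posterior. With `audio_weight = 0` the fragment
  carries no mass and fusion reduces to the identity on the video frames
  (not the window mean — averaging frames with each other is a side effect
  of distributing audio weight, and with no audio weight there is nothing
  to distribute). This keeps the weight-0 timeline identical to the
  video-only timeline frame by frame.
* **Sub-frame fragments.** A fragment shorter than one frame period can
  cover no frame; it is ignored with a warning, since there is no frame to
  assign its fusion to.

## Timeline metrics

The fused label sequence is run-length encoded into maximal, contiguous
phase segments. From the segments come the metrics used for timewise skill
characterization: total time in surgery, time per phase, occupancy
percentage, number of occurrences per phase, and the minimal / maximal /
mean occurrence duration (informative whenever a phase is visited more than
once, e.g. when packaging is interrupted by extra cleaning). Per-phase
times sum to the total and occupancies to 100% by construction; the tests
assert both to `1e-9`.

## Workflow models and their comparison

The procedure's *workflow* is modelled as the embedded Markov chain of
phase transitions: self-transitions are discarded (consecutive frames
overwhelmingly share a phase, so they carry no workflow information) and
entry $(i,j)$ of the row-stochastic matrix is the maximum-likelihood
estimate

$$\hat P_{ij} = \frac{\#\,i \to j}{\#\,i \to \cdot}$$

pooled across one or more procedures. A phase with no outgoing jump is
*terminal* and carries an all-zero row. A reference ("average") workflow is
built the same way from a database of procedures; pooling weights every
observed transition equally, and `method = "average"` weights every
procedure equally instead — both are defensible readings of an "average
workflow", and pooling is the default.

A trainee's workflow is compared to the reference row by row with the
first-order Wasserstein (earth mover's) distance. Phase indices are
embedded on the line in canonical order with unit spacing — the natural
choice given that the canonical order is the clinical order of the
procedure — so the distance has the closed form
$\sum_{k=1}^{n-1}\lvert F_p(k)-F_q(k)\rvert$ with CDFs $F$. The test suite
checks this closed form against an independent monotone-coupling transport
solver. Rows terminal in either model are excluded from the average (an
all-zero row is not a distribution) and reported as excluded rather than
silently dropped.

## Evaluation metrics

`evaluate_predictions()` scores a predicted label sequence against ground
truth: per-class precision, recall, F1 (harmonic mean of precision and
recall) and Jaccard index from the confusion matrix, macro-averaged over
the classes present in the truth (matching common phase-recognition
benchmarking practice, and avoiding undefined recall for absent classes);
plus overall accuracy. Two aggregate error rates are reported with
documented — and deliberately interpretive — definitions:
`avg_error_per_phase_pct` is the mean over truth-present classes of
$100(1-\text{recall})$, and `avg_error_pct` is $100(1-\text{accuracy})$.
Error-rate names vary across the phase-recognition literature and are often
left undefined; these are this package's definitions, not reconstructions
of anyone else's.

## The synthetic generator

`simulation_config()` + `simulate_run()` emulate a narrated teaching
procedure and two imperfect classifiers:

* **Phase sequence** from the embedded chain of a reference workflow. The
  default (`default_lc_workflow()`) is a forward chain with two clinically
  common loops: dissection occasionally interrupted by additional clipping
  (probability 0.15) and cleaning returning to packaging (0.25);
  extraction is terminal.
* **Dwell times** are lognormal per visit (positive, right-skewed, the
  usual shape of surgical durations), parameterized by their own mean and
  standard deviation. Defaults of 60/180/90/180/60/90/45 s across the
  seven phases with a coefficient of variation of 0.5 give procedures of
  roughly 8–15 minutes — teaching-video scale, large enough for several
  hundred frames at the default 1 fps.
* **Speech fragments** come from a renewal process: exponential silent
  gaps (at least `silence_min = 1` s) between fragments of truncated-normal
  duration (mean 4 s), about eight fragments per minute — a steadily
  narrating trainer. A candidate fragment crossing a phase transition is
  truncated at the boundary: narration about a phase stops when the phase
  changes, so every fragment lies within one true phase. With probability
  `offtask_prob = 0.1` a fragment is off-task and its true class is the
  pseudo-phase.
* **Classifier noise.** For each frame/fragment the *predicted* class is
  drawn from the confusion-matrix row of the true class, so the empirical
  per-class argmax accuracy equals the confusion diagonal exactly. The
  emitted posterior is $(1-s)\,\delta_{\text{pred}} + s\,\mathbf z$ with
  $s \sim U(0, \tfrac{1}{1+\text{concentration}})$ (default concentration
  1: top-1 probability between 0.5 and 1) and $\mathbf z$ a flat Dirichlet
  draw whose weight at the *true* class is raised by `truth_lean`
  (default 3). The truth-leaning residual emulates a classifier whose
  ranked posterior is more informative than its top-1 decision — top-2
  accuracy above top-1 accuracy, which every usable classifier exhibits —
  and it is exactly this graded evidence that late fusion pools. With
  `truth_lean = 0` the residual is uninformative noise and equal-weight
  fusion degenerates into following the speech argmax wherever speech is
  present, which helps nothing; the default regime is the one where
  combining independent modalities measurably raises frame accuracy.
* **Determinism.** One seed per simulation, consumed in a fixed documented
  order: the chain, dwells and fragment schedule use `seed`; video
  emissions `seed + 1`; audio emissions `seed + 2`. Each render function is
  therefore reproducible on its own, independent of call order.

What the generator does **not** emulate: visual or acoustic content (no
pixels, no waveforms), classifier errors that are correlated in time or
between modalities (real CNN errors cluster around phase transitions and
visually similar phases), annotation disagreement between experts, and
fragments genuinely straddling phase boundaries. Tests passing on this
generator therefore demonstrate the correctness of the pipeline's
*computations*, not the field performance of any classifier.

## Problem sizes and numerical tolerances

The test suite works at desk scale, chosen to exercise every statistical
property well inside a laptop budget: 100 simulated procedures
(≥ 300 frames each, ~80,000 frames in total) for the fusion-benefit check,
10,000 embedded transitions for workflow recovery, 200 random distribution
pairs for the transport-oracle equivalence, and 50–100 random cases for
each conservation and round-trip property. Probability sums are enforced to
`1e-9`, oracle equivalences to `1e-9`–`1e-12`, and serialized numbers use
fixed 12-decimal formatting — enough that every write/read round trip stays
within the `1e-9` ingest tolerance (9-decimal formatting would not be: a
7-entry row each rounded by `5e-10` can miss unit mass by more than
`1e-9`).

## Known limitations

* The per-window label copy quantizes segment boundaries to the frame
  grid; boundary timing is accurate to `1/fps` seconds.
* The equal 50/50 modality weighting is the published convention, not an
  optimum; `audio_weight` is exposed for sensitivity analyses.
* Workflow estimates from noisy frame labels inherit spurious transitions
  (each misclassified frame can create two embedded jumps). Comparisons
  against a reference are therefore most meaningful after smoothing or at
  high frame accuracy; the package deliberately reports what the labels
  contain rather than imposing a smoother.
* The Wasserstein ground metric treats adjacent phases as equidistant;
  a clinically weighted metric would need a domain-supplied cost matrix.
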