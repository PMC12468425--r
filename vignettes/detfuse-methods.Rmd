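---
title: "Methods: NMS ensemble fusion and paired evaluation of lesion detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMS ensemble fusion and paired evaluation of lesion detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detfuse)
```

## The problem

Screening endoscopy for Barrett's esophagus asks a detector to put a box
around every suspicious mucosal region. The clinical cost structure is
asymmetric: a missed lesion (false negative) can mean a missed
adenocarcinoma precursor, while a false positive costs review time or at
worst an unnecessary biopsy. Recall is therefore the primary metric, and
a natural strategy is to run several heterogeneous detectors and pool
their predictions — different architectures miss different lesions, so
the union can be more sensitive than any member. `detfuse` implements
that strategy as a reusable toolkit: fusion, evaluation, greedy ensemble
construction, and paired significance testing, with a synthetic study
generator that makes the whole stack testable end to end.

## Fusion model

Fusion is deliberately minimal. Per image, member detections are pooled
and one joint NMS pass is applied: boxes with confidence below the floor
are dropped; survivors are visited in descending confidence; a box is
suppressed when its IoU with an already-kept box is **at or above** the
threshold. Kept boxes retain their original coordinates and confidences
— no averaging, weighting or soft suppression. The comparator (`>=`
suppresses) and the tie order for equal confidences (larger area first,
then lexicographic model id, image id, `x_min`) are conventions chosen
to make output bit-reproducible; the suppression boundary itself has
measure zero for continuous confidences, so neither choice is
substantive.

Two tunable parameters matter:

* `iou_threshold` (default **0.3**) — dimensionless overlap at which two
  boxes are treated as the same finding, both in suppression and in
  truth matching. 0.3 is a lenient localization standard appropriate
  when finding the lesion matters more than outlining it tightly.
* `confidence_threshold` (default **0.1**) — the operating floor. A low
  floor is the recall-first choice: it admits hesitant detections at
  the price of precision.

## Matching and metrics

Evaluation matches detections to ground-truth lesions one-to-one per
image at the IoU threshold, then micro-averages counts over the test
set; precision, recall and F1 follow the usual ratios, with recall
computed per lesion (an image-level recall mode is available as a
sensitivity analysis via `recall_unit = "image"`). Lesion-free control
images contribute only false positives. Degenerate denominators (no
detections, or no lesions) yield 0 with a `degenerate` flag rather than
`NaN`, so batch reports stay total.

The assignment rule deserves a note. The field's habitual protocol is
one-pass greedy: detections in confidence order each claim the
highest-IoU free lesion. That protocol is *not* guaranteed to maximize
the number of matched lesions — a confident box overlapping two lesions
can claim the one a later box needed, stranding a lesion even on
three-box instances (in random small-instance simulations this struck
roughly 1 in 1300 cases). `detfuse` therefore uses
confidence-prioritized **maximum** matching: detections are still
processed in confidence order with highest-IoU preference, but an
incoming detection may displace an earlier claimant to one of its
alternative lesions (an augmenting path in the bipartite graph). The
matched count then provably equals the exhaustive optimum — the test
suite verifies this against brute-force enumeration — while keeping the
familiar semantics: duplicates of an already-matched lesion count as
false positives, and ties stay deterministic (IoU, then ground-truth
`x_min`).

## Greedy recall-first selection

`stepwise_select()` builds the ensemble forward: the first member is the
candidate with the highest standalone recall (evaluated as a singleton
fusion, i.e. after NMS at the operating point, so all steps are scored
identically); each later step adds the candidate maximizing fused
recall, with ties broken by fused precision and then model id. Members
keep being added to `max_size` even at zero or negative gain — fusion
depth is part of the design space being audited, and the per-step gains
are recorded in the trace — unless `stop_on_no_gain` is set. Selection
is scored on the same study it reports on; with a handful of candidates
this is mildly optimistic by construction, which is flagged here rather
than hidden behind an inner split.

A practical observation from the synthetic studies: the last fusion
steps buy fractions of a percent of recall, and on small studies a step
can even cost a lesion — a pooled false positive can outrank and
suppress a true positive in joint NMS. The effect is visible in the
worked example in the README (357 lesions) and vanishes at the default
study size.

## Paired statistics

Comparing a fused ensemble with a single detector on the *same* lesions
is a paired problem, and all three reported statistics respect that:

* **McNemar's test** uses only the discordant lesions — `b` found by
  system 1 alone, `c` by system 2 alone. The exact two-sided binomial
  form `min(1, 2·P(Bin(b+c, ½) ≤ min(b, c)))` is used below 25
  discordant pairs, the continuity-corrected chi-square
  `(|b−c|−1)²/(b+c)` above; `b + c = 0` gives p = 1. The split at 25 is
  the standard small-sample practice.
* **Stratified bootstrap CI**: images are resampled with replacement
  within the lesion-bearing and lesion-free strata, preserving stratum
  sizes; lesions and detections travel with their image, so within-image
  correlation is respected; the 95% interval is the 2.5/97.5 percentile
  of the resampled recall differences over `B = 1000` draws by default.
  The image is the exchangeable unit — resampling lesions directly would
  break within-image dependence.
* **P-score**: `PS = |E1 − E2| / sqrt(q(1−q)(1/n1 + 1/n2))` on error
  rates `E = 1 − recall` with `q` their mean — a z-like statistic with
  `PS ≥ 2` read as 95%-level significance. Since `E` is a per-lesion
  error rate, `n1 = n2` is taken to be the number of ground-truth
  lesions in the evaluation set. When both systems are perfect (or both
  totally wrong) `q(1−q) = 0` and PS is reported as 0 with a degenerate
  flag.

No multiplicity adjustment is applied to the per-pair p-values; when a
table of several comparisons is rendered, a clearly-labelled
Holm-adjusted column is appended as an extension so readers can apply
either convention. Every report records its seed (default `20250910`).

## The synthetic study generator

`generate_study()` emulates a two-stratum screening test set. Its
defaults are the package's reference study conditions and were fixed
once:

| parameter | default | rationale |
|---|---|---|
| images | 2400 (via `paper_like_spec()`) | ≈2000 lesions, enough for ±0.01 recall resolution |
| lesion-bearing fraction | 2220/3620 ≈ 0.613 | typical case/control imbalance of a screening set |
| lesions per positive image | 1:0.7, 2:0.2, 3:0.1 | most frames carry one finding; a documented arbitrary choice |
| image size | 640 × 512 px | common endoscopic processing resolution |
| lesion side | 60–200 px | visible mucosal patches, not specks |
| sensitivities | 0.926, 0.934, 0.923, 0.946, 0.922 | five detectors in the 0.92–0.95 band |
| FP rates | solved per detector | to land standalone precisions at 0.796, 0.755, 0.760, 0.717, 0.782 |
| confidences | TP ~ Beta(8,2), FP ~ Beta(2,8) | calibrated detectors: confident hits, hesitant ghosts |
| jitter | 4 px per coordinate | sub-box localization noise; IoU with truth stays ≈0.9 |
| miss correlation ρ | 0.6 | detectors agree on which lesions are hard more often than not |

The miss model couples detectors through a single latent difficulty
draw: with probability ρ a lesion is "coupled" and one shared uniform
`V` decides all detectors at once (detector `j` detects iff
`V ≤ s_j`, so misses coincide — the comonotone coupling); otherwise
detectors decide independently. Marginal sensitivities are unaffected by
ρ; only the *complementarity* of misses changes. This yields the closed
form used as the end-to-end oracle,

```
E[union recall] = ρ · max(s) + (1 − ρ) · (1 − Π(1 − s_j)),
```

which reduces to the independent union at ρ = 0 and to the best single
detector at ρ = 1, and decreases monotonically in ρ. With the default
sensitivities and ρ = 0.6 the expected fused recall is
`r round(expected_ensemble_recall(c(0.926, 0.934, 0.923, 0.946, 0.922), 0.6), 4)`
— a ~2–3 point gain over the best member, matching the magnitude that
makes recall-first fusion clinically interesting.

False-positive rates are solved analytically: expected TPs per image are
`frac_pos × E[lesions|positive] × sensitivity × P(TP conf ≥ floor)`, and
the Poisson FP rate is set so that `TP/(TP+FP)` hits the target
precision after accounting for FP confidences that the floor removes
(`fp_rate_for_precision()`).

What the generator does **not** model, and what passing tests therefore
do not show about real data: realistic pixel appearance (there are no
pixels), patient-level clustering of images, modality differences
(WLI/NBI is carried as metadata only), systematically hard lesion
subtypes beyond the single ρ knob, and — importantly — spatially
*correlated* false positives across detectors. Real detectors often ring
on the same distracting mucosa, and joint NMS then collapses their false
alarms; independent uniform FP placement cannot collapse, so fused
precision degrades faster here than one should expect in practice.
Fused recall, the primary quantity, is unaffected by this limitation.

## Numerical and degenerate-case choices

* Boxes are continuous rectangles; area is plain width × height, and
  clipping to image bounds can only shrink a box. Boxes degenerate after
  clipping are dropped with a warning, not an error.
* YOLO label serialization prints six decimals; parse ∘ serialize is
  identity within 1e-6 in normalized units.
* Ground-truth lesion placement rejects same-image overlap at IoU ≥ 0.3
  so one detection cannot legitimately claim two lesions at the default
  threshold.
* Table cells round half away from zero at 3 decimals; JSON reports
  keep full precision.
* All randomness (generation, bootstrap) flows through explicit seeds;
  generation restores the caller's RNG state.

## Problem sizes used in validation

The shipped validation suite runs at sizes chosen to give tight
statistical resolution while staying comfortably interactive: NMS is
checked against a brute-force quadratic oracle on 1000 random instances
of up to 50 boxes; matching against exhaustive optimal assignment on
1000 random ≤3-box instances; exact McNemar against the binomial tail
for every discordant table up to 12; bootstrap coverage over 200
replicate studies of ≈400 lesions at B = 500 (the 95% CI should cover a
designed 0.05 recall gap in 90–99% of replicates); and the end-to-end
fusion check on a ≈2000-lesion study, where fused recall must beat the
best member and sit within three Monte-Carlo standard errors of the
closed-form union recall.
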