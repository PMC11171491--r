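---
title: "Evaluating a majority-vote detection ensemble on chest radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a majority-vote detection ensemble on chest radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxreval)
```

## The problem

Commercial chest-radiograph (CXR) AI tools commonly combine several object
detectors: each model emits scored bounding boxes labelled with one of six
thoracic pathologies (consolidation, pleural effusion, pneumothorax, acute
pulmonary edema, cardiomegaly, pulmonary nodule), and a majority vote decides
which boxes survive. Validating such a tool raises three distinct statistical
tasks, all implemented here:

1. **the ensembling rule itself** — which boxes does the vote keep;
2. **the reference standard** — how several radiologists' boxes become one
   consensus ground truth;
3. **the comparison statistics** — standalone confusion metrics with
   confidence intervals, and a multi-reader multi-case (MRMC) comparison of
   aided versus unaided reading.

The package also ships a fully seeded synthetic study generator so that the
entire pipeline can be exercised, and its estimators validated against known
simulation parameters, without any imaging data.

## Box geometry

Boxes live on an integer pixel grid, origin top-left, with a **half-open**
convention: `pixel_box(x_min, y_min, x_max, y_max)` covers
$[x_{min},x_{max}) \times [y_{min},y_{max})$. Overlap means at least one
shared pixel, which makes "non-null Jaccard index" an exactly testable
discrete predicate and gives the edge case a definite answer: boxes sharing
only an edge or corner do *not* overlap. Consensus boxes are the corner-wise
arithmetic mean of the agreeing annotators' boxes, rounded half-up back onto
the grid; since every input side is at least one pixel, the average is always
a valid box.

## The voting rule

`ensemble_vote()` works per image and per pathology (no cross-label voting):

* detections from all models are grouped into connected components of the
  pairwise overlap graph — support is transitive through chains, so a box
  overlapping `b` which overlaps `c` shares a component with both;
* a component is retained when its members come from at least `min_support`
  **distinct** models (3 of 5 by default). Support is counted in models, not
  boxes: two boxes from one model contribute once;
* each retained component emits exactly one detection, its highest-scoring
  member — geometry is never merged or synthesized. Score ties break to the
  lowest model id and then lexicographic corners, so the output is
  deterministic;
* per-pathology score thresholds are applied **last**, to the emitted boxes
  only: sub-threshold boxes still vote.

`calibrate_thresholds()` chooses the per-pathology threshold on validation
data by sweeping every midpoint between adjacent distinct scores and
maximizing Youden's $J = \text{sensitivity} + \text{specificity} - 1$, ties
going to the higher (more specific) cut. A single explicit objective was
preferred over an unstated blend of sensitivity, specificity and mAP;
mAP-based calibration is out of scope.

## Consensus ground truth

`consensus_findings()` applies the same component construction to the
annotator panel (default three radiologists): a component supported by a
majority of distinct annotators ($\lceil (n+1)/2\rceil$, i.e. 2 of 3) becomes
one finding with the averaged box and the distinct-annotator count as
`support`. Two choices were genuinely open:

* **only the agreeing annotators enter the average.** Averaging in a
  dissenting disjoint box could produce a consensus box overlapping nothing
  that any annotator drew;
* **one box per annotator per component.** If an annotator contributed
  several boxes to one component, their box with the largest summed overlap
  with the other members represents them (lexicographic tie-break).

An image is ground-truth negative for a label iff no finding of that label
survives majority; explicit absence votes are not modelled.

## Image-level evaluation

`classify_image()` classifies each image per pathology: a ground-truth
positive image is **TP** when any predicted box of the label overlaps any
finding and **FN** otherwise — including when stray non-overlapping
predictions exist; a ground-truth negative image is **FP** when any
prediction is present, **TN** otherwise. The FN precedence is the only
reading of the per-box definitions under which the per-pathology tallies
conserve the study composition exactly (`tp + fn = ` positives, `fp + tn = `
negatives), which the enriched 500/1000-per-pathology design requires;
lesion-level counting is out of scope.

`metric_panel()` derives sensitivity, specificity, PPV, NPV, FPR and FNR
with Wilson score 95% intervals ($z = 1.959964$); undefined ratios are
reported as `NA` with a warning, never coerced to 0 or 1. `roc_auc()` is the
rank (Mann–Whitney) statistic with midrank ties, identical to the
trapezoidal area under the empirical ROC; `bootstrap_auc_ci()` is a
stratified percentile bootstrap (B = 2000 by default, resampling within each
class so no replicate is degenerate; BCa was not used). Study-level figures
are unweighted macro-averages over the six pathologies — macro matches every
published aggregate we cross-check, micro does not. AUC is never derived
from a single operating point: binary confusion counts cannot reproduce a
score-based ROC, so published AUCs are carried as data
(`reference_metric_table()`), not recomputed.

## Reader study statistics

`mrmc_summary()` summarises per-reader, per-condition outcomes (reading
time, rank AUC over the reported confidences, macro-averaged sensitivity and
specificity) and compares conditions outcome-by-outcome with a Welch
(unequal-variance) two-sided t-test; the plain "t-test" leaves the variant
open and Welch is the safer default — at the effect sizes involved the
conclusions are insensitive to the choice. Per-condition descriptives report
the normal-theory 95% half-width $z_{0.975}\,s/\sqrt{n}$, which reproduces
the published CI columns exactly. `percent_change(baseline, treated)` is
always relative to the unaided baseline; note that exchanging the arguments
inverts the ratio rather than flipping the sign.

`sample_size_auc()` finds the smallest equal per-group $n$ for which the
two-sided z-test of an AUC against a null value reaches the requested power,
with the Hanley–McNeil variance ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$)
evaluated under both hypotheses. For $\alpha = 0.05$, $\beta = 0.20$,
$A_1 = 0.80$ vs $A_0 = 0.50$ this gives **14 positive + 14 negative cases**;
commercial calculators that report 13 + 13 for the same inputs use a
slightly different variance or rounding convention, and we deliberately do
not add ad-hoc constants to force agreement.

## The synthetic study generator

`sim_config()` fixes the study conditions once; `simulate_study()` threads
one master seed through per-stage sub-streams, so a bundle is byte-identical
for a given (config, seed) and the caller's RNG state is untouched.

* **Composition.** Six per-pathology cohorts of 500 positive + 1000 negative
  images (one lesion per positive image by default; a multi-label switch
  exists but is off). Evaluating each pathology within its own cohort is
  what gives the exact 500/1000 row sums of the enriched design.
* **Lesions.** Log-uniform side lengths in [32, 256] px on a 1024×1024
  frame, uniform placement — plausible relative lesion scales for CXR signs,
  with no attempt at anatomical realism.
* **Detectors.** Five models at per-model sensitivity 0.85: independent
  detection puts the 3-of-5 ensemble at
  $\sum_{k\ge3}\binom{5}{k}0.85^k 0.15^{5-k} \approx 0.973$, the upper range
  observed for such tools. A co-detection correlation knob (shared
  per-lesion difficulty, Gaussian copula) exists, default 0. Scores are
  Beta(8, 2) for true and Beta(2, 5) for false detections, giving realistic
  score separation. Localization jitter is Gaussian per corner, clipped so
  the detected box keeps the lesion centre pixel — detectors that fire on a
  lesion localize it, and jittered copies of one lesion always share a
  pixel.
* **False positives** come from independent Poisson clutter (0.15 per image
  per model) *and* a shared per-image distractor (prevalence 0.15) that each
  model flags with probability 0.8. The distractor is essential: three
  independent uniform boxes virtually never co-localize, so without shared
  structure a 3-of-5 vote would drive the image-level false-positive rate to
  zero, which real ensembles (image-level FPR 11–21%) clearly do not show.
* **Annotators.** Jitter sd 4 px with the same centre-containment clipping;
  miss and spurious probabilities default to 0 and 0.01. The reference
  panel is treated as exhaustive on the designed lesions, so the consensus
  recovers the designed composition exactly — the conservation the enriched
  design states. Nonzero miss rates are exercised explicitly in tests,
  where the 2-of-3 loss rate matches the closed form $3p^2(1-p)+p^3$.
* **Readers.** 900 images with per-pathology positive counts
  (77/60/32/16/37/43 — the published per-anomaly counts, whose sum of 265
  slightly exceeds the published total of 260 abnormal images; we follow the
  per-anomaly counts), split into two 450-image sessions. Each reader draws
  a condition-level operating point (unaided 0.769/0.946, aided
  0.857/0.974) with across-reader spread 0.02/0.01, a mean reading time from
  the condition distribution (22.9 ± 2.3 s unaided, 14.7 ± 1.3 s aided) and
  log-normal per-image times (CV 0.3). Confidences are drawn conditionally
  on the call (Beta(8, 2) vs Beta(2, 8)), so reader AUC is defined but is a
  consequence of the operating point rather than an independent dial.
* **Metadata.** Age N(49.9, 23) truncated at 0, 54.5% female, manufacturer
  shares 17/11/38/28/6% across five vendors.

### What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis assumes —
composition, co-localization, score separation, operating points, reading
times — not radiographs. Parameter-recovery tests therefore validate the
estimators and the pipeline plumbing, and the closed-form checks validate
the arithmetic; they say nothing about how any real detector performs on
real images. Conversely, the exact checks against the bundled published
tables validate every derivable number in those tables without access to
the underlying image-level data.

Against-reader recovery uses tolerances derived from the simulation's own
sampling structure (across-reader trait spread plus per-pathology binomial
noise at the study's small per-pathology case counts, e.g. 8 cardiomegaly
positives per session). The published across-reader SD of 0.02 for
sensitivity is smaller than the binomial noise those case counts imply, so
it is used as the trait spread, not as a recovery tolerance.

## Numerical choices

* Rounding of averaged boxes: half-up (`floor(x + 0.5)`), not banker's.
* Vote and consensus tie-breaks are total orders (score, then model id /
  annotator overlap, then lexicographic corners) so outputs are permutation
  invariant.
* Connected components use a small union-find over the pairwise overlap
  matrix; groups are per image and pathology and rarely exceed a dozen
  boxes.
* Degenerate inputs: empty detection lists vote to empty output; a
  pathology without both classes fails calibration loudly, naming the
  pathology; zero denominators yield `NA` metrics with warnings; constant
  reader outcomes yield `NA` t-statistics rather than errors.
* Problem sizes: the default end-to-end study (9000 standalone images,
  48,600 reader records) simulates and evaluates in well under a minute on
  one CPU, so tests run it once and share the result.

## Limitations

* No lesion-level (FROC/mAP) evaluation, weighted-box fusion or
  non-maximum-suppression variants: the image-level rule is the scope.
* No correlated-MRMC variance modelling (Obuchowski–Rockette,
  Dorfman–Berbaum–Metz); conditions are compared with plain Welch t-tests
  on per-reader summaries.
* The generator places boxes geometrically, not anatomically, and renders
  no pixels; DICOM is deliberately not parsed — only detection and
  annotation geometry enter the pipeline.
* Annotator-skill modelling (latent-truth label fusion) and adjudication
  workflows are out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_positive_per_label = 50, n_negative_per_label = 100)
bundle <- simulate_study(cfg, seed = 7)
res <- evaluate_standalone(bundle)
res$counts
summary(res$panel)
mrmc_summary(bundle$reader$records, bundle$reader$truth)
```
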