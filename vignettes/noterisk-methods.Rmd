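---
title: "Methods: violence risk assessment from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: violence risk assessment from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(noterisk)
```

## The prediction problem

Each analysis unit is one inpatient admission to a psychiatric ward. The
predictor is the text a clinical team produced *before the prediction
moment*: all psychiatrist and nurse notes from 28 days before admission
through the first 24 hours, concatenated into one document. The outcome is
whether at least one violent incident — verbal or physical aggression
directed at another person — is reported in the window from 24 hours to 28
days after admission start. Incidents in the first 24 hours are excluded
from the outcome (they precede any realistic intervention window and
overlap the predictor window); self-harm, substance use, sexual
intimidation and vandalism never qualify. Incident severity (SOAS-R, an
integer score on 1–22) is carried through the data model but plays no role
in labelling.

Admissions are not independent: the same patient may be admitted
repeatedly, and episodes separated by a short absence (at most 14 days,
boundary inclusive) are administratively distinct but clinically one
admission, so they are merged before anything else happens. Admissions with
fewer than 100 words of documentation after the first 24 hours are dropped:
with essentially no follow-up notes, the absence of an incident report
cannot be distinguished from the absence of observation. Whether that
100-word rule should instead count predictor-window words is genuinely
ambiguous; we default to post-24-hour words and expose the alternative via
`build_cohort(count_window = "predictor")`.

A single tokenizer (lowercase, punctuation to whitespace, numerals kept) is
shared by the word-count rules, the embedding, and the term screen, so
"word" means the same thing in every stage.

## Document representation

Documents are embedded with paragraph vectors trained by negative sampling,
implemented in C++ in this package (distributed bag-of-words by default,
distributed memory with mean-of-context available). Training is
unsupervised and never reads outcomes, so the embedding corpus may be — and
ideally is — larger than the analysis cohort. Defaults follow the original
paragraph-vector literature without task-specific tuning: 300 dimensions,
context window 5, 20 epochs, minimum term count 5, 5 negative samples,
learning rate decaying linearly from 0.025 to 1e-4. All are exposed in
`embedding_config()`. For desk-scale synthetic experiments we use smaller
settings (dimension 16–32, 4–8 epochs, minimum count 3), which recover
planted signal comfortably at a few hundred admissions.

Two numerical choices matter for reproducibility. First, training and
inference are single-threaded with an internal xorshift RNG seeded from the
configuration, so identical inputs give bit-identical vectors. Second,
vectors for *all* analysis documents — including those seen in training —
are produced by the same inference path (fresh document vector trained
against frozen word matrices), so train-fold and test-fold vectors are
exchangeable by construction. A document with no in-vocabulary tokens
yields its random inference prior and a warning; it stays in the pipeline
rather than silently disappearing.

## Classifier and operating point

Scores come from a support vector machine with radial kernel (libsvm via
`e1071`), fit on vectors z-scored with training-fold statistics only.
Hyperparameters are selected from a grid — cost in {0.1, 1, 10, 100},
kernel width in {1/dimension, 0.001, 0.01, 0.1} — by inner cross-validated
AUC. No class weighting is applied; the heavy class imbalance (≈ 9%
positives) is handled at the operating point instead. The reported
threshold minimizes |FP − FN| over all cut points of the pooled
out-of-fold scores, ties broken toward fewer false positives. This
balancing rule is a deliberate reading of the near-equality of false
positives and false negatives that the approach is meant to exhibit; it is
not the only defensible operating point, and `select_threshold()` is a
separate, replaceable step.

## Validation design

Outer validation is 5-fold cross-validation with *patient-grouped* folds:
all admissions of a patient share a fold, so a model never scores an
admission of a patient it has already seen (the test suite quantifies the
leakage this prevents: with near-duplicate documents per patient, ungrouped
CV inflates AUC far above the grouped design). Inner hyperparameter
selection uses 5 patient-grouped folds of the outer-training set; 5 inner
folds is our choice, as the inner k is otherwise unspecified.

Two AUC summaries are reported side by side. The fold-mean AUC averages the
five outer-fold AUCs and is the headline number. The pooled AUC treats the
union of out-of-fold scores as one vector; it is the only single-vector
object to which DeLong's placement-value variance estimator applies, so the
standard error and 95% CI are attached to it. The two can diverge: SVM
decision values are not calibrated across folds, and pooling scores with
fold-specific scales can rank a high-scoring negative from one fold above a
low-scoring positive from another. A large gap between the two is a
diagnostic for score-scale heterogeneity, not a bug in either number.

AUC differences use DeLong's method: paired (with the placement-value
covariance) when two models score the identical admissions, unpaired
otherwise. We refer the unpaired statistic to the normal distribution; the
pROC implementation refers the same statistic to a t distribution with
Welch–Satterthwaite degrees of freedom, a difference that is immaterial at
cohort sizes in the thousands but visible in small simulations. Sensitivity
and specificity carry Wilson intervals and the relative risk a Katz
log-scale interval; these are standard approximations, stated as such
because the upstream method for pooled-metric CIs is not fully specified.

Subgroup analyses split the evaluated admissions disjointly: by length of
stay (cutoff: cohort median) for short vs long admissions, and by the day
of the first qualifying incident (cutoff: 14 days) for early vs late
violence. Outcome-negative admissions carry no incident day; we allocate
them to the two timing subgroups at random (seeded), in proportion to the
subgroup positive counts, which keeps the subgroups disjoint and their
prevalence comparable. This allocation is our design choice; the original
subgroup definitions are not available.

Transfer evaluation freezes everything learned at the source site — the
embedding space, the feature standardization, the classifier, the
threshold — and applies it unchanged to the target site, with a paired
DeLong comparison against the target's internal cross-validated scores on
the identical admissions.

## The synthetic corpus generator

The generator exists so that every stage above is testable against known
ground truth. It emulates the *statistical structure* of two real
psychiatric cohorts — admission and patient counts (readmissions via
1 + Poisson(rate − 1)), outcome prevalence (9.1% / 7.7%), lognormal length
of stay (median 16 / 15 days, IQR-matched spread), lognormal note lengths,
incident-timing fractions (68.4% / 48.8% of incidents in the first 4 weeks;
9.4% / 6.4% in the first 24 hours), a diagnosis mixture, and SOAS-R
severities (discrete triangular on 1–22, mode 12) — while notes themselves
are synthetic token streams: a Zipf-distributed background vocabulary into
which signal terms are injected per note with probability
`plogis(qlogis(base_rate) + log_odds × outcome)`. Site pairs share the
background vocabulary; each signal term is replaced by a site-local synonym
with probability `site_shift`, emulating cross-site vocabulary drift with
preserved meaning.

Construction details worth knowing:

* Outcomes are drawn first (exact Bernoulli prevalence); each positive
  admission is guaranteed one qualifying violent incident, and its length
  of stay is resampled to exceed 1.5 days so the outcome window intersects
  the admission (a negligible distortion of the stay distribution).
* Remaining incidents are attached to admissions proportionally to (capped)
  length of stay and placed into timing strata by deterministic count
  allocation, so the site-level timing fractions match the configured ones;
  when too few long admissions exist, the after-4-week stratum spills into
  the 4-week stratum.
* Under-documented admissions (the ones the cohort stage must exclude) are
  planted in a configured exact number.
* Notes are not natural language. Passing tests demonstrate that the
  pipeline recovers distributional term-level signal under the configured
  noise; they say nothing about tokenization subtleties, negation, spelling
  variation, or discourse structure in real clinical text.
* Note length and outcome are independent by default, as no joint
  distribution is specified for the real data; any documentation-intensity
  signal present in real notes is therefore absent here.

`site1_profile()` / `site2_profile()` carry the full-scale parameters;
`demo_profile()` (≈ 300–450 patients, ≈ 430–650 admissions, 40-word median
notes, 800-term vocabulary) is the desk-scale profile used throughout the
test suite and the acceptance script, chosen so the complete suite runs in
a couple of minutes on one CPU while leaving all rates at their full-scale
values.

## Seeds and determinism

Every run hangs off one integer seed. Stages derive child seeds through a
fixed multiplicative generator (`derive_seeds()`), so corpus generation,
fold assignment, embedding, classifier and bootstrap streams are
independent: changing one stage's code cannot silently reshuffle another's
randomness. Generation, embedding, fitting and inference are bit-exactly
reproducible for a fixed seed.

## Known limitations

* The FP/FN-balancing threshold rule is an interpretation; institutions
  weighing false negatives more heavily should replace it.
* DeLong inference is attached to pooled out-of-fold predictions; treating
  pooled CV scores as one sample is itself an approximation whose optimism
  under fold heterogeneity is documented above.
* MCC confidence intervals use a 2000-replicate nonparametric bootstrap; at
  very low term prevalence the percentile interval can be degenerate.
* The generator plants signal only in predictor-window notes and only as
  term presence; it cannot validate models that exploit word order beyond
  what paragraph vectors capture from synthetic streams.
* Real-data performance claims are outside what this package can establish:
  its evidence is oracle equivalence of the statistics and parameter
  recovery on synthetic corpora.
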