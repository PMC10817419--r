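---
title: "Classifying otitis from free-text pediatric notes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying otitis from free-text pediatric notes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otitext)
```

## The problem

Italian family pediatricians are not required to code outpatient
diagnoses with ICD codes, so much of what is known about common
infections such as otitis media lives in free-text diagnosis and note
fields. Surveillance of otitis epidemiology from such records requires
classifying every otitis-relevant visit into one of six mutually
exclusive classes, in this fixed order shared by every component of the
package (label vectors, network output neurons, confusion-matrix axes):

1. `no_otitis` — the record matched an otitis-like search string but is
   not an otitis case (negated mentions, other doctors' diagnoses,
   `-oma` nouns such as *ematoma*);
2. `otitis_not_media` — otitis that is not otitis media (e.g. *otite
   esterna*);
3. `om_not_acute` — otitis media without the acute qualifier (serous,
   catarrhal, chronic);
4. `aom` — acute otitis media without perforation or recurrence, the
   modal class (44–48% of screened records);
5. `aom_perforation` — AOM with tympanic-membrane perforation;
6. `aom_recurrent` — recurrent AOM.

Manual classification at database scale is infeasible, so the package
implements a seeded, testable re-creation of a deep-learning pipeline
for this task: corpus screening, text normalization and embedding, five
neural text-classification architectures, a logit-averaging ensemble,
and balanced evaluation metrics. Real pediatric records of this kind are
protected by data-privacy law and cannot ship with the package, so a
synthetic corpus generator stands in for them wherever data are needed.

## The synthetic corpus generator

`generate_corpus()` emulates the *statistical* and *linguistic*
structure that the analysis relies on, not realistic Italian prose:

* **Exact class composition.** Class counts are fixed by
  largest-remainder (Hamilton) apportionment of `class_proportions`
  rather than multinomial sampling, so tests can assert them exactly.
  The default proportions (0.19, 0.19, 0.125, 0.45, 0.035, 0.01) mirror
  the gold-standard composition of a published 880-record otitis test
  set, with AOM modal at 45%.
* **Demographics.** New patients are male with probability 0.522; a
  visit reuses an existing patient of its pediatrician with probability
  0.1, giving slightly more visits than children, as in real extracts.
* **Pediatrician clustering.** Per-pediatrician visit shares are drawn
  from a symmetric Dirichlet with concentration 5: uneven enough that
  proportion-preserving splitting is non-trivial, concentrated enough
  that every pediatrician is plausibly active.
* **Dates.** Uniform over 2004-01-01 to 2017-08-23, so a historical
  (training) versus later (validation/test) division is always possible.
* **Text.** Each record has three fields in fixed order — `diagnosis`,
  `notes`, `prescriptions`. The diagnosis carries a class keyword from
  the lexicon; notes carry background vocabulary plus a temperature
  (`febbre 38,5`); prescriptions carry a drug with a dose (`amoxicillina
  500 mg per 7 giorni`), so numeric normalization is always exercised.
* **Confounders**, at configurable rates, reproduce the documented error
  sources of free-text screening: negated otitis mentions and
  other-doctor references injected into `no_otitis` records, atypical
  perforation phrasing (*otorrea*, *timpano lacerato*) replacing the
  canonical keyword of `aom_perforation` records, and single-edit typos
  (deletion, substitution, adjacent transposition) on keywords.
* **Recurrent AOM** records take, with equal probability, either an
  explicit statement branch (*otite ricorrente*) or an episode-history
  branch whose machine-readable `episode_dates` satisfy the recurrence
  rule below — so both halves of the clinical definition are exercised.

At all-zero confounder rates the corpus is *learnable by construction*:
`keyword_oracle()` — longest-matching-phrase lookup — recovers every
gold label, which is the baseline the neural models are measured
against in the package's end-to-end tests. What passing those tests
shows is that the pipeline can recover a clean keyword-driven signal;
it does not show performance on real clinical prose, whose lexical
variety, negation patterns, and class overlap are far richer than any
generator of this kind.

The note-length default (10–120 tokens) is a configuration choice; the
true length distribution of the original records is not public.

## Record selection

Records enter the pipeline through a substring/regex search over each
text field separately (`select_records()`), mirroring search-string
screening of a primary-care database. The exact original search string
is not public; the default pattern covers the stems `otit`, `oma`
(which deliberately also catches `-oma` nouns — the origin of the
`no_otitis` class), perforation stems (`timpan`, `otorrea`, `perfor`),
and one-edit misspellings of *otite*. It is fully overridable via
`compile_search_pattern()` or a YAML file. Matching is per-field to
avoid spurious matches across field boundaries; whether the original
string used word-boundary anchors is unknown, so the default does not.

## Preprocessing and embeddings

Text fields are merged into one token stream with a `SEP` token between
consecutive non-empty fields; numeric tokens (integers, decimals with
comma or point — not mixed alphanumerics like `b12`) become `NUM`;
tokenization lowercases and drops punctuation except decimal separators
inside numbers. The vocabulary reserves `PAD` (index 0), `OOV`, `SEP`,
`NUM`, then orders tokens by descending frequency with lexicographic
tie-breaks. Records are encoded to a fixed length `L` (default 1000):
post-padded with `PAD`, head-truncated when longer — the diagnosis
field leads the merged order, so the head carries the diagnostic
signal.

Word vectors come from an in-package skip-gram with negative sampling
(`train_embeddings()`, default 300 dimensions): all window pairs are
positives, five unigram^(3/4) negatives each, vectorized minibatch SGD
with linear learning-rate decay. Two numerical choices matter:

* Duplicate-index gradient contributions within a batch are *averaged*,
  not summed. Very frequent tokens (`SEP`, `NUM`) can occur hundreds of
  times in a 512-pair batch; summed updates scale with that count and
  destabilize the table, while averaging keeps the per-token step size
  bounded regardless of batch composition.
* Reserved rows follow fixed conventions: `PAD` is the zero vector and
  is excluded from supervised gradient updates; `OOV` is a small random
  vector with components in [−0.01, 0.01].

Subword n-grams are deliberately out of scope: the embedding only
initializes the supervised models, which fine-tune it.

## The five architectures

All models share one skeleton: embedding layer (initialized from the
skip-gram table, then trainable) → batch normalization → dropout 0.2 →
zero or more convolutional stages → global pooling over positions →
a six-unit linear output whose logits are softmaxed at prediction time.
Every hidden layer is followed by batch normalization and then dropout,
in that order. The variants:

| id | name | convolutional stages |
|----|------|----------------------|
| 0 | simple embedding | none (global *average* pooling) |
| 1 | single kernel CNN | one conv layer (width 5, 128 filters) |
| 2 | sequential single kernel CNN | two conv layers in sequence (widths 5, 3) |
| 3 | multiple parallel kernel CNN | one parallel concatenation (widths 3/4/5, 64 filters each) |
| 4 | deep multiple parallel kernel CNN | two stacked parallel concatenations |

Kernel widths, filter counts, activations, and pooling are not pinned
down by the published description of this model family; the defaults
follow standard multi-kernel text-convolution practice (ReLU
activations, global max pooling for architectures 1–4) and are fully
configurable through `architecture_spec()`. Convolutions use 'same'
zero padding so parallel branches of different widths concatenate along
the channel axis and stack cleanly.

Training (`train_model()`) minimizes the batch-averaged cross-entropy
with Adam (learning rate 1e-3, standard betas — the original epoch
count and stopping rule are unstated; the package defaults to at most
50 epochs with patience-5 early stopping on a monitor set's loss).
Batch size (8 or 16) and hidden dropout (0.5 or 0.7) form the default
tuning grid. All forward/backward computation is vectorized base-R
matrix code (im2col convolutions); a numerical gradient check across
all five architectures is part of the test suite. Runs are
deterministic given the seed under single-threaded execution.

### Two-stage development and the ensemble

`two_stage_develop()` reproduces the tuning protocol: stage 1 trains
every grid point per architecture and selects by validation accuracy;
stage 2 retrains the winning configuration from scratch on the training
set plus a seeded 300-record sample of the validation set, and the
validation set arbitrates between the stage-1 and stage-2 fits. The
ensemble (`ensemble_predict()`) excludes the simple-embedding benchmark
and averages members' *pre-softmax logits* element-wise, applies
softmax once, and takes the arg-max (lowest index on ties). Averaging
before the softmax is the reading consistent with the published
description of the ensemble; since softmax is monotone, the predicted
class equals the arg-max of the mean logits, which the tests assert.

## Data splitting

`stratified_split()` draws the three sets so that each set's
per-pediatrician record counts equal the largest-remainder quota of the
pediatricians' full-corpus shares; training comes strictly before the
historical cutoff (default 2008-01-01), validation and test are drawn
disjointly from one seeded permutation of the later pool. Every set
must reach `min_records_per_set` (default 500). Coverage (≥1 record per
pediatrician) applies only where a pediatrician has eligible records in
the period — universal coverage was not achieved in the original
three-set design either. When a pediatrician's eligible records fall
short of their quota, the shortfall is redistributed to the largest
remaining pediatricians; infeasible requests fail with the binding
constraint named.

## Gold-standard support

`classify_recurrent()` implements the recurrence definition: at least 3
AOM episodes in any 183-day window or at least 4 in any 365-day window
(windows are fixed day counts, anchored at episode dates, closed
intervals), or an explicit clinician statement. The test suite checks
it against an exhaustive oracle that slides each window over every
candidate start day. Six months = 183 days and twelve months = 365 days
are package conventions; whether the original rule used calendar months
is unknown.

`adjudicate()` resolves dual-reviewer labels (third-reviewer label
wherever the two disagree), and `weighted_cohens_kappa()` quantifies
inter-rater agreement with linear (default), quadratic, or unweighted
disagreement weights over the canonical class order — which weighting
the original agreement figure used is unstated, hence configurable. A
genuinely degenerate kappa (zero chance disagreement, i.e. both raters
constant and equal) returns 0 with a warning rather than failing.

## Evaluation metrics

From a 6×6 confusion matrix (rows predicted, columns gold),
`metrics_report()` computes accuracy, balanced (macro) precision and
recall, and balanced F1. **Balanced F1 is the harmonic mean of balanced
precision and balanced recall**, not the macro-average of per-class F1
scores: on the published otitis results this package re-implements, the
harmonic-mean formula reproduces every per-architecture F1 from its own
precision/recall pair, while macro-F1 does not (95.32 vs the published
95.48 on the ensemble row — both numbers are recomputed in the test
suite). Macro-F1 is still reported as a secondary column. A class never
predicted (empty row) or absent from the gold standard (empty column)
contributes 0 to the balanced mean, with a warning — a conservative,
explicit convention. Percentages print at two decimals with half-up
rounding, matching the published tables; one consequence, asserted in
the tests, is that a published F1 recomputed from *rounded* precision
and recall can differ from the printed value by up to one unit in the
last digit.

## Problem sizes used by the packaged demonstrations

The full published configuration (300-dimensional embeddings,
1000-token encodings, 4926-record training set) is hours of CPU work;
the package's self-contained demonstrations use
`demo_run_config()`: 2000 visits over 20 pediatricians, 16-dimensional
embeddings, encoded length 48 (demo notes are 8–30 tokens plus
prescription and separators, so nothing is truncated), filter counts
24/16, one grid point (batch 16, dropout 0.5), at most 10 epochs with
patience-3 early stopping, and a 900/500/400 split at a 2011-01-01
cutoff (uniform dates leave roughly half the corpus historical at that
cutoff, giving both temporal pools a margin). On a noise-free corpus
this configuration reaches ensemble test accuracy at or near 1.0 in
roughly two minutes per seed on one CPU; every one of these sizes is an
ordinary function argument, so the full-scale configuration is a
parameter change, not a code change.

## Known limitations

* The synthetic corpus demonstrates pipeline correctness, not clinical
  performance; its lexical signal is far cleaner than real notes.
* The skip-gram is word-level only; no subword information, so typo
  variants are distinct vocabulary entries (or OOV).
* Patient-level leakage across sets is not controlled beyond
  pediatrician stratification, matching the original design's stated
  sampling rule.
* The original architectures' kernel geometry is unpublished; the
  defaults here are conventional, not a reconstruction.
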