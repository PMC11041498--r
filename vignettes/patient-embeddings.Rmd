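---
title: "Patient embeddings from claims diagnosis codes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient embeddings from claims diagnosis codes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patvec)
```

## The problem

Ambulatory claims data describe each patient as a string of 5-digit ICD-10
diagnosis codes billed quarter by quarter. Any regression or classification
task on such data first needs a numerical representation of the diagnosis
profile. The standard choice — binary encoding of a subset of common codes
— treats codes as unrelated indicator variables, discards everything
outside the subset, and leaves all interactions to the downstream learner.

`patvec` implements the alternative: a self-supervised embedding in the
Doc2Vec family. Each diagnosis code is treated as a *word* and a patient's
quarter-ordered code sequence as a *document*. Training a shallow
predictive network over these documents yields, jointly,

* **code vectors** (a Word2Vec-style embedding of the ICD vocabulary), and
* **patient vectors** (the document embeddings), a dense M-dimensional
  summary of the complete diagnosis profile.

## The model

The network is a single hidden layer whose parameters *are* the
embeddings. For a document $d$ with tokens $w_1,\dots,w_n$ and a position
$t$, the two training modes are:

* **Distributed memory (DM).** The hidden activation is the arithmetic
  mean of the document vector and the code vectors inside the context
  window: $h = \frac{1}{k}\bigl(v_d + \sum_{c \in \mathcal{C}_t}
  v_{w_c}\bigr)$, and $h$ predicts the target token $w_t$. The mean (rather
  than a sum or concatenation) keeps the scale of $h$ independent of the
  window width; the gradient is distributed as $\partial h / \partial v = 1/k$
  to every contributor.
* **Distributed bag of words (DBOW).** The document vector alone predicts
  each token of its document; interleaved skip-gram updates (each code
  predicting its in-window neighbours) train the code vectors at the same
  time, so DBOW also yields a usable code embedding.

Two output-layer approximations avoid the full softmax over the
vocabulary, and can be active separately or together (losses are summed):

* **Negative sampling.** Logistic loss over the true target plus
  `negative` draws from the noise distribution
  $p(w) \propto \mathrm{count}(w)^{\lambda}$, with the smoothing exponent
  $\lambda$ a tunable in $[-5, 5]$ (negative values oversample rare
  codes). Draws equal to the target are rejected and redrawn.
* **Hierarchical softmax.** A binary Huffman code over token counts; the
  loss is the sum of logistic path losses over the $O(\log V)$ internal
  nodes. Ties during tree construction are broken deterministically
  (leaf before internal node at equal count), so the tree is reproducible.

The learning rate decays linearly from `alpha` to `alpha/100` across all
scheduled token positions (`epochs` times the corpus length). The decay
floor is a package choice — only the initial rate is standard — and the
position count is taken *before* frequency downsampling so that the
schedule does not depend on random drops. A per-position random reduction
of the window (uniform on `1..window`) is applied by default, matching
reference implementations of this model family; `reduce_window = FALSE`
disables it, which the oracle tests use.

Initialization: document and code vectors uniform on $[-0.5/M, 0.5/M]$,
output layers (context and Huffman-node weights) zero, all drawn from a
seeded private stream. Training is single-threaded and bit-reproducible
for a fixed seed.

**Unseen patients.** Held-out patients are embedded by *inference*: all
trained weights are frozen, a fresh document vector is initialized from
the seeded stream and updated for `epochs` passes over the document with
the same loss and decay schedule. This is how every calibration,
validation or test patient obtains its vector — they are never part of
vectorization training.

## From claims to documents

Claims carry no ordering below the quarter: entries are grouped by billing
case and place of treatment, groups are sorted by quarter, and both groups
within a quarter and codes within a group are permuted uniformly at
random. Non-confirmed diagnoses are excluded, and a patient must retain at
least one confirmed entry to stay in the cohort. Entries are first put in
a canonical sort order so that documents depend only on content and seed,
not on row order.

Whether the within-quarter shuffle should be fixed once or redrawn every
epoch is genuinely open; the package redraws it per epoch by default
(treating the shuffle as part of sequence generation) and offers
`static_documents = TRUE` to freeze one permutation for strict
reproducibility studies.

The vocabulary keeps codes seen at least `min_count` times. The
conventional threshold on population-scale claims is 100 (it also serves
anonymization); synthetic desk-scale corpora use a smaller value (the
studies below use 5) since otherwise most of a small corpus would be
discarded. The threshold is a parameter, never hard-coded.

## Calibration: the 16-measure total score

A representation is judged by what it enables. Four outcomes — number of
cases, emergency utilization, age, gender — are each predicted with two
learners (linear/logistic regression and gradient-boosted trees), and two
metrics are recorded per task: $R^2$ and CPM for the real-valued outcomes,
AUROC and AUPRC for the binary ones. CPM is one minus the relative mean
absolute error,

$$\mathrm{CPM} = 1 - \frac{\sum_i |y_i - \hat y_i|}{\sum_i |y_i - \bar y|},$$

with the evaluation-set mean as reference (a median variant is available;
the mean is the documented default because the denominator choice is not
standardized). AUPRC uses the step-integral (average-precision)
convention, not the trapezoid — the two differ on coarse curves, so the
convention matters and is fixed here.

The 16 measures of a candidate representation are divided by the
same-named measures of the top-100 binary baseline and averaged: the
**total score**, with the baseline at exactly 1 by construction. $R^2$ and
CPM can be negative in practice although all measures are nominally in
$(0,1]$; measures are clamped to $[10^{-6}, 1]$ before ratio formation,
and a *reference* measure at the clamp floor is an error rather than a
silent near-zero division — a degenerate reference makes ratios
meaningless, and the remedy is a better-conditioned reference (larger
evaluation sample), not a guard constant.

Gradient-boosted trees are deliberately *untuned* in calibration (they
play the out-of-the-box role; only the separate drug-cost task offers
tuning). The fixed setting — 100 rounds, learning rate 0.05, depth 3,
`min_child_weight` 10, 80% row subsampling — is sized for cohorts of a few
thousand patients: with ~1,000 training rows and 100 binary features,
deep large-data defaults overfit the count outcome and destabilize the
sign of the reference measures. Train/validation membership is assigned by
hashing patient ids, so splits are reproducible and row-order invariant.

## The synthetic cohort generator

Real ambulatory claims cannot be shipped; the generator produces cohorts
with the structural features the pipeline depends on:

* quarterly entries grouped into cases at places of treatment;
* a long-tailed code frequency distribution (power-law within pools);
* 1–3 latent morbidity clusters per patient (Zipf-weighted, so clusters
  overlap and many patients are not cleanly clusterable);
* outcomes coupled to a log-normal latent severity: number of cases
  (negative-binomial, mean increasing in severity), emergency (logit
  increasing in severity), drug cost (zero-inflated log-normal), plus
  disease-dependent age and gender with one almost-exclusively-female
  pregnancy-like cluster;
* a small fraction (5%) of non-confirmed entries to exercise the
  inclusion filter.

Marginal targets are soft and chosen to resemble published claims-cohort
descriptions: ~18% emergency rate, ~21% zero drug cost, ~30 entries per
patient over three years. Two quantities have exact closed forms used as
Monte-Carlo oracles: the per-entry code distribution (by enumerating
latent disease sets) and the population emergency marginal (by integrating
the severity logit over the latent mixture).

All randomness flows from one integer seed through per-patient hashed
substreams, so cohorts are order-independent and byte-reproducible.

What the generator does *not* emulate: real ICD-10-GM semantics,
comorbidity networks beyond overlapping clusters, temporal disease
progression, coding-practice artefacts. Tests passing on synthetic
cohorts therefore demonstrate that the machinery is correct and that the
embedding recovers planted structure — not that any particular performance
level transfers to real claims.

## Study conditions

The bundled studies run at sizes a single CPU handles in minutes, chosen
once and kept fixed:

* **Low-dimension comparison** (embedding vs equal-size baseline):
  5,000 patients, 6 latent diseases, M = 16 embedding vs top-16 binary,
  both normalized by the top-100 reference, profiles over the full
  three-year window. 16 dimensions must summarize ~120 codes, the regime
  where compression should pay off.
* **Dropout robustness:** 6,000 patients, M = 100 vs top-100, evaluation
  profiles restricted to the last calendar year (the usual design: train
  the vectorization on full history, calibrate on current-year profiles).
  The restriction matters: over three years a patient's common codes
  recur, so presence bits barely react to dropout; one-year profiles are
  where missing codes actually hurt. Dropout is applied to the
  evaluation-side profiles by default (`dropout_training = TRUE` also
  perturbs the training claims; the right choice is ambiguous and both are
  provided). Drop counts use round-half-up with at least one code kept.
* Cohort sizes below ~4,000 leave the top-100 ordinary-least-squares
  reference measures for the count outcome near zero (sign-unstable),
  which the total score rejects by design; hence the sizes above.

## Hyperparameter search

`patvec_search()` maximizes any objective over the standard grid (window
1–10, epochs 1–20, negative 0–20, exponent −5..5, DM/DBOW, hierarchical
softmax on/off, log-uniform alpha 0.001–0.1; vector size, `min_count` and
downsampling held fixed). The default sampler is a tree-structured-Parzen
style rule: after a random start-up phase, candidates are drawn from a
Gaussian kernel density over the best quartile of completed trials and
ranked by the good/bad density ratio; booleans use smoothed Bernoulli
odds. A pre-drawn seeded random search is the fallback and is invariant
to evaluation order. Failing trials are logged and skipped. The trial
budget is a parameter; published analyses in this family do not report
theirs.

Downsampling defaults to off: on code corpora the most frequent codes
(hypertension-like chronic diagnoses) are exactly the signal carriers, and
discarding them is consistently detrimental.

## Numerical and degenerate-input choices

* Logistic arguments are clipped at ±30 before exponentiation (the
  gradient is numerically zero beyond).
* Noise draws equal to the target are rejected; a vocabulary of size 1
  cannot exclude and returns the single token.
* Documents empty after vocabulary filtering are flagged; `predict()`
  drops them and reports the ids in an attribute.
* Constant columns in code–dimension correlations yield 0 by convention.
* Ties in code ranking break lexicographically; Huffman ties prefer
  leaves; both choices exist purely for reproducibility.
* The projection and density-clustering backends are pluggable functions;
  the bundled defaults are PCA and a plain DBSCAN (noise label −1,
  neighbourhood radius from the 90th percentile of k-nearest-neighbour
  distances). Nonlinear manifold projections and hierarchical density
  clustering are drop-in replacements via the `method` argument —
  their internals are outside this package's scope.

## A small worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(sim_config(n_patients = 2000, seed = 11))
fit <- patvec(cohort, patvec_params(vector_size = 16, epochs = 5,
                                    min_count = 5, negative = 5,
                                    alpha = 0.025, window = 5))
fit
# embed held-out profiles, compare against binary baselines
study <- calibration_study(cohort, patvec_params(vector_size = 16,
                                                 epochs = 5, min_count = 5,
                                                 negative = 5),
                           ref_M = 100, eval_window = NULL, seed = 3)
study
```

## Known limitations

* Scores built from ratios of small reference measures are noisy;
  the total score is only as stable as its weakest reference measure.
* The engine holds the corpus and all matrices in memory and trains on a
  single thread; population-scale corpora are out of scope.
* The generator's outcome couplings are stand-ins. Published cohort tables
  report marginals only, so no test asserts agreement with any real
  cohort's joint distribution.
* Inference for a one-code patient is well-defined but weakly determined;
  vectors for very short documents should be interpreted cautiously.
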