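---
title: "Two-set literature ranking: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-set literature ranking: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litrank)
```

## The problem and the model

`litrank` addresses literature triage: a biologist has a set of genes or
abstracts embodying a phenomenon of interest (set A), optionally a
contrasting background (set B), and wants a query set of abstracts (set C)
ordered by relevance to A. Instead of a topic-specific pre-trained
classifier, a fresh model is trained per job from the user's own two sets,
so the definition of "interesting" is whatever the user's sets imply.

Each abstract is represented as a bag of dictionary keywords. A typed
dictionary maps surface forms to canonical term IDs (each term has exactly
one of nine types); tagging is case-insensitive, token-boundary-anchored,
longest-match and non-overlapping, and counts occurrences per canonical
term. The feature space is the union of terms seen in the A and B profiles
(V dimensions, ordered lexicographically for reproducibility), and each
abstract becomes the sparse count vector

$$x_j = \text{number of occurrences of keyword } j \text{ in the abstract.}$$

Counts are used raw — no tf-idf, no length normalization — because the
representation contract is occurrence counts and nothing more. Set C
vectors are restricted to the training vocabulary; an abstract with no
in-vocabulary keyword becomes a legal zero vector and is still scored (at
the intercept-only probability), since keyword-poor abstracts are data, not
errors.

The classifier is an L2-regularized logistic regression with an unpenalized
intercept:

$$\min_{w, b}\; \tfrac{1}{2}\lVert w\rVert^2 \;+\; C \sum_i \log\!\big(1 + e^{-y_i (w \cdot x_i + b)}\big),$$

whose fitted probability $P(A \mid x) = \sigma(b + w \cdot x)$ is the
ranking score. Scores are monotone in the linear decision value, so the
ranking is exactly the margin ordering. Assignment to set A requires a
score *strictly* greater than the threshold (default 0.5); a score exactly
at the threshold goes to B, the only reading consistent with assignment by
the opposite criterion.

## Penalty tuning

The penalty C is tuned in two stages under k-fold cross-validation
(default k = 5):

1. evaluate the eight points $C = 2^x$, $x = -3,\dots,4$;
2. if the training set is small (< 5,000 vectors), or moderate (< 10,000)
   with best first-stage accuracy below 80%, evaluate the fixed
   neighborhood row of the best exponent (e.g. $x = 2$ adds
   3.0, 3.5, 4.5, 5.0, 6.0). Refinement runs at most once — no recursion.

The chosen C maximizes cross-validated accuracy over every evaluated point,
with ties broken toward the smallest C: deterministic, and conservative in
the sense of preferring stronger regularization. The full trace is kept on
the fitted object (`fit$trace`, `plot(fit)`).

Fold assignment is not specified by the procedure's provenance, so a policy
had to be fixed: a seeded shuffle within each class followed by round-robin
dealing, i.e. label-stratified folds. Stratification stabilizes the small
training sets this tool is typically run with; the same seed (hence the
same folds) is used at every grid point so accuracies are comparable across
C. Two accuracies are reported: the cross-validated accuracy used for
selection, and a "test-set accuracy" from re-classifying the A∪B training
vectors with the final model — the latter is an optimistic, training-set
figure and is labelled as such.

## Numerical choices

* **Solver.** The ridge-logistic fit is delegated to `glmnet`
  (`alpha = 0`, `standardize = FALSE`, unpenalized intercept). The loss-side
  penalty C maps onto glmnet's per-observation scale as
  $\lambda = 1/(nC)$. The contract is the probability semantics of
  L2-regularized logistic regression, not bit-compatibility with any
  particular solver; exact probability calibration may differ from other
  implementations at the third decimal, which does not affect rankings.
* **Tolerance.** The recorded solver tolerance default is 0.1
  (`solver_config()`); the backend converges to much tighter precision
  (`thresh = 1e-10`), which only makes the optimum more exact.
* **Degenerate folds.** With stratified folds a single-class *training*
  split can only arise when a class has fewer members than folds; the fit
  then falls back to a constant predictor of the observed class. A
  single-class *final* training input is an error.
* **One-dimensional spaces.** The backend requires two columns; a V = 1
  space is padded with an all-zero column whose coefficient is discarded.
* **Ties in ranking.** Equal scores are ordered by ascending PMID — stable
  and reproducible. The A list is sorted by descending score; the B list
  ascending, so the most confidently-B abstracts lead it (the ordering of
  the B list is a genuinely open choice; this one makes both lists
  "most confident first").
* **Undefined ratios.** Precision or recall with a zero denominator is
  reported as `NA` ("undefined"), never coerced to 0, so extreme-threshold
  sweep points are not silently distorted. The MCC zero-denominator
  convention is the standard 0.
* **Dimensions.** Feature dimensions are 1-based, matching both R idiom and
  the conventional `label dim:count` sparse text export.

Other interpretation points settled here: ambiguous surface forms (one form,
several term IDs) credit *all* mapped terms per occurrence, since ambiguity
is preserved at input and the classifier can downweight noisy features;
counting is per canonical term with surface variants pooled; per-gene PMID
ordering follows link-table insertion order; duplicated abstracts become
repeated training vectors rather than being deduplicated; and the reported
"fraction correct" of a curated evaluation is emitted both as positive
predictive value and as overall accuracy, which near-coincide on the
benchmark arithmetic (162/186 ≈ 188/216 ≈ 0.87) but are distinct
quantities.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.5 | assignment to A requires score strictly above |
| `cutoff` | 0.85 | whole-index mode reports only scores above this (A) or below 1 − cutoff (B) |
| `input_cap` | 25,000 | per-input refusal limit, genes or abstracts |
| `folds` | 5 | cross-validation folds for tuning |
| `tolerance_e` | 0.1 | recorded solver termination tolerance |
| `mean_keywords` | 32 | generator's mean keywords per abstract, matching the average yield of dictionary-tagged abstracts |

The 0.85 cutoff applies only when set C defaulted to the whole index; an
explicit set C always returns the full ranked table.

## What the synthetic generator does and does not emulate

`generate_world()` produces a typed dictionary, two topic-conditioned
abstract populations (as raw text and as exact pre-tagged profiles),
gene→abstract link tables and ground-truth labels. Per abstract the keyword
count is Poisson(32 by default) and terms are drawn with replacement from
the topic's term distribution; term weights are Gamma draws (a Dirichlet up
to normalization) with a concentration knob. The separability parameter δ
is the fraction of topic-exclusive vocabulary: δ = 0 makes both topics one
identical distribution (nothing to learn; cross-validated accuracy sits at
chance), δ = 1 makes the vocabularies disjoint (a linear model recovers the
labels essentially perfectly). Gene links default to purity 1 (each
synthetic gene links only to its own topic's abstracts) with an impurity
knob for stress-testing expansion.

The generator deliberately does **not** produce realistic English prose,
multi-word surface forms (its surfaces are single unique tokens, so that
text-mode tagging and pre-tagged profiles agree exactly — multi-word and
ambiguous matching is exercised by dedicated dictionary fixtures instead),
keyword burstiness beyond Poisson sampling, or the correlated topic
structure of real Medline. Passing the recovery tests therefore shows the
pipeline is correct and well-calibrated on its own representational
assumptions, not that any particular precision is attainable on real
literature, where dictionary coverage and topic overlap dominate.

Test problem sizes were chosen to exercise the contracts at comfortable
margins: recovery runs use 200 training vectors per side with 200 held-out
abstracts on δ = 1 worlds and ten seeds of 100-per-side δ = 0 worlds for
the chance-level check; oracle-equivalence checks (tagging, vocabulary,
confusion counts) run on instances of at most a few hundred items where
brute-force enumeration is transparent.

## Known limitations

* No live identifier resolution: gene→PMID, Ensembl→Entrez and query→PMID
  mappings come from user-supplied flat files, and query inputs resolve only
  through a fixture table.
* The dictionary is user-supplied; tagging quality is bounded by its
  coverage. No disambiguation, abbreviation expansion or syntactic noun
  detection is attempted.
* Probability calibration inherits from the ridge-logistic fit; scores are
  comparable within a job, not across jobs with different training sets.
* Significance estimates (bootstrap/jackknife) are intentionally out of
  scope; the evaluation module reports point metrics and sweeps.
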