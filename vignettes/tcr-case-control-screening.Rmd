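---
title: "Case/control screening and classification of TCR-beta repertoires: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/control screening and classification of TCR-beta repertoires: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrscreen)
```

`tcrscreen` implements a diagnostic analysis for bulk TCR-beta repertoire
sequencing: given per-sample clonotype tables from diseased (case) and
healthy (control) donors, it asks whether disease status can be predicted
from (i) global repertoire diversity, (ii) the burden of disease-associated
public clonotypes, and (iii) the binary presence pattern of a screened
marker panel — and how small that panel can be made without losing
classification performance. This vignette records the models, the tunable
parameters, the numerical conventions, and the places where the design was
genuinely open.

## Clonotype identity

A clonotype is the triple (CDR3 amino-acid sequence, V gene, J gene),
canonicalized to the key `CDR3_V_J`. Allele suffixes (`*01`) are always
stripped; at the default `family` resolution the V gene number is also
stripped (`TRBV12-3*01` becomes `TRBV12`), because public clonotypes shared
across donors are reliably matched only at the family level, and family
labels are what marker panels in this setting are reported with. J genes
keep their gene number (`TRBJ1-1`): the J locus has no family substructure
worth collapsing. Rows whose CDR3 contains a stop codon (`*`) or that are
flagged non-productive are excluded by default ("productive uniques");
`productive_only = FALSE` disables this. Rows sharing a canonical key are
merged by summing template counts — a necessity, not a convenience, since
family-level collapsing maps distinct alleles onto one key.

Presence of a clonotype in a sample means its canonical key appears with
count >= 1 among the retained rows. No count threshold is applied: with
template counts spanning four orders of magnitude, any threshold would be
arbitrary, and the association test below is deliberately a presence test.

## Diversity indices

All indices are computed from count-derived frequencies
$p_i = c_i / \sum_j c_j$ and natural logarithms:

* Shannon $H' = -\sum_i p_i \ln p_i$ (nats), with $0 \ln 0 \equiv 0$.
* Simpson $\lambda = \sum_i p_i^2$ and inverse Simpson $1/\lambda$
  (the effective number of equally frequent clonotypes).
* Clonality $= 1 - H'/\ln n$, where $n$ is the number of unique
  clonotypes: 0 for a perfectly even repertoire, 1 for a monoclonal one.
* Hvj: the Shannon entropy of the count-weighted frequency distribution of
  distinct (V family, J gene) combinations. Weighting by template counts
  (rather than counting each clonotype once) keeps the index sensitive to
  clonal expansion, which is what it is meant to detect; the alternative
  clonotype-uniform weighting is a defensible reading but was not chosen.
* Singleton ratio $= n_1/(n-1)$, where $n_1$ is the number of clonotypes
  with template count exactly 1 — a proxy for the naive T-cell fraction.
  The $n-1$ denominator is the conventional printed form and can exceed 1
  (e.g. two singletons give 2/1); `denominator = "n"` switches to the plain
  proportion for users who prefer a bounded quantity.

Edge conventions: a single-clonotype repertoire has undefined clonality and
singleton ratio (division by $\ln 1$ or $n-1 = 0$); both return 0, the
no-information value. These conventions, and agreement of all six indices
with independently coded brute-force summations to 1e-12, are pinned by the
test suite.

## Association screening

For each clonotype key observed in at least one training sample, the 2x2
table (cases with / cases without / controls with / controls without) is
tested with Fisher's exact test, computed by direct hypergeometric
enumeration. The two-sided P-value sums the probabilities of all tables
with the observed margins whose probability does not exceed the observed
table's, with a relative tolerance of 1e-7 guarding against floating-point
ties — the same convention as `stats::fisher.test`, which the test suite
uses as an independent cross-check over an exhaustive sweep of tables with
margins up to 12. A one-sided `case_enriched` alternative (upper tail,
$P(X \ge a)$) is available because disease markers in this setting are
case-enriched, but two-sided is the default: sidedness was not specified in
the source analysis and the two-sided test is the conservative choice.

Screening retains keys with P strictly below the cutoff; the canonical
ladder is 0.1, 1e-2, 1e-3, 1e-4, and the resulting key sets are nested. A
cutoff of exactly 1 disables filtering, so "screen at 1" enumerates every
observed key with its table. No multiple-testing correction is applied —
the ladder itself is the control mechanism, and the screened sets feed a
held-out evaluation rather than a significance claim. Results are sorted by
ascending P-value with lexicographic tie-breaks, so output is byte-stable.

Keys for the test split are never screened: all feature construction for
test samples uses the key set screened on the training split only (leakage
guard).

## Feature representations and classifiers

Three sample-level representations feed the classifier bank:

1. six diversity indices (columns `clonality`, `shannon`, `invsimpson`,
   `hvj`, `singleton`, `simpson`, in that fixed order);
2. two-dimensional counts: total unique clonotypes and the number of
   screened associated clonotypes present;
3. the 0-1 presence matrix over the screened key list (column order follows
   the list).

The registry covers 14 classifiers: logistic regression, LDA, linear and
polynomial-kernel SVM, Gaussian naive Bayes, a CART decision tree, k-nearest
neighbours (k = 5), random forest (500 trees), two gradient-boosted tree
variants (exact and histogram growth, 100 rounds, learning rate 0.1),
AdaBoost over decision stumps (50 rounds, SAMME weighting), bagged trees
(50 bootstrap CART trees), a single-hidden-layer perceptron (8 units, weight
decay 0.01), and a cross-validated Platt-calibrated linear SVM. Defaults are
the textbook settings of the underlying implementations and are recorded in
the registry; no hyperparameter search is performed anywhere. AdaBoost,
bagging and the calibrated SVM are implemented in-package (boosted stumps
fitted by exact weighted threshold search); the rest delegate to the
standard R implementations. SVMs and the perceptron standardize features
internally using training-split statistics. Positive class is always
`case`; sensitivity is case recall. Scores are continuous (class
probability, or a signed margin for SVMs/AdaBoost oriented so that larger
means more case-like); hard labels use the natural threshold (0.5 for
probabilities, 0 for margins).

The LDA fit adds Gaussian jitter with standard deviation 1e-6 to the
training matrix (under the model's seed): screened presence features can be
constant within a class — including perfect separators, which have zero
pooled within-class variance — and the jitter keeps the covariance
invertible without measurably moving the discriminant.

AUC is the Mann-Whitney statistic $U/(n_+ n_-)$ computed from midranks, so
ties count 1/2; the suite checks exact agreement with an all-pairs oracle.
ROC points are swept over thresholds at the distinct score values.

## Importance and core-marker selection

Index importance is ranked four ways — random forest Gini, gain from the
two boosting variants, and permutation importance (mean accuracy drop over
shuffles of one column, under a random-forest model) — then aggregated by
elementwise importance sums and by summed ranks (ties share the mean rank;
the rank-sum ordering is the headline ordering because raw importances are
not on a common scale across methods).

Core-marker reduction runs three routes on the screened presence matrix:

* **Lasso**: L1-penalised logistic regression (`glmnet`); the panel is the
  set of non-zero coefficients at a penalty chosen by cross-validated
  deviance unless fixed by the user. Under exact collinearity the L1
  solution is not unique; coordinate descent may split weight across
  duplicate columns or park it on one.
* **RFECV**: recursive feature elimination driven by the estimator's own
  ranking signal (stump weights for AdaBoost, |coefficients| for linear
  models, Gini/gain for trees), one feature per iteration. Within each
  stratified 5-fold split — repeated 3 times with different shuffles — the
  held-out fold is scored at every dimension; the CV curve is the mean of
  per-fold AUCs. Per-fold scoring matters for margin classifiers, whose
  decision values are not comparable across refits, and repetition damps
  split-to-split noise, which otherwise dominates at n = 44. The selected
  dimension is the smallest one within one standard error of the curve's
  maximum. A strict arg-max was tried first and rejected: with fine-grained
  scores exact ties never occur and the arg-max drifts into noise-inflated
  dimensions, while coarse per-fold scores saturate and collapse the panel
  to two markers; the one-standard-error rule is the standard parsimony
  compromise (as in `cv.glmnet`).
* **Backward exclusion**: from a starting panel, greedily drop the single
  feature whose removal least harms (or most helps) the repeated-CV AUC of
  a chosen classifier, and accept removals while the score stays within
  `tolerance` of the best score seen so far. The default tolerance 0 keeps
  only removals that do not hurt; `Inf` runs the loop down to one survivor.
  Fold splits are fixed across the whole loop so candidate scores are
  comparable.

`selection_grid()` crosses RFECV estimators with evaluation classifiers and
reports dimension and held-out metrics per cell.

## The synthetic cohort generator

The generator exists so that every stage is testable end to end with known
ground truth. Its defaults are the study conditions: 22 + 22 training and
15 + 15 test repertoires, about 1,000 clonotypes per sample (uniform ±10%
jitter), and 12 planted associated clonotypes, each present in a sample
with probability 0.7 (cases) versus 0.05 (controls). Planted clones have
fixed CDR3/V/J identities drawn once per cohort, so each is a single exact
key cohort-wide, as a public clonotype would be.

Background structure:

* A shared pool of 5,000 public clonotypes. Pool clone at rank $r$ enters
  each sample independently with probability
  $\min(1, (r/r_0)^{-4})$, with $r_0$ solved so the expected public count
  matches 80% of the repertoire (the other 20% are freshly generated
  private clonotypes). The steep decay gives a small ubiquitous tier, a
  heavy tail of rarely shared clones, and — by design — few clones at
  intermediate incidence. That last property is the generator's calibration
  contract: only intermediate-incidence background clones can ever reach
  Fisher significance by chance, and the exponent was chosen by computing
  the expected number of null discoveries at the screening cutoff (a sum of
  exact binomial-Fisher tail products over the pool) and requiring it to
  stay within the design target of at most two false keys per cohort.
  Shallower decays (e.g. exponent 1.1) put hundreds of clones at
  intermediate incidence and violate that contract.
* Within a sample, template counts follow a Zipf law over a random clone
  ranking, $c_r = \max(2, \mathrm{round}(K r^{-1.1}))$ with
  $K = $ repertoire size / 2, except that the configured singleton fraction
  (default 0.5, a typical value for blood repertoires) of clonotypes is
  assigned count exactly 1. This yields realistic clonality without fitting
  any real dataset.
* V families (24) and J genes (13) are drawn from Zipf-weighted categorical
  usage distributions shuffled once per cohort.

What the generator does **not** emulate: phenotype effects on diversity
(case and control backgrounds are exchangeable, so index-based
classification of synthetic cohorts sits at chance — the pipeline correctly
reports no signal where none was planted); nucleotide-level structure, VDJ
recombination statistics, or biophysical CDR3 composition; sequencing-depth
variation beyond the ±10% size jitter; and correlations between planted
markers (they are conditionally independent given phenotype, which makes
marker panels less redundant than the near-deterministic markers seen in
real screens — a caveat when interpreting how far a panel can be reduced
without losing held-out AUC). Passing tests on synthetic cohorts therefore
validate the machinery and its statistics, not biological effect sizes.

Everything is reproducible from the single integer seed: cohort generation,
every model fit (each classifier is fitted under its spec's seed), fold
splits, and permutation shuffles. Two runs with one seed produce
byte-identical output trees.

## Problem sizes

The shipped analyses and checks run at the cohort scale above (74 samples,
~1,000 clonotypes each, ~12,000 observed keys per training split), with 20
generator seeds for anything reported as an average; smaller cohorts (16 +
12 samples, 120 clonotypes) are used where only mechanics are exercised.
These sizes were chosen to keep a full desk run in minutes while leaving
every statistical property measurable.

## Known limitations

* Clonotypes arrive pre-annotated; there is no nucleotide processing, V(D)J
  annotation, or alignment.
* The screen is presence-based only; abundance-level association is out of
  scope, as is any test other than Fisher's exact.
* No rarefaction or depth normalization is applied to the diversity
  indices; cohorts with very unequal sequencing depth should be normalized
  upstream.
* The greedy backward exclusion explores a single elimination path; it is
  not an exhaustive subset search, and with tolerance 0 its stopping point
  inherits the noise of the CV score.
* Binary presence panels have coarse score patterns: a $k$-marker panel
  yields at most $2^k$ distinct scores, which bounds how close a very small
  panel's ranking performance can come to the full panel's on finite test
  sets.
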