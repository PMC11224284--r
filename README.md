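# tcrscreen

Case/control screening and classification of TCR-beta repertoires.

Bulk immunosequencing of the T-cell receptor beta chain turns one blood or
tissue sample into a table of clonotypes — unique (CDR3 amino-acid
sequence, V gene, J gene) rearrangements with template counts. Disease
leaves two kinds of fingerprints in such tables: global ones (how diverse
or clonally expanded the repertoire is) and specific ones (particular
public clonotypes that appear far more often in patients than in healthy
donors). `tcrscreen` implements the full diagnostic analysis over both,
aimed at case/control cohorts such as glioma patients versus healthy
donors:

* **Repertoire diversity indices** — Shannon entropy
  `H' = -Σ p_i ln p_i`, Simpson `λ = Σ p_i²` and inverse Simpson `1/λ`,
  clonality `1 − H'/ln n`, V-J usage entropy (Hvj), and the singleton
  ratio `n₁/(n−1)` — plus importance ranking of the indices by random
  forest, gradient boosting, and permutation importance.
* **Association screening** — for every clonotype observed in the training
  cohort, a 2x2 presence/absence table against phenotype and a Fisher
  exact P-value (direct hypergeometric enumeration), screened across the
  cutoff ladder 0.1, 1e-2, 1e-3, 1e-4.
* **Three feature representations** — the six indices; two-dimensional
  counts (total clonotypes, associated clonotypes); and the 0-1 presence
  matrix of the screened panel.
* **A 14-classifier bank** — logistic, LDA, linear/polynomial SVM, naive
  Bayes, decision tree, kNN, random forest, two gradient-boosting
  variants, AdaBoost, bagging, MLP, calibrated linear SVM — evaluated by
  ROC/AUC (Mann-Whitney with ties as 1/2), accuracy, sensitivity and
  specificity on a held-out test split.
* **Core-marker reduction** — Lasso, recursive feature elimination with
  repeated cross-validation (RFECV, one-standard-error rule), and greedy
  one-by-one backward exclusion, shrinking the screened panel to a minimal
  marker set whose held-out AUC matches the full panel.
* **A seeded synthetic-cohort generator** with a Zipf background clonotype
  pool, public/private structure, controlled singleton mass, and planted
  associated clonotypes — so the whole pipeline is testable end to end
  with known ground truth and no external data.

Input formats: AIRR rearrangement TSV (`junction_aa`, `v_call`, `j_call`,
`duplicate_count`, `productive`) and immunoSEQ-export-style TSV
(`aminoAcid`, `vGeneName`, `jGeneName`, `count`), with custom column
mappings.

## Worked example

Read a (synthetic) AIRR-format sample shipped with the package, compute its
diversity profile, and test a presence table:

```r
library(tcrscreen)

f <- system.file("extdata", "synthetic_example_airr.tsv", package = "tcrscreen")
rep <- read_clonotype_table(f, dialect = "airr", sample_id = "donor_A")
rep
#> <tcr_repertoire> donor_A (unknown): 8 clonotypes, 80 templates

unlist(attr(rep, "load_report"))
#>                  rows_read       rows_dropped_invalid
#>                          9                          0
#> rows_dropped_nonproductive          duplicates_merged
#>                          1                          0

diversity_profile(rep)
#> <diversity_profile> richness=8 shannon=1.4114 clonality=0.3213 invsimpson=2.94 hvj=1.1143 singleton=0.2857

# a clonotype seen in 9/10 cases and 0/10 controls:
fisher_exact_p(9, 1, 0, 10)
#> [1] 0.000119076
```

One row was dropped as non-productive (stop codon in the CDR3): the profile
is computed over the 8 productive unique clonotypes. The clonality of 0.32
reflects the expanded top clone (42 of 80 templates); the Fisher P-value of
1.2e-4 is what the screen uses to flag a clonotype as disease-associated.

## The analysis workflow

The `analysis/` scripts run the four experiments on a simulated
study-shaped cohort (44 balanced training, 30 balanced test samples, 12
planted markers at incidence 0.7 in cases vs 0.05 in controls), writing all
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1    # cohort + manifest + ground truth
Rscript analysis/02_screen_associated.R    # Fisher screen, cutoff ladder
Rscript analysis/03_diversity_indices.R    # index importance + classification
Rscript analysis/04_classification.R       # two-dim and presence-matrix banks
Rscript analysis/05_core_selection.R       # RFECV + backward exclusion + Lasso
```

With seed 1 the screen reports, per cutoff (planted truth in parentheses):

```
  p < 1e-01 :   28 keys (12/12 planted)
  p < 1e-02 :   14 keys (12/12 planted)
  p < 1e-03 :   13 keys (12/12 planted)
  p < 1e-04 :   11 keys (11/12 planted)
```

and the downstream experiments print

```
two-dim features:  mean AUC 0.968 (best 1.000)
presence features: mean AUC 0.997 (best 1.000)
full 14-marker panel: test AUC 1.000
RFECV(adaboost): 6 markers (CV curve max 0.977)
core panel after backward exclusion: 4 markers (4 planted)
core panel test metrics: AUC 1.000, accuracy 1.000, sensitivity 1.000, specificity 1.000
```

i.e. the screen recovers the planted markers at 1e-2 with two false keys,
presence-based classifiers separate the held-out split almost perfectly,
and the selection chain reduces 14 screened markers to a 4-marker core with
no loss of held-out AUC. Index-based classification sits at chance on this
cohort by design — the generator plants presence signal only — which the
third script states explicitly.

`run_pipeline()` performs the same experiments from a single (YAML or list)
config into one report directory with a machine-readable run manifest.

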