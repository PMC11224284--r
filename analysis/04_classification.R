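#!/usr/bin/env Rscript

# Experiments B and C: two-dimensional features (total vs associated
# clonotype counts) and the multidimensional 0-1 presence matrix over the
# screened key set, each pushed through the classifier bank. Also exports a
# decision-boundary grid for the two-dimensional logistic model.

library(tcrscreen)

seed <- 1L
cohort <- read_cohort("results/cohort/manifest.tsv")
associated <- readLines("results/associated_keys_p0.01.txt")
cat(sprintf("using %d associated clonotypes screened at p < 0.01\n",
            length(associated)))

# B: two-dimensional counts
tr2 <- two_dim_feature_table(cohort$train, associated)
te2 <- two_dim_feature_table(cohort$test, associated)
write_matrix(tr2, "results/two_dim_train.tsv")
write_matrix(te2, "results/two_dim_test.tsv")
m2 <- classify_bank(tr2, te2, seed = seed)
write.table(m2, "results/two_dim_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

model2 <- fit_classifier(clf_spec("logistic", seed = seed), tr2)
rng <- apply(unclass(tr2), 2, range)
grid <- decision_boundary_grid(model2, list(x = rng[, 1], y = rng[, 2]),
                               resolution = 60)
write.table(grid$labels, "results/two_dim_boundary_grid.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

# C: multidimensional presence matrix
trm <- presence_matrix(cohort$train, associated)
tem <- presence_matrix(cohort$test, associated)
write_matrix(trm, "results/multidim_train.tsv")
write_matrix(tem, "results/multidim_test.tsv")
mm <- classify_bank(trm, tem, seed = seed)
write.table(mm, "results/multidim_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("two-dim features:  mean AUC %.3f (best %.3f)\n",
            mean(m2$auc), max(m2$auc)))
cat(sprintf("presence features: mean AUC %.3f (best %.3f)\n",
            mean(mm$auc), max(mm$auc)))
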