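#' Two-dimensional features: total and associated clonotype counts
#'
#' For one repertoire, the total number of distinct clonotypes (richness) and
#' the number of those that belong to a screened associated set.
#'
#' @param rep a `tcr_repertoire`.
#' @param associated character vector of associated clonotype keys.
#' @return named numeric `c(total_clonotypes, associated_count)`.
#' @export
two_dim_features <- function(rep, associated) {
  keys <- repertoire_keys(rep)
  c(total_clonotypes = length(keys),
    associated_count = length(intersect(keys, associated)))
}

#' @rdname two_dim_features
#' @param cohort list of `tcr_repertoire` objects.
#' @return `two_dim_feature_table()` returns a `tcr_features` matrix with the
#'   two columns, one row per sample.
#' @export
two_dim_feature_table <- function(cohort, associated) {
  vals <- t(vapply(cohort, two_dim_features, numeric(2),
                   associated = associated))
  rownames(vals) <- vapply(cohort, function(r) r$sample_id, character(1))
  feature_matrix(vals, cohort_phenotypes(cohort))
}

#' Binary presence matrix over an associated clonotype set
#'
#' The multidimensional 0-1 representation: entry (sample, key) is 1 when the
#' sample contains the clonotype key, 0 otherwise. Column order follows the
#' supplied key list, so matrices built for train and test splits align.
#'
#' @param cohort list of `tcr_repertoire` objects.
#' @param associated ordered character vector of clonotype keys (no
#'   duplicates).
#' @return a `tcr_features` matrix of 0/1 values.
#' @export
presence_matrix <- function(cohort, associated) {
  if (length(associated) == 0) stop("associated key set is empty", call. = FALSE)
  if (anyDuplicated(associated))
    stop("duplicate keys in associated set", call. = FALSE)
  vals <- t(vapply(cohort, function(r) {
    as.numeric(associated %in% repertoire_keys(r))
  }, numeric(length(associated))))
  rownames(vals) <- vapply(cohort, function(r) r$sample_id, character(1))
  colnames(vals) <- associated
  feature_matrix(vals, cohort_phenotypes(cohort))
}

DIVERSITY_FEATURES <- c("clonality", "shannon", "invsimpson", "hvj",
                        "singleton", "simpson")

#' Diversity-index feature table for a cohort
#'
#' One row per sample with the six repertoire indices in fixed column order
#' (`clonality`, `shannon`, `invsimpson`, `hvj`, `singleton`, `simpson`).
#'
#' @param cohort list of `tcr_repertoire` objects.
#' @return a `tcr_features` matrix with six columns.
#' @export
diversity_feature_table <- function(cohort) {
  vals <- t(vapply(cohort, function(r) {
    p <- diversity_profile(r)
    c(clonality = p$clonality, shannon = p$shannon,
      invsimpson = p$invsimpson, hvj = p$hvj,
      singleton = p$singleton_ratio, simpson = p$simpson)
  }, numeric(6)))
  rownames(vals) <- vapply(cohort, function(r) r$sample_id, character(1))
  feature_matrix(vals, cohort_phenotypes(cohort))
}
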