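#' Presence/absence contingency table for one clonotype
#'
#' Tallies, over a training cohort, how many case and control samples contain
#' a clonotype key (presence = canonical key observed with count >= 1). The
#' 2x2 table `(a, b, c, d)` is cases-with / cases-without / controls-with /
#' controls-without.
#'
#' @param cohort list of `tcr_repertoire` objects with `case`/`control`
#'   phenotypes.
#' @param key canonical clonotype key string.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
presence_counts <- function(cohort, key) {
  ph <- cohort_phenotypes(cohort)
  if (!all(c("case", "control") %in% ph))
    stop("cohort must contain both phenotypes", call. = FALSE)
  has <- vapply(cohort, function(r) key %in% repertoire_keys(r), logical(1))
  a <- sum(has & ph == "case")
  c_ <- sum(has & ph == "control")
  c(a = a, b = sum(ph == "case") - a,
    c = c_, d = sum(ph == "control") - c_)
}

#' Fisher's exact test P-value for a 2x2 presence table
#'
#' Direct hypergeometric computation. The two-sided P-value sums the
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed table's (within relative tolerance 1e-7, the usual
#' guard against floating-point ties); `case_enriched` is the one-sided upper
#' tail P(X >= a).
#'
#' @param a,b,c,d cell counts: cases with / cases without / controls with /
#'   controls without the clonotype. `a` may also be a length-4 vector.
#' @param alternative `"two_sided"` (default) or `"case_enriched"`.
#' @return P-value in `[0, 1]`.
#' @export
fisher_exact_p <- function(a, b = NULL, c = NULL, d = NULL,
                           alternative = c("two_sided", "case_enriched")) {
  alternative <- match.arg(alternative)
  if (length(a) == 4 && is.null(b)) { d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1] }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  if (any(cells != round(cells))) stop("cell counts must be integers", call. = FALSE)
  m <- a + b          # cases
  n <- c + d          # controls
  k <- a + c          # samples containing the clonotype
  if (m + n == 0) stop("empty table", call. = FALSE)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  if (alternative == "case_enriched") {
    p <- sum(probs[support >= a])
  } else {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(1, p)
}

# Vectorized two-sided/one-sided p over many (a, c) tables sharing margins
# (m cases, n controls): computes each distinct (a, c) pair once.
fisher_p_vec <- function(a, c, m, n, alternative = "two_sided") {
  key <- paste(a, c)
  uniq <- !duplicated(key)
  pu <- vapply(which(uniq), function(i) {
    fisher_exact_p(a[i], m - a[i], c[i], n - c[i], alternative = alternative)
  }, numeric(1))
  names(pu) <- key[uniq]
  unname(pu[key])
}

# presence incidence matrix helper: counts of case/control samples per key
presence_tally <- function(cohort) {
  ph <- cohort_phenotypes(cohort)
  keys <- lapply(cohort, repertoire_keys)
  all_keys <- unlist(keys, use.names = FALSE)
  is_case <- rep(ph == "case", times = lengths(keys))
  union_keys <- sort(unique(all_keys))
  a <- table(factor(all_keys[is_case], levels = union_keys))
  c_ <- table(factor(all_keys[!is_case], levels = union_keys))
  data.frame(key = union_keys, a = as.integer(a), c = as.integer(c_),
             stringsAsFactors = FALSE)
}

#' Screen a cohort for disease-associated clonotypes
#'
#' Tests every clonotype key observed in at least one training sample for
#' association between presence and phenotype with Fisher's exact test, and
#' returns those with P strictly below `cutoff`, sorted by ascending P-value
#' (ties broken lexicographically by key). A cutoff of 1 disables filtering
#' (every observed key is returned, including those at P = 1). No
#' multiple-testing correction is applied: the cutoff ladder is the control
#' mechanism.
#'
#' @inheritParams presence_counts
#' @param cutoff retain keys with `p_value < cutoff` (in `(0, 1]`).
#' @param alternative passed to [fisher_exact_p()].
#' @return data frame with columns `key`, `a`, `b`, `c`, `d`, `p_value`.
#' @export
screen <- function(cohort, cutoff = 0.1,
                   alternative = c("two_sided", "case_enriched")) {
  alternative <- match.arg(alternative)
  stopifnot(cutoff > 0, cutoff <= 1)
  ph <- cohort_phenotypes(cohort)
  if (!all(c("case", "control") %in% ph))
    stop("cohort must contain both phenotypes", call. = FALSE)
  m <- sum(ph == "case")
  n <- sum(ph == "control")
  tab <- presence_tally(cohort)
  if (nrow(tab) == 0) return(empty_screen())
  tab$b <- m - tab$a
  tab$d <- n - tab$c
  tab$p_value <- fisher_p_vec(tab$a, tab$c, m, n, alternative)
  keep <- if (cutoff >= 1) rep(TRUE, nrow(tab)) else tab$p_value < cutoff
  tab <- tab[keep, c("key", "a", "b", "c", "d", "p_value")]
  tab <- tab[order(tab$p_value, tab$key), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

empty_screen <- function() {
  data.frame(key = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

#' Associated key sets across a ladder of P-value cutoffs
#'
#' Runs the Fisher screen once and slices the result at each cutoff. With
#' cutoffs sorted descending the returned key sets are nested.
#'
#' @inheritParams screen
#' @param cutoffs numeric vector of thresholds, sorted descending
#'   (default ladder `0.1, 1e-2, 1e-3, 1e-4`).
#' @return named list (one element per cutoff) of key character vectors,
#'   each sorted as in [screen()].
#' @export
threshold_traverse <- function(cohort, cutoffs = c(0.1, 1e-2, 1e-3, 1e-4),
                               alternative = c("two_sided", "case_enriched")) {
  alternative <- match.arg(alternative)
  stopifnot(length(cutoffs) >= 1, all(diff(cutoffs) < 0) || length(cutoffs) == 1)
  full <- screen(cohort, cutoff = max(cutoffs), alternative = alternative)
  out <- lapply(cutoffs, function(ct) {
    if (ct >= 1) full$key else full$key[full$p_value < ct]
  })
  names(out) <- format(cutoffs, scientific = TRUE, trim = TRUE)
  out
}
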