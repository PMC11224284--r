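#' Shannon diversity index
#'
#' H' = -sum p_i ln(p_i) in nats, with the 0 * ln 0 = 0 convention. Applied to
#' clonotype frequencies it measures repertoire diversity; applied to V-J
#' combination frequencies it is the V-J (Hvj) diversity index.
#'
#' @param frequencies non-negative vector summing to 1 (tolerance 1e-9).
#' @return entropy in nats.
#' @export
shannon_index <- function(frequencies) {
  check_freqs(frequencies)
  p <- frequencies[frequencies > 0]
  -sum(p * log(p))
}

check_freqs <- function(p) {
  if (any(p < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  invisible(p)
}

#' Simpson and inverse Simpson indices
#'
#' Simpson's index is the collision probability sum(p_i^2); the inverse
#' Simpson index is its reciprocal (the effective number of equally frequent
#' clonotypes).
#'
#' @inheritParams shannon_index
#' @return named list with `simpson` and `invsimpson`.
#' @export
simpson_indices <- function(frequencies) {
  check_freqs(frequencies)
  s <- sum(frequencies^2)
  list(simpson = s, invsimpson = 1 / s)
}

clone_freqs <- function(rep) {
  counts <- rep$clonotypes$count
  if (length(counts) == 0) stop("empty repertoire", call. = FALSE)
  counts / sum(counts)
}

#' Clonality index
#'
#' Clonality = 1 - H' / ln(productive uniques): 0 for a perfectly even
#' repertoire, approaching 1 when a few clones dominate. For a single-clonotype
#' repertoire the normalisation is undefined and 0 (the no-amplification
#' value) is returned by convention.
#'
#' @param rep a `tcr_repertoire`.
#' @return clonality in `[0, 1]`.
#' @export
clonality_index <- function(rep) {
  n <- richness(rep)
  if (n == 0) stop("empty repertoire", call. = FALSE)
  if (n == 1) return(0)
  1 - shannon_index(clone_freqs(rep)) / log(n)
}

#' V-J combination diversity (Hvj)
#'
#' Shannon entropy over the template-count-weighted frequency distribution of
#' distinct (V family, J gene) combinations, reflecting how evenly sequencing
#' templates spread across V-J usage.
#'
#' @param rep a `tcr_repertoire`.
#' @return entropy in nats.
#' @export
hvj_index <- function(rep) {
  if (richness(rep) == 0) stop("empty repertoire", call. = FALSE)
  vj <- paste(rep$clonotypes$v_gene, rep$clonotypes$j_gene, sep = "_")
  w <- rowsum(rep$clonotypes$count, vj)[, 1L]
  shannon_index(w / sum(w))
}

#' Singleton ratio
#'
#' n_1 / (n - 1), where n_1 is the number of clonotypes seen with template
#' count exactly 1 and n the clonotype richness — a proxy for the naive T-cell
#' fraction. The `n - 1` denominator is the conventional form (it can exceed
#' 1); `denominator = "n"` gives the plain proportion. Returns 0 for a
#' single-clonotype repertoire, where the default denominator vanishes.
#'
#' @param rep a `tcr_repertoire`.
#' @param denominator `"n_minus_1"` (default) or `"n"`.
#' @return non-negative ratio.
#' @export
singleton_ratio <- function(rep, denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  n <- richness(rep)
  if (n == 0) stop("empty repertoire", call. = FALSE)
  n1 <- sum(rep$clonotypes$count == 1)
  if (denominator == "n") return(n1 / n)
  if (n == 1) return(0)
  n1 / (n - 1)
}

#' Full diversity profile of a repertoire
#'
#' Computes the six indices used throughout the analysis (Shannon, Simpson,
#' inverse Simpson, clonality, V-J entropy, singleton ratio) plus richness,
#' all from count-derived frequencies p_i = count_i / total templates.
#'
#' @inheritParams singleton_ratio
#' @return named list of class `diversity_profile` with elements `shannon`,
#'   `simpson`, `invsimpson`, `clonality`, `hvj`, `singleton_ratio`,
#'   `richness`.
#' @export
diversity_profile <- function(rep, denominator = c("n_minus_1", "n")) {
  p <- clone_freqs(rep)
  si <- simpson_indices(p)
  structure(list(
    shannon = shannon_index(p),
    simpson = si$simpson,
    invsimpson = si$invsimpson,
    clonality = clonality_index(rep),
    hvj = hvj_index(rep),
    singleton_ratio = singleton_ratio(rep, denominator),
    richness = richness(rep)
  ), class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf(paste0("<diversity_profile> richness=%d shannon=%.4f ",
                     "clonality=%.4f invsimpson=%.2f hvj=%.4f singleton=%.4f\n"),
              x$richness, x$shannon, x$clonality, x$invsimpson, x$hvj,
              x$singleton_ratio))
  invisible(x)
}
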