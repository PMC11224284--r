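# Seeded case/control cohort generator with planted associated clonotypes.
# Background clonotypes come from a shared public pool (Zipf-weighted
# inclusion, so sharing is heavy-tailed) plus per-sample private clones;
# within-sample template counts follow a Zipf law over clone rank with a
# controlled singleton mass. Planted clones are fixed CDR3_V_J identities
# whose per-sample presence probability depends on phenotype.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study cohort shape: 44 balanced training samples and
#' 30 balanced test samples, ~1,000 clonotypes per repertoire, and 12 planted
#' disease-associated clonotypes present in 70% of cases vs 5% of controls.
#'
#' @param n_case_train,n_ctrl_train,n_case_test,n_ctrl_test cohort sizes.
#' @param pool_size size of the shared public-clonotype pool.
#' @param zipf_exponent exponent of the Zipf laws (pool inclusion weights and
#'   within-sample clone counts).
#' @param repertoire_size mean clonotypes per sample.
#' @param repertoire_jitter relative uniform jitter on repertoire size.
#' @param private_fraction expected fraction of a sample's background
#'   clonotypes that are private (seen in that sample only).
#' @param publicity_exponent decay exponent of the pool sharing curve: pool
#'   clone `r` enters each sample independently with probability
#'   `min(1, (r / r0)^-publicity_exponent)`, `r0` solved so the expected
#'   public count matches `1 - private_fraction`. A steep default keeps
#'   mid-incidence background clones - the only ones a presence test can
#'   ever flag - rare, so the screen's null behaviour is clean.
#' @param n_planted number of planted associated clonotypes.
#' @param incidence_case,incidence_ctrl per-sample presence probability of
#'   each planted clonotype by phenotype.
#' @param singleton_fraction fraction of clonotypes with template count 1.
#' @param n_v_families,n_j_genes sizes of the V-family / J-gene label pools.
#' @param seed integer master seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_case_train = 22, n_ctrl_train = 22,
                             n_case_test = 15, n_ctrl_test = 15,
                             pool_size = 5000, zipf_exponent = 1.1,
                             repertoire_size = 1000,
                             repertoire_jitter = 0.1,
                             private_fraction = 0.2,
                             publicity_exponent = 4,
                             n_planted = 12,
                             incidence_case = 0.7, incidence_ctrl = 0.05,
                             singleton_fraction = 0.5,
                             n_v_families = 24, n_j_genes = 13,
                             seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_case_train >= 1, n_ctrl_train >= 1, n_case_test >= 0,
              n_ctrl_test >= 0, pool_size >= 1, repertoire_size >= 1,
              incidence_case >= 0, incidence_case <= 1,
              incidence_ctrl >= 0, incidence_ctrl <= 1,
              private_fraction >= 0, private_fraction <= 1,
              singleton_fraction >= 0, singleton_fraction <= 1,
              n_planted >= 0)
    if (n_planted > repertoire_size)
      stop("n_planted exceeds repertoire_size", call. = FALSE)
  })
  structure(cfg, class = "generator_config")
}

# random CDR3 amino-acid strings: canonical C...F junctions, length 10-17
random_cdr3 <- function(n, len_min = 10, len_max = 17) {
  lens <- sample(len_min:len_max, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0("CASS", paste(sample(AA_LETTERS, l - 5, replace = TRUE),
                         collapse = ""), "F")
  }, character(1))
}

# Zipf counts over within-sample rank with an enforced singleton mass:
# the first n - n_singletons ranks get max(2, round(K * r^-s)) templates,
# the rest get exactly 1.
zipf_counts <- function(n, exponent, singleton_fraction, scale) {
  n_single <- round(singleton_fraction * n)
  n_big <- n - n_single
  counts <- rep(1, n)
  if (n_big > 0) {
    r <- seq_len(n_big)
    counts[r] <- pmax(2, round(scale * r^(-exponent)))
  }
  counts
}

#' Generate a synthetic case/control TCR cohort
#'
#' Fully reproducible from `config$seed`. Each sample contains each planted
#' clonotype independently with its phenotype's incidence, plus background
#' clonotypes drawn from the public pool (without replacement, Zipf-weighted
#' by pool rank) and freshly generated private clonotypes; template counts
#' follow the within-sample Zipf law.
#'
#' @param config a [generator_config()].
#' @return list with `train` and `test` (named lists of `tcr_repertoire`),
#'   `truth` (character vector of planted keys) and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  v_labels <- paste0("TRBV", seq_len(config$n_v_families))
  j_labels <- paste0("TRBJ", c(paste0("1-", 1:6),
                               paste0("2-", 1:7)))[seq_len(config$n_j_genes)]
  # heavy-tailed V/J usage: Zipf weights over a random family order
  v_probs <- (sample(config$n_v_families))^(-1)
  v_probs <- v_probs / sum(v_probs)
  j_probs <- (sample(config$n_j_genes))^(-1)
  j_probs <- j_probs / sum(j_probs)

  draw_vj <- function(n) {
    list(v = sample(v_labels, n, replace = TRUE, prob = v_probs),
         j = sample(j_labels, n, replace = TRUE, prob = j_probs))
  }

  # shared public pool; planted clonotypes are fixed identities outside it
  pool_cdr3 <- unique(random_cdr3(ceiling(config$pool_size * 1.05)))
  while (length(pool_cdr3) < config$pool_size + config$n_planted) {
    pool_cdr3 <- unique(c(pool_cdr3, random_cdr3(config$pool_size)))
  }
  planted_cdr3 <- pool_cdr3[seq_len(config$n_planted)]
  pool_cdr3 <- pool_cdr3[config$n_planted + seq_len(config$pool_size)]
  pool_vj <- draw_vj(config$pool_size)
  planted_vj <- draw_vj(config$n_planted)
  truth <- if (config$n_planted > 0) {
    clonotype_key(planted_cdr3, planted_vj$v, planted_vj$j)
  } else character(0)

  # sharing curve: clone r is in a sample w.p. min(1, (r/r0)^-g); r0 solved
  # so the expected public count equals the public share of the repertoire
  target_public <- (1 - config$private_fraction) * config$repertoire_size
  g <- config$publicity_exponent
  r <- seq_len(config$pool_size)
  publicity <- if (sum(pmin(1, (r / config$pool_size)^(-g))) <= target_public) {
    rep(1, config$pool_size)   # degenerate: everything public in every sample
  } else {
    r0 <- stats::uniroot(function(r0) sum(pmin(1, (r / r0)^(-g))) - target_public,
                         c(1e-3, config$pool_size))$root
    pmin(1, (r / r0)^(-g))
  }

  make_sample <- function(sample_id, phenotype) {
    incidence <- if (phenotype == "case") config$incidence_case
                 else config$incidence_ctrl
    planted_in <- which(stats::runif(config$n_planted) < incidence)
    size <- round(config$repertoire_size *
                  stats::runif(1, 1 - config$repertoire_jitter,
                               1 + config$repertoire_jitter))
    n_background <- max(0, size - length(planted_in))
    pub <- which(stats::runif(config$pool_size) < publicity)
    if (length(pub) > n_background) pub <- sample(pub, n_background)
    n_private <- n_background - length(pub)
    priv_cdr3 <- random_cdr3(n_private)
    priv_vj <- draw_vj(n_private)
    records <- data.frame(
      cdr3_aa = c(planted_cdr3[planted_in], pool_cdr3[pub], priv_cdr3),
      v_gene = c(planted_vj$v[planted_in], pool_vj$v[pub], priv_vj$v),
      j_gene = c(planted_vj$j[planted_in], pool_vj$j[pub], priv_vj$j),
      stringsAsFactors = FALSE
    )
    n <- nrow(records)
    records <- records[sample.int(n), , drop = FALSE]  # random rank order
    records$count <- zipf_counts(n, config$zipf_exponent,
                                 config$singleton_fraction,
                                 scale = config$repertoire_size / 2)
    repertoire(sample_id, records, phenotype = phenotype)
  }

  make_split <- function(prefix, n_case, n_ctrl) {
    ids <- c(sprintf("%s_case_%02d", prefix, seq_len(n_case)),
             sprintf("%s_ctrl_%02d", prefix, seq_len(n_ctrl)))
    ph <- c(rep("case", n_case), rep("control", n_ctrl))
    reps <- mapply(make_sample, ids, ph, SIMPLIFY = FALSE)
    names(reps) <- ids
    reps
  }

  list(train = make_split("train", config$n_case_train, config$n_ctrl_train),
       test = make_split("test", config$n_case_test, config$n_ctrl_test),
       truth = truth, config = config)
}

#' Summary statistics of a generated cohort
#'
#' Per-sample richness, total templates, singleton fraction and planted-clone
#' tally, plus cohort-level empirical planted incidences by phenotype —
#' the generator's own validation that output matches configuration.
#'
#' @param cohort result of [generate_cohort()], or a plain list of
#'   repertoires (then `truth` must be given).
#' @param truth planted key set (defaults to `cohort$truth`).
#' @return list with `samples` (data frame) and `incidence` (named vector of
#'   mean per-sample planted presence by phenotype).
#' @export
cohort_summary <- function(cohort, truth = cohort$truth) {
  reps <- if (!is.null(cohort$train)) c(cohort$train, cohort$test) else cohort
  samples <- do.call(rbind, lapply(reps, function(r) {
    data.frame(
      sample_id = r$sample_id, phenotype = r$phenotype,
      richness = richness(r), templates = total_templates(r),
      singleton_fraction = mean(r$clonotypes$count == 1),
      planted_present = length(intersect(repertoire_keys(r), truth)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL
  incidence <- if (length(truth)) {
    tapply(samples$planted_present / length(truth), samples$phenotype, mean)
  } else NULL
  list(samples = samples, incidence = incidence)
}

#' Write a cohort to disk as AIRR tables plus a manifest
#'
#' One AIRR rearrangement TSV per sample (`junction_aa`, `v_call`, `j_call`,
#' `duplicate_count`, `productive`), a `manifest.tsv` (sample_id, file,
#' phenotype, split) and, when ground truth is known, `planted_keys.txt`.
#' Output is byte-deterministic given the cohort.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (split in c("train", "test")) {
    for (r in cohort[[split]]) {
      file <- paste0(r$sample_id, ".tsv")
      tab <- data.frame(
        junction_aa = r$clonotypes$cdr3_aa,
        v_call = r$clonotypes$v_gene,
        j_call = r$clonotypes$j_gene,
        duplicate_count = r$clonotypes$count,
        productive = "T"
      )
      utils::write.table(tab, file.path(dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = r$sample_id, file = file, phenotype = r$phenotype,
        split = split, stringsAsFactors = FALSE
      )
    }
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cohort$truth)) {
    writeLines(cohort$truth, file.path(dir, "planted_keys.txt"))
  }
  invisible(dir)
}
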