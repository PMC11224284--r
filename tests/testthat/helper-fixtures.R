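# Fixture builders and independent oracles shared across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# repertoire with given counts; distinct CDR3s, V/J cycled over small pools
make_rep <- function(counts, sample_id = "s1", phenotype = "unknown",
                     v = NULL, j = NULL) {
  n <- length(counts)
  if (is.null(v)) v <- paste0("TRBV", (seq_len(n) - 1) %% 4 + 1)
  if (is.null(j)) j <- paste0("TRBJ1-", (seq_len(n) - 1) %% 3 + 1)
  cdr3 <- sprintf("CASS%s%sF",
                  strrep("A", 3 + (seq_len(n) - 1) %% 5),
                  AA20[(seq_len(n) - 1) %% 20 + 1])
  cdr3 <- make.unique2(cdr3)
  repertoire(sample_id, data.frame(cdr3_aa = cdr3, v_gene = v, j_gene = j,
                                   count = counts), phenotype = phenotype)
}

# disambiguate repeated CDR3s with extra alanine runs (keeps AA alphabet)
make.unique2 <- function(x) {
  while (anyDuplicated(x)) {
    d <- duplicated(x)
    x[d] <- paste0(sub("F$", "", x[d]), "AF")
  }
  x
}

# cohort in which membership of one tracked clonotype is set explicitly:
# `members` is a logical vector over samples; every sample also gets `n_bg`
# shared background clones so repertoires are non-trivial
membership_cohort <- function(members, phenotypes, n_bg = 5) {
  stopifnot(length(members) == length(phenotypes))
  # background clones identical across samples; tracked clone appended
  tracked <- data.frame(cdr3_aa = "CWWWWWWF", v_gene = "TRBV9",
                        j_gene = "TRBJ2-1", count = 3)
  reps <- lapply(seq_along(members), function(i) {
    bg <- data.frame(
      cdr3_aa = sprintf("CASSGG%sF", AA20[seq_len(n_bg)]),
      v_gene = "TRBV1", j_gene = "TRBJ1-1", count = 2
    )
    rows <- if (members[i]) rbind(bg, tracked) else bg
    repertoire(paste0("s", i), rows, phenotype = phenotypes[i])
  })
  names(reps) <- paste0("s", seq_along(members))
  reps
}

tracked_key <- "CWWWWWWF_TRBV9_TRBJ2-1"

# independent diversity oracles: naive summations coded separately from the
# package's implementations
oracle_profile <- function(counts, vj) {
  p <- counts / sum(counts)
  sh <- 0
  for (pi in p) if (pi > 0) sh <- sh - pi * log(pi)
  simp <- 0
  for (pi in p) simp <- simp + pi * pi
  vj_tot <- tapply(counts, vj, sum)
  q <- vj_tot / sum(vj_tot)
  hvj <- 0
  for (qi in q) if (qi > 0) hvj <- hvj - qi * log(qi)
  n <- length(counts)
  n1 <- sum(counts == 1)
  list(shannon = sh, simpson = simp, invsimpson = 1 / simp,
       clonality = if (n > 1) 1 - sh / log(n) else 0,
       hvj = hvj,
       singleton_ratio = if (n > 1) n1 / (n - 1) else 0)
}

# all-pairs Mann-Whitney AUC oracle (ties as 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "case"]
  neg <- scores[labels == "control"]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random feature matrix with labels
random_fm <- function(n, p, seed, informative = 0, effect = 2) {
  set.seed(seed)
  labels <- rep(c("case", "control"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
  if (informative > 0) {
    shift <- (labels == "case") * effect
    x[, seq_len(informative)] <- x[, seq_len(informative)] + shift
  }
  feature_matrix(x, labels)
}

# presence-feature matrix with planted informative columns (binary data)
planted_presence_fm <- function(n = 200, n_inform = 3, n_noise = 17,
                                p_case = 0.7, p_ctrl = 0.05, seed = 1) {
  set.seed(seed)
  labels <- rep(c("case", "control"), length.out = n)
  probs_inform <- ifelse(labels == "case", p_case, p_ctrl)
  x_inf <- sapply(seq_len(n_inform), function(j) rbinom(n, 1, probs_inform))
  # noise incidences fixed per column so matrices from different seeds share
  # one distribution (train/test pairs stay exchangeable)
  p_noise <- seq(0.2, 0.8, length.out = n_noise)
  x_noise <- sapply(seq_len(n_noise), function(j) rbinom(n, 1, p_noise[j]))
  x <- cbind(x_inf, x_noise)
  dimnames(x) <- list(paste0("s", seq_len(n)),
                      c(paste0("inf", seq_len(n_inform)),
                        paste0("noise", seq_len(n_noise))))
  feature_matrix(x, labels)
}

small_config <- function(seed = 1, ...) {
  generator_config(n_case_train = 8, n_ctrl_train = 8, n_case_test = 6,
                   n_ctrl_test = 6, pool_size = 400, repertoire_size = 120,
                   n_planted = 6, seed = seed, ...)
}

hash_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  vapply(files, function(f) {
    paste(tools::md5sum(file.path(dir, f)), f)
  }, character(1))
}
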