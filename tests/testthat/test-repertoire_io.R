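test_that("clonotype keys collapse V to family and strip alleles", {
  expect_equal(clonotype_key("CASSLGGNTEAFF", "TRBV12-3*01", "TRBJ1-1*01"),
               "CASSLGGNTEAFF_TRBV12_TRBJ1-1")
  expect_equal(clonotype_key("CASSYSDTGELFF", "TRBV6", "TRBJ2-2"),
               "CASSYSDTGELFF_TRBV6_TRBJ2-2")
  expect_equal(clonotype_key("CASSF", "TRBV12-3", "TRBJ1-3",
                             v_resolution = "gene"),
               "CASSF_TRBV12-3_TRBJ1-3")
})

test_that("key canonicalization is idempotent and vectorized", {
  keys1 <- clonotype_key(c("CASSA", "CASSB"), c("TRBV12-3*01", "TRBV6"),
                         c("TRBJ1-1*01", "TRBJ2-2"))
  parts <- strsplit(keys1, "_")
  keys2 <- clonotype_key(sapply(parts, `[`, 1), sapply(parts, `[`, 2),
                         sapply(parts, `[`, 3))
  expect_identical(keys1, keys2)
})

test_that("unparseable gene labels pass through verbatim with a warning", {
  expect_warning(k <- clonotype_key("CASSA", "unresolved", "TRBJ1-1"),
                 "not parseable")
  expect_equal(k, "CASSA_unresolved_TRBJ1-1")
})

test_that("duplicate keys are merged by summing counts", {
  r <- repertoire("s", data.frame(
    cdr3_aa = c("CASSA", "CASSA", "CASSD"),
    v_gene = c("TRBV12-3*01", "TRBV12-1", "TRBV2"),
    j_gene = c("TRBJ1-1", "TRBJ1-1*02", "TRBJ1-2"),
    count = c(3, 4, 1)
  ))
  expect_equal(richness(r), 2)
  expect_equal(r$clonotypes$count[r$clonotypes$key == "CASSA_TRBV12_TRBJ1-1"], 7)
  expect_equal(total_templates(r), 8)
  expect_equal(attr(r, "load_report")$duplicates_merged, 1)
})

test_that("non-productive rows are filtered and reported; filter can be disabled", {
  recs <- data.frame(
    cdr3_aa = c("CASSA", "CASS*D", "CASSC"),
    v_gene = "TRBV1", j_gene = "TRBJ1-1", count = c(1, 2, 3),
    productive = c(TRUE, TRUE, FALSE)
  )
  r <- repertoire("s", recs)
  expect_equal(richness(r), 1)
  expect_equal(attr(r, "load_report")$rows_dropped_nonproductive, 2)
  r2 <- repertoire("s", recs, productive_only = FALSE)
  expect_equal(richness(r2), 3)
})

test_that("AIRR and immunoSEQ dialects load the same records identically", {
  rows <- data.frame(
    cdr3 = c("CASSLGGNTEAFF", "CASSYSDTGELFF", "CASSLGGNTEAFF"),
    v = c("TRBV12-3*01", "TRBV6-2", "TRBV12-1"),
    j = c("TRBJ1-1*01", "TRBJ2-2", "TRBJ1-1"),
    n = c(5, 2, 1)
  )
  airr <- tempfile(fileext = ".tsv")
  write.table(
    data.frame(junction_aa = rows$cdr3, v_call = rows$v, j_call = rows$j,
               duplicate_count = rows$n, productive = "T"),
    airr, sep = "\t", quote = FALSE, row.names = FALSE
  )
  iseq <- tempfile(fileext = ".tsv")
  write.table(
    data.frame(aminoAcid = rows$cdr3, vGeneName = rows$v, jGeneName = rows$j,
               count = rows$n),
    iseq, sep = "\t", quote = FALSE, row.names = FALSE
  )
  ra <- read_clonotype_table(airr, dialect = "airr", sample_id = "x")
  ri <- read_clonotype_table(iseq, dialect = "immunoseq", sample_id = "x")
  expect_identical(ra$clonotypes, ri$clonotypes)
  expect_equal(richness(ra), 2)   # family collapse merges the TRBV12 rows
  expect_equal(total_templates(ra), 8)
})

test_that("aggregation conserves the total count of rows passing filters", {
  set.seed(42)
  n <- 50
  recs <- data.frame(
    cdr3_aa = sample(c("CASSA", "CASSC", "CASSD", "CASSE"), n, replace = TRUE),
    v_gene = sample(c("TRBV1", "TRBV2-1", "TRBV2-2"), n, replace = TRUE),
    j_gene = "TRBJ1-1",
    count = sample(1:9, n, replace = TRUE)
  )
  r <- repertoire("s", recs)
  expect_equal(total_templates(r), sum(recs$count))
})

test_that("missing required columns produce a configuration error naming them", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(junction_aa = "CASSA", v_call = "TRBV1",
                         duplicate_count = 1),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clonotype_table(f, dialect = "airr"), "j_call")
})

test_that("an empty table after filtering raises an empty-repertoire error", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(junction_aa = "CAS*S", v_call = "TRBV1",
                         j_call = "TRBJ1-1", duplicate_count = 1,
                         productive = "T"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clonotype_table(f, dialect = "airr"), "no clonotypes")
})

test_that("feature matrices round-trip through TSV exactly", {
  vals <- matrix(c(0.25, 1.5, -2, 0, 3.125, 7), nrow = 2,
                 dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  fm <- feature_matrix(vals, c("case", "control"))
  path <- tempfile(fileext = ".tsv")
  write_matrix(fm, path)
  back <- read_matrix(path)
  expect_equal(unclass(back), unclass(fm))
  expect_equal(feature_labels(back), feature_labels(fm))
})

test_that("a 0/1 presence matrix is written with bare integer tokens", {
  vals <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("k1", "k2")))
  path <- tempfile(fileext = ".tsv")
  write_matrix(feature_matrix(vals, c("case", "control")), path)
  lines <- readLines(path)
  cells <- unlist(lapply(strsplit(lines[-1], "\t"), function(x) x[2:3]))
  expect_true(all(cells %in% c("0", "1")))
  expect_equal(unclass(read_matrix(path))[, "k1"], c(a = 0, b = 1))
})

test_that("an empty feature set round-trips as a 0-feature matrix", {
  fm <- feature_matrix(matrix(numeric(0), nrow = 2, ncol = 0,
                              dimnames = list(c("a", "b"), NULL)),
                       c("case", "control"))
  path <- tempfile(fileext = ".tsv")
  write_matrix(fm, path)
  back <- read_matrix(path)
  expect_equal(ncol(back), 0)
  expect_equal(rownames(back), c("a", "b"))
})
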