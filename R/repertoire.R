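AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonical clonotype key
#'
#' Builds the `CDR3_V_J` identity string used throughout the pipeline. V gene
#' labels are stripped of allele suffixes (`*01`) and, at `family` resolution,
#' of the gene number (`TRBV12-3` collapses to `TRBV12`); J labels keep their
#' gene number but lose the allele. Labels that do not look like gene names are
#' passed through verbatim with a warning, so foreign nomenclatures degrade
#' gracefully rather than failing.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences.
#' @param v_gene,j_gene character vectors of V/J gene labels (IMGT-style,
#'   e.g. `"TRBV12-3*01"`, `"TRBJ1-1"`).
#' @param v_resolution `"family"` (default) collapses V to the family level;
#'   `"gene"` keeps the gene number.
#' @return character vector of keys, one per input clonotype.
#' @examples
#' clonotype_key("CASSLGGNTEAFF", "TRBV12-3*01", "TRBJ1-1*01")
#' clonotype_key("CASSF", "TRBV12-3", "TRBJ1-3", v_resolution = "gene")
#' @export
clonotype_key <- function(cdr3_aa, v_gene, j_gene,
                          v_resolution = c("family", "gene")) {
  v_resolution <- match.arg(v_resolution)
  v <- normalize_gene(v_gene, strip_number = (v_resolution == "family"))
  j <- normalize_gene(j_gene, strip_number = FALSE)
  paste(toupper(cdr3_aa), v, j, sep = "_")
}

# Strip allele ("*01") always; strip "-n" gene number when strip_number.
# Unrecognisable labels are returned verbatim (warn once per call).
normalize_gene <- function(label, strip_number) {
  label <- trimws(as.character(label))
  ok <- grepl("^[A-Za-z]+[0-9]+([-/][0-9A-Za-z]+)?(\\*[0-9A-Za-z]+)?$", label)
  if (any(!ok & nzchar(label))) {
    warning(sprintf("%d gene label(s) not parseable; used verbatim (e.g. '%s')",
                    sum(!ok & nzchar(label)), label[!ok & nzchar(label)][1]),
            call. = FALSE)
  }
  out <- label
  out[ok] <- sub("\\*[0-9A-Za-z]+$", "", out[ok])
  if (strip_number) out[ok] <- sub("[-/][0-9A-Za-z]+$", "", out[ok])
  out
}

#' Construct a repertoire from clonotype records
#'
#' A repertoire is one sample's deduplicated clonotype table plus its phenotype
#' label. Records are validated (non-empty CDR3 over the 20 amino-acid
#' alphabet, count >= 1), optionally restricted to productive rearrangements,
#' canonicalized with [clonotype_key()], and rows sharing a canonical key are
#' merged by summing counts (family-level collapsing necessarily merges
#' alleles/genes of one family).
#'
#' @param sample_id sample identifier.
#' @param records data frame with columns `cdr3_aa`, `v_gene`, `j_gene`,
#'   `count` and optionally `productive` (logical; missing means productive).
#' @param phenotype `"case"`, `"control"` or `"unknown"`.
#' @param v_resolution passed to [clonotype_key()].
#' @param productive_only drop non-productive rows (default `TRUE`, matching
#'   the "productive uniques" convention).
#' @return an object of class `tcr_repertoire`: list with `sample_id`,
#'   `phenotype`, `clonotypes` (data frame `key`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `count`) and a `load_report` attribute counting dropped rows.
#' @export
repertoire <- function(sample_id, records, phenotype = "unknown",
                       v_resolution = c("family", "gene"),
                       productive_only = TRUE) {
  v_resolution <- match.arg(v_resolution)
  phenotype <- match.arg(phenotype, c("case", "control", "unknown"))
  stopifnot(is.data.frame(records))
  req <- c("cdr3_aa", "v_gene", "j_gene", "count")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_in <- nrow(records)
  records$cdr3_aa <- toupper(trimws(as.character(records$cdr3_aa)))
  records$count <- suppressWarnings(as.numeric(records$count))

  prod <- if ("productive" %in% names(records)) {
    parse_productive(records$productive)
  } else rep(TRUE, n_in)
  # a stop codon in the CDR3 marks a non-productive rearrangement
  prod <- prod & !grepl("\\*", records$cdr3_aa)

  valid <- nzchar(records$cdr3_aa) &
    grepl(sprintf("^[%s*]+$", paste(AA_LETTERS, collapse = "")), records$cdr3_aa) &
    !is.na(records$count) & records$count >= 1
  keep <- valid & (!productive_only | prod)

  report <- list(
    rows_read = n_in,
    rows_dropped_invalid = sum(!valid),
    rows_dropped_nonproductive = sum(valid & productive_only & !prod)
  )
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop("sample '", sample_id, "': no clonotypes left after filtering",
         call. = FALSE)
  }

  key <- clonotype_key(records$cdr3_aa, records$v_gene, records$j_gene,
                       v_resolution)
  agg <- rowsum(records$count, group = key)
  first <- !duplicated(key)
  tab <- data.frame(
    key = key[first],
    cdr3_aa = records$cdr3_aa[first],
    v_gene = normalize_gene(records$v_gene[first],
                            strip_number = (v_resolution == "family")),
    j_gene = normalize_gene(records$j_gene[first], strip_number = FALSE),
    stringsAsFactors = FALSE
  )
  tab$count <- as.numeric(agg[tab$key, 1L])
  tab <- tab[order(tab$key), , drop = FALSE]
  rownames(tab) <- NULL
  report$duplicates_merged <- nrow(records) - nrow(tab)

  structure(
    list(sample_id = as.character(sample_id), phenotype = phenotype,
         clonotypes = tab),
    load_report = report,
    class = "tcr_repertoire"
  )
}

parse_productive <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- toupper(trimws(as.character(x)))
  x %in% c("T", "TRUE", "YES", "Y", "1", "IN", "IN-FRAME", "PRODUCTIVE")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s (%s): %d clonotypes, %s templates\n",
              x$sample_id, x$phenotype, nrow(x$clonotypes),
              format(sum(x$clonotypes$count), big.mark = ",")))
  invisible(x)
}

#' @rdname repertoire_stats
#' @export
richness <- function(rep) nrow(rep$clonotypes)

#' Basic repertoire accessors
#'
#' `richness()` is the number of unique clonotypes ("productive uniques"),
#' `total_templates()` the summed template count, `repertoire_keys()` the
#' canonical key set.
#'
#' @param rep a `tcr_repertoire`.
#' @name repertoire_stats
#' @export
total_templates <- function(rep) sum(rep$clonotypes$count)

#' @rdname repertoire_stats
#' @export
repertoire_keys <- function(rep) rep$clonotypes$key

# Column names for the two supported table dialects.
DIALECT_COLUMNS <- list(
  airr = c(cdr3_aa = "junction_aa", v_gene = "v_call", j_gene = "j_call",
           count = "duplicate_count", productive = "productive"),
  immunoseq = c(cdr3_aa = "aminoAcid", v_gene = "vGeneName",
                j_gene = "jGeneName", count = "count",
                productive = "sequenceStatus")
)

#' Read a per-sample clonotype table
#'
#' Loads one sample's rearrangement table in either the AIRR rearrangement
#' dialect (`junction_aa`, `v_call`, `j_call`, `duplicate_count`,
#' `productive`) or an immunoSEQ-export-like dialect (`aminoAcid`,
#' `vGeneName`, `jGeneName`, `count`), canonicalizes clonotype identities and
#' merges duplicates. Rows failing validation are dropped and tallied in the
#' `load_report` attribute of the result.
#'
#' @param path TSV file path.
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param column_map optional named character vector overriding the dialect's
#'   column names; names among `cdr3_aa`, `v_gene`, `j_gene`, `count`,
#'   `productive`.
#' @param sample_id sample identifier (default: file name without extension).
#' @param phenotype,v_resolution,productive_only passed to [repertoire()].
#' @return a `tcr_repertoire`.
#' @export
read_clonotype_table <- function(path, dialect = c("airr", "immunoseq"),
                                 column_map = NULL,
                                 sample_id = sub("\\.[^.]*$", "", basename(path)),
                                 phenotype = "unknown",
                                 v_resolution = c("family", "gene"),
                                 productive_only = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- DIALECT_COLUMNS[[dialect]]
  if (!is.null(column_map)) cols[names(column_map)] <- column_map

  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- cols[c("cdr3_aa", "v_gene", "j_gene", "count")]
  absent <- required[!required %in% names(raw)]
  if (length(absent)) {
    stop(sprintf("column '%s' (for %s) not found in %s",
                 absent[1], names(absent)[1], path), call. = FALSE)
  }
  records <- data.frame(
    cdr3_aa = raw[[cols[["cdr3_aa"]]]],
    v_gene = raw[[cols[["v_gene"]]]],
    j_gene = raw[[cols[["j_gene"]]]],
    count = raw[[cols[["count"]]]],
    stringsAsFactors = FALSE
  )
  if (cols[["productive"]] %in% names(raw)) {
    records$productive <- parse_productive(raw[[cols[["productive"]]]])
  }
  repertoire(sample_id, records, phenotype = phenotype,
             v_resolution = v_resolution, productive_only = productive_only)
}

#' Read a cohort manifest and its clonotype tables
#'
#' The manifest is a TSV with columns `sample_id`, `file` (path relative to
#' the manifest), `phenotype` (`case`/`control`) and `split` (`train`/`test`).
#'
#' @param manifest_path manifest TSV path.
#' @param dialect,v_resolution passed to [read_clonotype_table()].
#' @return list with `train` and `test`, each a named list of
#'   `tcr_repertoire` objects.
#' @export
read_cohort <- function(manifest_path, dialect = "airr",
                        v_resolution = "family") {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "file", "phenotype", "split")
  if (!all(req %in% names(man))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(man$sample_id)) stop("duplicate sample_id in manifest")
  if (!all(c("case", "control") %in% man$phenotype[man$split == "train"])) {
    stop("train split must contain both phenotypes", call. = FALSE)
  }
  base <- dirname(manifest_path)
  load_split <- function(split) {
    rows <- man[man$split == split, , drop = FALSE]
    reps <- lapply(seq_len(nrow(rows)), function(i) {
      read_clonotype_table(file.path(base, rows$file[i]), dialect = dialect,
                           sample_id = rows$sample_id[i],
                           phenotype = rows$phenotype[i],
                           v_resolution = v_resolution)
    })
    names(reps) <- rows$sample_id
    reps
  }
  list(train = load_split("train"), test = load_split("test"))
}

cohort_phenotypes <- function(cohort) {
  vapply(cohort, function(r) r$phenotype, character(1))
}
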