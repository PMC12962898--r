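# Corpus container and delimited-file IO.
#
# A corpus is two tables: one row of study metadata per article, and a
# long-format findings table with one row per reported item. A finding list
# is keyed by (article_id, category, heading_phrase); item order within a
# list is carried by item_rank.

CATEGORIES <- c("metabolite", "target", "pathway")
FOCUS_LEVELS <- c("mixture", "single_compound")
METABOLITE_METHODS <- c("database_only", "experimental_integrated", "unknown")
TARGET_METHODS <- c("database_only", "omics_integrated", "unknown")

STUDY_COLS <- c(
  "article_id", "study_focus", "metabolite_method", "target_method",
  "complete_metabolite", "complete_target", "complete_pathway"
)
FINDING_COLS <- c("article_id", "category", "heading_phrase", "item_rank", "item_name")

#' Construct a corpus of study extraction records
#'
#' Bundles the study-metadata table and the long-format findings table into
#' a validated corpus object.
#'
#' @param studies data.frame with columns `article_id`, `study_focus`
#'   (`mixture`/`single_compound`), `metabolite_method`
#'   (`database_only`/`experimental_integrated`/`unknown`), `target_method`
#'   (`database_only`/`omics_integrated`/`unknown`), and logical
#'   `complete_metabolite`, `complete_target`, `complete_pathway`.
#' @param findings data.frame with columns `article_id`, `category`
#'   (`metabolite`/`target`/`pathway`), `heading_phrase`, `item_rank`,
#'   `item_name`; one row per reported item. May have zero rows.
#' @param source provenance label.
#' @param validate if `TRUE` (default) run [validate_corpus()] and stop on
#'   any violation.
#' @return an object of class `napc_corpus`: list with elements `studies`,
#'   `findings` (both `data.table`) and `provenance`.
#' @export
corpus <- function(studies, findings = NULL, source = "in-memory", validate = TRUE) {
  studies <- data.table::as.data.table(studies)
  if (is.null(findings) || nrow(findings) == 0L) {
    findings <- data.table::data.table(
      article_id = character(0), category = character(0),
      heading_phrase = character(0), item_rank = integer(0),
      item_name = character(0)
    )
  } else {
    findings <- data.table::as.data.table(findings)
  }
  studies[, article_id := as.character(article_id)]
  if (nrow(findings)) {
    findings[, article_id := as.character(article_id)]
    findings[, item_rank := as.integer(item_rank)]
  }
  obj <- structure(
    list(
      studies = studies[, STUDY_COLS, with = FALSE],
      findings = findings[, FINDING_COLS, with = FALSE],
      provenance = list(
        source = source,
        schema_version = "1",
        ingested_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "napc_corpus"
  )
  if (validate) {
    problems <- validate_corpus(obj)
    if (length(problems)) {
      stop("invalid corpus:\n", paste0("  - ", problems, collapse = "\n"),
           call. = FALSE)
    }
  }
  obj
}

#' @export
print.napc_corpus <- function(x, ...) {
  cat(sprintf(
    "<napc_corpus> %d studies, %d finding rows (%d lists) [source: %s]\n",
    nrow(x$studies), nrow(x$findings),
    if (nrow(x$findings)) nrow(unique(x$findings[, .(article_id, category, heading_phrase)])) else 0L,
    x$provenance$source
  ))
  invisible(x)
}

#' Validate a corpus
#'
#' Checks every schema invariant and returns *all* violations (not just the
#' first), each prefixed with the offending table and row number:
#' missing columns, duplicate `article_id`, invalid enum values, findings
#' rows referencing unknown studies (orphans), non-positive or missing item
#' ranks, and blank item names.
#'
#' @param x a `napc_corpus` (or a list with `studies`/`findings` tables).
#' @return character vector of human-readable problems; empty if valid.
#' @export
validate_corpus <- function(x) {
  st <- data.table::as.data.table(x$studies)
  fd <- data.table::as.data.table(x$findings)
  problems <- character(0)
  miss_s <- setdiff(STUDY_COLS, names(st))
  miss_f <- setdiff(FINDING_COLS, names(fd))
  if (length(miss_s)) {
    return(sprintf("studies table missing column(s): %s", paste(miss_s, collapse = ", ")))
  }
  if (length(miss_f)) {
    return(sprintf("findings table missing column(s): %s", paste(miss_f, collapse = ", ")))
  }

  dup <- st$article_id[duplicated(st$article_id)]
  for (d in unique(dup)) {
    rows <- which(st$article_id == d)
    problems <- c(problems, sprintf(
      "studies rows %s: duplicate article_id '%s'",
      paste(rows, collapse = ","), d))
  }
  bad_enum <- function(vals, allowed, col) {
    bad <- which(!(vals %in% allowed) | is.na(vals))
    sprintf("studies row %d: invalid %s '%s'", bad, col, vals[bad])
  }
  problems <- c(problems,
    bad_enum(st$study_focus, FOCUS_LEVELS, "study_focus"),
    bad_enum(st$metabolite_method, METABOLITE_METHODS, "metabolite_method"),
    bad_enum(st$target_method, TARGET_METHODS, "target_method"))
  for (col in c("complete_metabolite", "complete_target", "complete_pathway")) {
    bad <- which(is.na(st[[col]]))
    problems <- c(problems, sprintf("studies row %d: missing %s flag", bad, col))
  }

  if (nrow(fd)) {
    bad_cat <- which(!(fd$category %in% CATEGORIES) | is.na(fd$category))
    problems <- c(problems, sprintf(
      "findings row %d: unknown category '%s'", bad_cat, fd$category[bad_cat]))
    orphan <- which(!(fd$article_id %in% st$article_id))
    problems <- c(problems, sprintf(
      "findings row %d: article_id '%s' not present in studies table",
      orphan, fd$article_id[orphan]))
    bad_rank <- which(is.na(fd$item_rank) | fd$item_rank < 1L)
    problems <- c(problems, sprintf(
      "findings row %d: item_rank must be a positive integer", bad_rank))
    blank <- which(is.na(fd$item_name) | !nzchar(trimws(fd$item_name)))
    problems <- c(problems, sprintf("findings row %d: blank item_name", blank))
  }
  problems
}

#' Read a corpus from its two delimited files
#'
#' Reads the study-metadata and findings CSV files (UTF-8, comma-separated,
#' header row, minimal quoting) and returns a validated corpus. All
#' validation violations are reported together, with table and row
#' coordinates.
#'
#' @param studies_path path to `studies.csv`.
#' @param findings_path path to `findings.csv`.
#' @return a validated [corpus()].
#' @export
read_corpus <- function(studies_path, findings_path) {
  for (p in c(studies_path, findings_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  # base read.csv: full RFC4180 quote handling for fields embedding the
  # separator or quotes
  st <- utils::read.csv(studies_path, colClasses = c(article_id = "character"),
                        fileEncoding = "UTF-8")
  fd <- utils::read.csv(findings_path, colClasses = c(article_id = "character"),
                        fileEncoding = "UTF-8")
  corpus(st, fd, source = studies_path)
}

#' Write a corpus to its two delimited files
#'
#' Inverse of [read_corpus()]: emits `studies.csv` and `findings.csv` in the
#' documented dialect (UTF-8, comma separator, header row, quoting only
#' where a field embeds the separator or a quote). Round-tripping through
#' [read_corpus()] reproduces the corpus exactly, and re-serializing the
#' round-tripped corpus is byte-identical.
#'
#' @param x a `napc_corpus`.
#' @param studies_path,findings_path output paths (directories must exist).
#' @return invisibly, the two paths.
#' @export
write_corpus <- function(x, studies_path, findings_path) {
  stopifnot(inherits(x, "napc_corpus"))
  data.table::fwrite(x$studies, studies_path, quote = "auto", bom = FALSE)
  data.table::fwrite(x$findings, findings_path, quote = "auto", bom = FALSE)
  invisible(c(studies_path, findings_path))
}

#' Extract one article's record from a corpus
#'
#' Returns the study's metadata together with its finding lists, each list
#' an object with `category`, `heading_phrase` and ordered `items`.
#'
#' @param x a `napc_corpus`.
#' @param id article identifier.
#' @return list with the metadata fields and `finding_lists`.
#' @export
article_record <- function(x, id) {
  stopifnot(inherits(x, "napc_corpus"))
  row <- x$studies[article_id == id]
  if (nrow(row) == 0L) stop("unknown article_id: ", id, call. = FALSE)
  fd <- x$findings[article_id == id]
  lists <- list()
  if (nrow(fd)) {
    # lists in document (file) order; items ordered by item_rank
    keys <- unique(fd[, .(category, heading_phrase)])
    lists <- lapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i]
      sub <- fd[category == k$category & heading_phrase == k$heading_phrase]
      list(
        category = k$category,
        heading_phrase = k$heading_phrase,
        items = sub$item_name[order(sub$item_rank)]
      )
    })
  }
  c(as.list(row), list(finding_lists = lists))
}
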