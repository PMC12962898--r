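# Per-study extraction: glossary heading matching, list selection,
# nomenclature standardization and the exclusion gates.
#
# Fixed order of operations per study and category:
#   focus gate (single-compound studies, metabolite census only)
#   -> completeness gate
#   -> glossary heading match
#   -> list selection (smallest non-identical list)
#   -> synonym standardization + within-list dedup
#   -> item-count threshold gate
# Every failure mode is an exclusion reason, never an error.

EXCLUSION_REASONS <- c(
  "single_compound_study", "incomplete_data", "no_matching_heading",
  "exceeds_threshold"
)

#' Does a heading phrase match the glossary?
#'
#' True iff the normalized heading equals one of the glossary's normalized
#' phrases for the category (exact phrase equality, not substring).
#'
#' @param heading character vector of heading phrases.
#' @param glossary a [glossary()].
#' @param category `"metabolite"`, `"target"` or `"pathway"`.
#' @return logical vector.
#' @export
match_heading <- function(heading, glossary, category) {
  category <- match.arg(category, CATEGORIES)
  normalize_name(heading) %in% glossary[[category]]
}

#' Select one finding list among glossary-matched candidates
#'
#' Studies sometimes present several key-element lists for one category.
#' The most refined (fewest items) is kept; byte-identical lists collapse
#' to one. An equal-size tie between non-identical lists keeps the
#' first-occurring list and emits a warning.
#'
#' @param matched_lists list of finding lists, each a list with `items`
#'   (and optionally `heading_phrase`), in document order.
#' @return the selected finding list, or `NULL` if the input is empty.
#' @export
select_finding_list <- function(matched_lists) {
  if (length(matched_lists) == 0L) return(NULL)
  items <- lapply(matched_lists, `[[`, "items")
  uniq <- !duplicated(items)
  matched_lists <- matched_lists[uniq]
  items <- items[uniq]
  if (length(matched_lists) == 1L) return(matched_lists[[1L]])
  sizes <- lengths(items)
  best <- which(sizes == min(sizes))
  if (length(best) > 1L) {
    warning(sprintf(
      "tie between %d non-identical %d-item lists; keeping the first-occurring",
      length(best), sizes[best[1L]]), call. = FALSE)
  }
  matched_lists[[best[1L]]]
}

#' Standardize raw element names
#'
#' Normalizes each item, replaces known synonyms by their canonical display
#' name, and removes duplicates arising after unification, keeping first
#' occurrence order. Unknown names pass through as their normalized form.
#'
#' @param items character vector of raw names.
#' @param synonyms a [synonym_map()] (or `NULL`).
#' @return character vector of unique canonical names.
#' @export
standardize_elements <- function(items, synonyms = NULL) {
  out <- apply_synonyms(items, synonyms)
  out[!duplicated(out)]
}

#' Extract one study's per-category findings
#'
#' Applies the full gate sequence to a single article record and returns,
#' per category, either the standardized element list or the exclusion
#' reason.
#'
#' @param record an [article_record()].
#' @param glossary a [glossary()].
#' @param synonyms a [synonym_map()].
#' @param max_items item-count threshold applied to the standardized,
#'   deduplicated list (default 30).
#' @param dedupe_before_threshold if `TRUE` (default) the threshold is
#'   applied after synonym unification and dedup; if `FALSE`, to the raw
#'   item count of the selected list (exposed for sensitivity checking).
#' @return list with `article_id` and per-category outcomes, each either
#'   `list(status = "included", elements = ...)` or
#'   `list(status = "excluded", reason = ..., detail = ...)`.
#' @export
extract_study_findings <- function(record, glossary, synonyms = NULL,
                                   max_items = 30L,
                                   dedupe_before_threshold = TRUE) {
  out <- list(article_id = record$article_id)
  for (cat in CATEGORIES) {
    out[[cat]] <- .extract_one_category(record, cat, glossary, synonyms,
                                        max_items, dedupe_before_threshold)
  }
  out
}

.extract_one_category <- function(record, cat, glossary, synonyms,
                                  max_items, dedupe_before_threshold) {
  excl <- function(reason, detail = "") {
    list(status = "excluded", reason = reason, detail = detail)
  }
  if (cat == "metabolite" && identical(record$study_focus, "single_compound")) {
    return(excl("single_compound_study", "study focuses on a specific compound"))
  }
  if (!isTRUE(record[[paste0("complete_", cat)]])) {
    return(excl("incomplete_data", "category data incomplete or unclear"))
  }
  cand <- Filter(function(fl) {
    fl$category == cat && match_heading(fl$heading_phrase, glossary, cat)
  }, record$finding_lists)
  sel <- select_finding_list(cand)
  if (is.null(sel)) {
    return(excl("no_matching_heading", "no list under a glossary heading"))
  }
  raw_n <- length(sel$items)
  elements <- standardize_elements(sel$items, synonyms)
  gate_n <- if (dedupe_before_threshold) length(elements) else raw_n
  if (gate_n > max_items) {
    return(excl("exceeds_threshold",
                sprintf("%d items exceeds the %d-item threshold", gate_n, max_items)))
  }
  list(status = "included", elements = elements)
}

# Vectorized whole-corpus extraction for one category, ignoring the item
# threshold (applied later so sensitivity analyses reuse one pass).
# Returns list(status = data.table(article_id, status, reason, n_raw, n_items),
#              items  = data.table(article_id, element))
.extract_category <- function(corp, cat, glossary, synonyms) {
  st <- corp$studies
  fd <- data.table::copy(corp$findings[category == cat])
  status <- data.table::data.table(
    article_id = st$article_id,
    reason = NA_character_,
    n_raw = NA_integer_,
    n_items = NA_integer_
  )
  if (cat == "metabolite") {
    status[st$study_focus == "single_compound", reason := "single_compound_study"]
  }
  complete <- st[[paste0("complete_", cat)]]
  status[is.na(reason) & !complete, reason := "incomplete_data"]

  items <- data.table::data.table(article_id = character(0), element = character(0))
  open_ids <- status[is.na(reason), article_id]
  if (nrow(fd)) {
    fd <- fd[article_id %in% open_ids]
  }
  if (nrow(fd)) {
    fd <- fd[normalize_name(heading_phrase) %in% glossary[[cat]]]
  }
  if (nrow(fd)) {
    fd[, orig := .I]
    # one list per (study, heading); collapse byte-identical lists, then take
    # the smallest; equal-size ties keep the first-occurring list
    lists <- fd[, .(first_orig = min(orig), n_raw = .N,
                    sig = paste(item_name[order(item_rank)], collapse = "\r")),
                by = .(article_id, heading_phrase)]
    data.table::setorder(lists, first_orig)
    lists <- lists[!duplicated(lists[, .(article_id, sig)])]
    data.table::setorder(lists, article_id, n_raw, first_orig)
    keep <- lists[, .SD[1L], by = article_id]
    fd <- fd[keep[, .(article_id, heading_phrase)],
             on = c("article_id", "heading_phrase")]
    data.table::setorder(fd, article_id, item_rank, orig)
    fd[, element := apply_synonyms(item_name, synonyms)]
    fd <- fd[!duplicated(fd[, .(article_id, element)])]
    items <- fd[, .(article_id, element)]
    counts <- items[, .(k = .N), by = article_id]
    status[counts, on = "article_id", n_items := i.k]
    status[keep, on = "article_id", n_raw := i.n_raw]
  }
  status[is.na(reason) & is.na(n_items), reason := "no_matching_heading"]
  status[, status := data.table::fifelse(is.na(reason), "open", "excluded")]
  list(status = status, items = items)
}
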