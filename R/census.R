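# Cohort construction and the descriptive census: prevalence rankings,
# threshold-sensitivity, methodology-stratified contrasts and chemical
# class shares.

#' Build an eligibility cohort for one category
#'
#' Partitions every corpus study into the included cohort or exactly one
#' exclusion bucket, applying the fixed gate order (focus gate for the
#' metabolite census, completeness gate, glossary heading match, list
#' selection, standardization, item-count threshold). The returned object
#' carries the full exclusion ledger and a findings cache with the
#' standardized element list of every included study.
#'
#' @param corp a [corpus()].
#' @param category `"metabolite"`, `"target"` or `"pathway"`.
#' @param glossary a [glossary()].
#' @param synonyms a [synonym_map()] (or `NULL`).
#' @param max_items item-count threshold (default 30).
#' @param dedupe_before_threshold apply the threshold to the standardized,
#'   deduplicated count (default) or to the raw selected-list count.
#' @return object of class `napc_cohort`: list with `category`,
#'   `max_items`, `included_ids`, `excluded` (named list: reason -> id
#'   vector), `N`, and `findings` (data.table `article_id`, `element`).
#' @export
build_cohort <- function(corp, category, glossary, synonyms = NULL,
                         max_items = 30L, dedupe_before_threshold = TRUE) {
  category <- match.arg(category, CATEGORIES)
  ext <- .extract_category(corp, category, glossary, synonyms)
  .apply_threshold(ext, category, max_items, dedupe_before_threshold)
}

.apply_threshold <- function(ext, category, max_items, dedupe_before_threshold = TRUE) {
  status <- data.table::copy(ext$status)
  gate <- if (dedupe_before_threshold) status[["n_items"]] else status[["n_raw"]]
  over <- status[["status"]] == "open" & !is.na(gate) & gate > max_items
  status[over, c("status", "reason") := list("excluded", "exceeds_threshold")]
  included <- status[status == "open", article_id]
  excluded <- lapply(stats::setNames(nm = EXCLUSION_REASONS), function(r) {
    status[reason == r, article_id]
  })
  structure(
    list(
      category = category,
      max_items = max_items,
      included_ids = included,
      excluded = excluded,
      N = length(included),
      findings = ext$items[article_id %in% included]
    ),
    class = "napc_cohort"
  )
}

#' @export
print.napc_cohort <- function(x, ...) {
  cat(sprintf("<napc_cohort> %s, threshold %d: N = %d included\n",
              x$category, x$max_items, x$N))
  for (r in names(x$excluded)) {
    if (length(x$excluded[[r]])) cat(sprintf("  excluded %-22s %d\n", r, length(x$excluded[[r]])))
  }
  invisible(x)
}

#' Exclusion ledger as a table
#'
#' @param cohort a `napc_cohort`.
#' @return data.table with one row per outcome (`included` plus each
#'   exclusion reason) and its study count.
#' @export
cohort_ledger <- function(cohort) {
  data.table::data.table(
    category = cohort$category,
    max_items = cohort$max_items,
    outcome = c("included", names(cohort$excluded)),
    n_studies = c(cohort$N, lengths(cohort$excluded))
  )
}

#' Prevalence ranking of key elements
#'
#' Counts, for each canonical element, the number of cohort studies whose
#' standardized list contains it (each study at most once per element) and
#' ranks elements by count (descending), ties broken by canonical name
#' (ascending). Percentages are `100 * n/N` rounded half-up to one
#' decimal.
#'
#' @param cohort a `napc_cohort` from [build_cohort()].
#' @param top_n optional truncation to the leading rows.
#' @return object of class `napc_prevalence`: data.table with columns
#'   `element`, `n`, `N`, `percent`, `rank`; attributes `category`,
#'   `stratum`, `threshold`.
#' @export
prevalence <- function(cohort, top_n = NULL) {
  stopifnot(inherits(cohort, "napc_cohort"))
  tab <- cohort$findings[, .(n = .N), by = element]
  data.table::setorder(tab, -n, element)
  tab[, `:=`(
    N = cohort$N,
    percent = round_half_up(100 * n / cohort$N, 1),
    rank = seq_len(.N)
  )]
  if (!is.null(top_n)) tab <- head(tab, top_n)
  structure(tab,
            class = c("napc_prevalence", class(tab)),
            category = cohort$category,
            stratum = attr(cohort, "stratum") %||% "overall",
            threshold = cohort$max_items)
}

#' Threshold-sensitivity analysis
#'
#' Recomputes the cohort and prevalence ranking at increasingly
#' restrictive item-count thresholds (default 30, 20, 10, 5). A threshold
#' `t` cohort contains the studies whose standardized list has at most `t`
#' elements — studies are filtered, lists are never truncated, so
#' denominators shrink with `t`. Cohorts nest: `cohort(t1)` is a subset of
#' `cohort(t2)` whenever `t1 <= t2`.
#'
#' @inheritParams build_cohort
#' @param thresholds distinct positive item-count thresholds.
#' @param top_n optional truncation of each prevalence table.
#' @return object of class `napc_sensitivity`: list with per-threshold
#'   `cohorts` and `tables` (named by threshold) and `rank_stability`, a
#'   data.table element x threshold matrix of ranks (`NA` = absent).
#' @export
sensitivity <- function(corp, category, glossary, synonyms = NULL,
                        thresholds = c(30L, 20L, 10L, 5L), top_n = NULL) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0),
            !anyDuplicated(thresholds))
  category <- match.arg(category, CATEGORIES)
  ext <- .extract_category(corp, category, glossary, synonyms)
  cohorts <- lapply(thresholds, function(t) .apply_threshold(ext, category, t))
  names(cohorts) <- as.character(thresholds)
  tables <- lapply(cohorts, prevalence, top_n = top_n)
  elements <- unique(unlist(lapply(tables, function(tb) tb$element)))
  rs <- data.table::data.table(element = elements)
  for (t in names(tables)) {
    tb <- tables[[t]]
    rs[[paste0("rank_t", t)]] <- tb$rank[match(elements, tb$element)]
  }
  structure(list(thresholds = thresholds, cohorts = cohorts,
                 tables = tables, rank_stability = rs),
            class = "napc_sensitivity")
}

#' Methodology-stratified prevalence contrast
#'
#' Splits the cohort by how the category's inputs were obtained —
#' database-dependent versus experiment/omics-integrated — and computes a
#' prevalence table per stratum plus the per-element difference in
#' percentage points. Studies with an `unknown` method flag are excluded
#' from both strata (their count is reported); they remain in the overall
#' cohort. Pathways carry no method flag and cannot be stratified.
#'
#' @inheritParams build_cohort
#' @param flag_field `"metabolite_method"` or `"target_method"`; defaults
#'   to the flag matching `category`.
#' @param top_n optional truncation of the stratum tables.
#' @return object of class `napc_stratified`: list with `tables` (named
#'   `database_dependent`, `integrated`), `difference` (data.table:
#'   element, percent in each stratum, difference in percentage points),
#'   and `n_unknown`.
#' @export
stratify <- function(corp, category, glossary, synonyms = NULL,
                     flag_field = NULL, max_items = 30L, top_n = NULL) {
  category <- match.arg(category, CATEGORIES)
  if (category == "pathway") {
    stop("pathway studies carry no methodology flag; stratification is not defined",
         call. = FALSE)
  }
  default_flag <- paste0(category, "_method")
  flag_field <- flag_field %||% default_flag
  if (!identical(flag_field, default_flag)) {
    stop(sprintf("flag_field '%s' does not match category '%s' (expected '%s')",
                 flag_field, category, default_flag), call. = FALSE)
  }
  flags <- stats::setNames(corp$studies[[flag_field]], corp$studies$article_id)
  integrated_level <- setdiff(
    if (category == "metabolite") METABOLITE_METHODS else TARGET_METHODS,
    c("database_only", "unknown")
  )
  strata <- list(database_dependent = "database_only",
                 integrated = integrated_level)
  cohort <- build_cohort(corp, category, glossary, synonyms, max_items)
  n_unknown <- sum(flags[cohort$included_ids] == "unknown")
  tables <- lapply(strata, function(levels) {
    sub <- cohort
    sub$included_ids <- cohort$included_ids[flags[cohort$included_ids] %in% levels]
    sub$N <- length(sub$included_ids)
    sub$findings <- cohort$findings[article_id %in% sub$included_ids]
    prevalence(sub, top_n = top_n)
  })
  all_el <- unique(c(tables[[1]]$element, tables[[2]]$element))
  diff <- data.table::data.table(
    element = all_el,
    percent_database = tables$database_dependent$percent[
      match(all_el, tables$database_dependent$element)],
    percent_integrated = tables$integrated$percent[
      match(all_el, tables$integrated$element)]
  )
  diff[is.na(percent_database), percent_database := 0]
  diff[is.na(percent_integrated), percent_integrated := 0]
  diff[, difference_pp := percent_database - percent_integrated]
  attr(tables$database_dependent, "stratum") <- "database_dependent"
  attr(tables$integrated, "stratum") <- "integrated"
  structure(list(category = category, flag_field = flag_field,
                 tables = tables, difference = diff, n_unknown = n_unknown),
            class = "napc_stratified")
}

#' Chemical-class share among the top of a prevalence table
#'
#' Fraction of the top `top_k` ranked elements belonging to a focal
#' chemical class (e.g. flavonoids among the top 20 metabolites). If the
#' table is shorter than `top_k` the denominator is the table length.
#'
#' @param table a `napc_prevalence`.
#' @param classes a [class_map()].
#' @param focal_class class label of interest (default `"flavonoid"`).
#' @param top_k number of leading ranks considered (default 20).
#' @return object of class `napc_class_share`: list with `top_k`,
#'   `counts` (table of class -> count among the top-k) and `share`
#'   (fraction of the focal class).
#' @export
class_share <- function(table, classes, focal_class = "flavonoid", top_k = 20L) {
  stopifnot(inherits(table, "napc_prevalence"))
  top <- head(table, top_k)
  cls <- element_class(top$element, classes)
  counts <- table(cls)
  denom <- nrow(top)
  share <- if (denom == 0L) 0 else sum(cls == focal_class) / denom
  structure(list(top_k = top_k, counts = counts,
                 focal_class = focal_class, share = share),
            class = "napc_class_share")
}

#' Format a prevalence entry the way census tables print it
#'
#' @param n,N study count and cohort size.
#' @return character like `"63.2% (294/465)"`.
#' @export
format_prevalence <- function(n, N) {
  sprintf("%.1f%% (%d/%d)", round_half_up(100 * n / N, 1), n, N)
}
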