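# Report rendering and end-to-end orchestration.

#' Render a census report bundle
#'
#' Writes one delimited table per analysis (`prevalence_<category>_
#' <stratum>_<threshold>.csv`), one exclusion ledger per cohort
#' (`ledger_<category>.csv`), a machine-readable `summary.json` (cohort
#' sizes, exclusion counts, top-3 rows per table) and a `run.log` with the
#' configuration hash and seed. Deterministic for fixed inputs and seed.
#'
#' @param tables list of `napc_prevalence` tables.
#' @param ledgers list of `napc_cohort` objects.
#' @param out_dir output directory (created if missing).
#' @param seed integer recorded in the run log.
#' @param config optional configuration object recorded (hashed) in the
#'   run log.
#' @return invisibly, the paths written.
#' @export
render_report <- function(tables = list(), ledgers = list(), out_dir,
                          seed = NA_integer_, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- character(0)
  summary <- list(
    n_tables = length(tables), cohorts = list(), tables = list()
  )
  for (tb in tables) {
    key <- paste0(attr(tb, "category"), "_", attr(tb, "stratum"),
                  "_t", attr(tb, "threshold"))
    p <- file.path(out_dir, paste0("prevalence_", key, ".csv"))
    data.table::fwrite(as.data.frame(tb), p)
    paths <- c(paths, p)
    summary$tables[[key]] <- lapply(seq_len(min(3L, nrow(tb))), function(i) {
      list(element = tb$element[i], n = tb$n[i], N = tb$N[i],
           percent = tb$percent[i])
    })
  }
  for (co in ledgers) {
    p <- file.path(out_dir, paste0("ledger_", co$category, ".csv"))
    data.table::fwrite(cohort_ledger(co), p)
    paths <- c(paths, p)
    summary$cohorts[[co$category]] <- c(
      list(N = co$N, max_items = co$max_items),
      lapply(co$excluded, length)
    )
  }
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, sp)

  cfg_hash <- if (is.null(config)) "none" else {
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf), add = TRUE)
    jsonlite::write_json(config, tf, auto_unbox = TRUE, force = TRUE, digits = NA)
    unname(tools::md5sum(tf))
  }
  lp <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("napcensus %s", as.character(utils::packageVersion("napcensus"))),
    sprintf("seed: %s", seed),
    sprintf("config_md5: %s", cfg_hash),
    sprintf("tables: %d, ledgers: %d", length(tables), length(ledgers))
  ), lp)
  invisible(c(paths, lp))
}

#' Run the full census over a corpus
#'
#' Convenience orchestration: per category, builds the cohort, the overall
#' prevalence table and (optionally) the threshold-sensitivity and
#' methodology-stratified analyses, and renders the report bundle.
#'
#' @param corp a [corpus()].
#' @param glossary a [glossary()].
#' @param synonyms a [synonym_map()].
#' @param categories categories to census (default all three).
#' @param max_items overall item threshold (default 30).
#' @param thresholds sensitivity thresholds, or `NULL` to skip.
#' @param stratified compute stratified contrasts for metabolite/target
#'   categories (default `TRUE`).
#' @param top_n optional table truncation.
#' @param out_dir if non-`NULL`, render the report bundle there.
#' @param seed seed recorded in the run log.
#' @return list with per-category `cohorts`, `tables`, `sensitivity`,
#'   `stratified`.
#' @export
run_census <- function(corp, glossary, synonyms = NULL,
                       categories = CATEGORIES, max_items = 30L,
                       thresholds = c(30L, 20L, 10L, 5L), stratified = TRUE,
                       top_n = NULL, out_dir = NULL, seed = NA_integer_) {
  res <- list(cohorts = list(), tables = list(), sensitivity = list(),
              stratified = list())
  for (cat in categories) {
    co <- build_cohort(corp, cat, glossary, synonyms, max_items)
    res$cohorts[[cat]] <- co
    res$tables[[cat]] <- prevalence(co, top_n = top_n)
    if (!is.null(thresholds)) {
      res$sensitivity[[cat]] <- sensitivity(corp, cat, glossary, synonyms,
                                            thresholds = thresholds, top_n = top_n)
    }
    if (stratified && cat != "pathway") {
      res$stratified[[cat]] <- stratify(corp, cat, glossary, synonyms,
                                        max_items = max_items, top_n = top_n)
    }
  }
  if (!is.null(out_dir)) {
    all_tables <- c(res$tables,
                    unlist(lapply(res$stratified, function(s) s$tables),
                           recursive = FALSE))
    render_report(all_tables, res$cohorts, out_dir, seed = seed)
  }
  res
}
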