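# Shared assets and independent straight-line oracles used across tests.

GL <- synth_glossary()
SY <- synth_synonyms()

small_config <- function(seed, n = 15L, ...) {
  args <- utils::modifyList(
    list(n_studies = n, seed = seed,
         universe_size = c(metabolite = 30L, target = 30L, pathway = 30L),
         L_max = 8L, length_size = 3, length_mu = 4),
    list(...)
  )
  do.call(synthetic_config, args)
}

# Straight-line per-record reimplementation of the gate sequence,
# deliberately independent of the vectorized extraction path.
oracle_classify <- function(corp, cat, gl = GL, sy = SY, max_items = 30L) {
  lapply(stats::setNames(nm = corp$studies$article_id), function(id) {
    rec <- article_record(corp, id)
    if (cat == "metabolite" && rec$study_focus == "single_compound") {
      return(list(reason = "single_compound_study"))
    }
    if (!rec[[paste0("complete_", cat)]]) {
      return(list(reason = "incomplete_data"))
    }
    cand <- list()
    for (fl in rec$finding_lists) {
      if (fl$category == cat && normalize_name(fl$heading_phrase) %in% gl[[cat]]) {
        cand[[length(cand) + 1L]] <- fl$items
      }
    }
    cand <- cand[!duplicated(cand)]
    if (length(cand) == 0L) return(list(reason = "no_matching_heading"))
    sizes <- vapply(cand, length, integer(1))
    items <- cand[[which.min(sizes)]]   # which.min takes the first minimum
    els <- unique(apply_synonyms(items, sy))
    if (length(els) > max_items) return(list(reason = "exceeds_threshold"))
    list(elements = els)
  })
}

# Naive nested-loop prevalence recount from an oracle classification.
oracle_prevalence <- function(oracle) {
  inc <- Filter(function(x) is.null(x$reason), oracle)
  N <- length(inc)
  counts <- list()
  for (x in inc) for (e in x$elements) {
    counts[[e]] <- (counts[[e]] %||% 0L) + 1L
  }
  if (length(counts) == 0L) {
    return(data.frame(element = character(0), n = integer(0), N = integer(0)))
  }
  d <- data.frame(element = names(counts), n = unlist(counts), N = N,
                  row.names = NULL, stringsAsFactors = FALSE)
  d <- d[order(-d$n, d$element), ]
  rownames(d) <- NULL
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
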