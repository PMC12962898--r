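# Pinned-corpus builders: deterministic corpora whose cohort arithmetic and
# element counts are fixed exactly, used for worked examples and validation
# against printed census tables. All synthetic, built in code — no stored
# data.

.fixture_headings <- c(metabolite = "key metabolites", target = "key targets",
                       pathway = "key pathways")

#' Build a corpus with pinned exclusion counts and element counts
#'
#' Constructs a fully deterministic corpus in which, per category, a
#' prescribed number of studies fails each exclusion gate (disjoint
#' blocks) and the included studies are partitioned into strata with exact
#' per-element study counts. Used to pin n/N prevalence arithmetic.
#'
#' @param n_total corpus size.
#' @param spec named list (per category) with optional counts
#'   `single_compound`, `no_heading`, `over_threshold`, `incomplete` and a
#'   `strata` list; each stratum is `list(method =, n =, elements = c(name
#'   = count, ...), pad_to = NULL)`. Stratum sizes plus exclusions must sum
#'   to `n_total`. `pad_to` pads each study list with unique filler items
#'   up to the given length.
#' @return a [corpus()].
#' @export
pinned_corpus <- function(n_total, spec) {
  ids <- sprintf("P%05d", seq_len(n_total))
  studies <- data.table::data.table(
    article_id = ids,
    study_focus = "mixture",
    metabolite_method = "database_only",
    target_method = "database_only",
    complete_metabolite = TRUE,
    complete_target = TRUE,
    complete_pathway = TRUE
  )
  fd <- list()
  add <- function(id, cat, heading, items) {
    fd[[length(fd) + 1L]] <<- data.table::data.table(
      article_id = id, category = cat, heading_phrase = heading,
      item_rank = seq_along(items), item_name = items)
  }
  for (cat in names(spec)) {
    sp <- spec[[cat]]
    counts <- c(single_compound = sp$single_compound %||% 0L,
                no_heading = sp$no_heading %||% 0L,
                over_threshold = sp$over_threshold %||% 0L,
                incomplete = sp$incomplete %||% 0L)
    if (counts[["single_compound"]] > 0L && cat != "metabolite") {
      stop("single_compound exclusions only apply to the metabolite census",
           call. = FALSE)
    }
    n_inc <- sum(vapply(sp$strata, `[[`, numeric(1), "n"))
    if (sum(counts) + n_inc != n_total) {
      stop(sprintf("%s: exclusions (%d) + included (%d) must equal n_total (%d)",
                   cat, sum(counts), n_inc, n_total), call. = FALSE)
    }
    pos <- 0L
    take <- function(k) {
      out <- if (k > 0L) ids[pos + seq_len(k)] else character(0)
      pos <<- pos + k
      out
    }
    head_ok <- .fixture_headings[[cat]]
    sc_ids <- take(counts[["single_compound"]])
    if (length(sc_ids)) {
      studies[article_id %in% sc_ids, study_focus := "single_compound"]
      for (id in sc_ids) add(id, cat, head_ok, paste0("sc-", cat, "-", id))
    }
    for (id in take(counts[["no_heading"]])) {
      add(id, cat, "methods", paste0("nh-", cat, "-", id, "-", 1:3))
    }
    for (id in take(counts[["over_threshold"]])) {
      add(id, cat, head_ok, paste0("bulk-", cat, "-", id, "-", 1:31))
    }
    inc_ids <- take(counts[["incomplete"]])
    if (length(inc_ids)) {
      data.table::set(studies, which(ids %in% inc_ids),
                      paste0("complete_", cat), FALSE)
      for (id in inc_ids) add(id, cat, head_ok, paste0("inc-", cat, "-", id))
    }
    for (stratum in sp$strata) {
      s_ids <- take(stratum$n)
      if (!is.null(stratum$method)) {
        flag_col <- paste0(cat, "_method")
        data.table::set(studies, which(ids %in% s_ids), flag_col, stratum$method)
      }
      el <- stratum$elements %||% integer(0)
      if (length(el) && max(el) > stratum$n) {
        stop("element count exceeds stratum size in ", cat, call. = FALSE)
      }
      for (j in seq_along(s_ids)) {
        id <- s_ids[j]
        items <- names(el)[el >= j]
        items <- c(items, paste0("filler-", cat, "-", id))
        pad <- stratum$pad_to %||% 0L
        if (length(items) < pad) {
          items <- c(items, paste0("pad-", cat, "-", id, "-",
                                   seq_len(pad - length(items))))
        }
        add(id, cat, head_ok, items)
      }
    }
  }
  corpus(studies, data.table::rbindlist(fd), source = "pinned-fixture")
}

.census_exclusions <- list(
  metabolite = list(single_compound = 305L, no_heading = 259L,
                    over_threshold = 8L, incomplete = 1L),
  target = list(no_heading = 107L, over_threshold = 49L, incomplete = 2L),
  pathway = list(no_heading = 87L, over_threshold = 30L, incomplete = 4L)
)

#' Pinned fixture corpora and network
#'
#' Deterministic 1,038-study corpora reproducing the census arithmetic:
#' `fixture_table1()` pins the overall cohort sizes (465/880/917) and the
#' top-3 element counts per category; `fixture_table2()` pins the
#' methodology-stratified counts (328/137 metabolite strata, 725/153
#' target strata plus 2 unknown); `fixture_top5()` pins the restrictive
#' threshold sub-cohorts (258 studies with at most 5 metabolites, 162
#' listing Quercetin; 261 with at most 5 targets, 93 listing AKT1).
#' `fixture_taohong()` generates the compound-target network audit
#' fixture: five ghost flavonoid/sterol compounds with target degrees
#' 223, 125, 119, 118 and 109, in-vivo evidenced constituents with modest
#' degrees, the hub target AKT1 reachable only through ghosts, and the two
#' five-element core target sets to compare.
#'
#' @return a [corpus()]; for `fixture_taohong()` a list with `network`,
#'   `evidence`, `core_empirical`, `core_database`.
#' @export
fixture_table1 <- function() {
  pinned_corpus(1038L, list(
    metabolite = c(.census_exclusions$metabolite, list(strata = list(
      list(method = NULL, n = 465L,
           elements = c(Quercetin = 294L, Kaempferol = 223L, Luteolin = 144L))))),
    target = c(.census_exclusions$target, list(strata = list(
      list(method = NULL, n = 880L,
           elements = c(AKT1 = 429L, TNF = 344L, EGFR = 306L))))),
    pathway = c(.census_exclusions$pathway, list(strata = list(
      list(method = NULL, n = 917L,
           elements = c("AGE-RAGE signaling pathway" = 504L,
                        "PI3K-Akt signaling pathway" = 502L,
                        "Lipid and atherosclerosis" = 460L)))))
  ))
}

#' @rdname fixture_table1
#' @export
fixture_table2 <- function() {
  pinned_corpus(1038L, list(
    metabolite = c(.census_exclusions$metabolite, list(strata = list(
      list(method = "database_only", n = 328L,
           elements = c(Quercetin = 236L, Kaempferol = 178L,
                        "Beta-sitosterol" = 120L, Luteolin = 115L,
                        Stigmasterol = 57L)),
      list(method = "experimental_integrated", n = 137L,
           elements = c(Quercetin = 58L, Kaempferol = 45L, Luteolin = 29L,
                        Naringenin = 20L, Isorhamnetin = 20L))))),
    target = c(.census_exclusions$target, list(strata = list(
      list(method = "database_only", n = 725L,
           elements = c(AKT1 = 398L, TNF = 309L, EGFR = 270L,
                        IL6 = 256L, ESR1 = 235L)),
      list(method = "omics_integrated", n = 153L,
           elements = c(IL6 = 37L, PTGS2 = 37L, EGFR = 36L,
                        TNF = 35L, ESR1 = 33L, AKT1 = 30L)),
      list(method = "unknown", n = 2L)))),
    pathway = c(.census_exclusions$pathway, list(strata = list(
      list(method = NULL, n = 917L))))
  ))
}

#' @rdname fixture_table1
#' @export
fixture_top5 <- function() {
  pinned_corpus(1038L, list(
    metabolite = c(.census_exclusions$metabolite, list(strata = list(
      list(method = NULL, n = 258L, elements = c(Quercetin = 162L)),
      list(method = NULL, n = 207L, pad_to = 8L)))),
    target = c(.census_exclusions$target, list(strata = list(
      list(method = NULL, n = 261L, elements = c(AKT1 = 93L)),
      list(method = NULL, n = 619L, pad_to = 8L)))),
    pathway = c(.census_exclusions$pathway, list(strata = list(
      list(method = NULL, n = 917L))))
  ))
}

#' @rdname fixture_table1
#' @param seed integer seed for target assignment in the network fixture.
#' @export
fixture_taohong <- function(seed = 1L) {
  gen <- generate_network(
    ghost_profile = c(Quercetin = 223L, Luteolin = 125L, Kaempferol = 119L,
                      Baicalein = 118L, "Beta-sitosterol" = 109L),
    evidence_degrees = c("Ferulic acid" = 28L, "Vanillic acid" = 21L,
                         "Caffeic acid" = 35L, "Paeoniflorin" = 40L,
                         "Amygdalin" = 30L, "Hydroxysafflor yellow A" = 38L),
    n_targets = 300L, ghost_only_target = "AKT1", seed = seed
  )
  list(
    network = gen$network,
    evidence = gen$evidence,
    core_empirical = c("JUN", "PTGS2", "BCL2", "ESR1", "PPARG"),
    core_database = c("TP53", "HSP90AA1", "AKT1", "JUN", "EP300")
  )
}
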