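test_that("percent formatting rounds half up to one decimal", {
  expect_equal(round_half_up(100 * 429 / 880, 1), 48.8)   # exact .75 tie
  expect_equal(round_half_up(100 * 294 / 465, 1), 63.2)
  expect_equal(round_half_up(100 * 162 / 258, 1), 62.8)
  expect_equal(round_half_up(100 * 398 / 725, 1), 54.9)
  expect_equal(round_half_up(138.8, 0), 139)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_identical(format_prevalence(294, 465), "63.2% (294/465)")
})

test_that("cohort ledgers match an independent straight-line classification", {
  cp <- generate_corpus(small_config(seed = 31, n = 200,
                                     L_max = 35L, length_mu = 18,
                                     universe_size = c(metabolite = 60L, target = 60L,
                                                       pathway = 60L)))
  for (cat in c("metabolite", "target", "pathway")) {
    co <- build_cohort(cp, cat, GL, SY, max_items = 30)
    oracle <- oracle_classify(cp, cat, max_items = 30)
    inc_oracle <- names(Filter(function(x) is.null(x$reason), oracle))
    expect_setequal(co$included_ids, inc_oracle)
    for (r in names(co$excluded)) {
      expect_setequal(co$excluded[[r]],
                      names(Filter(function(x) identical(x$reason, r), oracle)))
    }
    # the findings cache matches the oracle's standardized lists
    for (id in head(inc_oracle, 20)) {
      expect_setequal(co$findings[co$findings$article_id == id, element],
                      oracle[[id]]$elements)
    }
  }
})

test_that("ledger partitions are conserved and disjoint", {
  for (seed in 1:5) {
    cp <- generate_corpus(small_config(seed = seed, n = 30))
    for (cat in c("metabolite", "target")) {
      co <- build_cohort(cp, cat, GL, SY)
      all_ids <- c(co$included_ids, unlist(co$excluded))
      expect_setequal(all_ids, cp$studies$article_id)
      expect_equal(length(all_ids), nrow(cp$studies))  # pairwise disjoint
      expect_equal(co$N, length(co$included_ids))
    }
  }
})

test_that("prevalence equals a hash-count oracle and orders deterministically", {
  cp <- generate_corpus(small_config(seed = 13, n = 30))
  co <- build_cohort(cp, "metabolite", GL, SY)
  tab <- prevalence(co)
  oracle <- oracle_prevalence(oracle_classify(cp, "metabolite"))
  expect_equal(tab$element, oracle$element)
  expect_equal(tab$n, oracle$n)
  expect_true(all(tab$N == co$N))
  expect_true(all(diff(tab$n) <= 0))                       # n non-increasing
  expect_true(all(tab$percent >= 0 & tab$percent <= 100))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(tab$n >= 1))                             # n = 0 never emitted
  expect_equal(tab$percent, round_half_up(100 * tab$n / tab$N, 1))
  # tie-break: equal counts ordered by canonical name ascending
  ties <- tab[tab$n %in% tab$n[duplicated(tab$n)], ]
  if (nrow(ties) > 1) {
    for (v in unique(ties$n)) {
      e <- ties$element[ties$n == v]
      expect_identical(e, sort(e))
    }
  }
})

test_that("sensitivity cohorts nest and degenerate corpora are threshold-invariant", {
  cp <- generate_corpus(small_config(seed = 77, n = 120, L_max = 12, length_mu = 6))
  s <- sensitivity(cp, "target", GL, SY, thresholds = c(12L, 8L, 4L, 2L))
  th <- sort(s$thresholds)
  for (i in seq_len(length(th) - 1)) {
    lo <- s$cohorts[[as.character(th[i])]]$included_ids
    hi <- s$cohorts[[as.character(th[i + 1])]]$included_ids
    expect_true(all(lo %in% hi))
  }
  # every study reports exactly 1 element -> identical tables at all thresholds
  ids <- sprintf("u%02d", 1:12)
  studies <- data.frame(article_id = ids, study_focus = "mixture",
                        metabolite_method = "database_only",
                        target_method = "database_only",
                        complete_metabolite = TRUE, complete_target = TRUE,
                        complete_pathway = TRUE)
  findings <- data.frame(article_id = ids, category = "target",
                         heading_phrase = "key targets", item_rank = 1L,
                         item_name = rep(c("AKT1", "TNF", "IL6"), 4))
  s1 <- sensitivity(corpus(studies, findings), "target", GL, SY)
  for (t in names(s1$tables)) {
    expect_equal(as.data.frame(s1$tables[[t]]), as.data.frame(s1$tables[[1]]),
                 ignore_attr = TRUE)
  }
})

test_that("stratified tables equal prevalence over manually split corpora and recombine", {
  cp <- generate_corpus(small_config(seed = 55, n = 150))
  st <- stratify(cp, "target", GL, SY)
  flags <- stats::setNames(cp$studies$target_method, cp$studies$article_id)
  # split-and-recount oracle: subset the corpus per stratum and recount
  for (stratum in c("database_only", "omics_integrated")) {
    keep <- cp$studies$article_id[flags == stratum]
    sub <- corpus(cp$studies[cp$studies$article_id %in% keep, ],
                  cp$findings[cp$findings$article_id %in% keep, ])
    tb_oracle <- oracle_prevalence(oracle_classify(sub, "target"))
    tb <- st$tables[[if (stratum == "database_only") "database_dependent" else "integrated"]]
    expect_equal(tb$element, tb_oracle$element)
    expect_equal(tb$n, tb_oracle$n)
  }
  # recombination: per element, flagged-study counts sum across strata
  co_all <- build_cohort(cp, "target", GL, SY)
  known_ids <- co_all$included_ids[flags[co_all$included_ids] != "unknown"]
  overall <- table(co_all$findings[co_all$findings$article_id %in% known_ids, element])
  a <- st$tables$database_dependent; b <- st$tables$integrated
  for (el in names(overall)) {
    na <- if (el %in% a$element) a$n[a$element == el] else 0L
    nb <- if (el %in% b$element) b$n[b$element == el] else 0L
    expect_equal(unname(na + nb), unname(as.integer(overall[el])))
  }
  expect_error(stratify(cp, "pathway", GL, SY), "no methodology flag")
  expect_error(stratify(cp, "target", GL, SY, flag_field = "metabolite_method"),
               "does not match")
})

test_that("a single-stratum corpus yields an empty table for the other stratum", {
  cp <- generate_corpus(small_config(seed = 3, n = 25,
                                     p_integrated = c(metabolite = 0, target = 0),
                                     unknown_rate = c(metabolite = 0, target = 0)))
  st <- stratify(cp, "target", GL, SY)
  expect_equal(nrow(st$tables$integrated), 0L)
  expect_gt(nrow(st$tables$database_dependent), 0L)
})

test_that("class share counts the focal class among the top-k", {
  tab <- structure(
    data.table::data.table(
      element = c(paste0("Flav", 1:15), paste0("Other", 1:10)),
      n = 25:1, N = 100L, percent = round_half_up(100 * (25:1) / 100, 1),
      rank = 1:25),
    class = c("napc_prevalence", "data.table", "data.frame"))
  cm <- class_map(paste0("Flav", 1:15), rep("flavonoid", 15))
  cs <- class_share(tab, cm, "flavonoid", top_k = 20)
  expect_equal(cs$share, 0.75)
  expect_equal(class_share(tab, class_map(), "flavonoid", 20)$share, 0)
  # filter-and-count oracle over random tables
  set.seed(8)
  for (i in 1:5) {
    k <- sample(3:25, 1)
    cls <- sample(c("flavonoid", "other"), 25, TRUE)
    cm2 <- class_map(tab$element, cls)
    expected <- sum(cls[seq_len(min(k, 25))] == "flavonoid") / min(k, 25)
    expect_equal(class_share(tab, cm2, "flavonoid", k)$share, expected)
  }
})

test_that("report bundles round-trip and the summary mirrors in-memory objects", {
  cp <- generate_corpus(small_config(seed = 17, n = 40))
  d <- withr::local_tempdir()
  res <- run_census(cp, GL, SY, thresholds = NULL, stratified = FALSE,
                    out_dir = d, seed = 17)
  for (cat in c("metabolite", "target", "pathway")) {
    p <- file.path(d, sprintf("prevalence_%s_overall_t30.csv", cat))
    expect_true(file.exists(p))
    back <- data.table::fread(p)
    expect_equal(back$element, res$tables[[cat]]$element)
    expect_equal(back$percent, res$tables[[cat]]$percent)
    lg <- data.table::fread(file.path(d, sprintf("ledger_%s.csv", cat)))
    expect_equal(lg$n_studies[lg$outcome == "included"], res$cohorts[[cat]]$N)
  }
  sm <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(sm$cohorts$metabolite$N, res$cohorts$metabolite$N)
  expect_equal(sm$tables$metabolite_overall_t30[[1]]$element,
               res$tables$metabolite$element[1])
  expect_true(file.exists(file.path(d, "run.log")))

  # empty analysis set still writes a valid summary
  d2 <- withr::local_tempdir()
  render_report(list(), list(), d2)
  expect_equal(jsonlite::read_json(file.path(d2, "summary.json"))$n_tables, 0L)
})
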