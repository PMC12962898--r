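test_that("a corpus ingests its two tables and exposes records with multiple lists", {
  studies <- data.frame(
    article_id = c("a1", "a2"), study_focus = "mixture",
    metabolite_method = "database_only", target_method = "database_only",
    complete_metabolite = TRUE, complete_target = TRUE, complete_pathway = TRUE
  )
  findings <- data.frame(
    article_id = c("a1", "a1", "a1"),
    category = c("metabolite", "metabolite", "target"),
    heading_phrase = c("key metabolites", "core components", "key targets"),
    item_rank = 1L,
    item_name = c("quercetin", "rutin", "AKT1")
  )
  cp <- corpus(studies, findings)
  expect_equal(nrow(cp$studies), 2L)
  rec <- article_record(cp, "a1")
  expect_length(rec$finding_lists, 3L)
  expect_length(Filter(function(f) f$category == "metabolite", rec$finding_lists), 2L)
  expect_length(article_record(cp, "a2")$finding_lists, 0L)

  # empty findings file: records with zero lists
  cp0 <- corpus(studies, NULL)
  expect_equal(nrow(cp0$findings), 0L)
  expect_length(article_record(cp0, "a1")$finding_lists, 0L)
})

test_that("validation reports every violation with row coordinates", {
  studies <- data.frame(
    article_id = c("a1", "a1", "a3"), study_focus = c("mixture", "mixture", "banana"),
    metabolite_method = "database_only", target_method = "database_only",
    complete_metabolite = TRUE, complete_target = TRUE, complete_pathway = TRUE
  )
  findings <- data.frame(
    article_id = c("a1", "zz", "a3"),
    category = c("metabolite", "target", "protein"),
    heading_phrase = "key metabolites", item_rank = 1L,
    item_name = c("x", "y", "z")
  )
  problems <- validate_corpus(list(studies = studies, findings = findings))
  expect_true(any(grepl("duplicate article_id 'a1'", problems)))
  expect_true(any(grepl("row 3: invalid study_focus 'banana'", problems)))
  expect_true(any(grepl("row 2: article_id 'zz'", problems)))
  expect_true(any(grepl("row 3: unknown category 'protein'", problems)))
  expect_gte(length(problems), 4L)   # all violations, not just the first
  expect_error(corpus(studies, findings), "invalid corpus")
})

test_that("write/read round-trip is the identity and re-serialization is byte-stable", {
  cp <- generate_corpus(small_config(seed = 42, n = 50))
  d <- withr::local_tempdir()
  sp <- file.path(d, "studies.csv"); fp <- file.path(d, "findings.csv")
  write_corpus(cp, sp, fp)
  back <- read_corpus(sp, fp)
  expect_equal(as.data.frame(back$studies), as.data.frame(cp$studies))
  expect_equal(as.data.frame(back$findings), as.data.frame(cp$findings))

  sp2 <- file.path(d, "studies2.csv"); fp2 <- file.path(d, "findings2.csv")
  write_corpus(back, sp2, fp2)
  expect_identical(readBin(sp, "raw", file.size(sp)), readBin(sp2, "raw", file.size(sp2)))
  expect_identical(readBin(fp, "raw", file.size(fp)), readBin(fp2, "raw", file.size(fp2)))
})

test_that("fields embedding the delimiter or quotes survive the round-trip", {
  studies <- data.frame(
    article_id = "a1", study_focus = "mixture",
    metabolite_method = "database_only", target_method = "database_only",
    complete_metabolite = TRUE, complete_target = TRUE, complete_pathway = TRUE
  )
  nasty <- 'epigallocatechin, 3-"gallate"'
  findings <- data.frame(article_id = "a1", category = "metabolite",
                         heading_phrase = "key metabolites",
                         item_rank = 1L, item_name = nasty)
  d <- withr::local_tempdir()
  write_corpus(corpus(studies, findings),
               file.path(d, "s.csv"), file.path(d, "f.csv"))
  back <- read_corpus(file.path(d, "s.csv"), file.path(d, "f.csv"))
  expect_identical(back$findings$item_name, nasty)
})

test_that("an empty corpus round-trips as header-only files", {
  cp <- generate_corpus(small_config(seed = 1, n = 0))
  d <- withr::local_tempdir()
  sp <- file.path(d, "s.csv"); fp <- file.path(d, "f.csv")
  write_corpus(cp, sp, fp)
  expect_length(readLines(sp), 1L)
  expect_length(readLines(fp), 1L)
  back <- read_corpus(sp, fp)
  expect_equal(nrow(back$studies), 0L)
  expect_equal(nrow(back$findings), 0L)
})

test_that("glossaries reject cross-category and blank phrases", {
  expect_s3_class(glossary(metabolite = "Key  Metabolites"), "napc_glossary")
  expect_identical(glossary(metabolite = "Key  Metabolites")$metabolite,
                   "key metabolites")
  expect_error(glossary(metabolite = "key findings", target = "Key Findings"),
               "two categories")
  gl <- read_glossary(default_glossary_path())
  expect_true("core targets" %in% gl$target)
})

test_that("synonym maps unify high-frequency aliases and enforce invariants", {
  m <- synonym_map(c("sophoretin", "meletin"), c("Quercetin", "Quercetin"))
  expect_identical(unname(apply_synonyms(c("Sophoretin", "MELETIN"), m)),
                   c("Quercetin", "Quercetin"))
  # one alias, two canonicals: hard error naming the alias
  expect_error(synonym_map(c("rutoside", "rutoside"), c("Rutin", "Quercetin")),
               "rutoside")
  # chained canonical: B is itself an alias of C
  expect_error(synonym_map(c("a", "b"), c("B", "C")), "chained")
  m2 <- read_synonyms(default_synonyms_path())
  expect_identical(unname(apply_synonyms("COX-2", m2)), "PTGS2")
})

test_that("synonym application is idempotent and total over random alias maps", {
  set.seed(99)
  pool <- replicate(100, paste(sample(letters, 8, TRUE), collapse = ""))
  canon <- paste0("Canon", sprintf("%02d", sample.int(30, 100, TRUE)))
  m <- synonym_map(pool, canon)
  probes <- c(pool, canon, "never seen name", "  Another  UNSEEN ")
  once <- apply_synonyms(probes, m)
  expect_identical(apply_synonyms(once, m), once)
  expect_identical(unname(apply_synonyms("never seen name", m)), "never seen name")
})

test_that("class maps label unmapped elements as unclassified", {
  cm <- read_classmap(default_classmap_path())
  expect_identical(unname(element_class(c("Quercetin", "Beta-sitosterol", "x17"), cm)),
                   c("flavonoid", "phytosterol", "unclassified"))
  expect_error(class_map("Quercetin", ""), "empty class label")
})
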