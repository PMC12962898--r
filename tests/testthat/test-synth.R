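test_that("the generator is deterministic in its seed", {
  cfg <- small_config(seed = 101, n = 30)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_equal(as.data.frame(a$studies), as.data.frame(b$studies))
  expect_equal(as.data.frame(a$findings), as.data.frame(b$findings))
  d <- withr::local_tempdir()
  write_corpus(a, file.path(d, "sa.csv"), file.path(d, "fa.csv"))
  write_corpus(b, file.path(d, "sb.csv"), file.path(d, "fb.csv"))
  expect_identical(readBin(file.path(d, "fa.csv"), "raw", file.size(file.path(d, "fa.csv"))),
                   readBin(file.path(d, "fb.csv"), "raw", file.size(file.path(d, "fb.csv"))))
  c2 <- generate_corpus(small_config(seed = 102, n = 30))
  expect_false(identical(as.data.frame(a$findings), as.data.frame(c2$findings)))
})

test_that("degenerate and infeasible configurations are handled", {
  expect_equal(nrow(generate_corpus(small_config(seed = 1, n = 0))$studies), 0L)
  expect_error(synthetic_config(universe_size = c(metabolite = 5L, target = 50L,
                                                  pathway = 50L), L_max = 10L),
               "infeasible")
  expect_error(synthetic_config(single_compound_rate = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(zipf_s = 0), "positive")
})

test_that("exact mode pins the exclusion arithmetic", {
  cfg <- synthetic_config(n_studies = 60, seed = 9,
                          universe_size = c(metabolite = 60L, target = 60L,
                                            pathway = 60L),
                          L_max = 35L, length_mu = 8)
  counts <- list(metabolite = c(single_compound = 10L, no_heading = 8L,
                                over_threshold = 3L, incomplete = 2L),
                 target = c(single_compound = 0L, no_heading = 5L,
                            over_threshold = 1L, incomplete = 1L),
                 pathway = c(single_compound = 0L, no_heading = 2L,
                             over_threshold = 2L, incomplete = 0L))
  cp <- generate_corpus(cfg, mode = "exact", exact_counts = counts)
  for (cat in names(counts)) {
    co <- build_cohort(cp, cat, GL, SY, max_items = 30)
    expect_equal(co$N, 60L - sum(counts[[cat]]))
    reason_of <- c(single_compound = "single_compound_study",
                   no_heading = "no_matching_heading",
                   over_threshold = "exceeds_threshold",
                   incomplete = "incomplete_data")
    got <- lengths(co$excluded)[reason_of[names(counts[[cat]])]]
    expect_equal(unname(got), unname(as.integer(counts[[cat]])))
  }
})

test_that("analytic inclusion probabilities match exhaustive enumeration", {
  # universe 4, fixed length 2, Zipf(1) database weights
  cfg <- synthetic_config(n_studies = 1, seed = 1,
                          universe_size = c(metabolite = 4L, target = 4L, pathway = 4L),
                          L_max = 2L, length_probs = c(0, 1),
                          zipf_s = 1)
  w <- (1:4)^-1 / sum((1:4)^-1)
  enum_incl <- function(w, i, l) {
    tot <- 0
    rec <- function(drawn, p) {
      if (length(drawn) == l) {
        if (i %in% drawn) tot <<- tot + p
        return()
      }
      for (j in setdiff(seq_along(w), drawn)) {
        rec(c(drawn, j), p * w[j] / sum(w[setdiff(seq_along(w), drawn)]))
      }
    }
    rec(integer(0), 1)
    tot
  }
  for (i in 1:4) {
    expect_equal(expected_prevalence(cfg, i, "metabolite", "database_dependent"),
                 enum_incl(w, i, 2), tolerance = 1e-12)
  }
  # mixture weights of the integrated stratum against the same oracle
  wi <- napcensus:::.stratum_weights(cfg, "metabolite", "integrated")
  for (i in 1:4) {
    expect_equal(expected_prevalence(cfg, i, "metabolite", "integrated"),
                 enum_incl(wi, i, 2), tolerance = 1e-12)
  }
})

test_that("symmetry and impossibility limits of the inclusion probability", {
  # uniform weights, universe 10, single draw: 1/10 for every element
  cfg <- synthetic_config(n_studies = 1, seed = 1, zipf_s = 1e-12,
                          universe_size = c(metabolite = 10L, target = 10L, pathway = 10L),
                          L_max = 1L, length_probs = 1)
  for (i in c(1, 5, 10)) {
    expect_equal(expected_prevalence(cfg, i, "metabolite", "database_dependent"),
                 0.1, tolerance = 1e-9)
  }
  # w = 0: integrated draws live entirely in the disease sub-universe
  cfg0 <- synthetic_config(n_studies = 1, seed = 1, w = 0,
                           universe_size = c(metabolite = 10L, target = 10L, pathway = 10L),
                           disease_fraction = 0.5, L_max = 3L,
                           length_probs = c(.3, .4, .3))
  expect_equal(expected_prevalence(cfg0, 1, "metabolite", "integrated"), 0)
  expect_gt(expected_prevalence(cfg0, 8, "metabolite", "integrated"), 0)
})

test_that("Monte Carlo estimates agree with the exact dynamic program", {
  cfg <- synthetic_config(n_studies = 1, seed = 3,
                          universe_size = c(metabolite = 12L, target = 12L, pathway = 12L),
                          L_max = 5L, length_probs = c(.2, .2, .2, .2, .2))
  set.seed(42)
  p_exact <- expected_prevalence(cfg, 1, "metabolite", "database_dependent",
                                 method = "exact")
  p_mc <- expected_prevalence(cfg, 1, "metabolite", "database_dependent",
                              method = "mc", nsim = 20000)
  expect_lt(abs(p_mc - p_exact), 4 * attr(p_mc, "se"))
})

test_that("generated networks embed the requested degree profile", {
  profile <- c(ghosta = 223L, ghostb = 125L, ghostc = 119L,
               ghostd = 118L, ghoste = 109L)
  gen <- generate_network(profile, c(evid1 = 20L, evid2 = 30L),
                          n_targets = 300L, seed = 5)
  deg <- compound_degrees(gen$network)
  expect_equal(deg[names(profile)], vapply(profile, as.integer, integer(1)))
  expect_equal(mean_degree(gen$network, names(profile))$rounded, 139L)
  expect_true(length(ghost_only_targets(gen$network, gen$evidence)) >= 1L)

  # random profiles under a recount oracle
  set.seed(10)
  for (i in 1:5) {
    pr <- stats::setNames(sample.int(40, 4), paste0("g", 1:4))
    ge <- generate_network(pr, c(ev = 10L), n_targets = 60L, seed = i)
    dg <- compound_degrees(ge$network)
    expect_equal(unname(dg[paste0("g", 1:4)]), unname(as.integer(pr)))
  }

  # zero ghosts: nothing to flag, and a ghost-only target is impossible
  gen0 <- generate_network(stats::setNames(integer(0), character(0)),
                           c(ev = 5L), n_targets = 20L,
                           ghost_only_target = NULL, seed = 2)
  expect_length(flag_ghosts(gen0$network, gen0$evidence), 0L)
  expect_error(generate_network(stats::setNames(integer(0), character(0)),
                                c(ev = 5L), n_targets = 20L, seed = 2),
               "at least one ghost")
  expect_error(generate_network(c(g = 500L), c(ev = 5L), n_targets = 100L),
               "infeasible degree")
})

test_that("rate-mode marginals converge to the configured gate rates", {
  cfg <- small_config(seed = 123, n = 1500,
                      single_compound_rate = 0.3,
                      no_heading_rate = c(metabolite = 0.2, target = 0.1, pathway = 0.05),
                      incomplete_rate = c(metabolite = 0.02, target = 0.02, pathway = 0.02))
  cp <- generate_corpus(cfg)
  n <- nrow(cp$studies)
  p_sc <- mean(cp$studies$study_focus == "single_compound")
  expect_lt(abs(p_sc - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  co <- build_cohort(cp, "target", GL, SY)
  p_nh <- length(co$excluded$no_matching_heading) / n
  expect_lt(abs(p_nh - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})
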