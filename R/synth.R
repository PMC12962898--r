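# Synthetic biased-corpus generator. Emulates the statistical structure the
# census assumes: a popularity-ranked (Zipf-like) element universe per
# category, database-dependent studies drawing from the popularity law,
# integrated studies drawing from a mixture of popularity and a uniform
# disease-specific sub-universe, configurable exclusion-gate rates, and an
# over-threshold tail in the list-length law. Also generates bipartite
# compound-target networks with an embedded ghost degree profile.

# Named rosters heading each universe; the remainder is synthetic filler.
.flavonoid_pool <- c(
  "Quercetin", "Kaempferol", "Luteolin", "Apigenin", "Naringenin",
  "Isorhamnetin", "Baicalein", "Wogonin", "Genistein", "Rutin",
  "Hesperetin", "Catechin", "Epicatechin", "Myricetin", "Chrysin",
  "Galangin", "Fisetin", "Morin", "Daidzein", "Taxifolin"
)
.nonflavonoid_pool <- c(
  "Beta-sitosterol", "Stigmasterol", "Ursolic acid", "Oleanolic acid",
  "Ferulic acid", "Vanillic acid", "Caffeic acid", "Chlorogenic acid",
  "Gallic acid", "Paeoniflorin", "Berberine", "Curcumin", "Resveratrol",
  "Emodin", "Rhein", "Astragaloside IV", "Ginsenoside Rg1", "Tanshinone IIA",
  "Salvianolic acid B", "Glycyrrhizin"
)
.nonflavonoid_class <- c(
  "phytosterol", "phytosterol", "triterpenoid", "triterpenoid",
  "phenolic acid", "phenolic acid", "phenolic acid", "phenolic acid",
  "phenolic acid", "monoterpene glycoside", "alkaloid", "curcuminoid",
  "stilbene", "anthraquinone", "anthraquinone", "triterpenoid saponin",
  "triterpenoid saponin", "diterpenoid quinone", "phenolic acid",
  "triterpenoid saponin"
)
.target_pool <- c(
  "AKT1", "TNF", "IL6", "EGFR", "ESR1", "TP53", "VEGFA", "STAT3", "JUN",
  "PTGS2", "MAPK3", "MAPK1", "CASP3", "IL1B", "BCL2", "TGFB1", "MMP9",
  "SRC", "HIF1A", "MYC"
)
.pathway_pool <- c(
  "PI3K-Akt signaling pathway", "AGE-RAGE signaling pathway",
  "Lipid and atherosclerosis", "Pathways in cancer",
  "MAPK signaling pathway", "TNF signaling pathway",
  "HIF-1 signaling pathway", "Apoptosis", "IL-17 signaling pathway",
  "NF-kappa B signaling pathway", "Calcium signaling pathway"
)
.synth_aliases <- list(
  "Quercetin" = c("Sophoretin", "Meletin"),
  "Kaempferol" = "Robigenin",
  "Luteolin" = "Digitoflavone",
  "Naringenin" = "Naringetol",
  "Beta-sitosterol" = "β-sitosterol",
  "Ferulic acid" = "4-hydroxy-3-methoxycinnamic acid",
  "AKT1" = c("PKB", "RAC-alpha serine/threonine-protein kinase"),
  "TNF" = c("TNF-α", "tumor necrosis factor alpha"),
  "IL6" = "interleukin-6",
  "EGFR" = c("ERBB1", "HER1"),
  "ESR1" = "estrogen receptor alpha",
  "TP53" = "p53",
  "PTGS2" = c("COX-2", "COX2"),
  "JUN" = "c-Jun",
  "VEGFA" = "VEGF-A"
)
.decoy_headings <- c(
  "methods", "all identified compounds", "screened components",
  "network construction", "docking results"
)

#' Synthetic-corpus configuration
#'
#' Full parameterization of the generative model. Defaults emulate a
#' census-scale study population: 1,038 studies, exclusion-gate rates
#' matching the observed cohort arithmetic (about 29% single-compound
#' studies, per-category no-matching-heading rates of roughly 25%/10%/8%,
#' rare incomplete records), Zipf exponent 1 over each element universe,
#' and a list-length law whose tail exceeds the 30-item threshold for a
#' fraction of a percent of studies.
#'
#' @param n_studies number of studies.
#' @param seed integer seed fixing the whole corpus.
#' @param universe_size named vector: elements per category universe.
#' @param zipf_s Zipf exponent(s) `s > 0`; popularity weight of the rank-r
#'   element is proportional to `1/r^s`. Scalar recycled per category.
#' @param flavonoid_fraction fraction of the top 20 metabolite-universe
#'   elements drawn from the flavonoid roster.
#' @param p_integrated named vector: probability that a study is
#'   experiment/omics-integrated, per category with a method flag.
#' @param unknown_rate named vector: probability of an `unknown` method
#'   flag.
#' @param w bias-mixture weight in `[0,1]`: integrated studies draw
#'   elements with weights `w * popularity + (1 - w) * uniform` over the
#'   disease-specific sub-universe; database-dependent studies draw from
#'   the popularity law alone. `w = 1` removes the integration benefit.
#' @param disease_fraction fraction of each universe (the low-popularity
#'   tail) forming the disease-specific sub-universe.
#' @param length_probs optional probability vector over list lengths
#'   `1..L_max`; default is a shifted negative binomial
#'   (`size = length_size`, `mu = length_mu`) truncated at `L_max`.
#' @param length_size,length_mu,L_max parameters of the default length law.
#' @param single_compound_rate probability a study focuses on a single
#'   compound (excluded from the metabolite census).
#' @param no_heading_rate named per-category probability that a study's
#'   list appears under a non-glossary (decoy) heading.
#' @param incomplete_rate named per-category probability of an incomplete
#'   record.
#' @param alias_rate probability that an item is rendered as one of its
#'   known synonyms rather than its canonical name.
#' @return object of class `napc_synth_config` (a validated list).
#' @export
synthetic_config <- function(n_studies = 1038L,
                             seed = 1L,
                             universe_size = c(metabolite = 300L, target = 500L, pathway = 200L),
                             zipf_s = 1,
                             flavonoid_fraction = 0.75,
                             p_integrated = c(metabolite = 0.295, target = 0.174),
                             unknown_rate = c(metabolite = 0, target = 0.002),
                             w = 0.3,
                             disease_fraction = 0.5,
                             length_probs = NULL,
                             length_size = 3, length_mu = 10, L_max = 40L,
                             single_compound_rate = 0.294,
                             no_heading_rate = c(metabolite = 0.249, target = 0.103, pathway = 0.084),
                             incomplete_rate = c(metabolite = 0.001, target = 0.002, pathway = 0.004),
                             alias_rate = 0.15) {
  if (length(zipf_s) == 1L) zipf_s <- stats::setNames(rep(zipf_s, 3), CATEGORIES)
  if (is.null(length_probs)) {
    p <- stats::dnbinom(0:(L_max - 1L), size = length_size, mu = length_mu - 1)
    length_probs <- p / sum(p)
  }
  cfg <- structure(list(
    n_studies = as.integer(n_studies), seed = as.integer(seed),
    universe_size = universe_size, zipf_s = zipf_s,
    flavonoid_fraction = flavonoid_fraction,
    p_integrated = p_integrated, unknown_rate = unknown_rate,
    w = w, disease_fraction = disease_fraction,
    length_probs = length_probs, L_max = as.integer(L_max),
    single_compound_rate = single_compound_rate,
    no_heading_rate = no_heading_rate, incomplete_rate = incomplete_rate,
    alias_rate = alias_rate
  ), class = "napc_synth_config")
  .validate_synth_config(cfg)
  cfg
}

.validate_synth_config <- function(cfg) {
  probs <- c(cfg$p_integrated, cfg$unknown_rate, cfg$w, cfg$disease_fraction,
             cfg$single_compound_rate, cfg$no_heading_rate,
             cfg$incomplete_rate, cfg$alias_rate, cfg$flavonoid_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_studies < 0L) stop("n_studies must be non-negative", call. = FALSE)
  if (any(cfg$zipf_s <= 0)) stop("zipf_s must be positive", call. = FALSE)
  if (cfg$L_max < 1L) stop("L_max must be >= 1", call. = FALSE)
  if (abs(sum(cfg$length_probs) - 1) > 1e-8 || any(cfg$length_probs < 0)) {
    stop("length_probs must be a probability vector over 1..L_max", call. = FALSE)
  }
  if (length(cfg$length_probs) != cfg$L_max) {
    stop("length_probs must have L_max entries", call. = FALSE)
  }
  for (cat in CATEGORIES) {
    u <- cfg$universe_size[[cat]]
    if (cfg$L_max > u) {
      stop(sprintf("infeasible config: L_max (%d) exceeds the %s universe (%d)",
                   cfg$L_max, cat, u), call. = FALSE)
    }
    if (cfg$w == 0) {
      sub <- .disease_subuniverse(cfg, cat)
      if (cfg$L_max > length(sub)) {
        stop(sprintf(
          "infeasible config: with w = 0, L_max (%d) exceeds the %s disease sub-universe (%d)",
          cfg$L_max, cat, length(sub)), call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Element universe of one category
#'
#' Popularity-ranked canonical element names with chemical-class labels.
#' The head of each universe carries realistic names (the metabolite head
#' mixes flavonoid and non-flavonoid rosters according to
#' `flavonoid_fraction`); the tail is synthetic filler.
#'
#' @param config a [synthetic_config()].
#' @param category census category.
#' @return data.table with columns `element`, `class`, ranked by
#'   decreasing popularity.
#' @export
synth_universe <- function(config, category) {
  category <- match.arg(category, CATEGORIES)
  u <- config$universe_size[[category]]
  if (category == "metabolite") {
    k <- round(20 * config$flavonoid_fraction)
    head20 <- c(.flavonoid_pool[seq_len(k)],
                .nonflavonoid_pool[seq_len(20 - k)])
    cls20 <- c(rep("flavonoid", k), .nonflavonoid_class[seq_len(20 - k)])
    rest_named <- setdiff(c(.flavonoid_pool, .nonflavonoid_pool), head20)
    rest_cls <- ifelse(rest_named %in% .flavonoid_pool, "flavonoid",
                       .nonflavonoid_class[match(rest_named, .nonflavonoid_pool)])
    els <- c(head20, rest_named)
    cls <- c(cls20, rest_cls)
  } else if (category == "target") {
    els <- .target_pool
    cls <- rep("protein", length(els))
  } else {
    els <- .pathway_pool
    cls <- rep("pathway", length(els))
  }
  if (u < length(els)) {
    els <- els[seq_len(u)]; cls <- cls[seq_len(u)]
  } else if (u > length(els)) {
    filler <- sprintf("%s-%03d", category, seq_len(u - length(els)))
    els <- c(els, filler)
    cls <- c(cls, rep("unclassified", length(filler)))
  }
  data.table::data.table(element = els, class = cls)
}

#' Synonym map and class map matching the synthetic universes
#'
#' The synonym map carries the roster aliases (e.g. "Sophoretin" ->
#' "Quercetin") plus identity rows for every roster name, so standardizing
#' preserves canonical display casing ("AKT1", "Quercetin").
#'
#' @param config a [synthetic_config()].
#' @return [synonym_map()] / [class_map()] covering the generator's
#'   rosters.
#' @export
synth_synonyms <- function(config = synthetic_config()) {
  roster <- c(.flavonoid_pool, .nonflavonoid_pool, .target_pool, .pathway_pool)
  al <- c(unlist(.synth_aliases, use.names = FALSE), roster)
  cn <- c(rep(names(.synth_aliases), lengths(.synth_aliases)), roster)
  synonym_map(al, cn)
}

#' @rdname synth_synonyms
#' @export
synth_classmap <- function(config = synthetic_config()) {
  u <- data.table::rbindlist(lapply(CATEGORIES, synth_universe, config = config))
  u <- u[class != "unclassified" & class != "protein" & class != "pathway"]
  class_map(u$element, u$class)
}

#' Glossary used by the synthetic generator
#'
#' @return the shipped placeholder [glossary()].
#' @export
synth_glossary <- function() {
  glossary(
    metabolite = c("key metabolites", "key compounds", "core components",
                   "key active ingredients", "main active compounds"),
    target = c("key targets", "core targets", "hub targets", "hub genes",
               "core genes"),
    pathway = c("key pathways", "core pathways", "main enriched pathways",
                "top kegg pathways")
  )
}

.zipf_weights <- function(u, s) {
  w <- (seq_len(u))^(-s)
  w / sum(w)
}

.disease_subuniverse <- function(config, category) {
  u <- config$universe_size[[category]]
  lo <- floor(u * (1 - config$disease_fraction)) + 1L
  seq.int(lo, u)
}

# Per-element draw weights of one stratum ("database_dependent" draws from
# the popularity law; "integrated" from the w-mixture with the uniform
# disease sub-universe).
.stratum_weights <- function(config, category, stratum) {
  u <- config$universe_size[[category]]
  z <- .zipf_weights(u, config$zipf_s[[category]])
  if (stratum == "database_dependent") return(z)
  sub <- .disease_subuniverse(config, category)
  unif <- numeric(u)
  unif[sub] <- 1 / length(sub)
  config$w * z + (1 - config$w) * unif
}

#' Generate a synthetic corpus
#'
#' Draws a study population from the configured generative model. In
#' `"rate"` mode every gate (single-compound focus, decoy heading,
#' incomplete record) fires independently at its configured rate and
#' over-threshold lists arise from the length-law tail. In `"exact"` mode
#' the per-category exclusion counts are pinned exactly (disjoint study
#' blocks per category), which reproduces a prescribed cohort arithmetic;
#' `exact_counts` defaults to [default_exact_counts()].
#'
#' All randomness flows from `config$seed` through one generator stream;
#' the same config yields a byte-identical corpus.
#'
#' @param config a [synthetic_config()].
#' @param mode `"rate"` (default) or `"exact"`.
#' @param exact_counts exact-mode exclusion profile: named list per
#'   category of counts `c(single_compound=, no_heading=, over_threshold=,
#'   incomplete=)`.
#' @param exact_max_items item threshold the exact-mode blocks are pinned
#'   against (default 30).
#' @return a [corpus()].
#' @export
generate_corpus <- function(config, mode = c("rate", "exact"),
                            exact_counts = NULL, exact_max_items = 30L) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  n <- config$n_studies
  ids <- sprintf("S%05d", seq_len(n))
  gl <- synth_glossary()
  universes <- lapply(stats::setNames(nm = CATEGORIES), synth_universe, config = config)
  weights <- lapply(stats::setNames(nm = CATEGORIES), function(cat) {
    list(database_dependent = .stratum_weights(config, cat, "database_dependent"),
         integrated = .stratum_weights(config, cat, "integrated"))
  })

  if (n == 0L) {
    return(corpus(
      data.table::data.table(article_id = character(0), study_focus = character(0),
                             metabolite_method = character(0), target_method = character(0),
                             complete_metabolite = logical(0), complete_target = logical(0),
                             complete_pathway = logical(0)),
      NULL, source = "synthetic"))
  }

  if (mode == "exact") {
    if (is.null(exact_counts)) exact_counts <- default_exact_counts()
    blocks <- lapply(stats::setNames(nm = CATEGORIES), function(cat) {
      ct <- exact_counts[[cat]]
      ct <- ct[c("single_compound", "no_heading", "over_threshold", "incomplete")]
      ct[is.na(ct)] <- 0L
      if (sum(ct) > n) stop("exact_counts exceed n_studies for ", cat, call. = FALSE)
      ends <- cumsum(ct)
      list(single_compound = seq_len(ct[1L]),
           no_heading = seq.int(ends[1L] + 1L, length.out = ct[2L]),
           over_threshold = seq.int(ends[2L] + 1L, length.out = ct[3L]),
           incomplete = seq.int(ends[3L] + 1L, length.out = ct[4L]))
    })
  }

  # study-level flags
  if (mode == "rate") {
    focus <- ifelse(runif(n) < config$single_compound_rate,
                    "single_compound", "mixture")
  } else {
    focus <- rep("mixture", n)
    focus[blocks$metabolite$single_compound] <- "single_compound"
  }
  draw_method <- function(cat, levels) {
    r <- runif(n)
    p_unk <- config$unknown_rate[[cat]] %||% 0
    p_int <- config$p_integrated[[cat]] %||% 0
    out <- rep("database_only", n)
    out[r < p_unk] <- "unknown"
    out[r >= p_unk & r < p_unk + p_int] <- levels[2L]
    out
  }
  met_method <- draw_method("metabolite", c("database_only", "experimental_integrated"))
  tgt_method <- draw_method("target", c("database_only", "omics_integrated"))

  complete <- lapply(stats::setNames(nm = CATEGORIES), function(cat) {
    if (mode == "rate") {
      runif(n) >= config$incomplete_rate[[cat]]
    } else {
      ok <- rep(TRUE, n)
      ok[blocks[[cat]]$incomplete] <- FALSE
      ok
    }
  })

  # per-study, per-category finding lists
  fd_id <- character(0); fd_cat <- character(0); fd_head <- character(0)
  fd_rank <- integer(0); fd_item <- character(0)
  acc <- vector("list", 3L * n); ai <- 0L
  for (cat in CATEGORIES) {
    u <- universes[[cat]]$element
    wts <- weights[[cat]]
    integrated_flag <- switch(cat,
      metabolite = met_method == "experimental_integrated",
      target = tgt_method == "omics_integrated",
      pathway = rep(FALSE, n))
    if (mode == "rate") {
      decoy <- runif(n) < config$no_heading_rate[[cat]]
      lens <- sample.int(config$L_max, n, replace = TRUE, prob = config$length_probs)
    } else {
      decoy <- rep(FALSE, n); decoy[blocks[[cat]]$no_heading] <- TRUE
      over_p <- config$length_probs
      over_p[seq_len(min(exact_max_items, config$L_max))] <- 0
      if (sum(over_p) == 0) stop("length law has no mass above the threshold; ",
                                 "cannot pin over_threshold counts", call. = FALSE)
      ok_p <- config$length_probs
      if (config$L_max > exact_max_items) {
        ok_p[seq.int(exact_max_items + 1L, config$L_max)] <- 0
      }
      lens <- sample.int(config$L_max, n, replace = TRUE, prob = ok_p / sum(ok_p))
      ob <- blocks[[cat]]$over_threshold
      if (length(ob)) {
        lens[ob] <- sample.int(config$L_max, length(ob), replace = TRUE,
                               prob = over_p / sum(over_p))
      }
    }
    phrases <- gl[[cat]]
    heads <- ifelse(decoy,
                    sample(.decoy_headings, n, replace = TRUE),
                    sample(phrases, n, replace = TRUE))
    for (i in seq_len(n)) {
      l <- lens[i]
      wv <- if (integrated_flag[i]) wts$integrated else wts$database_dependent
      if (l > sum(wv > 0)) {
        stop(sprintf("infeasible draw: list length %d exceeds the %s support (%d)",
                     l, cat, sum(wv > 0)), call. = FALSE)
      }
      idx <- sample.int(length(u), l, prob = wv)
      items <- u[idx]
      if (config$alias_rate > 0) {
        has_alias <- items %in% names(.synth_aliases)
        swap <- has_alias & runif(l) < config$alias_rate
        if (any(swap)) {
          items[swap] <- vapply(items[swap], function(e) {
            a <- .synth_aliases[[e]]
            a[[sample.int(length(a), 1L)]]
          }, character(1))
        }
      }
      ai <- ai + 1L
      acc[[ai]] <- list(article_id = ids[i], category = cat,
                        heading_phrase = heads[i],
                        item_rank = seq_len(l), item_name = items)
    }
  }
  findings <- data.table::rbindlist(lapply(acc[seq_len(ai)], function(x) {
    data.table::data.table(article_id = x$article_id, category = x$category,
                           heading_phrase = x$heading_phrase,
                           item_rank = x$item_rank, item_name = x$item_name)
  }))

  studies <- data.table::data.table(
    article_id = ids,
    study_focus = focus,
    metabolite_method = met_method,
    target_method = tgt_method,
    complete_metabolite = complete$metabolite,
    complete_target = complete$target,
    complete_pathway = complete$pathway
  )
  corpus(studies, findings, source = "synthetic")
}

#' Exact-mode exclusion profile of the census cohort arithmetic
#'
#' Per-category exclusion counts that reproduce cohort sizes 465
#' (metabolite), 880 (target) and 917 (pathway) from a 1,038-study corpus.
#'
#' @return named list of per-category count vectors.
#' @export
default_exact_counts <- function() {
  list(
    metabolite = c(single_compound = 305L, no_heading = 259L,
                   over_threshold = 8L, incomplete = 1L),
    target = c(single_compound = 0L, no_heading = 107L,
               over_threshold = 49L, incomplete = 2L),
    pathway = c(single_compound = 0L, no_heading = 87L,
                over_threshold = 30L, incomplete = 4L)
  )
}

# Exact avoidance mass per list length for successive weighted sampling
# without replacement: subset-mass dynamic program over bitmasks of the
# non-focal elements. Feasible for universes up to ~16 elements.
.avoid_levels <- function(w, i, lmax) {
  m <- length(w) - 1L
  stopifnot(m <= 16L)
  others <- setdiff(seq_along(w), i)
  wo <- w[others]
  W <- sum(w)
  bit <- 2^(seq_len(m) - 1)
  masks <- 0; probs <- 1
  wsum_of <- function(mk) {
    vapply(mk, function(x) sum(wo[bitwAnd(x, bit) > 0]), numeric(1))
  }
  avoid <- numeric(lmax)
  for (k in seq_len(lmax)) {
    wsums <- wsum_of(masks)
    nm <- integer(0); np <- numeric(0)
    for (j in seq_len(m)) {
      free <- bitwAnd(masks, bit[j]) == 0
      if (!any(free)) next
      nm <- c(nm, masks[free] + bit[j])
      np <- c(np, probs[free] * wo[j] / (W - wsums[free]))
    }
    if (!length(nm)) { avoid[k:lmax] <- 0; return(avoid) }
    agg <- rowsum(np, group = nm)
    masks <- as.numeric(rownames(agg))
    probs <- agg[, 1L]
    avoid[k] <- sum(probs)
  }
  avoid
}

#' Analytic inclusion probability of an element
#'
#' Probability that one study's sampled key-element list contains the
#' given element, under the configured stratum weights and list-length
#' law, for a weighted without-replacement draw. Computed exactly by a
#' subset-mass dynamic program for small universes (at most 17 elements),
#' otherwise by Monte Carlo with a reported standard error (attribute
#' `"se"`).
#'
#' @param config a [synthetic_config()].
#' @param element canonical element name or universe rank (integer).
#' @param category census category.
#' @param stratum `"database_dependent"` or `"integrated"`.
#' @param method `"auto"`, `"exact"` or `"mc"`.
#' @param nsim Monte Carlo replicates when `method = "mc"`.
#' @return inclusion probability in `[0, 1]`.
#' @export
expected_prevalence <- function(config, element, category = "metabolite",
                                stratum = c("database_dependent", "integrated"),
                                method = c("auto", "exact", "mc"),
                                nsim = 20000L) {
  category <- match.arg(category, CATEGORIES)
  stratum <- match.arg(stratum)
  method <- match.arg(method)
  u <- synth_universe(config, category)$element
  i <- if (is.numeric(element)) as.integer(element) else match(element, u)
  if (is.na(i) || i < 1L || i > length(u)) {
    stop("element not in the ", category, " universe: ", element, call. = FALSE)
  }
  wv <- .stratum_weights(config, category, stratum)
  lmax <- config$L_max
  if (method == "auto") {
    method <- if (length(wv) <= 17L && lmax <= 12L) "exact" else "mc"
  }
  if (method == "exact") {
    if (length(wv) > 17L) stop("universe too large for the exact DP; use method = 'mc'",
                               call. = FALSE)
    avoid <- .avoid_levels(wv, i, lmax)
    p <- sum(config$length_probs * (1 - avoid))
    return(p)
  }
  lens <- sample.int(lmax, nsim, replace = TRUE, prob = config$length_probs)
  hit <- vapply(lens, function(l) {
    i %in% sample.int(length(wv), l, prob = wv)
  }, logical(1))
  p <- mean(hit)
  attr(p, "se") <- sqrt(p * (1 - p) / nsim)
  p
}

#' Generate a bipartite compound-target network with an embedded ghost
#' degree profile
#'
#' Named ghost compounds receive exactly the requested numbers of distinct
#' targets; evidenced compounds receive their own (modest) requested
#' degrees; optionally one target is reachable only through ghosts.
#'
#' @param ghost_profile named integer vector: ghost compound -> distinct
#'   target degree. May be empty.
#' @param evidence_degrees named integer vector: evidenced compound ->
#'   degree.
#' @param n_targets size of the target universe.
#' @param ghost_only_target name of a target forced to connect only
#'   through ghost compounds (`NULL` to skip; requires at least one ghost).
#' @param seed integer seed.
#' @param synonyms a [synonym_map()] used to canonicalize node names
#'   (default [synth_synonyms()], which preserves roster display casing).
#' @return list with `network` (a [bipartite_network()]) and `evidence`
#'   (character vector of evidenced compounds).
#' @export
generate_network <- function(ghost_profile, evidence_degrees,
                             n_targets = 300L, ghost_only_target = "AKT1",
                             seed = 1L, synonyms = synth_synonyms()) {
  set.seed(seed)
  if (any(c(ghost_profile, evidence_degrees) > n_targets)) {
    stop("infeasible degree: exceeds the number of targets", call. = FALSE)
  }
  if (!is.null(ghost_only_target) && length(ghost_profile) == 0L) {
    stop("a ghost-only target requires at least one ghost compound", call. = FALSE)
  }
  targets <- sprintf("T%04d", seq_len(n_targets))
  if (!is.null(ghost_only_target)) targets[1L] <- ghost_only_target
  pool_evidenced <- if (is.null(ghost_only_target)) targets else targets[-1L]
  rows <- list()
  for (g in names(ghost_profile)) {
    d <- ghost_profile[[g]]
    tg <- sample(targets, d)
    if (!is.null(ghost_only_target) && !(ghost_only_target %in% tg)) {
      tg[1L] <- ghost_only_target   # anchor the ghost-only target
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      compound = g, target = tg, source = "database")
  }
  for (e in names(evidence_degrees)) {
    d <- evidence_degrees[[e]]
    if (d > length(pool_evidenced)) {
      stop("infeasible degree for evidenced compound ", e, call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      compound = e, target = sample(pool_evidenced, d), source = "database")
  }
  edges <- if (length(rows)) data.table::rbindlist(rows) else {
    data.table::data.table(compound = character(0), target = character(0),
                           source = character(0))
  }
  net <- bipartite_network(edges, synonyms = synonyms,
                           compounds = c(names(ghost_profile), names(evidence_degrees)),
                           targets = targets)
  list(network = net, evidence = apply_synonyms(names(evidence_degrees), synonyms))
}
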