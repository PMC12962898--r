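# Compound-target bipartite network audit: degree statistics, "chemical
# ghost" flagging (database compounds lacking in-vivo detection evidence),
# ghost-only target detection, and core-target-set comparison.

#' Construct a compound-target bipartite network
#'
#' Node names on both sides are canonicalized through the synonym map, and
#' duplicate (compound, target) pairs are dropped after canonicalization
#' (the first row's source label is kept).
#'
#' @param edges data.frame with columns `compound`, `target` and optional
#'   `source`.
#' @param synonyms a [synonym_map()] (or `NULL` for normalization only).
#' @param compounds,targets optional extra node names to declare (e.g.
#'   isolated compounds that should report degree 0).
#' @return object of class `napc_bipartite`: list with `compounds`,
#'   `targets` (character vectors) and `edges` (data.table).
#' @export
bipartite_network <- function(edges, synonyms = NULL,
                              compounds = character(0), targets = character(0)) {
  edges <- data.table::as.data.table(edges)
  if (!all(c("compound", "target") %in% names(edges))) {
    stop("edge table must have columns compound, target", call. = FALSE)
  }
  if (!"source" %in% names(edges)) edges[, source := NA_character_]
  edges[, compound := apply_synonyms(compound, synonyms)]
  edges[, target := apply_synonyms(target, synonyms)]
  edges <- edges[!duplicated(edges[, .(compound, target)])]
  structure(
    list(
      compounds = union(apply_synonyms(compounds, synonyms), unique(edges$compound)),
      targets = union(apply_synonyms(targets, synonyms), unique(edges$target)),
      edges = edges[, .(compound, target, source)],
      synonyms = synonyms
    ),
    class = "napc_bipartite"
  )
}

#' @export
print.napc_bipartite <- function(x, ...) {
  cat(sprintf("<napc_bipartite> %d compounds, %d targets, %d edges\n",
              length(x$compounds), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Load a compound-target edge list
#'
#' Reads a delimited file with columns `compound`, `target` and optional
#' `source` (TSV or CSV, inferred from the extension/content) and builds a
#' canonicalized, deduplicated [bipartite_network()]. Rows missing either
#' endpoint are a hard error reporting the row numbers.
#'
#' @param path edge-list file path.
#' @param synonyms a [synonym_map()] (or `NULL`).
#' @return a `napc_bipartite`.
#' @export
load_edges <- function(path, synonyms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\t", readLines(path, n = 1L)[1])) "\t" else ","
  d <- utils::read.csv(path, sep = sep, fileEncoding = "UTF-8")
  if (!all(c("compound", "target") %in% names(d))) {
    stop("edge file must have columns compound, target: ", path, call. = FALSE)
  }
  bad <- which(is.na(d$compound) | !nzchar(trimws(d$compound)) |
               is.na(d$target) | !nzchar(trimws(d$target)))
  if (length(bad)) {
    stop("malformed edge row(s) (missing endpoint): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bipartite_network(d, synonyms)
}

#' Read an in-vivo detection evidence list
#'
#' One compound per line (blank lines and `#` comments ignored),
#' canonicalized through the synonym map. The evidence set need not be a
#' subset of any network's compounds.
#'
#' @param path text file path.
#' @param synonyms a [synonym_map()] (or `NULL`).
#' @return character vector of canonical compound names.
#' @export
read_evidence <- function(path, synonyms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(apply_synonyms(x, synonyms))
}

#' Per-compound target degree
#'
#' Number of distinct targets each compound is linked to (edge multiplicity
#' across sources never counts twice). Declared compounds without edges
#' report 0.
#'
#' @param net a `napc_bipartite`.
#' @return named integer vector, one entry per declared compound.
#' @export
compound_degrees <- function(net) {
  stopifnot(inherits(net, "napc_bipartite"))
  deg <- stats::setNames(integer(length(net$compounds)), net$compounds)
  if (nrow(net$edges)) {
    tab <- net$edges[, .(k = data.table::uniqueN(target)), by = compound]
    deg[tab$compound] <- tab$k
  }
  deg
}

#' Mean target degree of a compound subset
#'
#' @param net a `napc_bipartite`.
#' @param subset non-empty character vector of compound names (canonical
#'   or alias), all present in the network.
#' @param synonyms a [synonym_map()] used to canonicalize `subset`
#'   (defaults to the map the network was built with).
#' @return list with `mean` (arithmetic mean) and `rounded`
#'   (round-half-up to the nearest integer).
#' @export
mean_degree <- function(net, subset, synonyms = net$synonyms) {
  subset <- unique(apply_synonyms(subset, synonyms))
  if (length(subset) == 0L) stop("empty compound subset", call. = FALSE)
  missing <- setdiff(subset, net$compounds)
  if (length(missing)) {
    stop("compound(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- compound_degrees(net)[subset]
  m <- mean(d)
  list(mean = m, rounded = as.integer(round_half_up(m, 0)))
}

#' Flag chemical-ghost compounds
#'
#' Network compounds without in-vivo detection evidence — the
#' database-derived constituents whose systemic exposure is unverified.
#'
#' @param net a `napc_bipartite`.
#' @param evidence character vector of evidenced compounds (canonicalized
#'   internally).
#' @param synonyms a [synonym_map()].
#' @return character vector of ghost compound names.
#' @export
flag_ghosts <- function(net, evidence, synonyms = net$synonyms) {
  stopifnot(inherits(net, "napc_bipartite"))
  setdiff(net$compounds, apply_synonyms(evidence, synonyms))
}

#' Targets reachable only through chemical ghosts
#'
#' Targets having at least one edge, every incident compound of which is a
#' ghost. These are the targets that enter the network exclusively through
#' unverified compounds.
#'
#' @inheritParams flag_ghosts
#' @return character vector of target names.
#' @export
ghost_only_targets <- function(net, evidence, synonyms = net$synonyms) {
  ghosts <- flag_ghosts(net, evidence, synonyms)
  if (nrow(net$edges) == 0L) return(character(0))
  tab <- net$edges[, .(all_ghost = all(compound %in% ghosts)), by = target]
  tab[all_ghost == TRUE, target]
}

#' Compare two core element sets
#'
#' @param a,b character vectors (treated as sets).
#' @return list with `intersection`, `jaccard` (`|a intersect b| / |a union b|`,
#'   1 for two empty sets), `a_only`, `b_only`.
#' @export
compare_core_sets <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  un <- union(a, b)
  list(
    intersection = intersect(a, b),
    jaccard = if (length(un) == 0L) 1 else length(intersect(a, b)) / length(un),
    a_only = setdiff(a, b),
    b_only = setdiff(b, a)
  )
}

#' Full chemical-ghost audit of a compound-target network
#'
#' Combines ghost flagging, degree statistics and ghost-only target
#' detection, optionally with a core-set comparison.
#'
#' @param net a `napc_bipartite`.
#' @param evidence character vector of in-vivo evidenced compounds.
#' @param synonyms a [synonym_map()].
#' @param core_a,core_b optional core target sets to compare (e.g. the
#'   empirically anchored versus the database-derived core).
#' @return object of class `napc_ghost_audit`: list with `ghosts`,
#'   `degrees` (all compounds), `ghost_mean` / `ghost_mean_rounded`,
#'   `background_mean` (mean degree over all network compounds),
#'   `evidenced_mean` (mean degree of evidenced compounds, `NA` if none),
#'   `ghost_only_targets`, and `core_comparison` (or `NULL`).
#' @export
ghost_audit <- function(net, evidence, synonyms = net$synonyms,
                        core_a = NULL, core_b = NULL) {
  evidence <- apply_synonyms(evidence, synonyms)
  ghosts <- flag_ghosts(net, evidence)
  deg <- compound_degrees(net)
  evidenced <- intersect(net$compounds, evidence)
  gm <- if (length(ghosts)) mean_degree(net, ghosts) else list(mean = NA_real_, rounded = NA_integer_)
  structure(
    list(
      ghosts = ghosts,
      degrees = deg,
      ghost_mean = gm$mean,
      ghost_mean_rounded = gm$rounded,
      background_mean = if (length(deg)) mean(deg) else NA_real_,
      evidenced_mean = if (length(evidenced)) mean(deg[evidenced]) else NA_real_,
      ghost_only_targets = ghost_only_targets(net, evidence),
      core_comparison = if (!is.null(core_a) && !is.null(core_b)) {
        compare_core_sets(core_a, core_b)
      }
    ),
    class = "napc_ghost_audit"
  )
}

#' @export
print.napc_ghost_audit <- function(x, ...) {
  cat(sprintf(
    "<napc_ghost_audit> %d ghosts (mean degree %.1f -> %s), %d ghost-only targets\n",
    length(x$ghosts), x$ghost_mean,
    ifelse(is.na(x$ghost_mean_rounded), "NA", x$ghost_mean_rounded),
    length(x$ghost_only_targets)))
  invisible(x)
}
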