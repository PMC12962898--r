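# Configuration assets: heading glossaries, synonym maps, chemical-class
# maps. The shipped defaults under inst/extdata are placeholders assembled
# from common usage ("key targets", "core targets", "hub genes", ...) and
# are meant to be replaced by a user-curated set for any real corpus.

#' Build a heading glossary
#'
#' A glossary holds, per category, the set of normalized heading phrases
#' under which a study's list counts as its key findings (e.g. "key
#' targets", "core targets"). Matching is exact on the normalized phrase —
#' deliberately not substring matching, so that e.g. "non-core targets"
#' never matches "core targets"; enumerate variants instead.
#'
#' @param metabolite,target,pathway character vectors of heading phrases.
#' @return object of class `napc_glossary`: named list of normalized
#'   phrase vectors.
#' @export
glossary <- function(metabolite = character(0), target = character(0),
                     pathway = character(0)) {
  g <- list(
    metabolite = unique(normalize_name(metabolite)),
    target = unique(normalize_name(target)),
    pathway = unique(normalize_name(pathway))
  )
  empty <- unlist(lapply(g, function(p) p[!nzchar(p)]))
  if (length(empty)) stop("glossary phrases empty after normalization", call. = FALSE)
  for (i in 1:2) for (j in (i + 1):3) {
    both <- intersect(g[[i]], g[[j]])
    if (length(both)) {
      stop(sprintf("glossary phrase in two categories (%s/%s): %s",
                   names(g)[i], names(g)[j], paste(both, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(g, class = "napc_glossary")
}

#' Read a glossary from a YAML file
#'
#' Expects top-level keys `metabolite`, `target`, `pathway`, each a list of
#' heading phrases.
#'
#' @param path YAML file path.
#' @return a [glossary()].
#' @export
read_glossary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  glossary(
    metabolite = as.character(y$metabolite %||% character(0)),
    target = as.character(y$target %||% character(0)),
    pathway = as.character(y$pathway %||% character(0))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a synonym map
#'
#' Maps normalized aliases to canonical display names (e.g. "sophoretin"
#' and "meletin" to "Quercetin"). Invariants enforced at construction:
#' each alias maps to exactly one canonical; no canonical's normalized form
#' is an alias of a *different* canonical (no chains); and application is
#' idempotent — each canonical's own normalized form is auto-registered as
#' a self-alias so that mapping a canonical returns it unchanged.
#'
#' @param alias character vector of aliases (normalized internally).
#' @param canonical character vector of canonical display names, parallel
#'   to `alias`.
#' @return object of class `napc_synonyms`: named character vector
#'   (normalized alias -> canonical).
#' @export
synonym_map <- function(alias = character(0), canonical = character(0)) {
  stopifnot(length(alias) == length(canonical))
  al <- normalize_name(alias)
  canonical <- as.character(canonical)
  if (any(!nzchar(al))) stop("blank alias in synonym map", call. = FALSE)
  if (any(!nzchar(canonical))) stop("blank canonical in synonym map", call. = FALSE)
  tab <- unique(data.table::data.table(alias = al, canonical = canonical))
  dup <- tab[, .N, by = alias][N > 1L, alias]
  if (length(dup)) {
    stop("alias mapped to multiple canonicals: ",
         paste(sprintf("'%s' -> {%s}", dup,
                       vapply(dup, function(a)
                         paste(tab[alias == a, canonical], collapse = ", "),
                         character(1))),
               collapse = "; "),
         call. = FALSE)
  }
  explicit <- stats::setNames(tab$canonical, tab$alias)
  # chain check: a canonical whose own normalized form is an alias of a
  # *different* canonical would make application non-idempotent
  cn_norm <- normalize_name(tab$canonical)
  hit <- explicit[cn_norm]
  chained <- !is.na(hit) & hit != tab$canonical
  if (any(chained)) {
    stop("chained canonical(s) in synonym map: ",
         paste(unique(sprintf("'%s' (itself an alias of '%s')",
                              tab$canonical[chained], hit[chained])),
               collapse = "; "),
         call. = FALSE)
  }
  # auto-register self-aliases so that application is idempotent
  self_new <- !(cn_norm %in% names(explicit))
  m <- c(explicit, stats::setNames(tab$canonical[self_new], cn_norm[self_new]))
  m <- m[!duplicated(names(m))]
  structure(m, class = "napc_synonyms")
}

#' Read a synonym map from a two-column CSV
#'
#' Expects columns `alias` and `canonical`. All map invariants are enforced
#' at load time; an alias mapped to two different canonicals or a chained
#' canonical is a hard error naming the offender.
#'
#' @param path CSV file path.
#' @return a [synonym_map()].
#' @export
read_synonyms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, encoding = "UTF-8")
  if (!all(c("alias", "canonical") %in% names(d))) {
    stop("synonym file must have columns alias, canonical", call. = FALSE)
  }
  synonym_map(d$alias, d$canonical)
}

#' Apply a synonym map to raw names
#'
#' Each name is normalized, then mapped to its canonical display name if
#' the map knows it, else left as its normalized form. The operation is
#' total and idempotent.
#'
#' @param x character vector of raw names.
#' @param synonyms a [synonym_map()], or `NULL` for normalization only.
#' @return character vector of canonical names.
#' @export
apply_synonyms <- function(x, synonyms = NULL) {
  nx <- normalize_name(x)
  if (is.null(synonyms) || length(synonyms) == 0L) return(nx)
  hit <- unname(unclass(synonyms)[nx])
  ifelse(is.na(hit), nx, hit)
}

#' Build / read a chemical-class map
#'
#' Maps canonical element names to chemical-class labels (e.g. flavonoid).
#' Elements absent from the map are treated as class `"unclassified"`.
#'
#' @param element character vector of canonical element names.
#' @param class character vector of class labels, parallel to `element`.
#' @return object of class `napc_classmap`: named character vector.
#' @export
class_map <- function(element = character(0), class = character(0)) {
  stopifnot(length(element) == length(class))
  class <- as.character(class)
  if (any(!nzchar(class))) stop("empty class label in class map", call. = FALSE)
  structure(stats::setNames(class, as.character(element)), class = "napc_classmap")
}

#' @rdname class_map
#' @param path CSV file path with columns `element`, `class`.
#' @export
read_classmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, encoding = "UTF-8")
  if (!all(c("element", "class") %in% names(d))) {
    stop("class map file must have columns element, class", call. = FALSE)
  }
  class_map(d$element, d$class)
}

#' Lookup chemical classes
#'
#' @param x character vector of canonical element names.
#' @param classes a [class_map()].
#' @return character vector of class labels, `"unclassified"` where unmapped.
#' @export
element_class <- function(x, classes) {
  hit <- unclass(classes)[as.character(x)]
  ifelse(is.na(hit), "unclassified", hit)
}

#' Paths of the shipped placeholder assets
#'
#' Convenience accessors for the default glossary, synonym and class-map
#' files under `inst/extdata`. These defaults are placeholders for testing
#' and examples; real analyses should supply curated files.
#'
#' @return file path.
#' @export
default_glossary_path <- function() system.file("extdata", "glossary.yaml", package = "napcensus")
#' @rdname default_glossary_path
#' @export
default_synonyms_path <- function() system.file("extdata", "synonyms.csv", package = "napcensus")
#' @rdname default_glossary_path
#' @export
default_classmap_path <- function() system.file("extdata", "classmap.csv", package = "napcensus")
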