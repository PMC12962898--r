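# Name normalization shared by heading matching, synonym mapping and the
# network audit. Everything downstream compares names only in this form.

# Greek letters commonly embedded in phytochemical names.
.greek_map <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu", "ω" = "omega",
  "Α" = "alpha", "Β" = "beta", "Γ" = "gamma",
  "Δ" = "delta", "Ε" = "epsilon", "Κ" = "kappa",
  "Λ" = "lambda", "Μ" = "mu", "Ω" = "omega"
)

# Typographic hyphens/dashes and the unicode minus, unified to ASCII "-".
.dash_chars <- "[‐‑‒–—―−]"

#' Normalize an element or heading name
#'
#' Canonical string form used for all name comparisons: case-folded, outer
#' whitespace stripped, internal whitespace runs collapsed to single spaces,
#' Greek letters transliterated (e.g. \eqn{\beta} to `"beta"`), and all
#' typographic hyphen/dash variants unified to `"-"`. The function is total
#' (any character input, `NA` passes through as `NA`) and idempotent.
#'
#' @param raw character vector of raw names.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_name("  QUERCETIN ")
#' normalize_name("β-sitosterol")
#' @export
normalize_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- enc2utf8(as.character(raw))
  for (g in names(.greek_map)) {
    x <- gsub(g, .greek_map[[g]], x, fixed = TRUE)
  }
  x <- gsub(.dash_chars, "-", x, perl = TRUE)
  x <- gsub(" ", " ", x, fixed = TRUE)     # NBSP
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- sub("^ +", "", x)
  sub(" +$", "", x)
}

#' Round half up
#'
#' Decimal rounding with ties away from zero (for the non-negative
#' quantities used here: half up), as used for printed prevalence
#' percentages, e.g. `100 * 429/880 = 48.75` rounds to `48.8`.
#' A small epsilon absorbs binary floating-point representation error in
#' ratios such as `100 * n/N`.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(100 * 429 / 880, 1) # 48.8
#' round_half_up(138.8, 0)           # 139
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
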