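`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a drug or preferred-term name
#'
#' Canonical form used throughout the package: whitespace trimmed and
#' collapsed, case folded to lower, then an optional synonym map applied.
#' Controlled-vocabulary matching (drug panels, MedDRA preferred terms)
#' is exact string equality after this normalization.
#'
#' @param x character vector of raw names.
#' @param synonyms named character vector mapping raw spellings to canonical
#'   ones; both sides are compared after trimming/case-folding.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_name(c("  Triamcinolone   Acetonide ", "GLAUCOMA"))
normalize_name <- function(x, synonyms = NULL) {
  out <- tolower(gsub("\\s+", " ", trimws(as.character(x))))
  if (length(synonyms)) {
    key <- tolower(gsub("\\s+", " ", trimws(names(synonyms))))
    val <- tolower(gsub("\\s+", " ", trimws(unname(synonyms))))
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  out
}

# canonical age tokens; decade strings plus the JADER categorical values
.age_tokens <- c(paste0(0:9, "0s"), "elderly", "adult", "unknown")

#' Canonicalize a raw age string
#'
#' Maps raw age spellings onto the canonical token set
#' `"0s".."90s", "elderly", "adult", "unknown"`. Empty strings and `NA`
#' become `NA` (missing); any unmapped non-empty value becomes `"unknown"`.
#'
#' @param raw character vector of raw age values.
#' @param synonyms optional named character vector of extra raw -> token
#'   mappings (e.g. source-specific spellings).
#' @return character vector of canonical tokens, `NA` for missing.
#' @export
normalize_age <- function(raw, synonyms = NULL) {
  x <- tolower(trimws(as.character(raw)))
  out <- rep(NA_character_, length(x))
  miss <- is.na(x) | x == ""
  if (length(synonyms)) {
    hit <- match(x, tolower(trimws(names(synonyms))))
    x[!is.na(hit)] <- tolower(trimws(unname(synonyms)))[hit[!is.na(hit)]]
  }
  known <- x %in% .age_tokens
  out[known & !miss] <- x[known & !miss]
  out[!known & !miss] <- "unknown"
  out
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(field, "probabilities must lie in [0, 1]")
  invisible(x)
}
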