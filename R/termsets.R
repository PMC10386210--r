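#' Load an adverse-event term set
#'
#' A term set defines the event of interest as a set of MedDRA preferred
#' terms (PTs), e.g. a narrow-scope standardized MedDRA query. PT matching
#' downstream is exact string equality after [normalize_name()] with the
#' set's synonym map.
#'
#' @param path YAML file with fields `name`, `pts` (list of PT strings),
#'   optional `provenance` and `synonyms` (raw spelling -> canonical PT).
#' @return an `event_term_set`: list with `name`, `pts` (normalized),
#'   `pts_display` (as shipped), `synonyms`, `provenance`.
#' @export
load_term_set <- function(path) {
  doc <- yaml::yaml.load_file(path)
  pts <- unlist(doc$pts)
  if (is.null(pts) || !length(pts)) stop("term set has no PTs", call. = FALSE)
  if (any(trimws(pts) == "")) stop("term set contains an empty PT", call. = FALSE)
  synonyms <- unlist(doc$synonyms %||% list())
  norm <- normalize_name(pts, synonyms)
  if (anyDuplicated(norm))
    stop(sprintf("term set contains duplicate PTs: %s",
                 paste(unique(pts[duplicated(norm)]), collapse = ", ")),
         call. = FALSE)
  structure(list(name = doc$name %||% basename(path), pts = norm,
                 pts_display = pts, synonyms = synonyms,
                 provenance = doc$provenance %||% ""),
            class = "event_term_set")
}

#' @export
print.event_term_set <- function(x, ...) {
  cat(sprintf("<event term set '%s': %d preferred terms>\n", x$name, length(x$pts)))
  invisible(x)
}

#' Construct a term set or drug panel in code
#'
#' Programmatic counterparts of [load_term_set()] and [load_panel()].
#'
#' @param pts,drugs character vector of PT / drug names.
#' @param name set name.
#' @param synonyms optional raw -> canonical synonym map.
#' @param provenance free-text provenance note.
#' @return an `event_term_set` / `drug_panel`.
#' @export
#' @examples
#' term_set(c("Glaucoma", "Ocular hypertension"), name = "example")
term_set <- function(pts, name = "custom", synonyms = NULL, provenance = "") {
  norm <- normalize_name(pts, synonyms)
  if (!length(norm) || any(norm == "")) stop("term set has no PTs", call. = FALSE)
  if (anyDuplicated(norm)) stop("term set contains duplicate PTs", call. = FALSE)
  structure(list(name = name, pts = norm, pts_display = as.character(pts),
                 synonyms = synonyms, provenance = provenance),
            class = "event_term_set")
}

#' @rdname term_set
#' @export
drug_panel <- function(drugs, name = "custom", synonyms = NULL,
                       provenance = "") {
  norm <- normalize_name(drugs, synonyms)
  if (!length(norm) || any(norm == "")) stop("panel has no drugs", call. = FALSE)
  if (anyDuplicated(norm)) stop("panel contains duplicate drugs", call. = FALSE)
  structure(list(name = name, drugs = norm,
                 drugs_display = as.character(drugs), synonyms = synonyms,
                 provenance = provenance),
            class = "drug_panel")
}

#' Load a drug panel
#'
#' @param path YAML file with fields `name`, `drugs` (ordered list of drug
#'   names), optional `provenance` and `synonyms`.
#' @return a `drug_panel`: list with `name`, `drugs` (normalized, order
#'   preserved), `drugs_display`, `synonyms`, `provenance`.
#' @export
load_panel <- function(path) {
  doc <- yaml::yaml.load_file(path)
  drugs <- unlist(doc$drugs)
  if (is.null(drugs) || !length(drugs)) stop("panel has no drugs", call. = FALSE)
  if (any(trimws(drugs) == "")) stop("panel contains an empty drug name", call. = FALSE)
  synonyms <- unlist(doc$synonyms %||% list())
  norm <- normalize_name(drugs, synonyms)
  if (anyDuplicated(norm))
    stop(sprintf("panel contains duplicate drugs: %s",
                 paste(unique(drugs[duplicated(norm)]), collapse = ", ")),
         call. = FALSE)
  structure(list(name = doc$name %||% basename(path), drugs = norm,
                 drugs_display = drugs, synonyms = synonyms,
                 provenance = doc$provenance %||% ""),
            class = "drug_panel")
}

#' @export
print.drug_panel <- function(x, ...) {
  cat(sprintf("<drug panel '%s': %d drugs>\n", x$name, length(x$drugs)))
  invisible(x)
}

#' Shipped defaults: the glaucoma PT set and the corticosteroid panel
#'
#' `glaucoma_term_set()` returns the 32-PT narrow-scope glaucoma event
#' definition; `corticosteroid_panel()` the 47-drug corticosteroid panel —
#' the configuration of a published JADER corticosteroid–glaucoma screen
#' shipped as package defaults.
#'
#' @return an `event_term_set` / `drug_panel`.
#' @export
glaucoma_term_set <- function() {
  load_term_set(system.file("extdata", "glaucoma_terms.yaml",
                            package = "srssignal", mustWork = TRUE))
}

#' @rdname glaucoma_term_set
#' @export
corticosteroid_panel <- function() {
  load_panel(system.file("extdata", "corticosteroid_panel.yaml",
                         package = "srssignal", mustWork = TRUE))
}

#' Does a case report the event?
#'
#' TRUE iff the case's PT set intersects the term set. Vectorized over a
#' whole analysis table by [cases_with_event()].
#'
#' @param case a single row of an `srs_cases` table (or any list with an
#'   `events` character vector).
#' @param terms an `event_term_set`.
#' @return logical scalar.
#' @export
case_has_event <- function(case, terms) {
  ev <- if (is.data.frame(case)) case$events[[1]] else case$events
  any(normalize_name(ev, terms$synonyms) %in% terms$pts)
}

#' @rdname case_has_event
#' @param cases an `srs_cases` analysis table.
#' @return logical vector, one element per case.
#' @export
cases_with_event <- function(cases, terms) {
  pts <- terms$pts
  # events are already normalized at table construction; apply the term set's
  # synonym map so corrupted source spellings still match
  if (length(terms$synonyms))
    vapply(cases$events,
           function(e) any(normalize_name(e, terms$synonyms) %in% pts),
           logical(1))
  else
    vapply(cases$events, function(e) any(e %in% pts), logical(1))
}

#' Restrict a term set to a single preferred term
#' @param terms an `event_term_set`.
#' @param pt one PT (normalized or display spelling).
#' @return an `event_term_set` containing only `pt`.
#' @export
single_pt_term_set <- function(terms, pt) {
  ptn <- normalize_name(pt, terms$synonyms)
  if (!ptn %in% terms$pts)
    stop(sprintf("PT '%s' is not in term set '%s'", pt, terms$name), call. = FALSE)
  structure(list(name = paste0(terms$name, ":", ptn), pts = ptn,
                 pts_display = pt, synonyms = terms$synonyms,
                 provenance = terms$provenance),
            class = "event_term_set")
}

#' Reference results of a published corticosteroid–glaucoma screen
#'
#' `reference_screen()` returns the 47 reported (ROR, 95% CI, p) rows of a
#' published JADER corticosteroid–glaucoma disproportionality screen;
#' p-values censored in print (e.g. `"<0.001"`) keep `p_censored = TRUE`
#' with `p_value` holding the censoring bound. `reference_pt_counts()`
#' returns the reported per-PT report counts for the 32 glaucoma terms.
#' These are fixtures for validating the signal criterion and the PT filter,
#' not outputs of this package.
#'
#' @return a data frame.
#' @export
reference_screen <- function() {
  path <- system.file("extdata", "corticosteroid_glaucoma_ror.csv",
                      package = "srssignal", mustWork = TRUE)
  d <- utils::read.csv(path, colClasses = c(p_value = "character"))
  d$p_censored <- grepl("^<", d$p_value)
  d$p_value <- as.numeric(sub("^<", "", d$p_value))
  d
}

#' @rdname reference_screen
#' @export
reference_pt_counts <- function() {
  utils::read.csv(system.file("extdata", "glaucoma_pt_counts.csv",
                              package = "srssignal", mustWork = TRUE))
}

#' Read an indicator-medication exclusion list
#'
#' Plain text, one drug name per line; blank lines and `#` comments ignored.
#' @param path file path; default is the shipped illustrative list of
#'   intraocular-pressure-lowering drugs.
#' @return character vector of drug names.
#' @export
load_exclusion_list <- function(path = system.file("extdata",
                                                   "glaucoma_medications.txt",
                                                   package = "srssignal",
                                                   mustWork = TRUE)) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}
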