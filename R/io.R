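#' @section The JADER dialect:
#' The three linked tables share a case identification number. Canonical
#' column layouts (UTF-8, comma-separated, quoted, header row):
#' \itemize{
#'   \item DEMO: `case_id, sex, age, reporter`
#'   \item DRUG: `case_id, drug_name, route, date, dose, dose_unit,
#'     divided_doses, role`
#'   \item REAC: `case_id, pt_name, outcome`
#' }
#' Multi-valued fields may hold several values joined by `";"` (and
#' combination drug names by the interpunct `"·"`); [stack_semicolon_fields()]
#' unstacks them.
#' @name jader-dialect
NULL

.jader_cols <- list(
  DEMO = c("case_id", "sex", "age", "reporter"),
  DRUG = c("case_id", "drug_name", "route", "date", "dose", "dose_unit",
           "divided_doses", "role"),
  REAC = c("case_id", "pt_name", "outcome")
)

read_raw_table <- function(path, name, encoding = "UTF-8") {
  if (!file.exists(path))
    stop(sprintf("%s table not found: %s", name, path), call. = FALSE)
  rows <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = encoding)
  if (!"case_id" %in% names(rows))
    stop(sprintf("%s table %s lacks a 'case_id' column", name, path),
         call. = FALSE)
  missing_cols <- setdiff(.jader_cols[[name]], names(rows))
  if (length(missing_cols))
    warning(sprintf("%s table is missing columns: %s (filled with empty strings)",
                    name, paste(missing_cols, collapse = ", ")))
  for (mc in missing_cols) rows[[mc]] <- rep("", nrow(rows))
  rows <- rows[, .jader_cols[[name]], drop = FALSE]
  flagged <- is.na(rows$case_id) | trimws(rows$case_id) == ""
  if (any(flagged))
    warning(sprintf("%s table: %d row(s) with empty case_id (flagged, kept)",
                    name, sum(flagged)))
  structure(
    list(name = name, rows = rows,
         lines = seq_len(nrow(rows)) + 1L,   # header is line 1
         flagged = flagged),
    class = "raw_table"
  )
}

#' Read one table of a JADER-dialect database
#'
#' Every field is read as a string; rows with an empty case identification
#' number are kept but flagged with a warning. A missing file or a missing
#' `case_id` column is a fatal error.
#'
#' @param path path to the CSV file.
#' @param encoding file encoding; the canonical dialect is UTF-8 (real JADER
#'   exports are Shift-JIS, pass `encoding = "Shift_JIS"`).
#' @return a `raw_table`: a list with the table `name`, the string-valued
#'   `rows`, source line numbers `lines`, and a logical `flagged` vector
#'   marking rows without a case id.
#' @seealso [build_analysis_table()], [stack_semicolon_fields()]
#' @export
read_demo <- function(path, encoding = "UTF-8") read_raw_table(path, "DEMO", encoding)

#' @rdname read_demo
#' @export
read_drug <- function(path, encoding = "UTF-8") read_raw_table(path, "DRUG", encoding)

#' @rdname read_demo
#' @export
read_reac <- function(path, encoding = "UTF-8") read_raw_table(path, "REAC", encoding)

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw %s table: %d rows, %d flagged>\n",
              x$name, nrow(x$rows), sum(x$flagged)))
  invisible(x)
}

#' Unstack semicolon-joined field values
#'
#' A row whose listed field holds k separator-joined values becomes k rows,
#' identical except that the field holds one value each; row order is
#' preserved. Rows without a separator pass through unchanged, so the total
#' number of atomic field values is conserved.
#'
#' @param table a `raw_table`.
#' @param fields character vector of field names to unstack.
#' @param seps separators to split on; defaults to `";"`. Combination drug
#'   names additionally split on the interpunct `"·"`.
#' @return a `raw_table` with the same columns.
#' @export
stack_semicolon_fields <- function(table, fields, seps = ";") {
  stopifnot(inherits(table, "raw_table"))
  missing_f <- setdiff(fields, names(table$rows))
  if (length(missing_f))
    stop(sprintf("fields not present in %s table: %s", table$name,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  pattern <- paste0("[", paste0("\\", seps, collapse = ""), "]")
  for (f in fields) {
    vals <- table$rows[[f]]
    has_sep <- grepl(pattern, vals)
    if (!any(has_sep)) next
    pieces <- as.list(vals)
    sp <- strsplit(vals[has_sep], pattern)
    # strsplit drops a trailing empty field: ";" -> "" "" needs explicit pad
    nsep <- lengths(gregexpr(pattern, vals[has_sep]))
    pieces[has_sep] <- mapply(
      function(p, k) c(p, rep("", max(0L, k + 1L - length(p)))),
      sp, nsep, SIMPLIFY = FALSE)
    reps <- lengths(pieces)
    idx <- rep(seq_along(vals), reps)
    table$rows <- table$rows[idx, , drop = FALSE]
    table$rows[[f]] <- unlist(pieces, use.names = FALSE)
    rownames(table$rows) <- NULL
    table$lines <- table$lines[idx]
    table$flagged <- table$flagged[idx]
  }
  table
}

stack_all <- function(table) {
  switch(table$name,
    DRUG = {
      t2 <- stack_semicolon_fields(
        table, c("route", "date", "dose", "dose_unit", "divided_doses"))
      stack_semicolon_fields(t2, "drug_name", seps = c(";", "·"))
    },
    DEMO = stack_semicolon_fields(table, "reporter"),
    REAC = table
  )
}

dedup_table <- function(table) {
  keep <- !duplicated(table$rows)
  table$rows <- table$rows[keep, , drop = FALSE]
  rownames(table$rows) <- NULL
  table$lines <- table$lines[keep]
  table$flagged <- table$flagged[keep]
  table
}

#' Build the case-level analysis table
#'
#' Executes the standard SRS construction procedure: unstack multi-valued
#' fields, drop exact-duplicate rows within each table, join the three tables
#' on the case identification number, and remove every case exposed to an
#' indicator medication (e.g. drugs that treat the event under study, which
#' would otherwise be counted as exposures among prevalent patients).
#' Rows flagged at read time (empty case id) are excluded from the join.
#' The counting unit downstream is the unique case, not the record row.
#'
#' @param demo,drug,reac `raw_table`s from [read_demo()] and friends (or
#'   [as_raw_table()]).
#' @param exclusion_drugs character vector of drug names; any case whose
#'   drug set intersects it (after normalization) is dropped entirely.
#' @param synonyms optional drug-name synonym map passed to [normalize_name()].
#' @param age_synonyms optional raw-age synonym map passed to [normalize_age()].
#' @return a list with `cases` (an `srs_cases` data frame: `case_id`, `sex`,
#'   `age`, and list columns `drugs` and `events` holding normalized sets)
#'   and `log` (a `flow_log` of record counts at every step).
#' @export
build_analysis_table <- function(demo, drug, reac, exclusion_drugs = character(),
                                 synonyms = NULL, age_synonyms = NULL) {
  stopifnot(inherits(demo, "raw_table"), inherits(drug, "raw_table"),
            inherits(reac, "raw_table"))
  log <- list()
  log[["raw DRUG"]] <- nrow(drug$rows)
  log[["raw REAC"]] <- nrow(reac$rows)
  log[["raw DEMO"]] <- nrow(demo$rows)

  demo <- stack_all(demo); drug <- stack_all(drug); reac <- stack_all(reac)
  log[["after stacking"]] <- nrow(demo$rows) + nrow(drug$rows) + nrow(reac$rows)

  demo <- dedup_table(demo); drug <- dedup_table(drug); reac <- dedup_table(reac)
  log[["after dedup"]] <- nrow(demo$rows) + nrow(drug$rows) + nrow(reac$rows)

  demo_ok <- demo$rows[!demo$flagged, , drop = FALSE]
  drug_ok <- drug$rows[!drug$flagged, , drop = FALSE]
  reac_ok <- reac$rows[!reac$flagged, , drop = FALSE]

  ids <- sort(unique(c(demo_ok$case_id, drug_ok$case_id, reac_ok$case_id)))
  if (!length(ids)) {
    warning("join produced zero cases")
    cases <- empty_cases()
    log[["after join"]] <- 0L
    log[["after exclusion"]] <- 0L
    return(list(cases = cases, log = structure(log, class = "flow_log")))
  }

  first_demo <- demo_ok[!duplicated(demo_ok$case_id), , drop = FALSE]
  di <- match(ids, first_demo$case_id)
  sex <- ifelse(is.na(di), NA_character_, first_demo$sex[di])
  sex[!is.na(sex) & sex == ""] <- NA_character_
  sex[!is.na(sex)] <- tolower(trimws(sex[!is.na(sex)]))
  age <- normalize_age(ifelse(is.na(di), NA_character_, first_demo$age[di]),
                       synonyms = age_synonyms)

  drug_sets <- make_case_sets(drug_ok$case_id,
                              normalize_name(drug_ok$drug_name, synonyms), ids)
  event_sets <- make_case_sets(reac_ok$case_id,
                               normalize_name(reac_ok$pt_name), ids)

  cases <- data.frame(case_id = ids, sex = sex, age = age,
                      stringsAsFactors = FALSE)
  cases$drugs <- unname(drug_sets)
  cases$events <- unname(event_sets)
  class(cases) <- c("srs_cases", "data.frame")
  log[["after join"]] <- nrow(cases)

  if (length(exclusion_drugs)) {
    excl <- normalize_name(exclusion_drugs, synonyms)
    drop <- vapply(cases$drugs, function(d) any(d %in% excl), logical(1))
    cases <- cases[!drop, , drop = FALSE]
    rownames(cases) <- NULL
  }
  log[["after exclusion"]] <- nrow(cases)

  list(cases = cases, log = structure(log, class = "flow_log"))
}

# sorted unique per-case value sets, vectorized (no per-case closures)
make_case_sets <- function(case_id, value, ids) {
  keep <- !is.na(value) & value != ""
  case_id <- case_id[keep]; value <- value[keep]
  o <- order(case_id, value, method = "radix")
  case_id <- case_id[o]; value <- value[o]
  dup <- duplicated(paste0(case_id, "\r", value))
  split(value[!dup], factor(case_id[!dup], levels = ids))
}

empty_cases <- function() {
  cases <- data.frame(case_id = character(), sex = character(),
                      age = character(), stringsAsFactors = FALSE)
  cases$drugs <- list(); cases$events <- list()
  class(cases) <- c("srs_cases", "data.frame")
  cases
}

#' Wrap an in-memory data frame as a raw table
#'
#' Convenience for feeding generated tables (see [generate_database()])
#' straight into [build_analysis_table()] without a round trip through CSV.
#'
#' @param rows data frame with the dialect's columns for `name`.
#' @param name one of `"DEMO"`, `"DRUG"`, `"REAC"`.
#' @return a `raw_table`.
#' @export
as_raw_table <- function(rows, name = c("DEMO", "DRUG", "REAC")) {
  name <- match.arg(name)
  rows <- as.data.frame(lapply(rows, as.character), stringsAsFactors = FALSE,
                        check.names = FALSE)
  for (mc in setdiff(.jader_cols[[name]], names(rows)))
    rows[[mc]] <- rep("", nrow(rows))
  rows <- rows[, .jader_cols[[name]], drop = FALSE]
  structure(
    list(name = name, rows = rows, lines = seq_len(nrow(rows)) + 1L,
         flagged = is.na(rows$case_id) | trimws(rows$case_id) == ""),
    class = "raw_table"
  )
}

#' @export
print.flow_log <- function(x, ...) {
  cat("Record counts through table construction:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.srs_cases <- function(x, ...) {
  cat(sprintf("<analysis table: %d cases, %d with >=1 drug, %d with >=1 event>\n",
              nrow(x), sum(lengths(x$drugs) > 0), sum(lengths(x$events) > 0)))
  invisible(x)
}

#' Write an analysis table and its flow log to disk
#'
#' The case table is written as CSV with the drug and event sets re-joined by
#' `";"`; the flow log as JSON.
#'
#' @param built result of [build_analysis_table()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_analysis_table <- function(built, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- data.frame(
    case_id = built$cases$case_id, sex = built$cases$sex, age = built$cases$age,
    drugs = vapply(built$cases$drugs, paste, "", collapse = ";"),
    events = vapply(built$cases$events, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  p1 <- file.path(out_dir, "analysis_table.csv")
  p2 <- file.path(out_dir, "flow_log.json")
  utils::write.csv(flat, p1, row.names = FALSE, na = "")
  jsonlite::write_json(unclass(built$log), p2, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(analysis_table = p1, flow_log = p2))
}

#' Read back an analysis table written by [write_analysis_table()]
#' @param path path to `analysis_table.csv`.
#' @return an `srs_cases` data frame.
#' @export
read_analysis_table <- function(path) {
  flat <- utils::read.csv(path, colClasses = "character")
  split_set <- function(v) lapply(strsplit(v, ";", fixed = TRUE),
                                  function(x) sort(unique(x[x != ""])))
  cases <- data.frame(case_id = flat$case_id,
                      sex = ifelse(flat$sex == "", NA_character_, flat$sex),
                      age = ifelse(flat$age == "", NA_character_, flat$age),
                      stringsAsFactors = FALSE)
  cases$drugs <- split_set(flat$drugs)
  cases$events <- split_set(flat$events)
  class(cases) <- c("srs_cases", "data.frame")
  cases
}
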