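.default_sex_probs <- c(male = 0.48, female = 0.48, missing = 0.04)
# loosely mimics the age mix of an adverse-event report stream: weighted to
# later decades, with the categorical "elderly"/"adult"/"unknown" values and
# a small missing fraction
.default_age_probs <- c("10s" = 0.04, "20s" = 0.07, "30s" = 0.09,
                        "40s" = 0.11, "50s" = 0.13, "60s" = 0.17,
                        "70s" = 0.16, "80s" = 0.09, "90s" = 0.02,
                        "elderly" = 0.04, "adult" = 0.04, "unknown" = 0.02,
                        missing = 0.02)

#' Configuration for the synthetic SRS database generator
#'
#' Defines the study conditions for a simulated spontaneous-reporting
#' database: per-drug marginal exposure probabilities, per-PT baseline
#' reporting probabilities, injected (drug, PT) association multipliers on
#' the odds scale, demographic token distributions, and "mess" rates
#' (duplicate rows and semicolon-merged multi-value fields). The defaults
#' encode the package's parameter-recovery study: 50,000 cases, six drugs
#' at 10% exposure, eight PTs at 1% baseline, and multipliers 2, 5 and 10
#' injected into three disjoint (drug, PT) pairs — disjoint so each pair's
#' population reporting odds ratio equals its multiplier exactly.
#'
#' @param n_cases number of reports (cases) to generate.
#' @param drugs named numeric vector: drug name -> marginal exposure
#'   probability in \[0, 1\].
#' @param events named numeric vector: PT name -> baseline reporting
#'   probability in \[0, 1\].
#' @param associations data frame with columns `drug`, `pt`, `multiplier`
#'   (>= 0): the odds multiplier applied to the PT's baseline odds for cases
#'   exposed to the drug. Pairs not listed have multiplier 1.
#' @param sex_probs named probabilities over `male`, `female`, `missing`.
#' @param age_probs named probabilities over the canonical age tokens plus
#'   `missing`.
#' @param duplicate_rate probability that a table row is duplicated.
#' @param merge_rate probability that a case's multiple DRUG rows are
#'   collapsed into one `";"`-joined row.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 50000,
                             drugs = stats::setNames(rep(0.1, 6),
                                                     paste0("drug_", letters[1:6])),
                             events = stats::setNames(rep(0.01, 8),
                                                      sprintf("pt_%02d", 1:8)),
                             associations = data.frame(
                               drug = c("drug_a", "drug_b", "drug_c"),
                               pt = c("pt_01", "pt_02", "pt_03"),
                               multiplier = c(2, 5, 10)),
                             sex_probs = .default_sex_probs,
                             age_probs = .default_age_probs,
                             duplicate_rate = 0.01,
                             merge_rate = 0.1,
                             seed = 1L) {
  if (!(length(n_cases) == 1 && is.numeric(n_cases) && n_cases >= 1 &&
        n_cases == round(n_cases)))
    stop_config("n_cases", "must be a positive integer")
  if (is.null(names(drugs)) || any(names(drugs) == ""))
    stop_config("drugs", "must be a named vector of exposure probabilities")
  check_prob(drugs, "drugs")
  if (is.null(names(events)) || any(names(events) == ""))
    stop_config("events", "must be a named vector of baseline probabilities")
  check_prob(events, "events")
  if (!is.data.frame(associations) ||
      !all(c("drug", "pt", "multiplier") %in% names(associations)))
    stop_config("associations", "must be a data frame with drug, pt, multiplier")
  if (nrow(associations)) {
    if (any(!associations$drug %in% names(drugs)))
      stop_config("associations", sprintf("unknown drug(s): %s",
        paste(setdiff(associations$drug, names(drugs)), collapse = ", ")))
    if (any(!associations$pt %in% names(events)))
      stop_config("associations", sprintf("unknown PT(s): %s",
        paste(setdiff(associations$pt, names(events)), collapse = ", ")))
    if (!is.numeric(associations$multiplier) ||
        anyNA(associations$multiplier) || any(associations$multiplier < 0) ||
        any(!is.finite(associations$multiplier)))
      stop_config("associations", "multipliers must be finite and >= 0")
    if (anyDuplicated(associations[, c("drug", "pt")]))
      stop_config("associations", "duplicate (drug, pt) pair")
  }
  for (nm in c("duplicate_rate", "merge_rate"))
    check_prob(get(nm), nm)
  check_prob(sex_probs, "sex_probs")
  if (!all(names(sex_probs) %in% c("male", "female", "missing")))
    stop_config("sex_probs", "names must be male, female, missing")
  if (abs(sum(sex_probs) - 1) > 1e-8)
    stop_config("sex_probs", "probabilities must sum to 1")
  check_prob(age_probs, "age_probs")
  if (!all(names(age_probs) %in% c(.age_tokens, "missing")))
    stop_config("age_probs", "unknown age token in names")
  if (abs(sum(age_probs) - 1) > 1e-8)
    stop_config("age_probs", "probabilities must sum to 1")
  if (!(length(seed) == 1 && is.numeric(seed) && seed == round(seed)))
    stop_config("seed", "must be a single integer")
  structure(list(n_cases = as.integer(n_cases), drugs = drugs, events = events,
                 associations = associations, sex_probs = sex_probs,
                 age_probs = age_probs,
                 duplicate_rate = duplicate_rate, merge_rate = merge_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic SRS config: %d cases, %d drugs, %d PTs, ",
                     "%d injected association(s), dup %.2g, merge %.2g, seed %d>\n"),
              x$n_cases, length(x$drugs), length(x$events),
              sum(x$associations$multiplier != 1), x$duplicate_rate,
              x$merge_rate, x$seed))
  invisible(x)
}

#' Read / write a synthetic configuration as YAML
#' @param path YAML file.
#' @return `load_synthetic_config()` returns a `synthetic_config`.
#' @export
load_synthetic_config <- function(path) {
  doc <- yaml::yaml.load_file(path)
  assoc <- if (length(doc$associations))
    do.call(rbind, lapply(doc$associations, as.data.frame))
  else data.frame(drug = character(), pt = character(), multiplier = numeric())
  synthetic_config(
    n_cases = doc$n_cases,
    drugs = unlist(doc$drugs),
    events = unlist(doc$events),
    associations = assoc,
    sex_probs = unlist(doc$sex_probs %||% as.list(.default_sex_probs)),
    age_probs = unlist(doc$age_probs %||% as.list(.default_age_probs)),
    duplicate_rate = doc$duplicate_rate %||% 0.01,
    merge_rate = doc$merge_rate %||% 0.1,
    seed = doc$seed %||% 1L)
}

#' Generate a JADER-shaped synthetic database
#'
#' Draws, for each case: exposure to each drug independently with its
#' marginal probability; each PT with probability
#' `plogis(qlogis(baseline) + sum of log multipliers over exposed drugs)`
#' (so an exposed drug multiplies the PT's baseline odds by its multiplier);
#' and sex/age/reporter tokens. The linked DEMO/DRUG/REAC tables are then
#' assembled (one PT per REAC row; one drug record per exposure) and mess is
#' injected last: whole-row duplicates at `duplicate_rate`, and per-case
#' `";"`-merges of multi-row DRUG records at `merge_rate`. Because mess is
#' drawn after all scientific randomness, runs with and without mess share
#' identical underlying data for one seed, and identical seeds give
#' byte-identical output.
#'
#' @param config a `synthetic_config`.
#' @return list with data frames `demo`, `drug`, `reac`, and `truth` (a
#'   `synthetic_truth` data frame with, per declared association: the
#'   multiplier and the realized exposure/event counts).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cases
  drug_names <- names(config$drugs)
  pt_names <- names(config$events)
  D <- length(drug_names); P <- length(pt_names)

  exposure <- matrix(0L, n, D, dimnames = list(NULL, drug_names))
  for (j in seq_len(D))
    exposure[, j] <- stats::rbinom(n, 1L, config$drugs[j])

  # log-odds shift per (drug, PT); multiplier 0 handled as a hard veto so the
  # event probability is exactly zero for exposed cases
  L <- matrix(0, D, P, dimnames = list(drug_names, pt_names))
  Z <- matrix(0, D, P, dimnames = list(drug_names, pt_names))
  if (nrow(config$associations)) {
    for (r in seq_len(nrow(config$associations))) {
      d <- config$associations$drug[r]; p <- config$associations$pt[r]
      m <- config$associations$multiplier[r]
      if (m > 0) L[d, p] <- log(m) else Z[d, p] <- 1
    }
  }
  base <- config$events
  eta <- exposure %*% L
  eta <- sweep(eta, 2, ifelse(base > 0, stats::qlogis(base), 0), `+`)
  prob <- stats::plogis(eta)
  prob[, base == 0] <- 0
  prob[(exposure %*% Z) > 0] <- 0
  event <- matrix(stats::rbinom(n * P, 1L, as.vector(prob)), n, P,
                  dimnames = list(NULL, pt_names))

  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  age <- sample(names(config$age_probs), n, replace = TRUE,
                prob = config$age_probs)
  reporter <- sample(c("physician", "pharmacist", "other"), n, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1))
  case_id <- sprintf("C%07d", seq_len(n))

  demo <- data.frame(case_id = case_id,
                     sex = ifelse(sex == "missing", "", sex),
                     age = ifelse(age == "missing", "", age),
                     reporter = reporter, stringsAsFactors = FALSE)

  exp_idx <- which(exposure == 1L, arr.ind = TRUE)
  exp_idx <- exp_idx[order(exp_idx[, 1], exp_idx[, 2]), , drop = FALSE]
  n_drug_rows <- nrow(exp_idx)
  drug_tab <- data.frame(
    case_id = case_id[exp_idx[, 1]],
    drug_name = drug_names[exp_idx[, 2]],
    route = sample(c("oral", "topical", "injection", "ophthalmic"),
                   n_drug_rows, replace = TRUE),
    date = rep("", n_drug_rows), dose = rep("", n_drug_rows),
    dose_unit = rep("", n_drug_rows), divided_doses = rep("", n_drug_rows),
    role = rep("suspected", n_drug_rows), stringsAsFactors = FALSE)

  ev_idx <- which(event == 1L, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1], ev_idx[, 2]), , drop = FALSE]
  n_reac_rows <- nrow(ev_idx)
  reac <- data.frame(
    case_id = case_id[ev_idx[, 1]],
    pt_name = pt_names[ev_idx[, 2]],
    outcome = sample(c("recovered", "recovering", "not recovered", "unknown"),
                     n_reac_rows, replace = TRUE),
    stringsAsFactors = FALSE)

  truth <- config$associations
  if (nrow(truth)) {
    truth$n_exposed <- colSums(exposure)[truth$drug]
    truth$n_exposed_event <- vapply(seq_len(nrow(truth)), function(r)
      sum(exposure[, truth$drug[r]] & event[, truth$pt[r]]), numeric(1))
    truth$n_unexposed <- n - truth$n_exposed
    truth$n_unexposed_event <- vapply(seq_len(nrow(truth)), function(r)
      sum(!exposure[, truth$drug[r]] & event[, truth$pt[r]]), numeric(1))
  } else {
    truth$n_exposed <- truth$n_exposed_event <- numeric(0)
    truth$n_unexposed <- truth$n_unexposed_event <- numeric(0)
  }
  class(truth) <- c("synthetic_truth", "data.frame")

  # ---- mess injection: drawn last so the core data above are seed-stable ----
  if (config$merge_rate > 0 && nrow(drug_tab)) {
    multi <- names(which(table(drug_tab$case_id) > 1))
    if (length(multi)) {
      do_merge <- multi[stats::runif(length(multi)) < config$merge_rate]
      if (length(do_merge)) {
        sel <- drug_tab$case_id %in% do_merge
        sub <- drug_tab[sel, , drop = FALSE]
        f <- factor(sub$case_id)
        join <- function(col) vapply(split(col, f), paste, "", collapse = ";")
        merged <- data.frame(case_id = levels(f),
                             drug_name = join(sub$drug_name),
                             route = join(sub$route), date = join(sub$date),
                             dose = join(sub$dose),
                             dose_unit = join(sub$dose_unit),
                             divided_doses = join(sub$divided_doses),
                             role = vapply(split(sub$role, f), `[`, "", 1),
                             stringsAsFactors = FALSE)
        drug_tab <- rbind(drug_tab[!sel, , drop = FALSE], merged)
        drug_tab <- drug_tab[order(drug_tab$case_id), , drop = FALSE]
        rownames(drug_tab) <- NULL
      }
    }
  }
  if (config$duplicate_rate > 0) {
    dup_rows <- function(tab) {
      if (!nrow(tab)) return(tab)
      pick <- which(stats::runif(nrow(tab)) < config$duplicate_rate)
      if (length(pick)) tab <- rbind(tab, tab[pick, , drop = FALSE])
      rownames(tab) <- NULL
      tab
    }
    demo <- dup_rows(demo); drug_tab <- dup_rows(drug_tab); reac <- dup_rows(reac)
  }

  list(demo = demo, drug = drug_tab, reac = reac, truth = truth)
}

#' Write generated tables in the JADER dialect
#'
#' Writes `DEMO.csv`, `DRUG.csv`, `REAC.csv` (UTF-8, quoted, header row) and
#' the ground truth as a `truth.json` sidecar; the files round-trip through
#' [read_demo()], [read_drug()] and [read_reac()].
#'
#' @param tables result of [generate_database()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_jader_dialect <- function(tables, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  paths <- c(demo = file.path(out_dir, "DEMO.csv"),
             drug = file.path(out_dir, "DRUG.csv"),
             reac = file.path(out_dir, "REAC.csv"),
             truth = file.path(out_dir, "truth.json"))
  utils::write.csv(tables$demo, paths[["demo"]], row.names = FALSE)
  utils::write.csv(tables$drug, paths[["drug"]], row.names = FALSE)
  utils::write.csv(tables$reac, paths[["reac"]], row.names = FALSE)
  jsonlite::write_json(as.data.frame(tables$truth), paths[["truth"]],
                       digits = NA, pretty = TRUE)
  paths
}
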