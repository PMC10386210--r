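#' Run the full signal-detection pipeline
#'
#' Orchestrates build -> screen -> demographics -> structure as one
#' reproducible run. Input is either a synthetic-database configuration or
#' paths to DEMO/DRUG/REAC CSVs; outputs land under
#' `out_dir/{build,screen,demographics,structure}/` with a `manifest.json`
#' at the root recording the configuration echo, package version,
#' timestamps, the flow log, every output file and its MD5 checksum.
#' Identical configuration and seed give identical numeric outputs.
#'
#' @param config a named list (or path to a YAML file) with fields:
#'   `synthetic` (a `synthetic_config`, a list of its arguments, or a path
#'   to a synthetic YAML) or `demo`/`drug`/`reac` paths; optional `terms`,
#'   `panel`, `exclude` paths (defaults: the shipped glaucoma term set,
#'   corticosteroid panel, and no exclusion for synthetic runs); `alpha`
#'   (default 0.05); `drug_min_reports`, `drug_min_event_reports`,
#'   `pt_min_reports` (defaults 100, 10, 50); `k` (default 3); `seed`;
#'   `out_dir` (required).
#' @return a `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::yaml.load_file(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir", call. = FALSE)
  alpha <- config$alpha %||% 0.05
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop_config("alpha", "must lie in (0, 1)")
  th <- c(config$drug_min_reports %||% 100,
          config$drug_min_event_reports %||% 10,
          config$pt_min_reports %||% 50)
  if (any(th < 1)) stop_config("thresholds", "must be >= 1")
  k <- config$k %||% 3
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  files <- character()
  stage <- "build"
  fail_marker <- file.path(out_dir, "FAILED")

  result <- tryCatch({
    ## ---- build stage ----
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      if (is.character(syn)) syn <- load_synthetic_config(syn)
      else if (!inherits(syn, "synthetic_config"))
        syn <- do.call(synthetic_config, syn)
      if (!is.null(config$seed)) syn$seed <- as.integer(config$seed)
      gen <- generate_database(syn)
      raw_dir <- file.path(out_dir, "build", "raw")
      files <- c(files, write_jader_dialect(gen, raw_dir))
      demo <- as_raw_table(gen$demo, "DEMO")
      drug <- as_raw_table(gen$drug, "DRUG")
      reac <- as_raw_table(gen$reac, "REAC")
      default_terms <- term_set(
        names(syn$events), name = "synthetic_events",
        provenance = "all PTs declared in the synthetic configuration")
      default_panel <- drug_panel(
        names(syn$drugs), name = "synthetic_panel",
        provenance = "all drugs declared in the synthetic configuration")
    } else {
      for (f in c("demo", "drug", "reac"))
        if (is.null(config[[f]]))
          stop(sprintf("config must provide '%s' (or a 'synthetic' block)", f),
               call. = FALSE)
      demo <- read_demo(config$demo); drug <- read_drug(config$drug)
      reac <- read_reac(config$reac)
      default_terms <- glaucoma_term_set()
      default_panel <- corticosteroid_panel()
    }
    exclusion <- if (!is.null(config$exclude)) load_exclusion_list(config$exclude)
      else character()
    built <- build_analysis_table(demo, drug, reac, exclusion)
    files <- c(files, write_analysis_table(built, file.path(out_dir, "build")))

    ## ---- screen stage ----
    stage <- "screen"
    terms <- if (!is.null(config$terms)) load_term_set(config$terms) else
      default_terms
    panel <- if (!is.null(config$panel)) load_panel(config$panel) else
      default_panel
    scr <- srs_screen(built$cases, panel, terms, alpha = alpha)
    p_scr <- file.path(out_dir, "screen", "screen_results.csv")
    dir.create(dirname(p_scr), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(scr), p_scr, row.names = FALSE)
    p_volc <- file.path(out_dir, "screen", "volcano.csv")
    utils::write.csv(volcano_data(scr), p_volc, row.names = FALSE)
    p_volc_png <- file.path(out_dir, "screen", "volcano.png")
    grDevices::png(p_volc_png, width = 800, height = 600)
    plot(scr)
    grDevices::dev.off()
    files <- c(files, screen = p_scr, volcano = p_volc, volcano_png = p_volc_png)

    ## ---- demographics stage ----
    stage <- "demographics"
    dem <- compare_demographics(built$cases, terms)
    p_dem <- file.path(out_dir, "demographics", "demographics.csv")
    dir.create(dirname(p_dem), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(dem), p_dem, row.names = FALSE)
    files <- c(files, demographics = p_dem)

    ## ---- structure stage ----
    stage <- "structure"
    struct_dir <- file.path(out_dir, "structure")
    structure_notes <- NULL
    str_res <- tryCatch(
      srs_structure(built$cases, panel, terms,
                    drug_min_reports = th[1], drug_min_event_reports = th[2],
                    pt_min_reports = th[3], k = k),
      error = function(e) {
        structure_notes <<- conditionMessage(e)
        NULL
      })
    cluster_cuts <- NULL
    if (!is.null(str_res)) {
      dir.create(struct_dir, recursive = TRUE, showWarnings = FALSE)
      p_mat <- file.path(struct_dir, "lnror_matrix.csv")
      utils::write.csv(as.data.frame(unclass(str_res$matrix)), p_mat)
      files <- c(files, matrix = p_mat,
                 render_dendrogram(str_res, struct_dir),
                 render_biplot(str_res, struct_dir))
      cluster_cuts <- lapply(c(2, min(k, nrow(str_res$matrix))), function(kk)
        as.list(stats::cutree(str_res$cluster$hclust, k = kk)))
      names(cluster_cuts) <- paste0("k", c(2, min(k, nrow(str_res$matrix))))
    } else {
      warning(sprintf("structure stage skipped: %s", structure_notes))
    }

    manifest <- list(
      tool = "srssignal", version = as.character(utils::packageVersion("srssignal")),
      started = started, finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config_echo(config), alpha = alpha,
      thresholds = list(drug_min_reports = th[1],
                        drug_min_event_reports = th[2], pt_min_reports = th[3]),
      k = k, flow_log = unclass(built$log),
      n_signals = sum(scr$is_signal),
      cluster_cuts = cluster_cuts,
      structure_notes = structure_notes,
      files = file_manifest(files, out_dir))
    p_man <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    if (file.exists(fail_marker)) unlink(fail_marker)
    structure(manifest, class = "run_manifest")
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               fail_marker)
    stop(sprintf("pipeline aborted in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

config_echo <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, "synthetic_config")) unclass(x)
    else if (is.data.frame(x)) as.list(x)
    else x
  })
}

file_manifest <- function(files, out_dir) {
  files <- unname(files)
  lapply(files, function(f)
    list(path = sub("^/", "", sub(out_dir, "", f, fixed = TRUE)),
         md5 = unname(tools::md5sum(f))))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("srssignal run (%s), %d output file(s), %d signal(s)\n",
              x$finished, length(x$files), x$n_signals))
  print(structure(x$flow_log, class = "flow_log"))
  invisible(x)
}

#' Self-check against bundled reference fixtures
#'
#' Recomputes a set of bundled checks and reports pass/fail: the three
#' demographic Fisher exact p-values on reported event/non-event cells, the
#' signal count obtained by applying the criterion to the 47 reported
#' (ROR, p) screen rows, the five-PT outcome of the >= 50-report filter on
#' the reported PT counts, the Haldane ROR identity on a balanced table,
#' and agreement of the Fisher implementation with direct hypergeometric
#' enumeration on a small table.
#'
#' @param reference list overriding the bundled fixtures (fields
#'   `screen`, `pt_counts`), mainly for sensitivity testing.
#' @return an `srs_selfcheck` data frame with columns `check`, `expected`,
#'   `observed`, `tolerance`, `pass`.
#' @export
selfcheck <- function(reference = list()) {
  screen <- reference$screen %||% reference_screen()
  pt_counts <- reference$pt_counts %||% reference_pt_counts()
  checks <- list()
  add <- function(check, expected, observed, tolerance) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, expected = expected, observed = observed,
      tolerance = tolerance,
      pass = is.finite(observed) && abs(observed - expected) <= tolerance,
      stringsAsFactors = FALSE)
  }
  # demographic comparisons on the reported event/non-event cells
  add("sex comparison p-value",
      0.445, fisher_exact_two_sided(c(653, 599030, 694, 609980)), 0.002)
  add("age >=70 comparison p-value",
      0.184, fisher_exact_two_sided(c(436, 468717, 709, 702259)), 0.002)
  add("age >=40 comparison p-value",
      0.488, fisher_exact_two_sided(c(949, 960658, 196, 210318)), 0.002)
  add("signal count on reported screen", 28,
      sum(apply_signal_criterion(screen$ror, screen$p_value,
                                 screen$p_censored, alpha = 0.05)), 0)
  add("PTs passing >=50-report filter", 5,
      length(filter_pt_counts(pt_counts, 50)), 0)
  add("Haldane ROR on balanced table", 1,
      haldane_ror(c(10, 10, 10, 10))$ror, 1e-12)
  enum <- fisher_enumeration_p(3, 7, 5, 5)
  add("Fisher vs hypergeometric enumeration", enum,
      fisher_exact_two_sided(c(3, 7, 5, 5)), 1e-10)
  res <- do.call(rbind, checks)
  structure(res, class = c("srs_selfcheck", "data.frame"))
}

# independent two-sided Fisher p by full enumeration over tables with the
# observed margins (minimum-likelihood convention); used by selfcheck
fisher_enumeration_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  xs <- max(0, n1 - m2):min(n1, m1)
  probs <- choose(m1, xs) * choose(m2, n1 - xs) / choose(m1 + m2, n1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' @export
print.srs_selfcheck <- function(x, ...) {
  d <- as.data.frame(x)
  d$expected <- signif(d$expected, 6); d$observed <- signif(d$observed, 6)
  print(d, row.names = FALSE)
  cat(sprintf("%d/%d checks passed\n", sum(x$pass), nrow(x)))
  invisible(x)
}
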