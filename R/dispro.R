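#' Build the 2x2 contingency table for one drug against an event set
#'
#' The classic disproportionality crosstabulation over all analysis cases:
#' \tabular{lcc}{
#'                           \tab event \tab non-event \cr
#'   reports with the drug   \tab a     \tab b         \cr
#'   all other reports       \tab c     \tab d         \cr
#' }
#' Each case is counted exactly once, so `a + b + c + d` equals the number
#' of cases.
#'
#' @param cases an `srs_cases` analysis table (deduplicated by case id).
#' @param drug one drug name (normalized internally).
#' @param terms an `event_term_set`.
#' @param synonyms optional drug synonym map.
#' @return a `contingency_2x2`: named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(cases, drug, terms, synonyms = NULL) {
  if (nrow(cases) == 0) {
    warning("empty case list: contingency table of zeros")
    return(structure(c(a = 0L, b = 0L, c = 0L, d = 0L), class = "contingency_2x2"))
  }
  dn <- normalize_name(drug, synonyms)
  exposed <- vapply(cases$drugs, function(d) dn %in% d, logical(1))
  event <- cases_with_event(cases, terms)
  contingency_2x2(sum(exposed & event), sum(exposed & !event),
                  sum(!exposed & event), sum(!exposed & !event))
}

#' Construct a 2x2 contingency table from its four cells
#' @param a,b,c,d non-negative integer counts (drug+event, drug only,
#'   event only, neither).
#' @return a `contingency_2x2` named integer vector.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  structure(as.integer(round(x)), names = c("a", "b", "c", "d"),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("with drug", "other reports"),
                              c("event", "non-event")))
  print(m)
  invisible(x)
}

#' Haldane-corrected reporting odds ratio with log-scale confidence interval
#'
#' Adds the continuity correction (0.5 by default) to every cell so the
#' ratio stays defined with zero cells, then computes
#' `ROR = (a')(d') / (b')(c')` and the Wald (Woolf) interval on the log
#' scale, `exp(ln ROR +/- z * sqrt(1/a' + 1/b' + 1/c' + 1/d'))` with
#' `z = qnorm(1 - (1 - conf_level)/2)`.
#'
#' @param table a `contingency_2x2` (or a length-4 vector a, b, c, d).
#' @param conf_level confidence level, default 0.95.
#' @param correction the Haldane continuity constant added to each cell.
#' @return list with `ror`, `ln_ror`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' haldane_ror(contingency_2x2(10, 90, 100, 900))
haldane_ror <- function(table, conf_level = 0.95, correction = 0.5) {
  x <- as.numeric(unclass(table))
  if (length(x) != 4 || anyNA(x)) stop("need four cells a, b, c, d", call. = FALSE)
  if (any(x < 0)) stop("contingency cells must be non-negative", call. = FALSE)
  x <- x + correction
  ror <- (x[1] * x[4]) / (x[2] * x[3])
  ln_ror <- log(ror)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / x))
  list(ror = ror, ln_ror = ln_ror,
       ci_low = exp(ln_ror - z * se), ci_high = exp(ln_ror + z * se))
}

#' Two-sided Fisher exact test on the raw 2x2 counts
#'
#' The two-sided p-value sums the hypergeometric point probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (the minimum-likelihood convention). The continuity
#' correction is never applied here; the exact test runs on raw counts.
#'
#' @param table a `contingency_2x2` (or length-4 vector a, b, c, d).
#' @return the p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.numeric(unclass(table))
  if (length(x) != 4 || anyNA(x) || any(x < 0))
    stop("need four non-negative cells a, b, c, d", call. = FALSE)
  if (sum(x) == 0) return(1)
  m <- matrix(x, nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

signal_flag <- function(ror, p, alpha) ror >= 1 & p < alpha

#' Screen a drug panel for disproportionality signals
#'
#' The central estimator of the package. For every drug in the panel it
#' builds the 2x2 table against the event term set, computes the
#' Haldane-corrected ROR with its log-scale confidence interval, the
#' two-sided Fisher exact p-value on the raw counts, and flags a signal when
#' `ROR >= 1` and `p < alpha`. Results are sorted by `ln_ror` descending,
#' ties broken by drug name. No multiplicity adjustment is applied by
#' default; `fdr = TRUE` adds a Benjamini-Hochberg adjusted column (the
#' signal flag still uses the raw p unless `signal_on_fdr = TRUE`).
#'
#' @param cases an `srs_cases` analysis table.
#' @param panel a `drug_panel` (or character vector of drug names).
#' @param terms an `event_term_set`.
#' @param alpha significance level for the signal flag; default 0.05.
#' @param conf_level confidence level of the ROR interval.
#' @param correction Haldane continuity constant.
#' @param fdr add a Benjamini-Hochberg adjusted p column.
#' @param signal_on_fdr flag signals on the adjusted p instead of the raw p.
#' @return an `srs_screen` data frame with one row per panel drug: the four
#'   cells, `n_reports = a + b`, `ror`, `ln_ror`, `ci_low`, `ci_high`,
#'   `p_value`, `is_signal`, volcano coordinates `volcano_y = -log10(p)` and
#'   `color_value = log10(n_reports)`.
#' @export
srs_screen <- function(cases, panel, terms, alpha = 0.05, conf_level = 0.95,
                       correction = 0.5, fdr = FALSE, signal_on_fdr = FALSE) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha < 1))
    stop("alpha must be a single number in [0, 1)", call. = FALSE)
  drugs <- if (inherits(panel, "drug_panel")) panel$drugs else
    normalize_name(panel)
  display <- if (inherits(panel, "drug_panel")) panel$drugs_display else
    as.character(panel)
  synonyms <- if (inherits(panel, "drug_panel")) panel$synonyms else NULL

  event <- cases_with_event(cases, terms)
  rows <- lapply(seq_along(drugs), function(i) {
    exposed <- vapply(cases$drugs, function(d) drugs[i] %in% d, logical(1))
    tab <- contingency_2x2(sum(exposed & event), sum(exposed & !event),
                           sum(!exposed & event), sum(!exposed & !event))
    est <- haldane_ror(tab, conf_level, correction)
    p <- fisher_exact_two_sided(tab)
    data.frame(drug = display[i], a = tab[["a"]], b = tab[["b"]],
               c = tab[["c"]], d = tab[["d"]], n_reports = tab[["a"]] + tab[["b"]],
               ror = est$ror, ln_ror = est$ln_ror,
               ci_low = est$ci_low, ci_high = est$ci_high, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (fdr) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  p_for_flag <- if (fdr && signal_on_fdr) res$p_adjusted else res$p_value
  res$is_signal <- signal_flag(res$ror, p_for_flag, alpha)
  res$volcano_y <- -log10(res$p_value)
  res$color_value <- ifelse(res$n_reports > 0, log10(res$n_reports), NA_real_)
  res <- res[order(-res$ln_ror, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("srs_screen", "data.frame"),
            alpha = alpha, conf_level = conf_level, correction = correction,
            terms = terms$name, n_cases = nrow(cases))
}

#' @export
print.srs_screen <- function(x, n = 10, ...) {
  cat(sprintf("Disproportionality screen: %d drugs vs '%s' (%d cases)\n",
              nrow(x), attr(x, "terms"), attr(x, "n_cases")))
  cat(sprintf("Signal criterion: ROR >= 1 and two-sided Fisher p < %g; %d signal(s)\n\n",
              attr(x, "alpha"), sum(x$is_signal)))
  show <- utils::head(as.data.frame(x)[, c("drug", "a", "n_reports", "ror",
                                           "ci_low", "ci_high", "p_value",
                                           "is_signal")], n)
  show$ror <- signif(show$ror, 4); show$ci_low <- signif(show$ci_low, 4)
  show$ci_high <- signif(show$ci_high, 4); show$p_value <- signif(show$p_value, 3)
  print(show, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.srs_screen <- function(object, ...) {
  sig <- object[object$is_signal, , drop = FALSE]
  structure(list(n_drugs = nrow(object), n_signals = nrow(sig),
                 alpha = attr(object, "alpha"), terms = attr(object, "terms"),
                 n_cases = attr(object, "n_cases"),
                 signals = as.data.frame(sig)[, c("drug", "ror", "ci_low",
                                                  "ci_high", "p_value", "n_reports")]),
            class = "summary.srs_screen")
}

#' @export
print.summary.srs_screen <- function(x, ...) {
  cat(sprintf("Screen of %d drugs against '%s' on %d cases\n",
              x$n_drugs, x$terms, x$n_cases))
  cat(sprintf("%d drug(s) meet the signal criterion (ROR >= 1, p < %g):\n",
              x$n_signals, x$alpha))
  if (x$n_signals) {
    s <- x$signals
    s$ror <- signif(s$ror, 4); s$ci_low <- signif(s$ci_low, 4)
    s$ci_high <- signif(s$ci_high, 4); s$p_value <- signif(s$p_value, 3)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.srs_screen <- function(object, ...) {
  stats::setNames(object$ln_ror, object$drug)
}

#' Volcano-plot coordinates for a screen
#'
#' One row per drug: `x = ln_ror`, `y = -log10(p)`, `color = log10(a + b)`.
#' Signals sit in the upper-right quadrant above the `y = -log10(alpha)`
#' reference (about 1.3 at alpha 0.05). A p-value underflowing to zero is
#' capped at `y_max` with a warning.
#'
#' @param results an `srs_screen`.
#' @param y_max cap applied when p underflows to 0.
#' @return data frame `(drug, x, y, color, is_signal)`.
#' @export
volcano_data <- function(results, y_max = 320) {
  stopifnot(inherits(results, "srs_screen"))
  if (nrow(results) == 0) stop("no screen results", call. = FALSE)
  y <- -log10(results$p_value)
  if (any(!is.finite(y))) {
    warning(sprintf("p-value underflow: capping -log10(p) at %g", y_max))
    y[!is.finite(y)] <- y_max
  }
  data.frame(drug = results$drug, x = results$ln_ror, y = y,
             color = results$color_value, is_signal = results$is_signal,
             stringsAsFactors = FALSE)
}

#' Volcano plot of a disproportionality screen
#'
#' Effect size (ln ROR) against significance (-log10 p), point colour
#' encoding log10 of the drug's report count (blue = few, red = many), with
#' a dashed reference line at the significance level and signal drugs
#' labelled.
#'
#' @param x an `srs_screen`.
#' @param label_signals label drugs meeting the signal criterion.
#' @param ... passed to [graphics::plot()].
#' @export
plot.srs_screen <- function(x, label_signals = TRUE, ...) {
  v <- volcano_data(x)
  pal <- grDevices::colorRampPalette(c("blue3", "grey60", "red3"))(100)
  cv <- v$color
  cv[is.na(cv)] <- min(cv, na.rm = TRUE)
  idx <- if (diff(range(cv)) > 0)
    1 + round(99 * (cv - min(cv)) / diff(range(cv))) else rep(50L, length(cv))
  graphics::plot(v$x, v$y, pch = 19, col = pal[idx],
                 xlab = "ln ROR", ylab = "-log10(p)", ...)
  graphics::abline(h = -log10(attr(x, "alpha")), lty = 2)
  graphics::abline(v = 0, lty = 3, col = "grey")
  if (label_signals && any(v$is_signal))
    graphics::text(v$x[v$is_signal], v$y[v$is_signal],
                   labels = v$drug[v$is_signal], pos = 4, cex = 0.6)
  invisible(v)
}

#' Apply the signal criterion to reported (ROR, p) pairs
#'
#' Used to validate the criterion against published screen tables whose
#' p-values may be censored in print (`"<0.001"`).
#'
#' @param ror numeric vector of reported RORs.
#' @param p_value numeric vector of p-values (censoring bound where censored).
#' @param p_censored logical vector: TRUE where the printed value was an
#'   upper bound ("< bound").
#' @param alpha significance level.
#' @return logical vector of signal flags.
#' @export
apply_signal_criterion <- function(ror, p_value, p_censored = FALSE,
                                   alpha = 0.05) {
  p_censored <- rep_len(p_censored, length(p_value))
  p_small <- ifelse(p_censored, p_value <= alpha, p_value < alpha)
  ror >= 1 & p_small
}
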