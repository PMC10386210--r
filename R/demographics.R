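.age70_high <- c("70s", "80s", "90s", "elderly")
.age_low70 <- c("0s", "10s", "20s", "30s", "40s", "50s", "60s")
.age40_high <- c("40s", "50s", "60s", "70s", "80s", "90s", "elderly")
.age_low40 <- c("0s", "10s", "20s", "30s")

#' Compare demographics between event and non-event cases
#'
#' Splits the analysis table by event status and tests three factors with
#' the two-sided Fisher exact test:
#' \itemize{
#'   \item `sex`: male vs female (cases with missing sex excluded);
#'   \item `age70`: age 70 and older (decades 70s/80s/90s plus the
#'     unspecified "elderly" category) vs younger decades;
#'   \item `age40`: age 40 and older (40s through 90s plus "elderly") vs
#'     younger decades.
#' }
#' For the age factors, cases with the categorical tokens `"adult"` and
#' `"unknown"` or a missing age are excluded; the under-10 decade counts
#' below both cut points.
#'
#' @param cases an `srs_cases` analysis table with normalized sex/age tokens.
#' @param terms an `event_term_set` defining the event.
#' @return an `srs_demographics` data frame with one row per factor: the
#'   2x2 cells (`a` = event & level 1, `b` = non-event & level 1, `c` =
#'   event & level 2, `d` = non-event & level 2), `n_used`, `n_excluded`,
#'   and `p_value`.
#' @export
compare_demographics <- function(cases, terms) {
  event <- cases_with_event(cases, terms)
  one <- function(factor_name, level1, level2, in1, in2) {
    used <- in1 | in2
    tab <- contingency_2x2(sum(event & in1), sum(!event & in1),
                           sum(event & in2), sum(!event & in2))
    p <- if (sum(tab[c("a", "c")]) == 0 || sum(tab[c("b", "d")]) == 0 ||
             sum(tab[c("a", "b")]) == 0 || sum(tab[c("c", "d")]) == 0) {
      warning(sprintf("factor '%s' has an empty margin: p = 1", factor_name))
      1
    } else fisher_exact_two_sided(tab)
    data.frame(factor = factor_name, level1 = level1, level2 = level2,
               a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
               n_used = sum(used), n_excluded = sum(!used), p_value = p,
               stringsAsFactors = FALSE)
  }
  sex <- cases$sex
  age <- cases$age
  res <- rbind(
    one("sex", "male", "female",
        !is.na(sex) & sex == "male", !is.na(sex) & sex == "female"),
    one("age70", ">=70", "<70",
        !is.na(age) & age %in% .age70_high, !is.na(age) & age %in% .age_low70),
    one("age40", ">=40", "<40",
        !is.na(age) & age %in% .age40_high, !is.na(age) & age %in% .age_low40)
  )
  structure(res, class = c("srs_demographics", "data.frame"),
            n_cases = nrow(cases), terms = terms$name)
}

#' @export
print.srs_demographics <- function(x, ...) {
  cat(sprintf("Demographic comparison, event = '%s' (%d cases)\n",
              attr(x, "terms"), attr(x, "n_cases")))
  d <- as.data.frame(x)
  d$p_value <- signif(d$p_value, 3)
  print(d, row.names = FALSE)
  invisible(x)
}
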