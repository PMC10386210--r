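test_that("contingency construction counts every case once", {
  terms <- make_terms("pt1")
  cases <- make_cases(paste0("C", 1:4),
                      drugs = list("dx", "dx", character(), character()),
                      events = list("pt1", character(), "pt1", character()))
  tab <- build_contingency(cases, "dx", terms)
  expect_identical(unclass(tab)[1:4], c(a = 1L, b = 1L, c = 1L, d = 1L))

  # no case exposed to the drug
  tab0 <- build_contingency(cases, "unseen", terms)
  expect_identical(unname(unclass(tab0)[1:2]), c(0L, 0L))
  expect_equal(sum(tab0), nrow(cases))

  # hand-tallied 20-case oracle
  tab20 <- build_contingency(twenty_case_fixture(), "dx",
                             make_terms(c("pt1", "pt2")))
  expect_identical(unclass(tab20)[1:4], c(a = 5L, b = 3L, c = 4L, d = 8L))

  expect_warning(tabE <- build_contingency(make_cases(character()), "dx", terms),
                 "empty")
  expect_equal(sum(tabE), 0)
})

test_that("Haldane ROR matches direct arithmetic on corrected cells", {
  # balanced table: ROR 1, interval symmetric about 1 on the log scale
  est <- haldane_ror(contingency_2x2(10, 10, 10, 10))
  expect_equal(est$ror, 1)
  expect_equal(log(est$ci_high), -log(est$ci_low))

  # all-zero table is computable through the correction alone
  expect_equal(haldane_ror(contingency_2x2(0, 0, 0, 0))$ror, 1)

  # spreadsheet oracle: (10.5 * 900.5) / (90.5 * 100.5) and the Wald interval
  est2 <- haldane_ror(contingency_2x2(10, 90, 100, 900))
  expect_equal(est2$ror, 9455.25 / 9095.25, tolerance = 1e-12)
  se <- sqrt(1 / 10.5 + 1 / 90.5 + 1 / 100.5 + 1 / 900.5)
  z <- qnorm(0.975)
  expect_equal(est2$ci_low, exp(log(9455.25 / 9095.25) - z * se), tolerance = 1e-12)
  expect_equal(est2$ci_high, exp(log(9455.25 / 9095.25) + z * se), tolerance = 1e-12)
  expect_equal(est2$ln_ror, log(est2$ror))

  expect_error(haldane_ror(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Haldane ROR satisfies inversion and monotonicity properties", {
  set.seed(11)
  for (i in 1:50) {
    x <- rpois(4, 20)
    r1 <- haldane_ror(contingency_2x2(x[1], x[2], x[3], x[4]))$ror
    r2 <- haldane_ror(contingency_2x2(x[3], x[4], x[1], x[2]))$ror
    expect_equal(r1 * r2, 1, tolerance = 1e-12)   # swapping rows inverts
  }
  for (i in 1:20) {
    x <- rpois(3, 15)
    rors <- vapply(0:10, function(a)
      haldane_ror(contingency_2x2(a, x[1], x[2], x[3]))$ror, numeric(1))
    expect_true(all(diff(rors) > 0))   # increasing a never decreases the ROR
  }
})

test_that("two-sided Fisher test agrees with the enumeration oracle", {
  # spot checks including zero margins
  expect_equal(fisher_exact_two_sided(c(0, 0, 3, 5)), 1)
  expect_equal(fisher_exact_two_sided(c(0, 0, 0, 0)), 1)
  set.seed(5)
  for (i in 1:40) {
    x <- as.integer(sample(0:8, 4, replace = TRUE))
    expect_equal(fisher_exact_two_sided(x),
                 oracle_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
  }
})

test_that("screening flags injected signals and orders by lnROR", {
  cfg <- synthetic_config(n_cases = 20000, seed = 9,
                          duplicate_rate = 0, merge_rate = 0)
  gen <- generate_database(cfg)
  built <- build_analysis_table(as_raw_table(gen$demo, "DEMO"),
                                as_raw_table(gen$drug, "DRUG"),
                                as_raw_table(gen$reac, "REAC"))
  terms <- make_terms("pt_03")
  scr <- srs_screen(built$cases, make_panel(names(cfg$drugs)), terms)
  expect_s3_class(scr, "srs_screen")
  expect_equal(nrow(scr), 6)
  expect_equal(scr$a + scr$b + scr$c + scr$d, rep(nrow(built$cases), 6))
  # the multiplier-10 drug tops the ranking and is flagged
  expect_identical(scr$drug[1], "drug_c")
  expect_true(scr$is_signal[1])
  expect_true(all(diff(scr$ln_ror) <= 0))
  # vacuous threshold
  scr0 <- srs_screen(built$cases, make_panel(names(cfg$drugs)), terms,
                     alpha = 0)
  expect_equal(sum(scr0$is_signal), 0)
  # a drug absent from every case yields a = b = 0, not an error
  scrx <- srs_screen(built$cases, make_panel("absent_drug"), terms)
  expect_equal(scrx$n_reports, 0)
})

test_that("volcano coordinates are consistent with the screen", {
  cases <- twenty_case_fixture()
  scr <- srs_screen(cases, make_panel(c("dx", "other")),
                    make_terms(c("pt1", "pt2")))
  v <- volcano_data(scr)
  expect_equal(v$y, -log10(scr$p_value))
  expect_equal(v$x, scr$ln_ror)
  expect_equal(v$color, log10(scr$n_reports))
  # upper-right quadrant membership matches the signal flag
  expect_identical(v$is_signal, v$x >= 0 & v$y > -log10(0.05))
  # a balanced table gives x exactly 0
  bal <- make_cases(paste0("B", 1:40),
                    drugs = c(rep(list("dx"), 20), rep(list("oth"), 20)),
                    events = rep(c(list("pt1"), list(character())), 20))
  scr_bal <- srs_screen(bal, make_panel("dx"), make_terms("pt1"))
  expect_equal(scr_bal$ln_ror, 0)
  expect_equal(volcano_data(scr_bal)$x, 0)
})

test_that("signal criterion on reported screen rows handles censored p-values", {
  ref <- reference_screen()
  expect_equal(nrow(ref), 47)
  flags <- apply_signal_criterion(ref$ror, ref$p_value, ref$p_censored,
                                  alpha = 0.05)
  expect_equal(sum(flags), 28)
  # censored "<0.001" counts as significant at 0.05, not at 0.0005
  expect_true(apply_signal_criterion(2, 0.001, TRUE, alpha = 0.05))
  expect_false(apply_signal_criterion(2, 0.001, TRUE, alpha = 5e-4))
})

test_that("optional Benjamini-Hochberg column adjusts but does not alter flags by default", {
  cases <- twenty_case_fixture()
  scr <- srs_screen(cases, make_panel(c("dx", "other")),
                    make_terms(c("pt1", "pt2")), fdr = TRUE)
  expect_true("p_adjusted" %in% names(scr))
  expect_true(all(scr$p_adjusted >= scr$p_value - 1e-12))
  scr_raw <- srs_screen(cases, make_panel(c("dx", "other")),
                        make_terms(c("pt1", "pt2")))
  expect_identical(scr$is_signal, scr_raw$is_signal)
})
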