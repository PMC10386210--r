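test_that("identical seeds give byte-identical databases and files", {
  cfg <- synthetic_config(n_cases = 300, seed = 5)
  g1 <- generate_database(cfg)
  g2 <- generate_database(cfg)
  expect_identical(g1, g2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_jader_dialect(g1, d1)
  p2 <- write_jader_dialect(g2, d2)
  for (k in c("demo", "drug", "reac"))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  # a different seed changes the data
  g3 <- generate_database(synthetic_config(n_cases = 300, seed = 6))
  expect_false(identical(g1$reac, g3$reac))
})

test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(n_cases = 0), "n_cases")
  expect_error(synthetic_config(drugs = c(drug_a = 1.5)), "drugs")
  expect_error(synthetic_config(events = c(pt_01 = -0.1)), "events")
  expect_error(synthetic_config(
    drugs = c(drug_a = 0.1), events = c(pt_01 = 0.01),
    associations = data.frame(drug = "ghost", pt = "pt_01", multiplier = 2)),
    "unknown drug")
  expect_error(synthetic_config(
    drugs = c(drug_a = 0.1), events = c(pt_01 = 0.01),
    associations = data.frame(drug = "drug_a", pt = "ghost", multiplier = 2)),
    "unknown PT")
  expect_error(synthetic_config(
    drugs = c(drug_a = 0.1), events = c(pt_01 = 0.01),
    associations = data.frame(drug = "drug_a", pt = "pt_01", multiplier = -1)),
    "multipliers")
  expect_error(synthetic_config(duplicate_rate = 2), "duplicate_rate")
  expect_error(synthetic_config(sex_probs = c(male = 1, female = 0.5,
                                              missing = 0)), "sex_probs")
})

test_that("an impossible event never occurs", {
  cfg <- synthetic_config(
    n_cases = 2000, seed = 2,
    drugs = c(drug_a = 0.5), events = c(pt_dead = 0, pt_live = 0.05),
    associations = data.frame(drug = "drug_a", pt = "pt_dead", multiplier = 0))
  gen <- generate_database(cfg)
  expect_false("pt_dead" %in% gen$reac$pt_name)
  expect_equal(gen$truth$n_exposed_event[gen$truth$pt == "pt_dead"], 0)
  # multiplier 0 with a positive baseline: no exposed case has the event
  cfg2 <- synthetic_config(
    n_cases = 2000, seed = 2,
    drugs = c(drug_a = 0.5), events = c(pt_x = 0.2),
    associations = data.frame(drug = "drug_a", pt = "pt_x", multiplier = 0))
  gen2 <- generate_database(cfg2)
  expect_equal(gen2$truth$n_exposed_event, 0)
  expect_gt(gen2$truth$n_unexposed_event, 0)
})

test_that("merge mess collapses a case's drug rows into one semicolon row", {
  cfg <- synthetic_config(
    n_cases = 200, seed = 4,
    drugs = c(drugA = 1, drugB = 1), events = c(pt_01 = 0.05),
    associations = data.frame(drug = character(), pt = character(),
                              multiplier = numeric()),
    duplicate_rate = 0, merge_rate = 1)
  gen <- generate_database(cfg)
  expect_equal(nrow(gen$drug), 200)            # one merged row per case
  expect_true(all(gen$drug$drug_name == "drugA;drugB"))
  expect_true(all(grepl(";", gen$drug$route)))
})

test_that("an empty drug list yields a header-only DRUG file", {
  cfg <- synthetic_config(
    n_cases = 50, seed = 1,
    drugs = setNames(numeric(0), character(0)), events = c(pt_01 = 0.1),
    associations = data.frame(drug = character(), pt = character(),
                              multiplier = numeric()))
  gen <- generate_database(cfg)
  expect_equal(nrow(gen$drug), 0)
  dir <- withr::local_tempdir()
  paths <- write_jader_dialect(gen, dir)
  expect_length(readLines(paths[["drug"]]), 1)   # header only
  expect_equal(nrow(read_drug(paths[["drug"]])$rows), 0)
})

test_that("mess injection does not change the cleaned analysis table", {
  base_args <- list(n_cases = 3000, seed = 12)
  clean_cfg <- do.call(synthetic_config,
                       c(base_args, duplicate_rate = 0, merge_rate = 0))
  messy_cfg <- do.call(synthetic_config,
                       c(base_args, duplicate_rate = 0.2, merge_rate = 0.5))
  build <- function(gen)
    build_analysis_table(as_raw_table(gen$demo, "DEMO"),
                         as_raw_table(gen$drug, "DRUG"),
                         as_raw_table(gen$reac, "REAC"))$cases
  clean <- build(generate_database(clean_cfg))
  messy <- build(generate_database(messy_cfg))
  expect_identical(clean$case_id, messy$case_id)
  expect_identical(clean$drugs, messy$drugs)
  expect_identical(clean$events, messy$events)
  expect_identical(clean$sex, messy$sex)
  expect_identical(clean$age, messy$age)
})

test_that("realized truth counts are consistent with the margins", {
  cfg <- synthetic_config(n_cases = 1000, seed = 3)
  gen <- generate_database(cfg)
  tr <- gen$truth
  expect_true(all(tr$n_exposed + tr$n_unexposed == 1000))
  expect_true(all(tr$n_exposed_event <= tr$n_exposed))
  expect_true(all(tr$n_unexposed_event <= tr$n_unexposed))
})

test_that("synthetic configuration round-trips through YAML", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "syn.yaml")
  writeLines(c(
    "n_cases: 500",
    "seed: 9",
    "drugs: {drug_a: 0.2, drug_b: 0.1}",
    "events: {pt_01: 0.02, pt_02: 0.01}",
    "associations:",
    "  - {drug: drug_a, pt: pt_01, multiplier: 5}",
    "duplicate_rate: 0",
    "merge_rate: 0"), f)
  cfg <- load_synthetic_config(f)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(cfg$n_cases, 500L)
  expect_equal(cfg$associations$multiplier, 5)
  gen <- generate_database(cfg)
  expect_equal(nrow(gen$demo), 500)
})
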