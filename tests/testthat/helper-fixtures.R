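# In-code fixture builders shared across test files.

make_terms <- function(pts, name = "test_terms", synonyms = NULL) {
  structure(list(name = name, pts = normalize_name(pts, synonyms),
                 pts_display = pts, synonyms = synonyms, provenance = ""),
            class = "event_term_set")
}

make_panel <- function(drugs, name = "test_panel") {
  structure(list(name = name, drugs = normalize_name(drugs),
                 drugs_display = drugs, synonyms = NULL, provenance = ""),
            class = "drug_panel")
}

make_cases <- function(case_id, sex = NA_character_, age = NA_character_,
                       drugs = NULL, events = NULL) {
  n <- length(case_id)
  cases <- data.frame(case_id = case_id,
                      sex = rep_len(sex, n), age = rep_len(age, n),
                      stringsAsFactors = FALSE)
  cases$drugs <- lapply(drugs %||% rep(list(character()), n),
                        function(d) sort(unique(normalize_name(d))))
  cases$events <- lapply(events %||% rep(list(character()), n),
                         function(e) sort(unique(normalize_name(e))))
  class(cases) <- c("srs_cases", "data.frame")
  cases
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 10-case fixture with one byte-identical duplicate DRUG row and two cases
# on the indicator medication "timolol". Hand-tallied flow counts:
# raw DRUG 12, raw REAC 8, raw DEMO 10; no separators so stacking leaves
# 30 records total; dedup removes the one duplicate DRUG row (29); join
# yields 10 cases; excluding timolol cases C03 and C09 leaves 8.
ten_case_tables <- function() {
  demo <- data.frame(
    case_id = sprintf("C%02d", 1:10),
    sex = c("male", "female", "male", "female", "male",
            "female", "male", "female", "male", "female"),
    age = c("40s", "50s", "60s", "70s", "20s",
            "30s", "80s", "adult", "unknown", ""),
    reporter = "physician", stringsAsFactors = FALSE)
  drug <- data.frame(
    case_id = c("C01", "C02", "C02", "C03", "C04", "C05", "C05",
                "C06", "C07", "C08", "C09", "C10"),
    drug_name = c("aspirin", "aspirin", "ibuprofen", "timolol",
                  "prednisolone", "prednisolone", "prednisolone",
                  "aspirin", "ibuprofen", "aspirin", "timolol", "ibuprofen"),
    route = "oral", date = "", dose = "", dose_unit = "",
    divided_doses = "", role = "suspected", stringsAsFactors = FALSE)
  reac <- data.frame(
    case_id = c("C01", "C02", "C04", "C05", "C06", "C07", "C09", "C10"),
    pt_name = c("glaucoma", "headache", "glaucoma", "nausea",
                "headache", "glaucoma", "nausea", "headache"),
    outcome = "recovered", stringsAsFactors = FALSE)
  list(demo = as_raw_table(demo, "DEMO"), drug = as_raw_table(drug, "DRUG"),
       reac = as_raw_table(reac, "REAC"))
}

# 20 cases for the hand-tallied contingency oracle: drug "dx", terms
# {pt1, pt2}; exposed = cases 1-8; events: 1-5 pt1 (a = 5), 6-8 none (b = 3),
# 9-12 pt2 (c = 4), 13-20 none (d = 8).
twenty_case_fixture <- function() {
  drugs <- c(rep(list("dx"), 8), rep(list("other"), 12))
  events <- c(rep(list("pt1"), 5), rep(list(character()), 3),
              rep(list("pt2"), 4), rep(list(character()), 8))
  make_cases(sprintf("K%02d", 1:20), drugs = drugs, events = events)
}

# independent two-sided Fisher oracle: exhaustive hypergeometric enumeration
# over all tables with the observed margins (minimum-likelihood convention)
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 + m2 == 0) return(1)
  xs <- max(0, n1 - m2):min(n1, m1)
  probs <- choose(m1, xs) * choose(m2, n1 - xs) / choose(m1 + m2, n1)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
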