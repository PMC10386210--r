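# cases with known report counts for the filter oracle:
# drug "d1" on 6 cases, "d2" on 4, "d3" on 1; pt "p1" on 5 cases, "p2" on 3.
structure_fixture <- function() {
  drugs <- c(rep(list("d1"), 6), rep(list("d2"), 4), list("d3"),
             rep(list(character()), 9))
  events <- c(rep(list("p1"), 4), list(character()), list("p2"),  # 1-6
              list("p1"), list("p2"),                             # 7-8
              list(character()), list(character()), list("p2"),   # 9-11
              rep(list(character()), 9))                          # 12-20
  make_cases(sprintf("S%02d", 1:20), drugs = drugs, events = events)
}

test_that("report-count filters match hand-applied thresholds", {
  cases <- structure_fixture()
  panel <- make_panel(c("d1", "d2", "d3"))
  terms <- make_terms(c("p1", "p2"))

  # vacuous thresholds keep everything
  m_all <- filter_and_build_matrix(cases, panel, terms, 1, 1, 1)
  expect_equal(dim(m_all), c(3, 2))

  # drug min 5 total reports keeps d1 only; pt min 4 keeps p1 only
  m <- filter_and_build_matrix(cases, panel, terms,
                               drug_min_reports = 5,
                               drug_min_event_reports = 1, pt_min_reports = 4)
  expect_identical(rownames(m), "d1")
  expect_identical(colnames(m), "p1")

  # the retained cell equals the pair's own Haldane lnROR over all cases
  a <- 4; b <- 2; cc <- 1; dd <- 13
  expect_equal(m["d1", "p1"],
               log((a + 0.5) * (dd + 0.5) / ((b + 0.5) * (cc + 0.5))),
               tolerance = 1e-12)

  # raising any threshold never adds a row or column
  for (th in list(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2))) {
    m_hi <- tryCatch(filter_and_build_matrix(cases, panel, terms,
                                             th[1], th[2], th[3]),
                     error = function(e) NULL)
    if (!is.null(m_hi)) {
      expect_true(all(rownames(m_hi) %in% rownames(m_all)))
      expect_true(all(colnames(m_hi) %in% colnames(m_all)))
    }
  }

  expect_error(filter_and_build_matrix(cases, panel, terms, 100, 10, 50),
               "no drug or no preferred term")
})

test_that("standalone PT filter applies the report threshold", {
  counts <- c(alpha = 60, beta = 50, gamma = 49, delta = 0)
  expect_identical(filter_pt_counts(counts, 50), c("alpha", "beta"))
  df <- data.frame(pt_name = names(counts), n_reports = unname(counts))
  expect_identical(filter_pt_counts(df, 50), c("alpha", "beta"))
})

test_that("Ward clustering reproduces a hand-computed merge sequence", {
  # 1-D points 0, 1, 10, 12. Ward distance between singletons is the
  # Euclidean distance, and a merge's height is sqrt(2 * increase in
  # within-cluster sum of squares):
  #   merge {0},{1} at 1; {10},{12} at 2;
  #   final: delta ESS = (2*2/4) * (11 - 0.5)^2 = 110.25, height sqrt(220.5)
  m <- matrix(c(0, 1, 10, 12), ncol = 1,
              dimnames = list(c("p1", "p2", "p3", "p4"), "x"))
  cl <- ward_cluster(m, k = 2)
  expect_equal(cl$hclust$height, c(1, 2, sqrt(220.5)), tolerance = 1e-12)
  expect_identical(cl$hclust$merge[1, ], c(-1L, -2L))
  expect_identical(cl$hclust$merge[2, ], c(-3L, -4L))
  expect_identical(cl$hclust$merge[3, ], c(1L, 2L))
  expect_equal(unname(cl$labels), c(1, 1, 2, 2))
  expect_true(all(diff(cl$hclust$height) >= 0))
})

test_that("Ward clustering degenerate cases and validation", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  cl <- ward_cluster(m, k = 2)
  expect_equal(cl$hclust$height[1], 0)            # identical rows merge first
  expect_identical(sort(cl$hclust$merge[1, ]), c(-2L, -1L))
  cl_n <- ward_cluster(m, k = 3)                  # singletons at the cut limit
  expect_equal(length(unique(cl_n$labels)), 3)
  expect_error(ward_cluster(m, k = 0), "k must be")
  expect_error(ward_cluster(m, k = 4), "k must be")
})

test_that("cluster labels are invariant to row permutation up to relabeling", {
  set.seed(21)
  m <- matrix(rnorm(14 * 5), 14, 5,
              dimnames = list(paste0("r", 1:14), paste0("c", 1:5)))
  lab <- ward_cluster(m, k = 3)$labels
  perm <- sample(14)
  lab_p <- ward_cluster(m[perm, ], k = 3)$labels[rownames(m)]
  tab <- table(lab, lab_p)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("covariance PCA matches a direct eigendecomposition", {
  set.seed(33)
  m <- matrix(rnorm(5 * 3), 5, 3,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:3)))
  pc <- covariance_pca(m)
  eg <- eigen(cov(m))
  # apply the same largest-loading-positive sign convention to the oracle
  V <- apply(eg$vectors, 2, function(v) v * sign(v[which.max(abs(v))]))
  expect_equal(unname(pc$loadings), V, tolerance = 1e-9)
  centered <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(pc$scores), unname(centered %*% V), tolerance = 1e-9)
  expect_equal(pc$contributions, 100 * eg$values / sum(eg$values),
               tolerance = 1e-9)
})

test_that("PCA contributions sum to 100 and reconstruction is exact", {
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(rnorm(14 * 5), 14, 5)
    pc <- covariance_pca(m)
    expect_equal(sum(pc$contributions), 100, tolerance = 1e-9)
    expect_true(all(diff(pc$contributions) <= 1e-12))  # PC1 >= PC2 >= ...
    expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-9,
                 ignore_attr = TRUE)                   # orthonormal
    recon <- pc$scores %*% t(pc$loadings)
    recon <- sweep(recon, 2, pc$center, `+`)
    expect_lt(max(abs(recon - m)), 1e-9)
  }
})

test_that("PCA degenerate inputs are rejected or collapse to one component", {
  m1 <- cbind(v = c(1, 2, 3, 4), w = 5)   # variance along one column only
  pc <- covariance_pca(m1)
  expect_equal(pc$contributions[1], 100, tolerance = 1e-9)
  expect_error(covariance_pca(matrix(1, 3, 3)), "zero total variance")
  expect_error(covariance_pca(matrix(1:2, 1, 2)), "at least 2 rows")
})

test_that("structure wrapper runs all stages and renders outputs", {
  set.seed(4)
  cases <- make_cases(
    sprintf("T%03d", 1:400),
    drugs = lapply(1:400, function(i) sample(c("d1", "d2", "d3", "d4"),
                                             sample(0:2, 1))),
    events = lapply(1:400, function(i) sample(c("p1", "p2", "p3"),
                                              sample(0:2, 1))))
  res <- srs_structure(cases, make_panel(c("d1", "d2", "d3", "d4")),
                       make_terms(c("p1", "p2", "p3")),
                       drug_min_reports = 10, drug_min_event_reports = 2,
                       pt_min_reports = 10, k = 3)
  expect_s3_class(res, "srs_structure")
  expect_equal(length(unique(res$cluster$labels)), 3)
  dir <- withr::local_tempdir()
  paths <- c(render_dendrogram(res, dir), render_biplot(res, dir))
  expect_true(all(file.exists(paths)))
  scores <- read.csv(paths[["scores"]])
  expect_equal(nrow(scores), nrow(res$matrix))
  loadings <- read.csv(paths[["loadings"]])
  expect_equal(nrow(loadings), ncol(res$matrix))
})
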