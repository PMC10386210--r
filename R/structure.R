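#' Report-count filters and the drugs x PTs lnROR matrix
#'
#' Restricts the panel to drugs with at least `drug_min_reports` total
#' reports and at least `drug_min_event_reports` reports of the event term
#' set, and the term set to PTs reported at least `pt_min_reports` times.
#' Each retained (drug, PT) cell holds the natural log of the
#' Haldane-corrected ROR from that pair's own 2x2 table — the drug against
#' all other reports, the event being that single PT, over the full
#' analysis table.
#'
#' @param cases an `srs_cases` analysis table.
#' @param panel a `drug_panel`.
#' @param terms an `event_term_set`.
#' @param drug_min_reports,drug_min_event_reports,pt_min_reports positive
#'   integer thresholds (defaults 100, 10, 50).
#' @param correction Haldane continuity constant.
#' @return an `lnror_matrix`: numeric matrix (drugs x PTs) with attributes
#'   `row_report_counts`, `row_event_counts`, `col_report_counts`.
#' @export
filter_and_build_matrix <- function(cases, panel, terms,
                                    drug_min_reports = 100,
                                    drug_min_event_reports = 10,
                                    pt_min_reports = 50,
                                    correction = 0.5) {
  th <- c(drug_min_reports, drug_min_event_reports, pt_min_reports)
  if (any(th < 1) || any(th != round(th)))
    stop("filter thresholds must be positive integers", call. = FALSE)

  drugs <- panel$drugs
  event_any <- cases_with_event(cases, terms)
  exposure <- vapply(drugs, function(dr)
    vapply(cases$drugs, function(d) dr %in% d, logical(1)),
    logical(nrow(cases)))
  drug_reports <- colSums(exposure)
  drug_event_reports <- colSums(exposure & event_any)

  pt_member <- vapply(terms$pts, function(pt)
    vapply(cases$events, function(e) pt %in% e, logical(1)),
    logical(nrow(cases)))
  pt_reports <- colSums(pt_member)

  keep_drug <- drug_reports >= drug_min_reports &
    drug_event_reports >= drug_min_event_reports
  keep_pt <- pt_reports >= pt_min_reports
  if (!any(keep_drug) || !any(keep_pt))
    stop("no drug or no preferred term passes the report-count filters",
         call. = FALSE)

  dsel <- which(keep_drug); psel <- which(keep_pt)
  m <- matrix(NA_real_, length(dsel), length(psel),
              dimnames = list(panel$drugs_display[dsel],
                              terms$pts_display[psel]))
  n <- nrow(cases)
  for (i in seq_along(dsel)) {
    exp_i <- exposure[, dsel[i]]
    for (j in seq_along(psel)) {
      ev_j <- pt_member[, psel[j]]
      a <- sum(exp_i & ev_j); b <- sum(exp_i) - a
      cc <- sum(ev_j) - a; dd <- n - a - b - cc
      m[i, j] <- haldane_ror(c(a, b, cc, dd), correction = correction)$ln_ror
    }
  }
  structure(m, class = c("lnror_matrix", "matrix"),
            row_report_counts = drug_reports[dsel],
            row_event_counts = drug_event_reports[dsel],
            col_report_counts = pt_reports[psel],
            thresholds = c(drug_min_reports = drug_min_reports,
                           drug_min_event_reports = drug_min_event_reports,
                           pt_min_reports = pt_min_reports))
}

#' Which preferred terms pass a report-count threshold?
#'
#' Stand-alone form of the PT filter, usable directly on reported per-PT
#' counts (e.g. [reference_pt_counts()]).
#'
#' @param counts named numeric vector, or a data frame with columns
#'   `pt_name` and `n_reports`.
#' @param min_reports threshold, default 50.
#' @return character vector of PT names passing.
#' @export
filter_pt_counts <- function(counts, min_reports = 50) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$n_reports, counts$pt_name)
  names(counts)[counts >= min_reports]
}

#' Ward hierarchical clustering of drug lnROR profiles
#'
#' Agglomerative clustering of the matrix rows with the Ward minimum-
#' variance criterion on Euclidean distances (`stats::hclust`, method
#' `"ward.D2"`, whose merge heights are `sqrt(2 * increase in within-cluster
#' sum of squares)`); cluster labels come from cutting the tree into `k`
#' groups.
#'
#' @param matrix an `lnror_matrix` (any numeric matrix works).
#' @param k number of clusters, between 1 and `nrow(matrix)`.
#' @return an `srs_cluster`: list with the `hclust` object, integer `labels`
#'   named by drug, and `k`.
#' @export
ward_cluster <- function(matrix, k = 3) {
  if (!(length(k) == 1 && k == round(k) && k >= 1 && k <= nrow(matrix)))
    stop(sprintf("k must be an integer in [1, %d]", nrow(matrix)), call. = FALSE)
  hc <- stats::hclust(stats::dist(unclass(matrix), method = "euclidean"),
                      method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels, k = k), class = "srs_cluster")
}

#' @export
print.srs_cluster <- function(x, ...) {
  cat(sprintf("Ward/Euclidean clustering of %d profiles, cut at k = %d\n",
              length(x$labels), x$k))
  print(split(names(x$labels), x$labels))
  invisible(x)
}

#' Principal component analysis on the covariance matrix
#'
#' Columns are centered but not scaled, so components diagonalize the
#' covariance (not correlation) matrix. To make runs comparable, each
#' component's sign is fixed so that its largest-magnitude loading entry is
#' positive. Contributions are eigenvalue shares of the total variance.
#'
#' @param matrix an `lnror_matrix` or numeric matrix with >= 2 rows and
#'   >= 2 columns; observations are drugs (rows), variables are PTs
#'   (columns).
#' @return an `srs_pca`: list with `scores` (rows x components), `loadings`
#'   (columns x components), `contributions` (% of variance, summing to
#'   100), `sdev` and `center`.
#' @export
covariance_pca <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (sum(apply(m, 2, stats::var)) <= 0)
    stop("zero total variance: PCA is degenerate", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  contributions <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = rotation,
                 contributions = contributions, sdev = pc$sdev,
                 center = pc$center),
            class = "srs_pca")
}

#' @export
print.srs_pca <- function(x, ...) {
  cat(sprintf("Covariance PCA: %d observations x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  k <- min(2, length(x$contributions))
  cat(sprintf("Contribution: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(k), x$contributions[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Structure analysis of a screened drug panel
#'
#' Convenience wrapper running the three structure stages in order:
#' [filter_and_build_matrix()], [ward_cluster()], [covariance_pca()].
#'
#' @inheritParams filter_and_build_matrix
#' @param k number of clusters for the tree cut.
#' @return an `srs_structure`: list with `matrix`, `cluster`, `pca`.
#' @export
srs_structure <- function(cases, panel, terms, drug_min_reports = 100,
                          drug_min_event_reports = 10, pt_min_reports = 50,
                          k = 3, correction = 0.5) {
  m <- filter_and_build_matrix(cases, panel, terms, drug_min_reports,
                               drug_min_event_reports, pt_min_reports,
                               correction)
  k <- min(k, nrow(m))
  structure(list(matrix = m, cluster = ward_cluster(m, k),
                 pca = covariance_pca(m)),
            class = "srs_structure")
}

#' @export
print.srs_structure <- function(x, ...) {
  cat(sprintf("lnROR matrix: %d drugs x %d PTs\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(x$cluster); print(x$pca)
  invisible(x)
}

#' Plot a structure analysis
#'
#' `type = "dendrogram"` draws the Ward tree with cluster-coloured labels;
#' `type = "scores"` the PC1/PC2 score plot coloured by cluster;
#' `type = "loadings"` the PT loading vectors on PC1/PC2.
#'
#' @param x an `srs_structure`.
#' @param type which panel to draw.
#' @param ... passed to the underlying plot call.
#' @export
plot.srs_structure <- function(x, type = c("dendrogram", "scores", "loadings"),
                               ...) {
  type <- match.arg(type)
  pal <- c("red3", "green4", "blue3", "orange3", "purple3", "grey40")
  lab <- x$cluster$labels
  if (type == "dendrogram") {
    plot(x$cluster$hclust, hang = -1, xlab = "", sub = "",
         main = "Ward clustering of lnROR profiles", ...)
  } else if (type == "scores") {
    s <- x$pca$scores
    graphics::plot(s[, 1], s[, 2], pch = 19,
                   col = pal[(lab[rownames(s)] - 1) %% length(pal) + 1],
                   xlab = sprintf("PC1 (%.1f%%)", x$pca$contributions[1]),
                   ylab = sprintf("PC2 (%.1f%%)", x$pca$contributions[2]), ...)
    graphics::text(s[, 1], s[, 2], rownames(s), pos = 3, cex = 0.6)
    graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  } else {
    l <- x$pca$loadings
    lim <- max(abs(l[, 1:2])) * 1.2
    graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim),
                   xlab = sprintf("PC1 (%.1f%%)", x$pca$contributions[1]),
                   ylab = sprintf("PC2 (%.1f%%)", x$pca$contributions[2]), ...)
    graphics::arrows(0, 0, l[, 1], l[, 2], length = 0.08, col = "blue3")
    graphics::text(l[, 1], l[, 2], rownames(l), pos = 3, cex = 0.7)
    graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Write structure-analysis figures and coordinate CSVs
#'
#' `render_dendrogram()` writes the Ward tree as PNG plus the merge history
#' and cluster labels as CSV; `render_biplot()` writes the PC1/PC2 score and
#' loading plots as PNG plus scores, loadings, and contributions as CSV.
#'
#' @param x an `srs_structure`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_dendrogram <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  png_path <- file.path(out_dir, "dendrogram.png")
  grDevices::png(png_path, width = 900, height = 600)
  plot(x, type = "dendrogram")
  grDevices::dev.off()
  hc <- x$cluster$hclust
  linkage <- data.frame(step = seq_len(nrow(hc$merge)),
                        left = hc$merge[, 1], right = hc$merge[, 2],
                        height = hc$height)
  p_link <- file.path(out_dir, "linkage.csv")
  p_lab <- file.path(out_dir, "cluster_labels.csv")
  utils::write.csv(linkage, p_link, row.names = FALSE)
  utils::write.csv(data.frame(drug = names(x$cluster$labels),
                              cluster = unname(x$cluster$labels)),
                   p_lab, row.names = FALSE)
  invisible(c(dendrogram = png_path, linkage = p_link, labels = p_lab))
}

#' @rdname render_dendrogram
#' @export
render_biplot <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p_scores_png <- file.path(out_dir, "pca_scores.png")
  grDevices::png(p_scores_png, width = 700, height = 700)
  plot(x, type = "scores")
  grDevices::dev.off()
  p_load_png <- file.path(out_dir, "pca_loadings.png")
  grDevices::png(p_load_png, width = 700, height = 700)
  plot(x, type = "loadings")
  grDevices::dev.off()
  p_scores <- file.path(out_dir, "pca_scores.csv")
  p_load <- file.path(out_dir, "pca_loadings.csv")
  p_contrib <- file.path(out_dir, "pca_contributions.csv")
  utils::write.csv(data.frame(drug = rownames(x$pca$scores),
                              round(x$pca$scores, 10)),
                   p_scores, row.names = FALSE)
  utils::write.csv(data.frame(pt = rownames(x$pca$loadings),
                              round(x$pca$loadings, 10)),
                   p_load, row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(x$pca$contributions),
                              contribution_pct = x$pca$contributions),
                   p_contrib, row.names = FALSE)
  invisible(c(scores_png = p_scores_png, loadings_png = p_load_png,
              scores = p_scores, loadings = p_load, contributions = p_contrib))
}
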