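# Sensitivity profiling across a screen: drug x cell-line AUC matrices,
# median-centered selectivity, pan-sensitive outlier flagging, top-active
# subsetting, and hierarchical clustering of z-scored profiles.

#' Assemble a drug x cell-line AUC matrix
#'
#' One AUC per (drug, line); pairs never fitted are `NA`. Row (drug) and
#' column (line) order is alphabetical, so the matrix is independent of input
#' order. Duplicate pairs are rejected rather than averaged — replicate
#' pooling belongs to the fitting stage.
#'
#' @param fits `data.frame` with columns `compound_id`, `cell_line`, `auc`
#'   (the output of [fit_screen()] qualifies).
#' @return a numeric matrix, drugs in rows, cell lines in columns.
#' @export
build_auc_matrix <- function(fits) {
  need <- c("compound_id", "cell_line", "auc")
  if (!all(need %in% names(fits))) {
    stopf("fits need columns: %s", paste(need, collapse = ", "))
  }
  drugs <- sort(unique(fits$compound_id))
  lines <- sort(unique(fits$cell_line))
  if (anyDuplicated(paste(fits$compound_id, fits$cell_line, sep = "\r"))) {
    stopf("duplicate (compound_id, cell_line) pairs in fits")
  }
  m <- matrix(NA_real_, nrow = length(drugs), ncol = length(lines),
              dimnames = list(drugs, lines))
  m[cbind(match(fits$compound_id, drugs), match(fits$cell_line, lines))] <-
    fits$auc
  m
}

#' Median-center AUCs per drug (normalized AUC)
#'
#' Subtracts from each entry that drug's median AUC across all cell lines
#' (missing entries excluded), removing inherent drug potency so the
#' remainder measures line-specific selectivity. Each drug row of the result
#' has median zero over its non-missing entries.
#'
#' @param mat AUC matrix from [build_auc_matrix()].
#' @return a matrix of normalized AUCs with the same shape and dimnames.
#' @export
normalize_auc <- function(mat) {
  if (any(apply(mat, 1, function(r) all(is.na(r))))) {
    stopf("some drug rows are entirely missing")
  }
  med <- apply(mat, 1, stats::median, na.rm = TRUE)
  sweep(mat, 1, med)
}

#' Most selectively effective drug for one cell line
#'
#' The drug maximizing normalized AUC in that line's column. Ties are broken
#' lexicographically by drug ID and flagged.
#'
#' @param normalized normalized-AUC matrix from [normalize_auc()].
#' @param cell_line column identifier.
#' @return list with `drug`, `margin` (gap to the runner-up; 0 when only one
#'   drug is available) and `tie` flag.
#' @export
most_selective_drug <- function(normalized, cell_line) {
  if (!cell_line %in% colnames(normalized)) {
    stopf("unknown cell line: %s", cell_line)
  }
  v <- normalized[, cell_line]
  if (all(is.na(v))) stopf("no non-missing values for line %s", cell_line)
  mx <- max(v, na.rm = TRUE)
  at_max <- sort(names(v)[!is.na(v) & v == mx])
  others <- v[!is.na(v) & v < mx]
  list(drug = at_max[1],
       margin = if (length(others) > 0) mx - max(others) else 0,
       tie = length(at_max) > 1)
}

#' Flag pan-sensitive outlier cell lines
#'
#' A line whose median normalized AUC across drugs sits more than `k` MADs
#' above the median of those per-line medians is flagged as uniformly
#' hypersensitive and should be removed from downstream comparisons. The MAD
#' uses the consistency-scaled convention (`stats::mad`).
#'
#' @param normalized normalized-AUC matrix from [normalize_auc()].
#' @param k flagging multiplier (default 3).
#' @return list with `flagged` (line IDs), `scores` (per-line medians) and
#'   `cutoff`. Fewer than 3 lines yields no flags, with a warning.
#' @export
flag_outlier_lines <- function(normalized, k = 3) {
  s <- apply(normalized, 2, stats::median, na.rm = TRUE)
  if (ncol(normalized) < 3) {
    warnf("fewer than 3 cell lines: outlier flagging skipped")
    return(list(flagged = character(0), scores = s, cutoff = NA_real_))
  }
  cutoff <- stats::median(s) + k * stats::mad(s)
  list(flagged = names(s)[s > cutoff], scores = s, cutoff = cutoff)
}

#' Select the most active fraction of drugs
#'
#' Drugs ranked by their median (or mean) AUC across lines; the top
#' `round(fraction * n_drugs)` are kept. Rank ties at the cutoff are broken
#' lexicographically by drug ID and flagged.
#'
#' @param mat AUC matrix.
#' @param fraction fraction of drugs to keep, in (0, 1\].
#' @param rank_by activity summary per drug: `"median"` (default) or
#'   `"mean"`.
#' @return list with `drugs` (selected IDs, ranked), `scores` (all drugs) and
#'   `tie_at_cutoff` flag.
#' @export
select_top_active <- function(mat, fraction = 0.25,
                              rank_by = c("median", "mean")) {
  rank_by <- match.arg(rank_by)
  if (nrow(mat) == 0) stopf("empty AUC matrix")
  if (!(fraction > 0 && fraction <= 1)) stopf("fraction must be in (0, 1]")
  f <- if (rank_by == "median") {
    function(r) stats::median(r, na.rm = TRUE)
  } else {
    function(r) mean(r, na.rm = TRUE)
  }
  scores <- apply(mat, 1, f)
  n_sel <- max(1L, round(fraction * nrow(mat)))
  ord <- order(-scores, names(scores))
  sel <- names(scores)[ord][seq_len(n_sel)]
  tie <- n_sel < nrow(mat) &&
    scores[ord[n_sel]] == scores[ord[n_sel + 1]]
  list(drugs = sel, scores = scores, tie_at_cutoff = tie)
}

#' Z-score AUCs within each drug
#'
#' Standardizes each drug row to mean 0 and sample (n-1) standard deviation
#' 1 over its non-missing entries. Rows with zero spread (or fewer than two
#' values) carry no contrast and are dropped with a warning.
#'
#' @param mat AUC matrix (possibly restricted to a drug subset).
#' @return a matrix of z-scores, constant rows removed.
#' @export
zscore_by_drug <- function(mat) {
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warnf("dropping %d constant or empty drug row(s): %s", sum(drop),
          paste(rownames(mat)[drop], collapse = ", "))
    mat <- mat[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  means <- rowMeans(mat, na.rm = TRUE)
  sweep(sweep(mat, 1, means), 1, sds, "/")
}

#' Two-way hierarchical clustering of z-scored profiles
#'
#' Agglomerative clustering of both drugs (rows) and cell lines (columns),
#' by default with correlation distance (1 - Pearson, pairwise-complete) and
#' average linkage. Rows and columns are sorted by identifier before
#' clustering so the merge order, heights and leaf order are deterministic
#' regardless of input order.
#'
#' @param z z-score matrix from [zscore_by_drug()] (>= 2 rows and columns).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`
#'   (leaf identifier orders) and `subset_used` (row IDs clustered).
#' @export
hierarchical_cluster <- function(z, distance = c("pearson", "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (nrow(z) < 2 || ncol(z) < 2) stopf("need >= 2 rows and >= 2 columns")
  z <- z[sort(rownames(z)), sort(colnames(z)), drop = FALSE]
  dfun <- function(m) {
    if (any(apply(m, 1, function(r) all(is.na(r))))) {
      stopf("clustering input contains an all-missing profile")
    }
    if (distance == "pearson") {
      stats::as.dist(1 - stats::cor(t(m), use = "pairwise.complete.obs"))
    } else {
      stats::dist(m)
    }
  }
  hr <- stats::hclust(dfun(z), method = linkage)
  hc <- stats::hclust(dfun(t(z)), method = linkage)
  list(row_hclust = hr, col_hclust = hc,
       row_order = rownames(z)[hr$order],
       col_order = colnames(z)[hc$order],
       subset_used = rownames(z))
}

#' Profile a fitted screen
#'
#' Convenience wrapper over the profiling stage: build the AUC matrix,
#' median-center per drug, flag pan-sensitive outlier lines (flagged lines
#' are removed before selectivity calls), pick each remaining line's most
#' selective drug, select the most active drug fraction, and cluster its
#' z-scored profiles (when the subset is large enough).
#'
#' @param fits fit table from [fit_screen()].
#' @param top_fraction fraction of drugs clustered (default 0.25).
#' @param outlier_k MAD multiplier for outlier flagging.
#' @param zscore_on cluster z-scores of `"raw"` (default) or `"normalized"`
#'   AUC rows.
#' @return list with `auc`, `normalized`, `outliers`, `selectivity`
#'   (per-line best drug table), `top_active`, `cluster` (or `NULL`).
#' @export
profile_screen <- function(fits, top_fraction = 0.25, outlier_k = 3,
                           zscore_on = c("raw", "normalized")) {
  zscore_on <- match.arg(zscore_on)
  mat <- build_auc_matrix(fits)
  norm <- normalize_auc(mat)
  out <- flag_outlier_lines(norm, k = outlier_k)
  keep <- setdiff(colnames(mat), out$flagged)
  mat_kept <- mat[, keep, drop = FALSE]
  norm_kept <- normalize_auc(mat_kept)
  sel <- do.call(rbind, lapply(keep, function(cl) {
    b <- most_selective_drug(norm_kept, cl)
    data.frame(cell_line = cl, drug = b$drug, margin = b$margin,
               tie = b$tie, stringsAsFactors = FALSE)
  }))
  top <- select_top_active(mat_kept, fraction = top_fraction)
  zsrc <- if (zscore_on == "raw") mat_kept else norm_kept
  zs <- suppressWarnings(
    zscore_by_drug(zsrc[top$drugs, , drop = FALSE])
  )
  cluster <- if (nrow(zs) >= 2 && ncol(zs) >= 2) hierarchical_cluster(zs)
  list(auc = mat, normalized = norm, outliers = out, selectivity = sel,
       top_active = top, cluster = cluster)
}
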