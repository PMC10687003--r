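# per-cell library normalization to 10,000 counts; log1p on top for testing
normalize_cells <- function(mat, scale = 1e4) {
  lib <- rowSums(mat)
  lib[lib == 0] <- 1
  mat * (scale / lib)
}

# vectorized two-sided Wilcoxon rank-sum (normal approximation with tie
# correction and continuity correction, matching
# wilcox.test(exact = FALSE, correct = TRUE))
rank_sum_test <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  X <- rbind(x1, x2)
  stat <- numeric(ncol(X)); pval <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(X[, j])
    ties <- sum(nt^3 - nt)
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
    if (sigma2 <= 0) { stat[j] <- U; pval[j] <- 1; next }
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    stat[j] <- U
    pval[j] <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = stat, p_value = pmin(1, pval))
}

#' Downsample the cells of one cluster/group to a fixed size
#'
#' Uniform sampling without replacement under a local seed; the caller's RNG
#' state is left untouched.
#'
#' @param cell_idx Indices (or ids) of the available cells.
#' @param n Target size (default 50).
#' @param seed Integer seed.
#' @return A subset of `cell_idx` of length `n`, or `NULL` (with a warning)
#'   when fewer than `n` cells are available.
#' @export
downsample_cells <- function(cell_idx, n = 50, seed) {
  if (length(cell_idx) < n) {
    warning("cluster has fewer than ", n, " cells; skipped")
    return(NULL)
  }
  if (length(cell_idx) == n) return(cell_idx)
  with_seed(seed, sample(cell_idx, n))
}

#' Differential expression between two cell groups of one cluster
#'
#' Counts are normalized per cell to 10,000, a two-sided Wilcoxon rank-sum
#' test is run per gene on the log1p-normalized values, p values are
#' BH-adjusted, and DEGs require adjusted p below `fdr` and
#' `|log2FC| >= lfc_threshold` (inclusive), where the fold change compares
#' normalized group means with a 0.01 pseudo-count. All-zero genes are
#' skipped.
#'
#' @param treated,mock Cell x gene count matrices (same genes).
#' @param lfc_threshold Fold-change threshold (default 0.15, inclusive).
#' @param fdr Adjusted-p threshold (default 0.01).
#' @return List: `results` data.frame (gene, log2_fc, p_value, adj_p, is_deg)
#'   and `degs` (character vector of DEG names).
#' @export
cluster_de_test <- function(treated, mock, lfc_threshold = 0.15, fdr = 0.01) {
  if (nrow(treated) < 2 || nrow(mock) < 2) stop("need >= 2 cells per side")
  genes <- colnames(treated)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(treated)))
  nz <- colSums(treated) + colSums(mock) > 0
  nt <- normalize_cells(treated)[, nz, drop = FALSE]
  nm <- normalize_cells(mock)[, nz, drop = FALSE]
  lfc <- log2((colMeans(nt) + 0.01) / (colMeans(nm) + 0.01))
  rs <- rank_sum_test(log1p(nt), log1p(nm))
  adj <- stats::p.adjust(rs$p_value, method = "BH")
  res <- data.frame(gene = genes[nz], log2_fc = lfc, p_value = rs$p_value,
                    adj_p = adj,
                    is_deg = adj < fdr & abs(lfc) >= lfc_threshold,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  list(results = res, degs = res$gene[res$is_deg])
}

#' Per-cluster DEG burden by repeated fixed-size downsampling
#'
#' For every cluster with at least `n` cells in each group, `reps`
#' repetitions each downsample both groups to `n` cells and count DEGs with
#' [cluster_de_test()]; cluster burdens are then compared pairwise with
#' two-sided unpaired t tests on the repetition vectors.
#'
#' @param counts Cell x gene count matrix.
#' @param meta `data.frame` with one row per cell: cluster, group
#'   (`mock`/`treated`), aligned with the rows of `counts`.
#' @param n Downsample size per cluster and group (default 50).
#' @param reps Number of repetitions (default 10).
#' @param seed Master seed; repetition seeds are derived children.
#' @param lfc_threshold,fdr Passed to [cluster_de_test()].
#' @return Object of class `burden_result`: `counts` (clusters x reps DEG
#'   counts), `mean`, `se`, `pairwise_p` matrix, `n`, `reps`, `engine`.
#' @export
burden_analysis <- function(counts, meta, n = 50, reps = 10, seed = 1,
                            lfc_threshold = 0.15, fdr = 0.01) {
  clusters <- sort(unique(meta$cluster))
  eligible <- clusters[vapply(clusters, function(cl) {
    sum(meta$cluster == cl & meta$group == "treated") >= n &&
      sum(meta$cluster == cl & meta$group == "mock") >= n
  }, TRUE)]
  skipped <- setdiff(clusters, eligible)
  if (length(skipped)) {
    warning("cluster(s) with fewer than ", n, " cells per group skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(eligible) < 2) stop("need >= 2 eligible clusters")
  burden <- matrix(NA_integer_, length(eligible), reps,
                   dimnames = list(eligible, paste0("rep", seq_len(reps))))
  for (ci in seq_along(eligible)) {
    cl <- eligible[ci]
    idx_t <- which(meta$cluster == cl & meta$group == "treated")
    idx_m <- which(meta$cluster == cl & meta$group == "mock")
    for (r in seq_len(reps)) {
      st <- downsample_cells(idx_t, n, child_seed(seed, 70 + ci, 2 * r))
      sm <- downsample_cells(idx_m, n, child_seed(seed, 70 + ci, 2 * r + 1))
      de <- cluster_de_test(counts[st, , drop = FALSE],
                            counts[sm, , drop = FALSE],
                            lfc_threshold, fdr)
      burden[ci, r] <- length(de$degs)
    }
  }
  pw <- matrix(NA_real_, length(eligible), length(eligible),
               dimnames = list(eligible, eligible))
  for (i in seq_along(eligible)) {
    for (j in seq_along(eligible)) {
      if (i >= j) next
      a <- burden[i, ]; b <- burden[j, ]
      pw[i, j] <- pw[j, i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
    }
  }
  structure(
    list(counts = burden, mean = rowMeans(burden),
         se = apply(burden, 1, stats::sd) / sqrt(reps),
         pairwise_p = pw, n = n, reps = reps,
         engine = "wilcoxon rank-sum (normal approximation)"),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat("burden_result:", nrow(x$counts), "clusters x", x$reps,
      "repetitions (n =", x$n, "cells/group, DE engine:", x$engine, ")\n")
  print(round(cbind(mean = x$mean, se = x$se), 2))
  invisible(x)
}
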