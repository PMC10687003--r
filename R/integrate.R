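#' Select up/down differentially expressed genes from a bulk table
#'
#' Thresholds follow the bulk analysis: mean normalized counts strictly above
#' `min_base_mean` and log2 fold change strictly beyond `+/- lfc_threshold`.
#'
#' @param e Expression table (gene_id, base_mean, log2_fc, ...).
#' @param min_base_mean Minimum mean normalized counts (default 150, strict).
#' @param lfc_threshold Fold-change threshold (default 0.15, strict).
#' @return List with character vectors `up` and `down`.
#' @export
select_degs <- function(e, min_base_mean = 150, lfc_threshold = 0.15) {
  expressed <- e$base_mean > min_base_mean
  list(up = e$gene_id[expressed & e$log2_fc > lfc_threshold],
       down = e$gene_id[expressed & e$log2_fc < -lfc_threshold])
}

#' Assign region calls to overlapping gene bodies
#'
#' A region is assigned to every gene whose body (txStart..txEnd, no flanks)
#' it overlaps by at least 1 bp; regions overlapping no gene go to the
#' `unassigned` bucket.
#'
#' @param regions Region call `data.frame`.
#' @param genes Gene model table.
#' @return List: `assignments` data.frame (gene_id + the region columns) and
#'   `unassigned` (row indices of regions overlapping no gene).
#' @export
assign_regions_to_genes <- function(regions, genes) {
  if (!nrow(regions)) {
    return(list(assignments = cbind(data.frame(gene_id = character()),
                                    regions), unassigned = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(genes))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  assignments <- cbind(data.frame(gene_id = genes$gene_id[si],
                                  stringsAsFactors = FALSE),
                       regions[qi, , drop = FALSE])
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = setdiff(seq_len(nrow(regions)), unique(qi)))
}

#' Classify methylation-expression concordance
#'
#' 5hmC mode: gain-activated genes have expression log2FC > 0 and at least
#' one gain region with p below `region_alpha`; loss-repressed genes are the
#' mirror image. 5mC mode: hyper-down genes are expression-down DEGs with at
#' least one hypermethylated DMR, hypo-up the mirror. When a gene carries
#' significant regions of both directions the most significant region decides
#' and the conflict is reported via `message()`.
#'
#' @param e Expression table.
#' @param gene_regions `assignments` from [assign_regions_to_genes()]; rows
#'   must carry `direction` and, for 5hmC mode, `p_value`/`fdr`.
#' @param mode `"5hmC"` or `"5mC"`.
#' @param region_alpha Region significance threshold for 5hmC mode
#'   (default 0.05 on the raw p, per the definition).
#' @param use_adjusted Use the region FDR instead of the raw p (default
#'   FALSE).
#' @param deg_sets For 5mC mode, the up/down sets from [select_degs()];
#'   computed from `e` with default thresholds when omitted.
#' @return List of gene-id character vectors: `gain_activated` and
#'   `loss_repressed` (5hmC) or `hyper_down` and `hypo_up` (5mC), plus
#'   `support` (the qualifying region rows).
#' @export
classify_concordance <- function(e, gene_regions, mode = c("5hmC", "5mC"),
                                 region_alpha = 0.05, use_adjusted = FALSE,
                                 deg_sets = NULL) {
  mode <- match.arg(mode)
  gr <- gene_regions
  if (mode == "5hmC") {
    pcol <- if (use_adjusted) gr$fdr else gr$p_value
    gr <- gr[pcol < region_alpha, , drop = FALSE]
    pcol <- if (use_adjusted) gr$fdr else gr$p_value
  } else {
    pcol <- rep(0, nrow(gr))  # DMR calls are already thresholded
  }
  # resolve genes with significant regions in both directions
  dir_of <- vapply(split(seq_len(nrow(gr)), gr$gene_id), function(i) {
    dirs <- unique(gr$direction[i])
    if (length(dirs) > 1) {
      best <- i[which.min(pcol[i])]
      message("gene ", gr$gene_id[i[1]],
              " has regions in both directions; using the more significant")
      gr$direction[best]
    } else dirs
  }, "")
  up_dir <- if (mode == "5hmC") "gain" else "hyper"
  dn_dir <- if (mode == "5hmC") "loss" else "hypo"
  genes_up_regions <- names(dir_of)[dir_of == up_dir]
  genes_dn_regions <- names(dir_of)[dir_of == dn_dir]
  if (mode == "5hmC") {
    pos <- e$gene_id[e$log2_fc > 0]
    neg <- e$gene_id[e$log2_fc < 0]
    out <- list(gain_activated = intersect(pos, genes_up_regions),
                loss_repressed = intersect(neg, genes_dn_regions))
  } else {
    if (is.null(deg_sets)) deg_sets <- select_degs(e)
    out <- list(hyper_down = intersect(deg_sets$down, genes_up_regions),
                hypo_up = intersect(deg_sets$up, genes_dn_regions))
  }
  out$support <- gr[gr$gene_id %in% unlist(out[1:2]), , drop = FALSE]
  out
}

#' One-sided binomial gene-set overlap test
#'
#' Tests whether a query gene set overlaps a disease list more than expected
#' when drawing `|query|` genes with per-gene hit probability
#' `|disease| / |universe|`; p is the exact upper binomial tail `P(X >= k)`.
#'
#' @param query,disease_list,universe Character vectors of gene ids; query
#'   and disease list must be subsets of the universe.
#' @return List: n (query size), m (list size), N (universe size),
#'   k (overlap), p_binomial.
#' @export
geneset_overlap_binomial <- function(query, disease_list, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(query); disease_list <- unique(disease_list)
  if (length(setdiff(query, universe))) stop("query not within universe")
  if (length(setdiff(disease_list, universe))) {
    stop("disease list not within universe")
  }
  n <- length(query); m <- length(disease_list); N <- length(universe)
  k <- length(intersect(query, disease_list))
  p0 <- m / N
  p <- if (k == 0) 1 else stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(n = n, m = m, N = N, k = k, p_binomial = p)
}

#' Correlate gene expression change with intragenic methylation change
#'
#' @param expr_lfc Per-gene expression log2 fold changes.
#' @param meth_lfc Per-gene aggregate methylation log fold changes (parallel
#'   vector, >= 3 pairs).
#' @return List: pearson_r, spearman_rho, p_value (Pearson, two-sided), n.
#' @export
methylation_expression_correlation <- function(expr_lfc, meth_lfc) {
  keep <- is.finite(expr_lfc) & is.finite(meth_lfc)
  x <- expr_lfc[keep]; y <- meth_lfc[keep]
  if (length(x) < 3) stop("need >= 3 paired genes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; correlation undefined")
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  list(pearson_r = unname(ct$estimate),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       p_value = ct$p.value, n = length(x))
}
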