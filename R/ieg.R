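#' Build gene-body and promoter analysis windows for a gene
#'
#' The body window runs from 1000 bp upstream of the TSS to 1000 bp
#' downstream of the TES; the promoter window runs from 3000 bp upstream to
#' 1000 bp downstream of the TSS. Both are strand-aware and clipped to
#' chromosome bounds.
#'
#' @param gene One row of a gene model table (gene_id, chrom, start, end,
#'   strand with strand in `+`/`-`).
#' @param layout Optional [genome_layout()] for clipping.
#' @param body_flank Flank added on both sides of the gene (default 1000 bp).
#' @param promoter_up,promoter_down Promoter extent around the TSS
#'   (defaults 3000 / 1000 bp).
#' @return List of two interval data frames, `body` and `promoter`.
#' @export
build_gene_regions <- function(gene, layout = NULL, body_flank = 1000,
                               promoter_up = 3000, promoter_down = 1000) {
  if (!gene$strand %in% c("+", "-")) stop("gene strand must be '+' or '-'")
  len <- if (!is.null(layout)) layout$chrom_lengths[[gene$chrom]] else Inf
  body <- c(gene$start - body_flank, gene$end + body_flank)
  if (gene$strand == "+") {
    prom <- c(gene$start - promoter_up, gene$start + promoter_down)
  } else {
    prom <- c(gene$end - promoter_down, gene$end + promoter_up)
  }
  clip <- function(iv) c(max(0, iv[1]), min(len, iv[2]))
  body <- clip(body); prom <- clip(prom)
  list(body = data.frame(chrom = gene$chrom, start = body[1], end = body[2],
                         strand = gene$strand, name = gene$gene_id,
                         stringsAsFactors = FALSE),
       promoter = data.frame(chrom = gene$chrom, start = prom[1],
                             end = prom[2], strand = gene$strand,
                             name = gene$gene_id, stringsAsFactors = FALSE))
}

#' Split a region into consecutive fixed-width tiles
#'
#' @param region One-row interval data frame.
#' @param tile Tile width in bp (default 500).
#' @param keep_partial Keep a clipped terminal tile shorter than `tile`
#'   (default FALSE: it is dropped).
#' @return Interval `data.frame` of tiles (possibly zero rows, with a warning
#'   when the region is shorter than one tile).
#' @export
tile_region <- function(region, tile = 500, keep_partial = FALSE) {
  if (tile < 1) stop("tile width must be >= 1")
  len <- region$end - region$start
  n_full <- floor(len / tile)
  if (n_full == 0 && !(keep_partial && len > 0)) {
    warning("region shorter than one tile; no tiles produced")
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  start <- region$start + (seq_len(n_full) - 1) * tile
  end <- start + tile
  if (keep_partial && len %% tile > 0) {
    start <- c(start, region$start + n_full * tile)
    end <- c(end, region$end)
  }
  data.frame(chrom = region$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Build the 2 x 10 group-by-sub-bin count matrix for one 500-bp tile
#'
#' The tile is split into ten 50-bp sub-bins; reads pooled across replicates
#' of each group are counted by the fragment-midpoint rule and scaled to
#' counts per million of the pooled group library.
#'
#' @param tile One-row interval of width 500 (or 10x `sub_bin`).
#' @param reads_treated,reads_mock Pooled fragment intervals per group.
#' @param lib_treated,lib_mock Pooled group library sizes.
#' @param sub_bin Sub-bin width (default 50).
#' @return 2 x 10 numeric matrix with rows `treated`, `mock`.
#' @export
region_matrix <- function(tile, reads_treated, reads_mock,
                          lib_treated, lib_mock, sub_bin = 50) {
  n_bins <- (tile$end - tile$start) / sub_bin
  if (n_bins != round(n_bins)) stop("tile width must be a multiple of sub_bin")
  n_bins <- as.integer(n_bins)
  count_row <- function(reads, lib) {
    if (is.null(reads) || !nrow(reads)) return(numeric(n_bins))
    rd <- reads[reads$chrom == tile$chrom, , drop = FALSE]
    mid <- floor((rd$start + rd$end) / 2)
    inside <- mid >= tile$start & mid < tile$end
    idx <- (mid[inside] - tile$start) %/% sub_bin + 1
    tabulate(idx, nbins = n_bins) * 1e6 / lib
  }
  rbind(treated = count_row(reads_treated, lib_treated),
        mock = count_row(reads_mock, lib_mock))
}

#' Build a region matrix from precomputed per-sub-bin counts
#'
#' @param treated,mock Numeric vectors of equal length (normally 10) of
#'   library-normalized sub-bin counts.
#' @return 2 x n matrix with rows `treated`, `mock`.
#' @export
region_matrix_from_counts <- function(treated, mock) {
  if (length(treated) != length(mock)) stop("rows must have equal length")
  rbind(treated = as.numeric(treated), mock = as.numeric(mock))
}

#' Pooled-variance two-sample t test on the two rows of a region matrix
#'
#' Textbook Student's t with pooled variance and `n1 + n2 - 2` degrees of
#' freedom (18 for the standard 2 x 10 matrix); the statistic is computed on
#' treated minus mock. Identical constant rows yield t = 0, p = 1.
#'
#' @param m A 2-row matrix (rows `treated`, `mock`).
#' @return List: t, df, p_value.
#' @export
region_ttest <- function(m) {
  if (nrow(m) != 2) stop("region matrix must have exactly 2 rows")
  x <- m[1, ]; y <- m[2, ]
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p_value = 0))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Cell-type weights for combining neuronal and non-neuronal levels
#'
#' Defaults to the cortical composition assumption of 28% neuronal and 72%
#' non-neuronal cells.
#'
#' @param f_neuron Neuronal fraction in `[0, 1]` (default 0.28).
#' @return List with `f_neuron` and `f_non_neuron` (summing to 1).
#' @export
cell_type_weights <- function(f_neuron = 0.28) {
  if (!is.finite(f_neuron) || f_neuron < 0 || f_neuron > 1) {
    stop("f_neuron must lie in [0, 1]")
  }
  list(f_neuron = f_neuron, f_non_neuron = 1 - f_neuron)
}

#' Cell-type-weighted combined 5hmC/5mC level
#'
#' `combined = level_neuron * f_neuron + level_non_neuron * (1 - f_neuron)`,
#' the weighted bulk-equivalent level for sorted-fraction data.
#'
#' @param level_neuron,level_non_neuron Non-negative levels measured in the
#'   NeuN+ and NeuN- fractions (vectorized).
#' @param weights A [cell_type_weights()] object.
#' @return Numeric combined level(s).
#' @examples
#' combined_level(1, 0)  # 0.28
#' combined_level(0, 1)  # 0.72
#' @export
combined_level <- function(level_neuron, level_non_neuron,
                           weights = cell_type_weights()) {
  if (any(level_neuron < 0) || any(level_non_neuron < 0)) {
    stop("levels must be non-negative")
  }
  level_neuron * weights$f_neuron + level_non_neuron * weights$f_non_neuron
}

#' Neuronal and non-neuronal expression log2 fold changes from cluster means
#'
#' Compartment expression is the unweighted mean over member clusters within
#' each group; the fold change uses a 0.01 pseudo-count to tolerate zero
#' means.
#'
#' @param cluster_means Long `data.frame`: gene_id, cluster, group
#'   (`mock`/`treated`), mean_expr.
#' @param neuronal_clusters Cluster labels belonging to the neuronal
#'   compartment; all others are non-neuronal.
#' @param pseudo Pseudo-count (default 0.01).
#' @return `data.frame`: gene_id, neuronal_log2fc, non_neuronal_log2fc.
#' @export
celltype_logfc <- function(cluster_means, neuronal_clusters, pseudo = 0.01) {
  clusters <- unique(cluster_means$cluster)
  non_neuronal <- setdiff(clusters, neuronal_clusters)
  if (!length(intersect(clusters, neuronal_clusters))) {
    stop("neuronal compartment is empty")
  }
  if (!length(non_neuronal)) stop("non-neuronal compartment is empty")
  comp_lfc <- function(members) {
    sub <- cluster_means[cluster_means$cluster %in% members, , drop = FALSE]
    agg <- stats::aggregate(mean_expr ~ gene_id + group, data = sub, FUN = mean)
    tr <- agg[agg$group == "treated", ]
    mo <- agg[agg$group == "mock", ]
    mo_expr <- mo$mean_expr[match(tr$gene_id, mo$gene_id)]
    data.frame(gene_id = tr$gene_id,
               lfc = log2((tr$mean_expr + pseudo) / (mo_expr + pseudo)),
               stringsAsFactors = FALSE)
  }
  neu <- comp_lfc(intersect(clusters, neuronal_clusters))
  non <- comp_lfc(non_neuronal)
  out <- data.frame(gene_id = neu$gene_id, neuronal_log2fc = neu$lfc,
                    stringsAsFactors = FALSE)
  out$non_neuronal_log2fc <- non$lfc[match(out$gene_id, non$gene_id)]
  out
}

#' Correlate IEG expression change with 5hmC and 5mC change
#'
#' Expects a per-gene table with expression log2FC and aggregate gene-body
#' 5hmC and promoter 5mC log2FC; reports Pearson and Spearman correlations
#' for IEGs (5hmC expected positive, 5mC expected negative), with non-IEG
#' genes summarized separately as controls.
#'
#' @param per_gene `data.frame` with columns gene_id, is_ieg, expr_log2fc,
#'   hmc_log2fc and optionally mec_log2fc.
#' @return List: `per_gene` (the input), `ieg` and `control` data frames of
#'   correlations (mark, pearson_r, spearman_rho, p_value, n).
#' @export
ieg_summary <- function(per_gene) {
  if (sum(per_gene$is_ieg) < 3) stop("need >= 3 IEGs")
  cor_block <- function(rows) {
    marks <- intersect(c("hmc_log2fc", "mec_log2fc"), names(per_gene))
    do.call(rbind, lapply(marks, function(mk) {
      x <- rows$expr_log2fc; y <- rows[[mk]]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) < 3 || stats::sd(x[keep]) == 0 ||
          stats::sd(y[keep]) == 0) {
        return(data.frame(mark = sub("_log2fc", "", mk), pearson_r = NA_real_,
                          spearman_rho = NA_real_, p_value = NA_real_,
                          n = sum(keep)))
      }
      ct <- stats::cor.test(x[keep], y[keep])
      data.frame(mark = sub("_log2fc", "", mk),
                 pearson_r = unname(ct$estimate),
                 spearman_rho = stats::cor(x[keep], y[keep],
                                           method = "spearman"),
                 p_value = ct$p.value, n = sum(keep),
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_gene = per_gene,
       ieg = cor_block(per_gene[per_gene$is_ieg, , drop = FALSE]),
       control = if (sum(!per_gene$is_ieg) >= 3) {
         cor_block(per_gene[!per_gene$is_ieg, , drop = FALSE])
       } else NULL)
}

#' Per-tile t tests over IEG gene bodies and promoters
#'
#' Consumes a long table of precomputed 50-bp per-group normalized counts
#' (one row per gene, context, tile and sub-bin) and runs [region_ttest()]
#' per tile; raw p values are BH-adjusted within each gene and context.
#'
#' @param profiles `data.frame` with columns gene_id, context (`body` /
#'   `promoter`), tile, bin, treated, mock.
#' @return `data.frame`: gene_id, context, tile, mean_treated, mean_mock, t,
#'   p_value, adj_p (BH within gene x context).
#' @export
ieg_region_tests <- function(profiles) {
  key <- interaction(profiles$gene_id, profiles$context, profiles$tile,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(profiles)), key), function(i) {
    sub <- profiles[i, ][order(profiles$bin[i]), ]
    m <- region_matrix_from_counts(sub$treated, sub$mock)
    tt <- region_ttest(m)
    data.frame(gene_id = sub$gene_id[1], context = sub$context[1],
               tile = sub$tile[1], mean_treated = mean(sub$treated),
               mean_mock = mean(sub$mock), t = tt$t, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$context, out$tile), , drop = FALSE]
  grp <- interaction(out$gene_id, out$context, drop = TRUE)
  out$adj_p <- stats::ave(out$p_value, grp,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}
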