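#' Assign a primary genomic feature to each region
#'
#' The feature of a region is decided at its midpoint with fixed precedence
#' promoter > 5'UTR > exon > 3'UTR > TTS > intron > intergenic. The promoter
#' window is TSS-`promoter_up` .. TSS+`promoter_down` (strand-aware) and the
#' TTS window runs `tts_down` bp downstream of the transcription end site.
#' CpG-island and repeat overlap are orthogonal any-overlap flags on the full
#' region, with the repeat class taken from the longest-overlap element.
#'
#' @param regions Interval `data.frame` of region calls.
#' @param genes Gene model table (see [read_gene_table()]); UTR features are
#'   only assigned when `utr5_*`/`utr3_*` interval columns are present.
#' @param cgi,repeats Optional interval data frames; `repeats` carries a
#'   class in its `name` column.
#' @param promoter_up,promoter_down,tts_down Window sizes in bp.
#' @return `data.frame`: one row per region with `feature`, `gene_id`,
#'   `cgi_overlap`, `repeat_class`.
#' @export
annotate_regions <- function(regions, genes, cgi = NULL, repeats = NULL,
                             promoter_up = 2000, promoter_down = 500,
                             tts_down = 1000) {
  if (!nrow(regions)) {
    return(data.frame(feature = character(), gene_id = character(),
                      cgi_overlap = logical(), repeat_class = character()))
  }
  mid_gr <- midpoint_granges(regions)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  tes <- ifelse(plus, genes$end, genes$start)
  prom <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, ifelse(plus, tss - promoter_up, tss - promoter_down)),
    end = ifelse(plus, tss + promoter_down, tss + promoter_up),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  tts <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, ifelse(plus, tes, tes - tts_down)),
    end = ifelse(plus, tes + tts_down, tes),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  exon <- NULL
  if (!is.null(genes$exon_starts)) {
    nex <- lengths(genes$exon_starts)
    exon <- data.frame(chrom = rep(genes$chrom, nex),
                       start = unlist(genes$exon_starts),
                       end = unlist(genes$exon_ends),
                       gene_id = rep(genes$gene_id, nex),
                       stringsAsFactors = FALSE)
  }
  body <- data.frame(chrom = genes$chrom, start = genes$start,
                     end = genes$end, gene_id = genes$gene_id,
                     stringsAsFactors = FALSE)
  feature_sets <- list(promoter = prom)
  if (!is.null(genes$utr5_start)) {
    feature_sets[["5'UTR"]] <- data.frame(chrom = genes$chrom,
                                          start = genes$utr5_start,
                                          end = genes$utr5_end,
                                          gene_id = genes$gene_id)
  }
  if (!is.null(exon)) feature_sets$exon <- exon
  if (!is.null(genes$utr3_start)) {
    feature_sets[["3'UTR"]] <- data.frame(chrom = genes$chrom,
                                          start = genes$utr3_start,
                                          end = genes$utr3_end,
                                          gene_id = genes$gene_id)
  }
  feature_sets$TTS <- tts
  feature_sets$intron <- body  # gene body fallback after exon precedence

  feature <- rep("intergenic", nrow(regions))
  gene_id <- rep(NA_character_, nrow(regions))
  unset <- rep(TRUE, nrow(regions))
  for (fname in names(feature_sets)) {
    fs <- feature_sets[[fname]]
    fs <- fs[fs$start < fs$end, , drop = FALSE]
    if (!nrow(fs)) next
    hits <- GenomicRanges::findOverlaps(mid_gr, as_granges(fs),
                                        select = "first")
    take <- unset & !is.na(hits)
    feature[take] <- fname
    gene_id[take] <- fs$gene_id[hits[take]]
    unset <- unset & !take
  }
  cgi_overlap <- rep(FALSE, nrow(regions))
  if (!is.null(cgi) && nrow(cgi)) {
    cgi_overlap <- IRanges::overlapsAny(as_granges(regions), as_granges(cgi))
  }
  repeat_class <- rep(NA_character_, nrow(regions))
  if (!is.null(repeats) && nrow(repeats)) {
    hits <- GenomicRanges::findOverlaps(as_granges(regions),
                                        as_granges(repeats))
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        as_granges(regions)[S4Vectors::queryHits(hits)],
        as_granges(repeats)[S4Vectors::subjectHits(hits)]))
      best <- tapply(seq_along(ov), S4Vectors::queryHits(hits),
                     function(i) i[which.max(ov[i])])
      qi <- as.integer(names(best))
      repeat_class[qi] <- repeats$name[S4Vectors::subjectHits(hits)[unlist(best)]]
    }
  }
  data.frame(chrom = regions$chrom, start = regions$start, end = regions$end,
             feature = feature, gene_id = gene_id, cgi_overlap = cgi_overlap,
             repeat_class = repeat_class, stringsAsFactors = FALSE)
}

#' Chromatin-state (or any labeled annotation) enrichment by Fisher's test
#'
#' For every state label a 2x2 table of query vs background regions by
#' overlaps-state vs not is tested with a two-sided Fisher exact test; odds
#' ratios are the sample cross-product ratio and p values are BH-adjusted
#' across states.
#'
#' @param query,background Interval data frames (background non-empty).
#' @param states Labeled segments; the label is the `name` column.
#' @return `data.frame`: state, n_query, n_background, odds_ratio, p_value,
#'   adj_p.
#' @export
state_enrichment <- function(query, background, states) {
  if (!nrow(query)) stop("query region set is empty")
  if (!nrow(background)) stop("background region set is empty")
  qgr <- as_granges(query); bgr <- as_granges(background)
  labels <- sort(unique(states$name))
  rows <- lapply(labels, function(lab) {
    seg <- states[states$name == lab, , drop = FALSE]
    a <- sum(IRanges::overlapsAny(qgr, as_granges(seg)))
    b <- sum(IRanges::overlapsAny(bgr, as_granges(seg)))
    nq <- nrow(query); nb <- nrow(background)
    p <- stats::fisher.test(matrix(c(a, nq - a, b, nb - b), 2))$p.value
    or <- if ((a + b) == 0 || (nq - a) == 0 && b == 0) {
      NA_real_
    } else if ((nq - a) * b == 0) {
      Inf
    } else {
      (a * (nb - b)) / ((nq - a) * b)
    }
    data.frame(state = lab, n_query = a, n_background = b,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Fraction of repeat elements with 5hmC gain among those overlapping calls
#'
#' Each repeat element overlapping at least one differential 5hmC region is
#' labeled by the direction with the larger total overlap length; the output
#' is the gain fraction overall and per repeat class.
#'
#' @param dhmrs Region calls with a `direction` column (`gain`/`loss`).
#' @param repeats Repeat intervals with class labels in `name`.
#' @return List: `overall` (gain fraction), `n_elements`, `per_class`
#'   data.frame (class, n, gain_fraction).
#' @export
repeat_gain_fraction <- function(dhmrs, repeats) {
  if (!nrow(dhmrs) || !nrow(repeats)) {
    return(list(overall = NA_real_, n_elements = 0L,
                per_class = data.frame(class = character(), n = integer(),
                                       gain_fraction = numeric())))
  }
  rgr <- as_granges(repeats); cgr <- as_granges(dhmrs)
  hits <- GenomicRanges::findOverlaps(rgr, cgr)
  if (!length(hits)) {
    return(list(overall = NA_real_, n_elements = 0L,
                per_class = data.frame(class = character(), n = integer(),
                                       gain_fraction = numeric())))
  }
  ov <- IRanges::width(IRanges::pintersect(rgr[S4Vectors::queryHits(hits)],
                                           cgr[S4Vectors::subjectHits(hits)]))
  dir <- dhmrs$direction[S4Vectors::subjectHits(hits)]
  qh <- S4Vectors::queryHits(hits)
  gain_ov <- tapply(ov * (dir == "gain"), qh, sum)
  loss_ov <- tapply(ov * (dir == "loss"), qh, sum)
  elem <- as.integer(names(gain_ov))
  is_gain <- gain_ov >= loss_ov  # ties resolved toward gain (documented)
  cls <- repeats$name[elem]
  per_class <- do.call(rbind, lapply(sort(unique(cls)), function(k) {
    sel <- cls == k
    data.frame(class = k, n = sum(sel), gain_fraction = mean(is_gain[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  list(overall = mean(is_gain), n_elements = length(elem),
       per_class = per_class)
}

#' Cross-tabulate repeat-element 5hmC gain with expression change
#'
#' Elements with gain-of-5hmC calls are bucketed by expression log2 fold
#' change: `up` / `down` when `|log2FC| >= lfc_threshold` (sign decides),
#' `unchanged` otherwise, `unmeasured` when no expression value exists.
#'
#' @param element_ids Identifiers of gain-of-5hmC repeat elements.
#' @param expression `data.frame` with columns element_id, log2_fc.
#' @param lfc_threshold Changed-vs-unchanged threshold (default 0.15).
#' @return `data.frame`: category, n, fraction (fractions sum to 1).
#' @export
crosstab_repeat_expression <- function(element_ids, expression,
                                       lfc_threshold = 0.15) {
  lfc <- expression$log2_fc[match(element_ids, expression$element_id)]
  category <- ifelse(is.na(lfc), "unmeasured",
                     ifelse(lfc >= lfc_threshold, "up",
                            ifelse(lfc <= -lfc_threshold, "down",
                                   "unchanged")))
  cats <- c("up", "down", "unchanged", "unmeasured")
  n <- vapply(cats, function(k) sum(category == k), 0L)
  keep <- n > 0 | cats != "unmeasured"
  out <- data.frame(category = cats[keep], n = n[keep],
                    stringsAsFactors = FALSE)
  out$fraction <- if (sum(out$n)) out$n / sum(out$n) else 0
  rownames(out) <- NULL
  out
}
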