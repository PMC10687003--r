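#' Define a genome layout
#'
#' A genome layout fixes the chromosome names, their order and their lengths.
#' Every interval and bin in the pipeline is validated against a layout, and
#' all outputs are sorted in layout chromosome order.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Numeric vector of chromosome lengths in bp (>= 1),
#'   parallel to `chrom_names`.
#' @return An object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have equal length")
  }
  if (length(chrom_names) == 0L) stop("a layout needs at least one chromosome")
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths < 1)) {
    stop("chromosome lengths must be finite and >= 1")
  }
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Construct a validated interval table
#'
#' Intervals use 0-based half-open coordinates (`start` inclusive, `end`
#' exclusive) throughout the package; BED input/output needs no conversion.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` per interval.
#' @param name Optional label per interval.
#' @param layout Optional [genome_layout()]; when given, intervals are checked
#'   to lie within chromosome bounds.
#' @return A `data.frame` with columns chrom, start, end, strand, name.
#' @export
intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                      layout = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   name = rep_len(as.character(name), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df, layout)
  df
}

validate_intervals <- function(df, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  }
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(df$chrom), layout$chrom_names)
    if (length(unknown)) {
      stop("interval on chromosome not in layout: ", unknown[1])
    }
    over <- which(df$end > layout$chrom_lengths[df$chrom])
    if (length(over)) {
      stop("interval exceeds chromosome length at row ", over[1])
    }
  }
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (1-based closed) for overlap queries
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# width-1 GRanges at interval midpoints
midpoint_granges <- function(df) {
  mid <- floor((df$start + df$end) / 2)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = mid + 1L, width = 1L)
  )
}

sort_intervals <- function(df, layout) {
  ord <- order(match(df$chrom, layout$chrom_names), df$start, df$end)
  df[ord, , drop = FALSE]
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled with consecutive `[k*w, (k+1)*w)` bins; the
#' terminal bin is clipped to the chromosome length and flagged so that
#' downstream differential testing can exclude short tails.
#'
#' @param layout A [genome_layout()].
#' @param width Bin width in bp (>= 1); the pipeline default is 500.
#' @return A `data.frame` with columns chrom, start, end, clipped (logical:
#'   terminal bin shorter than `width`).
#' @examples
#' make_genome_bins(genome_layout("chr1", 1200), 500)
#' @export
make_genome_bins <- function(layout, width = 500) {
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  if (length(width) != 1L || !is.finite(width) || width < 1) {
    stop("width must be a single value >= 1")
  }
  width <- as.numeric(width)
  pieces <- lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    n <- ceiling(len / width)
    start <- (seq_len(n) - 1) * width
    end <- pmin(start + width, len)
    data.frame(chrom = ch, start = start, end = end,
               clipped = (end - start) < width,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Assign reads to genome bins by fragment midpoint
#'
#' Each read/fragment is assigned to the single bin containing its midpoint,
#' so every read contributes to exactly one bin and totals are conserved.
#' Reads on chromosomes absent from the layout are skipped with a warning.
#'
#' @param reads Named list (one element per sample) of interval data frames
#'   (chrom, start, end); names must match `samples$sample_id`.
#' @param bins Bin table from [make_genome_bins()] (uniform width).
#' @param layout The [genome_layout()] the bins were built from.
#' @param samples Sample sheet `data.frame` with columns sample_id, group
#'   (`"mock"`/`"treated"`) and optionally library_size; when library_size is
#'   absent the per-sample total read count is used.
#' @return A `bin_counts` object (see [bin_counts()]); the number of skipped
#'   reads per sample is attached as attribute `"skipped"`.
#' @export
count_reads_in_bins <- function(reads, bins, layout, samples) {
  stopifnot(is.list(reads), all(samples$sample_id %in% names(reads)))
  width <- max(bins$end - bins$start)
  # per-chromosome offsets into the bin table (bins are layout-ordered)
  nbin <- vapply(layout$chrom_names, function(ch) sum(bins$chrom == ch), 0)
  offset <- stats::setNames(cumsum(c(0, nbin[-length(nbin)])), layout$chrom_names)
  counts <- matrix(0L, nrow = nrow(bins), ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  skipped <- stats::setNames(integer(nrow(samples)), samples$sample_id)
  for (sid in samples$sample_id) {
    rd <- reads[[sid]]
    known <- rd$chrom %in% layout$chrom_names
    if (any(!known)) {
      skipped[sid] <- sum(!known)
      warning(sum(!known), " read(s) on unknown chromosome skipped for sample ",
              sid, call. = FALSE)
      rd <- rd[known, , drop = FALSE]
    }
    if (!nrow(rd)) next
    mid <- floor((rd$start + rd$end) / 2)
    idx <- offset[rd$chrom] + mid %/% width + 1
    tab <- tabulate(idx, nbins = nrow(bins))
    counts[, sid] <- tab
  }
  lib <- samples$library_size
  if (is.null(lib)) lib <- pmax(colSums(counts), 1)
  out <- bin_counts(bins, counts, samples$sample_id, samples$group, lib)
  attr(out, "skipped") <- skipped
  out
}

#' Bin-level count matrix container
#'
#' @param bins Bin interval table (chrom, start, end, optionally clipped).
#' @param counts Integer matrix, bins x samples.
#' @param sample_ids Character vector of sample names (columns of `counts`).
#' @param group Per-sample group label, `"mock"` or `"treated"`.
#' @param library_sizes Per-sample total mapped reads; must be >= the column
#'   sums of `counts`.
#' @return An object of class `bin_counts`.
#' @export
bin_counts <- function(bins, counts, sample_ids, group, library_sizes) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins)) stop("counts rows must match bins")
  if (ncol(counts) != length(sample_ids)) stop("counts columns must match sample_ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(group %in% c("mock", "treated"))) {
    stop("group labels must be 'mock' or 'treated'")
  }
  library_sizes <- as.numeric(library_sizes)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(library_sizes + 1e-8 < colSums(counts))) {
    stop("library sizes must be >= column sums of counts")
  }
  colnames(counts) <- sample_ids
  structure(
    list(bins = bins, counts = counts,
         sample_ids = as.character(sample_ids),
         group = as.character(group),
         library_sizes = stats::setNames(library_sizes, sample_ids)),
    class = "bin_counts"
  )
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("bin_counts:", nrow(x$counts), "bins x", ncol(x$counts), "samples (",
      sum(x$group == "mock"), "mock /", sum(x$group == "treated"), "treated )\n")
  invisible(x)
}
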