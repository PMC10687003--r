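#' Read a BED3/BED6 file
#'
#' BED coordinates are 0-based half-open, matching the package's internal
#' convention, so no conversion takes place.
#'
#' @param path Path to a BED file.
#' @param layout Optional [genome_layout()] to validate coordinates against.
#' @return Interval `data.frame` (chrom, start, end, strand, name, score);
#'   strand is `"."` and name `NA` when the file is BED3.
#' @export
read_bed <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), NA)
  ))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   ".")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": need 0 <= start < end")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   name = name, score = score, stringsAsFactors = FALSE)
  validate_intervals(df, layout)
  df
}

#' Write intervals as BED
#'
#' @param df Interval `data.frame`; extra numeric columns listed in `extra`
#'   are appended after the canonical six.
#' @param path Output path.
#' @param extra Character vector of additional column names to append.
#' @export
write_bed <- function(df, path, extra = character()) {
  name <- if ("name" %in% names(df)) ifelse(is.na(df$name), ".", df$name) else "."
  score <- if ("score" %in% names(df)) ifelse(is.na(df$score), 0, df$score) else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$chrom, format_num(df$start), format_num(df$end),
                    name, score, strand, stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- format_num(df[[col]])
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), path)
  invisible(path)
}

format_num <- function(x) {
  if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE, digits = 15) else x
}

#' Write a table as deterministic TSV
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input path.
#' @return data.frame
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read a sample sheet
#'
#' The sample sheet (TSV: sample_id, group, library_size) is the single source
#' of group labels for count matrices and site tables.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns sample_id, group, library_size.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  if (!all(df$group %in% c("mock", "treated"))) {
    stop("sample sheet group must be 'mock' or 'treated'")
  }
  df
}

#' Per-CpG methylation count container
#'
#' @param chrom,pos Site coordinates (0-based bp), sorted within chromosome.
#' @param meth,total Integer matrices, sites x samples, with
#'   `meth <= total` elementwise.
#' @param sample_ids,group As in [bin_counts()].
#' @return Object of class `cpg_site_table`.
#' @export
cpg_site_table <- function(chrom, pos, meth, total, sample_ids, group) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (!all(dim(meth) == dim(total))) stop("meth/total dimensions differ")
  if (nrow(meth) != length(pos)) stop("matrix rows must match site count")
  if (any(meth > total)) stop("meth count exceeds total at some site")
  if (any(meth < 0) || any(total < 0)) stop("counts must be non-negative")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) stop("duplicate CpG site: ", key[duplicated(key)][1])
  ord <- order(chrom, pos)
  if (!all(group %in% c("mock", "treated"))) {
    stop("group labels must be 'mock' or 'treated'")
  }
  colnames(meth) <- sample_ids; colnames(total) <- sample_ids
  structure(
    list(chrom = as.character(chrom)[ord], pos = as.numeric(pos)[ord],
         meth = meth[ord, , drop = FALSE], total = total[ord, , drop = FALSE],
         sample_ids = as.character(sample_ids), group = as.character(group)),
    class = "cpg_site_table"
  )
}

#' @export
print.cpg_site_table <- function(x, ...) {
  cat("cpg_site_table:", length(x$pos), "sites x", length(x$sample_ids),
      "samples\n")
  invisible(x)
}

#' Read a per-CpG site table
#'
#' Expected format: TSV with columns `chrom`, `pos`, then one
#' `<sample>.meth` / `<sample>.total` pair per sample.
#'
#' @param path Path to the TSV.
#' @param samples Sample sheet data frame supplying group labels.
#' @return A [cpg_site_table()].
#' @export
read_site_table <- function(path, samples) {
  df <- read_tsv(path)
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  ids <- samples$sample_id
  mcols <- paste0(ids, ".meth"); tcols <- paste0(ids, ".total")
  missing <- setdiff(c(mcols, tcols), names(df))
  if (length(missing)) stop("site table lacks column(s): ",
                            paste(missing, collapse = ", "))
  cpg_site_table(df$chrom, df$pos,
                 as.matrix(df[mcols]), as.matrix(df[tcols]),
                 ids, samples$group)
}

#' Write a per-CpG site table
#' @param x A [cpg_site_table()].
#' @param path Output path.
#' @export
write_site_table <- function(x, path) {
  out <- data.frame(chrom = x$chrom, pos = x$pos, stringsAsFactors = FALSE)
  for (sid in x$sample_ids) {
    out[[paste0(sid, ".meth")]] <- x$meth[, sid]
    out[[paste0(sid, ".total")]] <- x$total[, sid]
  }
  write_tsv(out, path)
}

#' Read a gene model table
#'
#' TSV with columns gene_id, chrom, start, end, strand, is_ieg and optional
#' comma-separated exon_starts/exon_ends columns.
#'
#' @param path Path to the TSV.
#' @param layout Optional layout for validation.
#' @return data.frame of gene models; exons are parsed into list columns.
#' @export
read_gene_table <- function(path, layout = NULL) {
  df <- read_tsv(path)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (is.null(df$is_ieg)) df$is_ieg <- FALSE
  df$is_ieg <- as.logical(df$is_ieg)
  validate_intervals(df, layout)
  if (all(c("exon_starts", "exon_ends") %in% names(df))) {
    df$exon_starts <- lapply(strsplit(as.character(df$exon_starts), ","),
                             as.numeric)
    df$exon_ends <- lapply(strsplit(as.character(df$exon_ends), ","),
                           as.numeric)
    for (i in seq_len(nrow(df))) {
      es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
      if (any(es < df$start[i]) || any(ee > df$end[i])) {
        stop("exon outside gene body for ", df$gene_id[i])
      }
    }
  }
  df
}

#' Write a gene model table
#' @param genes Gene model data frame (list-column exons collapsed to
#'   comma-separated text).
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  if (is.list(out$exon_starts)) {
    out$exon_starts <- vapply(out$exon_starts, paste, "", collapse = ",")
    out$exon_ends <- vapply(out$exon_ends, paste, "", collapse = ",")
  }
  write_tsv(out, path)
}

#' Read a gene-level expression table
#'
#' @param path TSV with columns gene_id, base_mean, log2_fc, p_value, fdr.
#' @return data.frame
#' @export
read_expression_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "base_mean", "log2_fc", "p_value", "fdr")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("expression table lacks: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  df
}

#' Read a plain-text gene list (one id per line)
#' @param path Input path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
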