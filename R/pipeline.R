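#' Read a binned count matrix from a fixture TSV
#'
#' @param path TSV with columns chrom, start, end, optionally clipped, then
#'   one count column per sample.
#' @param samples Sample sheet data frame.
#' @return A [bin_counts()] object.
#' @export
read_bin_counts <- function(path, samples) {
  df <- read_tsv(path)
  bin_cols <- intersect(c("chrom", "start", "end", "clipped"), names(df))
  missing <- setdiff(samples$sample_id, names(df))
  if (length(missing)) stop("count table lacks sample column(s): ",
                            paste(missing, collapse = ", "))
  bin_counts(df[bin_cols], as.matrix(df[samples$sample_id]),
             samples$sample_id, samples$group, samples$library_size)
}

#' Default pipeline parameters
#'
#' Every threshold defaults to the analysis' standard value: 500 bp bins,
#' region FDR 0.05, DMR merge gap 100 bp, at least 6 DM CpGs with
#' |mean diff| > 0.2, bulk DEG thresholds base mean 150 and log2FC 0.15,
#' single-cell downsampling to 50 cells x 10 repetitions, neuronal fraction
#' 0.28.
#'
#' @param ... Named overrides.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(bin_width = 500, fdr_threshold = 0.05, merge_adjacent = TRUE,
            site_alpha = 0.05, merge_gap = 100, min_dm_sites = 6,
            min_mean_diff = 0.2, sign_consistency = 0.8, min_total = 10,
            min_base_mean = 150, lfc_threshold = 0.15, region_alpha = 0.05,
            use_adjusted = FALSE, burden_n = 50, burden_reps = 10,
            burden_fdr = 0.01, f_neuron = 0.28, meta_points = 40)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Run the full analysis on a fixture directory
#'
#' Executes the seven stages in dependency order — differential 5hmC calling,
#' global density statistics, DMR calling, annotation and enrichment,
#' concordance integration, IEG region statistics, and single-cell DEG
#' burden — writing deterministic TSV artifacts and a JSON run manifest
#' (parameters, seed, input checksums, per-stage record counts) to `out_dir`.
#'
#' @param fixture_dir Directory produced by [simulate_fixture()] (or
#'   hand-assembled with the same file contract).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the stochastic stages (burden downsampling).
#' @param params A [pipeline_params()] list.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(fixture_dir, out_dir, seed = 1,
                         params = pipeline_params()) {
  fp <- function(x) {
    path <- file.path(fixture_dir, x)
    if (!file.exists(path)) stop("input file not found: ", path)
    path
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(x) file.path(out_dir, x)
  inputs <- c("layout.tsv", "samples.tsv", "hmc_counts.tsv", "genes.tsv",
              "cgi.bed", "repeats.bed", "states.bed", "sites.tsv",
              "expression.tsv", "cells.tsv", "cells_meta.tsv",
              "ieg_profiles.tsv", "disease_genes.txt")
  checksums <- lapply(inputs, function(x) unname(tools::md5sum(fp(x))))
  names(checksums) <- inputs

  lay_df <- read_tsv(fp("layout.tsv"))
  layout <- genome_layout(lay_df$chrom, lay_df$length)
  samples <- read_sample_sheet(fp("samples.tsv"))
  genes <- read_gene_table(fp("genes.tsv"), layout)
  cgi <- read_bed(fp("cgi.bed"), layout)
  repeats <- read_bed(fp("repeats.bed"), layout)
  states <- read_bed(fp("states.bed"), layout)
  stages <- list()

  ## stage 1: differential 5hmC
  m <- read_bin_counts(fp("hmc_counts.tsv"), samples)
  testable <- if ("clipped" %in% names(m$bins)) {
    (m$bins$end - m$bins$start) >= params$bin_width / 2
  } else rep(TRUE, nrow(m$bins))
  mt <- bin_counts(m$bins[testable, , drop = FALSE],
                   m$counts[testable, , drop = FALSE],
                   m$sample_ids, m$group, m$library_sizes)
  disp <- estimate_common_dispersion(mt)
  bin_res <- bin_exact_test(mt, disp)
  dhmrs <- call_dhmrs(bin_res, params$fdr_threshold, params$merge_adjacent)
  bin_res$fdr <- stats::p.adjust(bin_res$p_value, "BH")
  write_tsv(bin_res, op("dhmr_bins.tsv"))
  write_tsv(dhmrs, op("dhmr_regions.tsv"))
  if (nrow(dhmrs)) {
    write_bed(transform(dhmrs, name = direction, score = n_bins),
              op("dhmr_regions.bed"), extra = c("log_fc", "p_value", "fdr"))
  }
  stages$dhmr <- list(n_bins_tested = nrow(bin_res), n_regions = nrow(dhmrs),
                      common_dispersion = disp$common_dispersion)

  ## stage 2: global density statistics
  nd <- normalize_cpm(m)
  reg <- global_regression(nd)
  body_regions <- genes[, c("chrom", "start", "end", "strand")]
  prof <- meta_profile(nd, body_regions, layout, params$meta_points)
  write_tsv(data.frame(statistic = c("slope", "intercept", "pearson_r",
                                     "p_value", "gene_body_fold_change",
                                     "gene_body_p"),
                       value = c(reg$slope, reg$intercept, reg$pearson_r,
                                 reg$p_value, prof$fold_change,
                                 prof$p_value)),
            op("global_stats.tsv"))
  write_tsv(data.frame(position = seq_len(nrow(prof$profile)),
                       mock = prof$profile[, "mock"],
                       treated = prof$profile[, "treated"]),
            op("gene_body_profile.tsv"))
  stages$global <- list(slope = reg$slope, pearson_r = reg$pearson_r)

  ## stage 3: DMR calling
  sites <- read_site_table(fp("sites.tsv"), samples)
  dmr_out <- call_dmrs(sites, params$min_total, params$site_alpha,
                       params$merge_gap, params$min_dm_sites,
                       params$min_mean_diff, params$sign_consistency)
  write_tsv(dmr_out$sites, op("dmr_sites.tsv"))
  write_tsv(dmr_out$dmrs, op("dmrs.tsv"))
  stages$dmr <- list(n_sites_tested = nrow(dmr_out$sites),
                     n_candidates = nrow(dmr_out$candidates),
                     n_dmrs = nrow(dmr_out$dmrs))

  ## stage 4: annotation and enrichment
  ann <- annotate_regions(dhmrs, genes, cgi, repeats)
  write_tsv(ann, op("dhmr_annotation.tsv"))
  cand_bg <- dmr_out$candidates[, c("chrom", "start", "end"), drop = FALSE]
  enr <- if (nrow(dmr_out$dmrs) && nrow(cand_bg)) {
    state_enrichment(dmr_out$dmrs, cand_bg, states)
  } else NULL
  if (!is.null(enr)) write_tsv(enr, op("dmr_state_enrichment.tsv"))
  rgf <- repeat_gain_fraction(dhmrs, repeats)
  write_tsv(data.frame(class = c(rgf$per_class$class, "overall"),
                       n = c(rgf$per_class$n, rgf$n_elements),
                       gain_fraction = c(rgf$per_class$gain_fraction,
                                         rgf$overall)),
            op("repeat_gain_fraction.tsv"))
  stages$annotate <- list(n_annotated = nrow(ann),
                          n_states_tested = if (is.null(enr)) 0L else nrow(enr))

  ## stage 5: concordance integration
  expr <- read_expression_table(fp("expression.tsv"))
  asg <- assign_regions_to_genes(dhmrs, genes)
  conc_h <- classify_concordance(expr, asg$assignments, "5hmC",
                                 params$region_alpha, params$use_adjusted)
  asg_m <- assign_regions_to_genes(dmr_out$dmrs, genes)
  conc_m <- classify_concordance(expr, asg_m$assignments, "5mC",
                                 deg_sets = select_degs(expr,
                                                        params$min_base_mean,
                                                        params$lfc_threshold))
  sets <- list(gain_activated = conc_h$gain_activated,
               loss_repressed = conc_h$loss_repressed,
               hyper_down = conc_m$hyper_down,
               hypo_up = conc_m$hypo_up)
  conc_df <- do.call(rbind, lapply(names(sets), function(nm) {
    data.frame(set = rep(nm, length(sets[[nm]])), gene_id = sets[[nm]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(conc_df, op("concordance_sets.tsv"))
  disease <- read_gene_list(fp("disease_genes.txt"))
  universe <- expr$gene_id
  ov <- geneset_overlap_binomial(conc_h$gain_activated,
                                 intersect(disease, universe), universe)
  write_tsv(data.frame(query = "gain_activated", n = ov$n, m = ov$m,
                       N = ov$N, k = ov$k, p_binomial = ov$p_binomial),
            op("disease_overlap.tsv"))
  stages$integrate <- list(n_gain_activated = length(conc_h$gain_activated),
                           n_loss_repressed = length(conc_h$loss_repressed),
                           n_hyper_down = length(conc_m$hyper_down),
                           n_hypo_up = length(conc_m$hypo_up))

  ## stage 6: IEG region statistics
  prof50 <- read_tsv(fp("ieg_profiles.tsv"))
  ieg_tests <- ieg_region_tests(prof50)
  write_tsv(ieg_tests, op("ieg_region_tests.tsv"))
  agg <- stats::aggregate(cbind(mean_treated, mean_mock) ~ gene_id + context,
                          data = ieg_tests, FUN = mean)
  lfc_of <- function(ctx) {
    sub <- agg[agg$context == ctx, ]
    stats::setNames(log2((sub$mean_treated + 0.01) / (sub$mean_mock + 0.01)),
                    sub$gene_id)
  }
  hmc_lfc <- lfc_of("body")
  mec_lfc <- lfc_of("promoter")
  gids <- names(hmc_lfc)
  per_gene <- data.frame(
    gene_id = gids,
    is_ieg = genes$is_ieg[match(gids, genes$gene_id)],
    expr_log2fc = expr$log2_fc[match(gids, expr$gene_id)],
    hmc_log2fc = unname(hmc_lfc),
    mec_log2fc = unname(mec_lfc[gids]), stringsAsFactors = FALSE)
  ieg_sum <- ieg_summary(per_gene)
  write_tsv(per_gene, op("ieg_summary.tsv"))
  write_tsv(ieg_sum$ieg, op("ieg_correlations.tsv"))
  stages$ieg <- list(n_genes = nrow(per_gene),
                     n_regions_tested = nrow(ieg_tests))

  ## stage 7: single-cell DEG burden
  cells_df <- read_tsv(fp("cells.tsv"))
  meta <- read_tsv(fp("cells_meta.tsv"))
  cm <- as.matrix(cells_df[, setdiff(names(cells_df), "cell"), drop = FALSE])
  rownames(cm) <- cells_df$cell
  cm <- cm[meta$cell, , drop = FALSE]
  bur <- burden_analysis(cm, meta, params$burden_n, params$burden_reps,
                         seed, params$lfc_threshold, params$burden_fdr)
  write_tsv(cbind(data.frame(cluster = rownames(bur$counts)),
                  as.data.frame(bur$counts),
                  mean = unname(bur$mean), se = unname(bur$se)),
            op("burden.tsv"))
  write_tsv(cbind(data.frame(cluster = rownames(bur$pairwise_p)),
                  as.data.frame(bur$pairwise_p)),
            op("burden_pairwise_p.tsv"))
  stages$burden <- list(n_clusters = nrow(bur$counts),
                        mean_burden = unname(bur$mean))

  manifest <- list(package = "epiremodel",
                   version = as.character(utils::packageVersion("epiremodel")),
                   seed = seed, parameters = params,
                   input_checksums = checksums, stages = stages)
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
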