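#' Generator settings for the synthetic study
#'
#' Defaults emulate the study design at desk scale: a 2 x 5 Mb toy genome
#' binned at 500 bp, 3 + 3 replicates, 50 gain and 50 loss planted 5hmC
#' regions at 3-fold effect, 20 hyper and 20 hypo planted DMRs with a 0.3
#' methylation shift over 10 CpGs each, expression changes stochastically
#' concordant with the planted epigenetic changes, and three single-cell
#' clusters with planted DEG burdens.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of generator settings.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chrA = 5e6, chrB = 5e6),
    bin_width = 500,
    n_genes = 300, frac_ieg = 0.05,
    n_cgi = 80, n_repeats = 400,
    state_labels = c("Tss", "Enh", "Tx", "ReprPC", "Quies"),
    mean_state_length = 2e4,
    # planted differential 5hmC regions (bin-aligned)
    n_gain = 50, n_loss = 50, region_bins = 4, fold = 3,
    # planted DMRs (site-defined)
    n_hyper = 20, n_hypo = 20, sites_per_dmr = 10, site_spacing = c(20, 50),
    delta = 0.3, n_bg_sites = 2000,
    hyper_base = 0.3, hypo_base = 0.7,
    # expression concordance
    concordant_frac = 0.8, deg_lfc = 1,
    # single-cell clusters
    clusters = data.frame(
      cluster = c("Ex1", "In1", "Astro"),
      neuronal = c(TRUE, TRUE, FALSE),
      n_per_group = c(150, 150, 150),
      n_deg = c(40, 20, 5),
      stringsAsFactors = FALSE),
    n_cell_genes = 800, cell_base = 1, cell_deg_base = 3,
    cell_deg_lfc = 1, cell_dispersion = 0.3,
    # IEG fine-scale profiles
    ieg_hmc_lfc_range = c(0.3, 1.5), ieg_mec_ratio = -0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Simulate the planted ground truth for one synthetic study
#'
#' Deterministic for a fixed (config, seed): builds the toy genome layout,
#' gene models (with exons and IEG flags), CpG-island / repeat /
#' chromatin-state annotations, the planted differential 5hmC regions and
#' DMRs, the planted expression effects (concordant with gene-body 5hmC
#' changes at the configured rate), IEG-specific effect sizes, and the
#' single-cell cluster specification.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return Object of class `synthetic_truth`.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  with_seed(child_seed(seed, 1), simulate_truth_impl(config))
}

simulate_truth_impl <- function(cfg) {
  layout <- genome_layout(names(cfg$chrom_lengths), cfg$chrom_lengths)
  w <- cfg$bin_width

  ## gene models: sequential placement with random gaps, round-robin chroms
  n_ieg <- ceiling(cfg$n_genes * cfg$frac_ieg)
  is_ieg <- sample(rep(c(TRUE, FALSE),
                       c(n_ieg, cfg$n_genes - n_ieg)))
  cursors <- stats::setNames(rep(4000, length(layout$chrom_names)),
                             layout$chrom_names)
  genes <- vector("list", cfg$n_genes)
  ch_i <- 0L
  for (g in seq_len(cfg$n_genes)) {
    placed <- FALSE
    for (try in seq_along(layout$chrom_names)) {
      ch_i <- ch_i %% length(layout$chrom_names) + 1L
      ch <- layout$chrom_names[ch_i]
      gap <- stats::runif(1, 2000, 18000)
      len <- if (is_ieg[g]) stats::runif(1, 1000, 3000) else
        stats::runif(1, 2000, 20000)
      start <- round(cursors[ch] + gap)
      end <- round(start + len)
      if (end + 4000 <= layout$chrom_lengths[[ch]]) {
        genes[[g]] <- data.frame(gene_id = sprintf("gene%03d", g), chrom = ch,
                                 start = start, end = end,
                                 strand = sample(c("+", "-"), 1),
                                 is_ieg = is_ieg[g], stringsAsFactors = FALSE)
        cursors[ch] <- end
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("gene models exceed the genome; reduce n_genes")
  }
  genes <- do.call(rbind, genes)
  # exons: alternate segments of a random partition of the gene body
  ex <- lapply(seq_len(nrow(genes)), function(i) {
    len <- genes$end[i] - genes$start[i]
    k <- sample(2:5, 1)
    cuts <- sort(stats::runif(2 * k - 1, 0.02, 0.98)) * len
    bounds <- round(c(0, cuts, len)) + genes$start[i]
    odd <- seq(1, 2 * k, by = 2)
    list(starts = bounds[odd], ends = bounds[odd + 1])
  })
  genes$exon_starts <- lapply(ex, `[[`, "starts")
  genes$exon_ends <- lapply(ex, `[[`, "ends")

  ## CpG islands: most at promoters, a few random
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  prom_idx <- sample(nrow(genes), min(cfg$n_cgi * 3 %/% 4, nrow(genes)))
  cgi <- data.frame(chrom = genes$chrom[prom_idx],
                    start = pmax(0, tss[prom_idx] - 500),
                    end = tss[prom_idx] + 500, stringsAsFactors = FALSE)
  n_rand <- cfg$n_cgi - nrow(cgi)
  if (n_rand > 0) {
    rc <- sample(layout$chrom_names, n_rand, replace = TRUE)
    rs <- round(stats::runif(n_rand, 0, layout$chrom_lengths[rc] - 1200))
    cgi <- rbind(cgi, data.frame(chrom = rc, start = rs, end = rs + 1000))
  }
  cgi$strand <- "."; cgi$name <- sprintf("CGI%03d", seq_len(nrow(cgi)))
  cgi <- sort_intervals(cgi, layout)

  ## repeats
  rc <- sample(layout$chrom_names, cfg$n_repeats, replace = TRUE)
  rlen <- round(stats::runif(cfg$n_repeats, 150, 600))
  rs <- round(stats::runif(cfg$n_repeats, 0,
                           layout$chrom_lengths[rc] - rlen - 1))
  repeats <- data.frame(
    chrom = rc, start = rs, end = rs + rlen, strand = ".",
    name = sample(c("SINE", "LINE", "LTR", "DNA", "other"), cfg$n_repeats,
                  replace = TRUE, prob = c(0.35, 0.3, 0.15, 0.1, 0.1)),
    stringsAsFactors = FALSE)
  repeats <- sort_intervals(repeats, layout)

  ## chromatin states: labeled segments tiling each chromosome
  states <- do.call(rbind, lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    seg_len <- round(stats::rexp(ceiling(3 * len / cfg$mean_state_length),
                                 1 / cfg$mean_state_length)) + 1000
    bounds <- pmin(cumsum(seg_len), len)
    bounds <- unique(c(0, bounds[bounds > 0], len))
    data.frame(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
               strand = ".",
               name = sample(cfg$state_labels, length(bounds) - 1,
                             replace = TRUE), stringsAsFactors = FALSE)
  }))
  rownames(states) <- NULL

  ## planted differential 5hmC regions: disjoint bin-aligned slots
  bins <- make_genome_bins(layout, w)
  full <- !bins$clipped
  slot_size <- cfg$region_bins
  slot_starts <- which(full & (seq_len(nrow(bins)) %% slot_size == 1))
  slot_ok <- vapply(slot_starts, function(i) {
    j <- i + slot_size - 1
    j <= nrow(bins) && bins$chrom[j] == bins$chrom[i] && all(full[i:j])
  }, TRUE)
  slot_starts <- slot_starts[slot_ok]
  n_regions <- cfg$n_gain + cfg$n_loss
  if (n_regions > length(slot_starts)) {
    stop("planted 5hmC regions exceed the genome; reduce counts or sizes")
  }
  if (n_regions > 0) {
    chosen <- sort(sample(slot_starts, n_regions))
    dirs <- sample(rep(c("gain", "loss"), c(cfg$n_gain, cfg$n_loss)))
    planted_dhmrs <- data.frame(
      chrom = bins$chrom[chosen], start = bins$start[chosen],
      end = bins$end[chosen + slot_size - 1], direction = dirs,
      fold = cfg$fold, stringsAsFactors = FALSE)
  } else {
    planted_dhmrs <- data.frame(chrom = character(), start = numeric(),
                                end = numeric(), direction = character(),
                                fold = numeric(), stringsAsFactors = FALSE)
  }

  ## planted DMRs: site-defined clusters kept clear of one another; half
  ## are anchored inside gene bodies so methylation-expression concordance
  ## has substance to recover
  n_dmr <- cfg$n_hyper + cfg$n_hypo
  dmr_dirs <- sample(rep(c("hyper", "hypo"), c(cfg$n_hyper, cfg$n_hypo)))
  approx_len <- cfg$sites_per_dmr * mean(cfg$site_spacing)
  anchors <- list()
  guard <- 5000
  for (d in seq_len(n_dmr)) {
    ok <- FALSE
    in_gene <- d %% 2 == 0
    for (try in 1:200) {
      if (in_gene) {
        gi <- sample(nrow(genes), 1)
        if (genes$end[gi] - genes$start[gi] < approx_len * 2) next
        ch <- genes$chrom[gi]
        a <- round(stats::runif(1, genes$start[gi],
                                genes$end[gi] - approx_len))
      } else {
        ch <- sample(layout$chrom_names, 1)
        a <- round(stats::runif(1, 0,
                                layout$chrom_lengths[[ch]] - approx_len * 2))
      }
      clash <- any(vapply(anchors, function(x) {
        x$chrom == ch && abs(x$pos - a) < approx_len + guard
      }, TRUE))
      if (!clash) { anchors[[d]] <- list(chrom = ch, pos = a); ok <- TRUE; break }
    }
    if (!ok) stop("planted DMRs exceed the genome; reduce counts")
  }
  if (n_dmr > 0) {
    planted_dmrs <- do.call(rbind, lapply(seq_len(n_dmr), function(d) {
      gaps <- sample(cfg$site_spacing[1]:cfg$site_spacing[2],
                     cfg$sites_per_dmr - 1, replace = TRUE)
      pos <- anchors[[d]]$pos + c(0, cumsum(gaps))
      base <- if (dmr_dirs[d] == "hyper") cfg$hyper_base else cfg$hypo_base
      shift <- if (dmr_dirs[d] == "hyper") cfg$delta else -cfg$delta
      data.frame(chrom = anchors[[d]]$chrom, start = min(pos),
                 end = max(pos) + 1,
                 direction = dmr_dirs[d], base_level = base, delta = shift,
                 sites = I(list(pos)), stringsAsFactors = FALSE)
    }))
    rownames(planted_dmrs) <- NULL
  } else {
    planted_dmrs <- data.frame(chrom = character(), start = numeric(),
                               end = numeric(), direction = character(),
                               base_level = numeric(), delta = numeric(),
                               stringsAsFactors = FALSE)
    planted_dmrs$sites <- list()
  }

  ## expression truth: genes whose bodies carry planted 5hmC regions are
  ## concordant with the configured probability
  hit <- GenomicRanges::findOverlaps(as_granges(genes),
                                     as_granges(planted_dhmrs))
  gi <- S4Vectors::queryHits(hit); ri <- S4Vectors::subjectHits(hit)
  first <- !duplicated(gi)
  deg <- data.frame(gene_id = genes$gene_id[gi[first]],
                    direction = planted_dhmrs$direction[ri[first]],
                    stringsAsFactors = FALSE)
  concordant <- stats::runif(nrow(deg)) < cfg$concordant_frac
  deg$true_log2fc <- ifelse(concordant,
                            ifelse(deg$direction == "gain", 1, -1) * cfg$deg_lfc,
                            0)
  planted_degs <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  planted_degs[deg$gene_id] <- deg$true_log2fc

  ## genes carrying a planted DMR in the body: concordant expression
  ## (hyper -> down, hypo -> up); genes already touched by a planted 5hmC
  ## region keep their 5hmC-driven effect
  hit_m <- GenomicRanges::findOverlaps(as_granges(genes),
                                       as_granges(planted_dmrs))
  gm <- S4Vectors::queryHits(hit_m); rm_ <- S4Vectors::subjectHits(hit_m)
  fm <- !duplicated(gm)
  dmr_genes <- genes$gene_id[gm[fm]]
  dmr_dir <- planted_dmrs$direction[rm_[fm]]
  free <- !(dmr_genes %in% deg$gene_id)
  conc_m <- stats::runif(length(dmr_genes)) < cfg$concordant_frac
  planted_degs[dmr_genes[free & conc_m]] <-
    ifelse(dmr_dir[free & conc_m] == "hyper", -1, 1) * cfg$deg_lfc

  ## IEG truth: per-IEG 5hmC gain in the body, 5mC loss at the promoter,
  ## expression change proportional to the 5hmC change
  ieg_ids <- genes$gene_id[genes$is_ieg]
  ieg_truth <- data.frame(
    gene_id = ieg_ids,
    hmc_log2fc = stats::runif(length(ieg_ids), cfg$ieg_hmc_lfc_range[1],
                              cfg$ieg_hmc_lfc_range[2]),
    stringsAsFactors = FALSE)
  ieg_truth$mec_log2fc <- cfg$ieg_mec_ratio * ieg_truth$hmc_log2fc
  ieg_truth$expr_log2fc <- 0.8 * ieg_truth$hmc_log2fc
  planted_degs[ieg_truth$gene_id] <- ieg_truth$expr_log2fc

  ## single-cell spec: modeled genes padded with background transcriptome
  ## ids so planted DEGs stay a small fraction of the library
  cell_genes <- genes$gene_id[seq_len(min(cfg$n_cell_genes, nrow(genes)))]
  if (cfg$n_cell_genes > length(cell_genes)) {
    cell_genes <- c(cell_genes,
                    sprintf("scg%04d",
                            seq_len(cfg$n_cell_genes - length(cell_genes))))
  }
  cl <- cfg$clusters
  if (any(cl$n_per_group < 50)) {
    warning("cluster(s) smaller than the 50-cell downsample size")
  }
  cell_degs <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    if (cl$n_deg[i] == 0) return(NULL)
    data.frame(cluster = cl$cluster[i],
               gene_id = sample(cell_genes, cl$n_deg[i]),
               log2fc = cfg$cell_deg_lfc, stringsAsFactors = FALSE)
  }))

  structure(
    list(config = cfg, layout = layout, genes = genes, cgi = cgi,
         repeats = repeats, chrom_states = states,
         planted_dhmrs = planted_dhmrs, planted_dmrs = planted_dmrs,
         planted_degs = planted_degs, ieg_truth = ieg_truth,
         cluster_spec = cl, cell_genes = cell_genes, cell_degs = cell_degs),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$layout$chrom_names), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$planted_dhmrs), "planted 5hmC regions,",
      nrow(x$planted_dmrs), "planted DMRs\n")
  invisible(x)
}

#' Planted 5hmC status of each genome bin
#'
#' @param truth A [simulate_truth()] object.
#' @param bins Bin table from [make_genome_bins()].
#' @return Character vector per bin: `"gain"`, `"loss"` or `"none"`.
#' @export
planted_bin_status <- function(truth, bins) {
  status <- rep("none", nrow(bins))
  hits <- GenomicRanges::findOverlaps(as_granges(bins),
                                      as_granges(truth$planted_dhmrs))
  status[S4Vectors::queryHits(hits)] <-
    truth$planted_dhmrs$direction[S4Vectors::subjectHits(hits)]
  status
}

#' Simulate binned 5hmC enrichment counts
#'
#' Per-bin baseline intensities are gamma-distributed; counts are negative
#' binomial with a common dispersion (Poisson when `dispersion = 0`) around
#' `intensity x sample depth`, with treated-group means multiplied by the
#' planted fold in gain regions and divided by it in loss regions. Library
#' sizes are set to the column sums (every simulated fragment falls in a
#' counted bin).
#'
#' @param truth A [simulate_truth()] object.
#' @param n_per_group Replicates per group (default 3, >= 2).
#' @param depth Expected reads per sample (default 1e6).
#' @param dispersion Common NB dispersion (default 0.05; >= 0).
#' @param seed Integer seed.
#' @return A [bin_counts()] object.
#' @export
simulate_5hmc_counts <- function(truth, n_per_group = 3, depth = 1e6,
                                 dispersion = 0.05, seed = 1) {
  if (n_per_group < 2) stop("need n_per_group >= 2")
  if (dispersion < 0) stop("dispersion must be >= 0")
  with_seed(child_seed(seed, 2), {
    bins <- make_genome_bins(truth$layout, truth$config$bin_width)
    nb <- nrow(bins)
    wts <- stats::rgamma(nb, shape = 5, rate = 5)
    wts <- wts / sum(wts)
    status <- planted_bin_status(truth, bins)
    fold <- truth$config$fold
    eff <- ifelse(status == "gain", fold, ifelse(status == "loss", 1 / fold, 1))
    ids <- c(paste0("mock_", seq_len(n_per_group)),
             paste0("treated_", seq_len(n_per_group)))
    grp <- rep(c("mock", "treated"), each = n_per_group)
    depth_j <- depth * stats::runif(length(ids), 0.9, 1.1)
    counts <- matrix(0L, nb, length(ids))
    for (j in seq_along(ids)) {
      mu <- wts * depth_j[j] * (if (grp[j] == "treated") eff else 1)
      counts[, j] <- if (dispersion == 0) stats::rpois(nb, mu) else
        stats::rnbinom(nb, mu = mu, size = 1 / dispersion)
    }
    bin_counts(bins, counts, ids, grp, colSums(counts))
  })
}

#' Simulate per-CpG methylation counts
#'
#' Sites comprise the planted DMR site clusters plus scattered background
#' CpGs. Baseline levels sit near 0.7 outside CpG islands and 0.1 inside;
#' planted regions use their configured base level, shifted by +/- delta in
#' the treated group (clipped to keep levels in (0, 1)). Per-sample totals
#' are Poisson around `coverage` and methylated counts are beta-binomial
#' with the given concentration (`precision = Inf` gives plain binomial).
#'
#' @param truth A [simulate_truth()] object.
#' @param n_per_group Samples per group (default 3).
#' @param coverage Mean reads per site per sample (default 30, >= 1).
#' @param precision Beta-binomial concentration (default 100, i.e. an
#'   intra-class correlation of about 1% between biological replicates;
#'   `Inf` gives plain binomial counts).
#' @param seed Integer seed.
#' @return A [cpg_site_table()].
#' @export
simulate_methylation <- function(truth, n_per_group = 3, coverage = 30,
                                 precision = 100, seed = 1) {
  if (coverage < 1) stop("coverage must be >= 1")
  with_seed(child_seed(seed, 3), {
    cfg <- truth$config
    pl <- truth$planted_dmrs
    site_chrom <- rep(pl$chrom, lengths(pl$sites))
    site_pos <- unlist(pl$sites)
    base <- rep(pl$base_level, lengths(pl$sites))
    shift <- rep(pl$delta, lengths(pl$sites))
    # background sites clear of planted regions
    bg_ch <- sample(truth$layout$chrom_names, cfg$n_bg_sites, replace = TRUE)
    bg_pos <- round(stats::runif(cfg$n_bg_sites, 0,
                                 truth$layout$chrom_lengths[bg_ch] - 1))
    bg <- data.frame(chrom = bg_ch, start = bg_pos, end = bg_pos + 1)
    in_planted <- IRanges::overlapsAny(as_granges(bg), as_granges(pl))
    bg <- bg[!in_planted, , drop = FALSE]
    in_cgi <- IRanges::overlapsAny(as_granges(bg), as_granges(truth$cgi))
    bg_base <- clamp(stats::rnorm(nrow(bg), ifelse(in_cgi, 0.1, 0.7), 0.03),
                     0.02, 0.98)
    site_chrom <- c(site_chrom, bg$chrom)
    site_pos <- c(site_pos, bg$start)
    base <- c(base, bg_base)
    shift <- c(shift, rep(0, nrow(bg)))
    key <- paste(site_chrom, site_pos)
    dup <- duplicated(key)
    site_chrom <- site_chrom[!dup]; site_pos <- site_pos[!dup]
    base <- base[!dup]; shift <- shift[!dup]

    pi_mock <- clamp(base, 0.02, 0.98)
    pi_treated <- clamp(base + shift, 0.02, 0.98)
    if (any(shift != 0) && all(pi_treated[shift != 0] %in% c(0.02, 0.98))) {
      warning("all planted sites clipped; delta too large for the baseline")
    }
    ns <- length(site_pos)
    ids <- c(paste0("mock_", seq_len(n_per_group)),
             paste0("treated_", seq_len(n_per_group)))
    grp <- rep(c("mock", "treated"), each = n_per_group)
    total <- matrix(stats::rpois(ns * length(ids), coverage), ns)
    meth <- matrix(0L, ns, length(ids))
    for (j in seq_along(ids)) {
      pi <- if (grp[j] == "treated") pi_treated else pi_mock
      meth[, j] <- rbetabinom(ns, total[, j], pi, precision)
    }
    cpg_site_table(site_chrom, site_pos, meth, total, ids, grp)
  })
}

#' Simulate a gene-level expression table
#'
#' `log2_fc` is the planted per-gene effect plus Gaussian noise; `base_mean`
#' is log-normal; p values come from a one-sample z test against the noise
#' model (a synthetic stand-in for an upstream differential-expression fit)
#' and are BH-adjusted.
#'
#' @param truth A [simulate_truth()] object.
#' @param noise_sd Gaussian noise SD on log2FC (default 0.1, >= 0).
#' @param seed Integer seed.
#' @return Expression `data.frame`: gene_id, base_mean, log2_fc, p_value,
#'   fdr, true_log2fc.
#' @export
simulate_expression <- function(truth, noise_sd = 0.1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(child_seed(seed, 4), {
    ids <- truth$genes$gene_id
    true_lfc <- unname(truth$planted_degs[ids])
    lfc <- true_lfc + stats::rnorm(length(ids), 0, noise_sd)
    base_mean <- stats::rlnorm(length(ids), log(300), 1)
    p <- if (noise_sd > 0) 2 * stats::pnorm(-abs(lfc) / noise_sd) else
      ifelse(lfc != 0, 0, 1)
    data.frame(gene_id = ids, base_mean = base_mean, log2_fc = lfc,
               p_value = p, fdr = stats::p.adjust(p, "BH"),
               true_log2fc = true_lfc, stringsAsFactors = FALSE)
  })
}

#' Simulate a clustered single-cell count matrix
#'
#' Genes have log-normal baseline means modulated per cluster; counts are
#' negative binomial per cell, and the planted DEGs of each cluster have
#' treated-group means multiplied by `2^log2fc`.
#'
#' @param truth A [simulate_truth()] object (cluster sizes and planted DEG
#'   counts come from its `cluster_spec`).
#' @param seed Integer seed.
#' @return List: `counts` (cells x genes integer matrix) and `meta`
#'   (cell, cluster, group).
#' @export
simulate_cells <- function(truth, seed = 1) {
  with_seed(child_seed(seed, 5), {
    cfg <- truth$config
    genes <- truth$cell_genes
    ng <- length(genes)
    base_mu <- stats::setNames(stats::rlnorm(ng, log(cfg$cell_base), 1), genes)
    # planted DEGs sit among the robustly expressed genes (the ones a
    # 50-cell test can see), as in real per-cluster DE results
    if (!is.null(truth$cell_degs)) {
      dg <- unique(truth$cell_degs$gene_id)
      base_mu[dg] <- stats::rlnorm(length(dg), log(cfg$cell_deg_base), 0.5)
    }
    cl <- truth$cluster_spec
    blocks <- list(); metas <- list()
    for (i in seq_len(nrow(cl))) {
      cl_mult <- stats::rlnorm(ng, 0, 0.2)
      mu <- base_mu * cl_mult
      deg <- truth$cell_degs[truth$cell_degs$cluster == cl$cluster[i], ,
                             drop = FALSE]
      mu_t <- mu
      if (nrow(deg)) {
        mu_t[deg$gene_id] <- mu_t[deg$gene_id] * 2^deg$log2fc
      }
      for (g in c("mock", "treated")) {
        nc <- cl$n_per_group[i]
        m <- if (g == "treated") mu_t else mu
        cnt <- matrix(stats::rnbinom(nc * ng, mu = rep(m, each = nc),
                                     size = 1 / cfg$cell_dispersion),
                      nrow = nc, ncol = ng)
        colnames(cnt) <- genes
        blocks[[length(blocks) + 1]] <- cnt
        metas[[length(metas) + 1]] <- data.frame(
          cluster = cl$cluster[i], group = g, stringsAsFactors = FALSE)[
            rep(1, nc), , drop = FALSE]
      }
    }
    counts <- do.call(rbind, blocks)
    meta <- do.call(rbind, metas)
    meta$cell <- sprintf("cell%05d", seq_len(nrow(meta)))
    rownames(counts) <- meta$cell
    rownames(meta) <- NULL
    list(counts = counts, meta = meta[, c("cell", "cluster", "group")])
  })
}

#' Simulate fine-scale per-group 5hmC/5mC profiles for IEG testing
#'
#' Emits library-normalized 50-bp sub-bin counts for each gene's body
#' (5hmC) and promoter (5mC) tiles, with the planted IEG effects applied to
#' the treated group. Non-IEG genes serve as negative controls.
#'
#' @param truth A [simulate_truth()] object.
#' @param gene_ids Genes to profile; defaults to all IEGs plus 10 control
#'   genes.
#' @param base_cpm Baseline sub-bin level (default 20).
#' @param cv Multiplicative noise coefficient of variation (default 0.15).
#' @param seed Integer seed.
#' @return Long `data.frame`: gene_id, context, tile, bin, treated, mock.
#' @export
simulate_ieg_profiles <- function(truth, gene_ids = NULL, base_cpm = 20,
                                  cv = 0.15, seed = 1) {
  with_seed(child_seed(seed, 6), {
    genes <- truth$genes
    if (is.null(gene_ids)) {
      controls <- utils::head(genes$gene_id[!genes$is_ieg], 10)
      gene_ids <- c(genes$gene_id[genes$is_ieg], controls)
    }
    it <- truth$ieg_truth
    out <- list()
    for (gid in gene_ids) {
      g <- genes[genes$gene_id == gid, , drop = FALSE]
      reg <- build_gene_regions(g, truth$layout)
      hmc_lfc <- if (gid %in% it$gene_id) it$hmc_log2fc[it$gene_id == gid] else 0
      mec_lfc <- if (gid %in% it$gene_id) it$mec_log2fc[it$gene_id == gid] else 0
      for (ctx in c("body", "promoter")) {
        tiles <- suppressWarnings(tile_region(reg[[ctx]]))
        if (!nrow(tiles)) next
        lfc <- if (ctx == "body") hmc_lfc else mec_lfc
        for (ti in seq_len(nrow(tiles))) {
          shape <- stats::rgamma(10, shape = 8, rate = 8 / base_cpm)
          mock <- shape * stats::rlnorm(10, 0, cv)
          treated <- shape * 2^lfc * stats::rlnorm(10, 0, cv)
          out[[length(out) + 1]] <- data.frame(
            gene_id = gid, context = ctx, tile = ti, bin = 1:10,
            treated = treated, mock = mock, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates truth and all stage inputs under one seed and writes them as
#' plain-text files: layout.tsv, samples.tsv, genes.tsv, cgi.bed,
#' repeats.bed, states.bed, hmc_counts.tsv, sites.tsv, expression.tsv,
#' cells.tsv, cells_meta.tsv, ieg_profiles.tsv, disease_genes.txt and
#' truth.json.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param n_per_group,depth,dispersion,coverage,precision,noise_sd Stage
#'   parameters passed through to the per-stage simulators.
#' @return The truth object, invisibly; files are written to `dir`.
#' @export
simulate_fixture <- function(dir, config = sim_config(), seed = 1,
                             n_per_group = 3, depth = 1e6, dispersion = 0.05,
                             coverage = 30, precision = 100, noise_sd = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config, seed)
  fp <- function(x) file.path(dir, x)

  write_tsv(data.frame(chrom = truth$layout$chrom_names,
                       length = unname(truth$layout$chrom_lengths)),
            fp("layout.tsv"))
  hmc <- simulate_5hmc_counts(truth, n_per_group, depth, dispersion, seed)
  write_tsv(data.frame(sample_id = hmc$sample_ids, group = hmc$group,
                       library_size = unname(hmc$library_sizes)),
            fp("samples.tsv"))
  cnt <- cbind(hmc$bins, as.data.frame(hmc$counts))
  write_tsv(cnt, fp("hmc_counts.tsv"))
  write_gene_table(truth$genes, fp("genes.tsv"))
  write_bed(truth$cgi, fp("cgi.bed"))
  write_bed(truth$repeats, fp("repeats.bed"))
  write_bed(truth$chrom_states, fp("states.bed"))
  sites <- simulate_methylation(truth, n_per_group, coverage, precision, seed)
  write_site_table(sites, fp("sites.tsv"))
  expr <- simulate_expression(truth, noise_sd, seed)
  write_tsv(expr, fp("expression.tsv"))
  cells <- simulate_cells(truth, seed)
  write_tsv(cbind(data.frame(cell = rownames(cells$counts)),
                  as.data.frame(cells$counts)), fp("cells.tsv"))
  write_tsv(cells$meta, fp("cells_meta.tsv"))
  prof <- simulate_ieg_profiles(truth, seed = seed)
  write_tsv(prof, fp("ieg_profiles.tsv"))
  # disease list: planted up-regulated genes diluted with random genes
  dl <- with_seed(child_seed(seed, 7), {
    up <- names(truth$planted_degs)[truth$planted_degs > 0]
    unique(c(up, sample(truth$genes$gene_id, 30)))
  })
  writeLines(sort(dl), fp("disease_genes.txt"))
  truth_json <- list(
    planted_dhmrs = truth$planted_dhmrs,
    planted_dmrs = truth$planted_dmrs[, c("chrom", "start", "end",
                                          "direction", "delta")],
    planted_degs = as.list(truth$planted_degs[truth$planted_degs != 0]),
    ieg_truth = truth$ieg_truth,
    cell_degs = truth$cell_degs,
    seed = seed)
  jsonlite::write_json(truth_json, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(truth)
}
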