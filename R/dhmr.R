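#' Counts-per-million normalization of binned counts
#'
#' @param m A [bin_counts()] object with positive library sizes.
#' @return A `normalized_density` object: the per-(bin, sample) CPM matrix
#'   plus per-group mean densities.
#' @export
normalize_cpm <- function(m) {
  if (any(m$library_sizes <= 0)) stop("library sizes must be positive")
  dens <- sweep(m$counts, 2, m$library_sizes, "/") * 1e6
  gm <- cbind(
    mock = rowMeans(dens[, m$group == "mock", drop = FALSE]),
    treated = rowMeans(dens[, m$group == "treated", drop = FALSE])
  )
  structure(
    list(bins = m$bins, density = dens, group_means = gm,
         sample_ids = m$sample_ids, group = m$group),
    class = "normalized_density"
  )
}

# scale counts to the geometric-mean library size (simplified quantile
# adjustment; see the methods vignette for what this drops relative to a
# full NB-quantile mapping)
adjusted_counts <- function(m) {
  L <- exp(mean(log(m$library_sizes)))
  list(counts = sweep(m$counts, 2, L / m$library_sizes, "*"),
       pseudo_lib = L)
}

# conditional log-likelihood of a group's counts given their total, as a
# function of dispersion phi (size r = 1/phi); terms free of phi are dropped.
# y: bins x samples matrix for ONE group.
cond_ll_group <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  tot <- rowSums(y)
  sum(lgamma(y + r)) - n * nrow(y) * lgamma(r) +
    nrow(y) * lgamma(n * r) - sum(lgamma(tot + n * r))
}

#' Estimate a common negative-binomial dispersion
#'
#' Counts are first scaled to the geometric-mean library size, then the single
#' dispersion maximizing the conditional log-likelihood summed over bins
#' (conditioning on per-group bin totals) is found by one-dimensional
#' optimization of the shrunken parameter delta = phi / (1 + phi).
#'
#' @param m A [bin_counts()] object with >= 2 samples per group.
#' @param subset_bins Optional logical/integer index of bins to use.
#' @return List with `common_dispersion`, `pseudo_library_size`, `n_bins_used`.
#' @export
estimate_common_dispersion <- function(m, subset_bins = NULL) {
  for (g in c("mock", "treated")) {
    if (sum(m$group == g) < 2) stop("need >= 2 samples per group")
  }
  adj <- adjusted_counts(m)
  y <- adj$counts
  if (!is.null(subset_bins)) y <- y[subset_bins, , drop = FALSE]
  keep <- rowSums(y) > 0
  if (!any(keep)) {
    warning("all-zero count matrix; dispersion set to 0")
    return(list(common_dispersion = 0, pseudo_library_size = adj$pseudo_lib,
                n_bins_used = 0L))
  }
  y <- y[keep, , drop = FALSE]
  ym <- y[, m$group == "mock", drop = FALSE]
  yt <- y[, m$group == "treated", drop = FALSE]
  nll <- function(delta) {
    phi <- delta / (1 - delta)
    -(cond_ll_group(ym, phi) + cond_ll_group(yt, phi))
  }
  opt <- stats::optimize(nll, interval = c(1e-6, 0.95), tol = 1e-6)
  delta <- opt$minimum
  # boundary solution: no extra-Poisson variation detectable
  phi <- if (delta <= 2e-6) 0 else delta / (1 - delta)
  list(common_dispersion = phi, pseudo_library_size = adj$pseudo_lib,
       n_bins_used = nrow(y))
}

# two-sided exact conditional NB p-value for one bin.
# s_t, s_m: rounded adjusted group sums; n_t, n_m: group sizes; phi: dispersion.
# The smaller tail (including the observed value) is doubled and capped at 1.
exact_nb_bin_p <- function(s_t, s_m, n_t, n_m, phi) {
  tt <- s_t + s_m
  if (tt == 0) return(1)
  s <- 0:tt
  if (phi <= 1e-12) {
    logw <- stats::dbinom(s, tt, n_t / (n_t + n_m), log = TRUE)
  } else {
    r <- 1 / phi
    logw <- lgamma(s + n_t * r) - lfactorial(s) +
      lgamma(tt - s + n_m * r) - lfactorial(tt - s)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  lower <- sum(w[s <= s_t])
  upper <- sum(w[s >= s_t])
  min(1, 2 * min(lower, upper))
}

#' Exact negative-binomial test per genome bin
#'
#' Library sizes are equalized by scaling to the geometric mean, group sums
#' are compared with a two-sided exact test conditional on their total (the
#' dispersion-0 limit is the conditional binomial test), and the fold change
#' is reported as `log2((treated mean + 0.5) / (mock mean + 0.5))` on adjusted
#' counts. The 0.5 pseudo-count enters the fold change only, never the test.
#'
#' @param m A [bin_counts()] object.
#' @param d Dispersion estimate from [estimate_common_dispersion()], or a
#'   single numeric dispersion.
#' @return `data.frame`: one row per bin with chrom, start, end, mean counts
#'   per group, log_fc, p_value.
#' @export
bin_exact_test <- function(m, d) {
  phi <- if (is.list(d)) d$common_dispersion else as.numeric(d)
  if (phi < 0) stop("dispersion must be >= 0")
  adj <- adjusted_counts(m)$counts
  is_t <- m$group == "treated"
  n_t <- sum(is_t); n_m <- sum(!is_t)
  if (n_t < 1 || n_m < 1) stop("both groups must be present")
  mean_t <- rowMeans(adj[, is_t, drop = FALSE])
  mean_m <- rowMeans(adj[, !is_t, drop = FALSE])
  s_t <- round(rowSums(adj[, is_t, drop = FALSE]))
  s_m <- round(rowSums(adj[, !is_t, drop = FALSE]))
  log_fc <- ifelse(s_t + s_m == 0, 0,
                   log2((mean_t + 0.5) / (mean_m + 0.5)))
  p <- vapply(seq_along(s_t), function(i) {
    exact_nb_bin_p(s_t[i], s_m[i], n_t, n_m, phi)
  }, 0)
  out <- m$bins
  out$mean_mock <- mean_m
  out$mean_treated <- mean_t
  out$log_fc <- log_fc
  out$p_value <- p
  out
}

#' Call differential 5hmC regions from per-bin tests
#'
#' Benjamini-Hochberg adjustment is applied over all tested bins; significant
#' bins become region calls directed by the sign of the fold change, and
#' (optionally) adjacent significant bins of the same direction are merged.
#'
#' @param bin_results Output of [bin_exact_test()].
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param merge_adjacent Merge touching same-direction significant bins into
#'   one region (default TRUE); with FALSE each significant bin is its own
#'   region call.
#' @return `data.frame` of region calls: chrom, start, end, direction
#'   (`gain`/`loss`), log_fc (mean over member bins), p_value (min), fdr
#'   (min), n_bins.
#' @export
call_dhmrs <- function(bin_results, fdr_threshold = 0.05,
                       merge_adjacent = TRUE) {
  fdr <- stats::p.adjust(bin_results$p_value, method = "BH")
  sig <- which(fdr < fdr_threshold & bin_results$log_fc != 0)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), log_fc = numeric(),
                      p_value = numeric(), fdr = numeric(), n_bins = integer(),
                      stringsAsFactors = FALSE)
  if (!length(sig)) return(empty)
  b <- bin_results[sig, , drop = FALSE]
  b$fdr <- fdr[sig]
  b$direction <- ifelse(b$log_fc > 0, "gain", "loss")
  if (!merge_adjacent) {
    run <- seq_len(nrow(b))
  } else {
    new_run <- c(TRUE, !(b$chrom[-1] == b$chrom[-nrow(b)] &
                           b$start[-1] == b$end[-nrow(b)] &
                           b$direction[-1] == b$direction[-nrow(b)]))
    run <- cumsum(new_run)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(b)), run), function(i) {
    data.frame(chrom = b$chrom[i[1]], start = min(b$start[i]),
               end = max(b$end[i]),
               direction = b$direction[i[1]],
               log_fc = mean(b$log_fc[i]),
               p_value = min(b$p_value[i]),
               fdr = min(b$fdr[i]),
               n_bins = length(i), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genome-wide regression of treated on mock density
#'
#' Ordinary least squares of the treated-group mean density on the mock-group
#' mean density over all bins; a slope below 1 indicates a genome-wide loss
#' of signal.
#'
#' @param nd A [normalize_cpm()] result.
#' @return List: slope, intercept, pearson_r, p_value, n_bins.
#' @export
global_regression <- function(nd) {
  x <- nd$group_means[, "mock"]
  y <- nd$group_means[, "treated"]
  if (length(x) < 3) stop("need >= 3 bins")
  if (stats::var(x) == 0) stop("zero variance in mock density")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = unname(ct$estimate),
       p_value = ct$p.value,
       n_bins = length(x))
}

#' Length-normalized average density profile over a region set
#'
#' Each region is rescaled to `n_points` relative positions (flipped for
#' minus-strand regions), the group-mean bin density is sampled at each
#' position, and positions are averaged across regions. Also returns the
#' per-region mean densities and a two-sided unpaired t test comparing them
#' between groups.
#'
#' @param nd A [normalize_cpm()] result built on uniform-width bins.
#' @param regions Interval `data.frame`; a `strand` column triggers the flip.
#' @param layout The [genome_layout()] the bins tile.
#' @param n_points Number of profile positions per region (default 40).
#' @return List: profile (n_points x 2 matrix, mock/treated), region_means
#'   data.frame, fold_change (treated/mock of set means), t, p_value.
#' @export
meta_profile <- function(nd, regions, layout, n_points = 40) {
  if (!nrow(regions)) stop("regions must be non-empty")
  width <- max(nd$bins$end - nd$bins$start)
  nbin <- vapply(layout$chrom_names, function(ch) sum(nd$bins$chrom == ch), 0)
  offset <- stats::setNames(cumsum(c(0, nbin[-length(nbin)])),
                            layout$chrom_names)
  strand <- if ("strand" %in% names(regions)) regions$strand else "."
  prof_m <- matrix(NA_real_, nrow(regions), n_points)
  prof_t <- matrix(NA_real_, nrow(regions), n_points)
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    pos <- regions$start[i] + ((seq_len(n_points) - 0.5) / n_points) * len
    idx <- offset[regions$chrom[i]] + floor(pmin(pos, len + regions$start[i] - 1)) %/% width + 1
    pm <- nd$group_means[idx, "mock"]
    pt <- nd$group_means[idx, "treated"]
    if (strand[i] == "-") { pm <- rev(pm); pt <- rev(pt) }
    prof_m[i, ] <- pm
    prof_t[i, ] <- pt
  }
  rm_means <- rowMeans(prof_m)
  rt_means <- rowMeans(prof_t)
  if (isTRUE(all.equal(rm_means, rt_means)) ||
      (stats::sd(rm_means) == 0 && stats::sd(rt_means) == 0)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(rt_means, rm_means, var.equal = FALSE)
  }
  mm <- mean(rm_means)
  list(profile = cbind(mock = colMeans(prof_m), treated = colMeans(prof_t)),
       region_means = data.frame(region = seq_len(nrow(regions)),
                                 mock = rm_means, treated = rt_means),
       fold_change = if (mm == 0) NA_real_ else mean(rt_means) / mm,
       t = unname(tt$statistic), p_value = tt$p.value)
}
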