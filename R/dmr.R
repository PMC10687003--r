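# negative beta-binomial log-likelihood over the samples of one site,
# with group-specific or shared mean and a shared concentration theta
bb_site_ll <- function(meth, total, pi, theta) {
  keep <- total > 0
  if (!any(keep)) return(0)
  sum(dbetabinom_log(meth[keep], total[keep],
                     rep_len(pi, length(meth))[keep], theta))
}

# 1-D maximization of the site log-likelihood over one mean, theta fixed
bb_opt_mean <- function(meth, total, theta, p_start) {
  obj <- function(lp) {
    -bb_site_ll(meth, total, clamp(stats::plogis(lp), 1e-6, 1 - 1e-6), theta)
  }
  opt <- stats::optimize(obj, interval = stats::qlogis(p_start) + c(-8, 8),
                         tol = 1e-7)
  -opt$objective
}

# residual moment components of one site: within-group sums of squares of
# the per-sample methylation proportions around each group's own mean, so a
# true group shift cannot inflate the dispersion estimate
bb_resid_moments <- function(meth, total, grp_t) {
  keep <- total > 0
  p <- meth[keep] / total[keep]
  g <- grp_t[keep]
  ss <- 0; df <- 0; base <- 0; ntot <- 0
  for (gv in c(FALSE, TRUE)) {
    pg <- p[g == gv]
    if (length(pg) >= 2) {
      ss <- ss + sum((pg - mean(pg))^2)
      df <- df + length(pg) - 1
      base <- base + (length(pg) - 1) * mean(pg) * (1 - mean(pg))
      ntot <- ntot + sum(total[keep][g == gv])
    }
  }
  c(ss = ss, df = df, base = base, n = ntot,
    nobs = sum(keep))
}

# shared concentration across all sites by pooled method of moments:
# E[residual var] = pbar(1-pbar) * (1/nbar + (1 - 1/nbar) * rho); solving
# with sums pooled over sites gives one intra-class correlation rho and
# theta = 1/rho - 1. A degenerate table (zero residual variance) cleanly
# yields the near-binomial upper limit.
bb_theta_pooled <- function(mom) {
  tot <- colSums(mom)
  if (tot["df"] == 0 || tot["base"] == 0) return(1 / 1e-3 - 1)
  v <- tot["ss"] / tot["df"]
  base <- tot["base"] / tot["df"]
  nbar <- max(1.5, tot["n"] / max(1, tot["nobs"]))
  rho <- clamp(unname((v / base - 1 / nbar) / (1 - 1 / nbar)), 1e-3, 0.5)
  1 / rho - 1
}

# group-specific-mean fit with the shared concentration held fixed; the
# same theta is reused in the common-mean fit so the models stay nested
fit_bb_alt <- function(meth, total, grp_t, theta) {
  p_m <- clamp(sum(meth[!grp_t]) / max(1, sum(total[!grp_t])), 1e-4, 1 - 1e-4)
  p_t <- clamp(sum(meth[grp_t]) / max(1, sum(total[grp_t])), 1e-4, 1 - 1e-4)
  ll <- bb_opt_mean(meth[!grp_t], total[!grp_t], theta, p_m) +
    bb_opt_mean(meth[grp_t], total[grp_t], theta, p_t)
  list(ll = ll, theta = theta)
}

fit_bb_null <- function(meth, total, theta) {
  p0 <- clamp(sum(meth) / max(1, sum(total)), 1e-4, 1 - 1e-4)
  bb_opt_mean(meth, total, theta, p0)
}

#' Per-CpG beta-binomial likelihood-ratio test
#'
#' For each site with sufficient pooled coverage in both groups, a
#' likelihood-ratio test compares a beta-binomial model with one common mean
#' against group-specific means. The concentration is shared: it is
#' estimated once for the whole table by pooling the within-group residual
#' variance of the per-sample proportions across sites (method of moments)
#' and held fixed in both fits, so a true group shift cannot masquerade as
#' overdispersion and a single noisy site cannot destroy its own power; the
#' statistic is referred to a chi-square with 1 df.
#' Group methylation levels are the pooled meth/total ratios.
#'
#' @param tab A [cpg_site_table()] with >= 2 samples per group.
#' @param min_total Minimum pooled total per group for a site to be tested
#'   (default 10); skipped sites are reported via attribute `"n_skipped"`.
#' @return `data.frame` of site results: chrom, pos, m_mock, m_treated,
#'   meth_diff, p_value.
#' @export
site_test <- function(tab, min_total = 10) {
  grp_t <- tab$group == "treated"
  if (sum(grp_t) < 2 || sum(!grp_t) < 2) stop("need >= 2 samples per group")
  tot_m <- rowSums(tab$total[, !grp_t, drop = FALSE])
  tot_t <- rowSums(tab$total[, grp_t, drop = FALSE])
  testable <- tot_m >= min_total & tot_t >= min_total
  n_skipped <- sum(!testable)
  idx <- which(testable)
  m_mock <- rowSums(tab$meth[, !grp_t, drop = FALSE])[idx] / tot_m[idx]
  m_treated <- rowSums(tab$meth[, grp_t, drop = FALSE])[idx] / tot_t[idx]
  mom <- t(vapply(idx, function(i) {
    bb_resid_moments(tab$meth[i, ], tab$total[i, ], grp_t)
  }, c(ss = 0, df = 0, base = 0, n = 0, nobs = 0)))
  theta <- bb_theta_pooled(mom)
  p <- vapply(idx, function(i) {
    meth <- tab$meth[i, ]; total <- tab$total[i, ]
    alt <- fit_bb_alt(meth, total, grp_t, theta)
    l0 <- fit_bb_null(meth, total, alt$theta)
    lrt <- max(0, 2 * (alt$ll - l0))
    stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }, 0)
  out <- data.frame(chrom = tab$chrom[idx], pos = tab$pos[idx],
                    m_mock = m_mock, m_treated = m_treated,
                    meth_diff = m_treated - m_mock, p_value = p,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Flag differentially methylated sites
#'
#' Mirrors the two-step site-calling convention of regression-based
#' methylation callers: each site's signed z score is first combined with
#' those of its neighbors within `neighbor_radius` bp (Stouffer's method;
#' isolated sites are unchanged), then the combined p values are BH-adjusted
#' across all tested sites and thresholded.
#'
#' @param results Output of [site_test()].
#' @param site_alpha Adjusted-p threshold (default 0.05).
#' @param neighbor_radius Half-width in bp of the combination window
#'   (default 100, matching the DMR merge scale); `0` disables the
#'   combination so the raw per-site p values are adjusted directly.
#' @return `results` with columns `combined_p`, `adj_p` and `is_dm` added.
#' @export
flag_dm_sites <- function(results, site_alpha = 0.05, neighbor_radius = 100) {
  if (!nrow(results)) {
    results$combined_p <- numeric(); results$adj_p <- numeric()
    results$is_dm <- logical()
    return(results)
  }
  p <- pmax(results$p_value, 1e-300)
  z <- ifelse(results$meth_diff >= 0, 1, -1) *
    stats::qnorm(p / 2, lower.tail = FALSE)
  comb <- p
  if (neighbor_radius > 0) {
    ord <- order(results$chrom, results$pos)
    for (ch in unique(results$chrom[ord])) {
      i <- ord[results$chrom[ord] == ch]
      pos <- results$pos[i]
      lo <- findInterval(pos - neighbor_radius - 0.5, pos) + 1
      hi <- findInterval(pos + neighbor_radius, pos)
      cz <- cumsum(c(0, z[i]))
      k <- hi - lo + 1
      Z <- (cz[hi + 1] - cz[lo]) / sqrt(k)
      comb[i] <- 2 * stats::pnorm(-abs(Z))
    }
  }
  results$combined_p <- comb
  results$adj_p <- stats::p.adjust(comb, method = "BH")
  results$is_dm <- results$adj_p < site_alpha
  results
}

#' Merge nearby differentially methylated sites into DMR candidates
#'
#' Within each chromosome, consecutive DM sites strictly less than
#' `merge_gap` bp apart are chained into one candidate spanning the first to
#' the last member site (end exclusive = last position + 1). Non-DM sites
#' falling inside the span are counted but do not break the chain.
#'
#' @param results Output of [flag_dm_sites()].
#' @param merge_gap Distance threshold in bp (default 100; strict `<`).
#' @return `data.frame` of candidates: chrom, start, end, n_dm_sites,
#'   mean_meth_diff (signed mean over DM member sites), n_non_dm_inside,
#'   plus list column `dm_pos`.
#' @export
merge_dm_sites <- function(results, merge_gap = 100) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_dm_sites = integer(), mean_meth_diff = numeric(),
                      n_non_dm_inside = integer(), stringsAsFactors = FALSE)
  dm <- results[results$is_dm, , drop = FALSE]
  if (!nrow(dm)) { empty$dm_pos <- list(); return(empty) }
  dm <- dm[order(dm$chrom, dm$pos), , drop = FALSE]
  new_chain <- c(TRUE, !(dm$chrom[-1] == dm$chrom[-nrow(dm)] &
                           (dm$pos[-1] - dm$pos[-nrow(dm)]) < merge_gap))
  chain <- cumsum(new_chain)
  cands <- do.call(rbind, lapply(split(seq_len(nrow(dm)), chain), function(i) {
    s <- min(dm$pos[i]); e <- max(dm$pos[i]) + 1
    inside <- results$chrom == dm$chrom[i[1]] & !results$is_dm &
      results$pos >= s & results$pos < e
    data.frame(chrom = dm$chrom[i[1]], start = s, end = e,
               n_dm_sites = length(i),
               mean_meth_diff = mean(dm$meth_diff[i]),
               n_non_dm_inside = sum(inside), stringsAsFactors = FALSE)
  }))
  cands$dm_pos <- unname(lapply(split(dm$pos, chain), identity))
  rownames(cands) <- NULL
  cands
}

#' Filter DMR candidates into final region calls
#'
#' Retains candidates with at least `min_dm_sites` DM CpGs ("more than 5" in
#' the default configuration), an absolute mean methylation difference over
#' DM sites above `min_mean_diff`, and (optionally) a consistent direction of
#' change across member sites.
#'
#' @param cands Output of [merge_dm_sites()].
#' @param min_dm_sites Minimum number of DM CpGs (default 6, i.e. `> 5`).
#' @param min_mean_diff Minimum `|mean meth diff|` over DM sites (default 0.2,
#'   strict `>`).
#' @param sign_consistency Minimum fraction of DM sites sharing the majority
#'   sign (default 0.8); `NULL` disables the guard (strict literal mode).
#' @param results Site results (needed to evaluate sign consistency); only
#'   required when `sign_consistency` is not `NULL`.
#' @return `data.frame` of DMR calls: chrom, start, end, direction
#'   (`hyper`/`hypo`), n_dm_sites, mean_meth_diff.
#' @export
filter_candidates <- function(cands, min_dm_sites = 6, min_mean_diff = 0.2,
                              sign_consistency = 0.8, results = NULL) {
  keep <- cands$n_dm_sites >= min_dm_sites &
    abs(cands$mean_meth_diff) > min_mean_diff
  if (!is.null(sign_consistency) && nrow(cands)) {
    if (is.null(results)) stop("results needed for the sign-consistency guard")
    frac <- vapply(seq_len(nrow(cands)), function(i) {
      pos <- cands$dm_pos[[i]]
      d <- results$meth_diff[results$chrom == cands$chrom[i] &
                               results$pos %in% pos & results$is_dm]
      s <- sign(d)
      if (!length(s)) return(0)
      max(sum(s > 0), sum(s < 0)) / length(s)
    }, 0)
    keep <- keep & frac >= sign_consistency
  }
  out <- cands[keep, c("chrom", "start", "end", "n_dm_sites",
                       "mean_meth_diff"), drop = FALSE]
  out$direction <- ifelse(out$mean_meth_diff > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "direction", "n_dm_sites",
          "mean_meth_diff")]
}

#' Full DMR calling pipeline
#'
#' Runs [site_test()], [flag_dm_sites()], [merge_dm_sites()] and
#' [filter_candidates()] with the standard defaults.
#'
#' @inheritParams site_test
#' @inheritParams flag_dm_sites
#' @inheritParams merge_dm_sites
#' @inheritParams filter_candidates
#' @param neighbor_radius Passed to [flag_dm_sites()].
#' @return List: `sites` (flagged site results), `candidates`, `dmrs`.
#' @export
call_dmrs <- function(tab, min_total = 10, site_alpha = 0.05, merge_gap = 100,
                      min_dm_sites = 6, min_mean_diff = 0.2,
                      sign_consistency = 0.8, neighbor_radius = 100) {
  res <- flag_dm_sites(site_test(tab, min_total), site_alpha, neighbor_radius)
  cands <- merge_dm_sites(res, merge_gap)
  dmrs <- filter_candidates(cands, min_dm_sites, min_mean_diff,
                            sign_consistency, results = res)
  list(sites = res, candidates = cands, dmrs = dmrs)
}
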