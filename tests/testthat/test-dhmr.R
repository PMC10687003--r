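test_that("CPM normalization scales by library size", {
  m <- make_small_counts(matrix(c(10, 10, 0, 10, 10, 0), 3, 2),
                         lib = c(1e6, 2e6))
  nd <- normalize_cpm(m)
  expect_equal(unname(nd$density[1, ]), c(10, 5))
  # equal libraries: densities proportional to counts
  m2 <- make_small_counts(matrix(c(1, 2, 4, 3, 6, 12), 3, 2),
                          lib = c(1e6, 1e6))
  nd2 <- normalize_cpm(m2)
  expect_equal(nd2$density[, 1] / m2$counts[, 1], rep(1, 3))
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(21)
  mu <- rgamma(2000, shape = 5, rate = 1 / 10)
  pois <- sapply(1:6, function(i) rpois(2000, mu))
  mp <- make_small_counts(pois)
  dp <- estimate_common_dispersion(mp)
  expect_lte(dp$common_dispersion, 0.01)

  nb <- sapply(1:6, function(i) rnbinom(2000, mu = mu, size = 1 / 0.2))
  mn <- make_small_counts(nb)
  dn <- estimate_common_dispersion(mn)
  expect_gte(dn$common_dispersion, 0.1)
  expect_lte(dn$common_dispersion, 0.3)

  # duplicated identical samples: no extra-Poisson variation
  dup <- make_small_counts(cbind(pois[, 1], pois[, 1], pois[, 1], pois[, 1]))
  expect_lte(estimate_common_dispersion(dup)$common_dispersion, 0.01)

  zero <- make_small_counts(matrix(0, 10, 4), lib = rep(10, 4))
  expect_warning(dz <- estimate_common_dispersion(zero), "all-zero")
  expect_equal(dz$common_dispersion, 0)
})

test_that("dispersion estimate agrees with the qCML reference at equal libraries", {
  skip_if_not_installed("edgeR")
  set.seed(22)
  mu <- rgamma(3000, shape = 4, rate = 1 / 20)
  y <- sapply(1:6, function(i) rnbinom(3000, mu = mu, size = 1 / 0.15))
  m <- make_small_counts(y, lib = rep(sum(mu) * 1.05, 6))
  ours <- estimate_common_dispersion(m)$common_dispersion
  dge <- edgeR::DGEList(counts = y, group = m$group,
                        lib.size = rep(sum(mu) * 1.05, 6))
  ref <- edgeR::estimateCommonDisp(dge)$common.dispersion
  expect_lt(abs(ours - ref) / ref, 0.15)
})

test_that("exact NB test matches the conditional binomial oracle at dispersion 0", {
  # headline example: group sums 0 vs 20, equal libraries
  counts <- rbind(c(0, 0, 0, 8, 6, 6))
  m <- make_small_counts(counts, lib = rep(1000, 6))
  res <- bin_exact_test(m, 0)
  expect_equal(res$p_value, 2 * 0.5^20, tolerance = 1e-12)

  # identical group sums give the maximal p
  m2 <- make_small_counts(rbind(c(5, 3, 2, 4, 4, 2)), lib = rep(1000, 6))
  expect_equal(bin_exact_test(m2, 0)$p_value, 1)

  # zero-total bins: p = 1, log_fc = 0
  m3 <- make_small_counts(rbind(c(0, 0, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 1)),
                          lib = rep(1000, 6))
  r3 <- bin_exact_test(m3, 0)
  expect_equal(r3$p_value[1], 1)
  expect_equal(r3$log_fc[1], 0)

  # random totals <= 30 against exhaustive enumeration
  set.seed(23)
  for (i in 1:50) {
    cm <- matrix(rpois(6, 2), 1)
    mm <- make_small_counts(cm, lib = rep(500, 6))
    p <- bin_exact_test(mm, 0)$p_value
    expect_equal(p, oracle_cond_binom_p(sum(cm[4:6]), sum(cm[1:3]), 3, 3),
                 tolerance = 1e-12)
  }
})

test_that("label swap flips the fold change and preserves p", {
  set.seed(24)
  cm <- matrix(rpois(60, 20), 10, 6)
  m <- make_small_counts(cm)
  m_sw <- make_small_counts(cm[, c(4:6, 1:3)])
  r <- bin_exact_test(m, 0.1)
  r_sw <- bin_exact_test(m_sw, 0.1)
  expect_equal(r$log_fc, -r_sw$log_fc, tolerance = 1e-9)
  expect_equal(r$p_value, r_sw$p_value, tolerance = 1e-9)
})

test_that("exact test p-values agree with the edgeR reference", {
  skip_if_not_installed("edgeR")
  set.seed(25)
  mu <- rgamma(300, shape = 5, rate = 1 / 30)
  y <- sapply(1:6, function(i) rnbinom(300, mu = mu, size = 1 / 0.1))
  m <- make_small_counts(y, lib = rep(max(colSums(y)), 6))
  res <- bin_exact_test(m, 0.1)
  dge <- edgeR::DGEList(counts = y, group = m$group,
                        lib.size = rep(max(colSums(y)), 6))
  dge$common.dispersion <- 0.1
  ref <- edgeR::exactTest(dge)$table$PValue
  keep <- res$p_value < 0.999 & ref < 0.999
  expect_gt(cor(log(res$p_value[keep]), log(ref[keep])), 0.99)
})

test_that("region calling applies BH, directions and the adjacency merge", {
  bins <- data.frame(chrom = rep("chr1", 6), start = (0:5) * 500,
                     end = (1:6) * 500)
  br <- cbind(bins, mean_mock = 10, mean_treated = 30,
              log_fc = c(2, 2, -2, 2, 0.1, 2),
              p_value = c(1e-8, 1e-8, 1e-8, 1e-8, 0.9, 1e-8))
  calls <- call_dhmrs(br, fdr_threshold = 0.05)
  # bins 1-2 merge (gain), bin 3 separate (loss), bin 4 separate after
  # direction change, bin 6 separate after the non-significant gap
  expect_equal(nrow(calls), 4)
  expect_equal(calls$start, c(0, 1000, 1500, 2500))
  expect_equal(calls$end, c(1000, 1500, 2000, 3000))
  expect_equal(calls$direction, c("gain", "loss", "gain", "gain"))
  expect_equal(calls$n_bins, c(2, 1, 1, 1))

  # unmerged mode reports each significant bin separately
  expect_equal(nrow(call_dhmrs(br, merge_adjacent = FALSE)), 5)
  # nothing significant -> empty
  br$p_value <- 0.5
  expect_equal(nrow(call_dhmrs(br)), 0)
  # BH: adjusted >= raw on a mixed example
  br$p_value <- c(0.001, 0.01, 0.02, 0.2, 0.5, 0.9)
  fdr <- p.adjust(br$p_value, "BH")
  expect_true(all(fdr >= br$p_value))
})

test_that("global regression recovers exact linear relations", {
  m <- make_small_counts(matrix(rpois(60, 50), 10, 6))
  nd <- normalize_cpm(m)
  nd$group_means[, "treated"] <- nd$group_means[, "mock"]
  r <- global_regression(nd)
  expect_equal(r$slope, 1, tolerance = 1e-9)
  expect_equal(r$pearson_r, 1, tolerance = 1e-9)

  nd$group_means[, "treated"] <- 0.8 * nd$group_means[, "mock"]
  expect_equal(global_regression(nd)$slope, 0.8, tolerance = 1e-9)

  nd$group_means[, "mock"] <- 5
  expect_error(global_regression(nd), "variance")
})

test_that("a global loss truth drives the regression slope below 1", {
  cfg <- small_config(n_gain = 2, n_loss = 60, fold = 2.5)
  tr <- simulate_truth(cfg, seed = 31)
  m <- simulate_5hmc_counts(tr, depth = 3e5, seed = 31)
  r <- global_regression(normalize_cpm(m))
  expect_lt(r$slope, 1)
})

test_that("meta profiles are strand-aware length-normalized averages", {
  lay <- genome_layout("chr1", 5000)
  bins <- make_genome_bins(lay, 500)
  dens <- matrix(5, nrow(bins), 2)
  nd <- list(bins = bins, density = dens,
             group_means = cbind(mock = rep(5, nrow(bins)),
                                 treated = rep(5, nrow(bins))),
             sample_ids = c("m", "t"), group = c("mock", "treated"))
  reg <- data.frame(chrom = "chr1", start = 1000, end = 3000, strand = "+")
  pr <- meta_profile(nd, reg, lay, n_points = 10)
  expect_equal(unname(pr$profile[, "mock"]), rep(5, 10))
  expect_equal(pr$fold_change, 1)
  expect_equal(pr$p_value, 1)

  # ascending density flips to descending on the minus strand
  nd$group_means[, "mock"] <- seq_len(nrow(bins))
  nd$group_means[, "treated"] <- seq_len(nrow(bins))
  minus <- data.frame(chrom = "chr1", start = 0, end = 5000, strand = "-")
  plus <- data.frame(chrom = "chr1", start = 0, end = 5000, strand = "+")
  pm <- meta_profile(nd, minus, lay, n_points = 10)
  pp <- meta_profile(nd, plus, lay, n_points = 10)
  expect_equal(unname(pm$profile[, "mock"]), rev(unname(pp$profile[, "mock"])))
  expect_true(all(diff(pm$profile[, "mock"]) <= 0))
  expect_error(meta_profile(nd, reg[0, ], lay), "non-empty")
})
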