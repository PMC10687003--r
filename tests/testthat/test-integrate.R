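test_that("DEG selection applies strict thresholds and partitions", {
  e <- data.frame(gene_id = paste0("g", 1:5),
                  base_mean = c(200, 100, 200, 200, 151),
                  log2_fc = c(0.2, 2, 0.15, -0.3, -0.16),
                  p_value = 0.01, fdr = 0.05)
  d <- select_degs(e)
  expect_equal(d$up, "g1")              # g2 fails base_mean, g3 is not strict
  expect_equal(sort(d$down), c("g4", "g5"))
  expect_length(intersect(d$up, d$down), 0)
})

test_that("regions are assigned to every overlapping gene body", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(1000, 4500), end = c(5000, 9000),
                      strand = "+", is_ieg = FALSE)
  regions <- data.frame(chrom = "chr1", start = c(2000, 4600, 20000),
                        end = c(2500, 4900, 20500),
                        direction = c("gain", "gain", "loss"),
                        log_fc = 1, p_value = 0.001, fdr = 0.01)
  a <- assign_regions_to_genes(regions, genes)
  # region 1 in gA only; region 2 overlaps both; region 3 unassigned
  expect_equal(a$assignments$gene_id[a$assignments$start == 2000], "gA")
  expect_equal(sort(a$assignments$gene_id[a$assignments$start == 4600]),
               c("gA", "gB"))
  expect_equal(a$unassigned, 3L)
})

test_that("concordance classification follows the definition", {
  e <- data.frame(gene_id = c("up1", "up2", "dn1", "none"),
                  base_mean = 500, log2_fc = c(1, 1, -1, 0.5),
                  p_value = 0.01, fdr = 0.01)
  gr <- data.frame(gene_id = c("up1", "up2", "dn1", "none"),
                   direction = c("gain", "loss", "loss", "gain"),
                   p_value = c(0.01, 0.01, 0.01, 0.2),
                   fdr = c(0.05, 0.05, 0.05, 0.6))
  cc <- classify_concordance(e, gr, mode = "5hmC")
  expect_equal(cc$gain_activated, "up1")
  # up2 has only loss regions -> no set; none's region is not significant
  expect_equal(cc$loss_repressed, "dn1")

  # conflict resolution: direction of the more significant region wins
  gr2 <- rbind(gr, data.frame(gene_id = "up2", direction = "gain",
                              p_value = 0.001, fdr = 0.01))
  expect_message(cc2 <- classify_concordance(e, gr2, mode = "5hmC"),
                 "both directions")
  expect_equal(sort(cc2$gain_activated), c("up1", "up2"))

  # monotone in alpha: smaller alpha never adds genes
  cc_tight <- classify_concordance(e, gr, mode = "5hmC", region_alpha = 0.001)
  expect_true(all(cc_tight$gain_activated %in% cc$gain_activated))
  expect_true(all(cc_tight$loss_repressed %in% cc$loss_repressed))

  # 5mC mode intersects DMR direction with the DEG sets
  em <- data.frame(gene_id = c("a", "b", "c"), base_mean = 500,
                   log2_fc = c(-1, 1, -1), p_value = 0.01, fdr = 0.01)
  grm <- data.frame(gene_id = c("a", "b", "c"),
                    direction = c("hyper", "hypo", "hypo"))
  cm <- classify_concordance(em, grm, mode = "5mC")
  expect_equal(cm$hyper_down, "a")
  expect_equal(cm$hypo_up, "b")
})

test_that("planted concordant genes are recovered end to end", {
  cfg <- small_config(n_gain = 25, n_loss = 25)
  tr <- simulate_truth(cfg, seed = 61)
  m <- simulate_5hmc_counts(tr, depth = 1e6, seed = 61)
  res <- bin_exact_test(m, estimate_common_dispersion(m))
  calls <- call_dhmrs(res)
  e <- simulate_expression(tr, noise_sd = 0.1, seed = 61)
  a <- assign_regions_to_genes(calls, tr$genes)
  cc <- suppressMessages(classify_concordance(e, a$assignments, mode = "5hmC"))
  # which genes were planted concordant with a gene-body 5hmC region?
  planted_up <- names(tr$planted_degs)[tr$planted_degs > 0 &
    !names(tr$planted_degs) %in% tr$ieg_truth$gene_id]
  planted_dn <- names(tr$planted_degs)[tr$planted_degs < 0]
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(tr$genes$chrom,
                           IRanges::IRanges(tr$genes$start + 1, tr$genes$end)),
    GenomicRanges::GRanges(tr$planted_dhmrs$chrom,
                           IRanges::IRanges(tr$planted_dhmrs$start + 1,
                                            tr$planted_dhmrs$end)))
  qh <- S4Vectors::queryHits(hit)
  dirs <- tr$planted_dhmrs$direction[S4Vectors::subjectHits(hit)]
  # restrict to genes whose planted regions all share one direction
  n_dir <- vapply(split(dirs, qh), function(d) length(unique(d)), 0L)
  unambiguous <- tr$genes$gene_id[as.integer(names(n_dir))[n_dir == 1]]
  planted_up <- intersect(planted_up, unambiguous)
  planted_dn <- intersect(planted_dn, unambiguous)
  rec_up <- mean(planted_up %in% cc$gain_activated)
  rec_dn <- mean(planted_dn %in% cc$loss_repressed)
  expect_gte(rec_up, 0.9)
  expect_gte(rec_dn, 0.9)
})

test_that("binomial overlap p matches exact summation", {
  uni <- paste0("g", 1:100)
  q <- uni[1:10]; dl <- uni[1:10]
  # all of the query in the list: closed form p0^n
  r <- geneset_overlap_binomial(q, dl, uni)
  expect_equal(r$k, 10)
  expect_equal(r$p_binomial, 0.1^10, tolerance = 1e-12)
  # no overlap: p = 1
  r0 <- geneset_overlap_binomial(uni[11:20], uni[1:10], uni)
  expect_equal(r0$p_binomial, 1)
  # worked case |query|=20, p0=0.2, k=10
  r2 <- geneset_overlap_binomial(uni[1:20], c(uni[1:10], uni[91:100]), uni)
  expect_equal(r2$p_binomial, oracle_binom_tail(10, 20, 0.2),
               tolerance = 1e-12)
  expect_equal(r2$p_binomial, 0.00259482740067, tolerance = 1e-9)

  # random cases against the oracle
  set.seed(62)
  for (i in 1:40) {
    n <- sample(1:50, 1); mlen <- sample(1:60, 1)
    q <- sample(uni, n); dl <- sample(uni, mlen)
    r <- geneset_overlap_binomial(q, dl, uni)
    expect_equal(r$p_binomial, oracle_binom_tail(r$k, r$n, r$m / r$N),
                 tolerance = 1e-12)
  }
  expect_error(geneset_overlap_binomial("x", "x", character()), "universe")
  expect_error(geneset_overlap_binomial("zz", uni[1], uni), "within universe")
})

test_that("expression-methylation correlation behaves at the poles", {
  x <- rnorm(50)
  expect_equal(methylation_expression_correlation(x, x)$pearson_r, 1)
  expect_equal(methylation_expression_correlation(x, -x)$pearson_r, -1)
  expect_warning(r <- methylation_expression_correlation(x, rep(1, 50)),
                 "constant")
  expect_true(is.na(r$pearson_r))
  expect_error(methylation_expression_correlation(1:2, 1:2), ">= 3")

  # independent vectors: |r| small in at least 19/20 seeds
  hits <- sum(vapply(1:20, function(s) {
    set.seed(s)
    abs(methylation_expression_correlation(rnorm(1000),
                                           rnorm(1000))$pearson_r) < 0.1
  }, TRUE))
  expect_gte(hits, 19)
})
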