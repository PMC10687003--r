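test_that("gene windows follow the strand-aware flank arithmetic", {
  lay <- genome_layout("chr1", 1e6)
  gp <- data.frame(gene_id = "g", chrom = "chr1", start = 5000, end = 7000,
                   strand = "+")
  r <- build_gene_regions(gp, lay)
  expect_equal(c(r$body$start, r$body$end), c(4000, 8000))
  expect_equal(c(r$promoter$start, r$promoter$end), c(2000, 6000))

  gm <- gp; gm$strand <- "-"
  rm_ <- build_gene_regions(gm, lay)
  expect_equal(c(rm_$body$start, rm_$body$end), c(4000, 8000))
  expect_equal(c(rm_$promoter$start, rm_$promoter$end), c(6000, 10000))

  # invariant: body = gene + 2000, promoter = 4000 bp, both strands
  expect_equal(r$body$end - r$body$start, (7000 - 5000) + 2000)
  expect_equal(r$promoter$end - r$promoter$start, 4000)
  expect_equal(rm_$promoter$end - rm_$promoter$start, 4000)

  # clipping at the chromosome edge
  ge <- data.frame(gene_id = "g", chrom = "chr1", start = 500, end = 900,
                   strand = "+")
  re <- build_gene_regions(ge, lay)
  expect_equal(c(re$promoter$start, re$promoter$end), c(0, 1500))
  expect_equal(re$body$start, 0)
})

test_that("tiling drops terminal partials by default", {
  reg <- data.frame(chrom = "chr1", start = 1000, end = 2500)
  expect_equal(nrow(tile_region(reg)), 3)
  reg$end <- 2600
  t3 <- tile_region(reg)
  expect_equal(nrow(t3), 3)
  expect_equal(t3$end[3], 2500)
  t4 <- tile_region(reg, keep_partial = TRUE)
  expect_equal(nrow(t4), 4)
  expect_equal(t4$end[4], 2600)
  reg$end <- 1499
  expect_warning(t0 <- tile_region(reg), "shorter")
  expect_equal(nrow(t0), 0)
  expect_error(tile_region(reg, tile = 0), "tile width")
})

test_that("the region matrix has 2 groups x 10 sub-bins, midpoint-counted", {
  tile <- data.frame(chrom = "chr1", start = 1000, end = 1500)
  # no reads -> zero matrix of the right shape
  m0 <- region_matrix(tile, NULL, NULL, 1e6, 1e6)
  expect_equal(dim(m0), c(2, 10))
  expect_true(all(m0 == 0))
  expect_equal(rownames(m0), c("treated", "mock"))

  # one read per sub-bin -> uniform row at CPM scale
  rd <- data.frame(chrom = "chr1", start = 1000 + (0:9) * 50,
                   end = 1000 + (0:9) * 50 + 10)
  m1 <- region_matrix(tile, rd, NULL, 1e6, 1e6)
  expect_equal(unname(m1["treated", ]), rep(1, 10))

  # reads outside the tile or on other chromosomes are ignored
  rd2 <- rbind(rd, data.frame(chrom = c("chr1", "chr9"),
                              start = c(5000, 1200), end = c(5010, 1210)))
  expect_equal(sum(region_matrix(tile, rd2, NULL, 1e6, 1e6)["treated", ]), 10)
})

test_that("region t statistic equals the textbook pooled-variance oracle", {
  m <- region_matrix_from_counts(1:10, 2:11)
  tt <- region_ttest(m)
  ref <- oracle_pooled_t(1:10, 2:11)
  expect_equal(tt$t, ref$t, tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p, tolerance = 1e-12)
  expect_equal(tt$t, -0.738548945876, tolerance = 1e-9)
  expect_equal(tt$df, 18)

  # identical rows: t = 0, p = 1
  same <- region_matrix_from_counts(rep(2, 10), rep(2, 10))
  expect_equal(region_ttest(same), list(t = 0, df = 18, p_value = 1))

  # swapping rows negates t
  sw <- region_ttest(region_matrix_from_counts(2:11, 1:10))
  expect_equal(sw$t, -tt$t, tolerance = 1e-12)

  set.seed(71)
  for (i in 1:200) {
    x <- rnorm(10, sd = runif(1, 0.5, 3)); y <- rnorm(10)
    got <- region_ttest(region_matrix_from_counts(x, y))
    ref <- oracle_pooled_t(x, y)
    expect_equal(got$t, ref$t, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  }
})

test_that("combined level is the fixed cell-type-weighted mixture", {
  expect_equal(combined_level(1, 0), 0.28)
  expect_equal(combined_level(0, 1), 0.72)
  for (x in c(0, 0.3, 2.5)) expect_equal(combined_level(x, x), x)
  # linearity and boundedness
  set.seed(72)
  a <- runif(20, 0, 5); b <- runif(20, 0, 5)
  cl <- combined_level(a, b)
  expect_equal(cl, 0.28 * a + 0.72 * b)
  expect_true(all(cl >= pmin(a, b) - 1e-12 & cl <= pmax(a, b) + 1e-12))
  w <- cell_type_weights(0.4)
  expect_equal(combined_level(1, 0, w), 0.4)
  expect_error(combined_level(-1, 0), "non-negative")
  expect_error(cell_type_weights(1.2), "0, 1")
})

test_that("compartment fold changes average member clusters", {
  cm <- expand.grid(gene_id = c("g1", "g2"),
                    cluster = c("Ex1", "In1", "Astro"),
                    group = c("mock", "treated"), stringsAsFactors = FALSE)
  cm$mean_expr <- 1
  # all equal -> log2FC 0 in both compartments
  r0 <- celltype_logfc(cm, c("Ex1", "In1"))
  expect_equal(r0$neuronal_log2fc, c(0, 0))
  expect_equal(r0$non_neuronal_log2fc, c(0, 0))

  # doubling all treated means -> log2FC close to 1 (pseudo-count damped)
  cm2 <- cm; cm2$mean_expr[cm2$group == "treated"] <- 2
  r2 <- celltype_logfc(cm2, c("Ex1", "In1"))
  expect_equal(r2$neuronal_log2fc, rep(log2(2.01 / 1.01), 2))

  # single-cluster compartment equals that cluster's fold change
  r1 <- celltype_logfc(cm2, c("Ex1"))
  expect_equal(r1$neuronal_log2fc, rep(log2(2.01 / 1.01), 2))
  expect_error(celltype_logfc(cm2, character()), "neuronal")
  expect_error(celltype_logfc(cm2, c("Ex1", "In1", "Astro")), "non-neuronal")
})

test_that("IEG summary recovers planted correlations and a permutation null", {
  # exact monotone construction
  per <- data.frame(gene_id = paste0("g", 1:10), is_ieg = TRUE,
                    expr_log2fc = 1:10, hmc_log2fc = (1:10) * 0.5,
                    mec_log2fc = -(1:10) * 0.3)
  s <- ieg_summary(per)
  expect_equal(s$ieg$spearman_rho[s$ieg$mark == "hmc"], 1)
  expect_equal(s$ieg$spearman_rho[s$ieg$mark == "mec"], -1)

  # generator truth: positive 5hmC and negative 5mC correlation
  # (many IEG-like genes so the permutation null is well resolved)
  tr <- simulate_truth(sim_config(n_genes = 120, frac_ieg = 0.85,
                                  n_bg_sites = 100), seed = 73)
  prof <- simulate_ieg_profiles(tr, seed = 73)
  tests <- ieg_region_tests(prof)
  agg <- aggregate(cbind(mean_treated, mean_mock) ~ gene_id + context,
                   data = tests, FUN = mean)
  lfc <- function(ctx) {
    sub <- agg[agg$context == ctx, ]
    setNames(log2((sub$mean_treated + 0.01) / (sub$mean_mock + 0.01)),
             sub$gene_id)
  }
  hmc <- lfc("body")
  e <- simulate_expression(tr, noise_sd = 0.1, seed = 73)
  ids <- intersect(names(hmc), tr$ieg_truth$gene_id)
  per2 <- data.frame(gene_id = ids, is_ieg = TRUE,
                     expr_log2fc = e$log2_fc[match(ids, e$gene_id)],
                     hmc_log2fc = unname(hmc[ids]),
                     mec_log2fc = unname(lfc("promoter")[ids]))
  s2 <- ieg_summary(per2)
  expect_gt(s2$ieg$pearson_r[s2$ieg$mark == "hmc"], 0.5)
  expect_lt(s2$ieg$pearson_r[s2$ieg$mark == "mec"], -0.3)

  # shuffled labels kill the correlation in >= 95% of permutations
  set.seed(74)
  null_ok <- vapply(1:100, function(i) {
    shuf <- per2
    shuf$expr_log2fc <- sample(shuf$expr_log2fc)
    abs(ieg_summary(shuf)$ieg$pearson_r[1]) < 0.3
  }, TRUE)
  expect_gte(mean(null_ok), 0.95)
})
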