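make_sites <- function(meth_mock, meth_treated, total = 10, pos = NULL,
                       chrom = "chr1") {
  n <- nrow(meth_mock)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  cpg_site_table(rep(chrom, n), pos,
                 cbind(meth_mock, meth_treated),
                 matrix(total, n, ncol(meth_mock) + ncol(meth_treated)),
                 c("m1", "m2", "m3", "t1", "t2", "t3"),
                 rep(c("mock", "treated"), each = 3))
}

test_that("site test is symmetric and detects complete separation", {
  # identical counts in both groups: no signal
  same <- make_sites(matrix(5, 1, 3), matrix(5, 1, 3))
  r <- site_test(same)
  expect_gt(r$p_value, 0.9)
  expect_equal(r$meth_diff, 0)

  # complete separation (0/30 pooled vs 30/30 pooled) is overwhelming
  sep <- make_sites(matrix(0, 1, 3), matrix(10, 1, 3))
  rs <- site_test(sep)
  expect_lt(rs$p_value, 1e-6)
  expect_gt(rs$meth_diff, 0.9)

  # label swap negates the difference, leaves p unchanged
  set.seed(41)
  mm <- matrix(rbinom(30, 10, 0.4), 10, 3)
  tt <- matrix(rbinom(30, 10, 0.7), 10, 3)
  r1 <- site_test(make_sites(mm, tt))
  r2 <- site_test(make_sites(tt, mm))
  expect_equal(r1$meth_diff, -r2$meth_diff, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
})

test_that("low-coverage sites are skipped, not tested", {
  tab <- make_sites(matrix(c(0, 5), 2, 3), matrix(c(1, 5), 2, 3),
                    total = matrix(c(2, 10), 2, 6))
  r <- site_test(tab, min_total = 10)
  expect_equal(nrow(r), 1)
  expect_equal(attr(r, "n_skipped"), 1)
})

test_that("DM flagging combines neighbors and adjusts across sites", {
  res <- data.frame(chrom = "chr1", pos = c(1000, 5000, 9000),
                    m_mock = 0.5, m_treated = 0.5, meth_diff = 0,
                    p_value = 1)
  f <- flag_dm_sites(res)
  expect_false(any(f$is_dm))

  # a single isolated site keeps its own p through the combination
  one <- data.frame(chrom = "chr1", pos = 100, m_mock = 0.2,
                    m_treated = 0.6, meth_diff = 0.4, p_value = 0.01)
  f1 <- flag_dm_sites(one)
  expect_equal(f1$combined_p, 0.01, tolerance = 1e-9)
  expect_equal(f1$adj_p, 0.01, tolerance = 1e-9)

  # equal p at well-separated sites: BH leaves them unchanged
  m <- data.frame(chrom = "chr1", pos = (1:5) * 10000, m_mock = 0.2,
                  m_treated = 0.6, meth_diff = 0.4, p_value = 0.04)
  fm <- flag_dm_sites(m)
  expect_equal(fm$adj_p, rep(0.04, 5), tolerance = 1e-9)

  # consistent neighbors within the radius reinforce each other
  near <- data.frame(chrom = "chr1", pos = c(0, 50, 100),
                     m_mock = 0.2, m_treated = 0.6, meth_diff = 0.4,
                     p_value = 0.02)
  fn <- flag_dm_sites(near)
  expect_true(all(fn$combined_p < 0.02))
  # and the combination can be switched off
  f0 <- flag_dm_sites(near, neighbor_radius = 0)
  expect_equal(f0$combined_p, near$p_value)
})

test_that("DM-site merging follows the strict distance rule", {
  res <- data.frame(chrom = "chr1", pos = c(100, 150, 300),
                    m_mock = 0.2, m_treated = 0.6, meth_diff = 0.4,
                    p_value = 1e-4, combined_p = 1e-4, adj_p = 1e-4,
                    is_dm = TRUE)
  cands <- merge_dm_sites(res, merge_gap = 100)
  expect_equal(nrow(cands), 2)
  expect_equal(cands$start, c(100, 300))
  expect_equal(cands$end, c(151, 301))
  expect_equal(cands$n_dm_sites, c(2, 1))

  # distance exactly 100 does not merge ("less than 100")
  res2 <- res[1:2, ]; res2$pos <- c(0, 100)
  expect_equal(nrow(merge_dm_sites(res2, merge_gap = 100)), 2)

  # non-DM sites inside the span are recorded but do not break the chain
  res3 <- data.frame(chrom = "chr1", pos = c(100, 150, 180),
                     m_mock = 0.2, m_treated = 0.6,
                     meth_diff = c(0.4, 0, 0.4), p_value = 1,
                     combined_p = 1, adj_p = 1,
                     is_dm = c(TRUE, FALSE, TRUE))
  c3 <- merge_dm_sites(res3, merge_gap = 100)
  expect_equal(nrow(c3), 1)
  expect_equal(c3$n_dm_sites, 2)
  expect_equal(c3$n_non_dm_inside, 1)
})

test_that("merging equals the brute-force transitive-closure oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    pos <- sort(sample(0:5000, n))
    is_dm <- runif(n) < 0.6
    res <- data.frame(chrom = "chr1", pos = pos, m_mock = 0.2,
                      m_treated = 0.6, meth_diff = 0.4, p_value = 0.001,
                      combined_p = 0.001, adj_p = 0.001, is_dm = is_dm)
    cands <- merge_dm_sites(res, merge_gap = 100)
    comp <- oracle_merge_components(pos[is_dm], gap = 100)
    expect_equal(nrow(cands), length(unique(comp)))
    if (length(comp)) {
      oracle_sizes <- as.integer(table(comp)[order(unique(comp))])
      expect_equal(cands$n_dm_sites, unname(as.integer(table(comp))))
      # every DM site in exactly one candidate; candidates disjoint & sorted
      expect_equal(sum(cands$n_dm_sites), sum(is_dm))
      if (nrow(cands) > 1) {
        expect_true(all(cands$start[-1] >= cands$end[-nrow(cands)]))
      }
    }
  }
})

test_that("candidate filtering applies the site-count and effect thresholds", {
  mk_cand <- function(n_dm, diffs, pos = seq_len(n_dm) * 50) {
    res <- data.frame(chrom = "chr1", pos = pos, m_mock = 0.3,
                      m_treated = 0.3 + diffs, meth_diff = diffs,
                      p_value = 1e-5, combined_p = 1e-5, adj_p = 1e-5,
                      is_dm = TRUE)
    list(cands = merge_dm_sites(res, merge_gap = 100), res = res)
  }
  keep <- mk_cand(6, rep(0.25, 6))
  out <- filter_candidates(keep$cands, results = keep$res)
  expect_equal(nrow(out), 1)
  expect_equal(out$direction, "hyper")

  # 5 DM sites rejected even with a large shift ("more than 5")
  five <- mk_cand(5, rep(0.5, 5))
  expect_equal(nrow(filter_candidates(five$cands, results = five$res)), 0)

  # small mean shift rejected
  weak <- mk_cand(6, rep(0.15, 6))
  expect_equal(nrow(filter_candidates(weak$cands, results = weak$res)), 0)

  # mixed-direction candidates fail the sign-consistency guard but pass
  # in strict literal mode
  mixed <- mk_cand(8, c(rep(0.8, 5), rep(-0.5, 3)))
  expect_equal(nrow(filter_candidates(mixed$cands, results = mixed$res)), 0)
  expect_equal(nrow(filter_candidates(mixed$cands, sign_consistency = NULL)), 1)

  # monotonicity: raising the site threshold never adds DMRs
  set.seed(43)
  res <- data.frame(chrom = "chr1", pos = sort(sample(0:3000, 40)),
                    m_mock = 0.3, m_treated = 0.55, meth_diff = 0.25,
                    p_value = 1e-4, combined_p = 1e-4, adj_p = 1e-4,
                    is_dm = runif(40) < 0.7)
  cands <- merge_dm_sites(res)
  n_prev <- Inf
  for (k in 2:8) {
    n_k <- nrow(filter_candidates(cands, min_dm_sites = k, results = res))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
})
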