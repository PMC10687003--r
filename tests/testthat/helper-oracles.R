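# Independent oracle implementations used to cross-check the package's own
# statistics. Each is a direct enumeration / textbook formula, kept separate
# from the implementation paths they validate.

# two-sided conditional binomial test by exhaustive enumeration: the
# dispersion-0 limit of the exact NB test (equal adjusted libraries)
oracle_cond_binom_p <- function(s_t, s_m, n_t, n_m) {
  tt <- s_t + s_m
  if (tt == 0) return(1)
  pr <- n_t / (n_t + n_m)
  w <- vapply(0:tt, function(s) choose(tt, s) * pr^s * (1 - pr)^(tt - s), 0)
  w <- w / sum(w)
  lower <- sum(w[0:tt <= s_t])
  upper <- sum(w[0:tt >= s_t])
  min(1, 2 * min(lower, upper))
}

# two-sided Fisher exact p by hypergeometric enumeration (sum of all table
# probabilities not exceeding the observed one, with the customary relative
# guard for floating-point ties)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper binomial tail by direct summation
oracle_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 0))
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# brute-force transitive closure of the "distance < gap" relation among DM
# sites on one chromosome; returns a component id per DM site
oracle_merge_components <- function(pos, gap) {
  n <- length(pos)
  if (!n) return(integer())
  adj <- abs(outer(pos, pos, "-")) < gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- comp[adj[i, ]]
      new <- min(linked)
      if (new < comp[i]) { comp[i] <- new; changed <- TRUE }
      if (any(comp[adj[i, ]] > comp[i])) {
        comp[adj[i, ]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# small two-group bin-count fixture built directly (not via the generator)
make_small_counts <- function(counts, group = rep(c("mock", "treated"),
                                                  each = ncol(counts) / 2),
                              lib = NULL, width = 100) {
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(nrow(counts)) - 1) * width,
                     end = seq_len(nrow(counts)) * width)
  ids <- paste0(group, "_", ave(seq_along(group), group, FUN = seq_along))
  if (is.null(lib)) lib <- pmax(colSums(counts), 1)
  bin_counts(bins, counts, ids, group, lib)
}

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(10000, 8000))

# compact generator settings so simulation-backed tests stay fast
small_config <- function(...) {
  sim_config(chrom_lengths = c(chrA = 5e5, chrB = 5e5), n_genes = 40,
             frac_ieg = 0.1, n_cgi = 10, n_repeats = 60, n_gain = 10,
             n_loss = 10, n_hyper = 5, n_hypo = 5, n_bg_sites = 300, ...)
}
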