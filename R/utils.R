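# Seed fan-out: one master seed deterministically yields per-stage child
# seeds (stage index x large odd multipliers, folded below 2^31) so each
# simulation stage can be regenerated independently of the others.
child_seed <- function(master, stage, index = 0L) {
  master <- as.numeric(master) %% 1e6
  as.integer((master * 10007 + stage * 65537 + index * 257) %% 2147483629)
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# log beta-binomial pmf: k successes of n, mean pi, concentration theta
# (alpha = pi*theta, beta = (1-pi)*theta); theta = Inf degenerates to binomial
dbetabinom_log <- function(k, n, pi, theta) {
  if (!is.finite(theta)) return(stats::dbinom(k, n, pi, log = TRUE))
  a <- pi * theta
  b <- (1 - pi) * theta
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

rbetabinom <- function(nobs, size, pi, theta) {
  if (!is.finite(theta)) return(stats::rbinom(nobs, size, pi))
  p <- stats::rbeta(nobs, pi * theta, (1 - pi) * theta)
  stats::rbinom(nobs, size, p)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
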