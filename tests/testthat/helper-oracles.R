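# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: explicit loops, coordinate-wise golden-section search,
# textbook formulas.

# NB log-likelihood of one bin-count row at (b0, bs), dispersion alpha.
oracleLoglik <- function(counts, s, x, b0, bs, alpha) {
  mu <- s * exp(b0 + bs * x)
  if (alpha <= 0) sum(stats::dpois(counts, mu, log = TRUE))
  else sum(stats::dnbinom(counts, size = 1 / alpha, mu = mu, log = TRUE))
}

# Dense grid search followed by coordinate-wise golden-section refinement
# of the same likelihood; independent of the package's Fisher scoring.
oracleShiftFit <- function(counts, s = rep(1, length(counts)),
                           x = c(-1, 0, 0, 1), alpha = 0) {
  b0grid <- seq(log(mean(counts / s) + 0.5) - 3,
                log(mean(counts / s) + 0.5) + 3, by = 0.05)
  bsgrid <- seq(-5, 5, by = 0.05)
  best <- c(b0 = b0grid[1], bs = 0)
  bestll <- -Inf
  for (b0 in b0grid) for (bs in bsgrid) {
    ll <- oracleLoglik(counts, s, x, b0, bs, alpha)
    if (ll > bestll) { bestll <- ll; best <- c(b0 = b0, bs = bs) }
  }
  for (it in 1:60) {
    o1 <- stats::optimize(function(b0)
      oracleLoglik(counts, s, x, b0, best["bs"], alpha),
      interval = best["b0"] + c(-0.1, 0.1), maximum = TRUE, tol = 1e-10)
    best["b0"] <- o1$maximum
    o2 <- stats::optimize(function(bs)
      oracleLoglik(counts, s, x, best["b0"], bs, alpha),
      interval = best["bs"] + c(-0.1, 0.1), maximum = TRUE, tol = 1e-10)
    best["bs"] <- o2$maximum
  }
  best
}

# Brute-force median-of-ratios with explicit loops.
oracleSizeFactors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  mm <- m[keep, , drop = FALSE]
  geo <- apply(mm, 1, function(r) exp(mean(log(r))))
  s <- numeric(ncol(m))
  for (b in seq_len(ncol(m))) s[b] <- median(mm[, b] / geo)
  s / exp(mean(log(s)))
}

# Textbook Welch t-test (Welch-Satterthwaite degrees of freedom).
oracleWelch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(t), df)
}

# Step-up BH with explicit monotonization.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Small deterministic screen fixture used by several tests.
tinyScreen <- function(seed = 101L, nGenes = 30L, ...) {
  simulateScreen(ScreenSimConfig(nGenes = nGenes, nNontargeting = 10L,
                                 seed = seed, ...))
}
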