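# Negative binomial GLM core (log link, fixed dispersion) shared by the
# sort-seq shift model and the translation-efficiency interaction model.
# Parameterization: y ~ NB(mean = mu, variance = mu + alpha * mu^2),
# mu = exp(offset + X %*% beta); alpha = 0 is the Poisson limit.

#' Fit a negative binomial GLM with known dispersion
#'
#' Fisher-scoring fit of a log-link NB regression with fixed dispersion
#' `alpha` (Poisson when `alpha = 0`). Standard errors come from the
#' observed information at the optimum. This is the single estimator behind
#' both the per-sgRNA isoform shift fit and the per-gene translation
#' efficiency interaction fit.
#'
#' @param y nonnegative integer response vector.
#' @param X model matrix (rows match `y`).
#' @param offset numeric offset on the log scale (e.g. log size factors).
#' @param alpha NB dispersion (>= 0).
#' @param tol convergence tolerance on the score vector (max abs).
#' @param maxit maximum Fisher scoring iterations.
#' @return list with `beta`, `se`, `mu`, `loglik`, `converged`, `iter`.
#' @export
fitNbGlm <- function(y, X, offset = rep(0, length(y)), alpha = 0,
                     tol = 1e-8, maxit = 100L) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(y) == nrow(X), length(offset) == length(y), alpha >= 0)
  if (all(y == 0))
    return(list(beta = rep(NA_real_, p), se = rep(NA_real_, p),
                mu = rep(0, length(y)), loglik = NA_real_,
                converged = FALSE, iter = 0L))
  # start: intercept at log mean of offset-corrected counts, others 0
  beta <- numeric(p)
  icpt <- which(apply(X, 2L, function(v) all(v == v[1L])))[1L]
  if (!is.na(icpt))
    beta[icpt] <- log(mean(y / exp(offset)) + 1e-8) / X[1L, icpt]
  ll <- nbLoglik(y, drop(exp(offset + X %*% beta)), alpha)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    mu <- drop(exp(offset + X %*% beta))
    score <- drop(crossprod(X, (y - mu) / (1 + alpha * mu)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu / (1 + alpha * mu)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step halving against divergence
    fac <- 1
    repeat {
      cand <- beta + fac * step
      llc <- nbLoglik(y, drop(exp(offset + X %*% cand)), alpha)
      if (is.finite(llc) && llc >= ll - 1e-12) { beta <- cand; ll <- llc; break }
      fac <- fac / 2
      if (fac < 1e-10) break
    }
    if (fac < 1e-10) break
  }
  mu <- drop(exp(offset + X %*% beta))
  wobs <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  infoObs <- crossprod(X, X * wobs)
  se <- tryCatch(sqrt(diag(solve(infoObs))), error = function(e)
    rep(NA_real_, p))
  list(beta = beta, se = se, mu = mu, loglik = ll,
       converged = converged, iter = it)
}

#' NB log-likelihood at fixed mean and dispersion
#'
#' @param y counts; @param mu means; @param alpha dispersion (0 = Poisson).
#' @return total log-likelihood.
#' @export
nbLoglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-300)
  if (alpha <= 0) return(sum(dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood for alpha given a design:
# l(alpha, betahat(alpha)) - 0.5 * log det(X' W X).
crAdjustedLoglik <- function(logAlpha, y, X, offset) {
  alpha <- exp(logAlpha)
  fit <- fitNbGlm(y, X, offset, alpha)
  if (!is.finite(fit$loglik)) return(-Inf)
  w <- fit$mu / (1 + alpha * fit$mu)
  d <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  fit$loglik - 0.5 * as.numeric(d)
}

# Per-row Cox-Reid ML dispersion (profile over beta), optimized on the log
# scale within [minAlpha, maxAlpha].
crmlDispersion <- function(y, X, offset, minAlpha = 1e-8, maxAlpha = 30) {
  if (all(y == 0) || length(unique(y)) == 1L) return(NA_real_)
  opt <- optimize(function(la) crAdjustedLoglik(la, y, X, offset),
                  interval = log(c(minAlpha, maxAlpha)), maximum = TRUE,
                  tol = 1e-4)
  exp(opt$maximum)
}

#' Estimate per-row NB dispersions with trend shrinkage
#'
#' Per-row Cox-Reid adjusted maximum-likelihood dispersions are fit first,
#' then a parametric mean-dispersion trend `alpha(mu) = a0 + a1 / mu` is
#' estimated across rows, and each row's final dispersion is the posterior
#' mode under a log-normal prior centered on the trend. With only a handful
#' of observations per row (four bins), the trend carries most of the
#' information; rows whose own likelihood is degenerate fall back to the
#' trend value.
#'
#' @param counts integer matrix, rows = features (sgRNAs or genes).
#' @param sizeFactors positive per-column size factors.
#' @param X model matrix shared by all rows (default intercept + nothing;
#'   pass the bin-covariate or interaction design).
#' @param priorVar variance of the log-normal prior around the trend
#'   (log scale). Small values shrink hard, appropriate when each row
#'   contributes few observations.
#' @param trendRows optional logical mask of rows eligible for trend
#'   fitting (e.g. excluding low-coverage rows).
#' @param minAlpha dispersion floor.
#' @return list with `alpha` (final per-row), `alphaGenewise`, `alphaTrend`
#'   (per-row trend value), `trendCoef` (a0, a1), `method`.
#' @export
estimateDispersions <- function(counts, sizeFactors,
                                X = cbind(rep(1, ncol(counts))),
                                priorVar = 0.25,
                                trendRows = NULL,
                                minAlpha = 1e-8) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 20L)
    warning("fewer than 20 rows; dispersion trend will be unstable")
  offset <- log(sizeFactors)
  baseMean <- rowMeans(sweep(counts, 2L, sizeFactors, "/"))
  aGene <- vapply(seq_len(n), function(i)
    crmlDispersion(counts[i, ], X, offset, minAlpha = minAlpha),
    numeric(1))
  if (is.null(trendRows)) trendRows <- rep(TRUE, n)
  usable <- trendRows & is.finite(aGene) & baseMean > 0
  use <- usable & aGene > 1e-7
  trendCoef <- c(a0 = NA_real_, a1 = NA_real_)
  method <- "parametric"
  if (sum(usable) > 0L && mean(aGene[usable] <= 1e-7) > 0.5) {
    # most rows profile to the dispersion floor: effectively Poisson data,
    # center the prior at the (floor-dominated) median
    method <- "near-poisson"
    trendCoef <- c(a0 = max(median(aGene[usable]), minAlpha), a1 = 0)
  } else if (sum(use) >= 10L) {
    fit <- tryCatch({
      dat <- data.frame(a = aGene[use], invMu = 1 / baseMean[use])
      g <- stats::glm(a ~ invMu, data = dat,
                      family = stats::Gamma(link = "identity"),
                      start = c(0.1, 1))
      cf <- stats::coef(g)
      if (any(!is.finite(cf)) || cf[1L] < 0 || cf[2L] < 0) NULL else cf
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      # nonnegative least-squares fallback before giving up on the trend
      ls <- stats::coef(stats::lm(aGene[use] ~ I(1 / baseMean[use])))
      ls <- pmax(ls, 0)
      if (any(ls > 0)) {
        method <- "least-squares"
        trendCoef <- c(a0 = unname(ls[1L]), a1 = unname(ls[2L]))
      } else {
        method <- "median-fallback"
        med <- median(aGene[use])
        trendCoef <- c(a0 = med, a1 = 0)
        warning("dispersion trend fit failed; using median dispersion")
      }
    } else trendCoef <- c(a0 = unname(fit[1L]), a1 = unname(fit[2L]))
  } else {
    method <- "median-fallback"
    med <- if (any(use)) median(aGene[use]) else 0.01
    trendCoef <- c(a0 = med, a1 = 0)
  }
  aTrend <- pmax(trendCoef[["a0"]] + trendCoef[["a1"]] / pmax(baseMean, 1e-8),
                 minAlpha)
  # Posterior mode: maximize CR loglik + log-normal prior around the trend.
  aFinal <- vapply(seq_len(n), function(i) {
    y <- counts[i, ]
    if (all(y == 0) || length(unique(y)) == 1L) return(aTrend[i])
    lp <- function(la)
      crAdjustedLoglik(la, y, X, offset) -
        (la - log(aTrend[i]))^2 / (2 * priorVar)
    opt <- optimize(lp, interval = log(c(minAlpha, 30)), maximum = TRUE,
                    tol = 1e-4)
    exp(opt$maximum)
  }, numeric(1))
  list(alpha = pmax(aFinal, minAlpha), alphaGenewise = aGene,
       alphaTrend = aTrend, trendCoef = trendCoef, method = method,
       baseMean = baseMean)
}

#' Single pooled moment-based dispersion
#'
#' Method-of-moments dispersion pooled across rows: for each row the excess
#' of the variance of size-factor-normalized counts over their mean, scaled
#' by the squared mean; the pooled estimate is the median over informative
#' rows. Provided as a transparent alternative to trend shrinkage.
#'
#' @inheritParams estimateDispersions
#' @return single dispersion value (>= 0).
#' @export
pooledDispersion <- function(counts, sizeFactors) {
  norm <- sweep(as.matrix(counts), 2L, sizeFactors, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  ok <- m > 0 & is.finite(v)
  a <- (v[ok] - m[ok]) / m[ok]^2
  max(median(a), 0)
}
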