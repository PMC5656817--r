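## Bayesian machinery: univariate slice sampling over SSE likelihoods with
## independent exponential priors, posterior summaries, hypothesis
## probabilities, harmonic-mean Bayes factors and AIC weights.

#' MCMC configuration
#'
#' @param generations Number of sweeps; each sweep updates every free
#'   parameter once by slice sampling.
#' @param priorMean Mean of the independent exponential prior placed on
#'   every free parameter (rate = 1/priorMean).  Default 0.5
#'   events/lineage/Myr, a broad prior on this time scale.
#' @param burnin Fraction of initial samples discarded (default 10%).
#' @param thin Keep every `thin`-th sweep (default 1, no thinning).
#' @param seed Integer seed; every run is reproducible given the seed.
#' @param sliceWidth Initial slice bracket width; defaults to `priorMean`.
#' @return An `mcmc_config`.
#' @export
mcmcConfig <- function(generations = 5000, priorMean = 0.5, burnin = 0.1,
                       thin = 1, seed = 1, sliceWidth = priorMean) {
  stopifnot(generations > 0, burnin >= 0, burnin < 1, priorMean > 0,
            thin >= 1, sliceWidth > 0)
  structure(list(generations = as.integer(generations),
                 priorMean = priorMean, burnin = burnin,
                 thin = as.integer(thin), seed = as.integer(seed),
                 sliceWidth = sliceWidth),
            class = "mcmc_config")
}

#' Slice-sampling MCMC over a log-likelihood
#'
#' Runs Neal's univariate slice sampler (stepping-out and shrinkage) on
#' each free parameter in turn, one full sweep per generation, targeting
#' `loglik + log prior` with independent exponential priors.  Parameters
#' are sampled on the natural scale with the slice interval truncated at 0,
#' so the exponential prior is exact.
#'
#' @param loglik Function of a numeric parameter vector returning a
#'   log-likelihood (may return `-Inf`).
#' @param npar Number of parameters, or a character vector of names.
#' @param config An [mcmcConfig()].
#' @param init Initial point; default the prior-mean vector.  If `loglik`
#'   is `-Inf` there, up to 20 re-initializations are drawn from the prior.
#' @return A `posterior_samples`: list with matrix `pars` (post burn-in,
#'   post thinning), vectors `loglik` and `logprior`, and `config`.
#' @export
sliceSample <- function(loglik, npar, config = mcmcConfig(), init = NULL) {
  parNames <- if (is.character(npar)) npar else paste0("p", seq_len(npar))
  np <- length(parNames)
  rate <- 1 / config$priorMean
  logpost <- function(x) {
    ll <- loglik(x)
    if (!is.finite(ll)) return(list(ll = -Inf, lp = -Inf, post = -Inf))
    lp <- sum(dexp(x, rate = rate, log = TRUE))
    list(ll = ll, lp = lp, post = ll + lp)
  }
  set.seed(config$seed)
  x <- if (is.null(init)) rep(config$priorMean, np) else rep_len(init, np)
  cur <- logpost(x)
  tries <- 0
  while (!is.finite(cur$post) && tries < 20) {
    x <- rexp(np, rate = rate)
    cur <- logpost(x)
    tries <- tries + 1
  }
  if (!is.finite(cur$post))
    stop("log-likelihood is -Inf at the initial point and at 20 prior draws")

  w <- rep(config$sliceWidth, np) # per-parameter slice widths
  ngen <- config$generations
  nburn <- floor(config$burnin * ngen)
  out <- matrix(NA_real_, ngen, np, dimnames = list(NULL, parNames))
  outll <- numeric(ngen)
  outlp <- numeric(ngen)
  for (g in seq_len(ngen)) {
    for (j in seq_len(np)) {
      z <- cur$post - rexp(1) # log slice height
      # stepping out, truncated at 0
      u <- runif(1)
      L <- max(0, x[j] - u * w[j])
      R <- L + w[j]
      xj <- x[j]
      evalAt <- function(v) {
        x[j] <- v
        logpost(x)
      }
      if (L > 0) {
        repeat {
          if (evalAt(L)$post <= z) break
          L <- max(0, L - w[j])
          if (L == 0) break
        }
      }
      repeat {
        if (evalAt(R)$post <= z) break
        R <- R + w[j]
      }
      # shrinkage
      repeat {
        xn <- runif(1, L, R)
        cand <- evalAt(xn)
        if (cand$post > z) {
          x[j] <- xn
          cur <- cand
          # during burn-in, tune the width toward the local slice scale
          if (g <= nburn)
            w[j] <- max(0.85 * w[j] + 0.15 * (2 * (R - L)), 1e-6)
          break
        }
        if (xn < xj) L <- xn else R <- xn
        if (R - L < 1e-300) { # degenerate slice; keep current point
          x[j] <- xj
          cur <- evalAt(xj)
          break
        }
      }
    }
    out[g, ] <- x
    outll[g] <- cur$ll
    outlp[g] <- cur$lp
  }
  keep <- seq_len(ngen) > floor(config$burnin * ngen)
  keep <- which(keep)
  keep <- keep[(seq_along(keep) - 1) %% config$thin == 0]
  structure(list(pars = out[keep, , drop = FALSE], loglik = outll[keep],
                 logprior = outlp[keep], config = config,
                 parNames = parNames),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples:", nrow(x$pars), "draws x", ncol(x$pars),
      "parameter(s) [", paste(x$parNames, collapse = ", "), "]\n")
  invisible(x)
}

#' Posterior probability of a condition
#'
#' The fraction of retained MCMC draws satisfying a predicate, i.e. the
#' posterior probability of the corresponding hypothesis (e.g. extinction
#' exceeds speciation in cave lineages).
#'
#' @param samples A `posterior_samples`, or a matrix of draws.
#' @param predicate Function taking a named parameter vector (one draw) and
#'   returning `TRUE`/`FALSE`.
#' @return Probability in `[0, 1]`.
#' @export
posteriorProbability <- function(samples, predicate) {
  m <- if (inherits(samples, "posterior_samples")) samples$pars else as.matrix(samples)
  if (nrow(m) < 1) stop("no retained samples")
  hits <- vapply(seq_len(nrow(m)), function(i) {
    v <- predicate(m[i, ])
    if (is.na(v)) stop("predicate returned NA (unknown parameter?)")
    isTRUE(v)
  }, TRUE)
  mean(hits)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; ties are broken toward the lowest start.
#'
#' @param x Numeric draws of one parameter or derived scalar (`n >= 10`).
#' @param mass Posterior mass (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
hpdInterval <- function(x, mass = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10) stop("need at least 10 draws for an HPD interval")
  s <- sort(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths) # which.min takes the first (lowest-start) tie
  c(s[i], s[i + m - 1])
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with empirical autocorrelations summed under
#' the initial-positive-sequence rule (stop before the first lag pair whose
#' sum is non-positive), capped at `n`.
#'
#' @param x Numeric chain (`n >= 10`).
#' @return Effective sample size.
#' @export
essChain <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 draws")
  if (var(x) == 0) {
    warning("zero-variance chain; reporting ESS = n")
    return(n)
  }
  rho <- acf(x, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[-1]
  ssum <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    ssum <- ssum + pair
    k <- k + 2
  }
  min(n, n / (1 + 2 * ssum))
}

#' Harmonic-mean Bayes factor between two chains
#'
#' Marginal likelihoods are estimated by the harmonic mean of the per-draw
#' likelihoods, computed stably in log space
#' (`ln m = -logmeanexp(-loglik)`), and compared as `2 (ln m1 - ln m0)`.
#' The harmonic-mean estimator is high-variance; a bootstrap standard
#' error of each `ln m` is attached so downstream comparisons can carry a
#' tolerance.
#'
#' @param loglik1,loglik0 Per-draw log-likelihood vectors (or
#'   `posterior_samples`) for the two models (1 = alternative, 0 = null).
#' @param nBoot Bootstrap replicates for the standard errors.
#' @return `2 ln BF` with attributes `lnMarg1`, `lnMarg0`, `se1`, `se0`.
#' @export
bayesFactorHarmonic <- function(loglik1, loglik0, nBoot = 200) {
  ll1 <- if (inherits(loglik1, "posterior_samples")) loglik1$loglik else loglik1
  ll0 <- if (inherits(loglik0, "posterior_samples")) loglik0$loglik else loglik0
  if (length(ll1) == 0 || length(ll0) == 0) stop("empty chain")
  lnm1 <- harmonicMeanLogLik(ll1)
  lnm0 <- harmonicMeanLogLik(ll0)
  se <- function(ll) {
    reps <- vapply(seq_len(nBoot), function(i)
      harmonicMeanLogLik(sample(ll, length(ll), replace = TRUE)), 1.0)
    sd(reps)
  }
  structure(2 * (lnm1 - lnm0), lnMarg1 = lnm1, lnMarg0 = lnm0,
            se1 = se(ll1), se0 = se(ll0))
}

# -logmeanexp(-ll), stable in log space
harmonicMeanLogLik <- function(ll) {
  x <- -ll
  m <- max(x)
  -(m + log(mean(exp(x - m))))
}

#' Akaike weights for a set of fitted models
#'
#' `AIC = 2k - 2 lnL`; weights are proportional to `exp(-dAIC/2)` and sum
#' to 1.  Models with non-finite `lnL` are excluded with a warning and get
#' weight `NA`.
#'
#' @param logLik Numeric vector of maximized log-likelihoods.
#' @param k Integer vector of free-parameter counts.
#' @return Data frame with `logLik`, `k`, `AIC`, `dAIC`, `weight`.
#' @export
aicWeights <- function(logLik, k) {
  if (length(logLik) < 2) stop("need at least two models")
  stopifnot(length(logLik) == length(k))
  ok <- is.finite(logLik)
  if (any(!ok)) warning(sum(!ok), " model(s) with non-finite lnL excluded")
  aic <- 2 * k - 2 * logLik
  d <- aic - min(aic[ok])
  w <- rep(NA_real_, length(aic))
  ew <- exp(-d[ok] / 2)
  w[ok] <- ew / sum(ew)
  data.frame(logLik = logLik, k = k, AIC = aic, dAIC = d, weight = w)
}

#' Maximum-likelihood fit of an SSE model
#'
#' Derivative-free local optimization (Nelder-Mead on log-rates) from
#' `nStarts` random starting points drawn from the exponential prior; the
#' best local optimum is returned.  Zero-valued fixed parameters stay
#' fixed (the optimization is over the model's free parameters only).
#'
#' @param model An `sse_model` (possibly constrained).
#' @param nStarts Number of random restarts (default 10).
#' @param priorMean Mean of the exponential used to draw starts.
#' @param seed Seed for the start draws.
#' @param maxit Iteration cap per start.
#' @return List with `par` (named, free parameters), `logLik`, `k`,
#'   `convergence`, and `starts` (per-start log-likelihoods).
#' @export
fitMLSse <- function(model, nStarts = 10, priorMean = 0.5, seed = 1,
                     maxit = 500) {
  stopifnot(inherits(model, "sse_model"))
  free <- model$free
  np <- length(free)
  negll <- function(logx) {
    # bounded domain: rates above e^3 ~ 20 events/Myr are far outside any
    # plausible regime and make the ODEs needlessly stiff
    if (any(logx > 3) || any(logx < -12)) return(1e10)
    v <- exp(logx)
    ll <- model$loglik(setNames(v, free))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  starts <- matrix(rexp(nStarts * np, rate = 1 / priorMean), nStarts, np)
  best <- NULL
  startLL <- numeric(nStarts)
  for (i in seq_len(nStarts)) {
    fit <- tryCatch(
      optim(log(pmax(starts[i, ], 1e-8)), negll, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) { startLL[i] <- -Inf; next }
    startLL[i] <- -fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  list(par = setNames(exp(best$par), free), logLik = -best$value, k = np,
       convergence = best$convergence, starts = startLL)
}
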