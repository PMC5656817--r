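test_that("slice sampler reproduces the exponential prior under a flat likelihood", {
  cfg <- mcmcConfig(generations = 5000, seed = 7, burnin = 0)
  post <- sliceSample(function(x) 0, 3, cfg)
  for (j in 1:3) {
    draws <- post$pars[, j]
    mcse <- sd(draws) / sqrt(essChain(draws)) # autocorrelation-aware MC error
    expect_lt(abs(mean(draws) - 0.5), 3 * mcse)
  }
  # second moment of Exp(0.5): E[X^2] = 2 * 0.25
  expect_equal(mean(post$pars^2), 0.5, tolerance = 0.08)
})

test_that("fixed seed gives a bit-identical draw sequence", {
  f <- function(x) -sum((x - 0.3)^2) * 50
  a <- sliceSample(f, 2, mcmcConfig(generations = 200, seed = 3))
  b <- sliceSample(f, 2, mcmcConfig(generations = 200, seed = 3))
  expect_identical(a$pars, b$pars)
  c <- sliceSample(f, 2, mcmcConfig(generations = 200, seed = 4))
  expect_false(identical(a$pars, c$pars))
})

test_that("slice sampler posterior matches quadrature on a 1-D target", {
  # Gaussian-like log-likelihood; posterior = prior x likelihood on (0, inf)
  ll <- function(x) -((x - 0.8)^2) / (2 * 0.04)
  post <- sliceSample(ll, 1, mcmcConfig(generations = 20000, seed = 11,
                                        burnin = 0.1))
  dens <- function(x) exp(ll(x)) * dexp(x, 2)
  Z <- integrate(dens, 0, Inf)$value
  qf <- function(p) uniroot(function(u)
    integrate(dens, 0, u)$value / Z - p, c(1e-6, 5))$root
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_equal(unname(quantile(post$pars[, 1], p, type = 7)), qf(p),
                 tolerance = 0.02)
  }
})

test_that("posterior probabilities are draw fractions", {
  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "a"))
  expect_equal(posteriorProbability(m, function(p) TRUE), 1)
  expect_equal(posteriorProbability(m, function(p) FALSE), 0)
  expect_equal(posteriorProbability(m, function(p) p["a"] > 2), 0.5)
  # complement rule is exact
  pred <- function(p) p["a"] > 2.5
  expect_equal(posteriorProbability(m, pred) +
                 posteriorProbability(m, function(p) !pred(p)), 1)
  expect_error(posteriorProbability(m, function(p) p["zz"] > 1), "NA")
})

test_that("HPD intervals are the shortest windows, ties to the lowest start", {
  expect_equal(hpdInterval(rep(3, 20)), c(3, 3))
  x <- 1:100
  expect_equal(hpdInterval(x, 0.95), c(1, 95)) # uniform grid: first window
  # exhaustive window-search oracle on irregular draws
  set.seed(5)
  y <- rgamma(61, 2, 3)
  m <- ceiling(0.95 * 61)
  s <- sort(y)
  widths <- vapply(seq_len(61 - m + 1), function(i) s[i + m - 1] - s[i], 1.0)
  i <- which.min(widths)
  expect_equal(hpdInterval(y, 0.95), c(s[i], s[i + m - 1]))
  # large-sample normal endpoints
  set.seed(6)
  z <- rnorm(1e5)
  h <- hpdInterval(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  expect_error(hpdInterval(1:5), "at least 10")
})

test_that("ESS follows the initial-positive-sequence estimator", {
  set.seed(8)
  x <- rnorm(1e4)
  expect_gt(essChain(x), 0.9 * 1e4)
  expect_lte(essChain(x), 1e4)
  # alternating series has negative lag-1 autocorrelation: ESS capped at n
  alt <- rep(c(0, 1), 500)
  expect_gt(essChain(alt), 500)
  # AR(1) with phi = 0.9: ESS ~= n (1 - phi) / (1 + phi)
  set.seed(9)
  n <- 2e4; phi <- 0.9
  ar <- numeric(n); for (i in 2:n) ar[i] <- phi * ar[i - 1] + rnorm(1)
  expect_equal(essChain(ar), n * (1 - phi) / (1 + phi), tolerance = 0.2)
  expect_warning(essChain(rep(2, 100)), "zero-variance")
})

test_that("harmonic-mean Bayes factors follow the log-space formula", {
  ll <- c(-5, -6, -7)
  expect_equal(bayesFactorHarmonic(ll, ll, nBoot = 10), 0, ignore_attr = TRUE)
  # constant log-likelihoods differing by delta give 2 * delta
  delta <- 1.7
  expect_equal(as.numeric(bayesFactorHarmonic(rep(-3 + delta, 50),
                                              rep(-3, 50), nBoot = 10)),
               2 * delta, tolerance = 1e-12)
  # hand-computed harmonic mean of likelihoods exp(-1), exp(-2), exp(-3)
  hand <- -log(mean(exp(c(1, 2, 3))))
  bf <- bayesFactorHarmonic(c(-1, -2, -3), c(-1, -2, -3), nBoot = 10)
  expect_equal(attr(bf, "lnMarg1"), hand, tolerance = 1e-12)
  expect_error(bayesFactorHarmonic(numeric(0), ll), "empty")
})

test_that("AIC weights are normalized and match the closed form", {
  w <- aicWeights(c(-10, -10), c(3, 3))
  expect_equal(w$weight, c(0.5, 0.5))
  # dAIC = 2 between two models: e^-1 / (1 + e^-1)
  w2 <- aicWeights(c(-10, -10), c(3, 4))
  expect_equal(w2$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 0.001)
  set.seed(10)
  w3 <- aicWeights(rnorm(5, -100, 5), c(2, 4, 6, 8, 10))
  expect_equal(sum(w3$weight), 1, tolerance = 1e-12)
  expect_warning(w4 <- aicWeights(c(-10, NA, -12), c(2, 2, 2)), "excluded")
  expect_true(is.na(w4$weight[2]))
  expect_equal(sum(w4$weight, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("multi-start ML reaches at least the best MCMC draw's likelihood", {
  set.seed(12)
  sim <- simulateSseForward("bisse",
                            c(lambda0 = 0.3, lambda1 = 0.15, mu0 = 0.05,
                              mu1 = 0.05, q01 = 0.05, q10 = 0.05),
                            40, "0", seed = 31)
  m <- makeSseModel("bisse", sim$tree, sim$states)
  post <- sliceSample(function(x) m$loglik(setNames(x, m$free)), m$free,
                      mcmcConfig(generations = 150, seed = 5))
  fit <- fitMLSse(m, nStarts = 5, seed = 6)
  expect_gte(fit$logLik, max(post$loglik) - 1e-6)
  expect_equal(fit$k, 6)
})
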