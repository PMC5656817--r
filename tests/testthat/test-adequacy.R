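yulePars <- c(lambda0 = 0.3, lambda1 = 0, mu0 = 0, mu1 = 0, q01 = 0, q10 = 0)

test_that("forward simulation honors trivial regimes and the tip target", {
  sim <- simulateSseForward("bisse",
                            c(lambda0 = 0.4, lambda1 = 0.4, mu0 = 0, mu1 = 0,
                              q01 = 0, q10 = 0), 25, "0", seed = 1)
  expect_equal(ape::Ntip(sim$tree), 25)
  expect_true(all(sim$states == "0"))
  expect_true(ultrametricityCheck(sim$tree)$ok)
})

test_that("a fixed seed reproduces Newick and states exactly", {
  p <- c(lambda0 = 0.3, lambda1 = 0.25, mu0 = 0.05, mu1 = 0.05,
         q01 = 0.1, q10 = 0.1)
  a <- simulateSseForward("bisse", p, 40, "0", seed = 7)
  b <- simulateSseForward("bisse", p, 40, "0", seed = 7)
  expect_identical(writeTimeTree(a$tree), writeTimeTree(b$tree))
  expect_identical(a$states, b$states)
})

test_that("pure-birth extant counts match the branching-process mean", {
  set.seed(2)
  lam <- 0.3; horizon <- 6
  counts <- replicate(600, {
    s <- simulateSseForward("bisse", yulePars, 2, "0", stop = "age",
                            maxT = horizon, maxRetry = 1)
    length(s$states)
  })
  expected <- exp(lam * horizon)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("single-lineage extinction matches the closed form", {
  set.seed(3)
  lam <- 0.2; mu <- 0.1; horizon <- 8
  p <- c(lambda0 = lam, lambda1 = 0, mu0 = mu, mu1 = 0, q01 = 0, q10 = 0)
  ext <- replicate(2000, {
    s <- simulateSseForward("bisse", p, 2, "0", stop = "age",
                            maxT = horizon, maxRetry = 1)
    length(s$states) == 0
  })
  pext <- mu * (exp((lam - mu) * horizon) - 1) /
    (lam * exp((lam - mu) * horizon) - mu)
  se <- sqrt(pext * (1 - pext) / 2000)
  expect_lt(abs(mean(ext) - pext), 4 * se)
})

test_that("GeoSSE reachability: no dispersal means no state change from B", {
  p <- c(sA = 0.3, sB = 0.3, sAB = 0.1, xA = 0.02, xB = 0.02, dA = 0, dB = 0)
  sim <- simulateSseForward("geosse", p, 30, "B", seed = 4)
  expect_true(all(sim$states == "B"))
})

test_that("conditioned simulation returns exactly the requested counts", {
  p <- c(lambda0 = 0.3, lambda1 = 0.3, mu0 = 0.03, mu1 = 0.03,
         q01 = 0.3, q10 = 0.3)
  for (seed in 1:5) {
    sim <- simulateConditioned("bisse", p, c("0" = 6, "1" = 6), "0",
                               seed = seed)
    expect_equal(unname(table(factor(sim$states, levels = c("0", "1")))),
                 c(6L, 6L), ignore_attr = TRUE)
    expect_equal(sim$mode, "conditioned")
    expect_true(attr(sim, "acceptance") > 0 && attr(sim, "acceptance") <= 1)
  }
  expect_error(simulateConditioned("bisse", p, c("0" = 11, "1" = 1), "0",
                                   seed = 1, maxAttempts = 5),
               "no simulation matched")
})

test_that("conditioned SSCD agrees with count-matched forward SSCD", {
  p <- c(lambda0 = 0.3, lambda1 = 0.3, mu0 = 0.02, mu1 = 0.02,
         q01 = 0.25, q10 = 0.25)
  set.seed(6)
  condS <- replicate(40, {
    s <- simulateConditioned("bisse", p, c("0" = 5, "1" = 5), "0")
    sscd(s$tree, s$states)
  })
  fwd <- c()
  while (length(fwd) < 40) {
    s <- simulateSseForward("bisse", p, 10, "0")
    if (sum(s$states == "0") == 5) fwd <- c(fwd, sscd(s$tree, s$states))
  }
  expect_gt(t.test(condS, fwd)$p.value, 0.001)
})

test_that("tip-count chi-squared follows the stated formula", {
  cm <- matrix(rep(c(30, 70), each = 40), 40, 2,
               dimnames = list(NULL, c("0", "1")))
  res <- tipCountTest(c("0" = 30, "1" = 70), cm)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # hand arithmetic: observed (10, 90) vs expected (50, 50)
  cm2 <- matrix(rep(c(50, 50), each = 40), 40, 2,
                dimnames = list(NULL, c("0", "1")))
  res2 <- tipCountTest(c("0" = 10, "1" = 90), cm2)
  expect_equal(res2$statistic, 64)
  expect_lt(res2$p, 1e-10)
  expect_equal(res2$df, 1)
  # three states: df = 2
  cm3 <- matrix(rep(c(20, 30, 50), each = 40), 40, 3,
                dimnames = list(NULL, c("A", "B", "AB")))
  expect_equal(tipCountTest(c(A = 20, B = 30, AB = 50), cm3)$df, 2)
  expect_error(tipCountTest(c("0" = 1, "1" = 1), cm[1:5, ]), ">= 30")
  expect_warning(
    res4 <- tipCountTest(c("0" = 5, "1" = 95),
                         matrix(rep(c(0, 100), each = 40), 40, 2,
                                dimnames = list(NULL, c("0", "1")))),
    "never simulated")
  expect_equal(res4$p, 0)
})

test_that("SSCD reproduces hand-enumerated values", {
  tr <- readTimeTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(sscd(tr, c(A = 0, B = 0, C = 1, D = 1)), 1)
  expect_equal(sscd(tr, c(A = 0, B = 0, C = 0, D = 0)), 0)
  expect_equal(sscd(tr, c(A = 0, B = 1, C = 0, D = 1)), 2)
})

test_that("SSCD distributions are label-swap invariant under state-independent rates", {
  p <- c(lambda0 = 0.3, lambda1 = 0.3, mu0 = 0.05, mu1 = 0.05,
         q01 = 0.2, q10 = 0.2)
  set.seed(8)
  vals <- replicate(60, {
    s <- simulateSseForward("bisse", p, 30, "0")
    flip <- setNames(ifelse(s$states == "0", "1", "0"), names(s$states))
    c(sscd(s$tree, s$states), sscd(s$tree, flip))
  })
  expect_equal(vals[1, ], vals[2, ]) # per-tree statistic is exactly symmetric
})

test_that("SSCD comparison covers and rejects where it should", {
  set.seed(9)
  simv <- rnorm(200, 10, 1)
  obs <- rnorm(20, 10, 1)
  res <- sscdComparison(obs, simv)
  expect_gt(res$p, 0.001)
  expect_gt(res$coverage95, 0.7)
  far <- obs + 100
  res2 <- sscdComparison(far, simv)
  expect_lt(res2$p, 1e-10)
  expect_equal(res2$coverage95, 0)
  # shifting the simulated values flips the t sign with the shift
  up <- sscdComparison(obs, simv + 50)
  dn <- sscdComparison(obs, simv - 50)
  expect_lt(up$t, 0)
  expect_gt(dn$t, 0)
  expect_error(sscdComparison(1, simv), ">= 2")
})
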