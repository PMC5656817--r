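## Felsenstein's threshold model: a binary trait is governed by the sign of
## an unobserved continuous "liability"; liability and an observed
## continuous trait (here log10 range size in km^2) evolve by correlated
## Brownian motion on the tree.  The target of inference is the
## correlation r of the 2x2 trait rate matrix R, with the liability
## variance fixed at 1 for identifiability, so
## R = [[1, r*sigma], [r*sigma, sigma^2]].
##
## Sampler: Gibbs updates of tip liabilities from their truncated-normal
## full conditionals (ancestral liabilities are integrated out analytically
## through the tree covariance C = vcv(tree)), Metropolis updates of r
## (uniform(-1,1) prior) and of log sigma (flat prior), and joint Gibbs
## updates of the two root means (flat prior; generalized-least-squares
## conditional).  Proposal scales adapt during burn-in, then freeze.

#' Bundle data for a threshold-model analysis
#'
#' @param tree A `phylo` (`>= 4` tips).
#' @param states Named binary vector over tip labels; state 0 corresponds
#'   to negative liability (the focal specialist is coded 0).
#' @param trait Named continuous trait over tip labels.
#' @return A `threshold_data` restricted to tips carrying both traits.
#' @export
thresholdData <- function(tree, states, trait) {
  common <- Reduce(intersect, list(tree$tip.label, names(states), names(trait)))
  if (length(common) < 4) stop("need >= 4 tips with both traits")
  if (length(common) < ape::Ntip(tree)) tree <- pruneToTaxa(tree, common)
  s <- as.integer(as.character(states[tree$tip.label]))
  if (any(is.na(s)) || !all(s %in% 0:1)) stop("states must be 0/1")
  if (length(unique(s)) < 2)
    stop("both binary states must be present (r is unidentifiable otherwise)")
  y <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(y))) stop("non-finite continuous trait value")
  structure(list(tree = tree, states = setNames(s, tree$tip.label),
                 trait = setNames(y, tree$tip.label)),
            class = "threshold_data")
}

#' Threshold-model MCMC
#'
#' Samples the joint posterior of the liability-trait correlation `r`, the
#' continuous-trait Brownian variance, the root means and the tip
#' liabilities.  Every retained liability draw sign-matches its tip's
#' binary state (state 0 = negative liability).
#'
#' @param data A [thresholdData()].
#' @param config An [mcmcConfig()]; `generations` are full sweeps.  The
#'   default here is 4000 sweeps with 25% burn-in.
#' @return A `threshold_posterior`: draws of `r`, `sigma`, the means, the
#'   per-draw log-likelihood, a thinned matrix of liability draws, plus
#'   `ess`, `hpd` and the posterior mean of `r`.
#' @export
thresholdMcmc <- function(data,
                          config = mcmcConfig(generations = 4000,
                                              burnin = 0.25)) {
  stopifnot(inherits(data, "threshold_data"))
  tree <- data$tree
  n <- ape::Ntip(tree)
  C <- ape::vcv(tree)
  W <- tryCatch(solve(C), error = function(e)
    stop("singular tree covariance matrix"))
  logdetC <- determinant(C, logarithm = TRUE)$modulus[1]
  state <- unname(data$states)
  # canonical orientation: run with the first tip in state 1 and mirror the
  # results back, so relabeling 0 <-> 1 flips the sign of r exactly
  flipped <- state[1] == 0L
  if (flipped) state <- 1L - state
  y <- unname(data$trait)
  one <- rep(1, n)
  s1W1 <- sum(W %*% one)

  set.seed(config$seed)
  # initial values
  l <- ifelse(state == 1, 0.5, -0.5)
  r <- 0
  sig <- max(sd(y), 1e-3)
  ml <- 0
  my <- mean(y)
  a <- as.vector(W %*% (l - ml)) # W (l - ml), maintained incrementally
  b <- as.vector(W %*% (y - my))

  Rinv <- function(r, sig) {
    det <- sig^2 * (1 - r^2)
    list(R11 = sig^2 / det, R12 = -r * sig / det, R22 = 1 / det,
         logdetR = log(det))
  }
  # -2 x log-likelihood core for the (r, sigma) Metropolis step
  nll2 <- function(r, sig, S11, S12, S22) {
    ri <- Rinv(r, sig)
    n * ri$logdetR + ri$R11 * S11 + 2 * ri$R12 * S12 + ri$R22 * S22
  }

  ngen <- config$generations
  nburn <- floor(config$burnin * ngen)
  rstep <- 0.2
  sstep <- 0.3
  racc <- 0; sacc <- 0; awin <- 0
  rdraws <- numeric(ngen)
  sdraws <- numeric(ngen)
  mdraws <- matrix(NA_real_, ngen, 2, dimnames = list(NULL, c("ml", "my")))
  lldraws <- numeric(ngen)
  keepLiab <- unique(round(seq(nburn + 1, ngen, length.out = min(200, ngen - nburn))))
  liab <- matrix(NA_real_, length(keepLiab), n)
  liabRow <- 1

  for (g in seq_len(ngen)) {
    ri <- Rinv(r, sig)
    sw <- liability_sweep_cpp(l, W, a, b, ml, state, ri$R11, ri$R12)
    l <- sw$l
    a <- as.vector(W %*% (l - ml)) # refresh to avoid incremental drift

    # root means: GLS conditional, jointly normal with covariance R / (1'W1)
    lc <- l; yc <- y
    mhat <- c(sum(W %*% lc) / s1W1, sum(W %*% yc) / s1W1)
    R <- matrix(c(1, r * sig, r * sig, sig^2), 2, 2)
    z <- rnorm(2)
    mm <- mhat + drop(t(chol(R / s1W1)) %*% z)
    ml <- mm[1]; my <- mm[2]
    a <- as.vector(W %*% (l - ml))
    b <- as.vector(W %*% (y - my))

    S11 <- sum((l - ml) * a)
    S12 <- sum((l - ml) * b)
    S22 <- sum((y - my) * b)

    # Metropolis on r (uniform(-1,1) prior)
    cur <- nll2(r, sig, S11, S12, S22)
    rp <- r + rstep * rnorm(1)
    if (rp > -1 && rp < 1) {
      prop <- nll2(rp, sig, S11, S12, S22)
      if (log(runif(1)) < -(prop - cur) / 2) {
        r <- rp; cur <- prop; racc <- racc + 1
      }
    }
    # Metropolis on log sigma (flat prior on log scale)
    sp <- sig * exp(sstep * rnorm(1))
    prop <- nll2(r, sp, S11, S12, S22)
    if (log(runif(1)) < -(prop - cur) / 2) {
      sig <- sp; sacc <- sacc + 1
    }
    awin <- awin + 1
    if (g <= nburn && awin == 50) { # adapt proposal scales during burn-in
      if (racc / 50 > 0.45) rstep <- rstep * 1.4
      if (racc / 50 < 0.2) rstep <- rstep * 0.7
      if (sacc / 50 > 0.45) sstep <- sstep * 1.4
      if (sacc / 50 < 0.2) sstep <- sstep * 0.7
      racc <- 0; sacc <- 0; awin <- 0
    }

    rdraws[g] <- r
    sdraws[g] <- sig
    mdraws[g, ] <- c(ml, my)
    lldraws[g] <- -0.5 * (nll2(r, sig, S11, S12, S22) + 2 * logdetC +
                            2 * n * log(2 * pi))
    if (liabRow <= length(keepLiab) && g == keepLiab[liabRow]) {
      liab[liabRow, ] <- l
      liabRow <- liabRow + 1
    }
  }

  if (flipped) {
    rdraws <- -rdraws
    mdraws[, "ml"] <- -mdraws[, "ml"]
    liab <- -liab
    state <- 1L - state
  }
  keep <- seq.int(nburn + 1, ngen)
  keep <- keep[(seq_along(keep) - 1) %% config$thin == 0]
  rk <- rdraws[keep]
  post <- structure(list(r = rk, sigma = sdraws[keep],
                         means = mdraws[keep, , drop = FALSE],
                         loglik = lldraws[keep],
                         liabilities = liab,
                         states = setNames(state, names(data$states)),
                         ess = essChain(rk),
                         hpd = hpdInterval(rk),
                         mean = mean(rk),
                         config = config),
                    class = "threshold_posterior")
  # orthant invariant: retained liability draws must sign-match the states
  bad <- sweep(sign(liab), 2, ifelse(state == 1, 1, -1), `*`) < 0
  if (any(bad, na.rm = TRUE))
    stop("internal error: liability draw violates its tip's state orthant")
  post
}

#' @export
print.threshold_posterior <- function(x, ...) {
  cat(sprintf("Threshold-model posterior: %d draws of r; mean r = %.3f, 95%% HPD [%.3f, %.3f], ESS = %.1f\n",
              length(x$r), x$mean, x$hpd[1], x$hpd[2], x$ess))
  cat("classification:", significance(x), "\n")
  invisible(x)
}

#' Classify a threshold-model correlation
#'
#' Significant when the 95% HPD interval of `r` excludes 0; the sign of
#' the interval gives the direction.
#'
#' @param posterior A `threshold_posterior`, or a numeric vector of `r`
#'   draws (`>= 100`).
#' @return One of `"significant+"`, `"significant-"`,
#'   `"not significant"`.
#' @export
significance <- function(posterior) {
  h <- if (inherits(posterior, "threshold_posterior")) {
    if (length(posterior$r) < 100) stop("need >= 100 retained draws")
    posterior$hpd
  } else if (is.numeric(posterior) && length(posterior) == 2) {
    posterior # an interval given directly
  } else {
    if (length(posterior) < 100) stop("need >= 100 retained draws")
    hpdInterval(posterior)
  }
  if (h[1] > 0) "significant+"
  else if (h[2] < 0) "significant-"
  else "not significant"
}
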