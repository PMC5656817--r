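## Posterior-predictive adequacy: simulate trees and tip states under
## fitted SSE parameters and compare them with observed data through
## tip-state counts (chi-squared) and the phylogenetic signal of the
## binary character (sum of sister-clade differences, SSCD).

#' Forward simulation of a tree with SSE character evolution
#'
#' Gillespie (exact event-time) simulation of lineage birth, death,
#' anagenetic state change and, for GeoSSE, cladogenetic range inheritance
#' and range loss.  With `stop = "taxa"` the simulation halts at the moment
#' the extant lineage count first reaches `nTips` and the tree is cut at
#' that event; extinct lineages are pruned.  With `stop = "age"` the
#' process runs to a fixed age `maxT` (used by the analytic birth-death
#' checks).
#'
#' @param kind `"bisse"` or `"geosse"`.
#' @param pars Named parameters (`lambda0...q10` or `sA...dB`).
#' @param nTips Target extant tip count (`stop = "taxa"`).
#' @param rootState Starting state (`"0"`/`"1"` or `"A"`/`"B"`/`"AB"`).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param rho Optional per-state sampling fractions; applied by binomial
#'   thinning of the surviving tips.
#' @param stop `"taxa"` (default) or `"age"`.
#' @param maxT Age horizon for `stop = "age"`.
#' @param maxRetry Retries when the clade dies before reaching `nTips`.
#' @return An `sse_sim`: list with `tree`, `states` (named by tip), `pars`,
#'   `kind`, `seed`, `mode`, `attempts`.
#' @export
simulateSseForward <- function(kind = c("bisse", "geosse"), pars, nTips,
                               rootState, seed = NULL, rho = NULL,
                               stop = c("taxa", "age"), maxT = NULL,
                               maxRetry = 200) {
  kind <- match.arg(kind)
  stop <- match.arg(stop)
  if (stop == "taxa" && nTips < 2) base::stop("nTips must be >= 2")
  if (stop == "age" && is.null(maxT)) base::stop("stop = 'age' needs maxT")
  pars <- namedPars(pars, if (kind == "bisse") BISSE_PARS else GEOSSE_PARS)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(maxRetry)) {
    sim <- simOnce(kind, pars, nTips, rootState, stop, maxT)
    if (!is.null(sim)) {
      if (!is.null(rho) && !is.null(sim$tree)) sim <- thinTips(sim, rho)
      sim$pars <- pars
      sim$kind <- kind
      sim$seed <- seed
      sim$mode <- "forward"
      sim$attempts <- attempt
      class(sim) <- "sse_sim"
      return(sim)
    }
  }
  base::stop("clade went extinct before reaching ", nTips, " tips in ",
             maxRetry, " attempts; parameters may imply near-certain extinction")
}

# one forward realization; NULL when the clade dies before the target
simOnce <- function(kind, pars, nTips, rootState, stopRule, maxT) {
  stateNames <- if (kind == "bisse") c("0", "1") else c("A", "B", "AB")
  s0 <- match(as.character(rootState), stateNames)
  if (is.na(s0)) base::stop("invalid root state")
  # per-record bookkeeping (records are branches of the complete tree)
  cap <- max(64L, 4L * nTips)
  parent <- integer(cap); tstart <- numeric(cap); tend <- numeric(cap)
  extinct <- logical(cap); tipState <- integer(cap); isLeaf <- logical(cap)
  nrec <- 1L
  parent[1] <- 0L; tstart[1] <- 0
  active <- 1L
  astate <- s0
  t <- 0
  grow <- function() { # extend vectors when capacity is hit
    parent <<- c(parent, integer(cap)); tstart <<- c(tstart, numeric(cap))
    tend <<- c(tend, numeric(cap)); extinct <<- c(extinct, logical(cap))
    tipState <<- c(tipState, integer(cap)); isLeaf <<- c(isLeaf, logical(cap))
    cap <<- length(parent)
  }
  if (kind == "bisse") {
    lam <- pars[c("lambda0", "lambda1")]
    mu <- pars[c("mu0", "mu1")]
    qmat <- matrix(c(0, pars["q10"], pars["q01"], 0), 2, 2)
    lineageRate <- lam + mu + rowSums(qmat)
  } else {
    g <- pars
    lineageRate <- c(g["sA"] + g["xA"] + g["dA"],
                     g["sB"] + g["xB"] + g["dB"],
                     g["sA"] + g["sB"] + g["sAB"] + g["xA"] + g["xB"])
  }
  repeat {
    rates <- lineageRate[astate]
    tot <- sum(rates)
    if (tot <= 0) { # absorbing: no events can ever occur
      if (stopRule == "taxa") return(NULL)
      t <- maxT
      break
    }
    dt <- rexp(1, tot)
    if (stopRule == "age" && t + dt > maxT) { t <- maxT; break }
    t <- t + dt
    i <- if (length(active) == 1) 1L else
      sample.int(length(active), 1, prob = rates)
    rec <- active[i]; st <- astate[i]
    if (kind == "bisse") {
      u <- runif(1) * lineageRate[st]
      if (u < lam[st]) ev <- "spec"
      else if (u < lam[st] + mu[st]) ev <- "ext"
      else ev <- "trans"
      if (ev == "spec") childStates <- c(st, st)
      if (ev == "trans") newState <- 3L - st
    } else {
      u <- runif(1) * lineageRate[st]
      if (st == 1L) { # A
        if (u < g["sA"]) { ev <- "spec"; childStates <- c(1L, 1L) }
        else if (u < g["sA"] + g["xA"]) ev <- "ext"
        else { ev <- "trans"; newState <- 3L } # dispersal A -> AB
      } else if (st == 2L) { # B
        if (u < g["sB"]) { ev <- "spec"; childStates <- c(2L, 2L) }
        else if (u < g["sB"] + g["xB"]) ev <- "ext"
        else { ev <- "trans"; newState <- 3L }
      } else { # AB
        cs <- cumsum(g[c("sA", "sB", "sAB", "xA", "xB")])
        if (u < cs[1]) { ev <- "spec"; childStates <- c(3L, 1L) }       # within-A
        else if (u < cs[2]) { ev <- "spec"; childStates <- c(3L, 2L) }  # within-B
        else if (u < cs[3]) { ev <- "spec"; childStates <- c(1L, 2L) }  # vicariance
        else if (u < cs[4]) { ev <- "trans"; newState <- 2L }           # lose A
        else { ev <- "trans"; newState <- 1L }                          # lose B
      }
    }
    if (ev == "trans") {
      astate[i] <- newState
    } else if (ev == "ext") {
      tend[rec] <- t; extinct[rec] <- TRUE; isLeaf[rec] <- TRUE
      tipState[rec] <- st
      active <- active[-i]; astate <- astate[-i]
      if (length(active) == 0) {
        if (stopRule == "taxa") return(NULL)
        break
      }
    } else { # speciation
      tend[rec] <- t
      if (nrec + 2L > cap) grow()
      c1 <- nrec + 1L; c2 <- nrec + 2L; nrec <- nrec + 2L
      parent[c(c1, c2)] <- rec; tstart[c(c1, c2)] <- t
      active <- c(active[-i], c1, c2)
      astate <- c(astate[-i], childStates)
      if (stopRule == "taxa" && length(active) >= nTips) break
    }
  }
  # close surviving lineages at the stop time
  for (i in seq_along(active)) {
    rec <- active[i]
    tend[rec] <- t; isLeaf[rec] <- TRUE; tipState[rec] <- astate[i]
  }
  alive <- isLeaf[seq_len(nrec)] & !extinct[seq_len(nrec)]
  if (sum(alive) < 2) {
    if (stopRule == "taxa") return(NULL)
    # degenerate outcome of a fixed-age run (0 or 1 survivors): no tree,
    # but the survivor states are still reportable for analytic checks
    return(list(tree = NULL,
                states = stateNames[tipState[which(alive)]]))
  }
  buildSimTree(nrec, parent, tstart, tend, extinct, isLeaf, tipState,
               stateNames)
}

buildSimTree <- function(nrec, parent, tstart, tend, extinct, isLeaf,
                         tipState, stateNames) {
  idx <- seq_len(nrec)
  leaves <- idx[isLeaf[idx]]
  internals <- idx[!isLeaf[idx]]
  ntip <- length(leaves)
  num <- integer(nrec)
  num[leaves] <- seq_len(ntip)
  root <- 1L
  num[root] <- ntip + 1L
  rest <- setdiff(internals, root)
  num[rest] <- ntip + 1L + seq_along(rest)
  nonroot <- idx[idx != root]
  edge <- cbind(num[parent[nonroot]], num[nonroot])
  len <- tend[nonroot] - tstart[nonroot]
  labs <- paste0("t", seq_len(ntip))
  tr <- list(edge = edge, edge.length = len, tip.label = labs,
             Nnode = length(internals))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  states <- setNames(stateNames[tipState[leaves]], labs)
  extinctTips <- labs[extinct[leaves]]
  if (length(extinctTips) > 0) {
    if (ntip - length(extinctTips) < 2) return(NULL)
    tr <- ape::drop.tip(tr, extinctTips)
    tr$root.edge <- NULL
    states <- states[tr$tip.label]
  }
  list(tree = tr, states = states)
}

thinTips <- function(sim, rho) {
  rho <- checkRho(rho, sort(unique(sim$states)))
  keepP <- rho[sim$states]
  keep <- runif(length(keepP)) < keepP
  if (sum(keep) < 2) base::stop("sampling-fraction thinning left < 2 tips")
  if (all(keep)) return(sim)
  sim$tree <- ape::drop.tip(sim$tree, names(sim$states)[!keep])
  sim$tree$root.edge <- NULL
  sim$states <- sim$states[sim$tree$tip.label]
  sim
}

#' @export
print.sse_sim <- function(x, ...) {
  cat("Simulated SSE dataset (", x$kind, ", ", x$mode, "): ",
      ape::Ntip(x$tree), " tips; state counts: ",
      paste(names(table(x$states)), table(x$states), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulation conditioned on exact tip-state counts
#'
#' Keeps state prevalence fixed by rejection: forward simulations are
#' drawn until the tip-state counts equal `counts` exactly.  The
#' acceptance rate is recorded; persistently low acceptance signals a
#' mismatch between the parameters and the requested counts.
#'
#' @param kind,pars,rootState,seed As [simulateSseForward()].
#' @param counts Named integer vector of required tip counts per state.
#' @param maxAttempts Rejection cap; exceeding it is an error.
#' @return An `sse_sim` with `mode = "conditioned"` and attribute
#'   `"acceptance"`.
#' @export
simulateConditioned <- function(kind = c("bisse", "geosse"), pars, counts,
                                rootState, seed = NULL, maxAttempts = 5000) {
  kind <- match.arg(kind)
  nTips <- sum(counts)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(maxAttempts)) {
    sim <- simulateSseForward(kind, pars, nTips, rootState, seed = NULL)
    obs <- table(factor(sim$states, levels = names(counts)))
    if (all(obs == counts)) {
      sim$mode <- "conditioned"
      sim$seed <- seed
      attr(sim, "acceptance") <- 1 / attempt
      return(sim)
    }
  }
  base::stop("no simulation matched the requested counts in ", maxAttempts,
             " attempts (acceptance < ", signif(1 / maxAttempts, 2),
             "); parameters and counts are likely incompatible")
}

#' Chi-squared test of simulated vs observed tip-state counts
#'
#' Expected counts are the mean simulated counts rescaled to the observed
#' total; the statistic is `sum((obs - exp)^2 / exp)` on `#states - 1`
#' degrees of freedom.
#'
#' @param observed Named integer vector of observed tip counts per state.
#' @param sims List of `sse_sim` datasets (`>= 30`), or a matrix of
#'   simulated counts (rows = simulations, named columns = states).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
tipCountTest <- function(observed, sims) {
  cm <- if (is.matrix(sims)) sims else
    t(vapply(sims, function(s)
      as.numeric(table(factor(s$states, levels = names(observed)))),
      numeric(length(observed))))
  if (!is.matrix(cm) || nrow(cm) < 30)
    base::stop("need >= 30 simulated datasets")
  colnames(cm) <- names(observed)
  expected <- colMeans(cm)
  expected <- expected / sum(expected) * sum(observed)
  if (any(expected == 0 & observed > 0)) {
    warning("state observed but never simulated; p = 0")
    return(list(statistic = Inf, df = length(observed) - 1, p = 0,
                expected = expected))
  }
  use <- expected > 0
  stat <- sum((observed[use] - expected[use])^2 / expected[use])
  df <- length(observed) - 1
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Sum of sister-clade differences
#'
#' Phylogenetic-signal statistic for a binary character on a bifurcating
#' tree: nodal values are computed tips-to-root as the mean of the two
#' daughter values, and SSCD is the sum over internal nodes of the
#' absolute difference between the daughter values.  Low SSCD means
#' strong clustering of states.
#'
#' @param tree A bifurcating `phylo`.
#' @param states Named binary (0/1) tip vector.
#' @return The SSCD statistic.
#' @export
sscd <- function(tree, states) {
  assertBifurcating(tree, "SSCD")
  ntip <- ape::Ntip(tree)
  if (is.null(names(states))) base::stop("states must be named by tip label")
  v <- numeric(ntip + tree$Nnode)
  v[seq_len(ntip)] <- as.numeric(as.character(states[tree$tip.label]))
  if (any(is.na(v[seq_len(ntip)]))) base::stop("missing or non-numeric state")
  po <- ape::reorder.phylo(tree, "postorder")
  total <- 0
  firstChild <- rep(NA_real_, ntip + tree$Nnode)
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    if (is.na(firstChild[par])) {
      firstChild[par] <- v[ch]
    } else {
      v[par] <- (firstChild[par] + v[ch]) / 2
      total <- total + abs(firstChild[par] - v[ch])
    }
  }
  total
}

#' Compare observed and simulated SSCD distributions
#'
#' Welch two-sample t-test of the SSCD means, plus the fraction of
#' observed SSCD values falling inside the simulated 50% and 95% empirical
#' percentile bands (type-7 quantiles).
#'
#' @param observed Numeric vector of SSCD values from the observed trees
#'   (`>= 2`).
#' @param simulated Numeric vector of SSCD values from simulated datasets
#'   (`>= 2`).
#' @return List with `p`, `t`, `coverage95`, `coverage50`, `band95`,
#'   `band50`.
#' @export
sscdComparison <- function(observed, simulated) {
  if (length(observed) < 2 || length(simulated) < 2)
    base::stop("need >= 2 SSCD values per distribution")
  if (sd(observed) == 0 && sd(simulated) == 0) {
    warning("zero variance in both SSCD samples")
    p <- if (mean(observed) == mean(simulated)) 1 else 0
    tt <- list(statistic = c(t = if (p == 1) 0 else Inf), p.value = p)
  } else {
    tt <- t.test(observed, simulated) # Welch by default
  }
  b95 <- quantile(simulated, c(0.025, 0.975), type = 7, names = FALSE)
  b50 <- quantile(simulated, c(0.25, 0.75), type = 7, names = FALSE)
  list(p = tt$p.value, t = unname(tt$statistic),
       coverage95 = mean(observed >= b95[1] & observed <= b95[2]),
       coverage50 = mean(observed >= b50[1] & observed <= b50[2]),
       band95 = b95, band50 = b50)
}

#' Run the full adequacy battery
#'
#' Draws parameter vectors from a posterior sample (or uses fixed
#' parameters), simulates `nSim` datasets of the observed size, and runs
#' the tip-count chi-squared test and the SSCD comparison against the
#' observed data.
#'
#' @param kind `"bisse"` or `"geosse"`.
#' @param observedCounts Named observed tip-state counts.
#' @param observedSscd Numeric vector of SSCD values from the observed
#'   tree(s) (binary coding; for GeoSSE the endemic focal state vs rest).
#' @param draws Matrix or `posterior_samples` of parameter draws, or a
#'   single named parameter vector.
#' @param nSim Number of posterior-predictive simulations (`>= 30`).
#' @param rootState Root state for the simulations.
#' @param seed Seed.
#' @param binaryFocal For GeoSSE simulations, the state mapped to 0 when
#'   computing SSCD (default `"A"`; all other states become 1).
#' @return An `adequacy_report` list.
#' @export
adequacyBattery <- function(kind, observedCounts, observedSscd, draws, nSim = 100,
                            rootState, seed = 1, binaryFocal = "A") {
  if (!is.null(seed)) set.seed(seed)
  m <- if (inherits(draws, "posterior_samples")) draws$pars
       else if (is.matrix(draws)) draws
       else matrix(draws, 1, length(draws), dimnames = list(NULL, names(draws)))
  nTips <- sum(observedCounts)
  sims <- vector("list", nSim)
  simSscd <- numeric(nSim)
  for (i in seq_len(nSim)) {
    p <- m[sample.int(nrow(m), 1), ]
    sims[[i]] <- simulateSseForward(kind, p, nTips, rootState)
    st <- sims[[i]]$states
    bin <- if (kind == "bisse") st else ifelse(st == binaryFocal, "0", "1")
    simSscd[i] <- sscd(sims[[i]]$tree, setNames(bin, names(st)))
  }
  tc <- tipCountTest(observedCounts, sims)
  sc <- if (length(observedSscd) >= 2) {
    sscdComparison(observedSscd, simSscd)
  } else {
    # single observed tree: Monte-Carlo two-sided tail probability in place
    # of the t-test, band membership in place of coverage fractions
    f <- mean(simSscd <= observedSscd)
    b95 <- quantile(simSscd, c(0.025, 0.975), type = 7, names = FALSE)
    b50 <- quantile(simSscd, c(0.25, 0.75), type = 7, names = FALSE)
    list(p = min(1, 2 * min(f, 1 - f)), t = NA_real_,
         coverage95 = as.numeric(observedSscd >= b95[1] & observedSscd <= b95[2]),
         coverage50 = as.numeric(observedSscd >= b50[1] & observedSscd <= b50[2]),
         band95 = b95, band50 = b50)
  }
  structure(list(tipCount = tc, sscd = sc, observedCounts = observedCounts,
                 observedSscd = observedSscd, simulatedSscd = simSscd,
                 nSim = nSim, kind = kind),
            class = "adequacy_report")
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat("Adequacy report (", x$kind, ", ", x$nSim, " simulations)\n", sep = "")
  cat(sprintf("  tip-count chi-squared: X2 = %.3f (df %d), p = %.4g\n",
              x$tipCount$statistic, x$tipCount$df, x$tipCount$p))
  cat(sprintf("  SSCD t-test: t = %.3f, p = %.4g; coverage 95%% = %.2f, 50%% = %.2f\n",
              x$sscd$t, x$sscd$p, x$sscd$coverage95, x$sscd$coverage50))
  invisible(x)
}
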