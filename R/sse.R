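## State-dependent speciation-extinction likelihoods.
##
## All three models (BiSSE, GeoSSE, HiSSE) share one pruning core: along
## every branch the extinction probabilities E_i(t) and data probabilities
## D_i(t) are integrated with an adaptive Dormand-Prince 5(4) scheme
## (absolute/relative tolerance 1e-8), D is renormalized per branch with the
## log of the normalizer accumulated, and daughter lineages are combined at
## nodes with the model's speciation kernel.  Incomplete sampling enters
## through per-state sampling fractions rho: a tip observed in state s
## initializes D_s = rho_s and every state starts with E_i(0) = 1 - rho_i.

BISSE_PARS <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
GEOSSE_PARS <- c("sA", "sB", "sAB", "xA", "xB", "dA", "dB")

# postorder traversal data shared by all likelihood calls on one tree
prepSseTree <- function(tree, ultra.tol = NULL) {
  validateTimeTree(tree)
  assertBifurcating(tree, "SSE likelihood")
  u <- ultrametricityCheck(tree, ultra.tol)
  if (!u$ok)
    stop(sprintf("tree not ultrametric within tolerance (deviation %.3g > tol %.3g)",
                 u$deviation, u$tol))
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, len = po$edge.length, ntip = ape::Ntip(tree),
       root = ape::Ntip(tree) + 1L, tiplab = tree$tip.label)
}

checkStates <- function(td, states, allowed) {
  if (is.null(names(states))) stop("states must be named by tip label")
  miss <- setdiff(td$tiplab, names(states))
  if (length(miss) > 0)
    stop("tip(s) missing a state: ", paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  s <- as.character(states[td$tiplab])
  bad <- setdiff(unique(s), allowed)
  if (length(bad) > 0)
    stop("invalid state value(s): ", paste(bad, collapse = ", "))
  s
}

checkRho <- function(rho, stateNames) {
  if (is.null(rho)) rho <- setNames(rep(1, length(stateNames)), stateNames)
  if (is.null(names(rho))) names(rho) <- stateNames
  rho <- rho[stateNames]
  if (any(is.na(rho)) || any(rho <= 0) || any(rho > 1))
    stop("sampling fractions must be in (0, 1] for every state")
  rho
}

# weights + survival conditioning applied to the root D vector
assembleRoot <- function(rootD, rootE, logcomp, lambdaRoot,
                         root = c("obs", "flat", "given", "fixed"),
                         root.p = NULL, condition.surv = FALSE) {
  root <- match.arg(root)
  k <- length(rootD)
  w <- switch(root,
    obs = {
      s <- sum(rootD)
      if (s <= 0) return(-Inf)
      rootD / s
    },
    flat = rep(1 / k, k),
    given = {
      if (is.null(root.p) || length(root.p) != k)
        stop("root = 'given' needs root.p of length ", k)
      root.p / sum(root.p)
    },
    fixed = {
      if (is.null(root.p)) stop("root = 'fixed' needs root.p naming a state")
      idx <- if (is.character(root.p)) match(root.p, names(rootD)) else as.integer(root.p)
      if (is.na(idx) || idx < 1 || idx > k) stop("invalid fixed root state")
      w <- rep(0, k); w[idx] <- 1; w
    })
  d <- rootD
  if (condition.surv) {
    denom <- sum(w * lambdaRoot * (1 - rootE)^2)
    if (!(denom > 0)) return(-Inf)
    d <- d / denom
  }
  val <- sum(w * d)
  if (!(val > 0) || !is.finite(val)) return(-Inf)
  log(val) + logcomp
}

musseCore <- function(td, states, lambda, mu, Q, rho, root, root.p,
                      condition.surv, constrainNode = 0L, constrainState = 0L,
                      rtol = 1e-8, atol = 1e-8) {
  k <- length(lambda)
  stateNames <- names(lambda)
  tipD <- matrix(0, td$ntip, k)
  obsOf <- attr(Q, "obsOf") # for hisse: observed state of each combined state
  for (i in seq_len(td$ntip)) {
    if (is.null(obsOf)) {
      j <- match(states[i], stateNames)
      tipD[i, j] <- rho[j]
    } else {
      j <- which(obsOf == states[i])
      tipD[i, j] <- rho[j]
    }
  }
  E0 <- 1 - rho
  res <- sse_pruning_cpp(td$edge, td$len, td$ntip, td$root, tipD, E0, 1L,
                         lambda, mu, Q, numeric(7), rtol, atol,
                         as.integer(constrainNode), as.integer(constrainState))
  if (!res$ok) return(-Inf)
  names(res$rootD) <- stateNames
  assembleRoot(res$rootD, res$rootE, res$logcomp, lambda, root, root.p,
               condition.surv)
}

#' BiSSE log-likelihood
#'
#' Joint likelihood of an ultrametric, bifurcating tree and a binary tip
#' character under state-dependent speciation (`lambda0`, `lambda1`),
#' extinction (`mu0`, `mu1`) and transition (`q01`, `q10`) rates, all in
#' events/lineage/Myr.
#'
#' @param tree A `phylo` object (bifurcating, ultrametric within tolerance).
#' @param states Named vector (tip labels) with values `0`/`1`.
#' @param pars Numeric vector, named or in the order
#'   `lambda0, lambda1, mu0, mu1, q01, q10`.
#' @param rho Sampling fractions per state (named `"0"`, `"1"`); default
#'   complete sampling.
#' @param root Root treatment: `"obs"` (weights proportional to the root D
#'   values; default), `"flat"`, `"given"` or `"fixed"`.
#' @param root.p State weights (`"given"`) or a state name (`"fixed"`).
#' @param condition.surv Condition the likelihood on survival of both root
#'   lineages (default `FALSE`).
#' @param ultra.tol Ultrametricity tolerance passed to
#'   [ultrametricityCheck()].
#' @return Log-likelihood (`-Inf` when the data are impossible under
#'   `pars`).
#' @export
bisseLoglik <- function(tree, states, pars, rho = NULL, root = "obs",
                        root.p = NULL, condition.surv = FALSE,
                        ultra.tol = NULL) {
  pars <- namedPars(pars, BISSE_PARS)
  td <- if (is.list(tree) && !inherits(tree, "phylo")) tree else prepSseTree(tree, ultra.tol)
  s <- checkStates(td, states, c("0", "1"))
  rho <- checkRho(rho, c("0", "1"))
  lambda <- setNames(pars[c("lambda0", "lambda1")], c("0", "1"))
  mu <- pars[c("mu0", "mu1")]
  Q <- matrix(c(0, pars["q10"], pars["q01"], 0), 2, 2)
  musseCore(td, s, lambda, mu, Q, rho, root, root.p, condition.surv)
}

#' GeoSSE log-likelihood
#'
#' Likelihood of a tree and a three-state geographic/habitat character
#' (`A` = endemic to region/habitat A, `B` = endemic to B, `AB` =
#' widespread) under within-region speciation `sA`, `sB`, between-region
#' speciation `sAB`, region loss/extinction `xA`, `xB` and range expansion
#' (dispersal) `dA` (A gains B, i.e. a cave-only lineage gaining surface
#' habitat when A is the cave state) and `dB`.
#'
#' @inheritParams bisseLoglik
#' @param states Named vector with values `"A"`, `"B"`, `"AB"`.
#' @param pars Numeric vector, named or ordered `sA, sB, sAB, xA, xB, dA,
#'   dB`.
#' @param rho Sampling fractions per state (named `"A"`, `"B"`, `"AB"`).
#' @return Log-likelihood.
#' @export
geosseLoglik <- function(tree, states, pars, rho = NULL, root = "obs",
                         root.p = NULL, condition.surv = FALSE,
                         ultra.tol = NULL) {
  pars <- namedPars(pars, GEOSSE_PARS)
  td <- if (is.list(tree) && !inherits(tree, "phylo")) tree else prepSseTree(tree, ultra.tol)
  s <- checkStates(td, states, c("A", "B", "AB"))
  rho <- checkRho(rho, c("A", "B", "AB"))
  tipD <- matrix(0, td$ntip, 3)
  idx <- match(s, c("A", "B", "AB"))
  tipD[cbind(seq_len(td$ntip), idx)] <- rho[idx]
  E0 <- 1 - rho
  res <- sse_pruning_cpp(td$edge, td$len, td$ntip, td$root, tipD, E0, 2L,
                         numeric(3), numeric(3), matrix(0, 3, 3),
                         unname(pars), 1e-8, 1e-8, 0L, 0L)
  if (!res$ok) return(-Inf)
  rootD <- setNames(res$rootD, c("A", "B", "AB"))
  lambdaRoot <- c(pars["sA"], pars["sB"], pars["sA"] + pars["sB"] + pars["sAB"])
  assembleRoot(rootD, res$rootE, res$logcomp, lambdaRoot, root, root.p,
               condition.surv)
}

#' HiSSE log-likelihood
#'
#' Likelihood of a binary tip character whose states may harbor unobserved
#' "hidden" diversification regimes.  The model structure (combined state
#' space, rate-sharing groups, allowed transitions) comes from a
#' [hisseSpec()]; a tip observed in state `s` initializes D at every
#' combined state whose observed component is `s`.  With hidden states
#' absent the computation reduces exactly to [bisseLoglik()].
#'
#' @inheritParams bisseLoglik
#' @param spec A `hisse_spec`, e.g. one entry of [hisseModelSet()].
#' @param pars Numeric vector over `spec$paramNames` (named or in order).
#' @param rho Sampling fractions per observed state (named `"0"`, `"1"`).
#' @return Log-likelihood.
#' @export
hisseLoglik <- function(tree, states, spec, pars, rho = NULL, root = "obs",
                        root.p = NULL, condition.surv = FALSE,
                        ultra.tol = NULL) {
  stopifnot(inherits(spec, "hisse_spec"))
  pars <- namedPars(pars, spec$paramNames)
  td <- if (is.list(tree) && !inherits(tree, "phylo")) tree else prepSseTree(tree, ultra.tol)
  s <- checkStates(td, states, c("0", "1"))
  rhoObs <- checkRho(rho, c("0", "1"))
  rates <- hisseRates(spec, pars)
  rhoFull <- rhoObs[spec$stateObs]
  musseCore(td, s, rates$lambda, rates$mu, rates$Q, rhoFull, root, root.p,
            condition.surv)
}

# expand a hisse spec + parameter vector into per-state lambda/mu and Q
hisseRates <- function(spec, pars) {
  lambda <- setNames(pars[spec$lamGroup], spec$states)
  mu <- setNames(pars[spec$muGroup], spec$states)
  k <- length(spec$states)
  Q <- matrix(0, k, k)
  if (nrow(spec$qEntries) > 0)
    Q[cbind(spec$qEntries$from, spec$qEntries$to)] <- pars[spec$qEntries$group]
  attr(Q, "obsOf") <- spec$stateObs
  list(lambda = lambda, mu = mu, Q = Q)
}

namedPars <- function(pars, template) {
  if (is.null(names(pars))) {
    if (length(pars) != length(template))
      stop("expected ", length(template), " parameters (", paste(template, collapse = ", "), ")")
    names(pars) <- template
  } else {
    miss <- setdiff(template, names(pars))
    if (length(miss) > 0)
      stop("missing parameter(s): ", paste(miss, collapse = ", "))
    pars <- pars[template]
  }
  if (any(!is.finite(pars)) || any(pars < 0))
    stop("all rates must be finite and >= 0")
  pars
}

#' Relative net diversification
#'
#' The ratio `(sA - xA) / (sB - xB)` of net diversification in the focal
#' state to net diversification in the alternative, used to compare
#' habitats across separate analyses.  Draws with a zero denominator are
#' returned as `NA` with the count recorded in attribute `"n_undefined"`.
#'
#' @param pars A named vector with entries `sA, xA, sB, xB`, or a matrix /
#'   data frame of posterior draws with those columns.
#' @return A number, or a vector over draws (attribute `"n_undefined"`).
#' @export
relativeNetDiversification <- function(pars) {
  if (is.matrix(pars) || is.data.frame(pars)) {
    pars <- as.data.frame(pars)
    num <- pars$sA - pars$xA
    den <- pars$sB - pars$xB
  } else {
    num <- pars[["sA"]] - pars[["xA"]]
    den <- pars[["sB"]] - pars[["xB"]]
  }
  out <- ifelse(den == 0, NA_real_, num / den)
  attr(out, "n_undefined") <- sum(den == 0)
  out
}

#' Marginal ancestral state probabilities
#'
#' For each internal node the likelihood is recomputed with that node
#' conditioned to each state in turn (the node's post-merge D vector zeroed
#' elsewhere); normalizing over states gives the marginal probability
#' vector, which sums to 1 at every node.
#'
#' @param tree,states,pars,rho,root,root.p,condition.surv As in the
#'   corresponding likelihood function.
#' @param kind `"bisse"`, `"geosse"` or `"hisse"`.
#' @param spec Required for `kind = "hisse"`.
#' @return Matrix (internal nodes x states) of probabilities; row names are
#'   ape node ids.
#' @export
marginalAncestralStates <- function(tree, states, kind, pars, spec = NULL,
                                    rho = NULL, root = "obs", root.p = NULL,
                                    condition.surv = FALSE) {
  kind <- match.arg(kind, c("bisse", "geosse", "hisse"))
  td <- prepSseTree(tree)
  llfun <- function(node, state) {
    switch(kind,
      bisse = musseConstrained(td, states, pars, rho, root, root.p,
                               condition.surv, node, state, kind),
      hisse = musseConstrained(td, states, pars, rho, root, root.p,
                               condition.surv, node, state, kind, spec),
      geosse = geosseConstrained(td, states, pars, rho, root, root.p,
                                 condition.surv, node, state))
  }
  k <- switch(kind, bisse = 2L, geosse = 3L,
              hisse = length(spec$states))
  stateNames <- switch(kind, bisse = c("0", "1"), geosse = c("A", "B", "AB"),
                       hisse = spec$states)
  nodes <- td$ntip + seq_len(td$ntip - 1L)
  out <- matrix(NA_real_, length(nodes), k,
                dimnames = list(nodes, stateNames))
  for (i in seq_along(nodes)) {
    ll <- vapply(seq_len(k), function(s) llfun(nodes[i], s), 1.0)
    if (all(!is.finite(ll))) stop("non-finite likelihood at node ", nodes[i])
    m <- max(ll)
    p <- exp(ll - m)
    out[i, ] <- p / sum(p)
  }
  out
}

musseConstrained <- function(td, states, pars, rho, root, root.p,
                             condition.surv, node, state, kind, spec = NULL) {
  s <- checkStates(td, states, c("0", "1"))
  rhoObs <- checkRho(rho, c("0", "1"))
  if (kind == "bisse") {
    pars <- namedPars(pars, BISSE_PARS)
    lambda <- setNames(pars[c("lambda0", "lambda1")], c("0", "1"))
    mu <- pars[c("mu0", "mu1")]
    Q <- matrix(c(0, pars["q10"], pars["q01"], 0), 2, 2)
    rhoFull <- rhoObs
  } else {
    pars <- namedPars(pars, spec$paramNames)
    rates <- hisseRates(spec, pars)
    lambda <- rates$lambda; mu <- rates$mu; Q <- rates$Q
    rhoFull <- rhoObs[spec$stateObs]
  }
  musseCore(td, s, lambda, mu, Q, rhoFull, root, root.p, condition.surv,
            constrainNode = node, constrainState = state)
}

geosseConstrained <- function(td, states, pars, rho, root, root.p,
                              condition.surv, node, state) {
  pars <- namedPars(pars, GEOSSE_PARS)
  s <- checkStates(td, states, c("A", "B", "AB"))
  rho <- checkRho(rho, c("A", "B", "AB"))
  tipD <- matrix(0, td$ntip, 3)
  idx <- match(s, c("A", "B", "AB"))
  tipD[cbind(seq_len(td$ntip), idx)] <- rho[idx]
  res <- sse_pruning_cpp(td$edge, td$len, td$ntip, td$root, tipD, 1 - rho, 2L,
                         numeric(3), numeric(3), matrix(0, 3, 3),
                         unname(pars), 1e-8, 1e-8, as.integer(node),
                         as.integer(state))
  if (!res$ok) return(-Inf)
  rootD <- setNames(res$rootD, c("A", "B", "AB"))
  lambdaRoot <- c(pars["sA"], pars["sB"], pars["sA"] + pars["sB"] + pars["sAB"])
  assembleRoot(rootD, res$rootE, res$logcomp, lambdaRoot, root, root.p,
               condition.surv)
}
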