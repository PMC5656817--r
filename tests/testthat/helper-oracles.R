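# Independent oracles used to check the likelihood engine.  These share no
# code with the package: fixed-step RK4 integration in plain R, closed-form
# birth-death and two-state Markov likelihoods, and a generic cladogenetic
# (ClaSSE-style) pruning implementation that GeoSSE embeds into.

BISSE_PARS_T <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")

randomCoalTree <- function(n, seed, height = NULL) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  if (!is.null(height))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * height
  tr
}

# fixed-step RK4 pruning for an anagenetic k-state SSE model; optionally
# conditions one node to a single state (post-merge D zeroed elsewhere)
rk4MusseLoglik <- function(tree, states, lambda, mu, Q, rho,
                           root = "obs", nstep = 300,
                           constrainNode = 0L, constrainState = 0L) {
  k <- length(lambda)
  stateNames <- colnames(Q)
  qs <- rowSums(Q)
  deriv <- function(y) {
    E <- y[1:k]; D <- y[(k + 1):(2 * k)]
    dE <- mu - (lambda + mu + qs) * E + lambda * E^2 + as.vector(Q %*% E)
    dD <- -(lambda + mu + qs) * D + as.vector(Q %*% D) + 2 * lambda * E * D
    c(dE, dD)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  Dn <- matrix(0, nn, k); En <- matrix(0, nn, k); seen <- integer(nn)
  for (i in seq_len(ntip)) {
    s <- match(as.character(states[tree$tip.label[i]]), stateNames)
    Dn[i, s] <- rho[s]
    En[i, ] <- 1 - rho
    if (constrainNode == i && s != constrainState) return(-Inf)
  }
  logcomp <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; len <- po$edge.length[e]
    y <- c(En[ch, ], Dn[ch, ])
    if (len > 0) {
      h <- len / nstep
      for (s in seq_len(nstep)) {
        k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
        k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    sc <- sum(y[(k + 1):(2 * k)])
    logcomp <- logcomp + log(sc)
    y[(k + 1):(2 * k)] <- y[(k + 1):(2 * k)] / sc
    if (seen[par] == 0) {
      En[par, ] <- y[1:k]; Dn[par, ] <- y[(k + 1):(2 * k)]; seen[par] <- 1
    } else {
      Dn[par, ] <- lambda * Dn[par, ] * y[(k + 1):(2 * k)]
      if (constrainNode == par)
        Dn[par, -constrainState] <- 0
      seen[par] <- 2
    }
  }
  rt <- ntip + 1
  D <- Dn[rt, ]
  w <- switch(root, flat = rep(1 / k, k), obs = D / sum(D))
  val <- sum(w * D)
  if (!(val > 0)) return(-Inf)
  log(val) + logcomp
}

# generic cladogenetic-SSE pruning (ClaSSE-style), RK4 fixed step.
# lamPairs: list over parent state i of a data frame (j, k, rate) of
# unordered daughter-state pairs (j <= k).
rk4ClasseLoglik <- function(tree, states, lamPairs, mu, Q, rho,
                            root = "obs", nstep = 300) {
  k <- length(mu)
  stateNames <- colnames(Q)
  qs <- rowSums(Q)
  Lam <- vapply(lamPairs, function(d) sum(d$rate), 1.0)
  deriv <- function(y) {
    E <- y[1:k]; D <- y[(k + 1):(2 * k)]
    dE <- numeric(k); dD <- numeric(k)
    for (i in seq_len(k)) {
      ls <- lamPairs[[i]]
      sE <- sum(ls$rate * E[ls$j] * E[ls$k])
      sD <- sum(ls$rate * (E[ls$j] * D[ls$k] + E[ls$k] * D[ls$j]))
      dE[i] <- mu[i] - (Lam[i] + mu[i] + qs[i]) * E[i] + sE +
        sum(Q[i, ] * E)
      dD[i] <- -(Lam[i] + mu[i] + qs[i]) * D[i] + sum(Q[i, ] * D) + sD
    }
    c(dE, dD)
  }
  merge2 <- function(DL, DR) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      ls <- lamPairs[[i]]
      out[i] <- sum(ls$rate * (DL[ls$j] * DR[ls$k] + DL[ls$k] * DR[ls$j]) / 2)
    }
    out
  }
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  Dn <- matrix(0, nn, k); En <- matrix(0, nn, k); seen <- integer(nn)
  for (i in seq_len(ntip)) {
    s <- match(as.character(states[tree$tip.label[i]]), stateNames)
    Dn[i, s] <- rho[s]; En[i, ] <- 1 - rho
  }
  logcomp <- 0
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; len <- po$edge.length[e]
    y <- c(En[ch, ], Dn[ch, ])
    if (len > 0) {
      h <- len / nstep
      for (s in seq_len(nstep)) {
        k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
        k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    sc <- sum(y[(k + 1):(2 * k)])
    logcomp <- logcomp + log(sc)
    y[(k + 1):(2 * k)] <- y[(k + 1):(2 * k)] / sc
    if (seen[par] == 0) {
      En[par, ] <- y[1:k]; Dn[par, ] <- y[(k + 1):(2 * k)]; seen[par] <- 1
    } else {
      Dn[par, ] <- merge2(Dn[par, ], y[(k + 1):(2 * k)])
      seen[par] <- 2
    }
  }
  rt <- ntip + 1
  D <- Dn[rt, ]
  w <- switch(root, flat = rep(1 / k, k), obs = D / sum(D))
  log(sum(w * D)) + logcomp
}

# GeoSSE expressed in the generic cladogenetic oracle (states A, B, AB)
classeFromGeosse <- function(p) {
  Q <- matrix(0, 3, 3, dimnames = list(c("A", "B", "AB"), c("A", "B", "AB")))
  Q["A", "AB"] <- p[["dA"]]
  Q["B", "AB"] <- p[["dB"]]
  Q["AB", "B"] <- p[["xA"]] # losing region A leaves a B endemic
  Q["AB", "A"] <- p[["xB"]]
  lamPairs <- list(
    data.frame(j = 1, k = 1, rate = p[["sA"]]),
    data.frame(j = 2, k = 2, rate = p[["sB"]]),
    data.frame(j = c(1, 2, 1), k = c(3, 3, 2),
               rate = c(p[["sA"]], p[["sB"]], p[["sAB"]])))
  list(lamPairs = lamPairs, mu = c(p[["xA"]], p[["xB"]], 0), Q = Q)
}

# closed-form log of the birth-death pruning D at the root (tip D = 1)
bdClosedLoglik <- function(tree, lambda, mu) {
  r <- lambda - mu
  logpsi <- function(t) r * t - 2 * log(lambda * exp(r * t) - mu)
  dep <- ape::node.depth.edgelength(tree)
  age <- max(dep) - dep
  n <- ape::Ntip(tree)
  lp <- (n - 1) * log(lambda)
  for (e in seq_len(nrow(tree$edge)))
    lp <- lp + logpsi(age[tree$edge[e, 1]]) - logpsi(age[tree$edge[e, 2]])
  lp
}

# two-state symmetric Markov character likelihood, uniform root weights
mk2Loglik <- function(tree, states, q) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  L <- matrix(0, ntip + tree$Nnode, 2)
  seen <- integer(ntip + tree$Nnode)
  for (i in seq_len(ntip))
    L[i, as.integer(as.character(states[tree$tip.label[i]])) + 1] <- 1
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; t <- po$edge.length[e]
    same <- (1 + exp(-2 * q * t)) / 2
    P <- matrix(c(same, 1 - same, 1 - same, same), 2, 2)
    v <- as.vector(P %*% L[ch, ])
    if (seen[par] == 0) { L[par, ] <- v; seen[par] <- 1 }
    else L[par, ] <- L[par, ] * v
  }
  log(mean(L[ntip + 1, ]))
}
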