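## Model objects: a likelihood bound to one tree + data, with a free
## parameter vector that constraint masks can shrink.  This is the surface
## the MCMC and ML machinery consume.

#' Bind an SSE likelihood to data
#'
#' Precomputes the tree traversal once and returns a model object whose
#' `$loglik` closure maps a full named parameter vector to the
#' log-likelihood.  [constrain()] derives restricted models from it.
#'
#' @param kind `"bisse"`, `"geosse"` or `"hisse"`.
#' @param tree A `phylo` object.
#' @param states Named tip-state vector (values per `kind`).
#' @param rho Per-state sampling fractions (see the likelihood functions).
#' @param spec A `hisse_spec` (required for `kind = "hisse"`).
#' @param root,root.p,condition.surv Root treatment defaults for the bound
#'   likelihood.
#' @param ultra.tol Ultrametricity tolerance.
#' @return An `sse_model` with elements `loglik(pars)`, `paramNames`,
#'   `free`, `fixed`, `root`.
#' @export
makeSseModel <- function(kind = c("bisse", "geosse", "hisse"), tree, states,
                         rho = NULL, spec = NULL, root = "obs", root.p = NULL,
                         condition.surv = FALSE, ultra.tol = NULL) {
  kind <- match.arg(kind)
  td <- prepSseTree(tree, ultra.tol)
  paramNames <- switch(kind,
    bisse = BISSE_PARS,
    geosse = GEOSSE_PARS,
    hisse = {
      if (is.null(spec)) stop("kind = 'hisse' requires a spec")
      spec$paramNames
    })
  force(states); force(rho); force(root.p); force(condition.surv)
  m <- list(kind = kind, paramNames = paramNames, free = paramNames,
            fixed = numeric(0), root = root, root.p = root.p,
            condition.surv = condition.surv, spec = spec, td = td,
            states = states, rho = rho, ntip = td$ntip)
  # precompute tip initialization once; per-call work is then just the
  # pruning pass and root assembly
  if (kind == "geosse") {
    s <- checkStates(td, states, c("A", "B", "AB"))
    rhoV <- checkRho(rho, c("A", "B", "AB"))
    tipD <- matrix(0, td$ntip, 3)
    idx <- match(s, c("A", "B", "AB"))
    tipD[cbind(seq_len(td$ntip), idx)] <- rhoV[idx]
    E0 <- 1 - rhoV
    m$loglik <- function(pars, root = m$root, root.p = m$root.p) {
      pars <- namedPars(pars, GEOSSE_PARS)
      res <- sse_pruning_cpp(td$edge, td$len, td$ntip, td$root, tipD, E0, 2L,
                             numeric(3), numeric(3), matrix(0, 3, 3),
                             unname(pars), 1e-8, 1e-8, 0L, 0L)
      if (!res$ok) return(-Inf)
      rootD <- setNames(res$rootD, c("A", "B", "AB"))
      lambdaRoot <- c(pars["sA"], pars["sB"],
                      pars["sA"] + pars["sB"] + pars["sAB"])
      assembleRoot(rootD, res$rootE, res$logcomp, lambdaRoot, root, root.p,
                   condition.surv)
    }
  } else {
    s <- checkStates(td, states, c("0", "1"))
    rhoObs <- checkRho(rho, c("0", "1"))
    if (kind == "hisse") {
      k <- length(spec$states)
      stateObs <- spec$stateObs
      rhoFull <- rhoObs[stateObs]
      stateNames <- spec$states
    } else {
      k <- 2L
      stateObs <- c("0", "1")
      rhoFull <- rhoObs
      stateNames <- c("0", "1")
    }
    tipD <- matrix(0, td$ntip, k)
    for (i in seq_len(td$ntip)) {
      j <- which(stateObs == s[i])
      tipD[i, j] <- rhoFull[j]
    }
    E0 <- 1 - rhoFull
    m$loglik <- function(pars, root = m$root, root.p = m$root.p) {
      pars <- namedPars(pars, m$paramNames)
      if (kind == "bisse") {
        lambda <- setNames(pars[c("lambda0", "lambda1")], stateNames)
        mu <- pars[c("mu0", "mu1")]
        Q <- matrix(c(0, pars["q10"], pars["q01"], 0), 2, 2)
      } else {
        rates <- hisseRates(spec, pars)
        lambda <- rates$lambda; mu <- rates$mu; Q <- rates$Q
      }
      res <- sse_pruning_cpp(td$edge, td$len, td$ntip, td$root, tipD, E0, 1L,
                             lambda, mu, Q, numeric(7), 1e-8, 1e-8, 0L, 0L)
      if (!res$ok) return(-Inf)
      names(res$rootD) <- stateNames
      assembleRoot(res$rootD, res$rootE, res$logcomp, lambda, root, root.p,
                   condition.surv)
    }
  }
  class(m) <- "sse_model"
  m
}

#' @export
print.sse_model <- function(x, ...) {
  cat("SSE model (", x$kind, if (!is.null(x$spec)) paste0("/", x$spec$name),
      "): ", x$ntip, " tips, ", length(x$free), " free parameter(s)",
      if (length(x$fixed) > 0)
        paste0(" [fixed: ", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "]"),
      ", root = ", x$root,
      if (identical(x$root, "fixed")) paste0(" (state ", x$root.p, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Constrain model parameters and/or the root state
#'
#' Fixes parameters to numeric values (removing them from the free vector)
#' and optionally overrides the root treatment to a fixed state — e.g. the
#' irreversible cave model fixes the dispersal rate out of caves to 0 and
#' the root to the surface state.
#'
#' @param model An `sse_model`.
#' @param fix Named numeric vector of parameters to fix.
#' @param root.state Optional state name; sets root mode `"fixed"`.
#' @return A new `sse_model` whose `$loglik` accepts the free parameters
#'   only (fixed values are filled in).
#' @export
constrain <- function(model, fix = numeric(0), root.state = NULL) {
  stopifnot(inherits(model, "sse_model"))
  if (length(fix) > 0) {
    if (is.null(names(fix)) || any(!nzchar(names(fix))))
      stop("'fix' must be a named numeric vector")
    unknown <- setdiff(names(fix), model$paramNames)
    if (length(unknown) > 0)
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    clash <- intersect(names(fix), names(model$fixed))
    for (p in clash)
      if (model$fixed[p] != fix[p])
        stop("contradictory constraints on '", p, "'")
  }
  out <- model
  out$fixed <- c(model$fixed[setdiff(names(model$fixed), names(fix))], fix)
  out$free <- setdiff(model$paramNames, names(out$fixed))
  if (!is.null(root.state)) {
    out$root <- "fixed"
    out$root.p <- root.state
  }
  base <- model$loglik
  fixed <- out$fixed
  paramNames <- model$paramNames
  freeNames <- out$free
  rootMode <- out$root
  rootP <- out$root.p
  out$loglik <- function(pars) {
    if (is.null(names(pars))) {
      if (length(pars) != length(freeNames))
        stop("expected ", length(freeNames), " free parameter(s)")
      names(pars) <- freeNames
    }
    full <- setNames(numeric(length(paramNames)), paramNames)
    full[names(fixed)] <- fixed
    full[freeNames] <- pars[freeNames]
    base(full, root = rootMode, root.p = rootP)
  }
  out
}

#' Number of free parameters of a model
#' @param model An `sse_model`.
#' @return Integer count.
#' @export
nFreeParams <- function(model) length(model$free)
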