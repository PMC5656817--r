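## Structural specifications for the hidden-state (HiSSE) model family.
##
## A spec lists the combined state space (observed state x optional hidden
## regime), which states share speciation/extinction parameters, and which
## transitions are allowed.  Dual transitions (simultaneous observed and
## hidden change) are structurally zero throughout.

#' Build a HiSSE model structure
#'
#' @param name Model name.
#' @param states Character vector of combined state names.
#' @param stateObs Character vector giving the observed state (`"0"` or
#'   `"1"`) of each combined state.
#' @param lamGroup,muGroup Character vectors mapping each combined state to
#'   the name of its speciation / extinction parameter (equal names share a
#'   parameter).
#' @param qEntries Data frame with columns `from`, `to` (combined-state
#'   indices) and `group` (transition-parameter name).
#' @return A `hisse_spec`.
#' @export
hisseSpec <- function(name, states, stateObs, lamGroup, muGroup, qEntries) {
  stopifnot(length(states) == length(stateObs),
            length(states) == length(lamGroup),
            length(states) == length(muGroup))
  paramNames <- unique(c(lamGroup, muGroup,
                         if (nrow(qEntries) > 0) qEntries$group))
  spec <- list(name = name, states = states, stateObs = stateObs,
               lamGroup = lamGroup, muGroup = muGroup, qEntries = qEntries,
               paramNames = paramNames, nFree = length(paramNames))
  class(spec) <- "hisse_spec"
  spec
}

#' @export
print.hisse_spec <- function(x, ...) {
  cat("HiSSE model spec '", x$name, "': ", length(x$states),
      " combined states (", paste(x$states, collapse = ", "), "), ",
      x$nFree, " free parameters\n", sep = "")
  invisible(x)
}

qdf <- function(...) {
  d <- do.call(rbind, lapply(list(...), function(e)
    data.frame(from = e[[1]], to = e[[2]], group = e[[3]],
               stringsAsFactors = FALSE)))
  if (is.null(d)) data.frame(from = integer(), to = integer(),
                             group = character()) else d
}

#' The six-model HiSSE set
#'
#' The model battery used for adequacy/model-selection tables:
#' \describe{
#'   \item{bisse}{No hidden states; identical to the BiSSE likelihood.}
#'   \item{cid2}{Character-independent, 2 diversification regimes:
#'     lambda/mu depend only on the hidden regime (A/B).}
#'   \item{cid4}{Character-independent, 4 hidden regimes (A-D).}
#'   \item{full}{Hidden regime under both observed states, lambda/mu free
#'     per combined state.}
#'   \item{hidden0}{Hidden regime only under observed state 0 (the cave
#'     state in the habitat analyses).}
#'   \item{hidden1}{Hidden regime only under observed state 1 (surface).}
#' }
#' Observed-state transitions (`q01`, `q10`) are shared across hidden
#' regimes, hidden-regime switches happen at a single rate `alpha`, and
#' dual transitions are forbidden.
#'
#' @return Named list of six `hisse_spec` objects.
#' @export
hisseModelSet <- function() {
  bisse <- hisseSpec("bisse",
    states = c("0", "1"), stateObs = c("0", "1"),
    lamGroup = c("lambda0", "lambda1"), muGroup = c("mu0", "mu1"),
    qEntries = qdf(list(1L, 2L, "q01"), list(2L, 1L, "q10")))

  # states 1:4 = 0A, 1A, 0B, 1B
  cid2 <- hisseSpec("cid2",
    states = c("0A", "1A", "0B", "1B"), stateObs = c("0", "1", "0", "1"),
    lamGroup = c("lambdaA", "lambdaA", "lambdaB", "lambdaB"),
    muGroup = c("muA", "muA", "muB", "muB"),
    qEntries = qdf(list(1L, 2L, "q01"), list(2L, 1L, "q10"),
                   list(3L, 4L, "q01"), list(4L, 3L, "q10"),
                   list(1L, 3L, "alpha"), list(3L, 1L, "alpha"),
                   list(2L, 4L, "alpha"), list(4L, 2L, "alpha")))

  hid <- c("A", "B", "C", "D")
  st8 <- as.vector(t(outer(hid, c("0", "1"), function(h, o) paste0(o, h))))
  # st8 = 0A 1A 0B 1B 0C 1C 0D 1D
  obs8 <- rep(c("0", "1"), 4)
  qe <- list(); idx <- 1
  for (g in 0:3) {
    qe[[idx]] <- list(2L * g + 1L, 2L * g + 2L, "q01"); idx <- idx + 1
    qe[[idx]] <- list(2L * g + 2L, 2L * g + 1L, "q10"); idx <- idx + 1
  }
  for (g1 in 0:3) for (g2 in 0:3) {
    if (g1 == g2) next
    qe[[idx]] <- list(2L * g1 + 1L, 2L * g2 + 1L, "alpha"); idx <- idx + 1
    qe[[idx]] <- list(2L * g1 + 2L, 2L * g2 + 2L, "alpha"); idx <- idx + 1
  }
  cid4 <- hisseSpec("cid4",
    states = st8, stateObs = obs8,
    lamGroup = paste0("lambda", rep(hid, each = 2)),
    muGroup = paste0("mu", rep(hid, each = 2)),
    qEntries = do.call(qdf, qe))

  full <- hisseSpec("full",
    states = c("0A", "1A", "0B", "1B"), stateObs = c("0", "1", "0", "1"),
    lamGroup = c("lambda0A", "lambda1A", "lambda0B", "lambda1B"),
    muGroup = c("mu0A", "mu1A", "mu0B", "mu1B"),
    qEntries = qdf(list(1L, 2L, "q01"), list(2L, 1L, "q10"),
                   list(3L, 4L, "q01"), list(4L, 3L, "q10"),
                   list(1L, 3L, "alpha"), list(3L, 1L, "alpha"),
                   list(2L, 4L, "alpha"), list(4L, 2L, "alpha")))

  # hidden regime only under observed state 0; lineages entering state 0
  # arrive in regime A
  hidden0 <- hisseSpec("hidden0",
    states = c("0A", "0B", "1"), stateObs = c("0", "0", "1"),
    lamGroup = c("lambda0A", "lambda0B", "lambda1"),
    muGroup = c("mu0A", "mu0B", "mu1"),
    qEntries = qdf(list(1L, 3L, "q01"), list(2L, 3L, "q01"),
                   list(3L, 1L, "q10"),
                   list(1L, 2L, "alpha"), list(2L, 1L, "alpha")))

  hidden1 <- hisseSpec("hidden1",
    states = c("0", "1A", "1B"), stateObs = c("0", "1", "1"),
    lamGroup = c("lambda0", "lambda1A", "lambda1B"),
    muGroup = c("mu0", "mu1A", "mu1B"),
    qEntries = qdf(list(1L, 2L, "q01"),
                   list(2L, 1L, "q10"), list(3L, 1L, "q10"),
                   list(2L, 3L, "alpha"), list(3L, 2L, "alpha")))

  list(bisse = bisse, cid2 = cid2, cid4 = cid4, full = full,
       hidden0 = hidden0, hidden1 = hidden1)
}
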