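## Seeded generators for every input the pipeline consumes, with known
## ground truth so parameter-recovery and calibration tests are
## self-contained.  Each generator can write its outputs (Newick + TSV)
## together with a JSON manifest from which the files can be regenerated
## byte-identically.

#' Generate an SSE scenario (tree + tip states)
#'
#' Wraps [simulateSseForward()] and records the generating parameters.
#'
#' @param kind `"bisse"` or `"geosse"`.
#' @param pars Named true parameters.
#' @param nTips Number of extant tips (`>= 10`).
#' @param rootState Root state.
#' @param seed Integer seed.
#' @param rho Optional per-state sampling fractions (binomial thinning).
#' @param dir Optional output directory; when given, writes
#'   `tree.nwk`, `states.tsv` and `manifest.json`.
#' @return A `synth_scenario` list with the dataset, truth and paths.
#' @export
genSseScenario <- function(kind, pars, nTips, rootState, seed, rho = NULL,
                           dir = NULL) {
  if (nTips < 10) stop("nTips must be >= 10 for a scenario")
  sim <- simulateSseForward(kind, pars, nTips, rootState, seed = seed,
                            rho = rho)
  out <- list(generator = kind, pars = as.list(sim$pars), nTips = nTips,
              rootState = rootState, seed = seed,
              rho = if (is.null(rho)) NULL else as.list(rho),
              tree = sim$tree, states = sim$states)
  class(out) <- "synth_scenario"
  if (!is.null(dir)) out <- writeScenario(out, dir)
  out
}

#' Generate a threshold-model scenario
#'
#' Simulates a Yule backbone tree (or uses a supplied tree), evolves a
#' (liability, continuous trait) pair by correlated Brownian motion with
#' trait covariance `[[1, r*sigma], [r*sigma, sigma^2]]`, and codes the
#' binary state as `liability > 0`.
#'
#' @param nTips Number of tips (ignored when `tree` is given).
#' @param r True liability-trait correlation (`|r| <= 1`).
#' @param seed Integer seed.
#' @param sigma Brownian standard-deviation scale of the continuous trait.
#' @param birth Speciation rate of the Yule backbone (per Myr).
#' @param meanTrait Root value of the continuous trait.
#' @param tree Optional `phylo` backbone (e.g. an empirical tree).
#' @param dir Optional output directory (writes `tree.nwk`, `traits.tsv`,
#'   `manifest.json`).
#' @return A `synth_scenario` with `tree`, `states`, `trait`,
#'   `liability`.
#' @export
genThresholdScenario <- function(nTips, r, seed, sigma = 1, birth = 0.15,
                                 meanTrait = 4, tree = NULL, dir = NULL) {
  stopifnot(abs(r) <= 1)
  set.seed(seed)
  if (is.null(tree)) {
    yule <- c(lambda0 = birth, lambda1 = 0, mu0 = 0, mu1 = 0, q01 = 0, q10 = 0)
    tree <- simulateSseForward("bisse", yule, nTips, "0")$tree
    # grow the tree to just before the next speciation event so no tip pair
    # is separated by zero time (keeps the tip covariance non-singular)
    delta <- rexp(1, rate = nTips * birth)
    term <- tree$edge[, 2] <= ape::Ntip(tree)
    tree$edge.length[term] <- tree$edge.length[term] + delta
  }
  n <- ape::Ntip(tree)
  R <- matrix(c(1, r * sigma, r * sigma, sigma^2), 2, 2)
  Rchol <- t(chol(R + diag(1e-12, 2)))
  ntot <- n + tree$Nnode
  vals <- matrix(NA_real_, ntot, 2)
  vals[ape::Ntip(tree) + 1L, ] <- c(0, meanTrait) # root
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    e <- pre$edge[i, ]
    step <- Rchol %*% rnorm(2) * sqrt(pre$edge.length[i])
    vals[e[2], ] <- vals[e[1], ] + step
  }
  liab <- setNames(vals[seq_len(n), 1], tree$tip.label)
  trait <- setNames(vals[seq_len(n), 2], tree$tip.label)
  states <- setNames(as.integer(liab > 0), tree$tip.label)
  out <- list(generator = "threshold", r = r, sigma = sigma, birth = birth,
              meanTrait = meanTrait, nTips = nTips, seed = seed,
              tree = tree, states = states, trait = trait, liability = liab)
  class(out) <- "synth_scenario"
  if (!is.null(dir)) out <- writeScenario(out, dir)
  out
}

#' Generate a habitat/range table
#'
#' Habitat sets are drawn from a categorical distribution over specialist
#' classes and a generalist class (generalists get two or three habitats);
#' `log10` range size is `baseline + effect[class] + N(0, noise)`.
#'
#' @param n Number of species.
#' @param seed Integer seed.
#' @param probs Class probabilities, named
#'   `lentic, lotic, cave, burrow, generalist`; default approximates the
#'   mix of habitat specialists seen in temperate freshwater crayfish.
#' @param effects Named class effects on log10 range size (km^2).
#' @param baseline Baseline log10 range size.
#' @param noise Gaussian noise SD on the log10 scale.
#' @param dir Optional output directory (writes `habitat.tsv`,
#'   `manifest.json`).
#' @return A `synth_scenario` with `table` (a `habitat_table` carrying
#'   `log10_range_km2`).
#' @export
genRangeTable <- function(n, seed,
                          probs = c(lentic = 0.05, lotic = 0.42, cave = 0.08,
                                    burrow = 0.23, generalist = 0.22),
                          effects = c(lentic = -0.4, lotic = -0.2,
                                      cave = -0.8, burrow = -0.4,
                                      generalist = 0.6),
                          baseline = 4.3, noise = 0.5, dir = NULL) {
  stopifnot(all(is.finite(effects)), abs(sum(probs) - 1) < 1e-9)
  set.seed(seed)
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  habitats <- vector("list", n)
  burrower <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (cls[i] == "generalist") {
      k <- sample(2:3, 1, prob = c(0.8, 0.2))
      habitats[[i]] <- sort(sample(HABITATS, k))
      if ("burrow" %in% habitats[[i]]) burrower[i] <- "secondary"
    } else {
      habitats[[i]] <- cls[i]
      if (cls[i] == "burrow") burrower[i] <- "primary"
    }
  }
  species <- sprintf("sp%03d", seq_len(n))
  log10km2 <- baseline + effects[cls] + rnorm(n, 0, noise)
  tab <- habitatTable(species, habitats, burrower)
  tab$log10_range_km2 <- unname(log10km2)
  out <- list(generator = "ranges", n = n, seed = seed,
              probs = as.list(probs), effects = as.list(effects),
              baseline = baseline, noise = noise, trueClass = cls,
              table = tab)
  class(out) <- "synth_scenario"
  if (!is.null(dir)) out <- writeScenario(out, dir)
  out
}

# serialize a scenario to dir; manifest records everything needed to
# regenerate the files byte-identically
writeScenario <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(sc$tree)) {
    tf <- file.path(dir, "tree.nwk")
    writeTimeTree(sc$tree, tf)
    files <- c(files, tree = tf)
  }
  if (sc$generator == "threshold") {
    df <- data.frame(species = names(sc$states), state = unname(sc$states),
                     trait = unname(sc$trait))
    path <- file.path(dir, "traits.tsv")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, traits = path)
  } else if (sc$generator == "ranges") {
    tab <- sc$table
    flags <- t(vapply(tab$habitats, function(h) as.integer(HABITATS %in% h),
                      integer(4)))
    colnames(flags) <- HABITATS
    df <- data.frame(species = tab$species, flags, burrower = tab$burrower,
                     log10_range_km2 = tab$log10_range_km2)
    path <- file.path(dir, "habitat.tsv")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, habitat = path)
  } else {
    df <- data.frame(species = names(sc$states), state = unname(sc$states))
    path <- file.path(dir, "states.tsv")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, states = path)
  }
  manifest <- sc[setdiff(names(sc), c("tree", "states", "trait", "liability",
                                      "table", "trueClass", "files",
                                      "manifest"))]
  manifest$files <- lapply(files, basename)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  sc$files <- c(files, manifest = mf)
  sc
}

#' Regenerate a scenario from its manifest
#'
#' Reruns the recorded generator with the recorded seed and parameters,
#' writing into `dir`; outputs are byte-identical to the originals.
#'
#' @param manifest Path to a `manifest.json`.
#' @param dir Output directory.
#' @return The regenerated `synth_scenario`.
#' @export
regenerateScenario <- function(manifest, dir) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  switch(m$generator,
    threshold = genThresholdScenario(m$nTips, m$r, m$seed, m$sigma, m$birth,
                                     m$meanTrait, dir = dir),
    ranges = genRangeTable(m$n, m$seed, unlist(m$probs), unlist(m$effects),
                           m$baseline, m$noise, dir = dir),
    genSseScenario(m$generator, unlist(m$pars), m$nTips, m$rootState,
                   m$seed, rho = if (is.null(m$rho)) NULL else unlist(m$rho),
                   dir = dir))
}
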