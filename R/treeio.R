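#' @useDynLib speleodiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import ape
#' @importFrom stats median optim pchisq pnorm qnorm quantile rbinom rexp
#'   rnorm runif sd t.test var setNames acf dexp rgamma
#' @importFrom utils read.delim write.table head tail
NULL

## Time-calibrated trees are ape "phylo" objects; branch lengths are in Myr.
## These helpers add the validation, pruning and label conventions the
## downstream state-dependent analyses rely on.

#' Read a time-calibrated tree from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that validates the result as a
#' usable time tree: unique non-empty tip labels and finite, non-negative
#' branch lengths.  Label bytes are never altered; quoted labels and
#' underscore conventions are preserved verbatim.
#'
#' @param text A Newick string (terminated by `;`).
#' @param file Alternatively, path to a Newick file.
#' @return An object of class `phylo`.  The attribute `"bifurcating"` records
#'   whether the tree is strictly bifurcating (polytomies are readable but
#'   rejected later by the SSE likelihoods).
#' @export
readTimeTree <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("provide either 'text' or 'file'")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  checkNewickSyntax(text)
  # shield single-quoted labels from the parser, restore their bytes after
  qlabs <- regmatches(text, gregexpr("'(?:[^']|'')*'", text))[[1]]
  if (length(qlabs) > 0) {
    ph <- sprintf("xQUOTEDx%dx", seq_along(qlabs))
    for (i in seq_along(qlabs))
      text <- sub(qlabs[i], ph[i], text, fixed = TRUE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: reader returned no tree")
  if (length(qlabs) > 0) {
    unq <- gsub("''", "'", substr(qlabs, 2, nchar(qlabs) - 1))
    for (i in seq_along(qlabs)) {
      tr$tip.label[tr$tip.label == ph[i]] <- unq[i]
      if (!is.null(tr$node.label))
        tr$node.label[tr$node.label == ph[i]] <- unq[i]
    }
  }
  validateTimeTree(tr)
  attr(tr, "bifurcating") <- ape::is.binary(tr) && ape::is.rooted(tr)
  tr
}

# cheap structural scan so malformed input is reported with a character
# offset rather than an opaque parser failure
checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string (length %d)",
                 depth, length(chars)), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("malformed Newick: missing ';' terminator at character %d",
                 length(chars) + 1L), call. = FALSE)
  invisible(TRUE)
}

#' Validate a tree for use in downstream analyses
#'
#' Checks the invariants every module assumes: class `phylo`, unique
#' non-empty tip labels, finite branch lengths `>= 0`.  Zero-length terminal
#' branches are allowed but reported with a message, because they degenerate
#' tip conditioning in the SSE likelihoods.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.
#' @export
validateTimeTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  nzero <- sum(tree$edge.length[term] == 0)
  if (nzero > 0)
    message(nzero, " zero-length terminal branch(es); tip conditioning may be degenerate")
  invisible(tree)
}

#' Write a tree to a Newick string
#'
#' Inverse of [readTimeTree()]: `readTimeTree(writeTimeTree(t))` reproduces
#' topology and branch lengths to 1e-9.  Labels containing characters
#' outside `[A-Za-z0-9_.|-]` are single-quoted.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
writeTimeTree <- function(tree, file = NULL, digits = 12) {
  validateTimeTree(tree)
  needsQuote <- grepl("[^A-Za-z0-9_.|/-]", tree$tip.label)
  orig <- tree$tip.label[needsQuote]
  if (any(needsQuote)) {
    ph <- sprintf("xQUOTEDx%dx", seq_along(orig))
    tree$tip.label[needsQuote] <- ph
  }
  out <- ape::write.tree(tree, digits = digits)
  if (any(needsQuote)) {
    quoted <- paste0("'", gsub("'", "''", orig), "'")
    for (i in seq_along(orig))
      out <- sub(ph[i], quoted[i], out, fixed = TRUE)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read or assemble a set of trees sharing one tip set
#'
#' Bootstrap replicate trees are stored one Newick string per line.  All
#' members must share an identical tip-label set.
#'
#' @param file Path to a file with one Newick tree per line.
#' @param trees Alternatively, a list of `phylo` objects.
#' @return A `multiPhylo` object with attribute `"ntrees"`.
#' @export
readTreeSet <- function(file = NULL, trees = NULL) {
  if (is.null(trees)) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    trees <- lapply(lines, function(x) readTimeTree(text = x))
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " does not share the tip-label set of tree 1")
  }
  out <- trees
  class(out) <- "multiPhylo"
  attr(out, "ntrees") <- length(out)
  out
}

#' Prune a tree to a set of tips
#'
#' Keeps exactly the requested tips, suppressing degree-2 internal nodes
#' with branch lengths summed, so root-to-tip distances of kept tips are
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (`>= 2`).
#' @return The pruned `phylo`.
#' @export
pruneToTaxa <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0)
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}

#' Collapse subspecies to one representative tip per species
#'
#' Tip labels following the `Genus_species[_subspecies]` convention are
#' grouped by their binomial (first two underscore-separated tokens); the
#' alphabetically first tip label per binomial is retained via
#' [pruneToTaxa()].  Which representative the original analyses kept is not
#' recorded anywhere, so alphabetical retention is this package's
#' convention.
#'
#' @param tree A `phylo` object.
#' @param sep Token separator in tip labels (default `"_"`).
#' @return A `phylo` with at most one tip per binomial.
#' @export
collapseSubspecies <- function(tree, sep = "_") {
  labs <- tree$tip.label
  toks <- strsplit(labs, sep, fixed = TRUE)
  binom <- vapply(toks, function(x) paste(head(x, 2), collapse = sep), "")
  keep <- vapply(split(labs, binom), function(x) sort(x)[1], "")
  if (length(keep) == length(labs)) return(tree)
  pruneToTaxa(tree, unname(keep))
}

#' Check ultrametricity and report the deviation
#'
#' Computes max minus min root-to-tip depth.  SSE likelihoods require the
#' deviation to be within tolerance; penalized-likelihood chronograms carry
#' rounding noise, hence the relative default.
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance; default `1e-6` times tree height.
#' @return List with `deviation`, `height`, `tol` and logical `ok`.
#' @export
ultrametricityCheck <- function(tree, tol = NULL) {
  depths <- nodeDepths(tree)[seq_len(ape::Ntip(tree))]
  height <- max(depths)
  if (is.null(tol)) tol <- 1e-6 * height
  dev <- max(depths) - min(depths)
  list(deviation = dev, height = height, tol = tol, ok = dev <= tol)
}

# root-to-node depths for all nodes (preorder accumulation)
nodeDepths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tr$edge)))
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  depth
}

# shared guard used by the SSE likelihoods and SSCD
assertBifurcating <- function(tree, what = "this operation") {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop(what, " requires a strictly bifurcating tree")
  invisible(tree)
}
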