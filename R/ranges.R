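## Habitat coding and geographic range-size summaries.
##
## Species occupy one or more of four habitat classes (lentic, lotic, cave,
## burrow).  Range sizes arrive as per-polygon areas in m^2 (GIS extraction
## is upstream and out of scope); total range is the polygon sum converted
## to km^2 and log10-transformed.

HABITATS <- c("lentic", "lotic", "cave", "burrow")

#' Build a habitat table
#'
#' @param species Character vector of species labels (unique).
#' @param habitats List of character vectors, each a non-empty subset of
#'   `c("lentic","lotic","cave","burrow")`.
#' @param burrower Optional character vector (`"primary"`, `"secondary"` or
#'   `NA`).  Primary (obligate) burrowers must have habitat set exactly
#'   `{burrow}`.
#' @return A `habitat_table` (data.frame with a list-column `habitats`).
#' @export
habitatTable <- function(species, habitats, burrower = NULL) {
  if (anyDuplicated(species)) stop("duplicate species in habitat table")
  if (length(habitats) != length(species))
    stop("species and habitats lengths differ")
  habitats <- lapply(habitats, function(h) {
    h <- unique(as.character(h))
    if (length(h) == 0) stop("species with empty habitat set")
    bad <- setdiff(h, HABITATS)
    if (length(bad) > 0) stop("unknown habitat(s): ", paste(bad, collapse = ", "))
    sort(h)
  })
  if (is.null(burrower)) burrower <- rep(NA_character_, length(species))
  prim <- !is.na(burrower) & burrower == "primary"
  bad <- prim & !vapply(habitats, function(h) identical(h, "burrow"), TRUE)
  if (any(bad))
    stop("primary burrowers must have habitat set exactly {burrow}: ",
         paste(species[bad], collapse = ", "))
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  out$habitats <- habitats
  out$burrower <- burrower
  class(out) <- c("habitat_table", class(out))
  out
}

#' Read a habitat/range TSV
#'
#' Expects columns `species`, four 0/1 habitat flags (`lentic`, `lotic`,
#' `cave`, `burrow`), optionally `burrower` and `log10_range_km2`.
#'
#' @param file Path to a tab-separated file with a header.
#' @return A `habitat_table`; any `log10_range_km2` column is carried along.
#' @export
readHabitatTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("species", HABITATS)
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  habs <- lapply(seq_len(nrow(d)), function(i)
    HABITATS[as.logical(unlist(d[i, HABITATS]))])
  tab <- habitatTable(d$species, habs,
                      if ("burrower" %in% names(d)) d$burrower else NULL)
  if ("log10_range_km2" %in% names(d)) tab$log10_range_km2 <- d$log10_range_km2
  tab
}

#' Total range size from polygon areas
#'
#' Sums per-polygon areas given in m^2, converts to km^2 and stores the
#' log10 value alongside.
#'
#' @param areas_m2 Numeric vector of polygon areas in m^2, all `> 0`.
#' @return List with `km2` and `log10_km2`.
#' @export
totalRangeKm2 <- function(areas_m2) {
  if (length(areas_m2) < 1) stop("need at least one polygon area")
  if (any(!is.finite(areas_m2)) || any(areas_m2 <= 0))
    stop("polygon areas must be finite and > 0")
  km2 <- sum(areas_m2) / 1e6
  list(km2 = km2, log10_km2 = log10(km2))
}

#' Binary habitat coding for one focal class
#'
#' Specialists in the focal habitat are coded 0 and everything else 1
#' (so for `focal = "cave"`: exclusively cave-dwelling = 0, any surface use
#' = 1).  For `focal = "generalist"` species occupying two or more habitats
#' are coded 0 and single-habitat species 1.
#'
#' @param table A `habitat_table`.
#' @param focal One of `"lentic"`, `"lotic"`, `"cave"`, `"burrow"`,
#'   `"generalist"`.
#' @return Named integer vector (0/1) over species.
#' @export
binaryCoding <- function(table, focal) {
  focal <- match.arg(focal, c(HABITATS, "generalist"))
  code <- vapply(table$habitats, function(h) {
    if (length(h) == 0) stop("species with empty habitat set")
    if (focal == "generalist") {
      if (length(h) >= 2) 0L else 1L
    } else {
      if (identical(h, focal)) 0L else 1L
    }
  }, 1L)
  setNames(code, table$species)
}

#' Three-state coding for region-style (GeoSSE) analyses
#'
#' Obligate cave-dwellers are `A`, species never using caves are `B`, and
#' troglophiles occupying caves plus another habitat are `AB`.
#'
#' @param table A `habitat_table`.
#' @return Named character vector over species with values in
#'   `c("A","B","AB")`.
#' @export
geoCoding <- function(table) {
  code <- vapply(table$habitats, function(h) {
    if (length(h) == 0) stop("species with empty habitat set")
    if (identical(h, "cave")) "A"
    else if (!"cave" %in% h) "B"
    else "AB"
  }, "")
  setNames(code, table$species)
}

#' Per-class median range size
#'
#' Medians are computed on the km^2 scale with the linear-interpolation
#' midpoint convention for even counts.  Empty classes are reported as
#' absent rather than zero.
#'
#' @param km2 Named numeric vector of range sizes in km^2 per species.
#' @param coding Named vector of class labels over (a superset of) the same
#'   species.
#' @return Data frame with `class`, `n` and `median_km2`, one row per class
#'   present.
#' @export
medianRangeByClass <- function(km2, coding) {
  common <- intersect(names(km2), names(coding))
  if (length(common) < length(names(km2)))
    message(length(names(km2)) - length(common), " species without coding dropped")
  cls <- split(km2[common], as.character(coding[common]))
  data.frame(class = names(cls),
             n = vapply(cls, length, 1L),
             median_km2 = vapply(cls, median, 1.0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Match tree tips with a trait table
#'
#' Prunes the tree to species present in `species` and reports how many tips
#' were dropped, mirroring the trimming of a phylogeny to the taxa that have
#' data.
#'
#' @param tree A `phylo`.
#' @param species Character vector of species with data.
#' @return List with pruned `tree` and `dropped` (labels removed).
#' @export
matchTreeData <- function(tree, species) {
  keep <- intersect(tree$tip.label, species)
  dropped <- setdiff(tree$tip.label, keep)
  if (length(dropped) > 0)
    message(length(dropped), " tip(s) without data dropped from tree")
  tree <- if (length(dropped) > 0) pruneToTaxa(tree, keep) else tree
  list(tree = tree, dropped = dropped)
}
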