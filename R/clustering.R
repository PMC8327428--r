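# Single-linkage threshold clustering over the UNITE species-hypothesis grid.
#
# A species hypothesis at threshold t is a connected component of the graph
# whose edges join record pairs with p-distance <= t/100 (inclusive: ties at
# exactly t merge). Missing distances -- pairs below the overlap minimum --
# contribute no edge; they are never treated as 0 or 1. Single linkage is
# what makes SH membership nest across thresholds.

.edgeTol <- 1e-12

#' Cluster records at one distance threshold
#'
#' @param D a [DistanceMatrix-class].
#' @param t distance threshold in percent (UNITE scale: `0.5` means 99.5%
#'   similarity); must be >= 0.
#' @param linkage `"single"` (connected components; the default and the SH
#'   model), or `"complete"`/`"average"` for sensitivity analysis (via
#'   [stats::hclust] on the same distances; missing pairs are not supported
#'   there).
#' @return named character vector id -> cluster label; each cluster is
#'   labelled by its lexicographically smallest member id. The threshold is
#'   attached as attribute `threshold`.
#' @examples
#' aln <- validateAlignment(c(a = "ACGT", b = "ACGT", c = "TTTT"))
#' D <- distanceMatrix(aln, minOverlap = 1)
#' clusterAtThreshold(D, 0)
#' @export
clusterAtThreshold <- function(D, t, linkage = c("single", "complete",
                                                 "average")) {
  linkage <- match.arg(linkage)
  stopifnot(is(D, "DistanceMatrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("threshold must be a single non-negative percent value")
  }
  ids <- seqIds(D)
  if (linkage == "single") {
    adj <- !is.na(D@d) & D@d <= t / 100 + .edgeTol
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]]),
      directed = FALSE,
      vertices = data.frame(name = ids))
    memb <- igraph::components(g)$membership[ids]
  } else {
    if (anyNA(D@d)) {
      stop("complete/average linkage requires a complete distance matrix")
    }
    hc <- stats::hclust(stats::as.dist(D@d), method = linkage)
    memb <- stats::setNames(stats::cutree(hc, h = t / 100 + .edgeTol), ids)
  }
  lab <- vapply(split(ids, memb), min, character(1L))
  out <- stats::setNames(lab[as.character(memb)], ids)
  attr(out, "threshold") <- t
  out
}

#' Sweep the species-hypothesis threshold grid
#'
#' Clusters the same distance matrix at every threshold of the grid
#' (default the UNITE range 0-3% in 0.5 steps). With single linkage the
#' cluster count is non-increasing and the partitions nest as the threshold
#' grows.
#'
#' @param D a [DistanceMatrix-class].
#' @param grid ascending numeric thresholds in percent.
#' @return a [ThresholdSweep-class].
#' @examples
#' aln <- validateAlignment(c(a = "ACGT", b = "ACGA", c = "TTTT"))
#' sw <- thresholdSweep(distanceMatrix(aln, minOverlap = 1))
#' clusterCounts(sw)
#' @export
thresholdSweep <- function(D, grid = seq(0, 3, by = 0.5)) {
  stopifnot(is(D, "DistanceMatrix"))
  if (length(grid) == 0L) stop("empty threshold grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted ascending")
  labels <- vapply(grid, function(t) clusterAtThreshold(D, t),
                   character(length(seqIds(D))))
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = length(seqIds(D)))
  dimnames(labels) <- list(seqIds(D), sprintf("%.1f%%", grid))
  new("ThresholdSweep", thresholds = as.numeric(grid), labels = labels)
}
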