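# Accessors and show() methods for the S4 containers.

# node times measured back from the tips (tips at 0, root oldest)
.nodeTimes <- function(tr) {
  if (length(tr$tip.label) == 1L) return(c(0, sum(tr$edge.length)))
  depth <- ape::node.depth.edgelength(tr)
  max(depth) - depth
}

#' @rdname ITSAlignment-class
#' @export
setMethod("seqIds", "ITSAlignment", function(x) rownames(x@seqs))

#' @rdname ITSAlignment-class
#' @export
setMethod("nSequences", "ITSAlignment", function(x) nrow(x@seqs))

#' @rdname ITSAlignment-class
#' @export
setMethod("nSites", "ITSAlignment", function(x) ncol(x@seqs))

#' @rdname ITSAlignment-class
#' @export
setMethod("regionMap", "ITSAlignment", function(x) x@regions)

#' @rdname ITSAlignment-class
#' @export
setMethod("alignmentMatrix", "ITSAlignment", function(x) x@seqs)

#' @rdname ITSAlignment-class
#' @export
setMethod("sequenceStrings", "ITSAlignment", function(x) .collapseRows(x@seqs))

setMethod("show", "ITSAlignment", function(object) {
  cat("ITSAlignment:", nSequences(object), "records x", nSites(object),
      "sites\n")
  if (nrow(object@regions) > 0L) {
    cat("regions:",
        paste(sprintf("%s[%d,%d)", object@regions$name, object@regions$start,
                      object@regions$end), collapse = " "), "\n")
  }
  ids <- seqIds(object)
  if (length(ids)) {
    cat("ids:", paste(utils::head(ids, 5L), collapse = ", "),
        if (length(ids) > 5L) "..." else "", "\n")
  }
})

#' Subset an alignment by record id
#'
#' @param x an `ITSAlignment`.
#' @param i record ids or indices.
#' @param j,...,drop ignored (kept for generic compatibility).
#' @return an `ITSAlignment` with the selected records.
#' @export
setMethod("[", "ITSAlignment", function(x, i, j, ..., drop = FALSE) {
  new("ITSAlignment", seqs = x@seqs[i, , drop = FALSE], regions = x@regions)
})

#' @rdname DistanceMatrix-class
#' @export
setMethod("seqIds", "DistanceMatrix", function(x) rownames(x@d))

#' @rdname DistanceMatrix-class
#' @export
setMethod("distances", "DistanceMatrix", function(x) x@d)

#' @rdname DistanceMatrix-class
#' @export
setMethod("comparedSites", "DistanceMatrix", function(x) x@compared)

setMethod("show", "DistanceMatrix", function(object) {
  n <- nrow(object@d)
  miss <- sum(is.na(object@d[upper.tri(object@d)]))
  cat("DistanceMatrix:", n, "records,", miss, "missing pair(s),",
      "min overlap", object@minOverlap, "sites\n")
  off <- object@d[upper.tri(object@d)]
  if (any(!is.na(off))) {
    cat(sprintf("p-distance range: %.4f - %.4f\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
})

#' @rdname ThresholdSweep-class
#' @export
setMethod("thresholds", "ThresholdSweep", function(x) x@thresholds)

#' @rdname ThresholdSweep-class
#' @export
setMethod("seqIds", "ThresholdSweep", function(x) rownames(x@labels))

#' @rdname ThresholdSweep-class
#' @export
setMethod("clusterCounts", "ThresholdSweep", function(x) {
  stats::setNames(apply(x@labels, 2L, function(v) length(unique(v))),
                  colnames(x@labels))
})

#' @rdname ThresholdSweep-class
#' @export
setMethod("partitionAt", "ThresholdSweep", function(x, t) {
  i <- which(abs(x@thresholds - t) < 1e-9)
  if (length(i) != 1L) {
    stop("threshold ", t, " is not on the grid (",
         paste(x@thresholds, collapse = ", "), ")")
  }
  out <- stats::setNames(x@labels[, i], rownames(x@labels))
  attr(out, "threshold") <- x@thresholds[i]
  out
})

setMethod("show", "ThresholdSweep", function(object) {
  cat("ThresholdSweep:", nrow(object@labels), "records over grid",
      paste0(object@thresholds, "%", collapse = ", "), "\n")
  cc <- clusterCounts(object)
  cat("clusters:", paste(cc, collapse = ", "), "\n")
})

#' @rdname SpeciesTreeModel-class
#' @export
setMethod("speciesNames", "SpeciesTreeModel", function(x) x@tree$tip.label)

#' @rdname SpeciesTreeModel-class
#' @export
setMethod("nodeTimes", "SpeciesTreeModel", function(x) .nodeTimes(x@tree))

#' @rdname SpeciesTreeModel-class
#' @export
setMethod("thetaValues", "SpeciesTreeModel", function(x) x@theta)

setMethod("show", "SpeciesTreeModel", function(object) {
  tm <- .nodeTimes(object@tree)
  cat("SpeciesTreeModel:", length(object@tree$tip.label), "species (",
      paste(utils::head(object@tree$tip.label, 5L), collapse = ", "),
      if (length(object@tree$tip.label) > 5L) "..." else "", ")\n")
  cat(sprintf("root age tau = %.4g, theta range %.4g - %.4g (subst/site)\n",
              max(tm), min(object@theta), max(object@theta)))
})

setMethod("show", "GeneGenealogy", function(object) {
  cat("GeneGenealogy:", length(object@tree$tip.label), "lineages from",
      length(unique(object@species)), "species\n")
})

#' @rdname DiagnosticTable-class
#' @export
setMethod("diagnosticPositions", "DiagnosticTable", function(x) x@table)

#' @rdname DiagnosticTable-class
#' @export
setMethod("nSites", "DiagnosticTable", function(x) nrow(x@table))

setMethod("show", "DiagnosticTable", function(object) {
  cat("DiagnosticTable:", nrow(object@table), "diagnostic column(s)")
  if (nrow(object@table)) {
    cat(" for", length(unique(object@table$species)), "species")
  }
  cat("\n")
  if (nrow(object@table)) {
    print(utils::head(object@table, 10L), row.names = FALSE)
    if (nrow(object@table) > 10L) cat("...\n")
  }
})
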