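# Comparison of threshold partitions with the reference species partition.
#
# "Strictly distinguished" is formalised as the `resolved` status: a species
# is resolved at threshold t when its reference members form exactly one
# cluster and that cluster contains no reference member of another species.
# Query (unlabelled) records never enter the status computation; they are
# reported with their cluster only.

#' Evaluate one partition against the reference species labels
#'
#' Status per species: `resolved` (one pure, complete cluster), `split`
#' (>= 2 clusters, all pure), `merged` (its single cluster also holds other
#' species), `mixed` (split and impure at once).
#'
#' @param partition named character vector id -> cluster label (from
#'   [clusterAtThreshold()] or [partitionAt()]).
#' @param map species map data.frame (`id`, `species`, `role`); see
#'   [speciesMap()].
#' @return data.frame `species`, `status`, `clusters` (`;`-separated
#'   labels), `nMembers`.
#' @examples
#' aln <- validateAlignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "TTTT"))
#' m <- speciesMap(data.frame(id = c("a1", "a2", "b1"),
#'                            species = c("A", "A", "B"),
#'                            role = "reference"))
#' p <- clusterAtThreshold(distanceMatrix(aln, minOverlap = 1), 0)
#' evaluatePartition(p, m)
#' @export
evaluatePartition <- function(partition, map) {
  ref <- map[map$role == "reference", , drop = FALSE]
  if (nrow(ref) == 0L) stop("no reference records in species map")
  missing <- setdiff(ref$id, names(partition))
  if (length(missing)) {
    stop("reference ids absent from partition: ",
         paste(missing, collapse = ", "))
  }
  species <- unique(ref$species)
  counts <- table(ref$species)
  if (any(counts == 0L)) stop("species with zero members")
  refClusters <- partition[ref$id]
  out <- lapply(species, function(s) {
    memberIds <- ref$id[ref$species == s]
    cl <- unique(unname(refClusters[memberIds]))
    pure <- vapply(cl, function(lab) {
      inCl <- ref$id[refClusters[ref$id] == lab]
      all(ref$species[match(inCl, ref$id)] == s)
    }, logical(1L))
    status <- if (length(cl) == 1L && pure) "resolved"
      else if (length(cl) >= 2L && all(pure)) "split"
      else if (length(cl) == 1L) "merged"
      else "mixed"
    data.frame(species = s, status = status,
               clusters = paste(sort(cl), collapse = ";"),
               nMembers = length(memberIds), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Minimal resolving threshold of a sweep
#'
#' The smallest grid threshold at which every species in `scope` is
#' `resolved`; `NA` when no grid point qualifies (e.g. two species sharing
#' identical ITS). The overall minimum over a scope equals the maximum of
#' the per-species minima on a shared grid.
#'
#' @param sweep a [ThresholdSweep-class].
#' @param map species map data.frame.
#' @param scope species labels to require (default: every reference
#'   species).
#' @return a grid threshold (percent distance) or `NA`. The similarity
#'   complement (e.g. 99.5 for 0.5) is attached as attribute `similarity`.
#' @export
minResolvingThreshold <- function(sweep, map, scope = NULL) {
  stopifnot(is(sweep, "ThresholdSweep"))
  ref <- map[map$role == "reference", , drop = FALSE]
  if (is.null(scope)) scope <- unique(ref$species)
  if (length(scope) == 0L) stop("empty scope")
  for (t in sweep@thresholds) {
    ev <- evaluatePartition(partitionAt(sweep, t), map)
    ev <- ev[ev$species %in% scope, , drop = FALSE]
    if (nrow(ev) == length(scope) && all(ev$status == "resolved")) {
      return(structure(t, similarity = 100 - t))
    }
  }
  structure(NA_real_, similarity = NA_real_)
}

#' Per-record threshold-by-cluster table
#'
#' Flat table mirroring the per-threshold colour-bar columns of an SH plot:
#' one row per record, one cluster column per grid threshold, plus the
#' species label and role. Re-grouping any column regenerates that
#' threshold's partition exactly.
#'
#' @param sweep a [ThresholdSweep-class].
#' @param map optional species map (adds `species` and `role` columns).
#' @return data.frame with columns `id`, `species`, `role`,
#'   `cluster@<t>%`...
#' @export
shTable <- function(sweep, map = NULL) {
  stopifnot(is(sweep, "ThresholdSweep"))
  ids <- seqIds(sweep)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    i <- match(ids, map$id)
    out$species <- map$species[i]
    out$role <- map$role[i]
  }
  lab <- sweep@labels
  colnames(lab) <- paste0("cluster@", colnames(lab))
  cbind(out, as.data.frame(lab, stringsAsFactors = FALSE))
}

#' Full per-threshold evaluation report
#'
#' @param sweep a [ThresholdSweep-class].
#' @param map species map data.frame.
#' @param scope species labels used for the minimal resolving threshold
#'   (default all reference species; always echoed in the result so the
#'   species scope of any threshold claim is explicit).
#' @return list with `statuses` (data.frame: threshold, species, status,
#'   clusters), `clusterCounts`, `perSpeciesMin` (named vector of each
#'   species' smallest resolving grid threshold), `minResolving` (overall,
#'   percent distance), `minResolvingSimilarity`, and `scope`.
#' @export
evalReport <- function(sweep, map, scope = NULL) {
  stopifnot(is(sweep, "ThresholdSweep"))
  ref <- map[map$role == "reference", , drop = FALSE]
  if (is.null(scope)) scope <- unique(ref$species)
  st <- do.call(rbind, lapply(sweep@thresholds, function(t) {
    ev <- evaluatePartition(partitionAt(sweep, t), map)
    cbind(threshold = t, ev)
  }))
  perMin <- vapply(unique(ref$species), function(s) {
    ok <- st$species == s & st$status == "resolved"
    if (any(ok)) min(st$threshold[ok]) else NA_real_
  }, numeric(1L))
  overall <- minResolvingThreshold(sweep, map, scope = scope)
  list(statuses = st,
       clusterCounts = clusterCounts(sweep),
       perSpeciesMin = perMin,
       minResolving = as.numeric(overall),
       minResolvingSimilarity = attr(overall, "similarity"),
       scope = scope)
}
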