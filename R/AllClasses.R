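#' @import methods
#' @importFrom stats rexp rbinom rgamma sd quantile setNames median
NULL

setOldClass("phylo")

#' Locus specification for the synthetic ITS generator
#'
#' Describes the simulated locus as an ordered set of contiguous regions
#' (typically ITS1, 5.8S, ITS2 and optionally a partial LSU), each with a
#' length in sites and a relative substitution-rate multiplier, plus the
#' substitution model used to evolve sequences.
#'
#' @slot regions data.frame with columns `name`, `length`, `rate`.
#' @slot model substitution model, `"JC69"` or `"HKY85"`.
#' @slot kappa transition/transversion rate ratio (HKY85 only).
#' @slot baseFreqs equilibrium base frequencies (A, C, G, T).
#' @seealso [locusSpec()]
#' @exportClass LocusSpec
setClass("LocusSpec",
  representation(regions = "data.frame", model = "character",
                 kappa = "numeric", baseFreqs = "numeric"))

setValidity("LocusSpec", function(object) {
  r <- object@regions
  if (!all(c("name", "length", "rate") %in% names(r)))
    return("regions needs columns name, length, rate")
  if (nrow(r) == 0L || sum(r$length) == 0L) return("zero total length")
  if (any(r$length <= 0) || any(r$length != as.integer(r$length)))
    return("region lengths must be positive integers")
  if (any(r$rate < 0)) return("rate multipliers must be non-negative")
  if (anyDuplicated(r$name)) return("duplicated region names")
  if (!object@model %in% c("JC69", "HKY85")) return("model must be JC69 or HKY85")
  if (length(object@baseFreqs) != 4L || abs(sum(object@baseFreqs) - 1) > 1e-8 ||
      any(object@baseFreqs < 0))
    return("baseFreqs must be 4 non-negative values summing to 1")
  if (object@kappa <= 0) return("kappa must be positive")
  TRUE
})

#' Species-tree model for the multispecies coalescent
#'
#' A rooted, binary, ultrametric species tree with divergence times tau and
#' per-population size parameters theta, both expressed in expected
#' substitutions per site (the usual coalescent-delimitation convention, so
#' no separate mutation-rate parameter is needed). Each node of the tree --
#' tips and ancestors alike -- is one population.
#'
#' @slot tree an [ape::phylo] tree; branch lengths in expected
#'   substitutions/site, all tips at time 0.
#' @slot theta named numeric, one value per population (tip labels first,
#'   then internal nodes in `ape` numbering order), each > 0.
#' @seealso [speciesTreeModel()], [simulateGenealogy()]
#' @exportClass SpeciesTreeModel
setClass("SpeciesTreeModel",
  representation(tree = "phylo", theta = "numeric"))

setValidity("SpeciesTreeModel", function(object) {
  tr <- object@tree
  ntip <- length(tr$tip.label)
  if (ntip < 1L) return("tree has no tips")
  if (is.null(tr$edge.length)) return("tree has no branch lengths")
  if (!ape::is.rooted(tr)) return("tree must be rooted")
  if (!ape::is.binary(tr) && ntip > 1L) return("tree must be binary")
  tm <- .nodeTimes(tr)
  if (any(abs(tm[seq_len(ntip)]) > 1e-10))
    return("tree must be ultrametric (all tips at time 0)")
  # parent strictly older than child
  pt <- tm[tr$edge[, 1L]] - tm[tr$edge[, 2L]]
  if (any(pt <= 0)) return("every parent must be strictly older than its children")
  if (length(object@theta) != ntip + tr$Nnode)
    return("theta must have one value per population (tips + internal nodes)")
  if (any(object@theta <= 0)) return("theta must be positive on every branch")
  TRUE
})

#' Gene genealogy sampled under the multispecies coalescent
#'
#' @slot tree rooted binary [ape::phylo] over sampled lineages; branch lengths
#'   in expected substitutions/site.
#' @slot species named character, tip label -> species label.
#' @seealso [simulateGenealogy()], [evolveSequences()]
#' @exportClass GeneGenealogy
setClass("GeneGenealogy",
  representation(tree = "phylo", species = "character"))

setValidity("GeneGenealogy", function(object) {
  tr <- object@tree
  if (!setequal(names(object@species), tr$tip.label))
    return("species map must cover exactly the tip labels")
  if (any(!nzchar(object@species))) return("empty species label")
  TRUE
})

#' Aligned ITS sequences with region annotation
#'
#' The central alignment container: equal-length IUPAC sequences (rows) with
#' a region map (e.g. ITS1 / 5.8S / ITS2) in 0-based half-open coordinates.
#' `-` is an alignment gap, `?` a missing (e.g. truncated) residue; both are
#' treated as "no information" by the distance and diagnostic code.
#'
#' @slot seqs character matrix, rows = records (rownames are the unique ids),
#'   columns = alignment positions.
#' @slot regions data.frame with columns `name`, `start`, `end`
#'   (0-based half-open).
#' @seealso [validateAlignment()], [distanceMatrix()]
#' @exportClass ITSAlignment
setClass("ITSAlignment",
  representation(seqs = "matrix", regions = "data.frame"))

setValidity("ITSAlignment", function(object) {
  m <- object@seqs
  if (nrow(m) > 0L) {
    ids <- rownames(m)
    if (is.null(ids) || any(!nzchar(ids))) return("records need non-empty ids")
    if (anyDuplicated(ids)) {
      return(paste0("duplicated ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    bad <- !(m %in% .ALPHABET)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      return(sprintf("illegal character '%s' in record '%s' at position %d",
                     m[w[1L], w[2L]], ids[w[1L]], w[2L]))
    }
  }
  res <- tryCatch(.checkRegions(object@regions, ncol(m)),
                  error = function(e) conditionMessage(e))
  if (is.character(res)) return(res)
  TRUE
})

#' Pairwise p-distance matrix with explicit missingness
#'
#' Symmetric matrix of uncorrected p-distances together with the per-pair
#' count of compared (both-unambiguous) sites. Pairs whose overlap falls
#' below `minOverlap` sites carry `NA` ("missing") and contribute no edge to
#' threshold clustering.
#'
#' @slot d numeric matrix in \[0,1\], `NA` = missing; zero diagonal.
#' @slot compared integer matrix of compared-site counts.
#' @slot minOverlap minimum overlap (sites) below which a pair is missing.
#' @seealso [distanceMatrix()], [clusterAtThreshold()]
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(d = "matrix", compared = "matrix", minOverlap = "integer"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (!identical(dim(d), dim(object@compared))) return("dimension mismatch")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("dimnames must be the record ids, identical on both margins")
  if (any(abs(diag(d)) > 0, na.rm = TRUE)) return("diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d)))) return("matrix must be symmetric")
  off <- d[upper.tri(d)]
  if (any(off < 0 | off > 1, na.rm = TRUE)) return("distances must lie in [0,1]")
  miss <- is.na(d) & upper.tri(d)
  short <- object@compared < object@minOverlap & upper.tri(d)
  if (!identical(which(miss), which(short)))
    return("missing entries must be exactly the pairs with overlap < minOverlap")
  TRUE
})

#' Threshold sweep over the species-hypothesis grid
#'
#' Single-linkage partitions of the same distance matrix at each threshold of
#' the UNITE-style grid (percent distance). Cluster labels are the
#' lexicographically smallest member id, so labelling is deterministic.
#'
#' @slot thresholds ascending numeric grid, in percent distance.
#' @slot labels character matrix: rows = record ids, one column per threshold.
#' @seealso [thresholdSweep()], [minResolvingThreshold()]
#' @exportClass ThresholdSweep
setClass("ThresholdSweep",
  representation(thresholds = "numeric", labels = "matrix"))

setValidity("ThresholdSweep", function(object) {
  t <- object@thresholds
  if (length(t) == 0L) return("empty threshold grid")
  if (is.unsorted(t, strictly = TRUE)) return("grid must be strictly ascending")
  if (any(t < 0)) return("negative threshold")
  if (ncol(object@labels) != length(t)) return("one label column per threshold")
  counts <- apply(object@labels, 2L, function(x) length(unique(x)))
  if (any(diff(counts) > 0)) return("cluster counts must be non-increasing in t")
  TRUE
})

#' Species-diagnostic alignment columns
#'
#' Columns whose state is fixed (and unambiguous) within one reference
#' species and absent from all other reference species; the basis for placing
#' short or low-quality sequences that were excluded from clustering.
#'
#' @slot table data.frame with columns `column` (0-based alignment index),
#'   `species`, `state`.
#' @slot profiles data.frame with columns `column`, `species`, `states`:
#'   the observed unambiguous states of every reference species at each
#'   diagnostic column (comma-separated).
#' @seealso [findDiagnosticPositions()], [placeSequence()]
#' @exportClass DiagnosticTable
setClass("DiagnosticTable",
  representation(table = "data.frame", profiles = "data.frame"))

setValidity("DiagnosticTable", function(object) {
  if (!all(c("column", "species", "state") %in% names(object@table)))
    return("table needs columns column, species, state")
  if (nrow(object@table) > 0L && is.unsorted(object@table$column))
    return("entries must be ordered by column index")
  TRUE
})
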