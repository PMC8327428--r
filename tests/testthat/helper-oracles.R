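# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results through different code paths
# than the package (matrix transitive closure, naive column scans).

# Strip the bookkeeping attribute from a partition vector.
bare <- function(p) {
  attr(p, "threshold") <- NULL
  p
}

# Single-linkage clusters by boolean transitive closure of the adjacency
# matrix; labels follow the package convention (smallest member id).
closureClusters <- function(d, t) {
  ids <- rownames(d)
  adj <- !is.na(d) & d <= t / 100 + 1e-12
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% adj) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labs <- vapply(seq_along(ids), function(i) min(ids[reach[i, ]]),
                 character(1L))
  stats::setNames(labs, ids)
}

# Naive per-column diagnostic scan (tolerance 0), independent of the
# package implementation.
naiveDiagnosticScan <- function(aln, map) {
  ref <- map[map$role == "reference", , drop = FALSE]
  m <- alignmentMatrix(aln)[ref$id, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  out <- data.frame(column = integer(0), species = character(0),
                    state = character(0), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    for (s in unique(ref$species)) {
      mine <- m[ref$species == s, j]
      others <- m[ref$species != s, j]
      if (all(mine %in% bases) && length(unique(mine)) == 1L &&
          !(mine[1L] %in% others[others %in% bases])) {
        out <- rbind(out, data.frame(column = j - 1L, species = s,
                                     state = mine[1L],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$column, out$species), , drop = FALSE]
}

# Random valid DistanceMatrix with an optional fraction of missing pairs.
randomDistanceMatrix <- function(n, missingFrac = 0, minOverlap = 100L) {
  ids <- sprintf("s%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  comp <- matrix(200L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (stats::runif(1) < missingFrac) {
      d[i, j] <- d[j, i] <- NA_real_
      comp[i, j] <- comp[j, i] <- 10L
    } else {
      d[i, j] <- d[j, i] <- stats::runif(1, 0, 0.04)
    }
  }
  new("DistanceMatrix", d = d, compared = comp,
      minOverlap = as.integer(minOverlap))
}

# Tiny aligned fixture with known structure.
toyAlignment <- function() {
  validateAlignment(c(
    a1 = "ACGTACGTAC",
    a2 = "ACGTACGTAC",
    b1 = "ACGTACGTTT",
    c1 = "TTTTACGTAC"))
}

# Minimal gene genealogy of two lineages separated by total path `b`.
pairGenealogy <- function(b, species = "A") {
  tr <- ape::read.tree(text = sprintf("(x_1:%.10f,x_2:%.10f);", b / 2, b / 2))
  new("GeneGenealogy", tree = tr,
      species = stats::setNames(rep(species, 2L), tr$tip.label))
}

# Locus of a single uniform-rate region.
plainLocus <- function(len, rate = 1) {
  locusSpec(regions = data.frame(name = "ITS", length = as.integer(len),
                                 rate = rate))
}
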