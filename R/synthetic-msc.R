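# Multispecies-coalescent generator for ITS-like synthetic data.
#
# Units follow the coalescent-delimitation convention: both the species
# divergence times tau and the population parameters theta are expressed in
# expected substitutions per site, so a pair of lineages in a population
# coalesces after an Exp(2/theta) waiting time (mean theta/2) and the
# expected pairwise divergence within a population is theta.

#' Construct a locus specification
#'
#' The default locus emulates a fungal ITS barcode: ITS1 (220 sites) and
#' ITS2 (230 sites) spacers evolving at the reference rate, the conserved
#' 5.8S gene (160 sites) at 0.1x, and optionally a partial LSU (300 sites)
#' at 0.2x.
#'
#' @param regions data.frame with columns `name`, `length`, `rate`
#'   (relative substitution-rate multiplier, >= 0).
#' @param model substitution model: `"JC69"` (default) or `"HKY85"`.
#' @param kappa transition/transversion rate ratio for HKY85.
#' @param baseFreqs equilibrium base frequencies in A, C, G, T order.
#' @param includeLSU add the optional partial-LSU region to the default
#'   regions table.
#' @return a [LocusSpec-class] object.
#' @examples
#' locusSpec()
#' locusSpec(model = "HKY85", kappa = 4)
#' @export
locusSpec <- function(regions = NULL, model = c("JC69", "HKY85"), kappa = 2,
                      baseFreqs = rep(0.25, 4), includeLSU = FALSE) {
  model <- match.arg(model)
  if (is.null(regions)) {
    regions <- data.frame(
      name = c("ITS1", "5.8S", "ITS2"),
      length = c(220L, 160L, 230L),
      rate = c(1, 0.1, 1),
      stringsAsFactors = FALSE)
    if (includeLSU) {
      regions <- rbind(regions, data.frame(name = "LSU", length = 300L,
                                           rate = 0.2))
    }
  }
  regions$length <- as.integer(regions$length)
  new("LocusSpec", regions = regions, model = model, kappa = kappa,
      baseFreqs = baseFreqs)
}

#' Region map (0-based half-open column intervals) of a locus
#'
#' @param locus a [LocusSpec-class].
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
locusRegions <- function(locus) {
  stopifnot(is(locus, "LocusSpec"))
  ends <- cumsum(locus@regions$length)
  data.frame(name = locus@regions$name,
             start = c(0L, ends[-length(ends)]),
             end = ends,
             stringsAsFactors = FALSE)
}

#' Construct a species-tree model
#'
#' @param tree an [ape::phylo] object or a Newick string; branch lengths are
#'   divergence times in expected substitutions/site, tips at time 0
#'   (ultrametric).
#' @param theta population-size parameter(s) in expected substitutions/site:
#'   either a single value recycled to every population, or one value per
#'   population (tips first, then internal nodes in `ape` node order).
#'   Ancestral populations default to the same theta as the descendants
#'   when a scalar is given.
#' @return a [SpeciesTreeModel-class].
#' @examples
#' m <- speciesTreeModel("((A:0.01,B:0.01):0.01,C:0.02);", theta = 0.002)
#' speciesNames(m)
#' @export
speciesTreeModel <- function(tree, theta) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  npop <- length(tree$tip.label) + tree$Nnode
  if (length(theta) == 1L) theta <- rep(theta, npop)
  names(theta) <- c(tree$tip.label,
                    paste0("anc", seq_len(tree$Nnode) + length(tree$tip.label)))
  new("SpeciesTreeModel", tree = tree, theta = theta)
}

#' Sample theta / tau hyperparameters from an inverse-gamma prior
#'
#' Inverse-gamma parameterised by shape `alpha` and scale `beta`, with mean
#' `beta / (alpha - 1)` for `alpha > 1` (conventions vary; this is the one
#' used by the usual coalescent-delimitation priors such as IG(3, 0.002),
#' whose mean is 0.001).
#'
#' @param n number of draws.
#' @param alpha shape (> 0).
#' @param beta scale (> 0).
#' @param seed optional integer seed.
#' @return numeric vector of positive draws.
#' @examples
#' mean(rInvGamma(1e4, 3, 0.002, seed = 1)) # ~ 0.001
#' @export
rInvGamma <- function(n, alpha, beta, seed = NULL) {
  stopifnot(alpha > 0, beta > 0)
  withSeed(seed, 1 / stats::rgamma(n, shape = alpha, rate = beta))
}

#' Simulate a gene genealogy under the multispecies coalescent
#'
#' Runs the standard multispecies-coalescent process on a species tree:
#' within each population carrying k lineages the waiting time to the next
#' coalescence is exponential with rate `k (k - 1) / theta` (time in expected
#' substitutions/site, so a pair coalesces after mean `theta / 2`);
#' lineages that fail to coalesce are handed to the parent population at its
#' divergence time tau. Consequently lineages from different species never
#' coalesce more recently than the species' divergence.
#'
#' @param model a [SpeciesTreeModel-class].
#' @param samplesPerSpecies named integer vector (species -> number of
#'   sampled lineages, each >= 1), or a single count applied to all species.
#' @param seed optional integer seed; the run is fully reproducible given it.
#' @return a [GeneGenealogy-class]; tip labels are `<species>_<k>`.
#' @examples
#' m <- speciesTreeModel("((A:0.01,B:0.01):0.01,C:0.02);", theta = 0.002)
#' g <- simulateGenealogy(m, c(A = 2, B = 2, C = 1), seed = 1)
#' g
#' @export
simulateGenealogy <- function(model, samplesPerSpecies, seed = NULL) {
  stopifnot(is(model, "SpeciesTreeModel"))
  validObject(model)
  tr <- model@tree
  sp <- tr$tip.label
  if (length(samplesPerSpecies) == 1L && is.null(names(samplesPerSpecies))) {
    samplesPerSpecies <- stats::setNames(rep(as.integer(samplesPerSpecies),
                                             length(sp)), sp)
  }
  if (length(samplesPerSpecies) == 0L) stop("empty species sample map")
  if (!all(names(samplesPerSpecies) %in% sp)) {
    stop("unknown species in sample map: ",
         paste(setdiff(names(samplesPerSpecies), sp), collapse = ", "))
  }
  samplesPerSpecies <- samplesPerSpecies[names(samplesPerSpecies)]
  if (any(samplesPerSpecies < 1L)) stop("sample counts must be >= 1")

  withSeed(seed, {
    ntip <- length(sp)
    times <- .nodeTimes(tr)
    parent <- rep(NA_integer_, ntip + tr$Nnode)
    parent[tr$edge[, 2L]] <- tr$edge[, 1L]
    root <- which(is.na(parent))

    # active lineages per population: list of (newick fragment, tip time)
    pool <- vector("list", ntip + tr$Nnode)
    lineageSpecies <- character(0)
    for (i in seq_along(sp)) {
      k <- samplesPerSpecies[[sp[i]]]
      if (is.null(k) || is.na(k)) next
      labs <- sprintf("%s_%d", sp[i], seq_len(k))
      pool[[i]] <- lapply(labs, function(l) list(nwk = l, t = 0))
      lineageSpecies[labs] <- sp[i]
    }

    coalesce <- function(lins, theta, t0, t1) {
      t <- t0
      while (length(lins) > 1L) {
        k <- length(lins)
        t <- t + stats::rexp(1L, rate = k * (k - 1) / theta)
        if (t >= t1) break
        pick <- sample.int(k, 2L)
        a <- lins[[pick[1L]]]; b <- lins[[pick[2L]]]
        merged <- list(
          nwk = sprintf("(%s:%.12g,%s:%.12g)", a$nwk, t - a$t, b$nwk, t - b$t),
          t = t)
        lins <- c(lins[-pick], list(merged))
      }
      lins
    }

    # process populations from the present backwards
    ord <- order(times[(ntip + 1L):(ntip + tr$Nnode)]) + ntip
    for (i in seq_len(ntip)) {       # tip populations
      if (is.null(pool[[i]]) || length(pool[[i]]) == 0L) next
      pool[[i]] <- coalesce(pool[[i]], model@theta[i], 0, times[parent[i]])
    }
    for (nd in ord) {                # ancestral populations, oldest last
      kids <- tr$edge[tr$edge[, 1L] == nd, 2L]
      lins <- do.call(c, pool[kids])   # NULL pools drop out
      if (is.null(lins)) lins <- list()
      stop_t <- if (nd == root) Inf else times[parent[nd]]
      pool[[nd]] <- coalesce(lins, model@theta[nd], times[nd], stop_t)
    }
    final <- pool[[root]]
    stopifnot(length(final) == 1L)
    nwk <- paste0(final[[1L]]$nwk, ";")
    gt <- ape::read.tree(text = nwk)
    if (is.null(gt$edge.length)) gt$edge.length <- numeric(0) # single lineage
    new("GeneGenealogy", tree = gt,
        species = lineageSpecies[gt$tip.label])
  })
}

.rateMatrixQ <- function(locus) {
  # rate order used by phangorn: a-c, a-g, a-t, c-g, c-t, g-t
  if (locus@model == "JC69") rep(1, 6)
  else c(1, locus@kappa, 1, 1, locus@kappa, 1)
}

#' Evolve sequences along a genealogy
#'
#' Sites evolve independently along the genealogy branches under the locus'
#' substitution model, region by region with the region's rate multiplier.
#' The root sequence is drawn from the model equilibrium frequencies and no
#' indels are generated, so the output is the true alignment.
#'
#' @param genealogy a [GeneGenealogy-class].
#' @param locus a [LocusSpec-class].
#' @param seed optional integer seed.
#' @return an [ITSAlignment-class] with the locus region map; row order
#'   follows the genealogy tip labels.
#' @export
evolveSequences <- function(genealogy, locus, seed = NULL) {
  stopifnot(is(genealogy, "GeneGenealogy"), is(locus, "LocusSpec"))
  validObject(locus)
  tr <- genealogy@tree
  tips <- tr$tip.label
  withSeed(seed, {
    blocks <- lapply(seq_len(nrow(locus@regions)), function(i) {
      len <- locus@regions$length[i]
      rate <- locus@regions$rate[i]
      if (rate == 0 || length(tips) == 1L || max(tr$edge.length) == 0) {
        # nothing can mutate: every record is the equilibrium root draw
        rootseq <- sample(.BASES, len, replace = TRUE, prob = locus@baseFreqs)
        m <- matrix(rep(rootseq, each = length(tips)), nrow = length(tips))
        rownames(m) <- tips
        m
      } else {
        sim <- phangorn::simSeq(tr, l = len, type = "DNA",
                                bf = locus@baseFreqs,
                                Q = .rateMatrixQ(locus), rate = rate)
        m <- toupper(as.character(sim))
        m[tips, , drop = FALSE]
      }
    })
    seqs <- do.call(cbind, blocks)
    rownames(seqs) <- tips
    new("ITSAlignment", seqs = seqs, regions = locusRegions(locus))
  })
}

.randomAmbiguity <- function(base) {
  codes <- names(.IUPAC_SETS)[vapply(.IUPAC_SETS, function(s) base %in% s,
                                     logical(1L))]
  sample(codes, 1L)
}

#' Apply database-style degradation to an alignment
#'
#' Emulates the quality problems of public ITS records: truncation to a
#' single spacer region (other columns become `?`), IUPAC ambiguities
#' sprinkled at a per-site rate, and substitutions planted inside the
#' conserved 5.8S domain (the "differences in conserved domains" pathology).
#'
#' @param aln an [ITSAlignment-class] with region annotation.
#' @param partialITS1,partialITS2 record ids to truncate to the named spacer,
#'   or a single count of records to pick at random.
#' @param ambiguate ids (or a count) of records receiving ambiguities.
#' @param ambiguityRate per-site probability of replacing an unambiguous
#'   residue by an IUPAC ambiguity code containing it, in \[0,1\].
#' @param domainDeviant ids (or a count) of records receiving substitutions
#'   inside `domainRegion`.
#' @param domainRate per-site substitution probability inside the domain,
#'   in \[0,1\].
#' @param domainRegion name of the conserved region (default `"5.8S"`).
#' @param seed optional integer seed.
#' @return list with elements `alignment` (degraded [ITSAlignment-class]) and
#'   `flags` (data.frame `id`, `flags`; flags are `;`-separated from
#'   `full_length`, `partial:ITS1`, `partial:ITS2`, `ambiguated`,
#'   `domain_deviant`).
#' @export
degradeAlignment <- function(aln, partialITS1 = character(0),
                             partialITS2 = character(0),
                             ambiguate = character(0), ambiguityRate = 0.05,
                             domainDeviant = character(0), domainRate = 0.02,
                             domainRegion = "5.8S", seed = NULL) {
  stopifnot(is(aln, "ITSAlignment"))
  if (nrow(aln@regions) == 0L) stop("region annotation required")
  if (ambiguityRate < 0 || ambiguityRate > 1 ||
      domainRate < 0 || domainRate > 1) {
    stop("degradation rates must lie in [0, 1]")
  }
  ids <- seqIds(aln)
  withSeed(seed, {
    pick <- function(x, taken) {
      if (is.numeric(x)) sample(setdiff(ids, taken), x) else {
        if (!all(x %in% ids)) stop("unknown ids: ",
                                   paste(setdiff(x, ids), collapse = ", "))
        x
      }
    }
    p1 <- pick(partialITS1, character(0))
    p2 <- pick(partialITS2, p1)
    if (length(intersect(p1, p2))) stop("a record cannot be partial to both spacers")
    am <- pick(ambiguate, character(0))
    dd <- pick(domainDeviant, character(0))

    m <- aln@seqs
    flags <- stats::setNames(rep("full_length", length(ids)), ids)
    for (id in p1) {
      keep <- .regionCols(aln@regions, "ITS1")
      m[id, setdiff(seq_len(ncol(m)), keep)] <- "?"
      flags[id] <- "partial:ITS1"
    }
    for (id in p2) {
      keep <- .regionCols(aln@regions, "ITS2")
      m[id, setdiff(seq_len(ncol(m)), keep)] <- "?"
      flags[id] <- "partial:ITS2"
    }
    for (id in am) {
      at <- which(m[id, ] %in% .BASES & stats::runif(ncol(m)) < ambiguityRate)
      for (j in at) m[id, j] <- .randomAmbiguity(m[id, j])
      if (length(at)) {
        flags[id] <- ifelse(flags[id] == "full_length", "ambiguated",
                            paste(flags[id], "ambiguated", sep = ";"))
      }
    }
    domCols <- .regionCols(aln@regions, domainRegion)
    for (id in dd) {
      at <- domCols[m[id, domCols] %in% .BASES &
                      stats::runif(length(domCols)) < domainRate]
      for (j in at) m[id, j] <- sample(setdiff(.BASES, m[id, j]), 1L)
      if (length(at)) {
        flags[id] <- ifelse(flags[id] == "full_length", "domain_deviant",
                            paste(flags[id], "domain_deviant", sep = ";"))
      }
    }
    list(alignment = new("ITSAlignment", seqs = m, regions = aln@regions),
         flags = data.frame(id = ids, flags = unname(flags[ids]),
                            stringsAsFactors = FALSE))
  })
}

#' A species-tree preset shaped like a recently radiated ITS species complex
#'
#' Five European species in two subclades with shallow divergences
#' (tau 0.004 within subclades, 0.012 between) and a small population
#' parameter (theta 5e-4), calibrated so that expected within-species ITS
#' divergence stays well below 0.5% while between-species divergence falls
#' in the 0.8-2.5% band -- the distance structure under which
#' species-hypothesis thresholds around 0.5% are informative. Single-locus
#' realisations fluctuate around the 0.5%/1% boundaries; that fragility is
#' part of what the threshold sweep measures.
#'
#' @param theta population parameter (expected substitutions/site) recycled
#'   to every population.
#' @return a [SpeciesTreeModel-class] over five species labels.
#' @export
complexPresetModel <- function(theta = 5e-4) {
  nwk <- paste0(
    "((R_albonigra:0.004,R_sp1:0.004):0.008,",
    "(R_ambusta:0.005,(R_nigrifacta:0.004,R_ustulata:0.004):0.001):0.007);")
  speciesTreeModel(nwk, theta = theta)
}

#' Generate a complete synthetic data set and write it to disk
#'
#' Composes [simulateGenealogy()], [evolveSequences()] and
#' [degradeAlignment()] from a single configuration, and (optionally) writes
#' the aligned FASTA, the truth table (TSV: id, species, flags, seed), the
#' species tree (Newick, tau node heights, theta in branch comments) and a
#' provenance JSON echoing the configuration. Byte-identical outputs for
#' identical configuration + seed.
#'
#' @param config a list (or path to a YAML/JSON file) with elements:
#'   `tree` (Newick string) and `theta`, or `preset = "complex"`;
#'   `samplesPerSpecies` (named vector or single count); optional `locus`
#'   (list of `regions`, `model`, `kappa`, `baseFreqs`); optional
#'   `degrade` (list of `partialITS1`, `partialITS2`, `ambiguate`,
#'   `ambiguityRate`, `domainDeviant`, `domainRate` -- counts or id vectors);
#'   optional `thetaPrior`/`tauPrior` (`list(alpha=, beta=)`) to draw theta
#'   (one value for all populations) and rescale node times from
#'   inverse-gamma priors; `seed` (integer, required for reproducibility).
#' @param outDir output directory, or `NULL` to skip writing.
#' @return (invisibly) list with `alignment`, `truth`, `model`, `genealogy`,
#'   `locus`, and `files` (paths written, or `NULL`).
#' @examples
#' ds <- generateDataset(list(preset = "complex", samplesPerSpecies = 2,
#'                            seed = 7))
#' ds$alignment
#' @export
generateDataset <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required for reproducibility")

  withSeed(seed, {
    model <- if (!is.null(config$tree)) {
      speciesTreeModel(config$tree, theta = config$theta %||% 0.002)
    } else if (identical(config$preset, "complex")) {
      complexPresetModel(theta = config$theta %||% 5e-4)
    } else stop("config must give 'tree' (+'theta') or preset = \"complex\"")

    if (!is.null(config$thetaPrior)) {
      th <- rInvGamma(1L, config$thetaPrior$alpha, config$thetaPrior$beta)
      model@theta[] <- th
    }
    if (!is.null(config$tauPrior)) {
      rootAge <- rInvGamma(1L, config$tauPrior$alpha, config$tauPrior$beta)
      tm <- .nodeTimes(model@tree)
      model@tree$edge.length <- model@tree$edge.length * rootAge / max(tm)
    }

    locus <- if (is.null(config$locus)) locusSpec() else {
      do.call(locusSpec, config$locus)
    }
    n <- config$samplesPerSpecies %||% 4L
    if (!is.null(names(n))) n <- unlist(n)
    genealogy <- simulateGenealogy(model, n)
    aln <- evolveSequences(genealogy, locus)
    dg <- config$degrade %||% list()
    deg <- degradeAlignment(aln,
      partialITS1 = dg$partialITS1 %||% character(0),
      partialITS2 = dg$partialITS2 %||% character(0),
      ambiguate = dg$ambiguate %||% character(0),
      ambiguityRate = dg$ambiguityRate %||% 0.05,
      domainDeviant = dg$domainDeviant %||% character(0),
      domainRate = dg$domainRate %||% 0.02)

    truth <- data.frame(id = seqIds(deg$alignment),
                        species = unname(genealogy@species[seqIds(deg$alignment)]),
                        flags = deg$flags$flags,
                        seed = as.integer(seed),
                        stringsAsFactors = FALSE)
    files <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      files <- list(
        fasta = file.path(outDir, "alignment.fasta"),
        truth = file.path(outDir, "truth.tsv"),
        tree = file.path(outDir, "species_tree.nwk"),
        config = file.path(outDir, "provenance.json"))
      writeFastaRecords(sequenceStrings(deg$alignment), files$fasta)
      utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(.newickWithTheta(model), files$tree)
      jsonlite::write_json(
        list(generator = "barcodeSH::generateDataset", config = config,
             regions = locusRegions(locus)),
        files$config, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    invisible(list(alignment = deg$alignment, truth = truth, model = model,
                   genealogy = genealogy, locus = locus, files = files))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Newick with theta carried in branch comments, e.g. A:0.004[&theta=0.0005]
.newickWithTheta <- function(model) {
  tr <- model@tree
  th <- model@theta
  ntip <- length(tr$tip.label)
  kids <- function(nd) tr$edge[tr$edge[, 1L] == nd, 2L]
  blen <- function(nd) tr$edge.length[match(nd, tr$edge[, 2L])]
  rec <- function(nd) {
    lab <- if (nd <= ntip) tr$tip.label[nd] else {
      paste0("(", paste(vapply(kids(nd), rec, character(1L)), collapse = ","),
             ")")
    }
    b <- blen(nd)
    if (is.na(b)) sprintf("%s[&theta=%.8g]", lab, th[nd])
    else sprintf("%s:%.10g[&theta=%.8g]", lab, b, th[nd])
  }
  root <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
  paste0(rec(root), ";")
}
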