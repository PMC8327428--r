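# Multispecies-coalescent generator: closed-form expectations, invariants,
# and degradation bookkeeping.

test_that("pair coalescence time is exponential with mean theta/2", {
  theta <- 0.002
  m <- speciesTreeModel("(A:0.001);", theta = theta)
  set.seed(11)
  tm <- replicate(500, {
    g <- simulateGenealogy(m, c(A = 2))
    g@tree$edge.length[1L]  # tip depth = TMRCA of the pair
  })
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - theta / 2), 3 * se)
})

test_that("lineages from different species never coalesce below the species divergence", {
  m <- speciesTreeModel("((A:0.004,B:0.004):0.006,C:0.01);", theta = 0.01)
  divTime <- function(s1, s2) if (setequal(c(s1, s2), c("A", "B"))) 0.004 else 0.01
  for (s in 1:20) {
    g <- simulateGenealogy(m, c(A = 2, B = 2, C = 2), seed = s)
    tm <- ape::cophenetic.phylo(g@tree) / 2  # TMRCA per pair
    sp <- g@species
    for (i in rownames(tm)) for (j in colnames(tm)) {
      if (sp[[i]] != sp[[j]]) {
        expect_gte(tm[i, j], divTime(sp[[i]], sp[[j]]) - 1e-9)
      }
    }
  }
})

test_that("genealogy topology matches the species tree when tau >> theta", {
  nwk <- "((((S1:0.01,S2:0.01):0.005,S3:0.015):0.005,S4:0.02):0.005,S5:0.025);"
  m <- speciesTreeModel(nwk, theta = 5e-4)
  st <- ape::unroot(m@tree)
  match <- vapply(seq_len(200), function(s) {
    g <- simulateGenealogy(m, 1, seed = 300 + s)
    gt <- g@tree
    gt$tip.label <- sub("_1$", "", gt$tip.label)
    ape::dist.topo(ape::unroot(gt), st) == 0
  }, logical(1L))
  expect_gte(mean(match), 0.99)
})

test_that("zero branch lengths give sequences identical to the root", {
  tr <- ape::read.tree(text = "(x_1:0,x_2:0,x_3:0);")
  g <- new("GeneGenealogy", tree = tr,
           species = setNames(rep("A", 3), tr$tip.label))
  a <- evolveSequences(g, plainLocus(200), seed = 4)
  s <- sequenceStrings(a)
  expect_length(unique(s), 1L)
})

test_that("a zero-rate region is invariant while spacers diverge", {
  g <- pairGenealogy(0.5)
  loc <- locusSpec(regions = data.frame(
    name = c("ITS1", "5.8S", "ITS2"),
    length = c(150L, 100L, 150L), rate = c(1, 0, 1)))
  a <- evolveSequences(g, loc, seed = 9)
  m <- alignmentMatrix(a)
  core <- 151:250
  expect_identical(m[1L, core], m[2L, core])
  expect_gt(sum(m[1L, -core] != m[2L, -core]), 0L)
})

test_that("realized JC69 p-distance matches the closed form", {
  b <- 0.05
  L <- 2e4
  g <- pairGenealogy(b)
  a <- evolveSequences(g, plainLocus(L), seed = 21)
  d <- pDistance(sequenceStrings(a)[1L], sequenceStrings(a)[2L])
  p <- 0.75 * (1 - exp(-4 * b / 3))
  se <- sqrt(p * (1 - p) / L)
  expect_lt(abs(as.numeric(d) - p), 3 * se)
})

test_that("HKY85 with high kappa favours transitions", {
  g <- pairGenealogy(0.2)
  loc <- locusSpec(regions = data.frame(name = "ITS", length = 20000L,
                                        rate = 1),
                   model = "HKY85", kappa = 20)
  a <- evolveSequences(g, loc, seed = 5)
  m <- alignmentMatrix(a)
  diff <- m[1L, ] != m[2L, ]
  pur <- c("A", "G")
  transition <- diff & ((m[1L, ] %in% pur) == (m[2L, ] %in% pur))
  expect_gt(sum(transition) / sum(diff), 0.5)
})

test_that("truncation blanks the other regions and is flagged", {
  ds <- generateDataset(list(preset = "complex", samplesPerSpecies = 2,
                             seed = 31))
  aln <- ds$alignment
  id <- seqIds(aln)[1L]
  deg <- degradeAlignment(aln, partialITS2 = id)
  m <- alignmentMatrix(deg$alignment)
  expect_true(all(m[id, 1:380] == "?"))
  expect_true(all(m[id, 381:610] != "?"))
  expect_identical(deg$flags$flags[deg$flags$id == id], "partial:ITS2")
  expect_true(all(deg$flags$flags[deg$flags$id != id] == "full_length"))
})

test_that("ambiguity rate 0 leaves records unchanged and full_length", {
  ds <- generateDataset(list(preset = "complex", samplesPerSpecies = 2,
                             seed = 32))
  deg <- degradeAlignment(ds$alignment, ambiguate = seqIds(ds$alignment)[1L],
                          ambiguityRate = 0)
  expect_identical(alignmentMatrix(deg$alignment),
                   alignmentMatrix(ds$alignment))
  expect_true(all(deg$flags$flags == "full_length"))
})

test_that("ambiguated site count is binomial with the stated rate", {
  g <- pairGenealogy(0.01)
  a <- evolveSequences(g, plainLocus(500), seed = 3)
  set.seed(17)
  counts <- replicate(200, {
    deg <- degradeAlignment(a, ambiguate = "x_1", ambiguityRate = 0.05)
    sum(alignmentMatrix(deg$alignment)["x_1", ] %in%
          c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"))
  })
  se <- sqrt(500 * 0.05 * 0.95) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 25), 3 * se)
  expect_error(degradeAlignment(a, ambiguate = "x_1", ambiguityRate = 1.5),
               "rates")
})

test_that("domain-deviant mode substitutes inside the conserved region only", {
  ds <- generateDataset(list(preset = "complex", samplesPerSpecies = 2,
                             seed = 33))
  id <- seqIds(ds$alignment)[1L]
  deg <- degradeAlignment(ds$alignment, domainDeviant = id, domainRate = 0.2,
                          seed = 8)
  changed <- which(alignmentMatrix(deg$alignment)[id, ] !=
                     alignmentMatrix(ds$alignment)[id, ])
  expect_true(all(changed >= 221 & changed <= 380))
  expect_gt(length(changed), 0L)
  expect_identical(deg$flags$flags[deg$flags$id == id], "domain_deviant")
})

test_that("generateDataset bookkeeping and determinism", {
  cfg <- list(preset = "complex", samplesPerSpecies = 4, seed = 77,
              degrade = list(partialITS1 = 1, ambiguate = 1))
  d1 <- withr::with_tempdir({
    generateDataset(cfg, outDir = "out")
  })
  expect_equal(nSequences(d1$alignment), 20L)
  expect_equal(nrow(d1$truth), 20L)
  expect_setequal(unique(d1$truth$species), speciesNames(d1$model))
  d2 <- generateDataset(cfg)
  expect_identical(alignmentMatrix(d1$alignment), alignmentMatrix(d2$alignment))
  expect_identical(d1$truth, d2$truth)
  d3 <- generateDataset(list(preset = "complex", samplesPerSpecies = 4,
                             seed = 78))
  expect_false(identical(alignmentMatrix(d1$alignment),
                         alignmentMatrix(d3$alignment)))
})

test_that("inverse-gamma sampler has mean beta/(alpha-1)", {
  x <- rInvGamma(1e4, 3, 0.002, seed = 13)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.001), 3 * se)
  expect_error(rInvGamma(10, -1, 0.002))
})

test_that("invalid models and sample maps are rejected", {
  expect_error(speciesTreeModel("((A:0.01,B:0.02):0.01,C:0.02);", 0.002),
               "ultrametric")
  expect_error(speciesTreeModel("((A:0.01,B:0.01):0.01,C:0.02);", -1),
               "positive")
  m <- speciesTreeModel("((A:0.01,B:0.01):0.01,C:0.02);", 0.002)
  expect_error(simulateGenealogy(m, stats::setNames(integer(0), character(0))),
               "empty")
  expect_error(simulateGenealogy(m, c(A = 0, B = 1, C = 1)), ">= 1")
  expect_error(simulateGenealogy(m, c(A = 1, Z = 1)), "unknown species")
})
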