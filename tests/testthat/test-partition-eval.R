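# Partition evaluation against the reference species labels.

refMap <- function(ids, species) {
  speciesMap(data.frame(id = ids, species = species, role = "reference",
                        stringsAsFactors = FALSE))
}

test_that("statuses cover resolved / merged / split / mixed", {
  m <- refMap(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  p <- c(a1 = "a1", a2 = "a1", b1 = "b1", b2 = "b1")
  ev <- evaluatePartition(p, m)
  expect_identical(ev$status, c("resolved", "resolved"))

  # two species fused into one cluster -> both merged
  pFused <- c(a1 = "a1", a2 = "a1", b1 = "a1", b2 = "a1")
  expect_identical(evaluatePartition(pFused, m)$status, c("merged", "merged"))

  # one species in two pure clusters -> split
  pSplit <- c(a1 = "a1", a2 = "a2", b1 = "b1", b2 = "b1")
  ev2 <- evaluatePartition(pSplit, m)
  expect_identical(ev2$status[ev2$species == "A"], "split")
  expect_identical(ev2$status[ev2$species == "B"], "resolved")

  # split and contaminated at once -> mixed
  pMixed <- c(a1 = "a1", a2 = "x", b1 = "x", b2 = "x")
  ev3 <- evaluatePartition(pMixed, m)
  expect_identical(ev3$status[ev3$species == "A"], "mixed")
  expect_identical(ev3$status[ev3$species == "B"], "merged")
})

test_that("query records are excluded from statuses but keep their cluster", {
  m <- speciesMap(data.frame(
    id = c("a1", "a2", "q1"), species = c("A", "A", "unknown"),
    role = c("reference", "reference", "query"), stringsAsFactors = FALSE))
  p <- c(a1 = "a1", a2 = "a1", q1 = "a1")  # query landed in A's cluster
  ev <- evaluatePartition(p, m)
  expect_identical(ev$status, "resolved")  # contamination by queries ignored
  sw <- new("ThresholdSweep", thresholds = 0,
            labels = matrix(p, ncol = 1, dimnames = list(names(p), "0.0%")))
  tab <- shTable(sw, m)
  expect_identical(tab$role, c("reference", "reference", "query"))
  expect_identical(tab[["cluster@0.0%"]], unname(p))
})

test_that("status is invariant under label renaming and record reordering", {
  m <- refMap(c("a1", "a2", "b1"), c("A", "A", "B"))
  p <- c(a1 = "x", a2 = "x", b1 = "y")
  q <- c(b1 = "k2", a2 = "k1", a1 = "k1")
  e1 <- evaluatePartition(p, m)
  e2 <- evaluatePartition(q, m)
  expect_identical(e1$status, e2$status[match(e1$species, e2$species)])
})

test_that("minimal resolving threshold on the planted complex is 0.5%", {
  ds <- syntheticComplexDataset()
  refIds <- ds$map$id[ds$map$role == "reference"]
  sw <- thresholdSweep(distanceMatrix(ds$alignment[refIds]))
  t <- minResolvingThreshold(sw, ds$map)
  expect_equal(as.numeric(t), 0.5)
  expect_equal(attr(t, "similarity"), 99.5)
  # per-species minima are all <= the overall minimum's grid point
  rep <- evalReport(sw, ds$map)
  expect_true(all(rep$perSpeciesMin <= 0.5))
  expect_equal(max(rep$perSpeciesMin), rep$minResolving)
})

test_that("species sharing identical sequences are never resolved", {
  aln <- validateAlignment(c(a1 = "ACGTACGT", a2 = "ACGTACGT",
                             b1 = "ACGTACGT"))
  m <- refMap(c("a1", "a2", "b1"), c("A", "A", "B"))
  sw <- thresholdSweep(distanceMatrix(aln, minOverlap = 1))
  expect_true(is.na(minResolvingThreshold(sw, m)))
})

test_that("a single species resolves at the first grid point connecting it", {
  aln <- validateAlignment(c(
    s1 = strrep("A", 200),
    s2 = paste0(strrep("A", 198), "CC"),                 # d = 1%
    s3 = paste0(strrep("A", 196), "CCCC")))              # d(s1,s3) = 2%
  m <- refMap(c("s1", "s2", "s3"), rep("A", 3))
  sw <- thresholdSweep(distanceMatrix(aln, minOverlap = 1))
  # oracle: first grid t with a connected single-linkage graph
  d <- distances(distanceMatrix(aln, minOverlap = 1))
  oracle <- NA_real_
  for (t in thresholds(sw)) {
    if (length(unique(closureClusters(d, t))) == 1L) { oracle <- t; break }
  }
  expect_equal(as.numeric(minResolvingThreshold(sw, m)), oracle)
  expect_equal(oracle, 1.0)
  # all identical members resolve already at 0
  aln0 <- validateAlignment(c(s1 = "ACGT", s2 = "ACGT"))
  sw0 <- thresholdSweep(distanceMatrix(aln0, minOverlap = 1))
  expect_equal(as.numeric(minResolvingThreshold(sw0, refMap(c("s1", "s2"),
                                                            c("A", "A")))), 0)
})

test_that("sh table is a faithful flat view of the sweep", {
  ds <- syntheticComplexDataset()
  refIds <- ds$map$id[ds$map$role == "reference"]
  sw <- thresholdSweep(distanceMatrix(ds$alignment[refIds]))
  tab <- shTable(sw, ds$map)
  expect_equal(nrow(tab), length(refIds))
  expect_equal(sum(grepl("^cluster@", names(tab))), length(thresholds(sw)))
  # regrouping a column regenerates the partition exactly
  for (t in c(0.5, 1.0)) {
    col <- sprintf("cluster@%.1f%%", t)
    expect_equal(stats::setNames(tab[[col]], tab$id), partitionAt(sw, t)[tab$id],
                 ignore_attr = TRUE)
  }
})

test_that("zero-member species are rejected", {
  m <- speciesMap(data.frame(id = character(0), species = character(0),
                             role = character(0), stringsAsFactors = FALSE))
  expect_error(evaluatePartition(c(a = "a"), m), "no reference")
})
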