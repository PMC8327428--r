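# Diagnostic columns, placement of short/low-quality records, query
# threading and the quality screen.

twoSpeciesAln <- function() {
  # species differ at exactly one column (6); invariant elsewhere
  validateAlignment(c(a1 = "ACGTACAACG", a2 = "ACGTACAACG",
                      b1 = "ACGTAGAACG", b2 = "ACGTAGAACG"))
}

twoSpeciesMap <- function() {
  speciesMap(data.frame(id = c("a1", "a2", "b1", "b2"),
                        species = c("A", "A", "B", "B"), role = "reference",
                        stringsAsFactors = FALSE))
}

test_that("a single differing column is diagnostic for both states", {
  dt <- findDiagnosticPositions(twoSpeciesAln(), twoSpeciesMap())
  tab <- diagnosticPositions(dt)
  expect_equal(nrow(tab), 2L)
  expect_equal(unique(tab$column), 5L)       # 0-based
  expect_setequal(tab$state, c("C", "G"))
  expect_setequal(tab$species, c("A", "B"))
})

test_that("identical species give an empty table; placement then errors", {
  aln <- validateAlignment(c(a1 = "ACGT", b1 = "ACGT"))
  m <- speciesMap(data.frame(id = c("a1", "b1"), species = c("A", "B"),
                             role = "reference", stringsAsFactors = FALSE))
  dt <- findDiagnosticPositions(aln, m)
  expect_equal(nrow(diagnosticPositions(dt)), 0L)
  expect_error(placeSequence("ACGT", dt), "empty")
})

test_that("the tolerance knob admits columns with a few missing members", {
  aln <- validateAlignment(c(a1 = "ACGTA", a2 = "AC-TA", a3 = "ACGTA",
                             a4 = "ACGTA",
                             b1 = "ACTTA", b2 = "ACTTA", b3 = "ACTTA",
                             b4 = "ACTTA"))
  m <- speciesMap(data.frame(id = c(paste0("a", 1:4), paste0("b", 1:4)),
                             species = rep(c("A", "B"), each = 4),
                             role = "reference", stringsAsFactors = FALSE))
  strict <- diagnosticPositions(findDiagnosticPositions(aln, m, tolerance = 0))
  loose <- diagnosticPositions(findDiagnosticPositions(aln, m, tolerance = 0.25))
  expect_false(any(strict$column == 2L & strict$species == "A"))
  expect_true(any(loose$column == 2L & loose$species == "A"))
  # B is fully observed at the column, so it is diagnostic for B either way
  expect_true(any(strict$column == 2L & strict$species == "B"))
})

test_that("planted diagnostic columns are recovered exactly (oracle scan)", {
  ds <- syntheticComplexDataset()
  refIds <- ds$map$id[ds$map$role == "reference"]
  dt <- findDiagnosticPositions(ds$alignment[refIds], ds$map)
  tab <- diagnosticPositions(dt)
  expect_identical(sort(tab$column), sort(unlist(ds$diagnosticColumns,
                                                 use.names = FALSE)))
  for (s in names(ds$diagnosticColumns)) {
    expect_setequal(tab$column[tab$species == s], ds$diagnosticColumns[[s]])
  }
  oracle <- naiveDiagnosticScan(ds$alignment[refIds], ds$map)
  got <- tab[order(tab$column, tab$species), c("column", "species", "state")]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(oracle)))
})

test_that("diagnostic tables from simulated alignments match the naive scan", {
  m <- speciesTreeModel("((A:0.01,B:0.01):0.01,C:0.02);", 0.001)
  loc <- plainLocus(150)
  for (s in 1:10) {
    g <- simulateGenealogy(m, 3, seed = 100 + s)
    a <- evolveSequences(g, loc, seed = 200 + s)
    map <- speciesMap(data.frame(id = seqIds(a),
                                 species = unname(g@species[seqIds(a)]),
                                 role = "reference", stringsAsFactors = FALSE))
    tab <- diagnosticPositions(findDiagnosticPositions(a, map))
    tab <- tab[order(tab$column, tab$species), ]
    oracle <- naiveDiagnosticScan(a, map)
    expect_equal(unname(as.matrix(tab[, c("column", "species", "state")])),
                 unname(as.matrix(oracle)))
  }
})

test_that("placement verdicts follow the decision rule", {
  ds <- syntheticComplexDataset()
  aln <- ds$alignment
  refIds <- ds$map$id[ds$map$role == "reference"]
  dt <- findDiagnosticPositions(aln[refIds], ds$map)

  # full-length copy of a reference member -> assigned, zero mismatches
  p <- placeSequence(alignmentMatrix(aln)["ust01", ], dt)
  expect_identical(p$verdict, "assigned")
  expect_identical(p$species, "Russula ustulata")
  expect_equal(sum(p$counts$mismatches[p$counts$species == p$species]), 0L)

  # ITS2-only record whose species has >= 3 ITS2 diagnostics -> assigned
  p1 <- placeSequence(alignmentMatrix(aln)["q_its2only", ], dt)
  expect_identical(p1$verdict, "assigned")
  expect_identical(p1$species, "Russula ustulata")

  # ITS1-only record covering a single diagnostic position -> uncertain
  p2 <- placeSequence(alignmentMatrix(aln)["q_its1only", ], dt)
  expect_identical(p2$verdict, "uncertain")

  # ambiguities at every diagnostic column -> uncertain with covered = 0
  p3 <- placeSequence(alignmentMatrix(aln)["q_ambiguous", ], dt)
  expect_identical(p3$verdict, "uncertain")
  expect_true(all(p3$counts$covered == 0L))
  expect_setequal(p3$flaggedColumns, unlist(ds$diagnosticColumns,
                                            use.names = FALSE))

  # record mismatching every covered species -> conflicting
  p4 <- placeSequence(alignmentMatrix(aln)["q_deviant", ], dt)
  expect_identical(p4$verdict, "conflicting")
})

test_that("placement is deterministic and invariant to table entry order", {
  ds <- syntheticComplexDataset()
  refIds <- ds$map$id[ds$map$role == "reference"]
  dt <- findDiagnosticPositions(ds$alignment[refIds], ds$map)
  set.seed(5)
  shuffled <- dt
  shuffled@table <- dt@table[sample(nrow(dt@table)), ]
  shuffled@table <- shuffled@table[order(shuffled@table$column), ]  # validity
  for (id in c("q_its2only", "q_deviant")) {
    q <- alignmentMatrix(ds$alignment)[id, ]
    expect_identical(placeSequence(q, dt)$verdict,
                     placeSequence(q, shuffled)$verdict)
  }
})

test_that("full-length clean queries are assigned to their true species", {
  m <- speciesTreeModel("((A:0.012,B:0.012):0.008,C:0.02);", 0.0005)
  loc <- locusSpec()
  correct <- 0L; eligible <- 0L
  for (s in 1:10) {
    g <- simulateGenealogy(m, 4, seed = 400 + s)
    a <- evolveSequences(g, loc, seed = 500 + s)
    ids <- seqIds(a)
    queryId <- ids[[1L]]
    truth <- g@species[[queryId]]
    refIds <- setdiff(ids, queryId)
    map <- speciesMap(data.frame(id = refIds,
                                 species = unname(g@species[refIds]),
                                 role = "reference", stringsAsFactors = FALSE))
    dt <- findDiagnosticPositions(a[refIds], map)
    tab <- diagnosticPositions(dt)
    if (sum(tab$species == truth) >= 3L) {
      eligible <- eligible + 1L
      p <- placeSequence(alignmentMatrix(a)[queryId, ], dt)
      correct <- correct + (identical(p$verdict, "assigned") &&
                              identical(p$species, truth))
    }
  }
  expect_gt(eligible, 0L)
  expect_equal(correct, eligible)
})

test_that("queries thread onto reference columns by pairwise alignment", {
  ds <- syntheticComplexDataset()
  refIds <- ds$map$id[ds$map$role == "reference"]
  aln <- ds$alignment[refIds]
  ref <- alignmentMatrix(aln)["nig01", ]

  # an exact substring reproduces the reference's column placement
  sub <- paste0(ref[101:500], collapse = "")
  th <- alignQuery(sub, aln)
  expect_identical(unname(th[101:500]), unname(ref[101:500]))
  expect_true(all(th[c(1:100, 501:610)] == "?"))
  expect_identical(attr(th, "reference"), "nig01")

  # a 1-substitution full-length copy aligns with full coverage
  mut <- ref
  mut[300] <- setdiff(c("A", "C", "G", "T"), mut[300])[1L]
  th2 <- alignQuery(paste0(mut, collapse = ""), aln)
  expect_equal(sum(th2 == "?"), 0L)
  expect_equal(which(th2 != ref), 300L)

  expect_error(alignQuery(strrep("AC", 30), aln), "8-mer")
})

test_that("quality screen flags partials, ambiguity and domain deviation", {
  ds <- syntheticComplexDataset()
  q <- screenQuality(ds$alignment, map = ds$map)
  flag <- stats::setNames(q$flags, q$id)
  expect_identical(flag[["alb01"]], "full_length")
  expect_identical(flag[["q_its2only"]], "partial:ITS2")
  expect_identical(flag[["q_its1only"]], "partial:ITS1")
  expect_identical(flag[["q_ambiguous"]], "full_length;high_ambiguity")
  expect_identical(flag[["q_deviant"]], "full_length;domain_deviant")
  expect_equal(q$coverage_ITS2[q$id == "q_its2only"], 1)
  expect_equal(q$coverage_ITS1[q$id == "q_its2only"], 0)

  # degrade()-produced truncation carries the same flag
  deg <- degradeAlignment(ds$alignment, partialITS2 = "alb03")
  q2 <- screenQuality(deg$alignment, map = ds$map, ids = "alb03")
  expect_identical(q2$flags, "partial:ITS2")
})
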