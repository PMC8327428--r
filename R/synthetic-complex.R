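# A deterministic, fully synthetic stand-in for a reference set of a
# recently radiated ITS species complex. It is NOT real data: differences
# between species are planted at known columns so that the distance
# structure mirrors the situation in which species-hypothesis thresholds
# around 0.5% are decisive -- within-species divergence <= 0.33%, closest
# between-species divergence ~1%, two subclades ~2.6% apart.

#' Synthetic five-species complex data set (deterministic)
#'
#' Builds a labelled reference alignment of five closely related species
#' (two subclades, as in a recent radiation) of four records each, plus four
#' query records reproducing the classic database pathologies: an ITS2-only
#' record (identifiable from ITS2 diagnostics), an ITS1-only record covering
#' a single diagnostic position (dubious), an ambiguity-laden record, and a
#' record deviating in the conserved 5.8S domain that matches no species.
#'
#' Planted structure on a 610-site ITS1/5.8S/ITS2 locus:
#' each species carries 3 private fixed differences (its diagnostic
#' positions), subclade 1 additionally carries 16 shared differences, and
#' within species two members carry one private substitution each. Pairwise
#' reference distances are therefore <= 2/610 within species, 6/610 between
#' species of the same subclade and >= 22/610 across subclades, so the sweep
#' yields 15 clusters at 0%, 5 at 0.5% and 2 from 1% upward.
#'
#' @param seed integer seed fixing the (arbitrary) base sequence and column
#'   choices; the structure above holds for every seed.
#' @return list with `alignment` (an [ITSAlignment-class] of 24 records),
#'   `map` (species map data.frame), `diagnosticColumns` (named list of
#'   planted 0-based diagnostic columns per species).
#' @examples
#' ds <- syntheticComplexDataset()
#' ds$alignment
#' @export
syntheticComplexDataset <- function(seed = 42L) {
  regions <- data.frame(name = c("ITS1", "5.8S", "ITS2"),
                        start = c(0L, 220L, 380L),
                        end = c(220L, 380L, 610L),
                        stringsAsFactors = FALSE)
  L <- 610L
  species <- c("Russula albonigra", "Russula sp. 1", "Russula ambusta",
               "Russula nigrifacta", "Russula ustulata")
  short <- c("alb", "sp1", "amb", "nig", "ust")
  withSeed(seed, {
    base <- sample(.BASES, L, replace = TRUE)
    its1 <- seq.int(1L, 220L)
    its2 <- seq.int(381L, 610L)
    pool <- sample(c(its1, its2))   # shuffled spacer columns (1-based)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    takeFrom <- function(region, n) {
      sel <- pool[pool %in% region][seq_len(n)]
      pool <<- setdiff(pool, sel)
      sel
    }
    # subclade-1 shared columns and per-species diagnostics
    cladeCols <- take(16L)
    diagCols <- list(
      alb = c(takeFrom(its1, 1L), takeFrom(its2, 2L)),
      sp1 = c(takeFrom(its1, 2L), takeFrom(its2, 1L)),
      amb = c(takeFrom(its1, 1L), takeFrom(its2, 2L)),
      nig = c(takeFrom(its1, 1L), takeFrom(its2, 2L)),
      ust = takeFrom(its2, 3L))
    memberCols <- lapply(stats::setNames(short, short), function(s) take(2L))

    alt <- function(b) setdiff(.BASES, b)[1L]  # deterministic alternative
    mutate <- function(seq, cols) {
      seq[cols] <- vapply(seq[cols], alt, character(1L))
      seq
    }
    consensus <- list()
    for (i in seq_along(short)) {
      s <- base
      if (short[i] %in% c("alb", "sp1")) s <- mutate(s, cladeCols)
      consensus[[short[i]]] <- mutate(s, diagCols[[short[i]]])
    }
    recs <- list()
    for (i in seq_along(short)) {
      cs <- consensus[[short[i]]]
      recs[[sprintf("%s01", short[i])]] <- cs
      recs[[sprintf("%s02", short[i])]] <- mutate(cs, memberCols[[short[i]]][1L])
      recs[[sprintf("%s03", short[i])]] <- cs
      recs[[sprintf("%s04", short[i])]] <- mutate(cs, memberCols[[short[i]]][2L])
    }
    # queries emulating database pathologies
    q1 <- consensus$ust; q1[seq_len(380L)] <- "?"          # ITS2 only
    q2 <- consensus$amb; q2[221:610] <- "?"                # ITS1 only
    q3 <- consensus$alb                                    # ambiguity-laden
    q3[unlist(diagCols)] <- "N"
    q4 <- base                                             # 5.8S deviant,
    devCols <- 221L + c(10L, 60L, 110L)                    # matches nothing
    q4 <- mutate(q4, devCols)
    recs[["q_its2only"]] <- q1
    recs[["q_its1only"]] <- q2
    recs[["q_ambiguous"]] <- q3
    recs[["q_deviant"]] <- q4

    m <- do.call(rbind, recs)
    aln <- new("ITSAlignment", seqs = m, regions = regions)
    map <- data.frame(
      id = rownames(m),
      species = c(rep(species, each = 4L),
                  species[5L], species[3L], species[1L], "unknown"),
      role = rep(c("reference", "query"), c(20L, 4L)),
      flags = "",
      stringsAsFactors = FALSE)
    # queries are unlabelled as far as the analysis is concerned
    map$species[map$role == "query"] <- "unknown"
    names(diagCols) <- species
    list(alignment = aln, map = speciesMap(map),
         diagnosticColumns = lapply(diagCols, function(x) sort(x) - 1L))
  })
}
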