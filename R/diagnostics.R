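# Species-diagnostic alignment columns and placement of short/low-quality
# records -- the procedure used for samples excluded from clustering or tree
# building. Queries are never added to the reference when computing
# diagnostics, so there is no leakage from query to reference.

#' Find species-diagnostic alignment columns
#'
#' A column is diagnostic for a reference species when its state there is
#' fixed -- present, unambiguous, and identical in every member (allowing up
#' to a fraction `tolerance` of members to be gap/ambiguous) -- and that
#' state is observed in no other reference species at the column. Reported
#' in ascending column order (0-based internally; add 1 for reports).
#'
#' @param aln an [ITSAlignment-class] containing the reference records.
#' @param map species map data.frame; only `role == "reference"` rows are
#'   used, and at least 2 reference species with >= 1 member each are
#'   required.
#' @param tolerance maximum fraction of a species' members allowed to be
#'   gap/ambiguous at a column while the column still counts as fixed
#'   (default 0: strict).
#' @return a [DiagnosticTable-class] (possibly empty).
#' @export
findDiagnosticPositions <- function(aln, map, tolerance = 0) {
  stopifnot(is(aln, "ITSAlignment"), tolerance >= 0, tolerance <= 1)
  ref <- map[map$role == "reference" & map$id %in% seqIds(aln), , drop = FALSE]
  species <- unique(ref$species)
  if (length(species) < 2L) stop("need >= 2 reference species")
  m <- aln@seqs[ref$id, , drop = FALSE]
  rows <- split(seq_len(nrow(m)), ref$species)

  entries <- list()
  profiles <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    isBase <- col %in% .BASES
    # per-species observed unambiguous states and missing fraction
    obs <- lapply(rows, function(i) unique(col[i][isBase[i]]))
    missFrac <- vapply(rows, function(i) mean(!isBase[i]), numeric(1L))
    fixed <- vapply(seq_along(rows), function(k) {
      length(obs[[k]]) == 1L && missFrac[k] <= tolerance
    }, logical(1L))
    for (k in seq_along(rows)) {
      if (!fixed[k]) next
      state <- obs[[k]]
      others <- unlist(obs[-k], use.names = FALSE)
      if (state %in% others) next
      entries[[length(entries) + 1L]] <- data.frame(
        column = j - 1L, species = names(rows)[k], state = state,
        stringsAsFactors = FALSE)
      profiles[[length(profiles) + 1L]] <- data.frame(
        column = j - 1L, species = names(rows),
        states = vapply(obs, function(s) paste(sort(s), collapse = ","),
                        character(1L)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(entries)) do.call(rbind, entries) else
    data.frame(column = integer(0), species = character(0),
               state = character(0), stringsAsFactors = FALSE)
  prof <- if (length(profiles)) unique(do.call(rbind, profiles)) else
    data.frame(column = integer(0), species = character(0),
               states = character(0), stringsAsFactors = FALSE)
  rownames(tab) <- rownames(prof) <- NULL
  new("DiagnosticTable", table = tab, profiles = prof)
}

#' Place a query sequence by diagnostic positions
#'
#' For each species, counts the diagnostic columns the query covers with an
#' unambiguous base (`covered`), how many match the diagnostic state
#' (`matches`) or not (`mismatches`), and how many are gap/ambiguous in the
#' query (`uncertain`). The verdict is deterministic:
#' * `assigned(S)` -- S is the unique covered species with zero mismatches
#'   and `covered >= minCovered`;
#' * `uncertain` -- a unique zero-mismatch species exists but with
#'   `covered < minCovered`, or >= 2 covered species tie at zero mismatches,
#'   or the query covers no diagnostic column at all;
#' * `conflicting` -- every covered species shows at least one mismatch
#'   (the record matches no species in the reference).
#'
#' @param query aligned residue string or character vector (same columns as
#'   the reference alignment; use [alignQuery()] for unaligned queries).
#' @param table a [DiagnosticTable-class] with at least one entry.
#' @param minCovered minimum covered diagnostic positions for a confident
#'   assignment (default 3: single-position matches are fragile to
#'   sequencing error).
#' @param id optional query id carried into the result.
#' @return list of class `PlacementResult`: `id`, `counts` (data.frame
#'   species, covered, matches, mismatches, uncertain), `verdict`,
#'   `species` (assigned species or `NA`), `flaggedColumns` (0-based
#'   uncertain positions).
#' @export
placeSequence <- function(query, table, minCovered = 3, id = NA_character_) {
  stopifnot(is(table, "DiagnosticTable"))
  tab <- table@table
  if (nrow(tab) == 0L) stop("empty diagnostic table")
  qv <- if (length(query) == 1L) strsplit(toupper(query), "")[[1L]] else
    toupper(query)
  if (max(tab$column) + 1L > length(qv)) {
    stop("query shorter than the diagnostic column range")
  }
  qs <- qv[tab$column + 1L]
  isBase <- qs %in% .BASES
  counts <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$species),
    function(i) {
      data.frame(covered = sum(isBase[i]),
                 matches = sum(isBase[i] & qs[i] == tab$state[i]),
                 mismatches = sum(isBase[i] & qs[i] != tab$state[i]),
                 uncertain = sum(!isBase[i]))
    }))
  counts <- data.frame(species = rownames(counts), counts,
                       row.names = NULL, stringsAsFactors = FALSE)
  counts <- counts[order(counts$species), , drop = FALSE]

  coveredSpecies <- counts[counts$covered > 0L, , drop = FALSE]
  zero <- coveredSpecies[coveredSpecies$mismatches == 0L, , drop = FALSE]
  if (nrow(coveredSpecies) == 0L) {
    verdict <- "uncertain"; assigned <- NA_character_
  } else if (nrow(zero) == 0L) {
    verdict <- "conflicting"; assigned <- NA_character_
  } else if (nrow(zero) > 1L) {
    verdict <- "uncertain"; assigned <- NA_character_
  } else if (zero$covered >= minCovered) {
    verdict <- "assigned"; assigned <- zero$species
  } else {
    verdict <- "uncertain"; assigned <- NA_character_
  }
  structure(list(id = id, counts = counts, verdict = verdict,
                 species = assigned,
                 flaggedColumns = sort(unique(tab$column[!isBase]))),
            class = "PlacementResult")
}

#' @export
print.PlacementResult <- function(x, ...) {
  cat("PlacementResult", if (!is.na(x$id)) paste0("for '", x$id, "'") else "",
      "\nverdict:", x$verdict,
      if (!is.na(x$species)) paste0("(", x$species, ")") else "", "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Place several queries and tabulate the verdicts
#'
#' @param aln an [ITSAlignment-class] containing the (aligned) queries.
#' @param ids query ids to place.
#' @param table a [DiagnosticTable-class].
#' @param minCovered see [placeSequence()].
#' @return data.frame: id, verdict, species, covered, matches, mismatches,
#'   uncertain (counts of the best zero-mismatch species, or the maximum
#'   covered species when none matches).
#' @export
placeSequences <- function(aln, ids, table, minCovered = 3) {
  out <- lapply(ids, function(id) {
    p <- placeSequence(aln@seqs[id, ], table, minCovered = minCovered,
                       id = id)
    best <- if (!is.na(p$species)) {
      p$counts[p$counts$species == p$species, , drop = FALSE]
    } else {
      zm <- p$counts[p$counts$mismatches == 0L & p$counts$covered > 0L, ,
                     drop = FALSE]
      if (nrow(zm)) zm[which.max(zm$covered), , drop = FALSE]
      else p$counts[which.max(p$counts$covered), , drop = FALSE]
    }
    data.frame(id = id, verdict = p$verdict,
               species = ifelse(is.na(p$species), NA_character_, p$species),
               covered = best$covered, matches = best$matches,
               mismatches = best$mismatches, uncertain = best$uncertain,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# shared 8-mer count between two (degapped) sequences
.sharedKmers <- function(a, b, k = 8L) {
  fa <- Biostrings::oligonucleotideFrequency(a, width = k)
  fb <- Biostrings::oligonucleotideFrequency(b, width = k)
  sum(pmin(fa, fb))
}

.degap <- function(s) gsub("[-?]", "", s)

#' Thread an unaligned query onto the reference alignment columns
#'
#' Picks the closest reference by shared 8-mer count, aligns the query to it
#' globally (match 1, mismatch -1, gap open 5, gap extend 1), and maps the
#' query residues onto the reference's alignment columns. Columns the query
#' does not cover become `?`; query insertions relative to the reference
#' cannot be represented and are dropped.
#'
#' @param query residue string (unaligned; may contain ambiguities).
#' @param aln reference [ITSAlignment-class].
#' @param id optional id attached to the result.
#' @return aligned character vector of length `nSites(aln)`, with the chosen
#'   reference id as attribute `reference`.
#' @export
alignQuery <- function(query, aln, id = NULL) {
  stopifnot(is(aln, "ITSAlignment"), nchar(query) > 0)
  q <- toupper(.degap(query))
  refStrings <- sequenceStrings(aln)
  refDegap <- vapply(refStrings, .degap, character(1L))
  qd <- Biostrings::DNAString(gsub("[^ACGT]", "N", q))
  shared <- vapply(refDegap, function(r) {
    .sharedKmers(qd, Biostrings::DNAString(gsub("[^ACGT]", "N", r)))
  }, numeric(1L))
  if (all(shared == 0)) {
    stop("query shares no 8-mer with any reference; skipped",
         if (!is.null(id)) paste0(" (", id, ")") else "")
  }
  best <- names(shared)[which.max(shared)]
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = gsub("[^ACGT]", "N", q),
    subject = gsub("[^ACGT]", "N", refDegap[[best]]),
    type = "global", substitutionMatrix = sub,
    gapOpening = 5, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qorig <- strsplit(q, "")[[1L]]

  # degapped reference position -> original alignment column
  refRow <- aln@seqs[best, ]
  refCols <- which(!refRow %in% c("-", "?"))

  out <- rep("?", nSites(aln))
  rpos <- 0L  # position in degapped reference
  qpos <- 0L  # position in query
  for (k in seq_along(pat)) {
    pgap <- pat[k] == "-"
    sgap <- sbj[k] == "-"
    if (!pgap) qpos <- qpos + 1L
    if (!sgap) rpos <- rpos + 1L
    if (!pgap && !sgap) out[refCols[rpos]] <- qorig[qpos]
  }
  attr(out, "reference") <- best
  out
}

#' Screen record quality
#'
#' Reproduces the screening used before tree building: records containing
#' only one spacer region, ambiguity-laden records, and records deviating
#' from the reference consensus inside the conserved 5.8S domain. Flags:
#' * `partial:ITS1` / `partial:ITS2` -- exactly one spacer covered >= 50%
#'   while the other is < 10%;
#' * `high_ambiguity` -- IUPAC-ambiguity fraction above
#'   `maxAmbiguityFraction` (of the non-missing residues);
#' * `domain_deviant` -- >= 2 unambiguous differences from the reference
#'   consensus within `domainRegion`;
#' * `full_length` otherwise (partial flags are mutually exclusive with it).
#'
#' @param aln an [ITSAlignment-class] with ITS1/ITS2 region annotation.
#' @param map optional species map; when given, the 5.8S consensus is built
#'   from the reference records only.
#' @param ids records to screen (default: all).
#' @param maxAmbiguityFraction ambiguity threshold (default 0.02).
#' @param domainRegion conserved region name (default `"5.8S"`).
#' @return data.frame: `id`, `flags` (`;`-separated), `ambiguityFraction`,
#'   and one `coverage_<region>` column per region (fraction of region
#'   columns carrying an unambiguous base).
#' @export
screenQuality <- function(aln, map = NULL, ids = NULL,
                          maxAmbiguityFraction = 0.02,
                          domainRegion = "5.8S") {
  stopifnot(is(aln, "ITSAlignment"))
  if (nrow(aln@regions) == 0L) stop("region annotation required")
  if (is.null(ids)) ids <- seqIds(aln)
  m <- aln@seqs

  consIds <- if (!is.null(map)) {
    intersect(map$id[map$role == "reference"], seqIds(aln))
  } else seqIds(aln)
  domCols <- .regionCols(aln@regions, domainRegion)
  consensus <- if (length(domCols) && length(consIds)) {
    apply(m[consIds, domCols, drop = FALSE], 2L, function(col) {
      col <- col[col %in% .BASES]
      if (!length(col)) NA_character_ else names(which.max(table(col)))
    })
  } else character(0)

  out <- lapply(ids, function(id) {
    row <- m[id, ]
    isBase <- row %in% .BASES
    isAmb <- row %in% .AMBIG
    nInfo <- sum(isBase | isAmb)
    ambFrac <- if (nInfo) sum(isAmb) / nInfo else 0
    cov <- vapply(aln@regions$name, function(r) {
      cols <- .regionCols(aln@regions, r)
      mean(isBase[cols])
    }, numeric(1L))
    flags <- character(0)
    c1 <- if ("ITS1" %in% names(cov)) cov[["ITS1"]] else NA_real_
    c2 <- if ("ITS2" %in% names(cov)) cov[["ITS2"]] else NA_real_
    if (!is.na(c1) && !is.na(c2)) {
      if (c1 >= 0.5 && c2 < 0.1) flags <- c(flags, "partial:ITS1")
      else if (c2 >= 0.5 && c1 < 0.1) flags <- c(flags, "partial:ITS2")
    }
    if (ambFrac > maxAmbiguityFraction) flags <- c(flags, "high_ambiguity")
    if (length(consensus)) {
      obs <- row[domCols]
      diffs <- sum(obs %in% .BASES & !is.na(consensus) & obs != consensus)
      if (diffs >= 2L) flags <- c(flags, "domain_deviant")
    }
    if (!length(flags) || identical(flags, "high_ambiguity") ||
        identical(flags, "domain_deviant") ||
        identical(flags, c("high_ambiguity", "domain_deviant"))) {
      flags <- c("full_length", flags)
    }
    df <- data.frame(id = id, flags = paste(flags, collapse = ";"),
                     ambiguityFraction = ambFrac, stringsAsFactors = FALSE)
    for (r in aln@regions$name) df[[paste0("coverage_", r)]] <- cov[[r]]
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
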