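# Pairwise p-distances with explicit overlap, gap and ambiguity rules.
#
# UNITE-style percent thresholds are complements of sequence similarity, so
# the uncorrected p-distance (similarity = 1 - d) is the right scale; no
# model correction is applied. Any IUPAC ambiguity (including N), '-' and
# '?' remove the column from the comparison for that pair ("pairwise
# deletion"): conservative and reproducible, matching the treatment of
# ambiguity-laden records as unreliable.

#' Pairwise uncorrected p-distance between two aligned records
#'
#' Compared sites are the columns where both residues are unambiguous bases
#' (A, C, G, T); the distance is `mismatches / compared`. When fewer than
#' `minOverlap` sites are comparable the pair is "missing" (`NA`) -- e.g. an
#' ITS1-only against an ITS2-only record shares no unambiguous column.
#'
#' @param a,b aligned residue strings (or character vectors) of equal
#'   length.
#' @param minOverlap minimum number of compared sites (default 100).
#' @return the p-distance in \[0,1\], or `NA` if the overlap is too short;
#'   the number of compared sites is attached as attribute `compared`.
#' @examples
#' pDistance("ACGT", "ACGA", minOverlap = 1)  # 0.25
#' pDistance("AC-TN", "ACGTA", minOverlap = 1) # 0, over 3 compared sites
#' @export
pDistance <- function(a, b, minOverlap = 100) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "")[[1L]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "")[[1L]] else toupper(b)
  if (length(av) != length(bv)) {
    stop("length mismatch: ", length(av), " vs ", length(bv))
  }
  ok <- av %in% .BASES & bv %in% .BASES
  compared <- sum(ok)
  d <- if (compared < minOverlap) NA_real_ else sum(av[ok] != bv[ok]) / compared
  structure(d, compared = compared)
}

#' Pairwise p-distance matrix of an alignment
#'
#' All-pairs version of [pDistance()], symmetric by construction, with the
#' per-pair compared-site counts retained so that missingness (short
#' overlap) is auditable.
#'
#' @param aln an [ITSAlignment-class] (or named character vector of aligned
#'   records) with at least 2 records.
#' @param minOverlap minimum compared sites per pair (default 100).
#' @return a [DistanceMatrix-class].
#' @export
distanceMatrix <- function(aln, minOverlap = 100) {
  if (!is(aln, "ITSAlignment")) aln <- validateAlignment(aln)
  m <- aln@seqs
  if (nrow(m) < 2L) stop("need at least 2 records")
  enc <- matrix(match(m, .BASES), nrow = nrow(m))  # non-ACGT -> NA
  n <- nrow(m)
  d <- matrix(0, n, n)
  comp <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]
    for (j in seq.int(i + 1L, n)) {
      xj <- enc[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      nc <- sum(ok)
      comp[i, j] <- comp[j, i] <- nc
      d[i, j] <- d[j, i] <-
        if (nc < minOverlap) NA_real_ else sum(xi[ok] != xj[ok]) / nc
    }
  }
  diag(comp) <- as.integer(rowSums(!is.na(enc)))
  dimnames(d) <- dimnames(comp) <- list(rownames(m), rownames(m))
  new("DistanceMatrix", d = d, compared = comp,
      minOverlap = as.integer(minOverlap))
}

#' Export a distance matrix
#'
#' @param D a [DistanceMatrix-class].
#' @param path output path.
#' @param format `"tsv"` (square, with ids, `NA` for missing) or
#'   `"phylip"` (square PHYLIP distance format; missing written as -1).
#' @return `path`, invisibly.
#' @export
exportDistances <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  stopifnot(is(D, "DistanceMatrix"))
  if (format == "tsv") {
    utils::write.table(data.frame(id = seqIds(D), D@d, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- D@d
    m[is.na(m)] <- -1
    lines <- c(sprintf("%5d", nrow(m)),
               vapply(seq_len(nrow(m)), function(i) {
                 paste0(formatC(rownames(m)[i], width = -10),
                        paste(sprintf("%.6f", m[i, ]), collapse = " "))
               }, character(1L)))
    writeLines(lines, path)
  }
  invisible(path)
}
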