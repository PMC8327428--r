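# FASTA / metadata input-output and input validation.
#
# Sequences are kept as plain upper-case character data internally; file I/O
# goes through Biostrings. Records may contain the full IUPAC alphabet plus
# '-' (alignment gap) and '?' (missing, e.g. truncated) -- '?' is outside the
# DNA alphabet, hence BStringSet rather than DNAStringSet on disk.

#' Read sequence records from a FASTA file
#'
#' The record id is the header up to the first whitespace; the remainder of
#' the description line is preserved as an opaque annotation (attribute
#' `descriptions`), never parsed. Residues are upper-cased and validated
#' against the IUPAC alphabet plus `-` and `?`.
#'
#' @param path path to a FASTA file.
#' @return named character vector of residue strings (names = ids), with a
#'   `descriptions` attribute. An empty file yields an empty vector with a
#'   warning.
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L || !any(grepl("^>", readLines(path, warn = FALSE)))) {
    warning("no FASTA records in ", path)
    return(structure(character(0), descriptions = character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(ss))
  names(res) <- ids
  for (i in seq_along(res)) {
    ch <- strsplit(res[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% .ALPHABET)
    if (length(bad)) {
      stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                   ch[bad[1L]], ids[i], bad[1L]))
    }
  }
  structure(res, descriptions = stats::setNames(desc, ids))
}

#' Write sequence records to a FASTA file
#'
#' Lossless counterpart of [readFastaRecords()]: writing then reading
#' returns identical (id, residues) pairs.
#'
#' @param records named character vector of residue strings.
#' @param path output path.
#' @param descriptions optional named character vector appended (after a
#'   space) to the header lines.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(records, path, descriptions = NULL) {
  stopifnot(length(records) == 0L || !is.null(names(records)))
  if (anyDuplicated(names(records))) stop("duplicate record ids")
  headers <- names(records)
  if (!is.null(descriptions)) {
    d <- descriptions[headers]
    has <- !is.na(d) & nzchar(d)
    headers[has] <- paste(headers[has], d[has])
  }
  ss <- Biostrings::BStringSet(unname(as.character(records)))
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read the sequence metadata table
#'
#' Tab-separated file with header columns `id`, `species`, `role`
#' (`reference` or `query`) and optionally `flags`. Every reference record
#' must carry a species label; query records may be `unknown`. Ids absent
#' from the supplied alignment are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @param alignment optional [ITSAlignment-class] used to cross-check ids.
#' @return data.frame with columns `id`, `species`, `role`, `flags`.
#' @export
readMetadata <- function(path, alignment = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "species", "role")
  if (!all(need %in% names(tab))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (!"flags" %in% names(tab)) tab$flags <- ""
  tab <- tab[, c("id", "species", "role", "flags")]
  speciesMap(tab, alignment = alignment)
}

#' Build / validate a species map
#'
#' @param map data.frame with columns `id`, `species`, `role` (and optional
#'   `flags`).
#' @param alignment optional [ITSAlignment-class]; ids not present in it are
#'   excluded with a warning.
#' @return validated data.frame (a plain species map).
#' @export
speciesMap <- function(map, alignment = NULL) {
  stopifnot(is.data.frame(map), all(c("id", "species", "role") %in% names(map)))
  if (!"flags" %in% names(map)) map$flags <- rep("", nrow(map))
  if (anyDuplicated(map$id)) {
    stop("duplicate ids in species map: ",
         paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  }
  if (!all(map$role %in% c("reference", "query"))) {
    stop("role must be 'reference' or 'query'")
  }
  noSpecies <- is.na(map$species) | !nzchar(map$species) |
    map$species == "unknown"
  if (any(map$role == "reference" & noSpecies)) {
    stop("reference record(s) without species label: ",
         paste(map$id[map$role == "reference" & noSpecies], collapse = ", "))
  }
  map$species[noSpecies] <- "unknown"
  if (!is.null(alignment)) {
    missing <- setdiff(map$id, seqIds(alignment))
    if (length(missing)) {
      warning("ids not in alignment, excluded: ",
              paste(missing, collapse = ", "))
      map <- map[!map$id %in% missing, , drop = FALSE]
      rownames(map) <- NULL
    }
  }
  map
}

#' Validate records into an alignment
#'
#' Checks that all records have equal length (reporting the offending ids
#' otherwise), that residues are legal, and that the region map fits within
#' the alignment; returns the central alignment container.
#'
#' @param records named character vector of aligned residue strings.
#' @param regionMap data.frame (`name`, `start`, `end`; 0-based half-open
#'   column intervals). `NULL` annotates the whole width as one `ITS` region.
#' @return an [ITSAlignment-class].
#' @examples
#' aln <- validateAlignment(c(s1 = "ACGT", s2 = "ACGA"))
#' nSites(aln)
#' @export
validateAlignment <- function(records, regionMap = NULL) {
  if (length(records) == 0L) stop("no records")
  if (is.null(names(records))) stop("records must be named by id")
  n <- nchar(records)
  if (length(unique(n)) != 1L) {
    tab <- table(n)
    common <- as.integer(names(tab)[which.max(tab)])
    stop("ragged alignment; offending ids: ",
         paste(names(records)[n != common], collapse = ", "))
  }
  m <- .toMatrix(records)
  if (is.null(regionMap)) {
    regionMap <- data.frame(name = "ITS", start = 0L, end = ncol(m),
                            stringsAsFactors = FALSE)
  }
  new("ITSAlignment", seqs = m, regions = regionMap)
}
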