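# Internal helpers shared across modules.

# IUPAC nucleotide alphabet plus the two "no information" codes used in files:
# '-' alignment gap, '?' missing (e.g. truncated) residue.
.BASES <- c("A", "C", "G", "T")
.AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.ALPHABET <- c(.BASES, .AMBIG, "-", "?")

# IUPAC ambiguity code -> set of bases it covers
.IUPAC_SETS <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the current stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number or NULL")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Split residue strings into a character matrix (rows = records).
.toMatrix <- function(records) {
  if (length(records) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  n <- nchar(records)
  if (length(unique(n)) != 1L) {
    bad <- names(records)[n != stats::median(n)]
    stop("records are not aligned (unequal lengths): ",
         paste(bad, collapse = ", "))
  }
  m <- do.call(rbind, strsplit(toupper(records), "", fixed = TRUE))
  rownames(m) <- names(records)
  m
}

.collapseRows <- function(m) {
  stats::setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

# Validate a region map data.frame (name, start, end; 0-based half-open).
.checkRegions <- function(regions, width) {
  stopifnot(is.data.frame(regions))
  need <- c("name", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("region map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(regions$name)) stop("duplicated region names")
  if (any(regions$start < 0) || any(regions$end > width) ||
      any(regions$end <= regions$start)) {
    stop("region intervals must satisfy 0 <= start < end <= ", width)
  }
  o <- order(regions$start)
  r <- regions[o, , drop = FALSE]
  if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
    stop("region intervals overlap")
  }
  invisible(regions)
}

# Column indices (1-based) of a named region.
.regionCols <- function(regions, name) {
  i <- match(name, regions$name)
  if (is.na(i)) return(integer(0))
  seq.int(regions$start[i] + 1L, regions$end[i])
}
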