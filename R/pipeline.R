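# End-to-end orchestration: (simulate | load) -> quality screen ->
# distances -> threshold sweep -> partition evaluation -> diagnostics ->
# report bundle. Everything in the bundle is reproducible from the
# provenance file alone (no timestamps are written, so identical
# configuration + seed gives byte-identical bundles).

#' Read a pipeline configuration file
#'
#' YAML or JSON, decided by file extension (`.json` -> JSON, anything else
#' parsed as YAML, of which JSON is a subset).
#'
#' @param path configuration file.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

.logStage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full threshold-testing pipeline
#'
#' The configuration carries exactly one of:
#' * `input`: list with `fasta`, `metadata` and optionally `regions`
#'   (data.frame or list with `name`, `start`, `end`); or
#' * `simulate`: a [generateDataset()] configuration (all records are then
#'   references labelled with their true species).
#'
#' Optional fields: `grid` (default 0-3% by 0.5), `minOverlap` (default
#' 100), `minCovered` (default 3), `tolerance` (diagnostics, default 0),
#' `includeFlagged` (default `FALSE`), `seed`.
#'
#' Records failing the quality screen (partial, high-ambiguity or
#' domain-deviant) and all `query`-role records are withheld from distance
#' clustering -- mirroring their exclusion before tree building -- and are
#' routed to diagnostic-position placement instead; `includeFlagged = TRUE`
#' forces everything into the clustering.
#'
#' @param config list or path to a YAML/JSON configuration.
#' @param outDir directory for the report bundle (`NULL`: nothing written).
#' @param verbose log one line per stage with record counts.
#' @return (invisibly) list with `alignment`, `map`, `quality`, `distances`,
#'   `sweep`, `table` (the per-id threshold x cluster table), `report`
#'   (see [evalReport()]), `diagnostics`, `placements`, `withheld`.
#' @examples
#' res <- runPipeline(list(simulate = list(preset = "complex",
#'                                         samplesPerSpecies = 2, seed = 3),
#'                         seed = 3), verbose = FALSE)
#' res$report$minResolving
#' @export
runPipeline <- function(config, outDir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config$input) == is.null(config$simulate)) {
    stop("config must contain exactly one of 'input' or 'simulate'")
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- sim$seed %||% config$seed
    ds <- generateDataset(sim)
    aln <- ds$alignment
    map <- speciesMap(data.frame(id = ds$truth$id, species = ds$truth$species,
                                 role = "reference", flags = ds$truth$flags,
                                 stringsAsFactors = FALSE))
    .logStage(verbose, "simulate", "%d records, %d species",
              nSequences(aln), length(unique(map$species)))
  } else {
    recs <- readFastaRecords(config$input$fasta)
    regions <- config$input$regions
    if (!is.null(regions) && !is.data.frame(regions)) {
      regions <- as.data.frame(lapply(regions, unlist),
                               stringsAsFactors = FALSE)
    }
    aln <- validateAlignment(recs, regionMap = regions)
    map <- readMetadata(config$input$metadata, alignment = aln)
    .logStage(verbose, "load", "%d records read, %d mapped",
              nSequences(aln), nrow(map))
  }

  quality <- screenQuality(aln, map = map)
  flagged <- quality$id[quality$flags != "full_length"]
  queries <- map$id[map$role == "query"]
  withheld <- union(queries, flagged)
  keep <- if (isTRUE(config$includeFlagged)) setdiff(seqIds(aln), queries)
    else setdiff(seqIds(aln), withheld)
  .logStage(verbose, "screen", "%d records flagged, %d withheld from clustering",
            length(flagged), length(setdiff(seqIds(aln), keep)))
  if (length(keep) < 2L) stop("fewer than 2 records left for clustering")

  D <- distanceMatrix(aln[keep], minOverlap = config$minOverlap %||% 100)
  .logStage(verbose, "distances", "%d x %d matrix, %d missing pair(s)",
            length(keep), length(keep), sum(is.na(D@d[upper.tri(D@d)])))

  grid <- config$grid %||% seq(0, 3, by = 0.5)
  sweep <- thresholdSweep(D, grid = grid)
  # statuses are computed over the records that entered the clustering;
  # withheld records are reported through the placement table instead
  report <- evalReport(sweep, map[map$id %in% keep, , drop = FALSE])
  .logStage(verbose, "sweep", "clusters per threshold: %s",
            paste(clusterCounts(sweep), collapse = ", "))

  # diagnostics come from the good-quality reference records only; queries
  # and flagged records are never part of the reference (no leakage)
  refClean <- intersect(keep, map$id[map$role == "reference"])
  diag <- if (length(unique(map$species[map$id %in% refClean])) >= 2L) {
    findDiagnosticPositions(aln[refClean], map,
                            tolerance = config$tolerance %||% 0)
  } else {
    new("DiagnosticTable",
        table = data.frame(column = integer(0), species = character(0),
                           state = character(0), stringsAsFactors = FALSE),
        profiles = data.frame(column = integer(0), species = character(0),
                              states = character(0), stringsAsFactors = FALSE))
  }
  toPlace <- setdiff(seqIds(aln), keep)
  placements <- if (length(toPlace) && nrow(diag@table)) {
    placeSequences(aln, toPlace, diag, minCovered = config$minCovered %||% 3)
  } else NULL
  .logStage(verbose, "diagnose", "%d diagnostic column(s), %d record(s) placed",
            nrow(diag@table), length(toPlace))

  tab <- shTable(sweep, map)
  res <- list(alignment = aln, map = map, quality = quality, distances = D,
              sweep = sweep, table = tab, report = report,
              diagnostics = diag, placements = placements,
              withheld = setdiff(seqIds(aln), keep))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.table(
      x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    exportDistances(D, file.path(outDir, "distances.tsv"))
    w(tab, "partitions.tsv")
    w(report$statuses, "statuses.tsv")
    w(quality, "quality.tsv")
    dtab <- diag@table
    if (nrow(dtab)) dtab$position <- dtab$column + 1L  # 1-based for reports
    w(dtab, "diagnostics.tsv")
    if (!is.null(placements)) w(placements, "placements.tsv")
    jsonlite::write_json(
      list(package = "barcodeSH",
           version = as.character(utils::packageVersion("barcodeSH")),
           seed = config$seed, config = config,
           distanceModel = "uncorrected p-distance, pairwise deletion",
           minOverlap = config$minOverlap %||% 100,
           grid = grid,
           clusterCounts = as.list(clusterCounts(sweep)),
           minResolving = report$minResolving,
           minResolvingSimilarity = report$minResolvingSimilarity,
           scope = report$scope),
      file.path(outDir, "provenance.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(
      list(statuses = report$statuses, perSpeciesMin = as.list(report$perSpeciesMin),
           clusterCounts = as.list(clusterCounts(sweep)),
           minResolving = report$minResolving),
      file.path(outDir, "eval.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    .logStage(verbose, "write", "report bundle in %s", outDir)
  }
  invisible(res)
}
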