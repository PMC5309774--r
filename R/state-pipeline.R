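# Per-structure metric aggregation, four-state classification and the
# summary table over a dataset manifest.

#' Default stalk-state boundaries
#'
#' Midpoints between adjacent group means of the four stalk positions
#' (open 4.0, intermediate 2 14.4, intermediate 1 20.4, closed 26.5
#' degrees), giving 9.2, 17.4 and 23.45 degrees.
#'
#' @export
stateBoundaries <- c(9.2, 17.4, 23.45)

#' Classify a stalk rotation into one of four states
#'
#' Intervals are left-closed: a rotation exactly at a boundary belongs to
#' the more-rotated state.
#'
#' @param rotation rotation angle(s) in degrees, >= 0
#' @param boundaries three ascending thresholds (degrees)
#' @return factor with levels open, intermediate2, intermediate1, closed
#' @export
classifyState <- function(rotation, boundaries = stateBoundaries) {
  if (length(boundaries) != 3L || is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be 3 strictly ascending thresholds")
  if (any(rotation < 0)) stop("rotation must be non-negative")
  lev <- c("open", "intermediate2", "intermediate1", "closed")
  idx <- findInterval(rotation, boundaries, left.open = FALSE) + 1L
  factor(lev[idx], levels = lev)
}

#' Build a dataset manifest
#'
#' @param sourceId unique structure identifiers
#' @param path coordinate file paths
#' @param speciesTag "bacterial" or "eukaryotic" per entry
#' @param trnaState E-site tRNA binding state per entry: one of "vacant",
#'   "P/E", "pe/E", "E/E", "unknown"
#' @param chain chain id carrying the large-subunit rRNA per entry
#' @param numberingOffset optional per-entry residue-numbering offset
#'   applied to that chain (0 = author numbering already matches)
#' @return data.frame manifest for \code{\link{runDataset}}
#' @export
datasetManifest <- function(sourceId, path, speciesTag = "bacterial",
                            trnaState = "unknown", chain = "A",
                            numberingOffset = 0L) {
  m <- data.frame(sourceId = sourceId, path = path,
                  speciesTag = speciesTag, trnaState = trnaState,
                  chain = chain, numberingOffset = numberingOffset,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$sourceId)) stop("sourceId values must be unique")
  m
}

#' Read a dataset manifest from YAML
#'
#' @param path YAML file with an \code{entries} list whose members carry
#'   source_id, path, species_tag, trna_state, chain and optionally
#'   numbering_offset
#' @return manifest data.frame
#' @export
readManifest <- function(path) {
  y <- yaml::read_yaml(path)
  e <- y$entries
  datasetManifest(
    sourceId = vapply(e, `[[`, "", "source_id"),
    path = vapply(e, `[[`, "", "path"),
    speciesTag = vapply(e, function(x) x$species_tag %||% "bacterial", ""),
    trnaState = vapply(e, function(x) x$trna_state %||% "unknown", ""),
    chain = vapply(e, function(x) x$chain %||% "A", ""),
    numberingOffset = vapply(e, function(x)
      as.integer(x$numbering_offset %||% 0L), integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full per-structure pipeline over a manifest
#'
#' For each entry: read the structure, renumber if needed, superpose on the
#' reference static core, measure the stalk rotation (screw angle of the
#' mobile domain against the static domain), the head-marker displacement,
#' and classify the state. Entries that fail are skipped with their reason
#' recorded; failure of the reference entry aborts.
#'
#' @param manifest data.frame from \code{\link{datasetManifest}}
#' @param referenceId sourceId of the open-state reference entry
#' @param staticSel,mobileSel,coreSel selection factories: functions
#'   (chain -> ResidueSelection); defaults use the shipped presets
#' @param marker marker factory: function (species, chain) -> marker list
#' @param boundaries classification boundaries in degrees
#' @param verbose log per-entry progress to stderr
#' @return list(records, summary, skipped): per-structure records, the
#'   per-tRNA-state group summary (mean, sd, N of rotation and
#'   displacement), and skipped entries with reasons
#' @export
runDataset <- function(manifest, referenceId = "4GD2",
                       staticSel = function(chain)
                         selectionPreset("l1-static-h75", chain),
                       mobileSel = function(chain)
                         selectionPreset("l1-mobile-h76", chain),
                       coreSel = function(chain)
                         selectionPreset("bacterial-23s-core", chain),
                       marker = function(species, chain)
                         displacementMarker(species, chain),
                       boundaries = stateBoundaries,
                       verbose = FALSE) {
  if (!(referenceId %in% manifest$sourceId))
    stop("reference ", referenceId, " not present in manifest")
  log <- function(...) if (verbose) message(...)
  loadEntry <- function(row) {
    s <- readStructure(row$path, speciesTag = row$speciesTag,
                       sourceId = row$sourceId)
    if (row$numberingOffset != 0L) {
      off <- stats::setNames(row$numberingOffset, row$chain)
      s <- applyNumberingMap(s, off)
    }
    s
  }
  refRow <- manifest[manifest$sourceId == referenceId, ]
  reference <- tryCatch(loadEntry(refRow), error = function(e)
    stop("reference entry failed: ", conditionMessage(e), call. = FALSE))
  records <- NULL
  skipped <- NULL
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    t0 <- Sys.time()
    rec <- tryCatch({
      s <- if (row$sourceId == referenceId) reference else loadEntry(row)
      ax <- domainRotation(s, reference,
                           staticSel(row$chain), mobileSel(row$chain))
      disp <- displacementAt(s, reference,
                             marker(row$speciesTag, row$chain),
                             coreSel = coreSel(row$chain))
      data.frame(sourceId = row$sourceId,
                 trnaState = row$trnaState,
                 stalkRotation = screwAngle(ax),
                 stalkDisplacement = disp,
                 stalkState = as.character(
                   classifyState(screwAngle(ax), boundaries)),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      if (row$sourceId == referenceId)
        stop("reference entry failed: ", conditionMessage(rec))
      log("skipping ", row$sourceId, ": ", conditionMessage(rec))
      skipped <- rbind(skipped, data.frame(sourceId = row$sourceId,
                                           reason = conditionMessage(rec)))
      next
    }
    log(sprintf("%s: rotation %.2f deg, displacement %.2f A (%.2fs)",
                row$sourceId, rec$stalkRotation, rec$stalkDisplacement,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    records <- rbind(records, rec)
  }
  summary <- do.call(rbind, lapply(split(records, records$trnaState),
                                   function(g)
    data.frame(trnaState = g$trnaState[1L],
               meanRotation = mean(g$stalkRotation),
               sdRotation = stats::sd(g$stalkRotation),
               meanDisplacement = mean(g$stalkDisplacement),
               sdDisplacement = stats::sd(g$stalkDisplacement),
               n = nrow(g), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(records = records, summary = summary, skipped = skipped)
}

#' Write per-structure records as TSV
#'
#' @param records data.frame of records (from \code{\link{runDataset}})
#' @param path output path
#' @export
writeRecordsTSV <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
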