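# Reading, writing and sub-setting coordinate models.
#
# Parsing of the standard dialects is delegated to bio3d (read.pdb /
# read.cif); this module only normalizes the atom table (altloc resolution,
# hetero filtering, ordering) into a StructureModel.

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with at least chain, resno, resid, atom, x, y, z;
#'   element, altloc and model are filled in when missing.
#' @param sourceId identifier (e.g. PDB ID).
#' @param speciesTag "bacterial", "eukaryotic" or "synthetic".
#' @param metadata optional list.
#' @return a \code{StructureModel}
#' @export
structureModel <- function(atoms, sourceId = "unknown",
                           speciesTag = "synthetic", metadata = list()) {
  if (is.null(atoms$element)) atoms$element <- .elementFromName(atoms$atom)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$model)) atoms$model <- 1L
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms[, .requiredAtomCols],
      sourceId = sourceId, speciesTag = speciesTag, metadata = metadata)
}

# Infer the element symbol from a PDB atom name (OP1 -> O, C1' -> C, ...).
.elementFromName <- function(atom) {
  sub("^([A-Za-z]).*$", "\\1", gsub("[0-9']", "", atom))
}

#' Read a coordinate file into a StructureModel
#'
#' Accepts PDB and mmCIF files. Only ATOM records are kept (hetero and
#' ligand records are ignored unless selected later from a file read with
#' \code{keepHetero = TRUE}). Alternate locations are resolved to the
#' highest-occupancy conformer, ties broken alphabetically by altloc code.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @param model model number to extract from multi-model files (default 1).
#' @param sourceId identifier stored in the result; defaults to the file
#'   base name without extension.
#' @param speciesTag stored species tag.
#' @param keepHetero keep HETATM records as well.
#' @return a \code{StructureModel}
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          model = 1L, sourceId = NULL,
                          speciesTag = "bacterial", keepHetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(sourceId)) sourceId <- tools::file_path_sans_ext(basename(path))
  multi <- model > 1L
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = multi, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = multi,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse ", format, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("empty coordinate set in ", path)
  if (multi) {
    if (nrow(raw$xyz) < model)
      stop("model ", model, " not present in ", path)
    xyz <- matrix(raw$xyz[model, ], ncol = 3L, byrow = TRUE)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  }
  if (!keepHetero) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("empty coordinate set (no ATOM records) in ", path)
  elety <- gsub('^"|"$', "", as.character(a$elety))  # mmCIF quoting
  atoms <- data.frame(chain = as.character(a$chain),
                      resno = as.integer(a$resno),
                      resid = as.character(a$resid),
                      atom = elety,
                      element = if (!is.null(a$elesy) && !all(is.na(a$elesy)))
                        as.character(a$elesy) else .elementFromName(elety),
                      x = a$x, y = a$y, z = a$z,
                      altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
                      model = as.integer(model),
                      occ = if (!is.null(a$o)) ifelse(is.na(a$o), 1, a$o) else 1,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- .resolveAltloc(atoms)
  atoms$occ <- NULL
  structureModel(atoms, sourceId = sourceId, speciesTag = speciesTag)
}

# Keep one altloc per (chain, resno, atom): highest occupancy, ties by
# alphabetical altloc code.
.resolveAltloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (!anyDuplicated(key)) return(atoms)
  o <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[o, , drop = FALSE]
  atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom)), , drop = FALSE]
}

#' Write a StructureModel as a PDB file
#'
#' Coordinates are written at the standard 3-decimal PDB precision, so a
#' read/write round trip preserves them to 1e-3 Angstrom.
#'
#' @param structure a \code{StructureModel}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeStructurePDB <- function(structure, path) {
  a <- atoms(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$atom, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Build a residue selection
#'
#' @param chain chain identifier(s), recycled against the ranges.
#' @param start,end inclusive residue bounds (author numbering).
#' @param atomFilter optional character vector of atom names to keep.
#' @return a \code{ResidueSelection}; overlapping ranges on one chain are
#'   merged.
#' @export
residueSelection <- function(chain, start, end, atomFilter = NULL) {
  r <- data.frame(chain = as.character(chain), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  out <- NULL
  for (ch in unique(r$chain)) {
    rr <- r[r$chain == ch, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    merged <- rr[1L, , drop = FALSE]
    for (i in seq_len(nrow(rr))[-1L]) {
      k <- nrow(merged)
      if (rr$start[i] <= merged$end[k] + 1L) {
        merged$end[k] <- max(merged$end[k], rr$end[i])
      } else merged <- rbind(merged, rr[i, ])
    }
    out <- rbind(out, merged)
  }
  rownames(out) <- NULL
  new("ResidueSelection", ranges = out,
      atomFilter = if (is.null(atomFilter)) character(0) else atomFilter)
}

#' Extract the atoms covered by a residue selection
#'
#' @param structure a \code{StructureModel}
#' @param selection a \code{ResidueSelection}
#' @return a \code{StructureModel} restricted to the selection, in residue
#'   order; requested residues that are absent from the structure are
#'   reported in \code{metadata$absentResidues}.
#' @export
selectAtoms <- function(structure, selection) {
  a <- atoms(structure)
  r <- selectionRanges(selection)
  missingChains <- setdiff(unique(r$chain), unique(a$chain))
  if (length(missingChains))
    stop("selection chain(s) not present in structure: ",
         paste(missingChains, collapse = ", "))
  keep <- rep(FALSE, nrow(a))
  wanted <- NULL
  for (i in seq_len(nrow(r))) {
    keep <- keep | (a$chain == r$chain[i] &
                    a$resno >= r$start[i] & a$resno <= r$end[i])
    wanted <- rbind(wanted, data.frame(chain = r$chain[i],
                                       resno = r$start[i]:r$end[i]))
  }
  sub <- a[keep, , drop = FALSE]
  flt <- atomFilter(selection)
  if (length(flt)) sub <- sub[sub$atom %in% flt, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("empty selection: no atoms matched")
  present <- unique(paste(sub$chain, sub$resno))
  absent <- wanted[!(paste(wanted$chain, wanted$resno) %in% present), ,
                   drop = FALSE]
  rownames(absent) <- NULL
  md <- structure@metadata
  md$absentResidues <- absent
  structureModel(sub, sourceId = structure@sourceId,
                 speciesTag = structure@speciesTag, metadata = md)
}

#' Residues covered by a selection, as a chain/resno table
#'
#' @param selection a \code{ResidueSelection}
#' @return data.frame(chain, resno)
#' @export
selectionResidues <- function(selection) {
  r <- selectionRanges(selection)
  out <- do.call(rbind, lapply(seq_len(nrow(r)), function(i)
    data.frame(chain = r$chain[i], resno = r$start[i]:r$end[i],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

.presetEnv <- new.env(parent = emptyenv())

.loadPresets <- function() {
  if (is.null(.presetEnv$cfg)) {
    path <- system.file("extdata", "selection_presets.yaml",
                        package = "stalkmech", mustWork = TRUE)
    .presetEnv$cfg <- yaml::read_yaml(path)
  }
  .presetEnv$cfg
}

#' Curated residue-selection presets
#'
#' Ships the selections used throughout the L1-stalk analysis: the
#' conserved large-subunit rRNA static cores (bacterial 23S and eukaryotic
#' 28S), the mobile H76 and static H75 stalk domains, and the head-domain
#' displacement markers. Residue numbers follow E. coli 23S rRNA numbering
#' (S. cerevisiae numbering for the 28S core); structures with a different
#' author numbering need a renumbering map (see
#' \code{\link{applyNumberingMap}}).
#'
#' @param name preset name; see \code{selectionPresetNames()}.
#' @param chain chain id the preset is instantiated on.
#' @param atomFilter optional atom-name filter.
#' @return a \code{ResidueSelection}
#' @export
selectionPreset <- function(name, chain = "A", atomFilter = NULL) {
  cfg <- .loadPresets()
  p <- cfg$presets[[name]]
  if (is.null(p))
    stop("unknown preset ", sQuote(name), "; available: ",
         paste(names(cfg$presets), collapse = ", "))
  rng <- do.call(rbind, p$ranges)
  residueSelection(chain = chain, start = rng[, 1L], end = rng[, 2L],
                   atomFilter = atomFilter)
}

#' @rdname selectionPreset
#' @export
selectionPresetNames <- function() names(.loadPresets()$presets)

#' @rdname selectionPreset
#' @param species "bacterial" or "eukaryotic"
#' @export
displacementMarker <- function(species = c("bacterial", "eukaryotic"),
                               chain = "A") {
  species <- match.arg(species)
  m <- .loadPresets()$markers[[species]]
  list(chain = chain, resno = as.integer(m$resno), atom = m$atom)
}

#' Renumber residues to a common (E. coli) numbering
#'
#' The analysis applies one numbering convention across structures from
#' different organisms; entries deposited with their own numbering are
#' renumbered with an explicit per-chain map before any preset is applied.
#' No mapping is ever guessed.
#'
#' @param structure a \code{StructureModel}
#' @param map either a named numeric vector of per-chain offsets
#'   (\code{c(A = 10)} adds 10 to every residue number on chain A) or a
#'   data.frame(chain, old, new) of explicit residue correspondences
#'   (residues without an entry are dropped).
#' @return the renumbered \code{StructureModel}
#' @export
applyNumberingMap <- function(structure, map) {
  a <- atoms(structure)
  if (is.numeric(map) && !is.null(names(map))) {
    for (ch in names(map))
      a$resno[a$chain == ch] <- a$resno[a$chain == ch] + as.integer(map[[ch]])
  } else if (is.data.frame(map)) {
    stopifnot(all(c("chain", "old", "new") %in% names(map)))
    key <- paste(a$chain, a$resno)
    mkey <- paste(map$chain, map$old)
    hit <- match(key, mkey)
    keep <- !is.na(hit)
    a <- a[keep, , drop = FALSE]
    a$resno <- as.integer(map$new[hit[keep]])
  } else stop("map must be a named offset vector or a data.frame(chain, old, new)")
  structureModel(a, sourceId = structure@sourceId,
                 speciesTag = structure@speciesTag,
                 metadata = structure@metadata)
}
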