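#' @import methods
NULL

#' Sugar-phosphate backbone atom names used for superposition and core
#' refinement
#'
#' The backbone is taken as the phosphate group plus the sugar atoms that
#' carry the chain: P, OP1, OP2, O5', C5', C4', C3', O3'. Base atoms are
#' deliberately excluded because they are often unmodeled in
#' medium-resolution ribosome structures.
#'
#' @export
backboneAtoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")

.requiredAtomCols <- c("chain", "resno", "resid", "atom", "element",
                       "x", "y", "z", "altloc", "model")

#' StructureModel: atomic coordinates of one conformer
#'
#' Holds one model of a macromolecular structure as a flat atom table with
#' author (PDB) residue numbering. Coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns chain, resno, resid, atom, element,
#'   x, y, z, altloc, model; ordered by (chain, resno).
#' @slot sourceId character, e.g. a PDB ID or a synthetic tag.
#' @slot speciesTag one of "bacterial", "eukaryotic", "synthetic".
#' @slot metadata list for auxiliary data (base-pair tables, ground truth
#'   of synthetic structures, absent-residue reports).
#'
#' @exportClass StructureModel
setClass("StructureModel",
         representation(atoms = "data.frame", sourceId = "character",
                        speciesTag = "character", metadata = "list"),
         prototype(sourceId = "unknown", speciesTag = "synthetic",
                   metadata = list()))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character(0)
  missing <- setdiff(.requiredAtomCols, names(a))
  if (length(missing))
    msgs <- c(msgs, paste("atoms lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a) == 0L)
    msgs <- c(msgs, "structure contains no atoms")
  if (!length(msgs)) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msgs <- c(msgs, "non-finite coordinates")
    key <- paste(a$chain, a$resno, a$atom, a$altloc, a$model)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicated (chain, resno, atom, altloc, model) atom identity")
    if (!(object@speciesTag %in% c("bacterial", "eukaryotic", "synthetic")))
      msgs <- c(msgs, "speciesTag must be bacterial, eukaryotic or synthetic")
    o <- order(a$chain, a$resno)
    if (!identical(o, seq_len(nrow(a))) && is.unsorted(o))
      msgs <- c(msgs, "atoms must be ordered by (chain, resno)")
  }
  if (length(msgs)) msgs else TRUE
})

#' ResidueSelection: inclusive residue ranges with an optional atom filter
#'
#' @slot ranges data.frame(chain, start, end), normalized so that ranges on
#'   the same chain do not overlap.
#' @slot atomFilter character vector of atom names; length 0 means all atoms.
#'
#' @exportClass ResidueSelection
setClass("ResidueSelection",
         representation(ranges = "data.frame", atomFilter = "character"),
         prototype(atomFilter = character(0)))

setValidity("ResidueSelection", function(object) {
  r <- object@ranges
  if (!all(c("chain", "start", "end") %in% names(r)))
    return("ranges needs columns chain, start, end")
  if (nrow(r) == 0L) return("empty selection")
  if (any(r$start > r$end)) return("range with start > end")
  for (ch in unique(r$chain)) {
    rr <- r[r$chain == ch, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    if (nrow(rr) > 1L && any(rr$start[-1L] <= rr$end[-nrow(rr)]))
      return(paste("overlapping ranges on chain", ch))
  }
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' Maps mobile coordinates x onto a reference frame as R x + t.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric, Angstrom.
#'
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation determinant != +1")
  TRUE
})

#' SuperpositionResult: optimal rigid fit of paired coordinate sets
#'
#' @slot transform RigidTransform mapping mobile onto reference.
#' @slot rmsd root-mean-square deviation (Angstrom) after the fit.
#' @slot nAtoms number of paired atoms used.
#' @slot perResidueRmsd named numeric, per-residue RMSD when residue
#'   identities were available (names "chain:resno").
#'
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(transform = "RigidTransform", rmsd = "numeric",
                        nAtoms = "integer", perResidueRmsd = "numeric"),
         prototype(perResidueRmsd = numeric(0)))

#' ScrewAxis: Euler-Rodrigues decomposition of a rigid-body motion
#'
#' Any proper rigid motion is a rotation by a single angle about one axis
#' combined with a translation (pitch) along that axis.
#'
#' @slot direction unit 3-vector along the axis.
#' @slot origin a point on the axis (Angstrom).
#' @slot angle rotation angle in degrees, in [0, 180].
#' @slot pitch translation along the axis (Angstrom).
#' @slot status "ok"; "undefined-axis" when the angle is below the floor so
#'   the direction is not meaningful; "near-180" when the direction was
#'   recovered from the symmetric part of the rotation.
#'
#' @exportClass ScrewAxis
setClass("ScrewAxis",
         representation(direction = "numeric", origin = "numeric",
                        angle = "numeric", pitch = "numeric",
                        status = "character"),
         prototype(status = "ok"))

setValidity("ScrewAxis", function(object) {
  if (length(object@direction) != 3L || length(object@origin) != 3L)
    return("direction and origin must be length 3")
  if (object@angle < 0 || object@angle > 180 + 1e-9)
    return("angle must lie in [0, 180] degrees")
  if (object@status != "undefined-axis" &&
      abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    return("direction must be a unit vector")
  TRUE
})

#' HelicalAxisTrace: fitted axis points of a nucleic-acid helix
#'
#' One axis point per base pair, labeled by the residue number of the
#' 5'-strand member of the pair.
#'
#' @slot labels integer residue labels, strictly ordered.
#' @slot points N x 3 matrix of axis points (Angstrom).
#'
#' @exportClass HelicalAxisTrace
setClass("HelicalAxisTrace",
         representation(labels = "integer", points = "matrix"))

setValidity("HelicalAxisTrace", function(object) {
  if (nrow(object@points) != length(object@labels))
    return("labels and points disagree in length")
  if (ncol(object@points) != 3L) return("points must be N x 3")
  if (length(object@labels) && is.unsorted(object@labels, strictly = TRUE))
    return("labels must be strictly increasing")
  TRUE
})
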