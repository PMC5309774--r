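# Accessors and show methods for the core classes.

#' @rdname StructureModel-class
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel-class
#' @export
setMethod("coords", "StructureModel", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  rownames(m) <- paste(x@atoms$chain, x@atoms$resno, x@atoms$atom, sep = ":")
  m
})

#' @rdname StructureModel-class
#' @export
setMethod("sourceId", "StructureModel", function(x) x@sourceId)

#' @rdname StructureModel-class
#' @export
setMethod("speciesTag", "StructureModel", function(x) x@speciesTag)

#' @rdname StructureModel-class
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", sQuote(object@sourceId),
      sprintf("(%s)\n", object@speciesTag))
  cat(sprintf("  %d atoms, %d residues, chains: %s\n", nrow(a),
              length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = " ")))
})

#' @rdname RigidTransform-class
#' @param x,object a \code{RigidTransform}
#' @export
setMethod("rotationMatrix", "RigidTransform", function(x) x@rotation)

#' @rdname RigidTransform-class
#' @export
setMethod("translationVector", "RigidTransform", function(x) x@translation)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 4), collapse = " "), "\n")
})

#' @rdname SuperpositionResult-class
#' @param x,object a \code{SuperpositionResult}
#' @export
setMethod("fitRMSD", "SuperpositionResult", function(x) x@rmsd)

#' @rdname SuperpositionResult-class
#' @export
setMethod("fitTransform", "SuperpositionResult", function(x) x@transform)

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: %d atoms, RMSD %.4f A\n",
              object@nAtoms, object@rmsd))
})

#' @rdname ScrewAxis-class
#' @param x,object a \code{ScrewAxis}
#' @export
setMethod("screwAngle", "ScrewAxis", function(x) x@angle)

#' @rdname ScrewAxis-class
#' @export
setMethod("axisDirection", "ScrewAxis", function(x) x@direction)

#' @rdname ScrewAxis-class
#' @export
setMethod("axisOrigin", "ScrewAxis", function(x) x@origin)

#' @rdname ScrewAxis-class
#' @export
setMethod("screwPitch", "ScrewAxis", function(x) x@pitch)

#' @rdname ScrewAxis-class
#' @export
setMethod("axisStatus", "ScrewAxis", function(x) x@status)

setMethod("show", "ScrewAxis", function(object) {
  cat(sprintf("ScrewAxis: angle %.3f deg, pitch %.3f A [%s]\n",
              object@angle, object@pitch, object@status))
  if (object@status != "undefined-axis") {
    cat("  direction:", paste(round(object@direction, 4), collapse = " "), "\n")
    cat("  origin:   ", paste(round(object@origin, 3), collapse = " "), "\n")
  }
})

#' @rdname HelicalAxisTrace-class
#' @param x,object a \code{HelicalAxisTrace}
#' @export
setMethod("traceLabels", "HelicalAxisTrace", function(x) x@labels)

#' @rdname HelicalAxisTrace-class
#' @export
setMethod("tracePoints", "HelicalAxisTrace", function(x) x@points)

setMethod("show", "HelicalAxisTrace", function(object) {
  cat(sprintf("HelicalAxisTrace: %d axis points, labels %d..%d\n",
              length(object@labels),
              if (length(object@labels)) min(object@labels) else NA_integer_,
              if (length(object@labels)) max(object@labels) else NA_integer_))
})

#' @rdname ResidueSelection-class
#' @param x,object a \code{ResidueSelection}
#' @export
setMethod("selectionRanges", "ResidueSelection", function(x) x@ranges)

#' @rdname ResidueSelection-class
#' @export
setMethod("atomFilter", "ResidueSelection", function(x) x@atomFilter)

setMethod("show", "ResidueSelection", function(object) {
  r <- object@ranges
  cat(sprintf("ResidueSelection: %d range(s) on chain(s) %s\n", nrow(r),
              paste(unique(r$chain), collapse = " ")))
  if (length(object@atomFilter))
    cat("  atom filter:", paste(object@atomFilter, collapse = " "), "\n")
})
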