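#' @rdname StructureModel-class
#' @param x,object a \code{StructureModel}
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname StructureModel-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname StructureModel-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname StructureModel-class
#' @export
setGeneric("speciesTag", function(x) standardGeneric("speciesTag"))

#' @rdname StructureModel-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname RigidTransform-class
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' @rdname RigidTransform-class
#' @export
setGeneric("translationVector", function(x) standardGeneric("translationVector"))

#' Apply a rigid transform to coordinates
#'
#' @param x a coordinate matrix (N x 3) or a \code{StructureModel}
#' @param transform a \code{RigidTransform}
#' @return an object of the same kind as \code{x} with transformed
#'   coordinates
#' @export
setGeneric("applyTransform", function(x, transform) standardGeneric("applyTransform"))

#' @rdname SuperpositionResult-class
#' @export
setGeneric("fitRMSD", function(x) standardGeneric("fitRMSD"))

#' @rdname SuperpositionResult-class
#' @export
setGeneric("fitTransform", function(x) standardGeneric("fitTransform"))

#' @rdname ScrewAxis-class
#' @export
setGeneric("screwAngle", function(x) standardGeneric("screwAngle"))

#' @rdname ScrewAxis-class
#' @export
setGeneric("axisDirection", function(x) standardGeneric("axisDirection"))

#' @rdname ScrewAxis-class
#' @export
setGeneric("axisOrigin", function(x) standardGeneric("axisOrigin"))

#' @rdname ScrewAxis-class
#' @export
setGeneric("screwPitch", function(x) standardGeneric("screwPitch"))

#' @rdname ScrewAxis-class
#' @export
setGeneric("axisStatus", function(x) standardGeneric("axisStatus"))

#' @rdname HelicalAxisTrace-class
#' @export
setGeneric("traceLabels", function(x) standardGeneric("traceLabels"))

#' @rdname HelicalAxisTrace-class
#' @export
setGeneric("tracePoints", function(x) standardGeneric("tracePoints"))

#' @rdname ResidueSelection-class
#' @export
setGeneric("selectionRanges", function(x) standardGeneric("selectionRanges"))

#' @rdname ResidueSelection-class
#' @export
setGeneric("atomFilter", function(x) standardGeneric("atomFilter"))
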