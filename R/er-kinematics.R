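# Euler-Rodrigues decomposition of rigid-body motion into a single screw
# axis, and the derived per-structure metrics (domain rotation angle and
# marker displacement).

#' Decompose a rigid transform into a screw axis
#'
#' The rotation angle follows from the trace of the rotation matrix,
#' \eqn{\theta = \arccos((\mathrm{tr}(R) - 1)/2)}; the axis direction from
#' the skew-symmetric part \eqn{(R_{32}-R_{23}, R_{13}-R_{31},
#' R_{21}-R_{12})}; the pitch is the translation component along the axis;
#' and the axis origin is the minimum-norm solution of
#' \eqn{(I - R)\,p = T_\perp}, i.e. the point on the axis closest to the
#' coordinate origin.
#'
#' @param transform a \code{RigidTransform}
#' @param angleFloor below this angle (degrees) the axis direction is
#'   numerically meaningless and the result is flagged "undefined-axis"
#'   (the angle itself is still returned). Default 0.25 degrees.
#' @return a \code{ScrewAxis}
#' @export
erDecompose <- function(transform, angleFloor = 0.25) {
  R <- transform@rotation
  T <- transform@translation
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(ct)
  angle <- .rad2deg(theta)
  if (angle < angleFloor) {
    return(new("ScrewAxis", direction = c(0, 0, 1), origin = numeric(3),
               angle = angle, pitch = sqrt(sum(T^2)),
               status = "undefined-axis"))
  }
  status <- "ok"
  if (angle > 180 - 0.25) {
    # near a half-turn the skew part vanishes; take the axis from the
    # symmetric part: the eigenvector of R with eigenvalue +1
    M <- R + diag(3)
    d <- M[, which.max(colSums(M^2))]
    d <- .unit(d)
    status <- "near-180"
  } else {
    d <- .unit(c(R[3L, 2L] - R[2L, 3L],
                 R[1L, 3L] - R[3L, 1L],
                 R[2L, 1L] - R[1L, 2L]))
  }
  pitch <- sum(T * d)
  Tp <- T - pitch * d
  # closed form for the minimum-norm point on the axis
  p <- 0.5 * (Tp + .cross3(d, Tp) / tan(theta / 2))
  new("ScrewAxis", direction = d, origin = p, angle = angle,
      pitch = pitch, status = status)
}

#' Rebuild the rigid transform described by a screw axis
#'
#' Inverse of \code{\link{erDecompose}}: rotation by \code{angle} about the
#' axis through \code{origin} along \code{direction}, plus \code{pitch}
#' translation along the axis.
#'
#' @param axis a \code{ScrewAxis}
#' @return a \code{RigidTransform}
#' @export
screwTransform <- function(axis) {
  R <- .rotationAbout(axis@direction, axis@angle)
  tr <- as.vector((diag(3) - R) %*% axis@origin) + axis@pitch * axis@direction
  new("RigidTransform", rotation = R, translation = tr)
}

#' Shift a screw axis origin to the point on the axis closest to a target
#'
#' Any point on the axis is a valid origin; for reporting, the point
#' closest to the mobile domain's centroid is the physically interpretable
#' choice.
#'
#' @param axis a \code{ScrewAxis}
#' @param point target point (length-3)
#' @return the \code{ScrewAxis} with relocated origin
#' @export
relocateAxisOrigin <- function(axis, point) {
  d <- axis@direction
  o <- axis@origin
  initialize(axis, origin = o + sum((point - o) * d) * d)
}

#' Screw-axis decomposition of domain motion between two conformers
#'
#' The paired structures are first superposed on the static selection,
#' which puts the query into the reference frame; the residual motion of
#' the mobile selection is then fit by a second superposition, whose
#' Euler-Rodrigues decomposition is the domain's screw axis. Backbone atoms
#' only are used, since base atoms are often unmodeled at medium
#' resolution.
#'
#' @param structure,reference \code{StructureModel}s
#' @param staticSel,mobileSel \code{ResidueSelection}s resolvable in both
#'   structures
#' @param backbone atom names used for pairing
#' @param angleFloor passed to \code{\link{erDecompose}}
#' @return a \code{ScrewAxis} in the reference frame, origin reported at
#'   the point on the axis closest to the reference mobile-domain centroid
#' @export
domainRotation <- function(structure, reference, staticSel, mobileSel,
                           backbone = backboneAtoms, angleFloor = 0.25) {
  bsel <- function(sel) initialize(sel, atomFilter =
    if (length(atomFilter(sel))) atomFilter(sel) else backbone)
  qStatic <- selectAtoms(structure, bsel(staticSel))
  rStatic <- selectAtoms(reference, bsel(staticSel))
  coreFit <- superpose(qStatic, rStatic)
  aligned <- applyTransform(structure, coreFit@transform)
  qMobile <- selectAtoms(aligned, bsel(mobileSel))
  rMobile <- selectAtoms(reference, bsel(mobileSel))
  mobFit <- superpose(qMobile, rMobile)
  ax <- erDecompose(invertTransform(mobFit@transform), angleFloor = angleFloor)
  if (ax@status == "undefined-axis") return(ax)
  relocateAxisOrigin(ax, colMeans(coords(rMobile)))
}

#' Displacement of a marker atom between core-superposed conformers
#'
#' @param structure,reference \code{StructureModel}s
#' @param marker list(chain, resno, atom), e.g. the phosphate at the top of
#'   the L1 stalk head domain
#' @param coreSel optional \code{ResidueSelection}; when given, the query is
#'   first superposed onto the reference on this selection (backbone
#'   atoms). When NULL the structures are assumed already superposed.
#' @param backbone atom names used for the core fit
#' @return Euclidean distance in Angstrom
#' @export
displacementAt <- function(structure, reference, marker, coreSel = NULL,
                           backbone = backboneAtoms) {
  if (!is.null(coreSel)) {
    sel <- initialize(coreSel, atomFilter =
      if (length(atomFilter(coreSel))) atomFilter(coreSel) else backbone)
    fit <- superpose(selectAtoms(structure, sel),
                     selectAtoms(reference, sel))
    structure <- applyTransform(structure, fit@transform)
  }
  p1 <- .markerCoord(structure, marker)
  p2 <- .markerCoord(reference, marker)
  sqrt(sum((p1 - p2)^2))
}

.markerCoord <- function(structure, marker) {
  a <- atoms(structure)
  hit <- a$chain == marker$chain & a$resno == marker$resno &
    a$atom == marker$atom
  if (!any(hit))
    stop("marker atom ", marker$chain, ":", marker$resno, ":", marker$atom,
         " not present in ", sourceId(structure))
  as.numeric(a[which(hit)[1L], c("x", "y", "z")])
}

#' Rotation angle between two conformers of a tethered domain
#'
#' Convenience wrapper returning just the screw angle of
#' \code{\link{domainRotation}} in degrees.
#'
#' @inheritParams domainRotation
#' @return numeric angle in degrees
#' @export
stalkRotation <- function(structure, reference, staticSel, mobileSel,
                          backbone = backboneAtoms) {
  screwAngle(domainRotation(structure, reference, staticSel, mobileSel,
                            backbone = backbone))
}
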