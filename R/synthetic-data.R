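# Synthetic coordinate generators with known ground truth: ideal A-form
# duplexes, hinged helices, and two-domain systems carrying an imposed
# screw motion. Residue geometry is deliberately simplified (backbone +
# C1' + planar ring atoms on an ideal helical lattice); it provides every
# atom the pipeline operations require without claiming physical realism.

.aformDefaults <- list(rise = 2.81, twist = 32.7, radius = 9.4,
                       pairSpan = 10.4)

# backbone atom offsets from the residue's C1' position, in cylindrical
# coordinates (dr / A, dtheta / deg, dz / A); theta and z offsets are
# mirrored on the antiparallel strand
.backboneOffsets <- rbind(
  P     = c(0.2, -14, -2.0),
  OP1   = c(1.5, -16, -2.3),
  OP2   = c(-0.8, -18, -2.2),
  "O5'" = c(0.3, -10, -1.5),
  "C5'" = c(0.5, -7, -1.0),
  "C4'" = c(0.3, -4, -0.6),
  "O4'" = c(-0.6, -5, -0.9),
  "C3'" = c(0.6, -2, 0.4),
  "O3'" = c(0.6, 2, 0.9),
  "C2'" = c(0.9, 0, 0.1),
  "O2'" = c(1.8, 2, -0.3))

# planar ring templates in base-plane coordinates (x toward the pairing
# partner, y in-plane perpendicular), Angstrom from C1'
.ringTemplates <- list(
  purine = rbind(N9 = c(1.47, 0.00), C4 = c(2.31, 1.08), N3 = c(2.05, 2.42),
                 C2 = c(3.08, 3.26), N1 = c(4.38, 2.90), C6 = c(4.70, 1.58),
                 C5 = c(3.64, 0.66), N7 = c(3.62, -0.70), C8 = c(2.34, -1.06)),
  pyrimidine = rbind(N1 = c(1.48, 0.00), C2 = c(2.16, 1.20),
                     N3 = c(3.52, 1.20), C4 = c(4.20, 0.00),
                     C5 = c(3.52, -1.20), C6 = c(2.16, -1.20)))

.complementBase <- c(A = "U", U = "A", G = "C", C = "G")

.helixSequence <- function(nBp, sequence) {
  if (is.null(sequence)) {
    sequence <- paste(rep_len(c("G", "C", "U", "A"), nBp), collapse = "")
  }
  s <- strsplit(toupper(sequence), "")[[1L]]
  if (length(s) != nBp) stop("sequence length must equal nBp")
  if (!all(s %in% names(.complementBase)))
    stop("sequence may only contain A, C, G, U")
  s
}

# Build the atom table of one ideal duplex along +z, with a pairIndex
# column used internally for hinging and selection.
.buildHelixAtoms <- function(nBp, rise, twist, radius, pairSpan, sequence,
                             chains, startRes) {
  delta <- .rad2deg(2 * asin(pairSpan / (2 * radius)))
  rows <- vector("list", 2L * nBp)
  for (i in seq_len(nBp)) {
    for (strand in 1:2) {
      theta0 <- (i - 1L) * twist + if (strand == 2L) delta else 0
      sgn <- if (strand == 2L) -1 else 1
      resno <- if (strand == 1L) startRes[1L] + i - 1L
               else startRes[2L] + nBp - i
      base <- if (strand == 1L) sequence[i] else
        .complementBase[[sequence[i]]]
      atomNames <- character(0); xyz <- NULL
      # C1'
      th <- .deg2rad(theta0)
  c1 <- c(radius * cos(th), radius * sin(th), (i - 1L) * rise)
      atomNames <- "C1'"
      xyz <- rbind(c1)
      # backbone (5'-terminal residue carries no phosphate group)
      is5prime <- (strand == 1L && i == 1L) || (strand == 2L && i == nBp)
      bb <- .backboneOffsets
      if (is5prime) bb <- bb[!(rownames(bb) %in% c("P", "OP1", "OP2")), ,
                             drop = FALSE]
      for (k in seq_len(nrow(bb))) {
        o <- bb[k, ]
        tha <- .deg2rad(theta0 + sgn * o[2L])
        xyz <- rbind(xyz, c((radius + o[1L]) * cos(tha),
                            (radius + o[1L]) * sin(tha),
                            (i - 1L) * rise + sgn * o[3L]))
        atomNames <- c(atomNames, rownames(bb)[k])
      }
      # ring atoms in the horizontal base plane, pointing at the partner
      thPartner <- .deg2rad(theta0 + if (strand == 1L) delta else -delta)
      partner <- c(radius * cos(thPartner), radius * sin(thPartner),
                   (i - 1L) * rise)
      e1 <- .unit(partner - c1)
      e2 <- .cross3(c(0, 0, 1), e1)
      tmpl <- if (base %in% c("A", "G")) .ringTemplates$purine
              else .ringTemplates$pyrimidine
      for (k in seq_len(nrow(tmpl))) {
        xyz <- rbind(xyz, c1 + tmpl[k, 1L] * e1 + sgn * tmpl[k, 2L] * e2)
        atomNames <- c(atomNames, rownames(tmpl)[k])
      }
      rows[[(i - 1L) * 2L + strand]] <- data.frame(
        chain = chains[strand], resno = resno, resid = base,
        atom = atomNames, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
        pairIndex = i, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.pairTable <- function(nBp, chains, startRes) {
  basePairs(chain1 = chains[1L], res1 = startRes[1L] + seq_len(nBp) - 1L,
            chain2 = chains[2L], res2 = startRes[2L] + nBp - seq_len(nBp))
}

.addNoise <- function(atoms, sigma, seed = NULL) {
  if (sigma <= 0) return(atoms)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(atoms)
  atoms$x <- atoms$x + stats::rnorm(n, 0, sigma)
  atoms$y <- atoms$y + stats::rnorm(n, 0, sigma)
  atoms$z <- atoms$z + stats::rnorm(n, 0, sigma)
  atoms
}

#' Generate an ideal A-form duplex
#'
#' Both strands' C1' atoms lie on a cylinder about the z axis; the duplex
#' axis is the z axis through the origin, with one base pair every
#' \code{rise} Angstrom. The paired C1'-C1' distance is \code{pairSpan}.
#'
#' @param nBp number of base pairs (>= 4)
#' @param rise helical rise per base pair (A)
#' @param twist helical twist per base pair (degrees)
#' @param radius C1' orbit radius (A)
#' @param pairSpan intra-pair C1'-C1' distance (A)
#' @param sequence optional 5'->3' base string for strand 1 (A/C/G/U);
#'   default repeats GCUA
#' @param chains chain ids of the two strands
#' @param startRes first residue number of each strand
#' @param noiseSigma isotropic Gaussian noise per coordinate (A)
#' @param seed RNG seed for the noise (deterministic output for fixed seed)
#' @param sourceId identifier of the generated model
#' @return a \code{StructureModel}; \code{metadata} carries the base-pair
#'   table (\code{basePairs}), the generator parameters (\code{helixSpec})
#'   and the ideal axis (\code{axisPoint}, \code{axisDirection})
#' @export
makeAformHelix <- function(nBp, rise = 2.81, twist = 32.7, radius = 9.4,
                           pairSpan = 10.4, sequence = NULL,
                           chains = c("A", "B"), startRes = c(1L, 1L),
                           noiseSigma = 0, seed = NULL,
                           sourceId = "synthetic-helix") {
  if (nBp < 4L) stop("nBp must be >= 4")
  if (rise <= 0) stop("rise must be positive")
  if (twist <= 0 || twist >= 60) stop("twist must lie in (0, 60) degrees")
  if (pairSpan >= 2 * radius) stop("pairSpan must be < 2 * radius")
  seq1 <- .helixSequence(nBp, sequence)
  a <- .buildHelixAtoms(nBp, rise, twist, radius, pairSpan, seq1, chains,
                        startRes)
  a <- .addNoise(a, noiseSigma, seed)
  md <- list(basePairs = .pairTable(nBp, chains, startRes),
             helixSpec = list(nBp = nBp, rise = rise, twist = twist,
                              radius = radius, pairSpan = pairSpan,
                              sequence = paste(seq1, collapse = ""),
                              noiseSigma = noiseSigma, seed = seed),
             axisPoint = c(0, 0, 0), axisDirection = c(0, 0, 1))
  structureModel(a[, setdiff(names(a), "pairIndex")], sourceId = sourceId,
                 speciesTag = "synthetic", metadata = md)
}

#' Generate an A-form duplex with a hinge
#'
#' The distal segment (base pairs after \code{hingeStep}) is rotated by
#' \code{bendAngle} about an axis through the point on the helix axis
#' midway between pairs \code{hingeStep} and \code{hingeStep + 1},
#' perpendicular to the helix axis.
#'
#' @inheritParams makeAformHelix
#' @param hingeStep base-pair step carrying the hinge
#'   (2 <= hingeStep <= nBp - 2)
#' @param bendAngle bend in degrees
#' @param bendDirection unit vector (perpendicular to z) about which the
#'   distal segment is rotated
#' @return a \code{StructureModel}; \code{metadata$groundTruth} records the
#'   imposed (hingeStep, bendAngle)
#' @export
makeHingedHelix <- function(nBp, hingeStep, bendAngle,
                            bendDirection = c(1, 0, 0), rise = 2.81,
                            twist = 32.7, radius = 9.4, pairSpan = 10.4,
                            sequence = NULL, chains = c("A", "B"),
                            startRes = c(1L, 1L), noiseSigma = 0,
                            seed = NULL, sourceId = "synthetic-hinged") {
  if (hingeStep < 2L || hingeStep > nBp - 2L)
    stop("hingeStep must lie in [2, nBp - 2]")
  if (abs(sum(bendDirection * c(0, 0, 1))) > 1e-8)
    stop("bendDirection must be perpendicular to the helix (z) axis")
  seq1 <- .helixSequence(nBp, sequence)
  a <- .buildHelixAtoms(nBp, rise, twist, radius, pairSpan, seq1, chains,
                        startRes)
  if (bendAngle != 0) {
    pivot <- c(0, 0, (hingeStep - 0.5) * rise)
    R <- .rotationAbout(bendDirection, bendAngle)
    idx <- a$pairIndex > hingeStep
    xyz <- as.matrix(a[idx, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2L, pivot) %*% t(R), 2L, pivot, "+")
    a[idx, c("x", "y", "z")] <- xyz
  }
  a <- .addNoise(a, noiseSigma, seed)
  md <- list(basePairs = .pairTable(nBp, chains, startRes),
             helixSpec = list(nBp = nBp, rise = rise, twist = twist,
                              radius = radius, pairSpan = pairSpan,
                              sequence = paste(seq1, collapse = ""),
                              noiseSigma = noiseSigma, seed = seed),
             groundTruth = list(hingeStep = hingeStep,
                                bendAngle = bendAngle,
                                bendDirection = bendDirection))
  structureModel(a[, setdiff(names(a), "pairIndex")], sourceId = sourceId,
                 speciesTag = "synthetic", metadata = md)
}

#' Generate a two-domain system with an imposed screw motion
#'
#' Mimics the architecture of a stalk: a static helix along z and a mobile
#' helix tethered at its distal end, roughly perpendicular (as H76 stands
#' on H75). The moved conformer applies the screw motion
#' (\code{angle} about the axis through \code{axisOrigin} along
#' \code{axisDirection}, plus \code{pitch}) to the mobile domain only;
#' Gaussian noise is then applied to all atoms of each conformer
#' independently.
#'
#' @param angle imposed rotation (degrees)
#' @param axisDirection unit axis of the imposed screw (default: the
#'   static-helix axis, z)
#' @param axisOrigin point on the imposed axis; default: the junction point
#'   above the static helix
#' @param pitch translation along the axis (A)
#' @param staticNbp,mobileNbp helix lengths in base pairs
#' @param noiseSigma per-coordinate Gaussian noise (A), applied to both
#'   conformers with independent draws
#' @param seed RNG seed (the moved conformer uses seed + 1)
#' @param rise,twist,radius,pairSpan shared A-form parameters
#' @return list(reference, moved, groundTruth, staticSel, mobileSel):
#'   two \code{StructureModel}s (static strands on chains A/B, mobile on
#'   C/D), the imposed motion, and ready-made selections for
#'   \code{\link{domainRotation}}
#' @export
makeTwoDomainSystem <- function(angle, axisDirection = c(0, 0, 1),
                                axisOrigin = NULL, pitch = 0,
                                staticNbp = 8L, mobileNbp = 12L,
                                noiseSigma = 0, seed = NULL, rise = 2.81,
                                twist = 32.7, radius = 9.4,
                                pairSpan = 10.4) {
  zTop <- (staticNbp - 1L) * rise
  if (is.null(axisOrigin)) axisOrigin <- c(0, 0, zTop + 6)
  axisDirection <- .unit(axisDirection)
  staticAtoms <- .buildHelixAtoms(staticNbp, rise, twist, radius, pairSpan,
                                  .helixSequence(staticNbp, NULL),
                                  c("A", "B"), c(1L, 1L))
  mobileAtoms <- .buildHelixAtoms(mobileNbp, rise, twist, radius, pairSpan,
                                  .helixSequence(mobileNbp, NULL),
                                  c("C", "D"), c(1L, 1L))
  # pose the mobile helix: axis along +y, base near the static helix top
  Rpose <- .rotationAbout(c(1, 0, 0), -90)
  shift <- c(0, 14, zTop + 6)
  xyz <- as.matrix(mobileAtoms[, c("x", "y", "z")]) %*% t(Rpose)
  xyz <- sweep(xyz, 2L, shift, "+")
  mobileAtoms[, c("x", "y", "z")] <- xyz

  assemble <- function(mob, noiseSeed) {
    a <- rbind(staticAtoms, mob)
    a <- .addNoise(a, noiseSigma, noiseSeed)
    a[, setdiff(names(a), "pairIndex")]
  }
  movedMobile <- mobileAtoms
  if (angle != 0 || pitch != 0) {
    ax <- new("ScrewAxis", direction = axisDirection, origin = axisOrigin,
              angle = angle, pitch = pitch, status = "ok")
    tr <- screwTransform(ax)
    xyz <- applyTransform(as.matrix(movedMobile[, c("x", "y", "z")]), tr)
    movedMobile[, c("x", "y", "z")] <- xyz
  }
  gt <- list(angle = angle, axisDirection = axisDirection,
             axisOrigin = axisOrigin, pitch = pitch,
             noiseSigma = noiseSigma, seed = seed)
  mdRef <- list(groundTruth = gt, role = "reference")
  mdMov <- list(groundTruth = gt, role = "moved")
  reference <- structureModel(assemble(mobileAtoms, seed),
                              sourceId = "synthetic-two-domain-ref",
                              speciesTag = "synthetic", metadata = mdRef)
  moved <- structureModel(assemble(movedMobile,
                                   if (is.null(seed)) NULL else seed + 1L),
                          sourceId = "synthetic-two-domain-moved",
                          speciesTag = "synthetic", metadata = mdMov)
  list(reference = reference, moved = moved, groundTruth = gt,
       staticSel = residueSelection(c("A", "B"), c(1L, 1L),
                                    c(staticNbp, staticNbp)),
       mobileSel = residueSelection(c("C", "D"), c(1L, 1L),
                                    c(mobileNbp, mobileNbp)))
}

#' Write a synthetic fixture with its ground-truth sidecar
#'
#' Writes the structure as PDB and its metadata (generator parameters,
#' base pairs, ground truth) as a JSON sidecar next to it.
#'
#' @param structure a generated \code{StructureModel}
#' @param path output PDB path; the sidecar is written at
#'   \code{paste0(path, ".json")}
#' @return invisibly, c(pdb = path, json = sidecar)
#' @export
writeSyntheticFixture <- function(structure, path) {
  writeStructurePDB(structure, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(structure@metadata, sidecar, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(pdb = path, json = sidecar))
}
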