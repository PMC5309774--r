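# Least-squares rigid superposition (Kabsch) and data-driven refinement of
# the static core used as the common reference frame.

#' Pair the atoms shared by two structures
#'
#' Atoms are matched by (chain, resno, atom name) and returned in a
#' deterministic order, so both coordinate matrices are correspondence
#' paired row by row.
#'
#' @param a,b \code{StructureModel}s
#' @return list(a, b): two N x 3 matrices with identical row names
#'   "chain:resno:atom"
#' @export
pairAtoms <- function(a, b) {
  ca <- coords(a)
  cb <- coords(b)
  shared <- intersect(rownames(ca), rownames(cb))
  if (!length(shared)) stop("no shared atoms between structures")
  shared <- sort(shared)
  list(a = ca[shared, , drop = FALSE], b = cb[shared, , drop = FALSE])
}

.kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  H <- crossprod(sweep(mobile, 2L, cm), sweep(reference, 2L, cr))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  new("RigidTransform", rotation = R,
      translation = as.vector(cr - R %*% cm))
}

#' Optimal rigid superposition of paired coordinate sets
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' correspondence-paired coordinates (Kabsch algorithm via SVD). No outlier
#' rejection is performed here; residue-level rejection lives in
#' \code{\link{refineStaticCore}}.
#'
#' @param mobile,reference either N x 3 coordinate matrices (paired row by
#'   row) or \code{StructureModel}s (paired by atom identity via
#'   \code{\link{pairAtoms}}).
#' @return a \code{SuperpositionResult}; its transform maps mobile onto the
#'   reference frame.
#' @export
superpose <- function(mobile, reference) {
  rn <- NULL
  if (is(mobile, "StructureModel") && is(reference, "StructureModel")) {
    p <- pairAtoms(mobile, reference)
    mobile <- p$a
    reference <- p$b
    rn <- rownames(mobile)
  }
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must be paired sets of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate input: need at least 3 paired atoms")
  sv <- svd(sweep(mobile, 2L, colMeans(mobile)))$d
  if (sum(sv > 1e-8 * max(sv, 1)) < 2L)
    stop("degenerate input: collinear coordinate set")
  tr <- .kabsch(mobile, reference)
  fitted <- applyTransform(mobile, tr)
  dev2 <- rowSums((fitted - reference)^2)
  perRes <- numeric(0)
  if (!is.null(rn)) {
    res <- sub(":[^:]+$", "", rn)
    m <- tapply(dev2, res, mean)
    perRes <- stats::setNames(sqrt(as.numeric(m)), names(m))
    perRes <- perRes[unique(res)]
  }
  new("SuperpositionResult", transform = tr, rmsd = sqrt(mean(dev2)),
      nAtoms = as.integer(n), perResidueRmsd = perRes)
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("matrix", "RigidTransform"),
          function(x, transform) {
  out <- x %*% t(transform@rotation)
  out <- sweep(out, 2L, transform@translation, "+")
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("StructureModel", "RigidTransform"),
          function(x, transform) {
  a <- atoms(x)
  m <- applyTransform(as.matrix(a[, c("x", "y", "z")]), transform)
  a$x <- m[, 1L]; a$y <- m[, 2L]; a$z <- m[, 3L]
  initialize(x, atoms = a)
})

#' Compose two rigid transforms
#'
#' @param first,second \code{RigidTransform}s; the result applies
#'   \code{first}, then \code{second}.
#' @return a \code{RigidTransform}
#' @export
composeTransforms <- function(first, second) {
  new("RigidTransform",
      rotation = second@rotation %*% first@rotation,
      translation = as.vector(second@rotation %*% first@translation) +
        second@translation)
}

#' @rdname composeTransforms
#' @param transform a \code{RigidTransform}
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.vector(-Rt %*% transform@translation))
}

#' Identity transform
#' @export
identityTransform <- function() {
  new("RigidTransform", rotation = diag(3), translation = numeric(3))
}

#' Data-driven refinement of a static core
#'
#' Starting from an initial selection, iteratively superposes every
#' structure onto the first on the current core (backbone atoms), computes
#' each residue's RMSD across the ensemble (root mean square over backbone
#' atoms and over all structures, against the anchor structure), and drops
#' residues at or above the threshold, until the residue set is stable.
#' Residues below the threshold are the operational definition of "static".
#'
#' @param structures list of \code{StructureModel}s (>= 2); the first is the
#'   anchor.
#' @param initial a \code{ResidueSelection} present in all structures;
#'   residues absent from any structure are dropped with a warning.
#' @param threshold RMSD cut in Angstrom (default 0.8).
#' @param backbone atom names used for fitting and RMSD.
#' @param maxIter iteration cap.
#' @return the stable \code{ResidueSelection}
#' @export
refineStaticCore <- function(structures, initial, threshold = 0.8,
                             backbone = backboneAtoms, maxIter = 50L) {
  if (length(structures) < 2L) stop("need at least 2 structures")
  resTab <- selectionResidues(initial)
  keyOf <- function(s) {
    a <- atoms(s)
    a <- a[a$atom %in% backbone, , drop = FALSE]
    unique(paste(a$chain, a$resno))
  }
  present <- Reduce(intersect, lapply(structures, keyOf))
  keys <- paste(resTab$chain, resTab$resno)
  absent <- setdiff(keys, present)
  if (length(absent)) {
    warning(length(absent), " initial residue(s) absent from at least one ",
            "structure were dropped")
    resTab <- resTab[keys %in% present, , drop = FALSE]
  }
  current <- paste(resTab$chain, resTab$resno)
  coordsOf <- function(s) {
    a <- atoms(s)
    a <- a[a$atom %in% backbone, , drop = FALSE]
    m <- as.matrix(a[, c("x", "y", "z")])
    rownames(m) <- paste(a$chain, a$resno, a$atom, sep = ":")
    m
  }
  mats <- lapply(structures, coordsOf)
  shared <- sort(Reduce(intersect, lapply(mats, rownames)))
  mats <- lapply(mats, function(m) m[shared, , drop = FALSE])
  resOfRow <- sub(":[^:]*$", "", shared)
  resOfRow <- sub(":", " ", resOfRow)
  initialSet <- current
  for (iter in seq_len(maxIter)) {
    rows <- resOfRow %in% current
    if (length(unique(resOfRow[rows])) < 3L)
      stop("core refinement failed to converge: fewer than 3 residues remain")
    ref <- mats[[1L]]
    dev2 <- matrix(0, nrow = length(resOfRow), ncol = length(mats) - 1L)
    for (i in seq_along(mats)[-1L]) {
      tr <- superpose(mats[[i]][rows, , drop = FALSE],
                      ref[rows, , drop = FALSE])@transform
      fitted <- applyTransform(mats[[i]], tr)
      dev2[, i - 1L] <- rowSums((fitted - ref)^2)
    }
    # every initial residue is re-evaluated each cycle, so residues only
    # displaced by an early compromise fit can re-enter the core
    m <- tapply(rowMeans(dev2), resOfRow, mean)
    perRes <- stats::setNames(sqrt(as.numeric(m)), names(m))
    perRes <- perRes[initialSet]
    nxt <- initialSet[perRes < threshold]
    # a poor compromise fit can push most residues over the threshold at
    # once; in that case shrink gradually (keep the best-fitting three
    # quarters of the current core) so the fit can re-anchor
    if (length(nxt) < length(current) / 2 && length(current) > 4L) {
      keepN <- ceiling(0.75 * length(current))
      nxt <- union(nxt, initialSet[order(perRes)][seq_len(keepN)])
    }
    if (setequal(nxt, current)) break
    current <- nxt
    if (iter == maxIter)
      warning("core refinement hit the iteration cap before converging")
  }
  keep <- strsplit(current, " ", fixed = TRUE)
  tab <- data.frame(chain = vapply(keep, `[`, "", 1L),
                    resno = as.integer(vapply(keep, `[`, "", 2L)))
  tab <- tab[order(tab$chain, tab$resno), , drop = FALSE]
  .collapseRanges(tab, atomFilter = atomFilter(initial))
}

# residue table -> ResidueSelection with maximal runs collapsed to ranges
.collapseRanges <- function(tab, atomFilter = character(0)) {
  out <- NULL
  for (ch in unique(tab$chain)) {
    r <- sort(unique(tab$resno[tab$chain == ch]))
    brk <- c(0L, which(diff(r) > 1L), length(r))
    for (i in seq_len(length(brk) - 1L))
      out <- rbind(out, data.frame(chain = ch, start = r[brk[i] + 1L],
                                   end = r[brk[i + 1L]]))
  }
  new("ResidueSelection", ranges = out,
      atomFilter = if (is.null(atomFilter)) character(0) else atomFilter)
}
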