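# Helical-axis tracing, deviation profiles and hinge (inflection)
# localization, plus the scalar groove-width and closest-approach
# measurements.
#
# The axis is traced from local step screws: within each window of three
# consecutive base pairs, the rigid transform advancing the first two pairs
# onto the last two is a one-step screw whose axis is the local helical
# axis. Each pair's axis point is the projection of its C1'-C1' midpoint
# onto the axis of the best-fitting covering window, so windows that
# straddle a hinge (poor rigid fits) never contaminate the trace.

#' Base-pair table
#'
#' @param chain1,res1 chain and residue number of the 5'-strand member
#' @param chain2,res2 chain and residue number of the paired residue
#' @return data.frame(chain1, res1, chain2, res2), one row per base pair,
#'   in helix order
#' @export
basePairs <- function(chain1, res1, chain2, res2) {
  data.frame(chain1 = as.character(chain1), res1 = as.integer(res1),
             chain2 = as.character(chain2), res2 = as.integer(res2),
             stringsAsFactors = FALSE)
}

#' Shipped base-pair list for the L1-stalk helices (H75 + H76)
#'
#' The pairing runs proximal to distal along the stalk, labeled by the
#' 5'-strand residue (E. coli numbering); the unpaired 2091-2092 linker
#' carries no axis point.
#'
#' @param chain chain id holding the 23S rRNA
#' @return a base-pair table for \code{\link{traceHelicalAxis}}
#' @export
stalkBasePairs <- function(chain = "A") {
  path <- system.file("extdata", "stalk_base_pairs.yaml",
                      package = "stalkmech", mustWork = TRUE)
  pr <- yaml::read_yaml(path)$pairs
  basePairs(chain1 = chain,
            res1 = vapply(pr, function(p) p[[1L]], numeric(1)),
            chain2 = chain,
            res2 = vapply(pr, function(p) p[[2L]], numeric(1)))
}

.residueCoords <- function(a, chain, resno) {
  m <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  out <- as.matrix(m[, c("x", "y", "z")])
  rownames(out) <- m$atom
  out
}

#' Trace the helical axis of a paired duplex
#'
#' @param structure a \code{StructureModel}
#' @param pairing base-pair table from \code{\link{basePairs}} (>= 4 pairs),
#'   ordered along the helix
#' @param anchorAtom atom whose per-pair midpoint anchors the axis points
#'   (default C1')
#' @param maxSkipFraction pairs lacking the anchor atom are skipped; more
#'   than this fraction skipped is an error
#' @return a \code{HelicalAxisTrace} labeled by the 5'-strand residue
#'   numbers
#' @export
traceHelicalAxis <- function(structure, pairing, anchorAtom = "C1'",
                             maxSkipFraction = 0.2) {
  a <- atoms(structure)
  n0 <- nrow(pairing)
  if (n0 < 4L) stop("need at least 4 base pairs to trace a helical axis")
  mids <- matrix(NA_real_, n0, 3L)
  resAtoms <- vector("list", n0)
  for (i in seq_len(n0)) {
    c1 <- .residueCoords(a, pairing$chain1[i], pairing$res1[i])
    c2 <- .residueCoords(a, pairing$chain2[i], pairing$res2[i])
    if (anchorAtom %in% rownames(c1) && anchorAtom %in% rownames(c2))
      mids[i, ] <- (c1[anchorAtom, ] + c2[anchorAtom, ]) / 2
    resAtoms[[i]] <- list(s1 = c1, s2 = c2)
  }
  skipped <- which(is.na(mids[, 1L]))
  if (length(skipped)) {
    if (length(skipped) / n0 > maxSkipFraction)
      stop("missing ", anchorAtom, " anchors in ", length(skipped), "/", n0,
           " base pairs (pairs ",
           paste(pairing$res1[skipped], collapse = ", "), ")")
    keep <- setdiff(seq_len(n0), skipped)
    pairing <- pairing[keep, , drop = FALSE]
    mids <- mids[keep, , drop = FALSE]
    resAtoms <- resAtoms[keep]
  }
  n <- nrow(pairing)
  if (n < 4L) stop("fewer than 4 usable base pairs after skipping")

  # paired coordinates of two consecutive pairs, matched atom-by-atom to
  # the next step's corresponding residues; backbone + anchor atoms only,
  # since base atoms are not comparable between unlike residue types
  stepAtoms <- c(backboneAtoms, "O4'", "C2'", "O2'", anchorAtom)
  stepSets <- function(w) {
    mob <- NULL; ref <- NULL
    for (k in 0:1) {
      from <- resAtoms[[w + k]]
      to <- resAtoms[[w + k + 1L]]
      for (s in c("s1", "s2")) {
        shared <- intersect(intersect(rownames(from[[s]]), stepAtoms),
                            rownames(to[[s]]))
        mob <- rbind(mob, from[[s]][shared, , drop = FALSE])
        ref <- rbind(ref, to[[s]][shared, , drop = FALSE])
      }
    }
    list(mob = mob, ref = ref)
  }
  nw <- n - 2L
  axes <- vector("list", nw)
  fitRmsd <- numeric(nw)
  for (w in seq_len(nw)) {
    ss <- stepSets(w)
    fit <- superpose(ss$mob, ss$ref)
    fitRmsd[w] <- fit@rmsd
    ax <- erDecompose(fit@transform)
    if (ax@status == "undefined-axis") {
      # degenerate straight-translation step: fall back to the chord
      d <- .unit(mids[w + 2L, ] - mids[w, ])
      ax <- new("ScrewAxis", direction = d, origin = mids[w + 1L, ],
                angle = ax@angle, pitch = ax@pitch, status = "ok")
    }
    if (sum(ax@direction * (mids[w + 2L, ] - mids[w, ])) < 0)
      ax <- initialize(ax, direction = -ax@direction)
    axes[[w]] <- ax
  }
  pts <- matrix(NA_real_, n, 3L)
  for (j in seq_len(n)) {
    covering <- intersect((j - 2L):j, seq_len(nw))
    w <- covering[which.min(fitRmsd[covering])]
    ax <- axes[[w]]
    o <- ax@origin; d <- ax@direction
    pts[j, ] <- o + sum((mids[j, ] - o) * d) * d
  }
  # light smoothing of interior points stabilizes noisy traces and leaves
  # an ideal straight helix exactly on its cylinder axis
  if (n >= 3L) {
    sm <- pts
    for (j in 2:(n - 1L)) sm[j, ] <- colMeans(pts[(j - 1L):(j + 1L), ])
    pts <- sm
  }
  labs <- as.integer(pairing$res1)
  o <- order(labs)
  spacing <- sqrt(rowSums(diff(pts[o, , drop = FALSE])^2))
  if (any(spacing < 1.5 | spacing > 4.5))
    warning("consecutive axis points spaced outside 1.5-4.5 A; ",
            "the duplex may not be A-form-like over the full pairing")
  new("HelicalAxisTrace", labels = labs[o], points = pts[o, , drop = FALSE])
}

#' Deviation of one helical-axis trace from a reference
#'
#' Structures must already share a frame (superposed on the common static
#' core). The profile is the per-label Euclidean distance between axis
#' points, over the labels the traces share.
#'
#' @param trace,reference \code{HelicalAxisTrace}s
#' @return data.frame(label, deviation)
#' @export
deviationProfile <- function(trace, reference) {
  shared <- intersect(traceLabels(trace), traceLabels(reference))
  if (!length(shared))
    stop("incompatible traces: no shared residue labels")
  shared <- sort(shared)
  p1 <- tracePoints(trace)[match(shared, traceLabels(trace)), , drop = FALSE]
  p2 <- tracePoints(reference)[match(shared, traceLabels(reference)), ,
                               drop = FALSE]
  data.frame(label = shared, deviation = sqrt(rowSums((p1 - p2)^2)))
}

#' Pointwise mean of helical-axis traces
#'
#' @param traces list of \code{HelicalAxisTrace}s sharing labels
#' @return a \code{HelicalAxisTrace} over the shared labels; the per-point
#'   spread (maximum pairwise distance between member traces) is attached
#'   as attribute \code{"spread"}
#' @export
averageTrace <- function(traces) {
  if (!length(traces)) stop("no traces given")
  shared <- sort(Reduce(intersect, lapply(traces, traceLabels)))
  if (!length(shared)) stop("incompatible traces: no shared residue labels")
  mats <- lapply(traces, function(tr)
    tracePoints(tr)[match(shared, traceLabels(tr)), , drop = FALSE])
  mean <- Reduce(`+`, mats) / length(mats)
  spread <- numeric(length(shared))
  if (length(mats) > 1L) {
    for (i in seq_along(mats)[-length(mats)])
      for (j in (i + 1L):length(mats))
        spread <- pmax(spread, sqrt(rowSums((mats[[i]] - mats[[j]])^2)))
  }
  out <- new("HelicalAxisTrace", labels = shared, points = mean)
  attr(out, "spread") <- spread
  out
}

#' Locate inflection points of a deviation profile
#'
#' Candidate hinges are local maxima of the second difference of the
#' moving-average-smoothed profile (computed at a lag equal to the
#' smoothing window, rescaled near the ends), filtered by topographic
#' prominence. Candidate positions are then refined jointly by a segmented
#' piecewise-linear least-squares fit of the profile (flat first segment,
#' one slope change per inflection), which localizes each slope change to
#' the nearest position.
#'
#' @param profile data.frame(label, deviation) from
#'   \code{\link{deviationProfile}}
#' @param smoothingWindow moving-average window (odd, default 3)
#' @param minProminence minimum prominence (Angstrom) of the smoothed
#'   second difference for a candidate to be reported (default 0.4)
#' @return data.frame(label, prominence), ordered by label; zero rows when
#'   the profile has no prominent curvature change
#' @export
findInflections <- function(profile, smoothingWindow = 3L,
                            minProminence = 0.4) {
  y <- profile$deviation
  labs <- profile$label
  n <- length(y)
  w <- as.integer(smoothingWindow)
  if (n < 2L * w + 3L)
    stop("profile too short for smoothing window ", w,
         ": need at least ", 2L * w + 3L, " points")
  sm <- .movingAverage(y, w)
  js <- 2:(n - 1L)
  d2 <- vapply(js, function(j) {
    L <- min(w, j - 1L, n - j)
    (sm[j + L] - 2 * sm[j] + sm[j - L]) * w / L
  }, numeric(1))
  cand <- integer(0); prom <- numeric(0)
  for (k in seq_along(d2)) {
    if (d2[k] >= d2[max(1L, k - 1L)] &&
        d2[k] >= d2[min(length(d2), k + 1L)]) {
      lmin <- min(d2[max(1L, k - w):k])
      rmin <- min(d2[k:min(length(d2), k + w)])
      pp <- d2[k] - max(lmin, rmin)
      if (pp >= minProminence) {
        cand <- c(cand, js[k]); prom <- c(prom, pp)
      }
    }
  }
  if (!length(cand))
    return(data.frame(label = integer(0), prominence = numeric(0)))
  o <- order(cand)
  cps <- cand[o]; prom <- prom[o]
  x <- seq_len(n)
  rss <- function(cp) {
    X <- cbind(1, vapply(cp, function(c) pmax(0, x - c), numeric(n)))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  for (pass in 1:2) {
    for (i in seq_along(cps)) {
      lo <- if (i == 1L) 2L else cps[i - 1L] + 1L
      hi <- if (i == length(cps)) n - 1L else cps[i + 1L] - 1L
      if (lo > hi) next
      trial <- lo:hi
      cps[i] <- trial[which.min(vapply(trial, function(c) {
        z <- cps; z[i] <- c; rss(z)
      }, numeric(1)))]
    }
  }
  data.frame(label = labs[cps], prominence = prom)
}

#' Distance between two named atoms
#'
#' Used for the P-P groove-width measurements across a helix.
#'
#' @param structure a \code{StructureModel}
#' @param atomA,atomB list(chain, resno, atom)
#' @return Euclidean distance in Angstrom
#' @export
grooveWidth <- function(structure, atomA, atomB) {
  sqrt(sum((.markerCoord(structure, atomA) -
            .markerCoord(structure, atomB))^2))
}

#' Closest approach between two selections
#'
#' Minimum heavy-atom distance between two residue selections, with the
#' achieving pair. When the selections overlap, identical atoms are
#' excluded. Ties are broken by atom-identity order.
#'
#' @param structure a \code{StructureModel}
#' @param selA,selB \code{ResidueSelection}s
#' @return list(distance, atomA, atomB) where the atoms are
#'   "chain:resno:atom" identifiers
#' @export
closestApproach <- function(structure, selA, selB) {
  ha <- function(sel) {
    m <- coords(.heavyAtoms(selectAtoms(structure, sel)))
    m[order(rownames(m)), , drop = FALSE]
  }
  ma <- ha(selA)
  mb <- ha(selB)
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * tcrossprod(ma, mb)
  d2[d2 < 0] <- 0
  same <- outer(rownames(ma), rownames(mb), "==")
  d2[same] <- Inf
  best <- which(d2 == min(d2), arr.ind = TRUE)
  best <- best[order(rownames(ma)[best[, 1L]], rownames(mb)[best[, 2L]]), ,
               drop = FALSE][1L, ]
  list(distance = sqrt(d2[best[1L], best[2L]]),
       atomA = rownames(ma)[best[1L]],
       atomB = rownames(mb)[best[2L]])
}

.heavyAtoms <- function(structure) {
  a <- atoms(structure)
  keep <- !(toupper(a$element) %in% c("H", "D"))
  initialize(structure, atoms = a[keep, , drop = FALSE])
}
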