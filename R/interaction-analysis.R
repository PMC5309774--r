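# Contact networks (minor-groove packing, intersubunit-bridge catalogs)
# and base-stacking overlap geometry.

.purines <- c("A", "G", "DA", "DG", "ADE", "GUA")
.pyrimidines <- c("C", "U", "T", "DC", "DT", "CYT", "URA", "URI", "THY")

.purineRing <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
.pyrimidineRing <- c("N1", "C2", "N3", "C4", "C5", "C6")

# A-minor convention: the minor-groove face of a nucleotide
.minorGrooveAtoms <- function(resid) {
  if (resid %in% .purines) c("O2'", "N1", "C2", "N3")
  else if (resid %in% .pyrimidines) c("O2'", "O2")
  else character(0)
}

#' Inter-selection contact map
#'
#' All heavy-atom pairs between two selections within a distance cutoff.
#' A contact is classed "minor_groove" when a nucleotide-side atom belongs
#' to the minor-groove face (O2' plus N1/C2/N3 of purines, O2 of
#' pyrimidines), following the A-minor interaction convention.
#'
#' @param structure a \code{StructureModel}
#' @param selA,selB \code{ResidueSelection}s
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0)
#' @return data.frame(atomA, atomB, distance, class), sorted by distance;
#'   zero rows when nothing is within the cutoff
#' @export
contactMap <- function(structure, selA, selB, cutoff = 4.0) {
  sa <- .heavyAtoms(selectAtoms(structure, selA))
  sb <- .heavyAtoms(selectAtoms(structure, selB))
  ma <- coords(sa)
  mb <- coords(sb)
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * tcrossprod(ma, mb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2 &
                 !outer(rownames(ma), rownames(mb), "=="), arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(atomA = character(0), atomB = character(0),
                      distance = numeric(0), class = character(0)))
  aa <- atoms(sa)[hit[, 1L], ]
  ab <- atoms(sb)[hit[, 2L], ]
  isMinor <- function(tab) {
    vapply(seq_len(nrow(tab)), function(i)
      tab$atom[i] %in% .minorGrooveAtoms(tab$resid[i]), logical(1))
  }
  cls <- ifelse(isMinor(aa) | isMinor(ab), "minor_groove", "other")
  out <- data.frame(atomA = rownames(ma)[hit[, 1L]],
                    atomB = rownames(mb)[hit[, 2L]],
                    distance = sqrt(d2[hit]),
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$atomA, out$atomB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.catalogEnv <- new.env(parent = emptyenv())

#' Named contact catalogs
#'
#' Curated expected-interaction catalogs for the L1-stalk analysis:
#' \code{"b9"} (the transient bridge between the stalk head and the small
#' subunit seen only in hybrid-state ribosomes), \code{"b7a"} (H68 against
#' small-subunit helix h23), \code{"h68-h75"}, \code{"h68-trna"} and
#' \code{"h68-h76"} (the minor-groove network around the large-subunit E
#' site). Each entry lists the residue sets on both sides; chain ids are
#' bound at evaluation time through the \code{chains} argument of
#' \code{\link{bridgeReport}}.
#'
#' @param name catalog name, or NULL to list available catalogs
#' @return a list of catalog entries
#' @export
contactCatalog <- function(name = NULL) {
  if (is.null(.catalogEnv$cfg)) {
    path <- system.file("extdata", "contact_catalogs.yaml",
                        package = "stalkmech", mustWork = TRUE)
    .catalogEnv$cfg <- yaml::read_yaml(path)
  }
  cats <- .catalogEnv$cfg$catalogs
  if (is.null(name)) return(names(cats))
  out <- cats[[name]]
  if (is.null(out))
    stop("unknown catalog ", sQuote(name), "; available: ",
         paste(names(cats), collapse = ", "))
  out
}

.catalogSelection <- function(side, chains) {
  chainKey <- side$chain
  chain <- chains[[chainKey]]
  if (is.null(chain)) return(NULL)
  res <- unlist(side$residues)
  if (is.null(res)) return(list(chain = chain, whole = TRUE))
  list(chain = chain, resno = as.integer(res), whole = FALSE)
}

.sideSelection <- function(structure, side) {
  a <- atoms(structure)
  if (!(side$chain %in% a$chain)) return(NULL)
  if (isTRUE(side$whole)) {
    res <- sort(unique(a$resno[a$chain == side$chain]))
  } else {
    res <- intersect(side$resno, a$resno[a$chain == side$chain])
    if (!length(res)) return(NULL)
  }
  .collapseRanges(data.frame(chain = side$chain, resno = res))
}

#' Evaluate a contact catalog against a structure
#'
#' One row per catalogued interaction: whether any heavy-atom pair is
#' within the cutoff, and the minimum distance found. Entries whose
#' residues or chains are not modeled in the structure are reported as
#' "absent residue" rather than raising an error, since protein L1 and
#' tRNA are unmodeled in several entries.
#'
#' @param structure a \code{StructureModel}
#' @param catalog catalog name (see \code{\link{contactCatalog}}) or a
#'   catalog list of the same shape
#' @param chains named list binding the catalog's chain keys (e.g. "rrna23s",
#'   "s7", "trna") to chain ids of this structure; keys bound to NULL are
#'   treated as absent
#' @param cutoff contact cutoff in Angstrom
#' @return data.frame(contact, found, minDistance, nContacts, status)
#' @export
bridgeReport <- function(structure, catalog, chains, cutoff = 4.0) {
  if (is.character(catalog)) catalog <- contactCatalog(catalog)
  rows <- lapply(catalog, function(entry) {
    out <- data.frame(contact = entry$name, found = NA,
                      minDistance = NA_real_, nContacts = 0L,
                      status = "absent residue", stringsAsFactors = FALSE)
    sa <- .catalogSelection(entry$a, chains)
    sb <- .catalogSelection(entry$b, chains)
    if (is.null(sa) || is.null(sb)) return(out)
    ra <- .sideSelection(structure, sa)
    rb <- .sideSelection(structure, sb)
    if (is.null(ra) || is.null(rb)) return(out)
    cm <- contactMap(structure, ra, rb, cutoff = cutoff)
    out$found <- nrow(cm) > 0L
    out$nContacts <- nrow(cm)
    out$status <- if (out$found) "found" else "not found"
    if (nrow(cm)) {
      out$minDistance <- min(cm$distance)
    } else {
      ca <- closestApproach(structure, ra, rb)
      out$minDistance <- ca$distance
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.ringCoords <- function(structure, chain, resno) {
  a <- atoms(structure)
  m <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  if (!nrow(m)) stop("residue ", chain, ":", resno, " not found")
  ring <- if (m$resid[1L] %in% .purines) .purineRing else .pyrimidineRing
  hit <- m[m$atom %in% ring, , drop = FALSE]
  missing <- setdiff(ring, hit$atom)
  if (length(missing))
    stop("missing ring atoms in ", chain, ":", resno, ": ",
         paste(missing, collapse = ", "))
  out <- as.matrix(hit[, c("x", "y", "z")])
  rownames(out) <- hit$atom
  out
}

#' Stacking overlap between two base pairs
#'
#' Quantifies the stacking between base-pair planes as the area of
#' intersection of their ring-atom convex hulls, projected onto the mean
#' plane of the first pair. The interplanar distance is measured between
#' pair centroids along the first pair's plane normal, and the planarity
#' angle is the angle between the two pairs' mean-plane normals.
#'
#' @param structure a \code{StructureModel}
#' @param pairA,pairB base pairs as list(list(chain, resno),
#'   list(chain, resno))
#' @return list(overlapArea, interplanarDistance, planarityAngle,
#'   areaA, areaB) with areas in square Angstrom and the angle in degrees
#' @export
stackingOverlap <- function(structure, pairA, pairB) {
  ringsOf <- function(pair) {
    rbind(.ringCoords(structure, pair[[1L]]$chain, pair[[1L]]$resno),
          .ringCoords(structure, pair[[2L]]$chain, pair[[2L]]$resno))
  }
  ra <- ringsOf(pairA)
  rb <- ringsOf(pairB)
  plA <- .fitPlane(ra)
  plB <- .fitPlane(rb)
  proj <- function(p) {
    rel <- sweep(p, 2L, plA$centroid)
    cbind(rel %*% plA$e1, rel %*% plA$e2)
  }
  hullA <- .hull2d(proj(ra))
  hullB <- .hull2d(proj(rb))
  inter <- .clipConvex(hullA, hullB)
  cosang <- abs(sum(plA$normal * plB$normal))
  list(overlapArea = .polygonArea(inter),
       interplanarDistance = abs(sum((plB$centroid - plA$centroid) *
                                       plA$normal)),
       planarityAngle = .rad2deg(acos(min(1, cosang))),
       areaA = .polygonArea(hullA),
       areaB = .polygonArea(hullB))
}
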