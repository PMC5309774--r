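test_that("contacts honor the distance cutoff", {
  at <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resid = "G",
                   atom = "N1", x = c(0, 3.9), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  s <- structureModel(at, speciesTag = "synthetic")
  selA <- residueSelection("A", 1, 1)
  selB <- residueSelection("B", 1, 1)
  cm <- contactMap(s, selA, selB, cutoff = 4.0)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$distance, 3.9, tolerance = 1e-10)
  expect_equal(nrow(contactMap(s, selA, selB, cutoff = 3.5)), 0L)
})

test_that("contact maps are symmetric and class minor-groove atoms", {
  h <- makeAformHelix(12)
  selA <- residueSelection("A", 1, 12)
  selB <- residueSelection("B", 1, 12)
  ab <- contactMap(h, selA, selB, cutoff = 3.0)
  ba <- contactMap(h, selB, selA, cutoff = 3.0)
  expect_gt(nrow(ab), 0L)
  expect_setequal(paste(ab$atomA, ab$atomB), paste(ba$atomB, ba$atomA))

  # an O2' ribose contact is minor-groove by the A-minor convention
  o2 <- ab[grepl(":O2'$", ab$atomA) | grepl(":O2'$", ab$atomB), ]
  if (nrow(o2)) expect_true(all(o2$class == "minor_groove"))
})

test_that("bridge reports mark unresolvable entries absent and find real contacts", {
  h <- makeAformHelix(10)
  catalog <- list(
    list(name = "strand-strand", a = list(chain = "rrna23s",
                                          residues = list(5L)),
         b = list(chain = "partner", residues = list(6L))),
    list(name = "needs-trna", a = list(chain = "rrna23s",
                                       residues = list(1L)),
         b = list(chain = "trna")))
  rep <- bridgeReport(h, catalog,
                      chains = list(rrna23s = "A", partner = "B",
                                    trna = NULL),
                      cutoff = 12)
  expect_equal(rep$status, c("found", "absent residue"))
  expect_true(rep$found[1])
  expect_true(is.na(rep$found[2]))
  expect_lte(rep$minDistance[1], 12)

  # same catalog with an unreachable cutoff: reported, not found, with the
  # true minimum distance
  far <- bridgeReport(h, catalog[1],
                      chains = list(rrna23s = "A", partner = "B"),
                      cutoff = 0.5)
  expect_equal(far$status, "not found")
  expect_gt(far$minDistance, 0.5)
})

test_that("shipped catalogs resolve and cover the stalk interaction network", {
  expect_setequal(contactCatalog(),
                  c("b9", "b7a", "h68-h75", "h68-trna", "h68-h76"))
  b9 <- contactCatalog("b9")
  expect_equal(length(b9), 4L)
  expect_error(contactCatalog("nope"), "unknown catalog")
})

stackPair <- function() {
  # one G-C pair plus an exact copy 3.4 A along the pair-plane normal (z)
  h <- makeAformHelix(10)
  a <- atoms(h)
  pair <- a[(a$chain == "A" & a$resno == 1) |
              (a$chain == "B" & a$resno == 10), , drop = FALSE]
  copy <- pair
  copy$resno <- copy$resno + 50L
  copy$z <- copy$z + 3.4
  structureModel(rbind(pair, copy), speciesTag = "synthetic")
}

test_that("a pair stacked on its translated copy overlaps completely", {
  s <- stackPair()
  ov <- stackingOverlap(s,
                        pairA = list(list(chain = "A", resno = 1L),
                                     list(chain = "B", resno = 10L)),
                        pairB = list(list(chain = "A", resno = 51L),
                                     list(chain = "B", resno = 60L)))
  expect_equal(ov$overlapArea, ov$areaA, tolerance = 1e-6)
  expect_equal(ov$areaA, ov$areaB, tolerance = 1e-10)
  expect_equal(ov$planarityAngle, 0, tolerance = 1e-6)
  expect_equal(ov$interplanarDistance, 3.4, tolerance = 1e-6)
  expect_gt(ov$areaA, 10)  # two rings project to a substantial polygon
})

test_that("a 15 A lateral offset eliminates the overlap", {
  s <- stackPair()
  a <- atoms(s)
  idx <- a$resno > 50
  a$x[idx] <- a$x[idx] + 15
  s2 <- structureModel(a, speciesTag = "synthetic")
  ov <- stackingOverlap(s2,
                        pairA = list(list(chain = "A", resno = 1L),
                                     list(chain = "B", resno = 10L)),
                        pairB = list(list(chain = "A", resno = 51L),
                                     list(chain = "B", resno = 60L)))
  expect_equal(ov$overlapArea, 0)
})

test_that("stacking overlap is rigid-motion invariant and bounded by hull areas", {
  s <- stackPair()
  pa <- list(list(chain = "A", resno = 1L), list(chain = "B", resno = 10L))
  pb <- list(list(chain = "A", resno = 51L), list(chain = "B", resno = 60L))
  set.seed(51)
  for (r in 1:5) {
    a <- atoms(s)
    idx <- a$resno > 50
    a[idx, c("x", "y")] <- a[idx, c("x", "y")] +
      matrix(runif(2, -6, 6), nrow = sum(idx), ncol = 2, byrow = TRUE)
    s2 <- structureModel(a, speciesTag = "synthetic")
    ov <- stackingOverlap(s2, pa, pb)
    expect_lte(ov$overlapArea, min(ov$areaA, ov$areaB) + 1e-9)

    g <- randomRigidTransform()
    ovG <- stackingOverlap(applyTransform(s2, g), pa, pb)
    expect_equal(ovG$overlapArea, ov$overlapArea, tolerance = 1e-3)
    expect_equal(ovG$interplanarDistance, ov$interplanarDistance,
                 tolerance = 1e-6)
  }
})

test_that("missing ring atoms are reported by name", {
  s <- stackPair()
  a <- atoms(s)
  a <- a[!(a$chain == "A" & a$resno == 1 & a$atom == "N7"), ]
  s2 <- structureModel(a, speciesTag = "synthetic")
  expect_error(stackingOverlap(s2,
                               list(list(chain = "A", resno = 1L),
                                    list(chain = "B", resno = 10L)),
                               list(list(chain = "A", resno = 51L),
                                    list(chain = "B", resno = 60L))),
               "N7")
})
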