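straight20 <- makeAformHelix(20)
trace20 <- traceHelicalAxis(straight20, straight20@metadata$basePairs)

test_that("the traced axis of an ideal helix sits on the generating cylinder axis", {
  pts <- tracePoints(trace20)
  offAxis <- sqrt(pts[, 1]^2 + pts[, 2]^2)  # generator axis is z
  expect_lt(max(offAxis), 0.5)
  spacing <- sqrt(rowSums(diff(pts)^2))
  expect_true(all(abs(spacing - 2.81) < 0.3))
  expect_equal(traceLabels(trace20), 1:20)
})

test_that("tracing is equivariant under rigid motion of the structure", {
  set.seed(31)
  g <- randomRigidTransform()
  moved <- applyTransform(straight20, g)
  trMoved <- traceHelicalAxis(moved, straight20@metadata$basePairs)
  expect_lt(max(abs(tracePoints(trMoved) -
                      applyTransform(tracePoints(trace20), g))), 1e-6)
})

test_that("a 30-degree bend shows up as a 30-degree tangent change", {
  hb <- makeHingedHelix(20, hingeStep = 10, bendAngle = 30)
  tr <- traceHelicalAxis(hb, hb@metadata$basePairs)
  pts <- tracePoints(tr)
  tangent <- function(idx) {
    d <- pts[idx[length(idx)], ] - pts[idx[1], ]
    d / sqrt(sum(d^2))
  }
  ang <- acos(sum(tangent(2:8) * tangent(12:18))) * 180 / pi
  expect_equal(ang, 30, tolerance = 2)
})

test_that("pairs lacking anchors are skipped, too many is an error", {
  h <- makeAformHelix(10)
  a <- atoms(h)
  drop1 <- structureModel(a[!(a$chain == "A" & a$resno == 5 &
                                a$atom == "C1'"), ],
                          speciesTag = "synthetic")
  tr <- traceHelicalAxis(drop1, h@metadata$basePairs)
  expect_false(5L %in% traceLabels(tr))
  expect_equal(length(traceLabels(tr)), 9L)

  gone <- a[!(a$atom == "C1'" & a$resno <= 5 & a$chain == "A"), ]
  expect_error(traceHelicalAxis(structureModel(gone, speciesTag = "synthetic"),
                                h@metadata$basePairs),
               "missing C1' anchors")
  expect_error(traceHelicalAxis(h, h@metadata$basePairs[1:3, ]),
               "at least 4")
})

test_that("deviation profiles measure pointwise axis displacement", {
  prof0 <- deviationProfile(trace20, trace20)
  expect_true(all(prof0$deviation == 0))

  shifted <- new("HelicalAxisTrace", labels = traceLabels(trace20),
                 points = sweep(tracePoints(trace20), 2,
                                c(7, 0, 0) / sqrt(1), "+"))
  prof7 <- deviationProfile(trace20, shifted)
  expect_equal(prof7$deviation, rep(7, 20), tolerance = 1e-10)
  # symmetry
  expect_equal(deviationProfile(shifted, trace20)$deviation, prof7$deviation)

  other <- new("HelicalAxisTrace", labels = 100:110,
               points = matrix(0, 11, 3))
  expect_error(deviationProfile(trace20, other), "no shared residue labels")
})

test_that("averaging traces gives the pointwise midline with spread", {
  single <- averageTrace(list(trace20))
  expect_equal(tracePoints(single), tracePoints(trace20))

  up <- new("HelicalAxisTrace", labels = traceLabels(trace20),
            points = sweep(tracePoints(trace20), 2, c(0, 3, 0), "+"))
  dn <- new("HelicalAxisTrace", labels = traceLabels(trace20),
            points = sweep(tracePoints(trace20), 2, c(0, -3, 0), "+"))
  mid <- averageTrace(list(up, dn))
  expect_lt(max(abs(tracePoints(mid) - tracePoints(trace20))), 1e-10)
  expect_equal(attr(mid, "spread"), rep(6, 20), tolerance = 1e-10)
})

test_that("a linear profile has no inflection", {
  prof <- data.frame(label = 1:20, deviation = seq(0, 10, length.out = 20))
  expect_equal(nrow(findInflections(prof)), 0L)
  expect_error(findInflections(data.frame(label = 1:6, deviation = 1:6)),
               "too short")
})

test_that("an imposed hinge is localized at the hinge step", {
  for (hg in c(6L, 13L)) {
    hb <- makeHingedHelix(20, hingeStep = hg, bendAngle = 25)
    prof <- deviationProfile(traceHelicalAxis(hb, hb@metadata$basePairs),
                             trace20)
    f <- findInflections(prof)
    expect_gt(nrow(f), 0L)
    best <- f$label[which.max(f$prominence)]
    expect_lte(abs(best - hg), 1L)
  }
})

test_that("hinges are recovered from noisy structures", {
  set.seed(33)
  hits <- 0L; total <- 0L
  for (bend in c(20, 40)) for (hg in c(5L, 12L)) for (r in 1:10) {
    hb <- makeHingedHelix(20, hingeStep = hg, bendAngle = bend,
                          noiseSigma = 0.2, seed = sample.int(2^30, 1))
    prof <- deviationProfile(traceHelicalAxis(hb, hb@metadata$basePairs),
                             trace20)
    f <- findInflections(prof)
    best <- if (nrow(f)) f$label[which.max(f$prominence)] else NA
    total <- total + 1L
    hits <- hits + as.integer(!is.na(best) && abs(best - hg) <= 1L)
  }
  expect_gte(hits / total, 0.9)
})

test_that("groove width is a plain interatomic distance", {
  h <- makeAformHelix(12)
  a <- atoms(h)
  p1 <- list(chain = "A", resno = 3L, atom = "P")
  p2 <- list(chain = "B", resno = 3L, atom = "P")
  d <- grooveWidth(h, p1, p2)
  x1 <- as.numeric(a[a$chain == "A" & a$resno == 3 & a$atom == "P",
                     c("x", "y", "z")])
  x2 <- as.numeric(a[a$chain == "B" & a$resno == 3 & a$atom == "P",
                     c("x", "y", "z")])
  expect_equal(d, sqrt(sum((x1 - x2)^2)))
  expect_error(grooveWidth(h, p1, list(chain = "A", resno = 99, atom = "P")),
               "marker atom")
})

test_that("closest approach finds the minimum heavy-atom pair deterministically", {
  at <- data.frame(chain = c("A", "A", "B", "B"),
                   resno = c(1L, 2L, 1L, 2L), resid = "G",
                   atom = c("N1", "N1", "N1", "N1"),
                   x = c(0, 10, 2, 20), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  s <- structureModel(at, speciesTag = "synthetic")
  ca <- closestApproach(s, residueSelection("A", 1, 2),
                        residueSelection("B", 1, 2))
  expect_equal(ca$distance, 2)
  expect_equal(ca$atomA, "A:1:N1")
  expect_equal(ca$atomB, "B:1:N1")

  # identical selections: self-pairs excluded, smallest intra distance
  ca2 <- closestApproach(s, residueSelection("A", 1, 2),
                         residueSelection("A", 1, 2))
  expect_equal(ca2$distance, 10)
})
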