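test_that("closed-form screw cases decompose exactly", {
  # identity -> zero angle, axis flagged undefined
  id <- erDecompose(identityTransform())
  expect_equal(screwAngle(id), 0)
  expect_equal(axisStatus(id), "undefined-axis")

  # 90 degrees about z through the origin, no translation
  tr <- new("RigidTransform",
            rotation = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
            translation = numeric(3))
  ax <- erDecompose(tr)
  expect_equal(screwAngle(ax), 90, tolerance = 1e-10)
  expect_equal(axisDirection(ax), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(screwPitch(ax), 0, tolerance = 1e-12)
  expect_lt(pointToLineDistance(axisOrigin(ax), c(0, 0, 0), c(0, 0, 1)),
            1e-10)
})

test_that("1000 random screws agree with the quaternion oracle to 1e-6", {
  set.seed(21)
  worst <- c(angle = 0, dir = 0, pitch = 0, axis = 0, rebuild = 0)
  for (i in 1:1000) {
    s <- randomScrew()
    tr <- new("RigidTransform", rotation = s$R, translation = s$t)
    ax <- erDecompose(tr)
    oracle <- quatDecompose(s$R)
    d <- axisDirection(ax)
    if (sum(d * oracle$axis) < 0) d <- -d
    worst["angle"] <- max(worst["angle"], abs(screwAngle(ax) - oracle$angle),
                          abs(screwAngle(ax) - s$angle))
    worst["dir"] <- max(worst["dir"], sqrt(sum((d - oracle$axis)^2)))
    worst["pitch"] <- max(worst["pitch"], abs(abs(screwPitch(ax)) -
                                                abs(s$pitch)))
    worst["axis"] <- max(worst["axis"],
                         pointToLineDistance(axisOrigin(ax), s$point, s$axis))
    rb <- screwTransform(ax)
    worst["rebuild"] <- max(worst["rebuild"],
                            max(abs(rotationMatrix(rb) - s$R)),
                            max(abs(translationVector(rb) - s$t)))
  }
  expect_lt(worst["angle"], 1e-6)
  expect_lt(worst["dir"], 1e-6)
  expect_lt(worst["pitch"], 1e-6)
  expect_lt(worst["axis"], 1e-6)
  expect_lt(worst["rebuild"], 1e-6)
})

test_that("near-180-degree rotations fall back to the symmetric route", {
  set.seed(22)
  u <- randomUnitVector()
  half <- 179.9 * pi / 360
  R <- quatToMatrix(c(cos(half), sin(half) * u))
  ax <- erDecompose(new("RigidTransform", rotation = R,
                        translation = numeric(3)))
  expect_equal(axisStatus(ax), "near-180")
  expect_equal(screwAngle(ax), 179.9, tolerance = 1e-6)
  expect_gt(abs(sum(axisDirection(ax) * u)), 1 - 1e-6)
})

test_that("domain rotation recovers imposed motion and its axis", {
  # no motion -> zero angle
  sys0 <- makeTwoDomainSystem(angle = 0)
  ax0 <- domainRotation(sys0$moved, sys0$reference, sys0$staticSel,
                        sys0$mobileSel)
  # acos() near +1 limits attainable precision to ~sqrt(machine eps)
  expect_lt(screwAngle(ax0), 1e-4)
  expect_equal(axisStatus(ax0), "undefined-axis")

  # 26.5 degrees, noiseless -> exact recovery including direction and axis
  sys <- makeTwoDomainSystem(angle = 26.5)
  ax <- domainRotation(sys$moved, sys$reference, sys$staticSel,
                       sys$mobileSel)
  expect_equal(screwAngle(ax), 26.5, tolerance = 1e-6)
  expect_gt(sum(axisDirection(ax) * sys$groundTruth$axisDirection),
            1 - 1e-6)
  expect_lt(pointToLineDistance(axisOrigin(ax), sys$groundTruth$axisOrigin,
                                sys$groundTruth$axisDirection), 1e-5)

  # 26.5 degrees at sigma = 0.2 A -> within half a degree
  sysN <- makeTwoDomainSystem(angle = 26.5, noiseSigma = 0.2, seed = 400L)
  axN <- domainRotation(sysN$moved, sysN$reference, sysN$staticSel,
                        sysN$mobileSel)
  expect_equal(screwAngle(axN), 26.5, tolerance = 0.5)
})

test_that("domain rotation is frame independent and direction symmetric", {
  sys <- makeTwoDomainSystem(angle = 17, noiseSigma = 0.1, seed = 41L)
  ax <- domainRotation(sys$moved, sys$reference, sys$staticSel, sys$mobileSel)

  set.seed(42)
  g <- randomRigidTransform()
  movedG <- applyTransform(sys$moved, g)
  axG <- domainRotation(movedG, sys$reference, sys$staticSel, sys$mobileSel)
  expect_equal(screwAngle(axG), screwAngle(ax), tolerance = 1e-6)

  axBack <- domainRotation(sys$reference, sys$moved, sys$staticSel,
                           sys$mobileSel)
  expect_equal(screwAngle(axBack), screwAngle(ax), tolerance = 1e-6)
})

test_that("imposed angles 5..30 degrees are recovered in order within 0.5", {
  angles <- c(5, 10, 15, 20, 25, 30)
  rec <- vapply(seq_along(angles), function(i) {
    sys <- makeTwoDomainSystem(angle = angles[i], noiseSigma = 0.2,
                               seed = 500L + i)
    screwAngle(domainRotation(sys$moved, sys$reference, sys$staticSel,
                              sys$mobileSel))
  }, numeric(1))
  expect_true(all(abs(rec - angles) < 0.5))
  expect_false(is.unsorted(rec))
})

test_that("marker displacement measures core-superposed distances", {
  sys <- makeTwoDomainSystem(angle = 26.5)
  marker <- list(chain = "C", resno = 12L, atom = "C1'")
  expect_equal(displacementAt(sys$reference, sys$reference, marker), 0)

  # marker translated by (3, 4, 0) -> 5 A (3-4-5 triangle)
  a <- atoms(sys$reference)
  idx <- a$chain == "C" & a$resno == 12L & a$atom == "C1'"
  a[idx, c("x", "y")] <- a[idx, c("x", "y")] + c(3, 4)
  shifted <- structureModel(a, sourceId = "shifted",
                            speciesTag = "synthetic")
  expect_equal(displacementAt(shifted, sys$reference, marker,
                              coreSel = sys$staticSel), 5,
               tolerance = 1e-6)

  expect_error(displacementAt(sys$reference, sys$reference,
                              list(chain = "C", resno = 999L, atom = "P")),
               "marker atom")
})
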