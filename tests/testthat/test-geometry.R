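test_that("reference mesh has the expected node and element counts", {
  m <- buildReferenceMesh(lvGeometry())
  expect_equal(nrow(endoNodes(m)), 510L)
  expect_equal(nrow(epiNodes(m)), 510L)
  expect_equal(nrow(hexahedra(m)), 480L)
  # every node used by at least one element
  expect_true(all(tabulate(hexahedra(m), 1020L) > 0))
})

test_that("epicardium is offset outward by the thickness field", {
  m <- buildReferenceMesh(lvGeometry(endoRadiusEq = 25, baseThickness = 10))
  rhoEndo <- sqrt(rowSums(endoNodes(m)[1:30, 1:2]^2))
  rhoEpi <- sqrt(rowSums(epiNodes(m)[1:30, 1:2]^2))
  expect_equal(rhoEndo, rep(25, 30), tolerance = 0.01)
  expect_equal(rhoEpi, rep(35, 30), tolerance = 0.01)
  expect_error(buildReferenceMesh(lvGeometry(), matrix(-1, 30, 17)),
               "non-positive wall thickness")
})

test_that("element Jacobians are positive at centroids for varied configs", {
  for (cfg in list(lvGeometry(), quickGeometry(),
                   lvGeometry(nCirc = 20, nLong = 11, endoRadiusEq = 20,
                              baseThickness = 6, longAxisLength = 60))) {
    m <- buildReferenceMesh(cfg)
    expect_gt(min(lvmda:::elementJacobians(m)), 0)
  }
})

test_that("local frames are orthonormal, right-handed and anatomically oriented", {
  m <- buildReferenceMesh(lvGeometry())
  fr <- computeLocalFrames(m)
  expect_lt(max(abs(rowSums(fr@eC * fr@eL))), 1e-10)
  expect_lt(max(abs(rowSums(fr@eC * fr@eR))), 1e-10)
  expect_lt(max(abs(rowSums(fr@eL * fr@eR))), 1e-10)
  expect_equal(sqrt(rowSums(fr@eC^2)), rep(1, 480), tolerance = 1e-10)
  handed <- rowSums(lvmda:::vcross(fr@eC, fr@eL) * fr@eR)
  expect_true(all(handed > 0))
  # longitudinal vector points toward the base (+z)
  expect_true(all(fr@eL[, 3] > 0))
  # sphere-like shell: the radial vector of a basal element near the x axis
  # matches the analytic outward normal at its centroid
  ms <- buildReferenceMesh(lvGeometry(endoRadiusEq = 25, baseThickness = 8,
                                      longAxisLength = 24.7))
  frs <- computeLocalFrames(ms)
  eq <- which(lvmda:::elementRow(ms) == 1 &
              lvmda:::elementCircIndex(ms) == 1)
  hx <- hexahedra(ms)[eq, ]
  ctr <- colMeans(rbind(endoNodes(ms), epiNodes(ms))[hx, ])
  nrm <- ctr / sqrt(sum(ctr^2))   # sphere: outward normal is radial
  expect_lt(sqrt(sum((frs@eR[eq, ] - nrm)^2)), 0.05)
  expect_gt(frs@eR[eq, 1], 0.9)   # and it points essentially along +x
})

test_that("frames are equivariant under rigid rotations", {
  m <- buildReferenceMesh(quickGeometry())
  fr <- computeLocalFrames(m)
  set.seed(7)
  for (rep in 1:3) {
    R <- randomRotation()
    m2 <- m
    m2@endoNodes <- endoNodes(m) %*% t(R)
    m2@epiNodes <- epiNodes(m) %*% t(R)
    fr2 <- computeLocalFrames(m2)
    expect_lt(max(abs(fr2@eC - fr@eC %*% t(R))), 1e-8)
    expect_lt(max(abs(fr2@eL - fr@eL %*% t(R))), 1e-8)
    expect_lt(max(abs(fr2@eR - fr@eR %*% t(R))), 1e-8)
  }
})

test_that("AHA segments partition the elements with the standard layout", {
  m <- buildReferenceMesh(lvGeometry())
  map <- assignAhaSegments(m, 16L)
  counts <- table(map@segment)
  expect_equal(sum(counts), 480)
  expect_equal(length(counts), 16L)
  # basal sextants hold equal element counts on the uniform grid
  expect_true(all(counts[1:6] == counts[1]))
  # first sextant past the anterior origin in the basal ring is segment 1
  e1 <- which(lvmda:::elementRow(m) == 1 & lvmda:::elementCircIndex(m) == 1)
  expect_equal(map@segment[e1], 1L)
  # element order does not matter for segment membership lists
  expect_setequal(unlist(map@elements), seq_len(480))
  map17 <- assignAhaSegments(m, 17L)
  expect_gt(length(map17@elements[[17]]), 0)
})

test_that("wall thickness is the radial gap and scales with radial stretch", {
  m <- buildReferenceMesh(lvGeometry(endoRadiusEq = 25, baseThickness = 10))
  th <- wallThickness(m)
  eq <- which(lvmda:::elementRow(m) == 1)
  expect_equal(mean(th[eq]), 10, tolerance = 0.02 * 10)
  # uniform radial stretch of 1.2: epi moved 20% further out along the gap
  disp <- matrix(0, 1020, 3)
  disp[511:1020, ] <- 0.2 * (epiNodes(m) - endoNodes(m))
  th2 <- wallThickness(m, displacementsAtPhase = disp)
  expect_equal(mean(th2[eq]), 12, tolerance = 0.02 * 12)
  expect_error(
    wallThickness(m, displacementsAtPhase = -3 * rbind(matrix(0, 510, 3),
                  epiNodes(m) - endoNodes(m))),
    "inverted")
})

test_that("HCM basal-septal bump puts peak segmental thickness in segment 2 or 3", {
  ph <- classPhenotype("HCM", ampCirc = -0.178, ampLong = -0.152,
                       tPeak = 0.414, thickness = 11.3, segmentJitterSd = 0,
                       thicknessPattern = list(type = "basal_septal_bump",
                                               amplitude = 5, sigmaPhi = 0.7,
                                               sigmaS = 0.18,
                                               centerPhi = 2 * pi / 3,
                                               centerS = 0.15))
  set.seed(3)
  s <- simulateSubject(ph, id = "BUMP")
  mesh <- referenceMesh(subjectDynamics(s))
  map <- assignAhaSegments(mesh, 16L)
  th <- wallThickness(mesh)
  segMean <- vapply(map@elements, function(e) mean(th[e]), numeric(1))
  expect_true(which.max(segMean) %in% c(2L, 3L))
})
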