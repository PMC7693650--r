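refHex <- function(h = 1) {
  corners <- as.matrix(expand.grid(x = c(0, h), y = c(0, h), z = c(0, h)))
  # trilinear node order: bottom quad counterclockwise, then top quad
  corners[c(1, 2, 4, 3, 5, 6, 8, 7), ]
}

test_that("deformation gradient reproduces translations and affine maps", {
  ref <- refHex()
  expect_equal(deformationGradient(ref, ref + rep(c(3, -2, 7), each = 8)),
               diag(3), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    A <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(A) <= 0) next
    expect_equal(deformationGradient(ref, ref %*% t(A)), A,
                 tolerance = 1e-10)
  }
  flat <- ref; flat[, 3] <- 0
  expect_error(deformationGradient(flat, ref), "singular")
})

test_that("deformation gradient matches a finite-difference oracle on a smooth warp", {
  warp <- function(p) cbind(p[, 1] + 0.05 * sin(p[, 2]),
                            p[, 2] + 0.04 * cos(p[, 3]),
                            p[, 3] + 0.03 * sin(p[, 1] + p[, 2]))
  h <- 0.02
  ref <- refHex(h)
  F <- deformationGradient(ref, warp(ref))
  ctr <- colMeans(ref)
  Ffd <- matrix(0, 3, 3)
  eps <- 1e-5
  for (j in 1:3) {
    dp <- dm <- ctr; dp[j] <- dp[j] + eps; dm[j] <- dm[j] - eps
    Ffd[, j] <- (warp(rbind(dp)) - warp(rbind(dm))) / (2 * eps)
  }
  expect_equal(F, Ffd, tolerance = 1e-4)
})

refQuad <- function() rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))

test_that("surface deformation gradient handles scale, rotation and affine maps", {
  q <- refQuad()
  expect_equal(surfaceDeformationGradient(q, 0.9 * q), 0.9 * diag(2),
               tolerance = 1e-10)
  set.seed(9)
  R <- randomRotation()
  Frot <- surfaceDeformationGradient(q, q %*% t(R))
  expect_equal(crossprod(Frot), diag(2), tolerance = 1e-10)
  for (rep in 1:5) {
    M <- diag(2) + matrix(rnorm(4, sd = 0.2), 2, 2)
    if (det(M) <= 0) next
    qd <- cbind(q[, 1:2] %*% t(M), 0)
    expect_equal(surfaceDeformationGradient(q, qd), M, tolerance = 1e-8)
  }
  degen <- q; degen[2, ] <- q[1, ]; degen[3, ] <- q[4, ]
  expect_error(surfaceDeformationGradient(degen, q), "degenerate")
})

test_that("Green-Lagrange tensor has its closed-form values and objectivity", {
  expect_equal(greenLagrange(diag(3)), matrix(0, 3, 3))
  E <- greenLagrange(diag(c(0.8, 1, 1)))
  expect_equal(E[1, 1], -0.18)
  expect_equal(E[2, 2], 0); expect_equal(E[3, 3], 0)
  set.seed(3)
  expect_equal(greenLagrange(randomRotation()), matrix(0, 3, 3),
               tolerance = 1e-12)
})

test_that("directional strain equals the fiber-length change of a matching F", {
  expect_equal(directionalStrain(matrix(0, 3, 3), c(0, 1, 0)), 0)
  E <- greenLagrange(diag(c(0.8, 1, 1)))
  expect_equal(directionalStrain(E, c(1, 0, 0)), -20)
  expect_error(directionalStrain(E, c(2, 0, 0)), "unit")
  set.seed(11)
  for (rep in 1:20) {
    S <- matrix(rnorm(9, sd = 0.1), 3, 3); S <- (S + t(S)) / 2
    C <- diag(3) + 2 * S
    if (min(eigen(C, symmetric = TRUE)$values) <= 0) next
    # polar-decomposition oracle: F = sqrt(C) stretches fibers directly
    eg <- eigen(C, symmetric = TRUE)
    Fp <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    expect_equal(directionalStrain(S, d), 100 * (sqrt(sum((Fp %*% d)^2)) - 1),
                 tolerance = 1e-10)
  }
})

test_that("principal strains bound every directional strain", {
  ps <- principalStrains(greenLagrange(diag(c(0.8, 0.9, 1.4))))
  expect_equal(ps$min, -20)
  expect_equal(ps$max, 40)
  set.seed(13)
  ps0 <- principalStrains(greenLagrange(randomRotation()))
  expect_equal(ps0$min, 0, tolerance = 1e-10)
  expect_equal(ps0$max, 0, tolerance = 1e-10)
  expect_error(principalStrains(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
  for (rep in 1:5) {
    S <- matrix(rnorm(9, sd = 0.08), 3, 3); S <- (S + t(S)) / 2
    if (min(1 + 2 * eigen(S, symmetric = TRUE)$values) <= 0) next
    ps <- principalStrains(S)
    for (k in 1:100) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      ds <- directionalStrain(S, d)
      expect_gte(ds, ps$min - 1e-9)
      expect_lte(ds, ps$max + 1e-9)
    }
  }
})

test_that("rigid-body motion yields zero strain in every combination", {
  m <- buildReferenceMesh(quickGeometry())
  nodes <- rbind(endoNodes(m), epiNodes(m))
  nph <- 5L
  disp <- array(0, dim = c(nrow(nodes), 3, nph))
  set.seed(21)
  for (k in 2:nph) {
    R <- randomRotation()
    disp[, , k] <- nodes %*% t(R) +
      matrix(rnorm(3, sd = 5), nrow(nodes), 3, byrow = TRUE) - nodes
  }
  dyn <- new("DynamicLVMesh", mesh = m, displacements = disp, cycleMs = 1000)
  ser <- strainTimeSeries(dyn)
  expect_lt(max(abs(strainValues(ser))), 1e-8)
  met <- temporalMetrics(ser, mesh = m)
  expect_lt(max(abs(peakAmp(met))), 1e-8)
})

test_that("strain series is zero at end-diastole and inverted elements are reported", {
  s <- hcmSubject()
  ser <- strainTimeSeries(subjectDynamics(s))
  expect_equal(max(abs(strainValues(ser)[, , 1])), 0)
  dyn <- subjectDynamics(s)
  bad <- dyn
  bad@displacements[1:510, , 3] <- bad@displacements[1:510, , 3] +
    3 * (epiNodes(referenceMesh(dyn)) - endoNodes(referenceMesh(dyn)))
  expect_error(strainTimeSeries(bad), "phase 3")
})

test_that("recovered global amplitudes match the phantom's analytic truth", {
  s <- hcmSubject()
  met <- hcmMetrics()
  g <- globalSummary(met)
  truth <- groundTruth(s)$global
  key <- paste(g$direction, g$layer, sep = ".")
  expect_lt(max(abs(g$amp - truth[key])), 0.5)
  # layer gradient: subendocardial shortening exceeds subepicardial
  expect_lt(g$amp[g$direction == "circ" & g$layer == "subendo"],
            g$amp[g$direction == "circ" & g$layer == "subepi"])
  expect_lt(g$amp[g$direction == "long" & g$layer == "subendo"],
            g$amp[g$direction == "long" & g$layer == "subepi"])
  # global longitudinal shortening against its construction truth
  expect_equal(longitudinalShortening(subjectDynamics(s)),
               groundTruth(s)$gls, tolerance = 1e-6)
})

test_that("oracle error decreases under mesh refinement", {
  s <- hcmSubject()
  gKey <- function(g) paste(g$direction, g$layer, sep = ".")
  g1 <- globalSummary(hcmMetrics())
  err1 <- max(abs(g1$amp - groundTruth(s)$global[gKey(g1)]))
  set.seed(101)
  s2 <- simulateSubject(noiselessHCM(), geometry = lvGeometry(nCirc = 45L,
                        nLong = 25L), id = "HCMfine")
  g2 <- globalSummary(extractMetrics(s2))
  err2 <- max(abs(g2$amp - groundTruth(s2)$global[gKey(g2)]))
  expect_lt(err2, err1)
})

test_that("temporal metrics match closed-form waveforms", {
  nph <- 30L
  mk <- function(v) {
    vals <- array(0, dim = c(1, 11, nph))
    vals[1, 1, ] <- v
    new("StrainSeries", values = vals, combos = strainComboTable(),
        cycleMs = 1000)
  }
  # peak at 0-based phase 12 -> 40% of cycle
  v <- numeric(nph); v[13] <- -10; v[12] <- -9; v[14] <- -9
  met <- temporalMetrics(mk(v))
  expect_equal(timeToPeak(met)[1, 1], 40)
  expect_equal(peakAmp(met)[1, 1], -10)
  # linear ramp 0 to -15% over a 1 s cycle: systolic rate -15 %/s
  ramp <- -15 * (seq_len(nph) - 1) / nph   # -15 %/s sampled on the phase grid
  met2 <- temporalMetrics(mk(ramp))
  expect_equal(peakSystolicRate(met2)[1, 1], -15, tolerance = 0.01)
  # raised cosine, amplitude -20, peak fraction 0.4: analytic extremal rate
  tf <- (seq_len(nph) - 1) / nph
  rc <- -20 * activationWaveform(tf, 0.4)
  met3 <- temporalMetrics(mk(rc))
  analytic <- -20 * pi / (2 * 0.4)   # %/s on a 1 s cycle
  expect_equal(peakSystolicRate(met3)[1, 1], analytic,
               tolerance = abs(analytic) * 0.05)
  # all-zero series: flagged as zero metrics, not an error
  met0 <- temporalMetrics(mk(numeric(nph)))
  expect_equal(timeToPeak(met0)[1, 1], 0)
  expect_equal(peakAmp(met0)[1, 1], 0)
})
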