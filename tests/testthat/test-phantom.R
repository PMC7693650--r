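test_that("activation waveform satisfies its boundary and midpoint values", {
  expect_equal(activationWaveform(0, 0.4), 0)
  expect_equal(activationWaveform(0.4, 0.4), 1)
  expect_equal(activationWaveform(1, 0.4), 0, tolerance = 1e-12)
  expect_equal(activationWaveform(0.2, 0.4), 0.5)
  # unique maximum on the 30-phase grid at 0-based phase 12 for peak 0.4
  tf <- (0:29) / 30
  expect_equal(which.max(activationWaveform(tf, 0.4)) - 1L, 12L)
  expect_error(activationWaveform(0.5, 1.2), "tPeakFrac")
})

test_that("subject simulation is deterministic and anchored at end-diastole", {
  set.seed(33); s1 <- simulateSubject(noiselessHCM(), id = "A")
  set.seed(33); s2 <- simulateSubject(noiselessHCM(), id = "A")
  expect_identical(displacements(subjectDynamics(s1)),
                   displacements(subjectDynamics(s2)))
  expect_equal(max(abs(displacements(subjectDynamics(s1))[, , 1])), 0)
  expect_equal(nPhases(subjectDynamics(s1)), 30L)
})

test_that("incompressible deformation preserves volume at the element level", {
  s <- hcmSubject()
  dyn <- subjectDynamics(s)
  mesh <- referenceMesh(dyn)
  nodes0 <- rbind(endoNodes(mesh), epiNodes(mesh))
  hx <- hexahedra(mesh)
  worst <- 0
  for (k in c(8, 14, 22)) {
    def <- nodes0 + displacements(dyn)[, , k]
    for (e in seq(1, nrow(hx), by = 7)) {
      F <- deformationGradient(nodes0[hx[e, ], ], def[hx[e, ], ])
      # product of principal stretches via an independent eigen route
      ev <- eigen(greenLagrange(F), symmetric = TRUE)$values
      worst <- max(worst, abs(prod(sqrt(1 + 2 * ev)) - 1))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("subendocardial amplitude recovery hits the configured target", {
  g <- globalSummary(hcmMetrics())
  expect_equal(g$amp[g$direction == "circ" & g$layer == "subendo"],
               -17.8, tolerance = 0.5)
  expect_equal(g$amp[g$direction == "long" & g$layer == "subendo"],
               -15.2, tolerance = 0.5)
})

test_that("time-to-peak is recovered within one phase at zero noise", {
  ph <- classPhenotype("HCM", ampCirc = -0.15, ampLong = -0.13,
                       tPeak = 0.45, thickness = 10, segmentJitterSd = 0)
  set.seed(4)
  s <- simulateSubject(ph, geometry = quickGeometry(), id = "T")
  met <- extractMetrics(s)
  ttp <- colMeans(timeToPeak(met))[1]     # circ subendo
  expect_lt(abs(ttp - 45), 100 / 30)
})

test_that("amplitude dose-response is strictly monotone", {
  rec <- vapply(c(-0.10, -0.16, -0.22), function(a) {
    ph <- classPhenotype("HCM", ampCirc = a, ampLong = a * 0.8,
                         tPeak = 0.4, thickness = 10, segmentJitterSd = 0)
    set.seed(8)
    s <- simulateSubject(ph, geometry = quickGeometry(), id = "D")
    g <- globalSummary(extractMetrics(s))
    g$amp[g$direction == "circ" & g$layer == "subendo"]
  }, numeric(1))
  expect_true(all(diff(abs(rec)) > 0))
})

test_that("mid-wall radial targeting reproduces the configured radial amplitude", {
  ph <- classPhenotype("HCM", ampCirc = -0.15, ampLong = -0.15,
                       tPeak = 0.43, thickness = 11.3, segmentJitterSd = 0,
                       ampReference = "midwall", radialTarget = 37.4)
  set.seed(10)
  s <- simulateSubject(ph, id = "R")
  g <- globalSummary(extractMetrics(s))
  expect_equal(g$amp[g$direction == "radial"], 37.4, tolerance = 0.5)
})

test_that("cohort manifests are complete, labeled and reproducible", {
  counts <- c(HCM = 2, CA = 1, AFD = 1, HTNcm = 1)
  co1 <- simulateCohort(counts, geometry = quickGeometry(), seed = 5)
  co2 <- simulateCohort(counts, geometry = quickGeometry(), seed = 5)
  expect_equal(nrow(co1$manifest), 5L)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(
    displacements(subjectDynamics(co1$subjects[[3]])),
    displacements(subjectDynamics(co2$subjects[[3]])))
  expect_equal(as.vector(table(co1$manifest$label)[c("HCM", "CA", "AFD",
                                                     "HTNcm")]),
               c(2L, 1L, 1L, 1L))
  empty <- simulateCohort(c(HCM = 0, CA = 0), geometry = quickGeometry(),
                          seed = 5)
  expect_equal(length(empty$subjects), 0L)
  expect_equal(nrow(empty$manifest), 0L)
  expect_error(simulateCohort(c(XX = 2), seed = 1), "no phenotype")
})

test_that("apical sparing preserves apical relative to basal strain for CA", {
  ph <- classPhenotype("CA", ampCirc = -0.14, ampLong = -0.126,
                       tPeak = 0.41, thickness = 10.7, segmentJitterSd = 0,
                       apicalSparing = 1.5)
  set.seed(12)
  s <- simulateSubject(ph, id = "CA0")
  met <- extractMetrics(s)
  mesh <- referenceMesh(subjectDynamics(s))
  rows <- lvmda:::elementRow(mesh)
  longAmp <- peakAmp(met)[, 4]   # long subendo
  basal <- mean(longAmp[rows <= 5])
  apical <- mean(longAmp[rows >= 12])
  expect_lt(apical, basal)  # more negative = better preserved shortening
})
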