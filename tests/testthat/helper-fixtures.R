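# Shared fixtures, generated in code. The cache avoids re-simulating the
# same deterministic subjects across test blocks.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, build(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

quickGeometry <- function() lvGeometry(nCirc = 12L, nLong = 7L)

noiselessHCM <- function() {
  classPhenotype("HCM", ampCirc = -0.178, ampLong = -0.152,
                 tPeak = 0.414, thickness = 11.3, segmentJitterSd = 0)
}

# default-resolution, noise-free HCM subject used by several oracle tests
hcmSubject <- function() {
  fixture("hcmSubject", function() {
    set.seed(101)
    simulateSubject(noiselessHCM(), id = "HCM0")
  })
}

hcmMetrics <- function() {
  fixture("hcmMetrics", function() extractMetrics(hcmSubject()))
}

# small synthetic two-class feature set (separable Gaussian clusters)
separableFeatures <- function(n = 60, d = 10, gap = 6, seed = 42) {
  set.seed(seed)
  lab <- rep(c("HCM", "CA"), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[lab == "HCM", 1:3] <- X[lab == "HCM", 1:3] + gap
  feat <- t(X)
  rownames(feat) <- sprintf("f%02d", seq_len(d))
  colnames(feat) <- sprintf("S%03d", seq_len(n))
  list(features = feat, label = lab)
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
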