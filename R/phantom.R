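## Synthetic dynamic LV phantom with analytic ground truth.
##
## The deformation is stretch-prescribed (kinematic, not force-based): the
## mid-wall surface is deformed so its circumferential radii and meridian
## chords scale by prescribed stretch fields exactly, and both faces are
## offset along the deformed mid-surface normal by half thickness times the
## radial stretch (1/(lc*ll) under incompressibility). Subendocardial and
## subepicardial in-plane strains then EMERGE from wall geometry with the
## clinically observed endo > epi amplitude gradient; a per-node calibration
## solves for the mid-wall prescription that makes the emergent
## subendocardial amplitudes equal the configured phenotype parameters.

#' Activation waveform
#'
#' Smooth piecewise raised-cosine activation with independent rise and decay
#' half-periods: a(0) = 0, a(tPeakFrac) = 1 (the unique maximum), a(1) = 0.
#'
#' @param tFrac time as a fraction of the cardiac cycle, in [0, 1]
#' @param tPeakFrac peak time as a fraction of the cycle, in (0, 1)
#' @return activation in [0, 1]
#' @export
activationWaveform <- function(tFrac, tPeakFrac) {
  if (tPeakFrac <= 0 || tPeakFrac >= 1)
    stop("tPeakFrac must lie strictly inside (0, 1)")
  stopifnot(all(tFrac >= 0 & tFrac <= 1))
  ifelse(tFrac <= tPeakFrac,
         0.5 * (1 - cos(pi * tFrac / tPeakFrac)),
         0.5 * (1 + cos(pi * (tFrac - tPeakFrac) / (1 - tPeakFrac))))
}

#' Class-conditional phenotype for the synthetic cohort
#'
#' Amplitudes are peak strains as negative fractions (e.g. -0.178 for
#' -17.8\%); by default they parameterize the subendocardial layer
#' (\code{ampReference = "subendo"}), in which case a calibration step solves
#' for the mid-wall prescription that realizes them. With
#' \code{ampReference = "midwall"} they are applied to the mid-wall directly.
#' \code{radialTarget} (percent, e.g. 37.4), when not NA and combined with
#' mid-wall referencing under incompressibility, draws a per-subject radial
#' amplitude and sets equal circumferential/longitudinal stretches so that
#' \code{1/(lc*ll)} matches it.
#'
#' @param label class label: HCM, CA, AFD or HTNcm
#' @param ampCirc,sdAmpCirc peak circumferential strain (fraction) and
#'   between-subject SD
#' @param ampLong,sdAmpLong peak longitudinal strain and SD
#' @param tPeak,sdTPeak time of peak systolic strain as fraction of cycle
#' @param thickness,sdThickness mean end-diastolic wall thickness, mm
#' @param thicknessPattern list: \code{type} one of "none",
#'   "basal_septal_bump", "concentric"; for the bump also \code{amplitude}
#'   (mm), \code{sigmaPhi}, \code{sigmaS}, \code{centerPhi}, \code{centerS}.
#'   The field is recentred so its global mean equals the drawn thickness.
#' @param apicalSparing apex-ward amplitude factor (>= 1; CA pattern),
#'   normalized to leave the global mean amplitude unchanged
#' @param segmentJitterSd SD of multiplicative per-AHA-segment amplitude noise
#' @param rrMs cardiac cycle duration, ms
#' @param ampReference "subendo" or "midwall"
#' @param radialTarget,sdRadialTarget optional transmural radial amplitude
#'   target in percent (mid-wall referencing only)
#' @return list of class \code{classPhenotype}
#' @export
classPhenotype <- function(label,
                           ampCirc, sdAmpCirc = 0,
                           ampLong, sdAmpLong = 0,
                           tPeak = 0.41, sdTPeak = 0,
                           thickness = 10, sdThickness = 0,
                           thicknessPattern = list(type = "none"),
                           apicalSparing = 1,
                           segmentJitterSd = 0.05,
                           rrMs = 1000,
                           ampReference = c("subendo", "midwall"),
                           radialTarget = NA_real_,
                           sdRadialTarget = 0) {
  ampReference <- match.arg(ampReference)
  stopifnot(abs(ampCirc) < 0.5, abs(ampLong) < 0.5,
            tPeak > 0, tPeak < 1, thickness > 0, apicalSparing >= 1)
  structure(list(label = label, ampCirc = ampCirc, sdAmpCirc = sdAmpCirc,
                 ampLong = ampLong, sdAmpLong = sdAmpLong,
                 tPeak = tPeak, sdTPeak = sdTPeak,
                 thickness = thickness, sdThickness = sdThickness,
                 thicknessPattern = thicknessPattern,
                 apicalSparing = apicalSparing,
                 segmentJitterSd = segmentJitterSd, rrMs = rrMs,
                 ampReference = ampReference,
                 radialTarget = radialTarget,
                 sdRadialTarget = sdRadialTarget),
            class = "classPhenotype")
}

#' Default class phenotypes
#'
#' Subendocardial circumferential/longitudinal amplitudes, time to peak,
#' and wall thickness (mean and between-subject SD) calibrated to the
#' published global means of the four hypertrophy etiologies; HCM carries a
#' basal-septal thickness bump, CA concentric thickening with apical strain
#' sparing, HTNcm mild concentric thickening and delayed circumferential
#' timing.
#'
#' @return named list of \code{\link{classPhenotype}} objects
#' @export
defaultPhenotypes <- function() {
  bump <- list(type = "basal_septal_bump", amplitude = 5, sigmaPhi = 0.7,
               sigmaS = 0.18, centerPhi = 2 * pi / 3, centerS = 0.15)
  list(
    HCM = classPhenotype("HCM", ampCirc = -0.178, sdAmpCirc = 0.037,
                         ampLong = -0.152, sdAmpLong = 0.039,
                         tPeak = 0.414, sdTPeak = 0.051,
                         thickness = 11.3, sdThickness = 2.3,
                         thicknessPattern = bump),
    CA = classPhenotype("CA", ampCirc = -0.142, sdAmpCirc = 0.059,
                        ampLong = -0.126, sdAmpLong = 0.051,
                        tPeak = 0.414, sdTPeak = 0.065,
                        thickness = 10.7, sdThickness = 2.7,
                        thicknessPattern = list(type = "concentric"),
                        apicalSparing = 1.5),
    AFD = classPhenotype("AFD", ampCirc = -0.165, sdAmpCirc = 0.026,
                         ampLong = -0.153, sdAmpLong = 0.020,
                         tPeak = 0.424, sdTPeak = 0.048,
                         thickness = 8.1, sdThickness = 1.9),
    HTNcm = classPhenotype("HTNcm", ampCirc = -0.172, sdAmpCirc = 0.035,
                           ampLong = -0.153, sdAmpLong = 0.038,
                           tPeak = 0.452, sdTPeak = 0.061,
                           thickness = 9.3, sdThickness = 1.2,
                           thicknessPattern = list(type = "concentric")))
}

# --- internal construction machinery -------------------------------------

# Reference quantities reused across phases
phantomRef <- function(mesh) {
  ref <- mesh@reference
  nCirc <- mesh@nCirc; nLong <- mesh@nLong
  mid <- ref$mid
  rho <- sqrt(mid[, , 1]^2 + mid[, , 2]^2)
  z <- mid[, , 3]
  dRho <- rho[, -1, drop = FALSE] - rho[, -nLong, drop = FALSE]
  dZ <- z[, -1, drop = FALSE] - z[, -nLong, drop = FALSE]
  ds <- sqrt(dRho^2 + dZ^2)
  endo <- matrixToGrid(mesh@endoNodes, nCirc, nLong)
  epi <- matrixToGrid(mesh@epiNodes, nCirc, nLong)
  list(nCirc = nCirc, nLong = nLong, mid = mid, rho = rho, z = z, ds = ds,
       dRho = dRho, half = ref$thickness / 2, normals = ref$normals,
       cphi = cos(ref$phi), sphi = sin(ref$phi),
       endo = endo, epi = epi,
       rhoEndo = sqrt(endo[, , 1]^2 + endo[, , 2]^2),
       rhoEpi = sqrt(epi[, , 1]^2 + epi[, , 2]^2),
       radialOp = radialNodeOperator(nLong))
}

# Operator turning per-chord radial targets t_j into a smooth node field x
# with (x_j + x_{j+1})/2 = t_j exactly: minimum-roughness solution of the
# underdetermined averaging system (KKT of min ||Dx||^2 s.t. Ax = t).
radialNodeOperator <- function(n) {
  A <- matrix(0, n - 1L, n)
  for (j in seq_len(n - 1L)) A[j, j] <- A[j, j + 1L] <- 0.5
  D <- diff(diag(n))
  L <- crossprod(D)
  K <- rbind(cbind(L, t(A)), cbind(A, matrix(0, n - 1L, n - 1L)))
  Ki <- solve(K)
  Ki[seq_len(n), n + seq_len(n - 1L), drop = FALSE]  # x = P %*% t
}

# chord-level radial targets (nCirc x (nLong-1)) -> smooth node field;
# floored away from zero so rough target profiles cannot oscillate the
# minimum-roughness solution into non-physical negative stretches
radialNodeField <- function(pr, tChord) {
  pmax(tChord %*% t(pr$radialOp), 0.25)
}

# element-consistent incompressible radial prescription: the element's
# in-plane stretch is the chord-average circumferential times the chord
# longitudinal stretch, so the per-chord radial target is its reciprocal
incompressibleRadial <- function(pr, mC, mL) {
  nLong <- pr$nLong
  w <- mC * pr$rho   # the element's xi-edge average is radius-weighted
  mCchord <- (w[, -1, drop = FALSE] + w[, -nLong, drop = FALSE]) /
    (pr$rho[, -1, drop = FALSE] + pr$rho[, -nLong, drop = FALSE])
  radialNodeField(pr, 1 / (mCchord * mL))
}

# chord stretches -> node values (average of adjacent chords)
chordToNode <- function(m) {
  nLong <- ncol(m) + 1L
  cbind(m[, 1], (m[, -1, drop = FALSE] + m[, -(nLong - 1L), drop = FALSE]) / 2,
        m[, nLong - 1L])
}

# Deform the shell for one set of stretch fields.
# lamC: node field (nCirc x nLong) mid-surface circumferential stretch
# lamL: chord field (nCirc x (nLong-1)) mid-surface meridian stretch
# lamR: node field, transmural (radial) stretch
constructPhase <- function(pr, lamC, lamL, lamR, clamp = FALSE,
                           capMargin = 0.9) {
  nLong <- pr$nLong
  rhoP <- lamC * pr$rho
  dRhoP <- rhoP[, -1, drop = FALSE] - rhoP[, -nLong, drop = FALSE]
  arg <- (lamL * pr$ds)^2 - dRhoP^2
  if (clamp) {
    arg <- pmax(arg, (0.05 * lamL * pr$ds)^2)
  } else if (any(arg <= 0))
    stop("non-invertible deformation: meridian construction degenerate ",
         "(longitudinal stretch too small for the circumferential field)")
  dzP <- sqrt(arg)
  zP <- cbind(pr$z[, 1], pr$z[, 1] - t(apply(dzP, 1, cumsum)))
  midP <- array(0, dim = c(pr$nCirc, nLong, 3))
  midP[, , 1] <- rhoP * pr$cphi
  midP[, , 2] <- rhoP * pr$sphi
  midP[, , 3] <- zP
  nrmP <- discreteNormals(midP, pr$normals)
  # cap the inward offset where it would exceed the local curvature radius
  # of the deformed mid-surface (prevents face folding at the apex for
  # extreme between-subject draws; inactive for typical amplitudes)
  lamR <- pmin(lamR, capMargin / (pr$half * surfaceCurvature(midP, nrmP)))
  off <- c(pr$half * lamR) * nrmP
  list(mid = midP, endo = midP - off, epi = midP + off, normals = nrmP)
}

# crude discrete curvature bound: normal turning rate per unit arc length,
# taken as the max of the circumferential and meridian directions
surfaceCurvature <- function(g, n) {
  nCirc <- dim(g)[1]; nLong <- dim(g)[2]
  ip <- c(2:nCirc, 1); im <- c(nCirc, 1:(nCirc - 1))
  dn <- sqrt((n[ip, , 1] - n[im, , 1])^2 + (n[ip, , 2] - n[im, , 2])^2 +
             (n[ip, , 3] - n[im, , 3])^2)
  dg <- sqrt((g[ip, , 1] - g[im, , 1])^2 + (g[ip, , 2] - g[im, , 2])^2 +
             (g[ip, , 3] - g[im, , 3])^2)
  kC <- dn / pmax(dg, 1e-9)
  jp <- pmin(seq_len(nLong) + 1L, nLong); jm <- pmax(seq_len(nLong) - 1L, 1L)
  dn <- sqrt((n[, jp, 1] - n[, jm, 1])^2 + (n[, jp, 2] - n[, jm, 2])^2 +
             (n[, jp, 3] - n[, jm, 3])^2)
  dg <- sqrt((g[, jp, 1] - g[, jm, 1])^2 + (g[, jp, 2] - g[, jm, 2])^2 +
             (g[, jp, 3] - g[, jm, 3])^2)
  kL <- dn / pmax(dg, 1e-9)
  pmax(kC, kL, 1e-9)
}

# Emergent face stretches of a constructed phase: circumferential per node
# (deformed/reference radius ratio) and longitudinal per meridian chord.
faceStretches <- function(pr, surfDef, surfRef, rhoRef) {
  nLong <- pr$nLong
  rhoD <- sqrt(surfDef[, , 1]^2 + surfDef[, , 2]^2)
  gC <- rhoD / rhoRef
  dD <- sqrt((surfDef[, -1, 1] - surfDef[, -nLong, 1])^2 +
             (surfDef[, -1, 2] - surfDef[, -nLong, 2])^2 +
             (surfDef[, -1, 3] - surfDef[, -nLong, 3])^2)
  dR <- sqrt((surfRef[, -1, 1] - surfRef[, -nLong, 1])^2 +
             (surfRef[, -1, 2] - surfRef[, -nLong, 2])^2 +
             (surfRef[, -1, 3] - surfRef[, -nLong, 3])^2)
  list(circ = gC, long = dD / dR)
}

# Solve for the mid-wall stretch fields whose emergent subendocardial
# stretches equal the targets. Damped fixed-point iteration; the response of
# the emergent face stretch to its own mid-wall prescription is strongly
# coupled across directions near the truncated apex (normal offset large
# relative to the local radius), so a small uniform damping factor is used
# for stability.
calibrateMidwall <- function(pr, gCtarget, gLtarget, incompressible,
                             lamRfixed = NULL, tol = 1e-9, maxIter = 500) {
  step <- 0.05
  mC <- gCtarget
  mL <- feasibleLong(pr, gCtarget, gLtarget)
  res <- Inf; prevRes <- Inf; stall <- 0L
  for (it in seq_len(maxIter)) {
    lamR <- if (incompressible) incompressibleRadial(pr, mC, mL) else
      lamRfixed
    s <- constructPhase(pr, mC, mL, lamR, clamp = TRUE)
    fs <- faceStretches(pr, s$endo, pr$endo, pr$rhoEndo)
    errC <- fs$circ - gCtarget
    errL <- fs$long - gLtarget
    res <- max(abs(errC), abs(errL))
    if (res < tol) break
    stall <- if (abs(res - prevRes) < 1e-12) stall + 1L else 0L
    if (stall >= 10L) break
    prevRes <- res
    mC <- pmin(pmax(mC - step * errC, 0.55), 1.6)
    mL <- pmin(pmax(mL - step * errL, 0.55), 1.6)
    mL <- feasibleLong(pr, mC, mL)
  }
  if (res > 0.05)
    warning("subendocardial targets partially infeasible near the apex ",
            "(residual ", signif(res, 2), "); closest feasible deformation used")
  list(mC = mC, mL = mL, iterations = it, residual = res)
}

# Project the meridian stretch field onto the feasible set of the arc
# construction: the deformed meridian chord must exceed its circumferential
# radius change (with a 5% margin), otherwise the shell cannot close.
feasibleLong <- function(pr, mC, mL) {
  nLong <- pr$nLong
  w <- mC * pr$rho
  B <- abs(w[, -1, drop = FALSE] - w[, -nLong, drop = FALSE])
  pmax(mL, 1.05 * B / pr$ds)
}

# segment-level multiplicative jitter factors mapped to nodes and chords
jitterFields <- function(mesh, map, factors) {
  nCirc <- mesh@nCirc; nLong <- mesh@nLong
  fElem <- factors[map@segment]                 # per element
  num <- matrix(0, nCirc, nLong); den <- matrix(0, nCirc, nLong)
  rows <- elementRow(mesh); cols <- elementCircIndex(mesh)
  for (e in seq_along(fElem)) {
    i <- cols[e]; j <- rows[e]; ip <- if (i == nCirc) 1L else i + 1L
    for (nd in list(c(i, j), c(ip, j), c(i, j + 1L), c(ip, j + 1L))) {
      num[nd[1], nd[2]] <- num[nd[1], nd[2]] + fElem[e]
      den[nd[1], nd[2]] <- den[nd[1], nd[2]] + 1
    }
  }
  node <- num / den
  # smooth across segment borders: abrupt circumferential jumps in the
  # longitudinal stretch integrate into jagged apex rings and can fold
  # elements, which no continuous myocardium would do
  node <- smoothGridField(smoothGridField(node))
  chord <- (node[, -1, drop = FALSE] + node[, -nLong, drop = FALSE]) / 2
  list(node = node, chord = chord)
}

# one pass of 1-2-1 smoothing, circular in phi and clamped in j
smoothGridField <- function(f) {
  nCirc <- nrow(f); nLong <- ncol(f)
  ip <- c(2:nCirc, 1); im <- c(nCirc, 1:(nCirc - 1))
  f <- (f[im, , drop = FALSE] + 2 * f + f[ip, , drop = FALSE]) / 4
  jp <- pmin(seq_len(nLong) + 1L, nLong); jm <- pmax(seq_len(nLong) - 1L, 1L)
  (f[, jm, drop = FALSE] + 2 * f + f[, jp, drop = FALSE]) / 4
}

thicknessFieldFor <- function(pattern, thickness, geometry) {
  nCirc <- geometry$nCirc; nLong <- geometry$nLong
  # apex-ward thinning, as in real ventricles; also keeps the transmural
  # offset below the apical curvature radius for thick-walled subjects
  s <- (seq_len(nLong) - 1) / (nLong - 1)
  Tf <- thickness * outer(rep(1, nCirc), 1 - 0.35 * s^2)
  if (identical(pattern$type, "basal_septal_bump")) {
    phi <- (seq_len(nCirc) - 1) * 2 * pi / nCirc
    dphi <- outer(phi, rep(1, nLong)) - pattern$centerPhi
    dphi <- atan2(sin(dphi), cos(dphi))         # wrap to [-pi, pi]
    dss <- outer(rep(1, nCirc), s) - pattern$centerS
    Tf <- Tf + pattern$amplitude *
      exp(-(dphi^2 / (2 * pattern$sigmaPhi^2) +
            dss^2 / (2 * pattern$sigmaS^2)))
  }
  Tf <- Tf + (thickness - mean(Tf))             # recentre to the drawn mean
  pmax(Tf, 2)
}

#' Simulate one synthetic subject
#'
#' Draws subject-level parameters from the phenotype (Gaussian with the
#' configured between-subject SDs, symmetric rejection so the means are
#' unbiased), builds the reference mesh with the phenotype thickness field,
#' and prescribes a smooth stretch-based deformation over \code{nPhases}
#' cardiac phases driven by the raised-cosine activation waveform. Uses the
#' current RNG state; see \code{\link{simulateCohort}} for seeded cohorts.
#'
#' @param phenotype a \code{\link{classPhenotype}}
#' @param geometry an \code{\link{lvGeometry}}
#' @param nPhases number of cardiac phases (default 30)
#' @param incompressible if TRUE the radial stretch is 1/(lc*ll) pointwise,
#'   making the prescribed deformation volume-preserving
#' @param id subject identifier
#' @return a \code{SubjectRecord} with analytic ground truth
#' @export
simulateSubject <- function(phenotype, geometry = lvGeometry(),
                            nPhases = 30L, incompressible = TRUE,
                            id = "S1") {
  stopifnot(inherits(phenotype, "classPhenotype"))
  ph <- phenotype
  # subject-level draws (order fixed for reproducibility)
  if (!is.na(ph$radialTarget)) {
    if (ph$ampReference != "midwall" || !incompressible)
      stop("radialTarget requires midwall amplitude referencing under incompressibility")
    rTar <- rnormBounded(1, ph$radialTarget, ph$sdRadialTarget,
                         lower = 2, upper = 120)
    lam <- sqrt(1 / (1 + rTar / 100))
    ampC <- ampL <- lam - 1
  } else {
    # joint draw with a physiological feasibility constraint: longitudinal
    # shortening exceeding circumferential by more than 4 strain-points
    # cannot be realized on the shell (and does not occur clinically)
    for (try in 1:1000) {
      ampC <- rnormBounded(1, ph$ampCirc, ph$sdAmpCirc, -0.45, -0.005)
      ampL <- rnormBounded(1, ph$ampLong, ph$sdAmpLong, -0.45, -0.005)
      if (ampL - ampC >= -0.04) break
    }
    if (ampL - ampC < -0.04) ampL <- ampC - 0.04
  }
  tp <- rnormBounded(1, ph$tPeak, ph$sdTPeak, 0.1, 0.9)
  T0 <- rnormBounded(1, ph$thickness, ph$sdThickness, 3, 25)

  Tf <- thicknessFieldFor(ph$thicknessPattern, T0, geometry)
  mesh <- buildReferenceMesh(geometry, Tf)
  map <- assignAhaSegments(mesh, 16L)
  jfac <- if (ph$segmentJitterSd > 0)
    rnormBounded(16, 1, ph$segmentJitterSd, 0.4, 1.6) else rep(1, 16)
  jit <- jitterFields(mesh, map, jfac)

  pr <- phantomRef(mesh)
  nLong <- geometry$nLong
  # apex-ward sparing profile, normalized to unit mean
  sNode <- (seq_len(nLong) - 1) / (nLong - 1)
  prof <- 1 + (ph$apicalSparing - 1) * sNode
  prof <- prof / mean(prof)
  profNode <- outer(rep(1, geometry$nCirc), prof)
  profChord <- (profNode[, -1, drop = FALSE] + profNode[, -nLong, drop = FALSE]) / 2

  gC <- 1 + ampC * profNode * jit$node
  gLchord <- 1 + ampL * profChord * jit$chord
  lamROne <- matrix(1, geometry$nCirc, nLong)
  if (ph$ampReference == "subendo") {
    cal <- calibrateMidwall(pr, gC, gLchord, incompressible,
                            lamRfixed = lamROne)
    mCpeak <- cal$mC; mLpeak <- cal$mL
  } else {
    mCpeak <- gC; mLpeak <- gLchord
  }

  tFrac <- (seq_len(nPhases) - 1) / nPhases
  act <- activationWaveform(tFrac, tp)
  nNodes <- nrow(mesh@endoNodes)
  nodes0 <- rbind(mesh@endoNodes, mesh@epiNodes)
  # Build all phases; if an extreme parameter draw folds an element near the
  # apex, tighten the transmural offset cap and rebuild (rare; leaves
  # typical subjects untouched).
  capMargin <- 0.9
  for (attempt in 1:6) {
    disp <- array(0, dim = c(2L * nNodes, 3L, nPhases))
    ok <- TRUE
    for (k in seq_len(nPhases)) {
      if (act[k] == 0) next
      mC <- 1 + (mCpeak - 1) * act[k]
      mL <- 1 + (mLpeak - 1) * act[k]
      lamR <- if (incompressible) incompressibleRadial(pr, mC, mL) else
        lamROne
      s <- constructPhase(pr, mC, mL, lamR, capMargin = capMargin)
      disp[seq_len(nNodes), , k] <- gridToMatrix(s$endo) - mesh@endoNodes
      disp[nNodes + seq_len(nNodes), , k] <-
        gridToMatrix(s$epi) - mesh@epiNodes
      if (min(elementJacobians(mesh, nodes0 + disp[, , k])) <= 0) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
    capMargin <- capMargin * 0.75
  }
  if (!ok) stop("non-invertible deformation: could not realize the drawn ",
                "parameters on this geometry")
  dyn <- new("DynamicLVMesh", mesh = mesh, displacements = disp,
             cycleMs = ph$rrMs)

  # analytic ground truth at the sampled peak phase
  kStar <- which.max(act)
  aMax <- act[kStar]
  mC <- 1 + (mCpeak - 1) * aMax
  mL <- 1 + (mLpeak - 1) * aMax
  lamR <- if (incompressible) incompressibleRadial(pr, mC, mL) else lamROne
  sPk <- constructPhase(pr, mC, mL, lamR, capMargin = capMargin)
  gt <- phantomGroundTruth(mesh, pr, sPk, mC, mL, lamR, kStar, nPhases, Tf)
  gt$tPeakFrac <- tp
  gt$aMax <- aMax

  new("SubjectRecord", id = id, label = ph$label, dynamics = dyn,
      groundTruth = gt,
      params = list(ampCirc = ampC, ampLong = ampL, tPeak = tp,
                    thickness = T0, jitter = jfac,
                    radialTarget = if (is.na(ph$radialTarget)) NA_real_ else
                      100 * (1 / ((1 + ampC)* (1 + ampL)) - 1),
                    incompressible = incompressible))
}

# Element-level analytic strain truths from the constructed peak surfaces
phantomGroundTruth <- function(mesh, pr, sPk, mC, mL, lamR, kStar, nPhases,
                               Tf) {
  rows <- elementRow(mesh); cols <- elementCircIndex(mesh)
  nCirc <- mesh@nCirc
  ip <- ifelse(cols == nCirc, 1L, cols + 1L)
  faceNodeMean <- function(fld) {  # node field -> per-element mean of 4 corners
    (fld[cbind(cols, rows)] + fld[cbind(ip, rows)] +
     fld[cbind(cols, rows + 1L)] + fld[cbind(ip, rows + 1L)]) / 4
  }
  chordMean <- function(fld) {     # chord field -> per-element mean of 2 chords
    (fld[cbind(cols, rows)] + fld[cbind(ip, rows)]) / 2
  }
  pct <- function(x) 100 * (x - 1)

  fsE <- faceStretches(pr, sPk$endo, pr$endo, pr$rhoEndo)
  fsP <- faceStretches(pr, sPk$epi, pr$epi, pr$rhoEpi)
  fsM <- faceStretches(pr, sPk$mid, pr$mid, pr$rho)
  endoC <- faceNodeMean(fsE$circ); endoL <- chordMean(fsE$long)
  epiC <- faceNodeMean(fsP$circ); epiL <- chordMean(fsP$long)
  midC <- faceNodeMean(fsM$circ); midL <- chordMean(fsM$long)
  radE <- faceNodeMean(lamR)
  minT <- pmin(midC, midL, radE); maxT <- pmax(midC, midL, radE)

  # global longitudinal shortening truth: emergent endo meridian arc ratio
  nLong <- pr$nLong
  dD <- sqrt((sPk$endo[, -1, 1] - sPk$endo[, -nLong, 1])^2 +
             (sPk$endo[, -1, 2] - sPk$endo[, -nLong, 2])^2 +
             (sPk$endo[, -1, 3] - sPk$endo[, -nLong, 3])^2)
  dR <- sqrt((pr$endo[, -1, 1] - pr$endo[, -nLong, 1])^2 +
             (pr$endo[, -1, 2] - pr$endo[, -nLong, 2])^2 +
             (pr$endo[, -1, 3] - pr$endo[, -nLong, 3])^2)
  gls <- 100 * (mean(rowSums(dD)) / mean(rowSums(dR)) - 1)

  elemThick <- faceNodeMean(Tf)
  list(
    global = c(circ.subendo = mean(pct(endoC)),
               circ.subepi = mean(pct(epiC)),
               circ.transmural = mean(pct(midC)),
               long.subendo = mean(pct(endoL)),
               long.subepi = mean(pct(epiL)),
               long.transmural = mean(pct(midL)),
               radial.transmural = mean(pct(radE)),
               minP.subendo = mean(pct(pmin(endoC, endoL))),
               minP.subepi = mean(pct(pmin(epiC, epiL))),
               minP.transmural = mean(pct(minT)),
               maxP.transmural = mean(pct(maxT))),
    elementMinPsubendo = pct(pmin(endoC, endoL)),
    gls = gls,
    thickness = mean(elemThick),
    tPeakPhasePct = 100 * (kStar - 1) / nPhases)
}

#' Simulate a class-conditional synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed and
#' subject index, so the same specification always reproduces bit-identical
#' displacement arrays.
#'
#' @param counts named integer vector of subjects per class, e.g.
#'   \code{c(HCM = 85, CA = 18, AFD = 30, HTNcm = 30)}
#' @param phenotypes named list of \code{\link{classPhenotype}} covering every
#'   requested label
#' @param geometry an \code{\link{lvGeometry}}
#' @param seed master seed
#' @param nPhases cardiac phases per cycle
#' @param incompressible passed to \code{\link{simulateSubject}}
#' @return list with \code{subjects} (list of \code{SubjectRecord}) and
#'   \code{manifest} (data.frame: id, label, seed, drawn parameters)
#' @export
simulateCohort <- function(counts, phenotypes = defaultPhenotypes(),
                           geometry = lvGeometry(), seed = 1L,
                           nPhases = 30L, incompressible = TRUE) {
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  missing <- setdiff(names(counts)[counts > 0], names(phenotypes))
  if (length(missing))
    stop("no phenotype for class(es): ", paste(missing, collapse = ", "))
  labels <- rep(names(counts), counts)
  n <- length(labels)
  subjects <- vector("list", n)
  rowsL <- vector("list", n)
  for (k in seq_len(n)) {
    sk <- deriveSeed(seed, 1L, k)
    set.seed(sk)
    id <- sprintf("S%03d", k)
    subjects[[k]] <- simulateSubject(phenotypes[[labels[k]]], geometry,
                                     nPhases, incompressible, id = id)
    p <- subjects[[k]]@params
    rowsL[[k]] <- data.frame(id = id, label = labels[k], seed = sk,
                             ampCirc = p$ampCirc, ampLong = p$ampLong,
                             tPeak = p$tPeak, thickness = p$thickness,
                             stringsAsFactors = FALSE)
  }
  manifest <- if (n) do.call(rbind, rowsL) else
    data.frame(id = character(), label = character(), seed = integer(),
               ampCirc = numeric(), ampLong = numeric(), tPeak = numeric(),
               thickness = numeric(), stringsAsFactors = FALSE)
  list(subjects = subjects, manifest = manifest)
}
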