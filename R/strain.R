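## Green-Lagrange strain machinery on hexahedral elements and their
## endo/epi membrane faces. All strains are stretch-based engineering
## strains, 100*(sqrt(1 + 2 eta) - 1), of material fibers: this is what makes
## the reported magnitudes (radial around +40%, minimum principal around
## -27%) behave like length changes rather than raw tensor components.

# trilinear shape-function derivatives at the element centroid; rows are the
# 8 local nodes (bottom quad then top quad), columns d/dxi, d/deta, d/dzeta
hexLocal <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
                  c(-1, -1, 1, 1, -1, -1, 1, 1),
                  c(-1, -1, -1, -1, 1, 1, 1, 1))
dNCentroid <- hexLocal / 8

#' Deformation gradient of a hexahedral element
#'
#' Evaluates F at the element centroid via trilinear shape-function
#' derivatives; exact for affine maps.
#'
#' @param refNodes,defNodes 8 x 3 matrices of node positions (reference and
#'   deformed), ordered bottom quad then top quad
#' @return the 3 x 3 deformation gradient
#' @export
deformationGradient <- function(refNodes, defNodes) {
  stopifnot(identical(dim(refNodes), c(8L, 3L)),
            identical(dim(defNodes), c(8L, 3L)))
  Jr <- t(refNodes) %*% dNCentroid
  if (abs(det(Jr)) < 1e-12)
    stop("singular reference Jacobian: degenerate element")
  unname((t(defNodes) %*% dNCentroid) %*% solve(Jr))
}

# Batched centroid Jacobian determinants for all elements of a mesh
elementJacobians <- function(mesh, nodes = NULL) {
  if (is.null(nodes)) nodes <- allNodes(mesh)
  x <- gatherElementNodes(nodes, mesh@hexahedra)
  J <- batchJacobian(x)
  batchDet3(J)
}

# x: nElem x 8 x 3 -> J: list of 9 component vectors, J[[3*(b-1)+a]] = J_ab
batchJacobian <- function(x) {
  out <- vector("list", 9)
  for (a in 1:3) {
    m <- x[, , a, drop = TRUE] %*% dNCentroid   # nElem x 3
    for (b in 1:3) out[[3 * (b - 1) + a]] <- m[, b]
  }
  out
}

batchDet3 <- function(J) {
  J[[1]] * (J[[5]] * J[[9]] - J[[8]] * J[[6]]) -
    J[[4]] * (J[[2]] * J[[9]] - J[[8]] * J[[3]]) +
    J[[7]] * (J[[2]] * J[[6]] - J[[5]] * J[[3]])
}

# F = Jd %*% solve(Jr), batched over elements; returns list of 9 vectors
batchF <- function(Jr, Jd) {
  d <- batchDet3(Jr)
  if (any(abs(d) < 1e-12)) stop("singular reference Jacobian in batch")
  # inverse via adjugate
  inv <- vector("list", 9)
  inv[[1]] <- (Jr[[5]] * Jr[[9]] - Jr[[8]] * Jr[[6]]) / d
  inv[[4]] <- -(Jr[[4]] * Jr[[9]] - Jr[[7]] * Jr[[6]]) / d
  inv[[7]] <- (Jr[[4]] * Jr[[8]] - Jr[[7]] * Jr[[5]]) / d
  inv[[2]] <- -(Jr[[2]] * Jr[[9]] - Jr[[8]] * Jr[[3]]) / d
  inv[[5]] <- (Jr[[1]] * Jr[[9]] - Jr[[7]] * Jr[[3]]) / d
  inv[[8]] <- -(Jr[[1]] * Jr[[8]] - Jr[[7]] * Jr[[2]]) / d
  inv[[3]] <- (Jr[[2]] * Jr[[6]] - Jr[[5]] * Jr[[3]]) / d
  inv[[6]] <- -(Jr[[1]] * Jr[[6]] - Jr[[4]] * Jr[[3]]) / d
  inv[[9]] <- (Jr[[1]] * Jr[[5]] - Jr[[4]] * Jr[[2]]) / d
  F <- vector("list", 9)
  for (a in 1:3) for (b in 1:3) {
    s <- 0
    for (k in 1:3) s <- s + Jd[[3 * (k - 1) + a]] * inv[[3 * (b - 1) + k]]
    F[[3 * (b - 1) + a]] <- s
  }
  F
}

# Green-Lagrange components from batched F: E = (F'F - I)/2, six components
batchE <- function(F) {
  C <- function(a, b) F[[a]] * F[[b]]
  list(
    e11 = (C(1, 1) + C(2, 2) + C(3, 3) - 1) / 2,
    e22 = (C(4, 4) + C(5, 5) + C(6, 6) - 1) / 2,
    e33 = (C(7, 7) + C(8, 8) + C(9, 9) - 1) / 2,
    e12 = (C(1, 4) + C(2, 5) + C(3, 6)) / 2,
    e13 = (C(1, 7) + C(2, 8) + C(3, 9)) / 2,
    e23 = (C(4, 7) + C(5, 8) + C(6, 9)) / 2)
}

# eta = d' E d for batched symmetric E and per-element unit directions d
batchQuadForm <- function(E, d) {
  d1 <- d[, 1]; d2 <- d[, 2]; d3 <- d[, 3]
  E$e11 * d1^2 + E$e22 * d2^2 + E$e33 * d3^2 +
    2 * (E$e12 * d1 * d2 + E$e13 * d1 * d3 + E$e23 * d2 * d3)
}

#' Green-Lagrange strain tensor
#'
#' @param F a 3 x 3 (or 2 x 2) deformation gradient
#' @return E = (F'F - I)/2, symmetric by construction
#' @export
greenLagrange <- function(F) {
  (crossprod(F) - diag(nrow(F))) / 2
}

#' Directional (fiber) strain
#'
#' Stretch-based strain of a material fiber along unit direction \code{d}:
#' \code{100 * (sqrt(1 + 2 d'Ed) - 1)}.
#'
#' @param E symmetric strain tensor (2x2 or 3x3)
#' @param d unit direction vector
#' @return strain in %
#' @export
directionalStrain <- function(E, d) {
  if (abs(sum(d^2) - 1) > 1e-8) stop("direction must be a unit vector")
  stretchStrain(drop(t(d) %*% E %*% d), "directional strain")
}

#' Minimum and maximum principal strains
#'
#' Eigendecomposes the Green-Lagrange tensor and converts each eigenvalue
#' \code{eta} to a stretch-based strain \code{100*(sqrt(1+2*eta)-1)}.
#' Eigenvector signs are fixed so that the first nonzero component is
#' positive.
#'
#' @param E symmetric strain tensor
#' @return list with \code{min}, \code{max} (%) and \code{vectors} (columns:
#'   minimum then maximum principal direction)
#' @export
principalStrains <- function(E) {
  if (max(abs(E - t(E))) > 1e-8) stop("strain tensor is not symmetric")
  eg <- eigen((E + t(E)) / 2, symmetric = TRUE)
  vals <- stretchStrain(eg$values, "principal strain")   # decreasing order
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    nzi <- which(abs(vecs[, k]) > 1e-12)[1]
    if (!is.na(nzi) && vecs[nzi, k] < 0) vecs[, k] <- -vecs[, k]
  }
  k <- length(vals)
  list(min = vals[k], max = vals[1], vectors = vecs[, c(k, 1), drop = FALSE])
}

#' In-plane (membrane) deformation gradient of a quadrilateral face
#'
#' Expresses the bilinear in-surface map in an orthonormal tangent basis of
#' the reference quad; the deformed basis is the reference basis projected
#' onto the deformed tangent plane, so a purely in-plane affine map is
#' recovered exactly.
#'
#' @param refQuad,defQuad 4 x 3 node matrices (quad corner order)
#' @return 2 x 2 in-plane deformation gradient
#' @export
surfaceDeformationGradient <- function(refQuad, defQuad) {
  stopifnot(identical(dim(refQuad), c(4L, 3L)),
            identical(dim(defQuad), c(4L, 3L)))
  t1 <- (-refQuad[1, ] + refQuad[2, ] + refQuad[3, ] - refQuad[4, ]) / 4
  t2 <- (-refQuad[1, ] - refQuad[2, ] + refQuad[3, ] + refQuad[4, ]) / 4
  if (sum(t1^2) < 1e-20) stop("degenerate reference tangent basis")
  u1 <- t1 / sqrt(sum(t1^2))
  w <- t2 - sum(t2 * u1) * u1
  if (sum(w^2) < 1e-20) stop("degenerate reference tangent basis")
  u2 <- w / sqrt(sum(w^2))
  A <- rbind(c(sum(t1 * u1), sum(t2 * u1)), c(0, sum(t2 * u2)))
  T1 <- (-defQuad[1, ] + defQuad[2, ] + defQuad[3, ] - defQuad[4, ]) / 4
  T2 <- (-defQuad[1, ] - defQuad[2, ] + defQuad[3, ] + defQuad[4, ]) / 4
  nd <- vcross(rbind(T1), rbind(T2))[1, ]
  if (sum(nd^2) < 1e-20) stop("degenerate deformed tangent basis")
  nd <- nd / sqrt(sum(nd^2))
  v1 <- u1 - sum(u1 * nd) * nd
  if (sum(v1^2) < 1e-12) stop("deformed plane orthogonal to reference plane")
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- u2 - sum(u2 * nd) * nd - sum(u2 * v1) * v1
  if (sum(v2^2) < 1e-12) stop("deformed plane orthogonal to reference plane")
  v2 <- v2 / sqrt(sum(v2^2))
  B <- rbind(c(sum(T1 * v1), sum(T2 * v1)), c(sum(T1 * v2), sum(T2 * v2)))
  B %*% solve(A)
}

# Batched membrane Green-Lagrange tensor for one face layer of all elements.
# x: nElem x 8 x 3 node array; faceNodes: the 4 local node indices.
# Returns list(e11, e22, e12, u1, u2) with the reference orthonormal basis.
batchSurfaceE <- function(xRef, xDef, faceNodes) {
  q <- function(x, k) x[, faceNodes[k], ]
  t1r <- (-q(xRef, 1) + q(xRef, 2) + q(xRef, 3) - q(xRef, 4)) / 4
  t2r <- (-q(xRef, 1) - q(xRef, 2) + q(xRef, 3) + q(xRef, 4)) / 4
  u1 <- rowsNormalize(t1r)
  w <- t2r - rowSums(t2r * u1) * u1
  u2 <- rowsNormalize(w)
  a11 <- rowSums(t1r * u1); a12 <- rowSums(t2r * u1); a22 <- rowSums(t2r * u2)
  if (any(abs(a11 * a22) < 1e-20)) stop("degenerate face tangent basis")
  t1d <- (-q(xDef, 1) + q(xDef, 2) + q(xDef, 3) - q(xDef, 4)) / 4
  t2d <- (-q(xDef, 1) - q(xDef, 2) + q(xDef, 3) + q(xDef, 4)) / 4
  g11 <- rowSums(t1d * t1d); g12 <- rowSums(t1d * t2d); g22 <- rowSums(t2d * t2d)
  # C = A^-T G A^-1 with A upper triangular [[a11, a12], [0, a22]]
  i11 <- 1 / a11; i12 <- -a12 / (a11 * a22); i22 <- 1 / a22
  c11 <- i11 * (g11 * i11)
  c12 <- i11 * (g11 * i12 + g12 * i22)
  c22 <- i12 * (g11 * i12 + 2 * g12 * i22) + i22 * g22 * i22
  list(e11 = (c11 - 1) / 2, e22 = (c22 - 1) / 2, e12 = c12 / 2,
       u1 = u1, u2 = u2)
}

# project per-element 3D unit directions into a face basis and renormalize
projectDirection <- function(d, u1, u2) {
  p1 <- rowSums(d * u1); p2 <- rowSums(d * u2)
  nn <- sqrt(p1^2 + p2^2)
  if (any(nn < 1e-8)) stop("direction orthogonal to face")
  cbind(p1 / nn, p2 / nn)
}

#' The direction-layer combinations reported by the pipeline
#'
#' Circumferential and longitudinal strains at subendocardial, subepicardial
#' and transmural layers; radial and maximum principal transmural only;
#' minimum principal at all three layers: 11 combinations.
#'
#' @return data.frame with columns \code{direction}, \code{layer}
#' @export
strainComboTable <- function() {
  data.frame(
    direction = c("circ", "circ", "circ", "long", "long", "long", "radial",
                  "minP", "minP", "minP", "maxP"),
    layer = c("subendo", "subepi", "transmural", "subendo", "subepi",
              "transmural", "transmural", "subendo", "subepi", "transmural",
              "transmural"),
    stringsAsFactors = FALSE)
}

#' Strain time series for a dynamic mesh
#'
#' For every cardiac phase, transmural strains come from the trilinear
#' hexahedral deformation gradient at the element centroid (projected on the
#' local circumferential/longitudinal/radial directions, or eigendecomposed
#' for principal strains); subendocardial and subepicardial strains come from
#' the 2D membrane tensors of the endo and epi faces (radial strain is
#' undefined there, hence transmural-only).
#'
#' @param dynamics a \code{DynamicLVMesh}
#' @param frames optional precomputed \code{LocalFrameField}
#' @return a \code{StrainSeries} (elements x 11 combos x phases, %)
#' @export
strainTimeSeries <- function(dynamics, frames = NULL) {
  mesh <- dynamics@mesh
  if (is.null(frames)) frames <- computeLocalFrames(mesh)
  nodes0 <- allNodes(mesh)
  xRef <- gatherElementNodes(nodes0, mesh@hexahedra)
  Jr <- batchJacobian(xRef)
  nph <- dim(dynamics@displacements)[3]
  ne <- nrow(mesh@hexahedra)
  combos <- strainComboTable()
  vals <- array(0, dim = c(ne, nrow(combos), nph))
  for (k in seq_len(nph)) {
    if (k == 1L) next  # reference phase: exactly zero
    xDef <- gatherElementNodes(nodes0 + dynamics@displacements[, , k],
                               mesh@hexahedra)
    Jd <- batchJacobian(xDef)
    F <- tryCatch(batchF(Jr, Jd), error = function(e)
      stop("inverted or degenerate element at phase ", k, ": ",
           conditionMessage(e)))
    detF <- batchDet3(list(F[[1]], F[[2]], F[[3]], F[[4]], F[[5]], F[[6]],
                           F[[7]], F[[8]], F[[9]]))
    if (any(detF <= 0))
      stop("inverted element ", which(detF <= 0)[1], " at phase ", k)
    E <- batchE(F)
    within01 <- function(eta, what) {
      if (any(1 + 2 * eta <= 0))
        stop("unphysical compression (", what, ") at phase ", k,
             ", element ", which(1 + 2 * eta <= 0)[1])
      100 * (sqrt(1 + 2 * eta) - 1)
    }
    vals[, 3, k] <- within01(batchQuadForm(E, frames@eC), "circ transmural")
    vals[, 6, k] <- within01(batchQuadForm(E, frames@eL), "long transmural")
    vals[, 7, k] <- within01(batchQuadForm(E, frames@eR), "radial transmural")
    ev <- symEigen3(E$e11, E$e22, E$e33, E$e12, E$e13, E$e23)
    vals[, 10, k] <- within01(ev[, 1], "min principal transmural")
    vals[, 11, k] <- within01(ev[, 3], "max principal transmural")
    for (layer in 1:2) {
      faceNodes <- if (layer == 1) 1:4 else 5:8
      S <- batchSurfaceE(xRef, xDef, faceNodes)
      dC <- projectDirection(frames@eC, S$u1, S$u2)
      dL <- projectDirection(frames@eL, S$u1, S$u2)
      etaC <- S$e11 * dC[, 1]^2 + S$e22 * dC[, 2]^2 + 2 * S$e12 * dC[, 1] * dC[, 2]
      etaL <- S$e11 * dL[, 1]^2 + S$e22 * dL[, 2]^2 + 2 * S$e12 * dL[, 1] * dL[, 2]
      ev2 <- symEigen2(S$e11, S$e22, S$e12)
      ic <- if (layer == 1) 1 else 2     # circ.subendo / circ.subepi
      il <- if (layer == 1) 4 else 5
      ip <- if (layer == 1) 8 else 9
      lname <- c("subendo", "subepi")[layer]
      vals[, ic, k] <- within01(etaC, paste("circ", lname))
      vals[, il, k] <- within01(etaL, paste("long", lname))
      vals[, ip, k] <- within01(ev2[, 1], paste("minP", lname))
    }
  }
  new("StrainSeries", values = vals, combos = combos,
      cycleMs = dynamics@cycleMs)
}

#' Temporal metrics of strain series
#'
#' Per element and direction-layer combination: signed peak-systolic
#' amplitude (the minimum for shortening combinations - circumferential,
#' longitudinal and minimum principal - and the maximum for radial and
#' maximum principal), time to peak as % of the cardiac cycle, and peak
#' systolic/diastolic strain rates from central differences. The
#' systole/diastole split is at the per-combination peak phase; ties break to
#' the earliest phase. All-zero series yield zero metrics with time-to-peak
#' 0 rather than an error.
#'
#' @param series a \code{StrainSeries}
#' @param mesh optional \code{LVMesh} to attach end-diastolic thickness
#' @param frames optional \code{LocalFrameField} for the thickness projection
#' @return an \code{ElementMetrics}
#' @export
temporalMetrics <- function(series, mesh = NULL, frames = NULL) {
  v <- series@values
  ne <- dim(v)[1]; nc <- dim(v)[2]; nph <- dim(v)[3]
  if (nph < 3) stop("need at least 3 phases")
  shortening <- series@combos$direction %in% c("circ", "long", "minP")
  dtS <- series@cycleMs / nph / 1000            # seconds per phase
  amp <- ttp <- srs <- srd <- matrix(0, ne, nc)
  for (ci in seq_len(nc)) {
    m <- matrix(v[, ci, ], nrow = ne)            # ne x nph
    sgn <- if (shortening[ci]) -1 else 1
    pk <- max.col(sgn * m, ties.method = "first")
    pAmp <- m[cbind(seq_len(ne), pk)]
    zero <- apply(abs(m), 1, max) == 0
    pk[zero] <- 1L
    pAmp[zero] <- 0
    amp[, ci] <- pAmp
    ttp[, ci] <- 100 * (pk - 1) / nph
    # central-difference rates, one-sided at the ends
    D <- matrix(0, ne, nph)
    D[, 2:(nph - 1)] <- (m[, 3:nph] - m[, 1:(nph - 2)]) / (2 * dtS)
    D[, 1] <- (m[, 2] - m[, 1]) / dtS
    D[, nph] <- (m[, nph] - m[, nph - 1]) / dtS
    colIdx <- matrix(seq_len(nph), ne, nph, byrow = TRUE)
    isSys <- colIdx <= pk
    Dsys <- D; Dsys[!isSys] <- NA
    Ddia <- D; Ddia[isSys] <- NA
    noDia <- pk == nph
    if (shortening[ci]) {
      sv <- do.call(pmin, c(asplit(Dsys, 2), na.rm = TRUE))
      dv <- do.call(pmax, c(asplit(Ddia, 2), na.rm = TRUE))
    } else {
      sv <- do.call(pmax, c(asplit(Dsys, 2), na.rm = TRUE))
      dv <- do.call(pmin, c(asplit(Ddia, 2), na.rm = TRUE))
    }
    dv[noDia] <- 0
    sv[zero] <- 0; dv[zero] <- 0
    srs[, ci] <- sv; srd[, ci] <- dv
  }
  thick <- if (!is.null(mesh)) wallThickness(mesh, frames = frames) else
    rep(NA_real_, ne)
  new("ElementMetrics", peakAmp = amp, timeToPeak = ttp,
      peakSystolicRate = srs, peakDiastolicRate = srd, edThickness = thick,
      combos = series@combos, cycleMs = series@cycleMs)
}

#' Extract per-element metrics from a dynamic mesh
#'
#' Convenience wrapper: local frames, strain time series and temporal
#' metrics (with end-diastolic thickness) in one call.
#'
#' @param dynamics a \code{DynamicLVMesh} or \code{SubjectRecord}
#' @return an \code{ElementMetrics}
#' @export
extractMetrics <- function(dynamics) {
  if (is(dynamics, "SubjectRecord")) dynamics <- dynamics@dynamics
  frames <- computeLocalFrames(dynamics@mesh)
  series <- strainTimeSeries(dynamics, frames)
  temporalMetrics(series, mesh = dynamics@mesh, frames = frames)
}

#' Global longitudinal shortening
#'
#' Percent change of the endocardial base-to-apex meridian arc length from
#' end-diastole to its minimum over the cycle, averaged over meridians.
#'
#' @param dynamics a \code{DynamicLVMesh}
#' @return global longitudinal shortening in % (negative for shortening)
#' @export
longitudinalShortening <- function(dynamics) {
  mesh <- dynamics@mesh
  nCirc <- mesh@nCirc; nLong <- mesh@nLong
  nph <- dim(dynamics@displacements)[3]
  L <- numeric(nph)
  for (k in seq_len(nph)) {
    endo <- mesh@endoNodes + dynamics@displacements[seq_len(nCirc * nLong), , k]
    g <- matrixToGrid(endo, nCirc, nLong)
    seg <- sqrt((g[, -1, 1] - g[, -nLong, 1])^2 +
                (g[, -1, 2] - g[, -nLong, 2])^2 +
                (g[, -1, 3] - g[, -nLong, 3])^2)
    L[k] <- mean(rowSums(seg))
  }
  100 * (min(L) - L[1]) / L[1]
}

#' Global (cohort-style) summary of element metrics
#'
#' Unweighted element means of each temporal metric per direction-layer
#' combination, plus mean end-diastolic thickness.
#'
#' @param metrics an \code{ElementMetrics}
#' @return data.frame with one row per combination and a \code{thickness}
#'   attribute (mm)
#' @export
globalSummary <- function(metrics) {
  out <- cbind(metrics@combos,
               amp = colMeans(metrics@peakAmp),
               ttp = colMeans(metrics@timeToPeak),
               srs = colMeans(metrics@peakSystolicRate),
               srd = colMeans(metrics@peakDiastolicRate))
  attr(out, "thickness") <- mean(metrics@edThickness)
  out
}
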