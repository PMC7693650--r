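#' Left-ventricular reference geometry configuration
#'
#' Describes a truncated prolate-spheroid LV shell: the endocardial surface is
#' an ellipsoid of revolution with equatorial radius \code{endoRadiusEq},
#' truncated at the base plane (equator) and with a fraction
#' \code{apexTruncation} of the apical pole removed to avoid degenerate pole
#' elements. The epicardial surface is offset outward along the wall normal by
#' the thickness field. The default 30 x 17 grid gives 510 nodes per layer.
#'
#' @param nCirc nodes around the circumference (>= 8)
#' @param nLong nodes from base to apex (>= 4)
#' @param endoRadiusEq equatorial endocardial radius, mm
#' @param baseThickness baseline wall thickness, mm
#' @param longAxisLength base-to-apex extent, mm
#' @param apexTruncation fraction in (0,1) of the prolate pole removed
#' @return a list of class \code{lvGeometry}
#' @export
lvGeometry <- function(nCirc = 30L, nLong = 17L, endoRadiusEq = 25,
                       baseThickness = 10, longAxisLength = 70,
                       apexTruncation = 0.1) {
  nCirc <- as.integer(nCirc); nLong <- as.integer(nLong)
  stopifnot(nCirc >= 8, nLong >= 4,
            endoRadiusEq > 0, baseThickness > 0, longAxisLength > 0,
            apexTruncation > 0, apexTruncation < 1)
  structure(list(nCirc = nCirc, nLong = nLong, endoRadiusEq = endoRadiusEq,
                 baseThickness = baseThickness,
                 longAxisLength = longAxisLength,
                 apexTruncation = apexTruncation),
            class = "lvGeometry")
}

nodeId <- function(i, j, nCirc) (j - 1L) * nCirc + i

gridToMatrix <- function(g) {
  # g: array nCirc x nLong x 3 -> (nCirc*nLong) x 3, i fastest
  matrix(g, ncol = 3)
}

matrixToGrid <- function(m, nCirc, nLong) array(m, dim = c(nCirc, nLong, 3))

# Outward unit normals of a structured surface grid (nCirc x nLong x 3).
# Central differences circumferentially (periodic) and longitudinally
# (one-sided at the base/apex edges); orientation matched to `orient`.
discreteNormals <- function(g, orient) {
  nCirc <- dim(g)[1]; nLong <- dim(g)[2]
  ip <- c(2:nCirc, 1); im <- c(nCirc, 1:(nCirc - 1))
  tC <- g[ip, , , drop = FALSE] - g[im, , , drop = FALSE]
  tL <- array(0, dim = dim(g))
  tL[, 2:(nLong - 1), ] <- g[, 3:nLong, , drop = FALSE] -
    g[, 1:(nLong - 2), , drop = FALSE]
  if (nLong >= 6) {
    # fourth-order central stencils where the surface curvature matters
    jj <- 3:(nLong - 2)
    tL[, jj, ] <- (g[, jj - 2, , drop = FALSE] -
                   8 * g[, jj - 1, , drop = FALSE] +
                   8 * g[, jj + 1, , drop = FALSE] -
                   g[, jj + 2, , drop = FALSE]) / 6
  }
  # second-order one-sided stencils at the base/apex edge rows
  tL[, 1, ] <- -3 * g[, 1, ] + 4 * g[, 2, ] - g[, 3, ]
  tL[, nLong, ] <- 3 * g[, nLong, ] - 4 * g[, nLong - 1, ] + g[, nLong - 2, ]
  a <- matrix(tC, ncol = 3); b <- matrix(tL, ncol = 3)
  n <- vcross(a, b)
  o <- matrix(orient, ncol = 3)
  s <- sign(rowSums(n * o)); s[s == 0] <- 1
  n <- rowsNormalize(n * s)
  array(n, dim = dim(g))
}

#' Build the reference (end-diastolic) two-layer LV mesh
#'
#' Nodes are generated from a mid-wall surface (the endocardial ellipsoid
#' offset by half the thickness field along the analytic surface normal); the
#' endo and epi layers are placed at minus/plus half thickness along the
#' discrete mid-surface normal, so the radial wall thickness equals the
#' thickness field by construction. Hexahedral elements join each endocardial
#' quad to its matched epicardial quad, ordered so the element Jacobian is
#' positive (xi circumferential, eta toward the base, zeta endo to epi).
#'
#' @param config an \code{\link{lvGeometry}}
#' @param thicknessField optional nCirc x nLong matrix of wall thickness (mm);
#'   defaults to the uniform \code{baseThickness}
#' @return an \code{LVMesh}
#' @export
buildReferenceMesh <- function(config, thicknessField = NULL) {
  stopifnot(inherits(config, "lvGeometry"))
  nCirc <- config$nCirc; nLong <- config$nLong
  b <- config$endoRadiusEq
  if (is.null(thicknessField))
    thicknessField <- matrix(config$baseThickness, nCirc, nLong)
  stopifnot(identical(dim(thicknessField), c(nCirc, nLong)))
  if (any(thicknessField <= 0)) {
    bad <- which(thicknessField <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive wall thickness at node (i=", bad[1], ", j=", bad[2], ")")
  }

  phi <- (seq_len(nCirc) - 1) * 2 * pi / nCirc
  alphaMax <- pi - (pi / 2) * config$apexTruncation
  alpha <- seq(pi / 2, alphaMax, length.out = nLong)
  aSemi <- config$longAxisLength / (-cos(alphaMax))

  # analytic endocardial surface and its outward normal, meridian components
  rhoE <- b * sin(alpha)             # per j
  zE <- aSemi * cos(alpha)           # 0 at base, negative toward apex
  nRho <- sin(alpha) / b
  nZ <- cos(alpha) / aSemi
  nn <- sqrt(nRho^2 + nZ^2)
  nRho <- nRho / nn; nZ <- nZ / nn

  cphi <- cos(phi); sphi <- sin(phi)
  mid <- array(0, dim = c(nCirc, nLong, 3))
  orient <- array(0, dim = c(nCirc, nLong, 3))
  half <- thicknessField / 2
  for (j in seq_len(nLong)) {
    rr <- rhoE[j] + half[, j] * nRho[j]
    mid[, j, 1] <- rr * cphi
    mid[, j, 2] <- rr * sphi
    mid[, j, 3] <- zE[j] + half[, j] * nZ[j]
    orient[, j, 1] <- nRho[j] * cphi
    orient[, j, 2] <- nRho[j] * sphi
    orient[, j, 3] <- nZ[j]
  }
  nrm <- discreteNormals(mid, orient)
  endo <- mid - c(half) * nrm
  epi <- mid + c(half) * nrm

  hexa <- buildHexConnectivity(nCirc, nLong)
  mesh <- new("LVMesh",
              endoNodes = gridToMatrix(endo), epiNodes = gridToMatrix(epi),
              hexahedra = hexa, nCirc = nCirc, nLong = nLong,
              reference = list(config = config, phi = phi, alpha = alpha,
                               aSemi = aSemi, mid = mid, normals = nrm,
                               thickness = thicknessField, orient = orient))
  validObject(mesh)
  jac <- elementJacobians(mesh)
  if (any(jac <= 0)) {
    e <- which.min(jac)
    stop("non-positive element Jacobian at element ", e,
         " (epi surface crosses endo); node ", mesh@hexahedra[e, 1])
  }
  mesh
}

# Element connectivity: for element (i, j) the endocardial quad is taken at
# rows j+1 (apexward) then j (baseward) so that eta points toward the base
# and the trilinear Jacobian is positive for a right-handed frame field.
buildHexConnectivity <- function(nCirc, nLong) {
  N <- nCirc * nLong
  ii <- rep(seq_len(nCirc), nLong - 1L)
  jj <- rep(seq_len(nLong - 1L), each = nCirc)
  ip <- ifelse(ii == nCirc, 1L, ii + 1L)
  n1 <- nodeId(ii, jj + 1L, nCirc); n2 <- nodeId(ip, jj + 1L, nCirc)
  n3 <- nodeId(ip, jj, nCirc);      n4 <- nodeId(ii, jj, nCirc)
  m <- cbind(n1, n2, n3, n4, n1 + N, n2 + N, n3 + N, n4 + N)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

elementRow <- function(mesh) rep(seq_len(mesh@nLong - 1L), each = mesh@nCirc)
elementCircIndex <- function(mesh) rep(seq_len(mesh@nCirc), mesh@nLong - 1L)

# all node coordinates stacked: endo layer then epi layer
allNodes <- function(mesh) rbind(mesh@endoNodes, mesh@epiNodes)

# gather per-element node coordinates: array (nElem x 8 x 3)
gatherElementNodes <- function(nodes, hexa) {
  ne <- nrow(hexa)
  out <- array(0, dim = c(ne, 8, 3))
  for (k in 1:8) out[, k, ] <- nodes[hexa[, k], ]
  out
}

#' Per-element local anatomical frames
#'
#' Builds an orthonormal right-handed triad per element from the element's own
#' geometry: the radial vector points from the endocardial face centroid to
#' the epicardial face centroid, the longitudinal vector is the mid-surface
#' tangent toward the base orthogonalized against the radial one, and the
#' circumferential vector completes the right-handed triad. Because every
#' ingredient is built from node differences the frames are exactly
#' equivariant under rigid rotations of the mesh.
#'
#' @param mesh an \code{LVMesh}
#' @return a \code{LocalFrameField}
#' @export
computeLocalFrames <- function(mesh) {
  x <- gatherElementNodes(allNodes(mesh), mesh@hexahedra)
  endoC <- (x[, 1, ] + x[, 2, ] + x[, 3, ] + x[, 4, ]) / 4
  epiC <- (x[, 5, ] + x[, 6, ] + x[, 7, ] + x[, 8, ]) / 4
  er <- epiC - endoC
  if (any(rowSums(er^2) == 0))
    stop("zero-length endo-to-epi vector in element ",
         which(rowSums(er^2) == 0)[1])
  er <- rowsNormalize(er)
  eta <- (x[, 4, ] - x[, 1, ] + x[, 3, ] - x[, 2, ] +
          x[, 8, ] - x[, 5, ] + x[, 7, ] - x[, 6, ]) / 4
  el <- eta - rowSums(eta * er) * er
  el <- rowsNormalize(el)
  ec <- vcross(el, er)
  new("LocalFrameField", eC = ec, eL = el, eR = er)
}

#' Assign elements to AHA segments
#'
#' Elements are split into basal, mid and apical thirds by their normalized
#' longitudinal (base-to-apex) position, then into 6/6/4 circumferential
#' sectors respectively. The circumferential origin (phi = 0) is the anterior
#' RV insertion, with angle increasing counterclockwise viewed from the base;
#' basal segment 1 is the first sextant past the origin. With
#' \code{nSegments = 17} the most apical element ring is split off as the
#' apical-cap segment (intended for wall-thickness features on a truncated
#' mesh; apical strain there is unreliable).
#'
#' @param mesh an \code{LVMesh}
#' @param nSegments 16 (default) or 17
#' @return an \code{AHASegmentMap}
#' @export
assignAhaSegments <- function(mesh, nSegments = 16L) {
  nSegments <- as.integer(nSegments)
  stopifnot(nSegments %in% c(16L, 17L))
  nRows <- mesh@nLong - 1L
  j <- elementRow(mesh)
  i <- elementCircIndex(mesh)
  s <- (j - 0.5) / nRows                      # 0 base -> 1 apex
  phiC <- (i - 0.5) * 2 * pi / mesh@nCirc
  ring <- ifelse(s < 1 / 3, 1L, ifelse(s < 2 / 3, 2L, 3L))
  sext <- pmin(floor(phiC / (pi / 3)), 5) + 1L
  quad <- pmin(floor(phiC / (pi / 2)), 3) + 1L
  seg <- ifelse(ring == 1L, sext,
                ifelse(ring == 2L, 6L + sext, 12L + quad))
  if (nSegments == 17L) seg[j == nRows] <- 17L
  seg <- as.integer(seg)
  elements <- lapply(seq_len(nSegments), function(k) which(seg == k))
  if (any(lengths(elements) == 0))
    stop("empty AHA segment at this resolution; use a finer mesh")
  new("AHASegmentMap", segment = seg, elements = elements,
      nSegments = nSegments)
}

#' Radial wall thickness per element
#'
#' Distance between the (optionally deformed) endocardial and epicardial face
#' centroids of each element, projected on the reference radial direction.
#'
#' @param mesh an \code{LVMesh}
#' @param displacementsAtPhase optional (2*nodes) x 3 displacement matrix
#' @param elements optional element ids (default all)
#' @param frames optional precomputed \code{LocalFrameField}
#' @return thickness in mm per requested element
#' @export
wallThickness <- function(mesh, displacementsAtPhase = NULL, elements = NULL,
                          frames = NULL) {
  if (is.null(frames)) frames <- computeLocalFrames(mesh)
  nodes <- allNodes(mesh)
  if (!is.null(displacementsAtPhase)) nodes <- nodes + displacementsAtPhase
  x <- gatherElementNodes(nodes, mesh@hexahedra)
  endoC <- (x[, 1, ] + x[, 2, ] + x[, 3, ] + x[, 4, ]) / 4
  epiC <- (x[, 5, ] + x[, 6, ] + x[, 7, ] + x[, 8, ]) / 4
  th <- rowSums((epiC - endoC) * frames@eR)
  if (!is.null(elements)) th <- th[elements]
  if (any(th <= 0))
    stop("negative projected wall thickness (inverted element ",
         which(th <= 0)[1], ")")
  th
}
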