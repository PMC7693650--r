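#' Write / read a subject container
#'
#' Single-file JSON container with named datasets: node arrays, hexahedral
#' connectivity, per-phase displacements, cycle duration and metadata
#' (subject id, class label, drawn parameters, ground truth). Full floating
#' point precision is kept so a round trip reproduces node coordinates
#' exactly.
#'
#' @param subject a \code{SubjectRecord} (or \code{DynamicLVMesh})
#' @param path output file (.json)
#' @return \code{readSubject} returns a \code{SubjectRecord}
#' @export
writeSubject <- function(subject, path) {
  if (is(subject, "DynamicLVMesh"))
    subject <- new("SubjectRecord", id = "anonymous", label = "unknown",
                   dynamics = subject, groundTruth = list(), params = list())
  dyn <- subject@dynamics
  mesh <- dyn@mesh
  payload <- list(
    format = "lvmda-subject", version = 1L,
    id = subject@id, label = subject@label,
    nCirc = mesh@nCirc, nLong = mesh@nLong,
    nPhases = dim(dyn@displacements)[3],
    cycleMs = dyn@cycleMs,
    geometry = unclass(mesh@reference$config),
    thickness = as.vector(mesh@reference$thickness),
    endoNodes = as.vector(mesh@endoNodes),
    epiNodes = as.vector(mesh@epiNodes),
    hexahedra = as.vector(mesh@hexahedra),
    displacements = as.vector(dyn@displacements),
    groundTruth = subject@groundTruth,
    params = subject@params)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeSubject
#' @export
readSubject <- function(path) {
  if (!file.exists(path)) stop("cannot open subject container: ", path)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "lvmda-subject"))
    stop("not an lvmda subject container: ", path)
  nCirc <- as.integer(p$nCirc); nLong <- as.integer(p$nLong)
  N <- nCirc * nLong
  g <- p$geometry
  cfg <- lvGeometry(nCirc, nLong, g$endoRadiusEq, g$baseThickness,
                    g$longAxisLength, g$apexTruncation)
  Tf <- matrix(p$thickness, nCirc, nLong)
  mesh <- buildReferenceMesh(cfg, Tf)
  # stored coordinates are authoritative (identical by construction)
  mesh@endoNodes <- matrix(p$endoNodes, N, 3)
  mesh@epiNodes <- matrix(p$epiNodes, N, 3)
  hexa <- matrix(as.integer(p$hexahedra), ncol = 8)
  if (!identical(hexa, mesh@hexahedra)) mesh@hexahedra <- hexa
  disp <- array(p$displacements, dim = c(2L * N, 3L, as.integer(p$nPhases)))
  dyn <- new("DynamicLVMesh", mesh = mesh, displacements = disp,
             cycleMs = p$cycleMs)
  gt <- if (is.null(p$groundTruth)) list() else p$groundTruth
  pa <- if (is.null(p$params)) list() else p$params
  new("SubjectRecord", id = p$id, label = p$label, dynamics = dyn,
      groundTruth = gt, params = pa)
}

#' Export a mesh phase as a legacy-VTK unstructured grid
#'
#' ASCII legacy VTK (DATASET UNSTRUCTURED_GRID, cell type 12 hexahedron)
#' for visualization of one cardiac phase, with optional point and cell
#' scalar fields.
#'
#' @param mesh an \code{LVMesh}
#' @param path output .vtk file
#' @param displacementsAtPhase optional (2*nodes) x 3 displacement matrix to
#'   deform the exported geometry
#' @param pointData named list of per-node scalar vectors
#' @param cellData named list of per-element scalar vectors
#' @return the path, invisibly
#' @export
writeVTK <- function(mesh, path, displacementsAtPhase = NULL,
                     pointData = list(), cellData = list()) {
  nodes <- allNodes(mesh)
  if (!is.null(displacementsAtPhase)) nodes <- nodes + displacementsAtPhase
  hexa <- mesh@hexahedra
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "lvmda LV mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(nodes), "double")), con)
  write(t(nodes), con, ncolumns = 3)
  writeLines(paste("CELLS", nrow(hexa), nrow(hexa) * 9L), con)
  write(t(cbind(8L, hexa - 1L)), con, ncolumns = 9)
  writeLines(paste("CELL_TYPES", nrow(hexa)), con)
  write(rep(12L, nrow(hexa)), con, ncolumns = 1)
  if (length(pointData)) {
    writeLines(paste("POINT_DATA", nrow(nodes)), con)
    for (nm in names(pointData)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      write(pointData[[nm]], con, ncolumns = 1)
    }
  }
  if (length(cellData)) {
    writeLines(paste("CELL_DATA", nrow(hexa)), con)
    for (nm in names(cellData)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      write(cellData[[nm]], con, ncolumns = 1)
    }
  }
  invisible(path)
}
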