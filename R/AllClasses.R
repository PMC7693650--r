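#' S4 container classes for 3D myocardial deformation analysis
#'
#' \code{LVMesh} holds the reference (end-diastolic) two-layer left-ventricular
#' mesh: index-matched endocardial and epicardial node layers joined by
#' transmural hexahedral elements. \code{DynamicLVMesh} adds per-phase nodal
#' displacements and the cardiac cycle duration. \code{LocalFrameField} stores
#' per-element orthonormal circumferential/longitudinal/radial triads.
#' \code{AHASegmentMap} maps elements to American Heart Association segments.
#' \code{StrainSeries} and \code{ElementMetrics} hold per-element strain time
#' series and their temporal summaries. \code{SubjectRecord} bundles one
#' synthetic subject with its analytic ground truth, and \code{CVResult}
#' holds cross-validated classifier performance.
#'
#' @name lvmda-classes
#' @aliases LVMesh-class DynamicLVMesh-class LocalFrameField-class
#'   AHASegmentMap-class StrainSeries-class ElementMetrics-class
#'   SubjectRecord-class CVResult-class
NULL

#' @rdname lvmda-classes
#' @slot endoNodes numeric matrix (nodes x 3), endocardial layer, mm
#' @slot epiNodes numeric matrix (nodes x 3), epicardial layer, index-matched
#' @slot hexahedra integer matrix (elements x 8), global node ids; nodes 1-4
#'   are the endocardial quad, 5-8 the matched epicardial quad
#' @slot nCirc,nLong integer grid resolution per layer
#' @slot reference list of reference-geometry data (mid-surface grid, normals,
#'   thickness field, geometry config) used by the phantom and thickness code
#' @export
setClass("LVMesh", representation(
  endoNodes = "matrix", epiNodes = "matrix", hexahedra = "matrix",
  nCirc = "integer", nLong = "integer", reference = "list"))

setValidity("LVMesh", function(object) {
  msg <- character()
  if (!identical(dim(object@endoNodes), dim(object@epiNodes)))
    msg <- c(msg, "endo and epi node layers must be index-matched")
  if (nrow(object@endoNodes) != object@nCirc * object@nLong)
    msg <- c(msg, "node count per layer must equal nCirc * nLong")
  if (ncol(object@hexahedra) != 8)
    msg <- c(msg, "hexahedra must have 8 nodes")
  nTot <- 2L * nrow(object@endoNodes)
  if (length(object@hexahedra) && (min(object@hexahedra) < 1 ||
                                   max(object@hexahedra) > nTot))
    msg <- c(msg, "hexahedron node ids out of range")
  if (length(object@hexahedra) &&
      !all(tabulate(object@hexahedra, nTot) > 0))
    msg <- c(msg, "every node must belong to at least one element")
  if (length(msg)) msg else TRUE
})

#' @rdname lvmda-classes
#' @slot mesh an \code{LVMesh}
#' @slot displacements numeric array (nodes*2 layers x 3 x phases), mm;
#'   phase 1 (end-diastole) is identically zero
#' @slot cycleMs cardiac cycle duration, ms
#' @export
setClass("DynamicLVMesh", representation(
  mesh = "LVMesh", displacements = "array", cycleMs = "numeric"))

setValidity("DynamicLVMesh", function(object) {
  msg <- character()
  d <- dim(object@displacements)
  if (length(d) != 3 || d[1] != 2 * nrow(object@mesh@endoNodes) || d[2] != 3)
    msg <- c(msg, "displacements must be (2*nodes) x 3 x phases")
  else {
    if (max(abs(object@displacements[, , 1])) > 1e-12)
      msg <- c(msg, "displacement at phase 1 (end-diastole) must be zero")
    if (!all(is.finite(object@displacements)))
      msg <- c(msg, "displacements must be finite")
  }
  if (length(object@cycleMs) != 1 || object@cycleMs <= 0)
    msg <- c(msg, "cycleMs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @rdname lvmda-classes
#' @slot eC,eL,eR numeric matrices (elements x 3): unit circumferential,
#'   longitudinal (toward base) and radial (endo to epi) vectors
#' @export
setClass("LocalFrameField", representation(
  eC = "matrix", eL = "matrix", eR = "matrix"))

setValidity("LocalFrameField", function(object) {
  for (nm in c("eC", "eL", "eR")) {
    v <- slot(object, nm)
    if (ncol(v) != 3) return("frame vectors must be 3D")
    if (max(abs(sqrt(rowSums(v^2)) - 1)) > 1e-8) return("frame vectors must be unit length")
  }
  TRUE
})

#' @rdname lvmda-classes
#' @slot segment integer vector, AHA segment id per element
#' @slot elements list of element-id vectors per segment
#' @slot nSegments 16 or 17
#' @export
setClass("AHASegmentMap", representation(
  segment = "integer", elements = "list", nSegments = "integer"))

setValidity("AHASegmentMap", function(object) {
  ids <- sort(unique(object@segment))
  if (length(object@elements) != object@nSegments)
    return("element list must have one entry per segment")
  if (any(ids < 1 | ids > object@nSegments))
    return("segment ids out of range")
  if (length(unlist(object@elements)) != length(object@segment))
    return("segment lists must partition the elements")
  TRUE
})

#' @rdname lvmda-classes
#' @slot values numeric array (elements x combos x phases), strain in %
#' @slot combos data.frame with columns direction, layer (11 rows by default)
#' @export
setClass("StrainSeries", representation(
  values = "array", combos = "data.frame", cycleMs = "numeric"))

setValidity("StrainSeries", function(object) {
  d <- dim(object@values)
  if (length(d) != 3 || d[2] != nrow(object@combos))
    return("values must be elements x combos x phases")
  if (max(abs(object@values[, , 1])) > 1e-8)
    return("strain at phase 1 (end-diastole) must be zero")
  TRUE
})

#' @rdname lvmda-classes
#' @slot peakAmp,timeToPeak,peakSystolicRate,peakDiastolicRate numeric
#'   matrices (elements x combos); units %, % of cycle, %/s, %/s
#' @slot edThickness numeric vector, end-diastolic wall thickness per
#'   element, mm
#' @export
setClass("ElementMetrics", representation(
  peakAmp = "matrix", timeToPeak = "matrix", peakSystolicRate = "matrix",
  peakDiastolicRate = "matrix", edThickness = "numeric",
  combos = "data.frame", cycleMs = "numeric"))

setValidity("ElementMetrics", function(object) {
  if (any(object@timeToPeak < 0 | object@timeToPeak > 100))
    return("time to peak must lie in [0, 100] % of cycle")
  if (any(!is.na(object@edThickness) & object@edThickness <= 0))
    return("end-diastolic thickness must be positive")
  TRUE
})

#' @rdname lvmda-classes
#' @slot id subject identifier
#' @slot label disease class, one of HCM, CA, AFD, HTNcm
#' @slot dynamics a \code{DynamicLVMesh}
#' @slot groundTruth list of analytic ground-truth stretch summaries
#' @slot params list of the drawn subject-level parameters
#' @export
setClass("SubjectRecord", representation(
  id = "character", label = "character", dynamics = "DynamicLVMesh",
  groundTruth = "list", params = "list"))

#' @rdname lvmda-classes
#' @slot folds list of per-fold results (roc, auc, confusion metrics, indices)
#' @slot metrics data.frame of per-fold scalar metrics
#' @slot summary data.frame with mean and sd (n-1) per metric over folds
#' @slot medianROC data.frame (fpr, tpr): pointwise median ROC over folds
#' @export
setClass("CVResult", representation(
  folds = "list", metrics = "data.frame", summary = "data.frame",
  medianROC = "data.frame", config = "list"))

setValidity("CVResult", function(object) {
  idx <- unlist(lapply(object@folds, `[[`, "testIndex"))
  if (anyDuplicated(idx))
    return("each subject must be tested in exactly one fold")
  TRUE
})

setMethod("show", "LVMesh", function(object) {
  cat("LVMesh:", nrow(object@endoNodes), "nodes per layer (",
      object@nCirc, "x", object@nLong, "),", nrow(object@hexahedra),
      "hexahedral elements\n")
})

setMethod("show", "DynamicLVMesh", function(object) {
  cat("DynamicLVMesh:", dim(object@displacements)[3], "phases over",
      object@cycleMs, "ms;")
  show(object@mesh)
})

setMethod("show", "SubjectRecord", function(object) {
  cat("SubjectRecord", object@id, "(", object@label, ")\n")
  show(object@dynamics)
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult over", length(object@folds), "folds\n")
  print(object@summary, digits = 3)
})

#' Accessors for lvmda containers
#'
#' @param x an lvmda S4 object
#' @return the requested component
#' @name lvmda-accessors
NULL

#' @rdname lvmda-accessors
#' @export
endoNodes <- function(x) x@endoNodes
#' @rdname lvmda-accessors
#' @export
epiNodes <- function(x) x@epiNodes
#' @rdname lvmda-accessors
#' @export
hexahedra <- function(x) x@hexahedra
#' @rdname lvmda-accessors
#' @export
referenceMesh <- function(x) x@mesh
#' @rdname lvmda-accessors
#' @export
displacements <- function(x) x@displacements
#' @rdname lvmda-accessors
#' @export
cycleMs <- function(x) if (is(x, "DynamicLVMesh")) x@cycleMs else x@cycleMs
#' @rdname lvmda-accessors
#' @export
nPhases <- function(x) dim(x@displacements)[3]
#' @rdname lvmda-accessors
#' @export
segmentOf <- function(x) x@segment
#' @rdname lvmda-accessors
#' @export
strainCombos <- function(x) x@combos
#' @rdname lvmda-accessors
#' @export
strainValues <- function(x) x@values
#' @rdname lvmda-accessors
#' @export
peakAmp <- function(x) x@peakAmp
#' @rdname lvmda-accessors
#' @export
timeToPeak <- function(x) x@timeToPeak
#' @rdname lvmda-accessors
#' @export
peakSystolicRate <- function(x) x@peakSystolicRate
#' @rdname lvmda-accessors
#' @export
peakDiastolicRate <- function(x) x@peakDiastolicRate
#' @rdname lvmda-accessors
#' @export
edThickness <- function(x) x@edThickness
#' @rdname lvmda-accessors
#' @export
groundTruth <- function(x) x@groundTruth
#' @rdname lvmda-accessors
#' @export
subjectDynamics <- function(x) x@dynamics
#' @rdname lvmda-accessors
#' @export
subjectLabel <- function(x) x@label
#' @rdname lvmda-accessors
#' @export
cvFolds <- function(x) x@folds
#' @rdname lvmda-accessors
#' @export
cvMetrics <- function(x) x@metrics
#' @rdname lvmda-accessors
#' @export
cvSummary <- function(x) x@summary
#' @rdname lvmda-accessors
#' @export
medianROC <- function(x) x@medianROC
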