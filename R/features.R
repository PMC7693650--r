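#' Segmental feature schema
#'
#' Enumerates the ordered per-subject feature vector: for each temporal
#' metric (peak amplitude, time to peak, peak systolic rate, peak diastolic
#' rate) every direction-layer combination in every AHA segment, plus
#' end-diastolic wall thickness per segment. The default taxonomy gives
#' 16 x (11 x 4 + 1) = 720 features.
#'
#' @param nSegments number of AHA segments (16 default)
#' @param combos data.frame of direction-layer combinations
#'   (\code{\link{strainComboTable}})
#' @param metrics character vector of temporal metrics to include
#' @param includeThickness add per-segment end-diastolic thickness features
#' @return data.frame of class \code{featureSchema} with columns
#'   \code{name}, \code{metric}, \code{direction}, \code{layer},
#'   \code{segment}
#' @export
featureSchema <- function(nSegments = 16L, combos = strainComboTable(),
                          metrics = c("amp", "ttp", "srs", "srd"),
                          includeThickness = TRUE) {
  segs <- seq_len(nSegments)
  rows <- list()
  for (m in metrics) {
    for (ci in seq_len(nrow(combos))) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, direction = combos$direction[ci],
        layer = combos$layer[ci], segment = segs, stringsAsFactors = FALSE)
    }
  }
  if (includeThickness)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "edthickness", direction = "radial", layer = "wall",
      segment = segs, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$name <- sprintf("%s.%s.%s.seg%d", out$metric, out$direction,
                      out$layer, out$segment)
  stopifnot(!anyDuplicated(out$name))
  out <- out[, c("name", "metric", "direction", "layer", "segment")]
  class(out) <- c("featureSchema", "data.frame")
  out
}

#' Aggregate element metrics to AHA segment means
#'
#' Unweighted mean over the elements of each segment, per metric and
#' direction-layer combination.
#'
#' @param metrics an \code{ElementMetrics}
#' @param map an \code{AHASegmentMap}
#' @return list of (nSegments x nCombos) matrices per temporal metric plus a
#'   per-segment thickness vector
#' @export
aggregateToSegments <- function(metrics, map) {
  if (length(map@segment) != nrow(metrics@peakAmp))
    stop("segment map does not match the element metrics")
  if (any(lengths(map@elements) == 0)) stop("empty AHA segment")
  segMean <- function(m) {
    out <- matrix(0, map@nSegments, ncol(m))
    for (k in seq_len(map@nSegments))
      out[k, ] <- colMeans(m[map@elements[[k]], , drop = FALSE])
    out
  }
  list(amp = segMean(metrics@peakAmp),
       ttp = segMean(metrics@timeToPeak),
       srs = segMean(metrics@peakSystolicRate),
       srd = segMean(metrics@peakDiastolicRate),
       edthickness = vapply(map@elements, function(e)
         mean(metrics@edThickness[e]), numeric(1)))
}

# ordered feature vector for one subject
featureVector <- function(metrics, map, schema) {
  agg <- aggregateToSegments(metrics, map)
  combos <- metrics@combos
  comboKey <- paste(combos$direction, combos$layer)
  out <- numeric(nrow(schema))
  for (r in seq_len(nrow(schema))) {
    if (schema$metric[r] == "edthickness") {
      out[r] <- agg$edthickness[schema$segment[r]]
    } else {
      ci <- match(paste(schema$direction[r], schema$layer[r]), comboKey)
      if (is.na(ci))
        stop("schema requires missing combination: ", schema$name[r])
      out[r] <- agg[[schema$metric[r]]][schema$segment[r], ci]
    }
  }
  names(out) <- schema$name
  out
}

#' Build the subjects-by-features table
#'
#' Assembles the ordered segmental feature vectors of a cohort into a
#' \code{SummarizedExperiment}: assay \code{features} is features x subjects,
#' \code{rowData} carries the schema, \code{colData} the subject ids and
#' binary HCM labels. Metadata records the units (strain %, time-to-peak %
#' of cycle, rates %/s, thickness mm).
#'
#' @param metricsList named list of \code{ElementMetrics}, one per subject
#' @param labels character vector of class labels (HCM positive)
#' @param map an \code{AHASegmentMap} shared by all subjects
#' @param schema a \code{\link{featureSchema}}
#' @return a \code{SummarizedExperiment}
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
buildFeatureTable <- function(metricsList, labels, map,
                              schema = featureSchema(map@nSegments)) {
  stopifnot(length(metricsList) == length(labels))
  ids <- names(metricsList)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(metricsList))
  X <- vapply(metricsList, featureVector, numeric(nrow(schema)),
              map = map, schema = schema)
  if (length(metricsList)) {
    X <- matrix(X, nrow = nrow(schema), dimnames = list(schema$name, ids))
  } else {
    X <- matrix(numeric(0), nrow = nrow(schema), ncol = 0,
                dimnames = list(schema$name, NULL))
  }
  if (anyNA(X)) stop("missing values in the feature table")
  SummarizedExperiment(
    assays = list(features = X),
    rowData = DataFrame(schema),
    colData = DataFrame(subject_id = ids, label = labels,
                        hcm = as.integer(labels == "HCM")),
    metadata = list(units = c(amp = "%", ttp = "% of cycle", srs = "%/s",
                              srd = "%/s", edthickness = "mm"),
                    nSegments = map@nSegments))
}

#' Write / read a feature table as CSV
#'
#' Subjects are rows; the first two columns are \code{subject_id} and
#' \code{label}, followed by the schema-ordered feature columns.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{buildFeatureTable}}
#' @param path output file
#' @return \code{readFeatureCSV} returns a list with the feature matrix
#'   (features x subjects), ids and labels
#' @export
writeFeatureCSV <- function(se, path) {
  X <- t(SummarizedExperiment::assay(se, "features"))
  df <- data.frame(subject_id = se$subject_id, label = se$label,
                   X, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  # schema sidecar: feature enumeration plus units, to prevent unit drift
  sidecar <- list(
    schema = as.data.frame(SummarizedExperiment::rowData(se)),
    units = as.list(S4Vectors::metadata(se)$units))
  jsonlite::write_json(sidecar, paste0(path, ".schema.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- t(as.matrix(df[, setdiff(names(df), c("subject_id", "label")),
                      drop = FALSE]))
  colnames(X) <- df$subject_id
  list(features = X, subject_id = df$subject_id, label = df$label)
}

#' Cohort mean atlas of a peak-amplitude field
#'
#' Element-wise mean across subjects of the peak strain amplitude for one
#' direction-layer combination (the numeric counterpart of a rendered
#' average strain atlas), with a node-averaged version for point-data
#' export.
#'
#' @param metricsList list of \code{ElementMetrics} sharing one mesh topology
#' @param mesh the shared \code{LVMesh}
#' @param direction,layer the requested combination
#' @return list with \code{element} (per-element mean, %) and \code{node}
#'   (per-node average of adjacent elements)
#' @export
meanAtlas <- function(metricsList, mesh, direction = "minP",
                      layer = "subendo") {
  stopifnot(length(metricsList) >= 1)
  combos <- metricsList[[1]]@combos
  ci <- which(combos$direction == direction & combos$layer == layer)
  if (!length(ci)) stop("unknown combination ", direction, ".", layer)
  ne <- nrow(metricsList[[1]]@peakAmp)
  for (m in metricsList)
    if (nrow(m@peakAmp) != ne) stop("mesh topology mismatch across subjects")
  elemMean <- rowMeans(vapply(metricsList, function(m) m@peakAmp[, ci],
                              numeric(ne)))
  nNodes <- 2L * nrow(mesh@endoNodes)
  num <- numeric(nNodes); den <- numeric(nNodes)
  for (k in 1:8) {
    idx <- mesh@hexahedra[, k]  # ids are unique within one corner column
    num[idx] <- num[idx] + elemMean
    den[idx] <- den[idx] + 1
  }
  list(element = elemMean, node = ifelse(den > 0, num / den, NA_real_))
}
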