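#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: cohort composition,
#' geometry, phenotypes, network settings and the master seed from which
#' every stage seed is derived. Can also be loaded from a YAML file holding
#' the scalar fields (counts, seed, epochs, nBoot, nPhases).
#'
#' @param counts named subjects-per-class vector
#' @param seed master seed; all stage seeds derive from it
#' @param geometry an \code{\link{lvGeometry}}
#' @param phenotypes named list of \code{\link{classPhenotype}}
#' @param nPhases cardiac phases
#' @param epochs,lr network training settings
#' @param nBoot bootstrap resamples for the marker baselines
#' @param markers feature names to use as single-marker baselines; defaults
#'   to the per-segment end-diastolic thickness block summarized globally
#' @return list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(counts = c(HCM = 85, CA = 18, AFD = 30,
                                      HTNcm = 30),
                           seed = 1L, geometry = lvGeometry(),
                           phenotypes = defaultPhenotypes(),
                           nPhases = 30L, epochs = 100L, lr = 0.01,
                           nBoot = 500L, markers = NULL) {
  structure(list(counts = counts, seed = as.integer(seed),
                 geometry = geometry, phenotypes = phenotypes,
                 nPhases = as.integer(nPhases), epochs = as.integer(epochs),
                 lr = lr, nBoot = as.integer(nBoot), markers = markers),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with fields counts (named), seed, nPhases, epochs,
#'   lr, nBoot
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  if (!is.null(y$counts)) cfg$counts <- unlist(y$counts)
  for (f in c("seed", "nPhases", "epochs", "nBoot"))
    if (!is.null(y[[f]])) cfg[[f]] <- as.integer(y[[f]])
  if (!is.null(y$lr)) cfg$lr <- y$lr
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> features -> cross-validate -> marker baselines,
#' with a run manifest recording the master seed, every derived stage seed,
#' cohort composition and (when files are written) output checksums. Two
#' runs with the same configuration produce identical results.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param outDir optional directory; when given, the feature CSV, CV result
#'   JSON and manifest JSON are written there
#' @param verbose print stage progress
#' @return list: cohort manifest, feature table (SummarizedExperiment),
#'   \code{CVResult}, marker baselines, global per-subject summary
#'   data.frame, and the run manifest
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seeds <- list(cohort = deriveSeed(config$seed, 1L),
                cv = deriveSeed(config$seed, 2L),
                boot = deriveSeed(config$seed, 3L))
  say("simulating cohort (", sum(config$counts), " subjects)")
  cohort <- simulateCohort(config$counts, config$phenotypes,
                           config$geometry, seed = config$seed,
                           nPhases = config$nPhases)
  say("extracting strain metrics")
  metricsList <- lapply(cohort$subjects, extractMetrics)
  names(metricsList) <- cohort$manifest$id
  mesh <- cohort$subjects[[1]]@dynamics@mesh
  map <- assignAhaSegments(mesh, 16L)
  schema <- featureSchema(16L)
  say("building feature table (", nrow(schema), " features)")
  se <- buildFeatureTable(metricsList, cohort$manifest$label, map, schema)
  gsum <- do.call(rbind, lapply(seq_along(metricsList), function(i) {
    g <- globalSummary(metricsList[[i]])
    data.frame(id = cohort$manifest$id[i], label = cohort$manifest$label[i],
               combo = paste(g$direction, g$layer, sep = "."),
               amp = g$amp, ttp = g$ttp,
               thickness = attr(g, "thickness"),
               gls = longitudinalShortening(cohort$subjects[[i]]@dynamics))
  }))
  say("cross-validating the network classifier")
  netCfg <- networkConfig(nrow(schema), epochs = config$epochs,
                          lr = config$lr, seed = seeds$cv)
  cv <- crossValidate(se, netCfg)
  say("single-marker baselines")
  X <- SummarizedExperiment::assay(se, "features")
  y <- as.integer(se$label == "HCM")
  markers <- config$markers
  if (is.null(markers)) {
    thickRows <- grep("^edthickness", rownames(X), value = TRUE)
    globalThickness <- colMeans(X[thickRows, , drop = FALSE])
    baselines <- list(
      globalEDThickness = markerBaseline(globalThickness, y,
                                         nBoot = config$nBoot,
                                         seed = seeds$boot))
  } else {
    baselines <- lapply(setNames(markers, markers), function(m)
      markerBaseline(X[m, ], y, nBoot = config$nBoot, seed = seeds$boot))
  }
  manifest <- list(
    tool = "lvmda", version = as.character(utils::packageVersion("lvmda")),
    masterSeed = config$seed, stageSeeds = seeds,
    counts = as.list(config$counts), nSubjects = sum(config$counts),
    nFeatures = nrow(schema),
    subjectSeeds = cohort$manifest$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fcsv <- file.path(outDir, "features.csv")
    writeFeatureCSV(se, fcsv)
    cvJson <- file.path(outDir, "cv_result.json")
    jsonlite::write_json(list(metrics = cv@metrics, summary = cv@summary,
                              medianROC = cv@medianROC),
                         cvJson, digits = NA, auto_unbox = TRUE, na = "null")
    sums <- tools::md5sum(c(fcsv, cvJson))
    manifest$checksums <- as.list(setNames(unname(sums), basename(names(sums))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, na = "null")
  }
  list(cohortManifest = cohort$manifest, features = se, cv = cv,
       baselines = baselines, globalSummary = gsum, manifest = manifest)
}
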