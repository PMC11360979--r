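#' Blind a cohort manifest
#'
#' Shuffles the manifest rows with a seeded permutation, strips the
#' group column, and assigns anonymous identifiers, emulating the
#' randomized, category-blinded image analysis of the study design.
#' The blinding key (kept separately) inverts the operation exactly.
#'
#' @param manifest data.frame with at least `subject_id` and `group`
#'   columns; subject ids must be unique.
#' @param seed integer seed for the permutation.
#' @return list with `blinded` (shuffled manifest, no `group`, plus
#'   `blinded_id`) and `key` (`blinded_id`, `subject_id`, `group`,
#'   `original_row`, `seed`).
#' @export
blindManifest <- function(manifest, seed) {
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject ids in manifest")
  n <- nrow(manifest)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  blinded <- manifest[perm, setdiff(names(manifest),
                                    c("group", "blinded_id")),
                      drop = FALSE]
  blinded$blinded_id <- sprintf("B%03d", seq_len(n))
  rownames(blinded) <- NULL
  key <- data.frame(blinded_id = blinded$blinded_id,
                    subject_id = manifest$subject_id[perm],
                    group = manifest$group[perm],
                    original_row = perm,
                    seed = as.integer(seed))
  list(blinded = blinded, key = key)
}

#' Invert a blinded manifest
#'
#' Restores the group column and the original row order using the
#' blinding key; `unblindManifest(blindManifest(m, s)$blinded, key)`
#' reproduces `m` row for row.
#'
#' @param blinded blinded manifest from [blindManifest()].
#' @param key blinding key from [blindManifest()].
#' @return the manifest in original order with `group` restored.
#' @export
unblindManifest <- function(blinded, key) {
  m <- match(blinded$blinded_id, key$blinded_id)
  if (any(is.na(m))) stop("blinded ids not covered by the key")
  out <- blinded
  out$group <- key$group[m]
  out <- out[order(key$original_row[m]), ]
  out$blinded_id <- NULL
  rownames(out) <- NULL
  out[c("subject_id", "group",
        setdiff(names(out), c("subject_id", "group")))]
}

#' Analyze one stained image
#'
#' Runs the per-image pipeline: optical-density transform, stain
#' deconvolution, cell detection with DAB positivity, and peak/subpeak
#' ROI scoring.
#'
#' @param image file path (TIFF/PNG), an RGB array in `[0, 255]`, or a
#'   [SimulatedImage-class].
#' @param mpp microns per pixel (taken from a `SimulatedImage`
#'   automatically).
#' @param stains a [StainMatrix-class].
#' @param detection a [DetectionParams-class].
#' @param geometry a [ROIGeometry-class].
#' @param guard white-point guard passed to [rgbToOD()]; file input uses
#'   the 8-bit default.
#' @return list with `cells` (cell table), `rois` ([findPeakROIs()]
#'   rows), and `clampedFraction` (deconvolution clamp accounting).
#' @export
analyzeImage <- function(image, mpp = NULL, stains = hdabStainMatrix(),
                         detection = DetectionParams(),
                         geometry = ROIGeometry(), guard = 1) {
  if (is(image, "SimulatedImage")) {
    mpp <- image@mpp
    arr <- image@rgb
  } else if (is.character(image)) {
    arr <- unclass(EBImage::readImage(image)) * 255
    if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
      stop("image file must be RGB: ", image)
    arr <- arr[, , 1:3, drop = FALSE]
  } else {
    arr <- image
  }
  if (is.null(mpp)) stop("mpp calibration is required")
  od <- rgbToOD(arr, mpp = mpp, guard = guard)
  maps <- deconvolve(od, stains)
  cells <- detectCells(maps, detection, mpp = mpp)
  d <- dim(arr)
  rois <- findPeakROIs(cells, width = d[1] * mpp, height = d[2] * mpp,
                       geometry = geometry)
  list(cells = cells, rois = rois,
       clampedFraction = attr(maps, "clampedFraction"))
}

## ---------------------------------------------------------------------------
## YAML configuration
## ---------------------------------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' Converts a YAML file into validated parameter objects.  Recognized
#' top-level keys: `output_dir`, `mpp`, `manifest` (path to an existing
#' cohort manifest), `stains` (`hematoxylin`, `dab`, optional
#' `residual`, each 3 numbers), `detection`, `roi`, and `simulate`
#' (the synthetic-cohort block; every [SimulationParams-class] field is
#' addressable).
#'
#' @param path YAML file path.
#' @return list with elements `output_dir`, `mpp`, `manifest`, `stains`,
#'   `detection`, `geometry`, `simulate` (a `SimulationParams` or
#'   `NULL`), `alpha`.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pick <- function(block, key, default) {
    if (!is.null(block[[key]])) block[[key]] else default
  }
  stains <- if (is.null(cfg$stains)) hdabStainMatrix() else
    StainMatrix(cfg$stains$hematoxylin, cfg$stains$dab,
                cfg$stains$residual)
  ## pass through only the keys present so constructor defaults rule
  argsFrom <- function(block, keymap) {
    a <- list()
    for (k in names(keymap))
      if (!is.null(block[[k]])) a[[keymap[[k]]]] <- block[[k]]
    a
  }
  detection <- do.call(DetectionParams, argsFrom(cfg$detection, list(
    sigma_um = "sigma", nuclear_threshold = "nuclearThreshold",
    min_area_um2 = "minArea", max_area_um2 = "maxArea",
    dab_threshold = "dabThreshold", seed_separation_um = "seedSeparation")))
  roi <- cfg$roi
  geometry <- ROIGeometry(roiArea = pick(roi, "area_mm2", 0.1),
                          stride = pick(roi, "stride_um", NA_real_))
  simulate <- NULL
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    a <- argsFrom(s$patchiness, list(
      parent_intensity_mm2 = "parentIntensity",
      cluster_radius_um = "clusterRadius",
      offspring_mean = "offspringMean"))
    a <- c(a, argsFrom(s$stain, list(
      hematoxylin_od = "hematoxylinOD", dab_positive_od = "dabPositiveOD",
      dab_negative_od = "dabNegativeOD", noise_sd = "noiseSD",
      nucleus_radius_mean_um = "nucleusRadiusMean",
      nucleus_radius_sd_um = "nucleusRadiusSD")))
    if (!is.null(s$groups))
      a$groups <- do.call(rbind, lapply(s$groups, as.data.frame))
    img <- s$image
    if (!is.null(img))
      a$imageSize <- c(pick(img, "width_px", 2048L),
                       pick(img, "height_px", 2048L))
    a$mpp <- pick(img, "mpp", pick(cfg, "mpp", 0.5))
    a$roiArea <- pick(roi, "area_mm2", 0.1)
    a$seed <- pick(s, "seed", 1L)
    simulate <- do.call(SimulationParams, a)
  }
  list(output_dir = cfg$output_dir,
       mpp = pick(cfg, "mpp", 0.5),
       manifest = cfg$manifest,
       stains = stains, detection = detection, geometry = geometry,
       simulate = simulate,
       alpha = pick(cfg, "alpha", 0.05))
}

## ---------------------------------------------------------------------------
## end-to-end pipeline
## ---------------------------------------------------------------------------

#' Run the full cohort pipeline
#'
#' Optionally simulates a cohort, then for every manifest row (in
#' blinded presentation order) analyzes the image, writes the per-image
#' cell table, accumulates ROI results, unblinds, and builds the
#' group-comparison tables.  All intermediate CSVs, machine-readable
#' JSON results and a plain-text run log (parameters, seeds, clamping
#' and dropped-value accounting, package version) are written to the
#' output directory.  Blinding affects only presentation order and
#' labels, never the per-subject measurements, so blinded and unblinded
#' runs agree subject for subject.
#'
#' @param config configuration list from [readPipelineConfig()], or a
#'   path to a YAML file.
#' @param outputDir overrides `config$output_dir`.
#' @return Invisibly, a list with `rois` (per-subject ROI table,
#'   unblinded), `tables` (from [buildComparisonTable()]), `manifest`,
#'   and `log` (path).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- if (!is.null(outputDir)) outputDir else config$output_dir
  if (is.null(outDir)) stop("an output directory is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("DABquant %s pipeline run, %s",
                        as.character(utils::packageVersion("DABquant")),
                        format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  simDir <- NULL
  if (!is.null(config$simulate)) {
    simDir <- file.path(outDir, "simulated")
    sim <- simulateCohort(config$simulate, simDir, stains = config$stains)
    manifestPath <- file.path(simDir, "manifest.csv")
    logLines <- c(logLines,
                  sprintf("simulated cohort: %d subjects, master seed %d",
                          nrow(sim$manifest), config$simulate@seed))
  } else {
    manifestPath <- config$manifest
    if (is.null(manifestPath)) stop("config needs 'manifest' or 'simulate'")
  }
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  if (is.null(manifest$subject_id) || is.null(manifest$image_path))
    stop("manifest must have subject_id and image_path columns: ",
         manifestPath)
  baseDir <- dirname(manifestPath)

  ## analyze in blinded presentation order when available
  ord <- if (!is.null(manifest$blinded_id)) order(manifest$blinded_id)
         else seq_len(nrow(manifest))
  cellDir <- file.path(outDir, "cells")
  dir.create(cellDir, showWarnings = FALSE)
  roiRows <- list()
  clampMax <- 0
  for (i in ord) {
    path <- manifest$image_path[i]
    if (!file.exists(path)) path <- file.path(baseDir, manifest$image_path[i])
    if (!file.exists(path))
      stop("unreadable image for subject ", manifest$subject_id[i], ": ",
           manifest$image_path[i])
    res <- analyzeImage(path, mpp = config$mpp, stains = config$stains,
                        detection = config$detection,
                        geometry = config$geometry)
    utils::write.csv(res$cells,
                     file.path(cellDir,
                               paste0(manifest$subject_id[i], ".csv")),
                     row.names = FALSE)
    roiRows[[length(roiRows) + 1L]] <-
      cbind(data.frame(subject_id = manifest$subject_id[i],
                       group = manifest$group[i]), res$rois)
    clampMax <- max(clampMax, res$clampedFraction)
  }
  rois <- do.call(rbind, roiRows)
  rois <- rois[order(match(rois$subject_id, manifest$subject_id),
                     rois$roi_rank), ]
  rownames(rois) <- NULL
  utils::write.csv(rois, file.path(outDir, "rois.csv"), row.names = FALSE)
  logLines <- c(logLines,
                sprintf("analyzed %d images; max clamped-pixel fraction %.4f",
                        nrow(manifest), clampMax))

  tables <- NULL
  if (!is.null(manifest$group) && length(unique(manifest$group)) == 3L) {
    dropped <- 0
    withCallingHandlers(
      tables <- buildComparisonTable(rois, alpha = config$alpha),
      message = function(m) {
        logLines <<- c(logLines, sub("\n$", "", conditionMessage(m)))
        dropped <<- dropped + 1
        invokeRestart("muffleMessage")
      })
    utils::write.csv(tables$summaries,
                     file.path(outDir, "group_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$comparisons,
                     file.path(outDir, "group_comparisons.csv"),
                     row.names = FALSE)
    for (mode in unique(tables$summaries$mode))
      utils::write.csv(layoutModeTable(tables, mode),
                       file.path(outDir, paste0("table_", mode, ".csv")),
                       row.names = FALSE, na = "")
    jsonlite::write_json(tables, file.path(outDir, "results.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  } else {
    logLines <- c(logLines,
                  "group comparison skipped (three labeled groups required)")
  }
  logPath <- file.path(outDir, "run.log")
  writeLines(c(logLines, "parameters:",
               utils::capture.output(print(config$detection),
                                     print(config$geometry),
                                     print(config$stains))),
             logPath)
  invisible(list(rois = rois, tables = tables, manifest = manifest,
                 log = logPath))
}
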