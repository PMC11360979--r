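#' @import methods
NULL

## ---------------------------------------------------------------------------
## StainMatrix
## ---------------------------------------------------------------------------

#' Stain optical-density matrix for color deconvolution
#'
#' Holds the 3x3 matrix whose columns are the unit-norm optical-density
#' vectors of hematoxylin, DAB and a residual channel.  Multiplying a
#' per-pixel stain concentration vector by this matrix yields the pixel's
#' RGB optical density (Beer-Lambert mixing); [deconvolve()] applies its
#' inverse.
#'
#' @slot M numeric 3x3 matrix; columns are unit-norm OD vectors
#'   (hematoxylin, DAB, residual).
#'
#' @seealso [StainMatrix()], [hdabStainMatrix()], [deconvolve()]
#' @export
setClass("StainMatrix", representation(M = "matrix"))

setValidity("StainMatrix", function(object) {
  M <- object@M
  if (!is.numeric(M) || !all(dim(M) == c(3L, 3L)))
    return("stain matrix must be a numeric 3x3 matrix")
  if (any(!is.finite(M)))
    return("stain matrix must be finite")
  norms <- sqrt(colSums(M^2))
  if (any(abs(norms - 1) > 1e-9))
    return("each stain column must have Euclidean norm 1")
  ## chromogen vectors are absorbances and cannot be negative; the residual
  ## column is a geometric complement (cross product) and may be signed
  if (any(M[, 1:2] < -1e-12))
    return("hematoxylin and DAB columns must be non-negative")
  if (kappa(M, exact = TRUE) > 1e6)
    return("stain matrix is ill-conditioned (condition number > 1e6)")
  TRUE
})

#' Construct a stain matrix from stain vectors
#'
#' Columns are normalized to unit Euclidean norm.  When `residual` is
#' `NULL` it is completed as the normalized cross product of the
#' hematoxylin and DAB vectors, so the matrix is always invertible for
#' non-collinear stains.
#'
#' @param hematoxylin,dab,residual numeric length-3 OD vectors (R, G, B
#'   components); need not be pre-normalized.
#' @return A [StainMatrix-class] object.
#' @examples
#' StainMatrix(c(0.65, 0.70, 0.29), c(0.27, 0.57, 0.78))
#' @export
StainMatrix <- function(hematoxylin, dab, residual = NULL) {
  unit <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(!is.finite(v)))
      stop("stain vectors must be finite numeric vectors of length 3")
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("stain vector has zero norm")
    v / n
  }
  h <- unit(hematoxylin)
  d <- unit(dab)
  r <- if (is.null(residual)) {
    unit(c(h[2] * d[3] - h[3] * d[2],
           h[3] * d[1] - h[1] * d[3],
           h[1] * d[2] - h[2] * d[1]))
  } else unit(residual)
  M <- cbind(hematoxylin = h, dab = d, residual = r)
  rownames(M) <- c("R", "G", "B")
  new("StainMatrix", M = M)
}

#' Default H-DAB stain matrix
#'
#' The widely used reference vectors for the hematoxylin + DAB stain
#' combination (hematoxylin approximately (0.650, 0.704, 0.286), DAB
#' approximately (0.269, 0.568, 0.778)), with the residual completed as
#' their normalized cross product.
#'
#' @return A [StainMatrix-class] object.
#' @export
hdabStainMatrix <- function() {
  StainMatrix(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778))
}

#' @describeIn StainMatrix-class the underlying 3x3 matrix
#' @param x,... passed to the underlying method.
#' @export
setMethod("as.matrix", "StainMatrix", function(x, ...) x@M)

setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix (columns = unit OD vectors)\n")
  print(round(object@M, 4))
  invisible(object)
})

## ---------------------------------------------------------------------------
## ODImage
## ---------------------------------------------------------------------------

#' Optical-density image
#'
#' A per-pixel stack of RGB optical densities together with the
#' microns-per-pixel calibration.  Produced by [rgbToOD()]; consumed by
#' [deconvolve()].  The array is indexed `[x, y, channel]` following the
#' EBImage convention.
#'
#' @slot od numeric array `nx x ny x 3` of optical densities (>= 0).
#' @slot mpp microns per pixel (> 0).
#'
#' @seealso [rgbToOD()], [deconvolve()]
#' @export
setClass("ODImage", representation(od = "array", mpp = "numeric"))

setValidity("ODImage", function(object) {
  d <- dim(object@od)
  if (length(d) != 3L || d[3] != 3L)
    return("od must be an nx x ny x 3 array")
  if (any(!is.finite(object@od)))
    return("od values must be finite")
  if (any(object@od < 0))
    return("od values must be >= 0 (clamped)")
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
    return("mpp must be a single positive number")
  TRUE
})

#' @rdname ODImage-class
#' @param od numeric `nx x ny x 3` array of optical densities.
#' @param mpp microns per pixel.
#' @export
ODImage <- function(od, mpp) new("ODImage", od = od, mpp = as.numeric(mpp))

setMethod("show", "ODImage", function(object) {
  d <- dim(object@od)
  cat(sprintf("ODImage %d x %d px @ %.3g um/px (max OD %.3f)\n",
              d[1], d[2], object@mpp, max(object@od)))
  invisible(object)
})

#' @describeIn ODImage-class pixel dimensions of the image
#' @export
setMethod("dim", "ODImage", function(x) dim(x@od))

## ---------------------------------------------------------------------------
## DetectionParams
## ---------------------------------------------------------------------------

#' Cell detection and positivity parameters
#'
#' Parameters for [detectCells()].  All lengths are physical (microns),
#' independent of pixel size.  The DAB positivity threshold `dabThreshold`
#' is the "arbitrary limit" of the scoring protocol: a cell is positive
#' when its mean DAB optical density strictly exceeds it.
#'
#' @slot sigma Gaussian smoothing sigma in um applied to the
#'   hematoxylin + DAB sum before thresholding.
#' @slot nuclearThreshold OD threshold on the smoothed sum defining
#'   nuclear foreground.
#' @slot minArea minimum object area in um^2; smaller objects are
#'   discarded (also after watershed splitting).
#' @slot maxArea area in um^2 above which an object is split by
#'   watershed on the distance transform.
#' @slot dabThreshold positivity threshold tau on a cell's mean DAB OD.
#' @slot seedSeparation minimum separation of watershed seeds in um
#'   (nominally one nucleus radius).
#'
#' @seealso [detectCells()], [classifyPositive()]
#' @export
setClass("DetectionParams",
         representation(sigma = "numeric", nuclearThreshold = "numeric",
                        minArea = "numeric", maxArea = "numeric",
                        dabThreshold = "numeric", seedSeparation = "numeric"))

setValidity("DetectionParams", function(object) {
  sc <- function(v) length(v) == 1L && is.finite(v)
  if (!all(vapply(list(object@sigma, object@nuclearThreshold, object@minArea,
                       object@maxArea, object@seedSeparation),
                  sc, logical(1))))
    return("all parameters must be finite scalars")
  if (object@sigma < 0) return("sigma must be >= 0")
  if (object@nuclearThreshold < 0) return("nuclearThreshold must be >= 0")
  if (object@minArea <= 0 || object@minArea >= object@maxArea)
    return("need 0 < minArea < maxArea")
  if (length(object@dabThreshold) != 1L || is.na(object@dabThreshold) ||
      object@dabThreshold < 0)
    return("dabThreshold must be a scalar >= 0 (Inf allowed)")
  if (object@seedSeparation <= 0) return("seedSeparation must be > 0")
  TRUE
})

#' @rdname DetectionParams-class
#' @param sigma,nuclearThreshold,minArea,maxArea,dabThreshold,seedSeparation
#'   see the slot documentation.
#' @export
DetectionParams <- function(sigma = 1.0, nuclearThreshold = 0.2,
                            minArea = 16, maxArea = 40,
                            dabThreshold = 0.2, seedSeparation = 2.75) {
  new("DetectionParams", sigma = sigma, nuclearThreshold = nuclearThreshold,
      minArea = minArea, maxArea = maxArea, dabThreshold = dabThreshold,
      seedSeparation = seedSeparation)
}

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(paste0("DetectionParams: sigma %.3g um, nuclear OD > %.3g, ",
                     "area [%.3g, %.3g] um^2, tau = %.3g OD\n"),
              object@sigma, object@nuclearThreshold, object@minArea,
              object@maxArea, object@dabThreshold))
  invisible(object)
})

## ---------------------------------------------------------------------------
## ROIGeometry
## ---------------------------------------------------------------------------

#' Square region-of-interest geometry
#'
#' Defines the fixed-area square window used for peak/subpeak scoring and
#' the stride of the placement search grid.  The default area of 0.1 mm^2
#' gives a side length of sqrt(0.1) mm = 316.23 um.
#'
#' @slot roiArea window area in mm^2.
#' @slot stride search-grid stride in um; `NA` means one tenth of the
#'   window side.
#'
#' @seealso [findPeakROIs()], [roiMetrics()]
#' @export
setClass("ROIGeometry", representation(roiArea = "numeric", stride = "numeric"))

setValidity("ROIGeometry", function(object) {
  if (length(object@roiArea) != 1L || !is.finite(object@roiArea) ||
      object@roiArea <= 0)
    return("roiArea must be a single positive number (mm^2)")
  if (length(object@stride) != 1L ||
      (!is.na(object@stride) && object@stride <= 0))
    return("stride must be NA or a positive number (um)")
  TRUE
})

#' @rdname ROIGeometry-class
#' @param roiArea,stride see the slot documentation.
#' @export
ROIGeometry <- function(roiArea = 0.1, stride = NA_real_) {
  new("ROIGeometry", roiArea = roiArea, stride = as.numeric(stride))
}

#' @describeIn ROIGeometry-class side length of the square window in um
#' @param geometry a [ROIGeometry-class] object.
#' @export
roiSide <- function(geometry) sqrt(geometry@roiArea) * 1000

#' @describeIn ROIGeometry-class effective search stride in um
#' @export
roiStride <- function(geometry) {
  if (is.na(geometry@stride)) roiSide(geometry) / 10 else geometry@stride
}

setMethod("show", "ROIGeometry", function(object) {
  cat(sprintf("ROIGeometry: %.3g mm^2 square (side %.1f um), stride %.1f um\n",
              object@roiArea, roiSide(object), roiStride(object)))
  invisible(object)
})

## ---------------------------------------------------------------------------
## SimulationParams
## ---------------------------------------------------------------------------

#' Synthetic H-DAB cohort parameters
#'
#' Describes the study design emulated by the generator: subject groups
#' with per-subject positive-cell fractions (Beta, matched by moments to
#' the group mean/SD) and cell densities (Gamma, matched by moments), a
#' Thomas cluster process making positive cells spatially "patchy", and
#' the optical rendering model.
#'
#' Default group parameters follow the iNOS two-ROI percent-positive
#' summary of the emulated study: healthy volunteers (n = 15, positive
#' fraction 0.38 +/- 0.31), GERD (n = 21, 0.59 +/- 0.28) and EoE
#' (n = 20, 0.63 +/- 0.29).  The total cell density (2500 +/- 800 per
#' mm^2, equal across groups) is set at the scale where individual
#' nuclei remain resolvable at the default 0.5 um/px; group differences
#' are carried by the positive fraction.
#'
#' @slot groups data.frame with columns `label`, `n_subjects`,
#'   `positive_fraction_mean`, `positive_fraction_sd`,
#'   `cell_density_mean`, `cell_density_sd` (densities per mm^2).
#' @slot parentIntensity Thomas-process parent intensity per mm^2.
#' @slot clusterRadius Thomas-process dispersal sigma in um.
#' @slot offspringMean mean offspring per parent; `NA` derives it from
#'   the subject's positive intensity divided by `parentIntensity`.
#' @slot imageSize integer (width, height) in pixels.
#' @slot mpp microns per pixel.
#' @slot roiArea ROI area in mm^2 the images must accommodate (the image
#'   must hold at least four disjoint windows).
#' @slot hematoxylinOD nuclear hematoxylin OD amplitude (all cells).
#' @slot dabPositiveOD DAB OD amplitude of positive cells.
#' @slot dabNegativeOD background DAB OD of negative cells.
#' @slot noiseSD additive Gaussian pixel noise SD in OD space.
#' @slot nucleusRadiusMean,nucleusRadiusSD rendered nucleus radius
#'   distribution in um (normal, truncated at 0.5 um).
#' @slot seed master integer seed; per-subject seeds derive from it.
#'
#' @seealso [simulateCohort()], [sampleCellPositions()], [renderImage()]
#' @export
setClass("SimulationParams",
         representation(groups = "data.frame",
                        parentIntensity = "numeric",
                        clusterRadius = "numeric",
                        offspringMean = "numeric",
                        imageSize = "integer",
                        mpp = "numeric",
                        roiArea = "numeric",
                        hematoxylinOD = "numeric",
                        dabPositiveOD = "numeric",
                        dabNegativeOD = "numeric",
                        noiseSD = "numeric",
                        nucleusRadiusMean = "numeric",
                        nucleusRadiusSD = "numeric",
                        seed = "integer"))

setValidity("SimulationParams", function(object) {
  g <- object@groups
  need <- c("label", "n_subjects", "positive_fraction_mean",
            "positive_fraction_sd", "cell_density_mean", "cell_density_sd")
  if (!all(need %in% names(g)))
    return(paste("groups must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) < 1L) return("at least one group is required")
  if (anyDuplicated(g$label)) return("group labels must be unique")
  if (any(g$n_subjects < 1)) return("each group needs n_subjects >= 1")
  if (any(g$positive_fraction_mean < 0 | g$positive_fraction_mean > 1))
    return("positive_fraction_mean must lie in [0, 1]")
  if (any(g$positive_fraction_sd < 0 | g$cell_density_mean < 0 |
          g$cell_density_sd < 0))
    return("SDs and densities must be >= 0")
  pos <- function(v) length(v) == 1L && is.finite(v) && v >= 0
  if (!pos(object@parentIntensity) || object@parentIntensity <= 0)
    return("parentIntensity must be > 0")
  if (!pos(object@clusterRadius) || object@clusterRadius <= 0)
    return("clusterRadius must be > 0")
  if (!pos(object@hematoxylinOD) || !pos(object@dabPositiveOD) ||
      !pos(object@dabNegativeOD) || !pos(object@noiseSD))
    return("stain amplitudes and noise SD must be finite and >= 0")
  if (object@nucleusRadiusMean <= 0 || object@nucleusRadiusSD < 0)
    return("nucleus radius mean must be > 0 and SD >= 0")
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    return("imageSize must be two pixel dimensions >= 8")
  if (object@mpp <= 0) return("mpp must be > 0")
  areaMM2 <- prod(as.numeric(object@imageSize)) * object@mpp^2 / 1e6
  if (areaMM2 < 4 * object@roiArea)
    return(sprintf(paste0("image physical area (%.3g mm^2) must be at least ",
                          "4x the ROI area (%.3g mm^2) so that disjoint peak ",
                          "and subpeak windows fit"),
                   areaMM2, object@roiArea))
  ## Beta moment matching needs sd^2 < mean (1 - mean) unless degenerate
  v <- g$positive_fraction_sd^2
  bad <- g$positive_fraction_sd > 0 &
    v >= g$positive_fraction_mean * (1 - g$positive_fraction_mean)
  if (any(bad))
    return(sprintf("positive_fraction_sd of group '%s' is too large for a Beta distribution with mean %.3g",
                   g$label[which(bad)[1]],
                   g$positive_fraction_mean[which(bad)[1]]))
  TRUE
})

#' @rdname SimulationParams-class
#' @param groups,parentIntensity,clusterRadius,offspringMean,imageSize,mpp,roiArea,hematoxylinOD,dabPositiveOD,dabNegativeOD,noiseSD,nucleusRadiusMean,nucleusRadiusSD,seed
#'   see the slot documentation.
#' @export
SimulationParams <- function(groups = defaultGroups(),
                             parentIntensity = 10,
                             clusterRadius = 100,
                             offspringMean = NA_real_,
                             imageSize = c(2048L, 2048L),
                             mpp = 0.5,
                             roiArea = 0.1,
                             hematoxylinOD = 0.5,
                             dabPositiveOD = 0.6,
                             dabNegativeOD = 0.05,
                             noiseSD = 0.02,
                             nucleusRadiusMean = 2.75,
                             nucleusRadiusSD = 0.25,
                             seed = 1L) {
  new("SimulationParams", groups = as.data.frame(groups),
      parentIntensity = parentIntensity, clusterRadius = clusterRadius,
      offspringMean = as.numeric(offspringMean),
      imageSize = as.integer(imageSize), mpp = mpp, roiArea = roiArea,
      hematoxylinOD = hematoxylinOD, dabPositiveOD = dabPositiveOD,
      dabNegativeOD = dabNegativeOD, noiseSD = noiseSD,
      nucleusRadiusMean = nucleusRadiusMean,
      nucleusRadiusSD = nucleusRadiusSD, seed = as.integer(seed))
}

#' Default three-group cohort structure
#'
#' Healthy volunteers, GERD and EoE groups with positive-fraction
#' moments taken from the emulated study's iNOS percent-positive
#' summary; the shared cell density keeps nuclei resolvable by the
#' detector at the default pixel size.
#'
#' @return data.frame suitable for the `groups` slot of
#'   [SimulationParams-class].
#' @export
defaultGroups <- function() {
  data.frame(
    label = c("HV", "GERD", "EoE"),
    n_subjects = c(15L, 21L, 20L),
    positive_fraction_mean = c(0.38, 0.59, 0.63),
    positive_fraction_sd = c(0.31, 0.28, 0.29),
    cell_density_mean = c(2500, 2500, 2500),
    cell_density_sd = c(800, 800, 800),
    stringsAsFactors = FALSE)
}

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf("SimulationParams: %d group(s), image %d x %d px @ %.3g um/px, seed %d\n",
              nrow(object@groups), object@imageSize[1], object@imageSize[2],
              object@mpp, object@seed))
  cat(sprintf("  patchiness: %.3g parents/mm^2, cluster sigma %.3g um\n",
              object@parentIntensity, object@clusterRadius))
  print(object@groups, row.names = FALSE)
  invisible(object)
})
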