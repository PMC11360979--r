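#' Convert an RGB brightfield image to optical density
#'
#' Applies the Beer-Lambert inverse `OD = -log10((v + guard) / i0)` per
#' channel and clamps negative values (brighter than the white point) to
#' zero.  The default `guard = 1` protects 8-bit zeros; pass `guard = 0`
#' for continuous (unquantized) renders.
#'
#' @param image numeric array `nx x ny x 3` with values in `[0, 255]`,
#'   or an `EBImage::Image` in `[0, 1]` (rescaled internally).
#' @param mpp microns per pixel carried into the result.
#' @param i0 incident (white) intensity, default 255.
#' @param guard additive guard against `log10(0)`, default 1.
#' @return An [ODImage-class].
#' @examples
#' img <- array(200, dim = c(4, 4, 3))
#' rgbToOD(img, mpp = 0.5)
#' @export
rgbToOD <- function(image, mpp, i0 = 255, guard = 1) {
  if (inherits(image, "Image")) image <- unclass(image) * 255
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image must be an nx x ny x 3 RGB array")
  if (any(image < 0 | image > 255))
    stop("pixel values must lie in [0, 255]")
  od <- -log10((image + guard) / i0)
  od[od < 0] <- 0
  ODImage(od, mpp)
}

#' Unmix stain concentrations by color deconvolution
#'
#' Inverts the stain OD mixing matrix per pixel, recovering hematoxylin,
#' DAB and residual concentration maps.  Negative concentrations (noise
#' pushing a pixel outside the stain simplex) are clamped to zero; the
#' fraction of affected pixels is reported in the `clampedFraction`
#' attribute of the returned list.
#'
#' @param od an [ODImage-class].
#' @param stains a [StainMatrix-class]; default [hdabStainMatrix()].
#' @return Named list of matrices `hematoxylin`, `dab`, `residual`
#'   (each `nx x ny`), with attributes `clampedFraction` and `mpp`.
#' @examples
#' od <- rgbToOD(array(128, dim = c(2, 2, 3)), mpp = 0.5)
#' maps <- deconvolve(od)
#' attr(maps, "clampedFraction")
#' @export
deconvolve <- function(od, stains = hdabStainMatrix()) {
  stopifnot(is(od, "ODImage"), is(stains, "StainMatrix"))
  validObject(stains)
  M <- as.matrix(stains)
  d <- dim(od@od)
  odMat <- matrix(od@od, ncol = 3L)          # pixels x channels
  conc <- odMat %*% t(solve(M))              # solves M c = od per pixel
  nneg <- sum(conc < -1e-12)
  clampedFraction <- nneg / length(conc)
  conc[conc < 0] <- 0
  out <- list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
              dab         = matrix(conc[, 2], d[1], d[2]),
              residual    = matrix(conc[, 3], d[1], d[2]))
  attr(out, "clampedFraction") <- clampedFraction
  attr(out, "mpp") <- od@mpp
  out
}

#' Export a concentration map as a 32-bit float TIFF
#'
#' Debug output for inspecting deconvolved stain maps at full numeric
#' precision in external viewers.  Float TIFF storage covers `[0, 1]`,
#' so pixel values are written as `concentration / scale`; multiply by
#' `scale` when reading the file back.
#'
#' @param map single-channel matrix (e.g. `deconvolve(od)$dab`).
#' @param path output file path.
#' @param scale full-scale concentration in OD units (default 4, well
#'   above any physical H-DAB concentration); values beyond it clip.
#' @return the path, invisibly.
#' @export
writeConcentrationMap <- function(map, path, scale = 4) {
  stopifnot(is.matrix(map), scale > 0)
  ## tiff expects row-major (y, x) orientation
  tiff::writeTIFF(pmin(t(map) / scale, 1), path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}
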