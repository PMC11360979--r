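#' Detect cells and classify DAB positivity
#'
#' Segments nuclei from deconvolved stain maps and classifies each cell
#' as DAB-positive when its mean DAB optical density strictly exceeds
#' the positivity threshold.  Detection runs on the hematoxylin + DAB
#' sum, so strongly DAB-stained cells that mask the counterstain are
#' still counted as cells.
#'
#' The pipeline: Gaussian smoothing of the sum map, thresholding at the
#' nuclear OD threshold, hole filling, removal of objects below the
#' minimum area, and splitting of objects above the maximum area using
#' peaks of the distance transform as seeds (minimum seed separation
#' about one nucleus radius) with marker-controlled region growing.
#' Centroids are intensity-weighted for unsplit objects (exact for an
#' isolated disc) and placed at the distance-transform peak for split
#' pieces.  Per-object mean DAB and hematoxylin ODs come from the
#' unsmoothed maps.  Objects touching the image border are retained;
#' ROI membership is decided later by centroid.
#'
#' @param maps deconvolved concentration maps as returned by
#'   [deconvolve()] (list with `hematoxylin` and `dab` matrices).
#' @param params a [DetectionParams-class].
#' @param mpp microns per pixel; defaults to the `mpp` attribute of
#'   `maps` when present.
#' @return data.frame with one row per detected cell: `x_um`, `y_um`
#'   (centroid), `area_um2`, `dab_od`, `hema_od`, `positive`.
#' @seealso [classifyPositive()]
#' @export
detectCells <- function(maps, params = DetectionParams(),
                        mpp = attr(maps, "mpp")) {
  stopifnot(is(params, "DetectionParams"))
  validObject(params)
  if (is.null(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("mpp must be a single positive number")
  hema <- maps$hematoxylin
  dab <- maps$dab
  if (is.null(hema) || is.null(dab) || !identical(dim(hema), dim(dab)))
    stop("maps must contain hematoxylin and dab matrices of equal shape")

  total <- hema + dab
  sigmaPx <- params@sigma / mpp
  smooth <- if (sigmaPx > 0) EBImage::gblur(total, sigma = sigmaPx) else total
  mask <- smooth > params@nuclearThreshold
  if (!any(mask)) return(emptyCellTable())
  mask <- EBImage::fillHull(mask)

  lab <- EBImage::bwlabel(mask)
  nx <- dim(lab)[1]
  minPx <- params@minArea / mpp^2
  maxPx <- params@maxArea / mpp^2
  areasPx <- tabulate(lab)
  keep <- which(areasPx >= minPx)
  small <- keep[areasPx[keep] <= maxPx]
  big <- keep[areasPx[keep] > maxPx]

  objStats <- function(idx, labs, weights = NULL) {
    npx <- as.numeric(rowsum(rep(1, length(idx)), labs))
    w <- if (is.null(weights)) rep(1, length(idx)) else weights
    sw <- as.numeric(rowsum(w, labs))
    xi <- ((idx - 1L) %% nx) + 1L
    yi <- ((idx - 1L) %/% nx) + 1L
    data.frame(
      x_um = as.numeric(rowsum((xi - 0.5) * w, labs)) / sw * mpp,
      y_um = as.numeric(rowsum((yi - 0.5) * w, labs)) / sw * mpp,
      area_um2 = npx * mpp^2,
      dab_od = as.numeric(rowsum(dab[idx], labs)) / npx,
      hema_od = as.numeric(rowsum(hema[idx], labs)) / npx)
  }

  cells <- emptyCellTable()[0, 1:5]
  if (length(small)) {
    m <- array(match(lab, small), dim = dim(lab))
    idx <- which(!is.na(m))
    cells <- objStats(idx, m[idx], weights = total[idx])
  }

  if (length(big)) {
    bigMask <- array(lab %in% big, dim = dim(lab))
    dm <- EBImage::distmap(bigMask)
    ## seeds: distance-transform peaks at least ~0.8 seed separations
    ## apart (matching the resolvable nucleus spacing), interior only
    sepPx <- max(2L, as.integer(round(0.8 * params@seedSeparation / mpp)))
    dil <- EBImage::dilate(dm, EBImage::makeBrush(2L * sepPx + 1L, "disc"))
    peaks <- (dm == dil) & bigMask & (dm >= 2)
    if (any(peaks)) {
      seedLab <- EBImage::bwlabel(peaks)
      ## large lambda makes propagation spatially dominated, so pieces
      ## meet at the equidistance line between seeds
      ws <- EBImage::propagate(dm, seedLab, mask = bigMask, lambda = 1000)
      wsv <- as.integer(ws)
      wa <- tabulate(wsv)
      idx <- which(wsv > 0L)
      labs <- wsv[idx]
      ok <- wa >= minPx
      pieces <- objStats(idx, labs)
      ## replace piece centroids with their seed-plateau centroids
      sidx <- which(peaks)
      slab <- wsv[sidx]
      sxi <- ((sidx - 1L) %% nx) + 1L
      syi <- ((sidx - 1L) %/% nx) + 1L
      nsp <- as.numeric(rowsum(rep(1, length(sidx)), slab))
      seedx <- as.numeric(rowsum(sxi - 0.5, slab)) / nsp * mpp
      seedy <- as.numeric(rowsum(syi - 0.5, slab)) / nsp * mpp
      pieceIds <- as.integer(rownames(rowsum(rep(1, length(idx)), labs)))
      seedIds <- as.integer(rownames(rowsum(rep(1, length(sidx)), slab)))
      mseed <- match(pieceIds, seedIds)
      hasSeed <- !is.na(mseed)
      pieces$x_um[hasSeed] <- seedx[mseed[hasSeed]]
      pieces$y_um[hasSeed] <- seedy[mseed[hasSeed]]
      cells <- rbind(cells, pieces[ok[pieceIds], ])
    }
  }
  if (nrow(cells) == 0L) return(emptyCellTable())
  rownames(cells) <- NULL
  classifyPositive(cells, params@dabThreshold)
}

emptyCellTable <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0),
             dab_od = numeric(0), hema_od = numeric(0),
             positive = logical(0))
}

#' Set DAB positivity flags
#'
#' A cell is positive when its mean DAB optical density strictly exceeds
#' the threshold `tau` ("exceeding" is a strict inequality).  The
#' operation is idempotent and uses no other inputs.
#'
#' @param cells data.frame with a `dab_od` column.
#' @param tau positivity threshold (>= 0; `Inf` marks every cell
#'   negative, `0` marks every cell with any DAB signal positive).
#' @return `cells` with the `positive` logical column set.
#' @export
classifyPositive <- function(cells, tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 0)
    stop("tau must be a single number >= 0")
  cells$positive <- cells$dab_od > tau
  cells
}
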