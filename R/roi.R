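#' Score a square window by positive-cell count
#'
#' Counts the positive cells whose centroid lies in the half-open
#' window `[x, x + side) x [y, y + side)`.  This count is the search's
#' scoring function: at fixed window area it is proportional to
#' positives per mm^2, the "most affected" criterion.
#'
#' @param cells cell table with `x_um`, `y_um`, `positive`.
#' @param x,y window origin in um.
#' @param side window side in um.
#' @return integer count of positive cells in the window.
#' @export
scoreWindow <- function(cells, x, y, side) {
  sum(cells$positive &
        cells$x_um >= x & cells$x_um < x + side &
        cells$y_um >= y & cells$y_um < y + side)
}

## search-grid origins along one axis: stride steps plus a flush window at
## the far edge so the whole field is coverable
windowOrigins <- function(extent, side, stride) {
  if (extent < side - 1e-9)
    stop("image extent (", extent, " um) is smaller than the ROI side (",
         side, " um)")
  xs <- seq(0, extent - side + 1e-9, by = stride)
  sort(unique(c(xs, extent - side)))
}

## counts of positives and of all cells for every (xs, ys) window origin;
## returns two length(xs) x length(ys) matrices
countWindows <- function(cells, xs, ys, side) {
  eps <- 1e-9
  nposM <- matrix(0L, length(xs), length(ys))
  ncellM <- matrix(0L, length(xs), length(ys))
  if (nrow(cells)) {
    xAll <- cells$x_um
    for (i in seq_along(xs)) {
      inx <- xAll >= xs[i] & xAll < xs[i] + side
      if (!any(inx)) next
      yAllS <- sort(cells$y_um[inx])
      yPosS <- sort(cells$y_um[inx & cells$positive])
      ncellM[i, ] <- findInterval(ys + side - eps, yAllS) -
        findInterval(ys - eps, yAllS)
      if (length(yPosS))
        nposM[i, ] <- findInterval(ys + side - eps, yPosS) -
          findInterval(ys - eps, yPosS)
    }
  }
  list(npos = nposM, ncell = ncellM)
}

#' Metrics for one square ROI
#'
#' Membership is by cell centroid within the half-open window, so a
#' tiling of windows assigns every cell to exactly one.  With no cells
#' in the window the percent-positive value is `NA` (flagged missing)
#' while positives per mm^2 is 0.
#'
#' @param cells cell table with `x_um`, `y_um`, `positive`.
#' @param x,y window origin in um.
#' @param geometry a [ROIGeometry-class].
#' @return one-row data.frame: `x_um`, `y_um`, `side_um`, `n_cells`,
#'   `n_positive`, `pos_percent`, `pos_per_mm2`.
#' @export
roiMetrics <- function(cells, x, y, geometry = ROIGeometry()) {
  stopifnot(is(geometry, "ROIGeometry"))
  side <- roiSide(geometry)
  inw <- cells$x_um >= x & cells$x_um < x + side &
    cells$y_um >= y & cells$y_um < y + side
  n <- sum(inw)
  np <- sum(inw & cells$positive)
  data.frame(x_um = x, y_um = y, side_um = side,
             n_cells = n, n_positive = np,
             pos_percent = if (n > 0) 100 * np / n else NA_real_,
             pos_per_mm2 = np / geometry@roiArea)
}

#' Find the peak and subpeak ROIs
#'
#' Grid search over window origins (stride `roiStride(geometry)`, plus
#' flush windows at the far edges) maximizing the positive-cell count.
#' Ties are broken by higher percent positive, then by the smallest
#' (y, x) origin.  The subpeak is the best window with zero area overlap
#' with the peak window, operationalizing the "next most affected"
#' region as a distinct one.  When both ROIs are requested the peak is
#' the best-scoring window that still admits a zero-overlap partner, so
#' the returned pair is the jointly best disjoint pair; on fields at
#' least three window sides long this coincides with the unconstrained
#' maximum.
#'
#' @param cells cell table with `x_um`, `y_um`, `positive`.
#' @param width,height image extent in um.
#' @param geometry a [ROIGeometry-class].
#' @param k number of ROIs: 1 (peak only) or 2 (peak and subpeak).
#' @return data.frame of `k` [roiMetrics()] rows with a leading
#'   `roi_rank` column (1 = peak, 2 = subpeak).
#' @export
findPeakROIs <- function(cells, width, height, geometry = ROIGeometry(),
                         k = 2) {
  stopifnot(is(geometry, "ROIGeometry"), k %in% c(1, 2))
  side <- roiSide(geometry)
  stride <- roiStride(geometry)
  xs <- windowOrigins(width, side, stride)
  ys <- windowOrigins(height, side, stride)
  cnt <- countWindows(cells, xs, ys, side)

  grid <- expand.grid(xi = seq_along(xs), yi = seq_along(ys))
  grid$x <- xs[grid$xi]
  grid$y <- ys[grid$yi]
  grid$npos <- cnt$npos[cbind(grid$xi, grid$yi)]
  grid$ncell <- cnt$ncell[cbind(grid$xi, grid$yi)]
  grid$pct <- ifelse(grid$ncell > 0, grid$npos / grid$ncell, -1)

  pickBest <- function(g) g[order(-g$npos, -g$pct, g$y, g$x)[1L], ]
  if (k == 2) {
    ## a window admits a zero-overlap partner when some grid origin lies
    ## at least one side away along x or along y
    eps <- 1e-9
    awayX <- grid$x >= side - eps | grid$x <= max(xs) - side + eps
    awayY <- grid$y >= side - eps | grid$y <= max(ys) - side + eps
    feasible <- awayX | awayY
    if (!any(feasible))
      stop("image too small for a subpeak window disjoint from the peak")
    peak <- pickBest(grid[feasible, ])
  } else {
    peak <- pickBest(grid)
  }
  out <- cbind(roi_rank = 1L, roiMetrics(cells, peak$x, peak$y, geometry))
  if (k == 2) {
    disjoint <- abs(grid$x - peak$x) >= side - 1e-9 |
      abs(grid$y - peak$y) >= side - 1e-9
    sub <- pickBest(grid[disjoint, ])
    out <- rbind(out,
                 cbind(roi_rank = 2L, roiMetrics(cells, sub$x, sub$y,
                                                 geometry)))
  }
  rownames(out) <- NULL
  out
}

#' Per-subject peak/subpeak summary
#'
#' Combines the peak and subpeak ROI rows into the three per-subject
#' analysis values for each metric: the two separate readings, the peak
#' reading, and their arithmetic mean (a missing percent propagates to
#' the mean).
#'
#' @param rois data.frame from [findPeakROIs()] with `roi_rank` 1 and 2.
#' @return one-row data.frame with `peak_*`, `subpeak_*` and `mean_*`
#'   columns for `pos_percent` and `pos_per_mm2`.
#' @export
subjectSummary <- function(rois) {
  stopifnot(all(c(1L, 2L) %in% rois$roi_rank))
  pk <- rois[rois$roi_rank == 1L, ]
  sp <- rois[rois$roi_rank == 2L, ]
  data.frame(
    peak_pos_percent = pk$pos_percent,
    subpeak_pos_percent = sp$pos_percent,
    mean_pos_percent = (pk$pos_percent + sp$pos_percent) / 2,
    peak_pos_per_mm2 = pk$pos_per_mm2,
    subpeak_pos_per_mm2 = sp$pos_per_mm2,
    mean_pos_per_mm2 = (pk$pos_per_mm2 + sp$pos_per_mm2) / 2)
}
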