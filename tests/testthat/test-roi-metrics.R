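randomCells <- function(n, width, height, pPos = 0.5, seed = 1) {
  withr::with_seed(seed, data.frame(
    x_um = runif(n, 0, width), y_um = runif(n, 0, height),
    positive = runif(n) < pPos))
}

test_that("ROI metrics follow their defining arithmetic", {
  geom <- ROIGeometry(roiArea = 0.1)
  side <- roiSide(geom)
  expect_equal(side, sqrt(0.1) * 1000)
  cells <- data.frame(x_um = seq(10, 100, 10), y_um = seq(10, 100, 10),
                      positive = c(rep(TRUE, 4), rep(FALSE, 6)))
  r <- roiMetrics(cells, 0, 0, geom)
  expect_identical(r$n_cells, 10L)
  expect_identical(r$n_positive, 4L)
  expect_equal(r$pos_percent, 40)
  expect_identical(r$pos_per_mm2, 4 / 0.1)   # exact
  # empty window: percent flagged missing, density exactly zero
  r0 <- roiMetrics(cells[0, ], 0, 0, geom)
  expect_true(is.na(r0$pos_percent))
  expect_identical(r0$pos_per_mm2, 0 / 0.1)
  # half-open membership: a centroid on the far edge is excluded
  edge <- data.frame(x_um = c(0, side), y_um = c(0, 0),
                     positive = c(TRUE, TRUE))
  expect_identical(roiMetrics(edge, 0, 0, geom)$n_cells, 1L)
})

test_that("peak and subpeak capture two separated clusters", {
  geom <- ROIGeometry(roiArea = 0.01)   # side 100 um
  mk <- function(n, cx, cy, seed) withr::with_seed(seed, data.frame(
    x_um = runif(n, cx - 30, cx + 30), y_um = runif(n, cy - 30, cy + 30),
    positive = TRUE))
  cells <- rbind(mk(30, 60, 60, 1), mk(20, 260, 260, 2))
  rois <- findPeakROIs(cells, width = 320, height = 320, geometry = geom)
  expect_identical(rois$n_positive, c(30L, 20L))
  side <- roiSide(geom)
  expect_true(abs(rois$x_um[1] - rois$x_um[2]) >= side - 1e-9 ||
                abs(rois$y_um[1] - rois$y_um[2]) >= side - 1e-9)
})

test_that("with no positives the peak falls on the first grid window", {
  cells <- data.frame(x_um = c(50, 150), y_um = c(50, 150),
                      positive = FALSE)
  rois <- findPeakROIs(cells, 300, 300, ROIGeometry(0.01))
  expect_identical(rois$x_um[1], 0)
  expect_identical(rois$y_um[1], 0)
  expect_identical(rois$n_positive, c(0L, 0L))
})

test_that("1-px-stride grid search equals the exhaustive oracle", {
  geom <- ROIGeometry(roiArea = 0.01, stride = 1)   # side 100 um, 1 um grid
  # unconstrained peak on a compact field
  for (seed in 1:3) {
    cells <- randomCells(200, 200, 200, seed = seed)
    rois <- findPeakROIs(cells, 200, 200, geometry = geom, k = 1)
    expect_identical(rois$n_positive[1],
                     as.integer(bruteForcePeak(cells, 200, 200,
                                               roiSide(geom), stride = 1)))
  }
  # on fields of three window sides the disjoint-pair constraint is
  # vacuous and the full peak/subpeak search matches the oracle
  cells <- randomCells(250, 320, 320, seed = 11)
  rois <- findPeakROIs(cells, 320, 320, geometry = geom)
  expect_identical(rois$n_positive[1],
                   as.integer(bruteForcePeak(cells, 320, 320,
                                             roiSide(geom), stride = 1)))
})

test_that("default stride stays close to the exhaustive optimum", {
  # clustered positives (the regime peak scoring is designed for)
  geom <- ROIGeometry(roiArea = 0.01)            # stride = side / 10
  mkClustered <- function(seed, W = 300) withr::with_seed(seed, {
    ctr <- matrix(runif(6, 50, W - 50), ncol = 2)
    npos <- c(60, 35, 20)
    pos <- do.call(rbind, lapply(1:3, function(k) data.frame(
      x_um = pmin(pmax(rnorm(npos[k], ctr[k, 1], 40), 0), W - 1e-6),
      y_um = pmin(pmax(rnorm(npos[k], ctr[k, 2], 40), 0), W - 1e-6),
      positive = TRUE)))
    rbind(pos, data.frame(x_um = runif(150, 0, W),
                          y_um = runif(150, 0, W), positive = FALSE))
  })
  ratios <- vapply(1:40, function(seed) {
    cells <- mkClustered(seed)
    got <- findPeakROIs(cells, 300, 300, geometry = geom)$n_positive[1]
    opt <- bruteForcePeak(cells, 300, 300, roiSide(geom), stride = 1)
    got / max(opt, 1L)
  }, numeric(1))
  # aggregate capture of the exhaustive optimum
  expect_gte(mean(ratios), 0.95)
  expect_gte(min(ratios), 0.85)
})

test_that("peak dominates the mean of two which dominates the subpeak", {
  geom <- ROIGeometry(roiArea = 0.01)
  for (seed in 1:10) {
    cells <- randomCells(120, 250, 250, pPos = 0.4, seed = seed)
    rois <- findPeakROIs(cells, 250, 250, geometry = geom)
    s <- subjectSummary(rois)
    expect_gte(rois$n_positive[1], rois$n_positive[2])
    expect_gte(s$peak_pos_per_mm2, s$mean_pos_per_mm2)
    expect_gte(s$mean_pos_per_mm2, s$subpeak_pos_per_mm2)
  }
})

test_that("a field too small for a disjoint subpeak fails loudly", {
  cells <- data.frame(x_um = 75, y_um = 75, positive = TRUE)
  expect_error(findPeakROIs(cells, 150, 150, ROIGeometry(0.01)),
               "too small")
  # but the peak alone is available on the same field
  one <- findPeakROIs(cells, 150, 150, ROIGeometry(0.01), k = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_positive, 1L)
})

test_that("metrics are stable under a change of pixel size", {
  # the same physical scene rendered at 0.5 and 1.0 um/px must yield
  # closely matching ROI readings (scoring operates in physical units)
  pA <- smallParams(npix = 440L, mpp = 0.5, noiseSD = 0, roiArea = 0.01)
  pB <- smallParams(npix = 220L, mpp = 1.0, noiseSD = 0, roiArea = 0.01)
  truth <- withr::with_seed(9L, data.frame(
    x_um = runif(120, 5, 215), y_um = runif(120, 5, 215),
    radius_um = 2.75, positive = runif(120) < 0.4))
  resA <- analyzeImage(renderImage(truth, pA), geometry = ROIGeometry(0.01))
  resB <- analyzeImage(renderImage(truth, pB), geometry = ROIGeometry(0.01))
  expect_lt(abs(nrow(resA$cells) - nrow(resB$cells)) / nrow(resA$cells),
            0.05)
  expect_lt(abs(resA$rois$n_positive[1] - resB$rois$n_positive[1]) /
              max(resA$rois$n_positive[1], 1L), 0.1)
})
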