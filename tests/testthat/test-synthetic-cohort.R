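test_that("zero and unit positive fractions give pure point processes", {
  p0 <- smallParams(f = 0, d = 1500, npix = 300L)
  c0 <- sampleCellPositions(p0, "G", 101L)
  expect_gt(nrow(c0), 0)
  expect_true(all(!c0$positive))

  p1 <- smallParams(f = 1, d = 800, npix = 300L)
  c1 <- sampleCellPositions(p1, "G", 101L)
  expect_gt(nrow(c1), 0)
  expect_true(all(c1$positive))
})

test_that("sampling and rendering are deterministic under a fixed seed", {
  p <- smallParams(f = 0.4, d = 1200, npix = 200L, roiArea = 2e-3)
  a <- sampleCellPositions(p, "G", 7L)
  b <- sampleCellPositions(p, "G", 7L)
  expect_identical(a, b)
  ia <- renderImage(a, p, seed = 55L)
  ib <- renderImage(b, p, seed = 55L)
  expect_identical(ia@rgb, ib@rgb)
  # different subject seeds give different point sets
  expect_false(identical(a$x_um,
                         sampleCellPositions(p, "G", 8L)$x_um))
})

test_that("ground truth is internally consistent", {
  p <- smallParams(f = 0.3, d = 2000, npix = 300L, roiArea = 5e-3)
  cells <- sampleCellPositions(p, "G", 31L)
  img <- renderImage(cells, p, seed = 32L)
  expect_identical(nrow(img@truth), nrow(cells))
  expect_identical(img@subject$true_fraction,
                   sum(cells$positive) / nrow(cells))
  areaMM2 <- prod(dim(img@rgb)[1:2]) * p@mpp^2 / 1e6
  expect_equal(trueDensity(img), nrow(cells) / areaMM2)
  # the hard-core rule held: no pair closer than 0.8 x radius sum
  if (nrow(cells) > 1) {
    D <- as.matrix(dist(cells[, c("x_um", "y_um")]))
    lim <- 0.8 * outer(cells$radius_um, cells$radius_um, "+")
    diag(D) <- Inf
    expect_true(all(D >= lim - 1e-9))
  }
})

test_that("empty point sets render as a white image", {
  p <- smallParams(npix = 64L, noiseSD = 0, roiArea = 2e-4)
  img <- renderImage(emptyCells <- data.frame(x_um = numeric(0),
                                              y_um = numeric(0),
                                              radius_um = numeric(0),
                                              positive = logical(0)), p)
  expect_true(all(img@rgb == 255))
})

test_that("subject positive fractions match the configured Beta moments", {
  f <- withr::with_seed(2026L, DABquant:::rbetaMoments(1000, 0.63, 0.29))
  expect_true(all(f >= 0 & f <= 1))
  expect_lt(abs(mean(f) - 0.63), 0.03)
  expect_lt(abs(sd(f) - 0.29), 0.03)
  d <- withr::with_seed(2026L, DABquant:::rgammaMoments(1000, 2500, 800))
  expect_lt(abs(mean(d) / 2500 - 1), 0.05)
  # degenerate SDs give constants
  expect_identical(DABquant:::rbetaMoments(5, 0.4, 0), rep(0.4, 5))
  expect_identical(DABquant:::rgammaMoments(5, 100, 0), rep(100, 5))
})

test_that("a very wide cluster kernel is indistinguishable from Poisson", {
  # Clark-Evans index of the positives against a Monte-Carlo Poisson
  # envelope; tiny nuclei make the hard-core correction negligible
  p <- smallParams(f = 1, d = 400, npix = 1000L, mpp = 0.5,
                   roiArea = 6e-3, nucleusRadiusMean = 0.6,
                   nucleusRadiusSD = 0, parentIntensity = 10,
                   clusterRadius = 1000)
  cells <- sampleCellPositions(p, "G", 909L)
  ce <- function(x, y, W) {
    D <- as.matrix(dist(cbind(x, y)))
    diag(D) <- Inf
    mean(apply(D, 1, min)) / (0.5 * sqrt(W^2 / length(x)))
  }
  W <- 500
  obs <- ce(cells$x_um, cells$y_um, W)
  env <- withr::with_seed(77L, vapply(1:39, function(i) {
    n <- rpois(1, 400 * W^2 / 1e6)
    ce(runif(n, 0, W), runif(n, 0, W), W)
  }, numeric(1)))
  expect_gte(obs, min(env))
  expect_lte(obs, max(env))
})

test_that("densities beyond the packing limit fail with a named error", {
  p <- smallParams(f = 0, d = 2e5, npix = 200L, roiArea = 2e-3)
  expect_error(sampleCellPositions(p, "G", 5L), "cell_density_mean")
})

test_that("a simulated cohort has one manifest row per subject", {
  p <- tinyCohortParams(nPerGroup = 2L, npix = 160L)
  g <- p@groups; g$n_subjects <- c(15L, 21L, 20L); p@groups <- g
  sim <- simulateCohort(p, dir = tempfile(), writeImages = FALSE)
  expect_identical(nrow(sim$manifest), 56L)
  expect_identical(nrow(sim$truth), 56L)
  expect_false("group" %in% names(sim$blinded))
  expect_setequal(sim$blinded$subject_id, sim$manifest$subject_id)
  # same master seed reproduces the cohort exactly
  sim2 <- simulateCohort(p, dir = tempfile(), writeImages = FALSE)
  expect_identical(sim$manifest, sim2$manifest)
  expect_identical(sim$truth, sim2$truth)
})
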