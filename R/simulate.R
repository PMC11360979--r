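## Synthetic H-DAB cohort generator: subject-level parameters are drawn from
## moment-matched Beta (positive fraction) and Gamma (cell density)
## distributions; negative cells form a homogeneous Poisson process and
## positive cells a Thomas cluster process ("patchy" staining); nuclei are
## rendered as absorbing discs through the Beer-Lambert forward model.

## Beta draw matched to a mean/SD; sd = 0 degenerates to the constant mean
rbetaMoments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop(sprintf("sd %.3g is too large for a Beta with mean %.3g", sd, mean))
  nu <- mean * (1 - mean) / v - 1
  pmin(pmax(stats::rbeta(n, mean * nu, (1 - mean) * nu), 0), 1)
}

## Gamma draw matched to a mean/SD; sd = 0 degenerates to the constant mean
rgammaMoments <- function(n, mean, sd) {
  if (sd == 0 || mean == 0) return(rep(mean, n))
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

## ---------------------------------------------------------------------------
## hard-core placement with a spatial hash grid
## ---------------------------------------------------------------------------

newPlacement <- function(W, H, cellSize, capacity) {
  e <- new.env(parent = emptyenv())
  e$ngx <- max(1L, as.integer(ceiling(W / cellSize)))
  e$ngy <- max(1L, as.integer(ceiling(H / cellSize)))
  e$cs <- cellSize
  e$buckets <- vector("list", e$ngx * e$ngy)
  e$x <- numeric(capacity); e$y <- numeric(capacity)
  e$r <- numeric(capacity); e$n <- 0L
  e
}

bucketOf <- function(e, x, y) {
  gx <- min(e$ngx, max(1L, as.integer(x / e$cs) + 1L))
  gy <- min(e$ngy, max(1L, as.integer(y / e$cs) + 1L))
  c(gx, gy)
}

## TRUE when (x, y, r) is closer than 0.8 x the radius sum to an accepted
## nucleus (the reject-and-resample overlap rule)
conflicts <- function(e, x, y, r) {
  g <- bucketOf(e, x, y)
  for (gx in max(1L, g[1] - 1L):min(e$ngx, g[1] + 1L))
    for (gy in max(1L, g[2] - 1L):min(e$ngy, g[2] + 1L)) {
      ids <- e$buckets[[(gy - 1L) * e$ngx + gx]]
      if (is.null(ids)) next
      d2 <- (e$x[ids] - x)^2 + (e$y[ids] - y)^2
      if (any(d2 < (0.8 * (e$r[ids] + r))^2)) return(TRUE)
    }
  FALSE
}

acceptPoint <- function(e, x, y, r) {
  e$n <- e$n + 1L
  if (e$n > length(e$x)) {
    grow <- function(v) c(v, numeric(length(v)))
    e$x <- grow(e$x); e$y <- grow(e$y); e$r <- grow(e$r)
  }
  e$x[e$n] <- x; e$y[e$n] <- y; e$r[e$n] <- r
  g <- bucketOf(e, x, y)
  b <- (g[2] - 1L) * e$ngx + g[1]
  e$buckets[[b]] <- c(e$buckets[[b]], e$n)
  invisible(e)
}

#' Sample ground-truth cell positions for one subject
#'
#' Draws the subject's positive fraction `f` (Beta matched by moments to
#' the group mean/SD, truncated to `[0, 1]`) and total cell density `d`
#' (Gamma matched by moments), then places negative cells as a
#' homogeneous Poisson process of intensity `d (1 - f)` and positive
#' cells as a Thomas cluster process of total intensity `d f` (parents
#' outside the field, up to a 3-sigma buffer, contribute edge
#' offspring).  Nuclei closer than 0.8 x the sum of their radii are
#' rejected and resampled with bounded retries; exhausting the retries
#' raises an error naming the offending density parameter.
#'
#' @param params a [SimulationParams-class].
#' @param group group label (must match `params@groups$label`).
#' @param subjectSeed integer seed controlling every draw for this
#'   subject.
#' @return data.frame with `x_um`, `y_um`, `radius_um`, `positive`, and
#'   attributes `fraction_sampled`, `density_sampled`, `group`.
#' @export
sampleCellPositions <- function(params, group, subjectSeed) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  gi <- match(group, params@groups$label)
  if (is.na(gi)) stop("unknown group: ", group)
  g <- params@groups[gi, ]
  W <- params@imageSize[1] * params@mpp
  H <- params@imageSize[2] * params@mpp
  areaMM2 <- W * H / 1e6
  maxTries <- 100L

  withr::with_seed(as.integer(subjectSeed), {
    f <- rbetaMoments(1, g$positive_fraction_mean, g$positive_fraction_sd)
    d <- rgammaMoments(1, g$cell_density_mean, g$cell_density_sd)

    drawRadius <- function(n)
      pmax(stats::rnorm(n, params@nucleusRadiusMean, params@nucleusRadiusSD),
           0.5)
    rMax <- params@nucleusRadiusMean + 5 * params@nucleusRadiusSD
    pl <- newPlacement(W, H, cellSize = max(1, 1.6 * rMax),
                       capacity = max(64L, as.integer(1.5 * d * areaMM2)))
    positive <- logical(0)

    ## positive cells first (the clustered, tighter-packed component)
    if (f > 0 && d > 0) {
      sigma <- params@clusterRadius
      buf <- 3 * sigma
      kappa <- params@parentIntensity
      mu <- if (is.na(params@offspringMean)) d * f / kappa
            else params@offspringMean
      nPar <- stats::rpois(1, kappa * (W + 2 * buf) * (H + 2 * buf) / 1e6)
      if (nPar > 0) {
        px <- stats::runif(nPar, -buf, W + buf)
        py <- stats::runif(nPar, -buf, H + buf)
        nOff <- stats::rpois(nPar, mu)
        for (p in seq_len(nPar)) {
          for (o in seq_len(nOff[p])) {
            x <- px[p] + stats::rnorm(1, 0, sigma)
            y <- py[p] + stats::rnorm(1, 0, sigma)
            if (x < 0 || x >= W || y < 0 || y >= H) next  # edge thinning
            r <- drawRadius(1)
            tries <- 0L
            while (conflicts(pl, x, y, r)) {
              tries <- tries + 1L
              if (tries > maxTries)
                stop("could not place positive cells without overlap; ",
                     "cell_density_mean (x positive fraction) too high for ",
                     "the cluster geometry")
              repeat {
                x <- px[p] + stats::rnorm(1, 0, sigma)
                y <- py[p] + stats::rnorm(1, 0, sigma)
                if (x >= 0 && x < W && y >= 0 && y < H) break
              }
            }
            acceptPoint(pl, x, y, r)
          }
        }
      }
      positive <- rep(TRUE, pl$n)
    }

    nNeg <- stats::rpois(1, d * (1 - f) * areaMM2)
    for (j in seq_len(nNeg)) {
      x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
      r <- drawRadius(1)
      tries <- 0L
      while (conflicts(pl, x, y, r)) {
        tries <- tries + 1L
        if (tries > maxTries)
          stop("could not place negative cells without overlap; ",
               "cell_density_mean too high for the image area")
        x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
      }
      acceptPoint(pl, x, y, r)
    }
    positive <- c(positive, rep(FALSE, pl$n - length(positive)))

    out <- data.frame(x_um = pl$x[seq_len(pl$n)], y_um = pl$y[seq_len(pl$n)],
                      radius_um = pl$r[seq_len(pl$n)], positive = positive)
    attr(out, "fraction_sampled") <- f
    attr(out, "density_sampled") <- d
    attr(out, "group") <- as.character(g$label)
    out
  })
}

## ---------------------------------------------------------------------------
## rendering
## ---------------------------------------------------------------------------

#' Rendered synthetic image with ground truth
#'
#' The continuous (float, 0-255) RGB render of one synthetic subject,
#' the per-cell ground truth, and the pixel calibration.  The float
#' array preserves the forward model exactly; [writeImage()]/file output
#' quantizes to 8 bits.
#'
#' @slot rgb numeric array `nx x ny x 3`, values in `[0, 255]`.
#' @slot truth data.frame of rendered cells (`x_um`, `y_um`,
#'   `radius_um`, `positive`).
#' @slot mpp microns per pixel.
#' @slot subject list with the sampled `fraction` and `density` and the
#'   realized `true_fraction` (exactly n positive / n total) and
#'   `true_density` (cells per mm^2).
#' @export
setClass("SimulatedImage",
         representation(rgb = "array", truth = "data.frame", mpp = "numeric",
                        subject = "list"))

setMethod("show", "SimulatedImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("SimulatedImage %d x %d px @ %.3g um/px: %d cells (%d positive)\n",
              d[1], d[2], object@mpp, nrow(object@truth),
              sum(object@truth$positive)))
  invisible(object)
})

#' @describeIn SimulatedImage-class exact ground-truth positive fraction
#' @param image a `SimulatedImage`.
#' @export
trueFraction <- function(image) {
  n <- nrow(image@truth)
  if (n == 0) return(NA_real_)
  sum(image@truth$positive) / n
}

#' @describeIn SimulatedImage-class ground-truth cell density per mm^2
#' @export
trueDensity <- function(image) {
  d <- dim(image@rgb)
  nrow(image@truth) / (d[1] * d[2] * image@mpp^2 / 1e6)
}

## linear indices of the pixels inside a disc of radius r (um) at (x, y) um
discIndices <- function(nx, ny, x, y, r, mpp) {
  ix <- max(1L, as.integer(floor((x - r) / mpp))):
    min(nx, as.integer(ceiling((x + r) / mpp + 1)))
  iy <- max(1L, as.integer(floor((y - r) / mpp))):
    min(ny, as.integer(ceiling((y + r) / mpp + 1)))
  dx2 <- ((ix - 0.5) * mpp - x)^2
  dy2 <- ((iy - 0.5) * mpp - y)^2
  mask <- outer(dx2, dy2, "+") <= r^2
  (rep(ix, times = length(iy)) +
     rep((iy - 1L) * nx, each = length(ix)))[as.vector(mask)]
}

#' Render a point set as an H-DAB brightfield image
#'
#' Each nucleus becomes a filled disc of stain concentrations
#' (hematoxylin for every nucleus; the positive or background DAB
#' amplitude by label).  Per pixel, RGB transmittance follows the
#' Beer-Lambert law `255 * 10^(-M c)` with `M` the stain matrix and `c`
#' the concentration vector; overlapping discs add their optical
#' densities.  Gaussian noise (SD `params@noiseSD`) is added in OD space
#' and the result clipped to `[0, 255]`.  The returned array is
#' continuous; quantization happens only when writing to file.
#'
#' @param cells data.frame from [sampleCellPositions()] (columns `x_um`,
#'   `y_um`, `radius_um`, `positive`).
#' @param params a [SimulationParams-class].
#' @param stains a [StainMatrix-class] used as the forward mixing model.
#' @param seed optional integer seed for the noise draw; `NULL` uses the
#'   current RNG state.
#' @return A [SimulatedImage-class].
#' @export
renderImage <- function(cells, params, stains = hdabStainMatrix(),
                        seed = NULL) {
  stopifnot(is(params, "SimulationParams"))
  nx <- params@imageSize[1]; ny <- params@imageSize[2]
  mpp <- params@mpp
  cH <- matrix(0, nx, ny)
  cD <- matrix(0, nx, ny)
  for (i in seq_len(nrow(cells))) {
    idx <- discIndices(nx, ny, cells$x_um[i], cells$y_um[i],
                       cells$radius_um[i], mpp)
    cH[idx] <- cH[idx] + params@hematoxylinOD
    cD[idx] <- cD[idx] + (if (cells$positive[i]) params@dabPositiveOD
                          else params@dabNegativeOD)
  }
  M <- as.matrix(stains)
  od <- array(0, dim = c(nx, ny, 3L))
  for (k in 1:3) od[, , k] <- M[k, 1] * cH + M[k, 2] * cD
  if (params@noiseSD > 0) {
    addNoise <- function() {
      for (k in 1:3)
        od[, , k] <<- od[, , k] +
          matrix(stats::rnorm(nx * ny, 0, params@noiseSD), nx, ny)
    }
    if (is.null(seed)) addNoise()
    else withr::with_seed(as.integer(seed), addNoise())
  }
  rgb <- 255 * 10^(-od)
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  nT <- nrow(cells); nP <- sum(cells$positive)
  new("SimulatedImage", rgb = rgb, truth = cells, mpp = mpp,
      subject = list(
        group = attr(cells, "group"),
        fraction = attr(cells, "fraction_sampled"),
        density = attr(cells, "density_sampled"),
        true_fraction = if (nT > 0) nP / nT else NA_real_,
        true_density = nT / (nx * ny * mpp^2 / 1e6)))
}

## ---------------------------------------------------------------------------
## cohort simulation
## ---------------------------------------------------------------------------

#' Simulate a full blinded cohort
#'
#' Generates one image per subject, a manifest linking subjects to
#' groups and image files, a blinded (shuffled, group-free) manifest for
#' analysis, the blinding key, and per-subject ground truth.  A single
#' master seed (`params@seed`) deterministically derives every
#' per-subject sampling seed, rendering-noise seed and the blinding
#' permutation, so identical parameters reproduce identical cohorts
#' bit for bit.
#'
#' @param params a [SimulationParams-class].
#' @param dir output directory (created if needed).  Images are written
#'   under `dir/images/`, ground truth under `dir/ground_truth/`.
#' @param stains forward-model [StainMatrix-class].
#' @param writeImages write 8-bit TIFF images to disk (default TRUE).
#' @param keepImages additionally return the in-memory
#'   [SimulatedImage-class] objects (memory-heavy for large images).
#' @return Invisibly, a list with `manifest`, `blinded`, `key`, `truth`
#'   (per-subject summary data.frame), `dir`, and optionally `images`.
#' @export
simulateCohort <- function(params, dir, stains = hdabStainMatrix(),
                           writeImages = TRUE, keepImages = FALSE) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  g <- params@groups
  nsub <- sum(g$n_subjects)
  seeds <- withr::with_seed(params@seed,
                            sample.int(2147483646L, 2L * nsub + 1L))
  sampleSeeds <- seeds[seq_len(nsub)]
  noiseSeeds <- seeds[nsub + seq_len(nsub)]
  blindSeed <- seeds[2L * nsub + 1L]

  if (writeImages) {
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  }

  subjects <- unlist(lapply(seq_len(nrow(g)), function(i)
    sprintf("%s_%02d", g$label[i], seq_len(g$n_subjects[i]))))
  groupsOf <- rep(g$label, g$n_subjects)

  truth <- vector("list", nsub)
  images <- if (keepImages) vector("list", nsub) else NULL
  paths <- character(nsub)
  for (j in seq_len(nsub)) {
    cells <- sampleCellPositions(params, groupsOf[j], sampleSeeds[j])
    img <- renderImage(cells, params, stains, seed = noiseSeeds[j])
    paths[j] <- file.path("images", paste0(subjects[j], ".tif"))
    if (writeImages) {
      EBImage::writeImage(EBImage::Image(img@rgb / 255,
                                         colormode = "Color"),
                          file.path(dir, paths[j]), type = "tiff",
                          compression = "deflate", bits.per.sample = 8L)
      utils::write.csv(cells,
                       file.path(dir, "ground_truth",
                                 paste0(subjects[j], ".csv")),
                       row.names = FALSE)
    }
    if (keepImages) images[[j]] <- img
    truth[[j]] <- data.frame(
      subject_id = subjects[j], group = groupsOf[j],
      fraction_sampled = img@subject$fraction,
      density_sampled = img@subject$density,
      n_cells = nrow(cells), n_positive = sum(cells$positive),
      true_fraction = img@subject$true_fraction,
      true_density = img@subject$true_density)
  }
  truth <- do.call(rbind, truth)

  manifest <- data.frame(subject_id = subjects, group = groupsOf,
                         image_path = paths, seed = sampleSeeds,
                         stringsAsFactors = FALSE)
  bl <- blindManifest(manifest, blindSeed)
  manifest$blinded_id <- bl$key$blinded_id[match(manifest$subject_id,
                                                 bl$key$subject_id)]
  if (writeImages) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(bl$blinded, file.path(dir, "manifest_blinded.csv"),
                     row.names = FALSE)
    utils::write.csv(bl$key, file.path(dir, "blinding_key.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "cohort_truth.csv"),
                     row.names = FALSE)
  }
  out <- list(manifest = manifest, blinded = bl$blinded, key = bl$key,
              truth = truth, dir = dir)
  if (keepImages) out$images <- images
  invisible(out)
}
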