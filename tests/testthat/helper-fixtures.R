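# Shared fixtures: small simulation configurations and a ground-truth
# matcher used by the detection and acceptance tests.

# single-group parameter set on a small field; density per mm^2
smallParams <- function(f = 0.5, fsd = 0, d = 2500, dsd = 0,
                        npix = 420L, mpp = 0.5, roiArea = 0.01,
                        noiseSD = 0.02, ...) {
  roiArea <- min(roiArea, (npix * mpp)^2 / 1e6 / 4)
  SimulationParams(
    groups = data.frame(label = "G", n_subjects = 1L,
                        positive_fraction_mean = f,
                        positive_fraction_sd = fsd,
                        cell_density_mean = d, cell_density_sd = dsd),
    imageSize = c(npix, npix), mpp = mpp, roiArea = roiArea,
    noiseSD = noiseSD, ...)
}

# three-group cohort at reduced field size for pipeline tests
tinyCohortParams <- function(nPerGroup = 2L, npix = 420L, seed = 1L) {
  g <- defaultGroups()
  g$n_subjects <- rep(nPerGroup, 3L)
  SimulationParams(groups = g, imageSize = c(npix, npix), mpp = 0.5,
                   roiArea = min(0.01, (npix * 0.5)^2 / 1e6 / 4),
                   seed = seed)
}

# greedy nearest-neighbor matching of detections to ground truth within
# a tolerance (um); returns recovery and positivity-label agreement
matchRecovery <- function(truth, det, tol = 2) {
  if (nrow(det) == 0L || nrow(truth) == 0L)
    return(list(recovery = 0, labelAgreement = NA_real_,
                nTruth = nrow(truth), nMatched = 0L, agree = 0L))
  D <- outer(truth$x_um, det$x_um, "-")^2 + outer(truth$y_um, det$y_um, "-")^2
  matched <- rep(NA_integer_, nrow(truth))
  used <- rep(FALSE, nrow(det))
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j]) && D[i, j] <= tol^2) {
      matched[i] <- j
      used[j] <- TRUE
    }
  }
  ok <- !is.na(matched)
  list(recovery = mean(ok),
       labelAgreement = mean(det$positive[matched[ok]] == truth$positive[ok]),
       nTruth = nrow(truth), nMatched = sum(ok),
       agree = sum(det$positive[matched[ok]] == truth$positive[ok]))
}

# exhaustive window search counting positive centroids directly; the
# independent oracle for the grid search
bruteForcePeak <- function(cells, width, height, side, stride = 1) {
  xs <- sort(unique(c(seq(0, width - side, by = stride), width - side)))
  ys <- sort(unique(c(seq(0, height - side, by = stride), height - side)))
  best <- -1L
  px <- cells$x_um[cells$positive]
  py <- cells$y_um[cells$positive]
  for (x0 in xs) {
    inx <- px >= x0 & px < x0 + side
    if (sum(inx) <= best) next
    yy <- py[inx]
    for (y0 in ys) {
      s <- sum(yy >= y0 & yy < y0 + side)
      if (s > best) best <- s
    }
  }
  best
}
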