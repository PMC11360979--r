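#' Collect per-group value lists for one analysis mode
#'
#' The three analysis modes mirror the reporting structure of the
#' emulated study: `two_rois_pooled` contributes both the peak and the
#' subpeak reading per subject (2 values), `peak_only` the rank-1 ROI,
#' and `mean_of_two` the per-subject arithmetic mean of the two readings
#' (a missing reading propagates to the mean).  Missing values (empty
#' windows give `NA` percent positive) are dropped from the returned
#' lists with a logged count.
#'
#' @param roiTable long data.frame with columns `subject_id`, `group`,
#'   `roi_rank` (1 = peak, 2 = subpeak) and the metric columns.
#' @param mode one of `"two_rois_pooled"`, `"peak_only"`,
#'   `"mean_of_two"`.
#' @param metric metric column name, `"pos_percent"` or
#'   `"pos_per_mm2"`.
#' @return named list (by group) of numeric vectors.
#' @export
collectValues <- function(roiTable, mode = c("two_rois_pooled", "peak_only",
                                             "mean_of_two"),
                          metric = c("pos_percent", "pos_per_mm2")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  need <- c("subject_id", "group", "roi_rank", metric)
  if (!all(need %in% names(roiTable)))
    stop("roiTable must have columns: ", paste(need, collapse = ", "))

  perGroup <- split(roiTable, roiTable$group)
  out <- lapply(perGroup, function(tab) {
    v <- switch(mode,
      two_rois_pooled = {
        ## interleave peak and subpeak per subject
        tab <- tab[order(tab$subject_id, tab$roi_rank), ]
        tab[[metric]]
      },
      peak_only = tab[[metric]][tab$roi_rank == 1L],
      mean_of_two = {
        m <- tapply(tab[[metric]], tab$subject_id, function(z) {
          if (length(z) != 2L) return(NA_real_)
          mean(z)  # NA propagates
        })
        as.numeric(m)
      })
    v
  })
  dropped <- sum(vapply(out, function(v) sum(is.na(v)), numeric(1)))
  if (dropped > 0)
    message(dropped, " missing value(s) dropped in mode '", mode,
            "', metric '", metric, "'")
  lapply(out, function(v) v[!is.na(v)])
}

#' Summary-row statistics for one group
#'
#' Computes the summary rows of the group-comparison tables: mean,
#' median, 75th and 25th percentiles (linear interpolation between
#' order statistics), their difference as the IQR, and the sample
#' standard deviation (n - 1 denominator).
#'
#' @param values numeric vector (at least 2 values).
#' @param label optional group label used in error messages.
#' @return one-row data.frame: `n_values`, `mean`, `median`, `p75`,
#'   `p25`, `iqr`, `sd`.
#' @export
summarizeGroup <- function(values, label = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("need at least 2 values to summarize",
         if (!is.null(label)) paste0(" group '", label, "'") else "")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  data.frame(n_values = length(values),
             mean = mean(values),
             median = stats::median(values),
             p75 = q[2], p25 = q[1],
             iqr = q[2] - q[1],
             sd = stats::sd(values))
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties.  When the combined sample size
#' is at most `exactLimit` and there are no ties, the two-tailed p-value
#' comes from exact enumeration of all rank assignments; otherwise from
#' the normal approximation with tie correction and continuity
#' correction.  Identical samples give p = 1.
#'
#' @param a,b numeric samples (non-empty).
#' @param alpha significance level for the `significant` flag.
#' @param exactLimit maximum combined size for exact enumeration.
#' @return one-row data.frame: `n_a`, `n_b`, `U` (for sample `a`), `p`,
#'   `method` ("exact" or "normal"), `alpha`, `significant`.
#' @export
mannWhitneyU <- function(a, b, alpha = 0.05, exactLimit = 16L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  nA <- length(a); nB <- length(b); N <- nA + nB
  comb <- c(a, b)
  rk <- rank(comb)                     # midranks
  U <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(comb) > 0L

  if (N <= exactLimit && !ties) {
    sets <- utils::combn(N, nA)
    Us <- colSums(matrix(seq_len(N)[sets], nrow = nA)) - nA * (nA + 1) / 2
    pLE <- mean(Us <= U + 1e-9)
    pGE <- mean(Us >= U - 1e-9)
    p <- min(1, 2 * min(pLE, pGE))
    method <- "exact"
  } else {
    mU <- nA * nB / 2
    tieTab <- table(comb)
    tieSum <- sum(tieTab^3 - tieTab)
    s2 <- nA * nB / 12 * ((N + 1) - tieSum / (N * (N - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mU) - 0.5) / sqrt(s2)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal"
  }
  data.frame(n_a = nA, n_b = nB, U = U, p = p, method = method,
             alpha = alpha, significant = p < alpha)
}

#' Build the full group-comparison table
#'
#' For each analysis mode and metric: one summary per group and three
#' pairwise two-tailed Mann-Whitney comparisons in the reporting order
#' first-vs-third, second-vs-first, third-vs-second group (HV vs EoE,
#' GERD vs HV, EoE vs GERD for the default cohort).  No multiple-testing
#' correction is applied; raw p-values are reported.
#'
#' @param roiTable long ROI data.frame (see [collectValues()]); exactly
#'   three groups must be present.
#' @param metrics,modes subsets of the metrics and analysis modes.
#' @param alpha significance level.
#' @param groupOrder optional character vector fixing the group order;
#'   defaults to order of first appearance.
#' @return list with data.frames `summaries` and `comparisons`.
#' @export
buildComparisonTable <- function(roiTable,
                                 metrics = c("pos_percent", "pos_per_mm2"),
                                 modes = c("two_rois_pooled", "peak_only",
                                           "mean_of_two"),
                                 alpha = 0.05, groupOrder = NULL) {
  groups <- if (is.null(groupOrder)) unique(roiTable$group) else groupOrder
  if (length(groups) != 3L || !all(groups %in% roiTable$group))
    stop("exactly three groups must be present (got: ",
         paste(unique(roiTable$group), collapse = ", "), ")")
  pairs <- list(c(1L, 3L), c(2L, 1L), c(3L, 2L))

  summaries <- list(); comparisons <- list()
  for (mode in modes) for (metric in metrics) {
    vals <- collectValues(roiTable, mode, metric)
    for (gl in groups) {
      s <- summarizeGroup(vals[[gl]], label = gl)
      summaries[[length(summaries) + 1L]] <-
        cbind(data.frame(group = gl, metric = metric, mode = mode), s)
    }
    for (pr in pairs) {
      gA <- groups[pr[1]]; gB <- groups[pr[2]]
      cmp <- mannWhitneyU(vals[[gA]], vals[[gB]], alpha = alpha)
      comparisons[[length(comparisons) + 1L]] <-
        cbind(data.frame(group_a = gA, group_b = gB, metric = metric,
                         mode = mode), cmp)
    }
  }
  list(summaries = do.call(rbind, summaries),
       comparisons = do.call(rbind, comparisons))
}

#' Lay one analysis mode out as a publication-style table
#'
#' Rearranges [buildComparisonTable()] output for a single mode into
#' the familiar wide layout: one column per group and metric; rows
#' Mean, Mdn, 75th Perc, 25th Perc, IQR, SD, then the U statistic and
#' two-tailed p of each pairwise comparison (placed under the first
#' group of the pair).
#'
#' @param tables result of [buildComparisonTable()].
#' @param mode the analysis mode to lay out.
#' @return data.frame with a `stat` column and one column per
#'   group/metric combination.
#' @export
layoutModeTable <- function(tables, mode) {
  su <- tables$summaries[tables$summaries$mode == mode, ]
  cm <- tables$comparisons[tables$comparisons$mode == mode, ]
  if (nrow(su) == 0L) stop("no summaries for mode: ", mode)
  groups <- unique(su$group)
  metrics <- unique(su$metric)
  cols <- as.vector(t(outer(groups, metrics, paste, sep = "_")))
  statRows <- c("Mean", "Mdn", "75th Perc", "25th Perc", "IQR", "SD")
  fields <- c("mean", "median", "p75", "p25", "iqr", "sd")
  pairs <- unique(cm[, c("group_a", "group_b")])
  rows <- c(statRows,
            as.vector(t(cbind(sprintf("U (%s vs. %s)", pairs$group_a,
                                      pairs$group_b),
                              sprintf("P (%s vs. %s)", pairs$group_a,
                                      pairs$group_b)))))
  out <- data.frame(stat = rows)
  for (cn in cols) out[[cn]] <- NA_real_
  for (i in seq_along(statRows)) for (g in groups) for (m in metrics)
    out[i, paste(g, m, sep = "_")] <-
      su[[fields[i]]][su$group == g & su$metric == m]
  for (j in seq_len(nrow(pairs))) for (m in metrics) {
    r <- cm[cm$group_a == pairs$group_a[j] &
              cm$group_b == pairs$group_b[j] & cm$metric == m, ]
    cn <- paste(pairs$group_a[j], m, sep = "_")
    out[length(statRows) + 2L * j - 1L, cn] <- r$U
    out[length(statRows) + 2L * j, cn] <- r$p
  }
  out
}
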