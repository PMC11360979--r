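roiTableFor <- function(values) {
  # build a two-ROI table from per-subject (peak, subpeak) value pairs
  do.call(rbind, lapply(seq_along(values), function(i) {
    data.frame(subject_id = sprintf("S%02d", i), group = "G",
               roi_rank = 1:2, pos_percent = values[[i]],
               pos_per_mm2 = values[[i]] * 10)
  }))
}

test_that("separated samples give the enumerated exact p-value", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$U, 0)
  expect_equal(r$p, 0.1)          # 2 x 1/choose(6, 3)
  expect_identical(r$method, "exact")
  # identical samples are maximally compatible with the null
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mannWhitneyU(rep(2, 5), rep(2, 7))$p, 1)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("the exact path agrees with the enumeration oracle everywhere", {
  set.seed(101)
  for (r in 1:80) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    repeat {
      a <- round(rnorm(nA), 3); b <- round(rnorm(nB), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    mine <- mannWhitneyU(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE,
                                        correct = FALSE))
    expect_identical(mine$method, "exact")
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # U symmetry: U_A + U_B = nA nB
    expect_equal(mine$U + mannWhitneyU(b, a)$U, nA * nB)
  }
})

test_that("the tied normal approximation matches the reference test", {
  set.seed(202)
  for (r in 1:40) {
    a <- round(rnorm(15), 1); b <- round(rnorm(21), 1)
    mine <- mannWhitneyU(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE))
    expect_identical(mine$method, "normal")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("group summaries compute the table rows as defined", {
  s <- summarizeGroup(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  expect_identical(s$iqr, s$p75 - s$p25)
  # five points pin the quartiles to order statistics (type-7)
  s5 <- summarizeGroup(c(100, 1300, 2000, 5880, 7000))
  expect_equal(s5$p25, 1300)
  expect_equal(s5$p75, 5880)
  expect_equal(s5$iqr, 4580)
  # order relation and identity on arbitrary samples
  set.seed(5)
  for (r in 1:20) {
    s <- summarizeGroup(rnorm(sample(3:40, 1)))
    expect_lte(s$p25, s$median)
    expect_lte(s$median, s$p75)
    expect_identical(s$iqr, s$p75 - s$p25)
  }
  expect_error(summarizeGroup(1, label = "HV"), "HV")
})

test_that("analysis modes collect the right values per subject", {
  tab <- roiTableFor(list(c(10, 6), c(20, 10), c(30, 14)))
  pooled <- collectValues(tab, "two_rois_pooled", "pos_percent")$G
  expect_identical(length(pooled), 6L)
  peak <- collectValues(tab, "peak_only", "pos_percent")$G
  expect_identical(peak, c(10, 20, 30))
  m2 <- collectValues(tab, "mean_of_two", "pos_percent")$G
  expect_identical(sort(m2), c(8, 15, 22))
  # pooled and mean-of-two have equal overall means with no missing data
  expect_equal(mean(pooled), mean(m2))
  # a missing reading propagates to the subject mean and is dropped
  tab$pos_percent[2] <- NA
  expect_message(
    m2d <- collectValues(tab, "mean_of_two", "pos_percent")$G,
    "missing")
  expect_identical(length(m2d), 2L)
})

test_that("the comparison table covers all modes, metrics and pairs", {
  mkGroup <- function(g, n, shift, seed) {
    withr::with_seed(seed, do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(subject_id = sprintf("%s%02d", g, i), group = g,
                 roi_rank = 1:2,
                 pos_percent = pmin(pmax(rnorm(2, 30 + shift, 10), 0), 100),
                 pos_per_mm2 = pmax(rnorm(2, 300 + 10 * shift, 100), 0)))))
  }
  tab <- rbind(mkGroup("HV", 15, 0, 1), mkGroup("GERD", 21, 20, 2),
               mkGroup("EoE", 20, 25, 3))
  res <- buildComparisonTable(tab)
  expect_identical(nrow(res$summaries), 3L * 2L * 3L)
  expect_identical(nrow(res$comparisons), 3L * 2L * 3L)
  # pooled mode uses two values per subject
  expect_identical(res$summaries$n_values[res$summaries$mode ==
    "two_rois_pooled" & res$summaries$group == "HV"], c(30L, 30L))
  # comparison order follows the reporting convention
  expect_identical(unique(paste(res$comparisons$group_a, "vs",
                                res$comparisons$group_b)),
                   c("HV vs EoE", "GERD vs HV", "EoE vs GERD"))
  expect_true(all(res$comparisons$U >= 0))
  expect_true(all(res$comparisons$p > 0 & res$comparisons$p <= 1))
  expect_error(buildComparisonTable(tab[tab$group != "HV", ]), "three")
  # wide publication-style layout: 6 stat rows + U/p per pair
  wide <- layoutModeTable(res, "peak_only")
  expect_identical(nrow(wide), 6L + 2L * 3L)
  expect_identical(names(wide)[1:3], c("stat", "HV_pos_percent",
                                       "HV_pos_per_mm2"))
  expect_equal(wide$HV_pos_percent[wide$stat == "IQR"],
               res$summaries$iqr[res$summaries$group == "HV" &
                 res$summaries$metric == "pos_percent" &
                 res$summaries$mode == "peak_only"])
})

test_that("a large location shift is detected in nearly every cohort", {
  hits <- vapply(1:50, function(seed) {
    hv <- roiTableFor(as.list(as.data.frame(t(withr::with_seed(seed,
      matrix(rnorm(30, 10, 3), ncol = 2))))))
    eo <- roiTableFor(as.list(as.data.frame(t(withr::with_seed(seed + 500,
      matrix(rnorm(30, 25, 3), ncol = 2))))))
    vA <- hv$pos_percent; vB <- eo$pos_percent
    mannWhitneyU(vA, vB)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
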