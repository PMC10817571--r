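test_that("confusion counts match identity, hand-worked and edge cases", {
  truth <- matrix(0L, 4, 4); truth[1:2, 1:2] <- 1L
  pred <- matrix(0L, 4, 4); pred[1:2, 2:3] <- 1L
  cc <- confusion(pred, truth)
  expect_equal(cc[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 2L, fn = 2L, tn = 10L))

  m <- random_mask(8, 8)
  ci <- confusion(m, m)
  expect_equal(ci$tp, sum(m)); expect_equal(ci$fp, 0); expect_equal(ci$fn, 0)
  expect_equal(ci$tn, 64 - sum(m))

  cz <- confusion(matrix(0L, 4, 4), truth)
  expect_equal(cz$tp, 0); expect_equal(cz$fp, 0); expect_equal(cz$fn, 4)
  expect_error(confusion(matrix(0L, 3, 3), truth),
               class = "nervetrace_geometry_error")
  expect_error(confusion(matrix(0.5, 4, 4), truth),
               class = "nervetrace_type_error")
})

test_that("confusion counts equal the per-pixel double-loop oracle", {
  set.seed(13)
  for (i in 1:100) {
    a <- random_mask(16, 16, runif(1, 0.2, 0.8))
    b <- random_mask(16, 16, runif(1, 0.2, 0.8))
    expect_identical(unclass(confusion(a, b))[c("tp", "fp", "tn", "fn")],
                     oracle_confusion(a, b)[c("tp", "fp", "tn", "fn")])
  }
})

test_that("metric formulas reproduce hand substitutions and degenerate conventions", {
  m <- metrics_from_counts(list(tp = 2, fp = 2, fn = 2))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$dice, 0.5)
  expect_equal(m$iou, 1 / 3)

  perfect <- metrics_from_counts(list(tp = 7, fp = 0, fn = 0))
  expect_equal(unlist(perfect[c("precision", "recall", "dice", "iou")]),
               c(precision = 1, recall = 1, dice = 1, iou = 1))
  disjoint <- metrics_from_counts(list(tp = 0, fp = 3, fn = 5))
  expect_equal(unlist(disjoint[c("precision", "recall", "dice", "iou")]),
               c(precision = 0, recall = 0, dice = 0, iou = 0))

  both_empty <- metrics_from_counts(list(tp = 0, fp = 0, fn = 0))
  expect_equal(unlist(both_empty[c("precision", "recall", "dice", "iou")]),
               c(precision = 1, recall = 1, dice = 1, iou = 1))
  empty_pred <- metrics_from_counts(list(tp = 0, fp = 0, fn = 4))
  expect_equal(empty_pred$precision, 0)
  expect_equal(empty_pred$recall, 0)
})

test_that("iou = dice/(2 - dice), dice is harmonic mean, swap symmetry", {
  set.seed(14)
  for (i in 1:100) {
    a <- random_mask(16, 16, runif(1, 0.1, 0.9))
    b <- random_mask(16, 16, runif(1, 0.1, 0.9))
    m <- seg_metrics(a, b)
    expect_equal(m$iou, m$dice / (2 - m$dice), tolerance = 1e-12)
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$dice, 2 / (1 / m$precision + 1 / m$recall),
                   tolerance = 1e-12)
    }
    sw <- seg_metrics(b, a)
    expect_equal(sw$precision, m$recall, tolerance = 1e-12)
    expect_equal(sw$recall, m$precision, tolerance = 1e-12)
    expect_equal(sw$dice, m$dice, tolerance = 1e-12)
    expect_equal(sw$iou, m$iou, tolerance = 1e-12)
    if (sum(a * b) > 0) expect_gt(m$iou, 0)  # any overlap gives IoU > 0
  }
})

test_that("metric summaries: means, SDs, IoU histogram and modal bin", {
  one <- summarize_metrics(list(metrics_from_counts(list(tp = 2, fp = 2, fn = 2))))
  expect_equal(one$summary$sd, rep(0, 4))
  expect_equal(one$summary$mean[one$summary$metric == "iou"], 1 / 3)

  df <- data.frame(precision = c(0.8, 0.8, 0.9), recall = c(0.9, 0.85, 0.95),
                   dice = c(0.84, 0.82, 0.92), iou = c(0.75, 0.72, 0.85))
  s <- summarize_metrics(df)
  expect_equal(s$iou_mode, 0.7)
  expect_equal(s$iou_min, 0.72)
  expect_equal(sum(s$iou_hist), 3)
  expect_equal(unname(s$iou_hist[8]), 2)  # [0.7, 0.8)

  const <- df[c(1, 1, 1), ]
  expect_equal(max(summarize_metrics(const)$iou_hist), 3)
  expect_error(summarize_metrics(list()), class = "nervetrace_size_error")
})
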