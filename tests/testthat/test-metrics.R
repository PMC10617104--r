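test_that("overlap metrics match hand-counted values and conventions", {
  # P = 60 px, T = 40 px, intersection = 30 px
  p2 <- matrix(0L, 20, 10); p2[1:6, ] <- 1L
  t2 <- matrix(0L, 20, 10); t2[4:6, ] <- 1L; t2[10, ] <- 1L
  m <- overlap_metrics(p2, t2, 1L)
  expect_equal(m[["iou"]], 30 / 70, tolerance = 1e-12)
  expect_equal(m[["pa"]], 0.75, tolerance = 1e-12)
  expect_equal(m[["dsc"]], 0.6, tolerance = 1e-12)

  expect_equal(unname(overlap_metrics(p2, p2, 1L)), c(1, 1, 1))
  expect_equal(unname(overlap_metrics(p2, matrix(0L, 20, 10), 1L)), c(0, 0, 0))
  expect_equal(unname(overlap_metrics(matrix(0L, 5, 5), matrix(0L, 5, 5), 2L)),
               c(1, 1, 1))
  expect_error(overlap_metrics(p2, matrix(0L, 5, 5), 1L), "same grid")
})

test_that("dsc = 2 iou / (1 + iou) and dsc >= iou across random mask pairs", {
  set.seed(77)
  for (i in 1:15) {
    p <- matrix(rbinom(400, 1L, 0.4), 20, 20)
    t <- matrix(rbinom(400, 1L, 0.4), 20, 20)
    m <- overlap_metrics(p, t, 1L)
    expect_equal(m[["dsc"]], 2 * m[["iou"]] / (1 + m[["iou"]]), tolerance = 1e-12)
    expect_gte(m[["dsc"]], m[["iou"]])
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("confusion statistics reproduce the reference matrix", {
  cs <- confusion_stats(tp = 18, fn = 4, fp = 2, tn = 22)
  expect_equal(round(cs$sen * 100, 1), 81.8)
  expect_equal(round(cs$spe * 100, 1), 91.7)
  expect_equal(round(cs$acc * 100, 1), 87.0)

  perfect <- confusion_stats(10, 0, 0, 10)
  expect_equal(c(perfect$acc, perfect$sen, perfect$spe), c(1, 1, 1))
  sym <- confusion_stats(1, 1, 1, 1)
  expect_equal(c(sym$acc, sym$sen, sym$spe), c(0.5, 0.5, 0.5))

  # undefined rates are flagged, not NaN
  nopos <- confusion_stats(0, 0, 2, 3)
  expect_true(is.na(nopos$sen))
  expect_false(nopos$defined[["sen"]])
  expect_error(confusion_stats(0, 0, 0, 0), "empty")
})

test_that("average precision handles the canonical toy cases", {
  gt <- list(list(image = 1L, box = c(0, 0, 10, 10)))
  # all ground truths matched by the top detections, no false positives
  d_perfect <- list(list(image = 1L, box = c(0, 0, 10, 10), confidence = 0.9))
  expect_equal(average_precision(d_perfect, gt)$ap, 1)

  # 1 gt, 2 detections, only the lower-confidence one matches -> AP = 0.5
  d_mixed <- list(list(image = 1L, box = c(50, 50, 60, 60), confidence = 0.9),
                  list(image = 1L, box = c(0, 0, 10, 10), confidence = 0.6))
  expect_equal(average_precision(d_mixed, gt)$ap, 0.5)

  # no ground truth: undefined, flagged as NA
  expect_true(is.na(average_precision(d_perfect, list())$ap))
  expect_equal(average_precision(list(), gt)$ap, 0)
})

test_that("average precision matches the exhaustive oracle on random instances", {
  set.seed(88)
  for (rep in 1:8) {
    n_gt <- sample(2:6, 1)
    gt <- lapply(seq_len(n_gt), function(i) {
      x <- runif(1, 0, 80); y <- runif(1, 0, 80)
      list(image = sample(1:2, 1), box = c(x, y, x + runif(1, 8, 20), y + runif(1, 8, 20)))
    })
    dets <- lapply(seq_len(sample(3:10, 1)), function(i) {
      g <- gt[[sample(n_gt, 1)]]
      jit <- runif(4, -3, 3)
      list(image = if (runif(1) < 0.8) g$image else sample(1:2, 1),
           box = g$box + jit, confidence = runif(1))
    })
    fast <- average_precision(dets, gt, iou_threshold = 0.5)$ap
    slow <- bf_average_precision(dets, gt, iou_threshold = 0.5)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone transforms of the confidences", {
  set.seed(91)
  gt <- lapply(1:4, function(i) {
    x <- i * 20
    list(image = 1L, box = c(x, x, x + 10, x + 10))
  })
  dets <- lapply(1:6, function(i) {
    g <- gt[[((i - 1) %% 4) + 1]]
    list(image = 1L, box = g$box + runif(4, -2, 2), confidence = runif(1))
  })
  ap1 <- average_precision(dets, gt, 0.5)$ap
  dets2 <- lapply(dets, function(d) { d$confidence <- d$confidence^3 + 1; d })
  expect_equal(average_precision(dets2, gt, 0.5)$ap, ap1, tolerance = 1e-12)
})

test_that("the rank AUC equals exhaustive pair counting and handles extremes", {
  expect_equal(roc_auc(c(5, 4, 1, 0), c("IA", "IA", "IB", "IB"))$auc, 1)
  set.seed(95)
  big <- roc_auc(rnorm(4000), rep(c("IA", "IB"), 2000))
  expect_lt(abs(big$auc - 0.5), 0.05)

  for (rep in 1:6) {
    n <- sample(8:20, 1)
    scores <- sample(1:6, n, replace = TRUE)  # force ties
    labels <- sample(c("IA", "IB"), n, replace = TRUE)
    if (length(unique(labels)) < 2L) labels[1:2] <- c("IA", "IB")
    expect_equal(roc_auc(scores, labels)$auc, bf_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep("IA", 5)), "both classes")
})

test_that("the rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(101)
  scores <- rnorm(60)
  labels <- ifelse(scores + rnorm(60) > 0, "IA", "IB")
  if (length(unique(labels)) < 2L) skip("degenerate draw")
  ours <- roc_auc(scores, labels)$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("IB", "IA"),
                                   direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("DeLong placement values average to the AUCs", {
  set.seed(105)
  s_a <- rnorm(40); s_b <- s_a + rnorm(40)
  labels <- sample(c("IA", "IB"), 40, replace = TRUE)
  labels[1:2] <- c("IA", "IB")
  dl <- delong_test(s_a, s_b, labels)
  expect_equal(dl$auc_a, roc_auc(s_a, labels)$auc, tolerance = 1e-12)
  expect_equal(dl$auc_b, roc_auc(s_b, labels)$auc, tolerance = 1e-12)
})

test_that("DeLong flags identical scores and separates anti-paired scores", {
  s <- c(3, 2.5, 2, 1, 0.5, 0)
  labels <- c("IA", "IA", "IA", "IB", "IB", "IB")
  same <- delong_test(s, s, labels)
  expect_true(same$degenerate)
  expect_equal(same$auc_a, same$auc_b)

  set.seed(107)
  x <- c(rnorm(30, 2), rnorm(30, 0))
  labels2 <- rep(c("IA", "IB"), each = 30)
  anti <- delong_test(x, -x, labels2)
  expect_gt(abs(anti$z), 2)
  expect_lt(anti$p, 0.05)
})

test_that("DeLong variance agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(111)
  labels <- rep(c("IA", "IB"), each = 25)
  s_a <- ifelse(labels == "IA", rnorm(50, 1), rnorm(50, 0))
  s_b <- 0.5 * s_a + rnorm(50, sd = 0.8)
  ours <- delong_test(s_a, s_b, labels)
  ra <- suppressMessages(pROC::roc(labels, s_a, levels = c("IB", "IA"), direction = "<"))
  rb <- suppressMessages(pROC::roc(labels, s_b, levels = c("IB", "IA"), direction = "<"))
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-8)
})
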