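test_that("ASA reproduces hand-worked cases and the brute-force oracle", {
  # perfect partition
  gt <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_equal(asa(gt, gt), 1)
  # one predicted cluster over a 60/40 ground-truth split
  gt2 <- array(c(rep(1, 60), rep(2, 40)), dim = c(10, 10))
  pred2 <- array(1, dim = c(10, 10))
  expect_equal(asa(pred2, gt2), 0.6)
  set.seed(31)
  for (i in 1:25) {
    pred <- matrix(sample(0:4, 49, replace = TRUE), 7, 7)
    gt <- matrix(sample(1:3, 49, replace = TRUE), 7, 7)
    expect_equal(asa(pred, gt), oracle_asa(pred, gt), tolerance = 1e-12)
  }
  expect_error(asa(pred2, array(0, dim = c(10, 10))))
})

test_that("majority labeling calls lesions strictly and ties go to background", {
  pred <- matrix(c(1, 1, 2, 2), 2, 2)
  lesion <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_identical(label_clusters_majority(pred, lesion), 1L)  # unanimous
  # cluster 2 is exactly 50/50 -> background
  expect_false(2L %in% label_clusters_majority(pred, lesion))
  set.seed(17)
  for (i in 1:20) {
    pred <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    lesion <- matrix(runif(36) < 0.5, 6, 6)
    expect_identical(label_clusters_majority(pred, lesion),
                     oracle_majority(pred, lesion))
  }
})

test_that("lesion ASA-Dice reproduces the worked example and its degenerate cases", {
  # one lesion cluster of 10 elements, 6 overlapping a GT lesion of 8
  pred <- array(0L, dim = c(10, 10))
  pred[1:10] <- 1L                      # cluster of 10
  gt <- array(0L, dim = c(10, 10))
  gt[5:12] <- 1L                        # lesion of 8, overlap 6
  expect_equal(sum(pred == 1 & gt == 1), 6)
  expect_equal(asa_dice(pred, gt), 2 * 6 / (10 + 8))
  expect_equal(asa_dice(pred, gt), 2 / 3, tolerance = 1e-12)
  # lesion clusters exactly tiling the lesion
  pred3 <- gt; pred3[gt == 0] <- 2L
  expect_equal(asa_dice(pred3, gt), 1)
  # total miss: no majority-lesion cluster
  expect_equal(asa_dice(array(2L, dim = c(10, 10)), gt), 0)
  # both empty -> vacuously perfect, with a warning
  expect_warning(v <- asa_dice(array(0L, dim = c(4, 4)),
                               array(0L, dim = c(4, 4))), "empty")
  expect_equal(v, 1)
  set.seed(23)
  for (i in 1:20) {
    pred <- matrix(sample(0:4, 64, replace = TRUE), 8, 8)
    gt <- matrix(sample(0:2, 64, replace = TRUE, prob = c(.6, .2, .2)), 8, 8)
    if (sum(gt > 0) == 0) next
    expect_equal(asa_dice(pred, gt), oracle_asa_dice(pred, gt),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics follow the printed formulas and flag 0/0 as undefined", {
  m <- confusion_metrics(list(TP = 2, TN = 0, FP = 1, FN = 1))
  expect_equal(m$dice, 4 / 6)
  m2 <- confusion_metrics(list(TP = 5, TN = 10, FP = 0, FN = 0))
  expect_equal(m2$dice, 1); expect_equal(m2$precision, 1)
  expect_equal(m2$sensitivity, 1)
  m3 <- confusion_metrics(list(TP = 0, TN = 4, FP = 0, FN = 0))
  expect_true(is.na(m3$precision))   # 0/0, not 0
  expect_true(is.na(m3$sensitivity))
  set.seed(41)
  for (i in 1:20) {
    mp <- random_mask_pair(6)
    cc <- confusion_counts(mp$pred, mp$gt)
    oc <- oracle_confusion(mp$pred, mp$gt)
    expect_equal(cc$TP, oc$TP); expect_equal(cc$TN, oc$TN)
    expect_equal(cc$FP, oc$FP); expect_equal(cc$FN, oc$FN)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, length(mp$pred))
    m <- confusion_metrics(cc)
    for (v in m) if (!is.na(v)) expect_true(v >= 0 && v <= 1)
  }
})

test_that("Hausdorff95 handles coincident, offset and random boundaries", {
  sq <- array(FALSE, dim = c(12, 12)); sq[4:9, 4:9] <- TRUE
  expect_equal(hausdorff95(sq, sq), 0)
  # two parallel one-pixel lines offset by 3: every nearest distance is 3
  a <- array(FALSE, dim = c(12, 12)); a[2, ] <- TRUE
  b <- array(FALSE, dim = c(12, 12)); b[5, ] <- TRUE
  expect_equal(hausdorff95(a, b), 3)
  expect_equal(hausdorff95(a, b, spacing = c(2, 1)), 6)  # physical spacing
  set.seed(53)
  for (i in 1:15) {
    mp <- random_mask_pair(7)
    got <- hausdorff95(mp$pred, mp$gt)
    expect_equal(got, oracle_hd95(mp$pred, mp$gt), tolerance = 1e-10)
    expect_equal(got, hausdorff95(mp$gt, mp$pred))  # symmetric by definition
    expect_gte(got, 0)
  }
  expect_error(hausdorff95(array(FALSE, c(3, 3)), sq[1:3, 1:3]))
})

test_that("refining a predicted partition never decreases ASA", {
  set.seed(67)
  for (i in 1:15) {
    pred <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    gt <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    # refine: split every cluster in two by a random subset
    refined <- pred + 10L * matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    expect_gte(asa(refined, gt) + 1e-12, asa(pred, gt))
  }
})
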