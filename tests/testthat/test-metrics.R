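worked_example <- function() {
  # 4x4 frame: truth has 4 foreground pixels, prediction hits 3 of them,
  # misses 1 and adds 1 false positive -> tp=3 fp=1 fn=1 tn=11
  truth <- matrix(0L, 4, 4); truth[1, 1] <- truth[1, 2] <- truth[2, 1] <- truth[2, 2] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 1] <- pred[1, 2] <- pred[2, 1] <- 1L
  pred[4, 4] <- 1L
  list(pred = pred, truth = truth)
}

test_that("confusion counts enumerate every pixel", {
  w <- worked_example()
  cc <- confusion_counts(w$pred, w$truth)
  expect_equal(cc, list(tp = 3L, fp = 1L, fn = 1L, tn = 11L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 16L)

  same <- confusion_counts(w$truth, w$truth)
  expect_equal(same, list(tp = 4L, fp = 0L, fn = 0L, tn = 12L))

  none <- confusion_counts(matrix(0L, 4, 4), w$truth)
  expect_equal(none, list(tp = 0L, fp = 0L, fn = 4L, tn = 12L))

  expect_error(confusion_counts(matrix(0L, 3, 3), w$truth), "differ")
})

test_that("the worked example scores IoU 0.6, Dice 0.75, mPA 5/6 exactly", {
  w <- worked_example()
  cc <- confusion_counts(w$pred, w$truth)
  expect_equal(iou_score(cc), 0.6)
  expect_equal(dice_score(cc), 0.75)
  expect_equal(pixel_accuracy_per_class(cc), (3 / 4 + 11 / 12) / 2)
})

test_that("degenerate and extreme cases follow the both-empty convention", {
  empty <- confusion_counts(matrix(0L, 3, 3), matrix(0L, 3, 3))
  expect_equal(iou_score(empty), 1)
  expect_equal(dice_score(empty), 1)
  expect_equal(pixel_accuracy_per_class(empty), 1)  # fg class absent, excluded

  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  disjoint <- confusion_counts(a, b)
  expect_equal(iou_score(disjoint), 0)
  expect_equal(dice_score(disjoint), 0)
})

test_that("metrics agree with the set-based oracle and with each other", {
  set.seed(44)
  for (k in 1:120) {
    H <- sample(2:16, 1); W <- sample(2:16, 1)
    pred <- random_mask(H, W, runif(1)); truth <- random_mask(H, W, runif(1))
    cc <- confusion_counts(pred, truth)
    oc <- oracle_metrics(pred, truth)
    expect_equal(iou_score(cc), oc$iou, tolerance = 1e-14)
    expect_equal(dice_score(cc), oc$dice, tolerance = 1e-14)
    expect_equal(pixel_accuracy_per_class(cc), oc$mpa, tolerance = 1e-14)
    # symmetry and the Dice = 2 IoU/(1+IoU) identity
    expect_equal(iou_score(cc), iou_score(confusion_counts(truth, pred)))
    expect_equal(dice_score(cc), 2 * iou_score(cc) / (1 + iou_score(cc)),
                 tolerance = 1e-14)
  }
})

test_that("correcting one foreground pixel never decreases IoU or Dice", {
  set.seed(45)
  for (k in 1:40) {
    truth <- random_mask(8, 8, 0.4)
    pred <- truth; pred[random_mask(8, 8, 0.3) == 1L] <- 0L
    missed <- which(truth == 1L & pred == 0L)
    if (length(missed) == 0) next
    cc0 <- confusion_counts(pred, truth)
    pred[missed[1]] <- 1L
    cc1 <- confusion_counts(pred, truth)
    expect_gte(iou_score(cc1), iou_score(cc0))
    expect_gte(dice_score(cc1), dice_score(cc0))
  }
})

test_that("micro and per-image aggregation behave as documented", {
  set.seed(46)
  p <- random_mask(6, 6, 0.3); t1 <- random_mask(6, 6, 0.3)
  single_micro <- evaluate_dataset(list(p), list(t1), mode = "micro")
  single_per <- evaluate_dataset(list(p), list(t1), mode = "per_image")
  for (f in c("mpa", "miou", "iou_fg", "dice"))
    expect_equal(single_micro[[f]], single_per[[f]])

  # two images, equal pixel and foreground counts, IoU 1 and 0
  a <- matrix(0L, 4, 4); a[1:2, 1] <- 1L
  b <- matrix(0L, 4, 4); b[3:4, 4] <- 1L
  rep2 <- evaluate_dataset(list(a, a), list(a, b), mode = "per_image")
  expect_equal(mean(rep2$per_image$iou_fg), 0.5)
  expect_equal(rep2$iou_fg, 0.5)

  # micro dice always equals the IoU transform of pooled counts
  preds <- lapply(1:5, function(i) random_mask(7, 9, 0.2))
  truths <- lapply(1:5, function(i) random_mask(7, 9, 0.2))
  mi <- evaluate_dataset(preds, truths, mode = "micro")
  expect_equal(mi$dice, 2 * mi$iou_fg / (1 + mi$iou_fg), tolerance = 1e-14)
  expect_equal(mi$miou, (mi$iou_fg + mi$iou_bg) / 2)

  expect_error(evaluate_dataset(list(), list()), "empty")
})

test_that("metric reports serialise to TSV with a summary row", {
  set.seed(47)
  rep <- evaluate_dataset(list(random_mask(5, 5)), list(random_mask(5, 5)),
                          ids = "case1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(rep, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$id, c("case1", "<micro>"))
  expect_equal(tab$miou[2], rep$miou)
})
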