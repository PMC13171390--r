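# Confusion metrics, AUC, and PR curves against brute-force oracles.

test_that("worked confusion cases", {
  gt <- matrix(c(1, 0, 1, 0), 2, 2)   # column-major: [1,0;1,0]
  # perfect prediction
  r <- vessel_metrics(gt, gt)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1); expect_equal(r$dice, 1)
  # total disagreement
  r2 <- vessel_metrics(1 - gt, gt)
  expect_equal(r2$sensitivity, 0); expect_equal(r2$specificity, 0)
  # the 2x2 worked case: gt = [1,1,0,0], pred = [1,0,1,0]
  gt3 <- matrix(c(1, 1, 0, 0), 2, 2)
  pr3 <- matrix(c(1, 0, 1, 0), 2, 2)
  r3 <- vessel_metrics(pr3, gt3)
  expect_equal(unlist(r3[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  expect_equal(r3$accuracy, 0.5)
  expect_equal(r3$dice, 0.5)
})

test_that("rates reproduce a per-pixel loop oracle on random grids", {
  set.seed(123)
  for (i in 1:60) {
    pred <- matrix(runif(32 * 32), 32, 32)
    gt <- matrix(rbinom(32 * 32, 1, runif(1, .05, .9)), 32, 32)
    mask <- matrix(rbinom(32 * 32, 1, .8), 32, 32)
    th <- runif(1, .2, .8)
    got <- vessel_metrics(pred, gt, mask, th)
    want <- oracle_confusion(pred, gt, mask, th)
    for (f in names(want)) {
      if (is.nan(want[[f]])) expect_true(is.nan(got[[f]]))
      else expect_equal(got[[f]], want[[f]], info = f)
    }
    expect_equal(got$tp + got$fp + got$tn + got$fn, sum(mask))
  }
})

test_that("undefined rates are NaN and flagged, never silently 0", {
  r <- vessel_metrics(matrix(0.1, 4, 4), matrix(0, 4, 4))
  expect_true(is.nan(r$sensitivity))
  expect_true("sensitivity" %in% r$undefined)
  expect_true("auc_roc" %in% r$undefined)
})

test_that("AUC equals the positive-negative pair enumeration", {
  # worked 4-pixel case
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  sc <- matrix(c(0.9, 0.4, 0.6, 0.1), 2, 2)
  expect_equal(auc_roc(sc, gt), 0.75)
  # perfect separation and constant scores
  expect_equal(auc_roc(matrix(c(.9, .8, .2, .1), 2, 2), gt), 1.0)
  expect_equal(auc_roc(matrix(0.5, 2, 2), gt), 0.5)
  set.seed(99)
  for (i in 1:25) {
    sc <- matrix(sample(seq(0, 1, by = .05), 64, replace = TRUE), 8, 8)
    gt <- matrix(rbinom(64, 1, .4), 8, 8)
    if (all(gt == 0) || all(gt == 1)) next
    expect_equal(auc_roc(sc, gt), oracle_auc_pairs(as.vector(sc), as.vector(gt)))
  }
  expect_warning(auc_roc(matrix(.5, 2, 2), matrix(1, 2, 2)), "one class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  sc <- matrix(runif(100), 10, 10)
  gt <- matrix(rbinom(100, 1, .3), 10, 10)
  a0 <- auc_roc(sc, gt)
  expect_equal(auc_roc(sc^3, gt), a0)
  expect_equal(auc_roc(plogis(5 * sc - 2), gt), a0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  sc <- matrix(runif(400), 20, 20)
  gt <- matrix(rbinom(400, 1, .25), 20, 20)
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(gt), as.vector(sc),
                                      direction = "<", levels = c("0", "1"),
                                      quiet = TRUE)))
  expect_equal(auc_roc(sc, gt), ref, tolerance = 1e-12)
})

test_that("PR curve endpoints and monotonicity", {
  set.seed(8)
  sc <- matrix(runif(64), 8, 8)
  gt <- matrix(rbinom(64, 1, .4), 8, 8)
  pc <- pr_curve(sc, gt, n_thresholds = 21)
  expect_equal(pc$recall[pc$threshold == 0], 1.0)
  # recall non-increasing as threshold rises
  pc_sorted <- pc[order(pc$threshold), ]
  expect_true(all(diff(pc_sorted$recall) <= 1e-12))
  # perfect scores contain (recall 1, precision 1)
  pc2 <- pr_curve(gt, gt, n_thresholds = 11)
  expect_true(any(pc2$recall == 1 & pc2$precision == 1))
  # worked case at threshold 0.5
  gt3 <- matrix(c(1, 1, 0, 0), 2, 2)
  pr3 <- matrix(c(0.9, 0.4, 0.6, 0.1), 2, 2)
  pc3 <- pr_curve(pr3, gt3, n_thresholds = 3)
  row <- pc3[abs(pc3$threshold - 0.5) < 1e-9, ]
  expect_equal(row$recall, 0.5)
  expect_equal(row$precision, 0.5)
})

test_that("masking equals explicit subsetting", {
  set.seed(12)
  pred <- matrix(runif(100), 10, 10)
  gt <- matrix(rbinom(100, 1, .3), 10, 10)
  mask <- matrix(rbinom(100, 1, .6), 10, 10)
  a <- vessel_metrics(pred, gt, mask)
  keep <- mask == 1
  b <- vessel_metrics(matrix(pred[keep], ncol = 1),
                      matrix(gt[keep], ncol = 1))
  for (f in c("sensitivity", "specificity", "accuracy", "dice", "iou", "auc_roc"))
    expect_equal(a[[f]], b[[f]], info = f)
})

test_that("aggregate evaluation is the mean of per-image reports", {
  set.seed(14)
  preds <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
  gts <- replicate(3, matrix(rbinom(64, 1, .3), 8, 8), simplify = FALSE)
  ev <- evaluate_predictions(preds, gts)
  expect_equal(ev$aggregate$dice,
               mean(vapply(ev$per_image, function(r) r$dice, numeric(1))))
})
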