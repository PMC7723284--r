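# Confusion-matrix metrics, AUROC, report layout.

test_that("confusion counts and symmetry under prediction flips", {
  y <- c(rep("ADD", 6), rep("NC", 4))
  cm <- confusion(y, y, "ADD")
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(6, 4, 0, 0))
  flip <- ifelse(y == "ADD", "NC", "ADD")
  cmf <- confusion(y, flip, "ADD")
  expect_equal(c(cmf$TP, cmf$TN), c(0, 0))
  expect_equal(c(cmf$FN, cmf$FP), c(cm$TP, cm$TN))
  expect_error(confusion(character(0), character(0), "ADD"), "non-empty")
})

test_that("metric formulas reproduce the hand-computed case", {
  cm <- structure(list(TP = 2, TN = 2, FP = 1, FN = 1, positive_class = "ADD"),
                  class = "confusion_matrix")
  m <- metrics(cm)
  expect_equal(m$accuracy, 200 / 3, tolerance = 1e-9)
  expect_equal(m$precision, 200 / 3, tolerance = 1e-9)
  expect_equal(m$recall, 200 / 3, tolerance = 1e-9)
  expect_equal(m$f1, 200 / 3, tolerance = 1e-9)
  expect_equal(m$mcc, 1 / 3, tolerance = 1e-9)

  perfect <- metrics(confusion(c("a", "a", "b"), c("a", "a", "b"), "a"))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)
  expect_equal(perfect$mcc, 1)
})

test_that("zero denominators yield NA metrics and zero MCC", {
  all_neg <- confusion(c("a", "b", "b"), c("b", "b", "b"), "a")
  m <- metrics(all_neg)
  expect_true(is.na(m$precision)) # TP + FP = 0
  expect_equal(m$mcc, 0)
})

test_that("the F1 helper reproduces a reported ensemble cell", {
  expect_equal(f1_score(90.62, 95.08), 92.80, tolerance = 0.01)
  expect_true(is.na(f1_score(0, 0)))
})

test_that("rank-based AUROC matches pair counting and tie conventions", {
  expect_equal(auroc(c(0.9, 0.8, 0.3), c(1, 1, 0), positive_class = 1), 1.0)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.3), c(1, 0, 0, 1), positive_class = 1), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0), positive_class = 1), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1), positive_class = 1), "both classes")
})

test_that("report tables have the region + ensemble layout with F1 identities", {
  set.seed(21)
  units <- c("LH", "RH", "LA", "RA", "LI", "RI", "ensemble")
  mk <- function(task) {
    pos <- strsplit(task, "v")[[1]][1]
    neg <- strsplit(task, "v")[[1]][2]
    truth <- rep(c(pos, neg), each = 10)
    do.call(rbind, lapply(units, function(u) {
      pred <- ifelse(runif(20) < 0.8, truth, ifelse(truth == pos, neg, pos))
      data.frame(
        subject_id = sprintf("s%02d", 1:20), class_label = truth,
        task = task, unit = u,
        S_i = pmin(pmax(ifelse(pred == pos, 0.8, 0.2) + rnorm(20, 0, 0.05), 0), 1),
        S_j = NA_real_, predicted = pred, stringsAsFactors = FALSE
      )
    }))
  }
  dec <- rbind(mk("ADDvNC"), mk("mADvNC"))
  tab <- report_table(dec)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$unit[7], "ensemble")
  expect_equal(sum(tab$unit == "ensemble"), 1)
  expect_true(all(c("ADDvNC.f1", "mADvNC.auroc") %in% names(tab)))
  for (tn in c("ADDvNC", "mADvNC")) {
    p <- tab[[paste0(tn, ".precision")]]
    r <- tab[[paste0(tn, ".recall")]]
    f <- tab[[paste0(tn, ".f1")]]
    expect_equal(f, round(2 * p * r / (p + r), 2), tolerance = 0.011)
  }
  one_task <- dec[dec$task == "ADDvNC" & dec$unit != "LI", ]
  expect_warning(report_table(one_task), "no decisions")
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    truth <- sample(c("pos", "neg"), n, replace = TRUE)
    pred <- sample(c("pos", "neg"), n, replace = TRUE)
    cm <- confusion(truth, pred, "pos")
    marg <- c(cm$TP + cm$FP, cm$TP + cm$FN, cm$TN + cm$FP, cm$TN + cm$FN)
    if (any(marg == 0)) next
    expect_equal(
      metrics(cm)$mcc,
      cor(as.numeric(truth == "pos"), as.numeric(pred == "pos")),
      tolerance = 1e-9
    )
  }
})
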