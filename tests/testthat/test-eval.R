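test_that("instance reconciliation follows the largest-area rule", {
  pred <- matrix(0L, 40, 40)
  pred[1:25, 1:40] <- class_code("GP3")    # 1000 px
  pred[26:40, 1:40] <- class_code("GP4")   # 600 px
  mask <- matrix(TRUE, 40, 40)
  rec <- reconcile_instance_label(pred, mask)
  expect_identical(rec$label, "GP3")
  expect_identical(unname(rec$areas[["GP3"]]), 1000L)

  single <- matrix(class_code("GP5"), 10, 10)
  expect_identical(reconcile_instance_label(single,
                                            matrix(TRUE, 10, 10))$label,
                   "GP5")

  tie <- matrix(0L, 10, 10)
  tie[1:5, ] <- class_code("GP3"); tie[6:10, ] <- class_code("GP4")
  expect_identical(reconcile_instance_label(tie, matrix(TRUE, 10, 10))$label,
                   "GP4")  # severity breaks exact ties

  unscored <- matrix(0L, 10, 10)
  expect_error(reconcile_instance_label(unscored, matrix(TRUE, 10, 10)),
               "unscored")
})

test_that("classification metrics match the 2x2 arithmetic", {
  gt <- c("GP3", "GP4", "benign", "stroma")
  expect_equal(suppressWarnings(classification_metrics(gt, gt))$macro_f1, 1)
  expect_equal(suppressWarnings(classification_metrics(gt, gt))$binary$npv, 1)

  # gt (M, M, N, N), pred (M, N, N, N)
  gt2 <- c("GP3", "GP5", "benign", "stroma")
  pr2 <- c("GP3", "benign", "benign", "stroma")
  b <- suppressWarnings(classification_metrics(gt2, pr2))$binary
  expect_equal(b$sensitivity, 0.5)
  expect_equal(b$specificity, 1)
  expect_equal(b$ppv, 1)
  expect_equal(b$npv, 2 / 3)

  # GP5 counts as malignant in the binary grouping
  expect_equal(suppressWarnings(classification_metrics(
    c("GP5", "benign"), c("GP5", "benign")))$binary$sensitivity, 1)

  # macro F1 is the arithmetic mean of per-class F1
  mt <- suppressWarnings(classification_metrics(gt2, pr2))
  expect_equal(mt$macro_f1, mean(mt$per_class$f1), tolerance = 1e-12)
  expect_warning(classification_metrics(c("GP3", "GP4"), c("GP3", "GP4")),
                 "excluded")
})

test_that("metrics are invariant to joint permutation of the label vectors", {
  set.seed(61)
  gt <- sample(gleason_classes(), 60, replace = TRUE)
  pred <- sample(gleason_classes(), 60, replace = TRUE)
  perm <- sample.int(60)
  a <- suppressWarnings(classification_metrics(gt, pred))
  b <- suppressWarnings(classification_metrics(gt[perm], pred[perm]))
  expect_equal(a$per_class, b$per_class)
  expect_equal(a$binary, b$binary)
})

test_that("the grade-group mapping is total and matches the clinical table", {
  expected <- list("3+3" = 1L, "3+4" = 2L, "4+3" = 3L, "3+5" = 4L,
                   "5+3" = 4L, "4+4" = 4L, "4+5" = 5L, "5+4" = 5L,
                   "5+5" = 5L)
  for (p in 3:5) for (s in 3:5) {
    gg <- grade_group(p, s)
    expect_identical(gg$group, expected[[paste(p, s, sep = "+")]])
    expect_identical(gg$gleason_score, p + s)
  }
})

test_that("slide-level Gleason derivation uses areas and the 5% floor", {
  pred <- matrix(0L, 100, 100)
  pred[1:60, 1:100] <- class_code("GP3")
  pred[61:100, 1:100] <- class_code("GP4")
  gg <- slide_gleason(pred)
  expect_identical(gg$group, 2L)          # 3 + 4
  expect_identical(gg$primary, 3L)

  pred2 <- matrix(class_code("GP4"), 50, 50)
  expect_identical(slide_gleason(pred2)$group, 4L)  # 4 + 4 = 8

  benign <- matrix(class_code("benign"), 50, 50)
  expect_true(is.na(slide_gleason(benign)$group))

  # secondary below the 5% floor collapses to the primary
  pred3 <- matrix(class_code("GP4"), 100, 100)
  pred3[1:2, 1:100] <- class_code("GP3")  # 2% of malignant area
  expect_identical(slide_gleason(pred3)$gleason_score, 8L)
  pred3[1:10, 1:100] <- class_code("GP3") # 10%
  expect_identical(slide_gleason(pred3)$group, 3L)  # 4 + 3
})

test_that("quadratic weighted kappa matches its defining formula", {
  expect_equal(quadratic_weighted_kappa(c(1, 2, 3), c(1, 2, 3), 5), 1)
  expect_equal(quadratic_weighted_kappa(c(1, 2), c(2, 1), 2), -1)
  set.seed(71)
  a <- sample.int(5, 40, replace = TRUE)
  b <- sample.int(5, 40, replace = TRUE)
  expect_equal(quadratic_weighted_kappa(a, b, 5),
               quadratic_weighted_kappa(b, a, 5), tolerance = 1e-12)
  expect_error(quadratic_weighted_kappa(1, 1, 1), "k")

  # independent direct-formula oracle: explicit double loop over pairs
  qwk_direct <- function(a, b, k) {
    n <- length(a)
    num <- 0; den <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      w <- (i - j)^2 / (k - 1)^2
      o <- sum(a == i & b == j) / n
      e <- (sum(a == i) / n) * (sum(b == j) / n)
      num <- num + w * o
      den <- den + w * e
    }
    1 - num / den
  }
  for (rep in 1:25) {
    set.seed(rep)
    k <- sample(2:6, 1)
    a <- sample.int(k, 30, replace = TRUE)
    b <- sample.int(k, 30, replace = TRUE)
    if (length(unique(c(a, b))) == 1L) next
    expect_lt(abs(quadratic_weighted_kappa(a, b, k) - qwk_direct(a, b, k)),
              1e-12)
  }
})

test_that("timing summaries reproduce fold speedups and reductions", {
  expect_equal(timing_summary(1267, 508)$fold_speedup, 2.5)
  expect_identical(
    suppressWarnings(timing_summary(c(148, 147), 84))$percent_reduction, 43L)
  same <- timing_summary(c(100, 100), c(100, 100))
  expect_equal(same$fold_speedup, 1)
  expect_identical(same$percent_reduction, 0L)
  expect_warning(unequal <- timing_summary(c(10, 20, 30), c(5, 6)), "paired")
  expect_true(is.na(unequal$p_value))
  paired <- timing_summary(c(100, 120, 140, 160), c(50, 60, 70, 80))
  expect_lt(paired$p_value, 0.05)
  expect_error(timing_summary(c(-1, 5), 3), "positive")
})

test_that("annotation-level evaluation reconciles instances against rasters", {
  img <- mixed_slide(53, side = 256, block_side = 64)
  ann <- generate_annotation_set(img$labels, 1, seed = 1)
  perfect <- suppressWarnings(evaluate_annotations(img$labels, ann))
  expect_equal(perfect$metrics$macro_f1, 1)
  # instances mostly unscored are excluded
  partial <- img$labels
  partial[1:128, ] <- 0L
  ev <- suppressWarnings(evaluate_annotations(partial, ann))
  expect_lte(nrow(ev$instances), length(ann))
})
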