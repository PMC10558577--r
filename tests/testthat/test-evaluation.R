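test_that("confusion matrix has fixed ascending-code shape", {
  truth <- rep(size_labels()$code, each = 20)
  cm <- confusion_matrix(truth, truth)
  expect_equal(dim(cm), c(9, 9))
  expect_equal(sum(diag(cm)), 180)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm1 <- confusion_matrix("3310", "4110")
  expect_equal(sum(cm1), 1)
  expect_equal(cm1["3310", "4110"], 1L)

  expect_error(confusion_matrix(c("3308", "3310"), "3308"),
               class = "implant_cardinality_error")
  expect_error(confusion_matrix("9999", "3308"), class = "implant_value_error")
})

test_that("one-vs-rest binarization matches the published counts", {
  rp <- reconstruct_predictions(reference_counts("deep_learning"))
  cm <- confusion_matrix(rp$truth, rp$pred)
  b <- binarize(cm, "3310")
  expect_equal(c(b$TP, b$TN, b$FP, b$FN), c(19, 160, 0, 1))
  # accounting identity: sum of TP = total - total errors
  tps <- vapply(size_labels()$code, function(cc) binarize(cm, cc)$TP, 0L)
  expect_equal(sum(tps), sum(cm) - total_errors(rp$truth, rp$pred))
  # perfect matrix: no off-diagonal mass
  perfect <- confusion_matrix(rp$truth, rp$truth)
  for (cc in size_labels()$code) {
    bp <- binarize(perfect, cc)
    expect_equal(bp$FP + bp$FN, 0L)
  }
})

test_that("ratio metrics reproduce published rows to printed precision", {
  m1 <- compute_metrics(binary_counts(19, 160, 0, 1))
  expect_equal(implantsize:::round_half_up(unlist(m1)),
               c(accuracy = 0.994, sensitivity = 0.950, specificity = 1.000,
                 f1 = 0.974, ppv = 1.000, npv = 0.994, auc = 0.975))
  m2 <- compute_metrics(binary_counts(18, 159, 1, 2))
  expect_equal(implantsize:::round_half_up(unlist(m2)),
               c(accuracy = 0.983, sensitivity = 0.900, specificity = 0.994,
                 f1 = 0.923, ppv = 0.947, npv = 0.988, auc = 0.947))
  m3 <- compute_metrics(binary_counts(20, 160, 0, 0))
  expect_true(all(unlist(m3) == 1))

  # invariants: auc is exactly balanced accuracy; complements sum to one
  set.seed(3)
  for (i in 1:50) {
    cts <- as.list(sample(0:40, 4, replace = TRUE))
    if (sum(unlist(cts)) == 0) next
    b <- do.call(binary_counts, cts)
    m <- compute_metrics(b)
    expect_identical(m$auc, (m$sensitivity + m$specificity) / 2)
    if (b$n_pos > 0) {
      expect_equal(m$sensitivity + b$FN / b$n_pos, 1)
    }
    expect_equal(m$accuracy, (b$TP + b$TN) / (b$TP + b$TN + b$FP + b$FN))
  }

  # zero-denominator convention
  z <- compute_metrics(binary_counts(0, 10, 0, 0))
  expect_equal(z$sensitivity, 0)
  expect_equal(z$ppv, 0)
  expect_equal(z$f1, 0)
  expect_error(compute_metrics(binary_counts(0, 0, 0, 0)),
               class = "implant_domain_error")
})

test_that("DeLong interval matches published bounds and degenerates cleanly", {
  ci1 <- auc_ci_delong(binary_counts(19, 160, 0, 1))
  expect_equal(implantsize:::round_half_up(ci1$ci_low), 0.926)
  expect_equal(ci1$ci_high, 1)
  ci2 <- auc_ci_delong(binary_counts(18, 159, 1, 2))
  expect_equal(implantsize:::round_half_up(ci2$ci_low), 0.879)
  expect_equal(ci2$ci_high, 1)
  perf <- auc_ci_delong(binary_counts(20, 160, 0, 0))
  expect_identical(perf$variance, 0)
  expect_equal(c(perf$ci_low, perf$ci_high), c(1, 1))
  # variance is zero iff the label is classified perfectly
  imp <- auc_ci_delong(binary_counts(19, 160, 0, 1))
  expect_gt(imp$variance, 0)
  expect_error(auc_ci_delong(binary_counts(0, 160, 0, 0)),
               class = "implant_domain_error")
})

test_that("total error counts follow the confusion-matrix trace", {
  truth <- c("3308", "3310", "4110")
  expect_equal(total_errors(truth, truth), 0L)
  expect_equal(total_errors(truth, c("3308", "4110", "4110")), 1L)
  expect_error(total_errors(truth, truth[1:2]),
               class = "implant_cardinality_error")
})

test_that("metrics table always reports nine rows in code order", {
  truth <- rep(size_labels()$code, each = 4)
  pred <- truth
  pred[1] <- "4812"  # single error touching two labels only
  tab <- metrics_table(truth, pred)
  expect_equal(nrow(tab), 9)
  expect_identical(tab$code, size_labels()$code)
  perfect <- metrics_table(truth, truth)
  expect_true(all(perfect$accuracy == 1 & perfect$auc == 1 &
                  perfect$ci_low == 1))
  expect_equal(sum(tab$FN), total_errors(truth, pred))
})

test_that("chi-square comparison follows the Pearson formula", {
  codes <- size_labels()$code
  truth <- rep(codes, each = 20)
  # identical models: statistic 0, p 1 (degenerate where both are perfect)
  cmp0 <- suppressWarnings(compare_before_after(truth, truth, truth))
  expect_true(all(cmp0$statistic == 0))
  expect_true(all(cmp0$p_value == 1))
  expect_true(all(!cmp0$significant))

  # textbook oracle on the 2x2 table [[170,10],[179,1]]
  o <- matrix(c(170, 10, 179, 1), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  stat_oracle <- sum((o - e)^2 / e)
  # build predictions realizing exactly that correctness table for 3308
  pred_b <- truth; pred_b[which(truth == "3308")[1:10]] <- "3310"
  pred_a <- truth; pred_a[which(truth == "3308")[1]] <- "3310"
  cmp <- suppressWarnings(compare_before_after(truth, pred_b, pred_a))
  row <- cmp[cmp$code == "3308", ]
  expect_equal(row$statistic, stat_oracle, tolerance = 1e-12)
  expect_identical(row$significant, row$p_value < 0.05)

  # a large induced improvement is flagged as significant
  pred_bad <- truth
  idx <- which(truth == "4110")
  pred_bad[idx[1:15]] <- "4112"
  cmp2 <- suppressWarnings(compare_before_after(truth, pred_bad, truth))
  expect_true(cmp2$significant[cmp2$code == "4110"])
})

test_that("reconstructed predictions reproduce every one-vs-rest count", {
  for (model in c("deep_learning", "clustering")) {
    counts <- reference_counts(model)
    rp <- reconstruct_predictions(counts)
    cm <- confusion_matrix(rp$truth, rp$pred)
    for (i in seq_len(nrow(counts))) {
      b <- binarize(cm, counts$code[i])
      expect_equal(c(b$TP, b$TN, b$FP, b$FN),
                   c(counts$TP[i], counts$TN[i], counts$FP[i], counts$FN[i]))
    }
  }
  bad <- reference_counts("clustering")
  bad$FN[1] <- bad$FN[1] + 1L
  expect_error(reconstruct_predictions(bad), class = "implant_value_error")
})

test_that("scatter export carries all points, nine centroids, padded axes", {
  cfg <- sim_preset("full", per_class = 10, seed = 23)
  f <- generate_features(cfg)
  m <- map_clusters_to_labels(fit_size_model(f, w = 2, seed = 5), f)
  df <- scatter_data(f, m)
  expect_equal(sum(df$role == "point"), nrow(f))
  expect_equal(sum(df$role == "centroid"), 9)
  expect_setequal(df$code[df$role == "centroid"], size_labels()$code)
  # centroid coordinates are reported in the untransformed mm plane
  expect_equal(sort(df$D_mm[df$role == "centroid"]),
               sort(m$centroids[, 1] / m$w))

  p <- scatter_plot(f, m)
  b <- ggplot2::ggplot_build(p)
  xr <- b$layout$panel_params[[1]]$x.range
  yr <- b$layout$panel_params[[1]]$y.range
  expect_lt(xr[1], min(f$D_mm)); expect_gt(xr[2], max(f$D_mm))
  expect_lt(yr[1], min(f$L_mm)); expect_gt(yr[2], max(f$L_mm))

  csv <- withr::local_tempfile(fileext = ".csv")
  img <- withr::local_tempfile(fileext = ".pdf")
  scatter_export(f, m, csv, img)
  expect_true(file.size(csv) > 0 && file.size(img) > 0)
  back <- implantsize:::read_table_csv(csv, numeric_cols = c("D_mm", "L_mm"))
  expect_equal(nrow(back), nrow(df))
})
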