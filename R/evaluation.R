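#' Nine-class confusion matrix
#'
#' Rows are true size codes, columns predicted codes, both in fixed
#' ascending-code order over the nine catalogue sizes (so the matrix shape
#' is stable regardless of which codes appear).
#'
#' @param truth,pred Equal-length character vectors of size codes.
#' @return A 9 x 9 integer matrix of counts with dimnames `truth`/`pred`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    isz_error("truth and pred must have equal length", "implant_cardinality_error")
  }
  codes <- size_codes()
  bad <- setdiff(unique(c(truth, pred)), codes)
  if (length(bad)) {
    isz_error(sprintf("unknown size code(s): %s", paste(bad, collapse = ", ")),
              "implant_value_error")
  }
  m <- table(truth = factor(truth, levels = codes),
             pred = factor(pred, levels = codes))
  matrix(as.integer(m), 9, 9, dimnames = list(truth = codes, pred = codes))
}

#' One-vs-rest counts for a single size code
#'
#' Treats `code` as positive and the eight other sizes as negative:
#' TP is the diagonal cell, FN the rest of the row, FP the rest of the
#' column, TN everything else.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param code The positive size code.
#' @return A `binary_counts` object.
#' @export
binarize <- function(cm, code) {
  codes <- size_codes()
  if (!code %in% codes) {
    isz_error(sprintf("unknown size code '%s'", code), "implant_value_error")
  }
  tp <- cm[code, code]
  fn <- sum(cm[code, ]) - tp
  fp <- sum(cm[, code]) - tp
  tn <- sum(cm) - tp - fn - fp
  binary_counts(tp, tn, fp, fn)
}

#' Construct one-vs-rest TP/TN/FP/FN counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `binary_counts` object (list with `TP`, `TN`, `FP`, `FN`,
#'   `n_pos = TP + FN`, `n_neg = TN + FP`).
#' @export
binary_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v))) {
    isz_error("counts must be non-negative integers", "implant_value_error")
  }
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn),
                 n_pos = as.integer(tp + fn), n_neg = as.integer(tn + fp)),
            class = "binary_counts")
}

#' Performance metrics from one-vs-rest counts
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, F1 `2*recall*precision/(recall+precision)`, PPV
#' `TP/(TP+FP)`, NPV `TN/(TN+FN)`, and the single-operating-point AUC
#' `(sensitivity+specificity)/2` (the ROC of a hard-label classifier has
#' one interior point, so its area reduces to balanced accuracy). Any
#' metric with a zero denominator is defined as 0.
#'
#' @param counts A `binary_counts` object.
#' @return One-row data frame with columns `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `ppv`, `npv`, `auc`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "binary_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) {
    isz_error("empty counts: nothing was evaluated", "implant_domain_error")
  }
  frac <- function(num, den) if (den == 0) 0 else num / den
  se <- frac(counts$TP, counts$n_pos)
  sp <- frac(counts$TN, counts$n_neg)
  ppv <- frac(counts$TP, counts$TP + counts$FP)
  data.frame(
    accuracy = (counts$TP + counts$TN) / total,
    sensitivity = se,
    specificity = sp,
    f1 = frac(2 * se * ppv, se + ppv),
    ppv = ppv,
    npv = frac(counts$TN, counts$TN + counts$FN),
    auc = (se + sp) / 2
  )
}

#' DeLong confidence interval for the single-operating-point AUC
#'
#' Treats the hard classifier as a two-valued score (predicted-positive =
#' 1, predicted-negative = 0) and applies the DeLong placement-value
#' variance estimator: each positive's placement is the fraction of
#' negatives scored below it (ties count half), and symmetrically for
#' negatives; `var = var(pos placements)/n_pos + var(neg placements)/n_neg`
#' with sample (n-1) variances. The interval is `auc +/- z * sqrt(var)`,
#' clipped to [0, 1]. The variance is zero exactly when the classifier is
#' perfect on that label, collapsing both bounds onto 1.
#'
#' @param counts A `binary_counts` object with at least one positive and
#'   one negative.
#' @param z Normal critical value (1.96 for a 95% interval).
#' @return List with `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
auc_ci_delong <- function(counts, z = 1.96) {
  stopifnot(inherits(counts, "binary_counts"))
  if (counts$n_pos == 0 || counts$n_neg == 0) {
    isz_error("DeLong CI needs both positives and negatives",
              "implant_domain_error")
  }
  pos <- rep(c(1, 0), c(counts$TP, counts$FN))
  neg <- rep(c(1, 0), c(counts$FP, counts$TN))
  plac_pos <- vapply(pos, function(s) {
    (sum(neg < s) + 0.5 * sum(neg == s)) / length(neg)
  }, numeric(1))
  plac_neg <- vapply(neg, function(s) {
    (sum(pos > s) + 0.5 * sum(pos == s)) / length(pos)
  }, numeric(1))
  auc <- mean(plac_pos)
  v <- function(p) if (length(p) > 1L) stats::var(p) else 0
  variance <- v(plac_pos) / length(pos) + v(plac_neg) / length(neg)
  half <- z * sqrt(variance)
  list(auc = auc, variance = variance,
       ci_low = max(0, auc - half), ci_high = min(1, auc + half))
}

#' Count misclassified records
#'
#' @param truth,pred Equal-length code vectors.
#' @return Number of positions where `truth != pred` (equals the evaluated
#'   total minus the confusion-matrix trace).
#' @export
total_errors <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    isz_error("truth and pred must have equal length", "implant_cardinality_error")
  }
  sum(truth != pred)
}

#' Per-label metrics table with DeLong confidence intervals
#'
#' One row per catalogue size in ascending code order, mirroring the
#' standard report layout: one-vs-rest counts, the six ratio metrics, the
#' single-operating-point AUC and its 95% DeLong interval. Values are
#' exact; use [format_metrics()] for the 3-decimal display convention.
#'
#' @param truth,pred Equal-length code vectors.
#' @param z Normal critical value for the CI.
#' @return Data frame with 9 rows and columns `code`, `TP`, `TN`, `FP`,
#'   `FN`, `accuracy`, `sensitivity`, `specificity`, `f1`, `ppv`, `npv`,
#'   `auc`, `ci_low`, `ci_high`.
#' @export
metrics_table <- function(truth, pred, z = 1.96) {
  cm <- confusion_matrix(truth, pred)
  metrics_from_counts(counts_from_cm(cm), z = z)
}

counts_from_cm <- function(cm) {
  codes <- size_codes()
  do.call(rbind, lapply(codes, function(code) {
    b <- binarize(cm, code)
    data.frame(code = code, TP = b$TP, TN = b$TN, FP = b$FP, FN = b$FN,
               stringsAsFactors = FALSE)
  }))
}

#' Metrics table from tabulated one-vs-rest counts
#'
#' Same as [metrics_table()] but starting from already-tabulated counts
#' (e.g. a published benchmark table) instead of prediction vectors.
#'
#' @param counts_df Data frame with columns `code`, `TP`, `TN`, `FP`, `FN`.
#' @param z Normal critical value for the CI.
#' @return As [metrics_table()].
#' @export
metrics_from_counts <- function(counts_df, z = 1.96) {
  need <- c("code", "TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts_df))) {
    isz_error("counts_df needs columns code, TP, TN, FP, FN",
              "implant_format_error")
  }
  rows <- lapply(seq_len(nrow(counts_df)), function(i) {
    b <- binary_counts(counts_df$TP[i], counts_df$TN[i],
                       counts_df$FP[i], counts_df$FN[i])
    m <- compute_metrics(b)
    ci <- auc_ci_delong(b, z = z)
    cbind(counts_df[i, need], m,
          data.frame(ci_low = ci$ci_low, ci_high = ci$ci_high))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a metrics table for display
#'
#' Applies half-up rounding to 3 decimals to every metric column, the
#' convention of the benchmark report.
#'
#' @param metrics Data frame from [metrics_table()] or
#'   [metrics_from_counts()].
#' @param digits Decimal places (default 3).
#' @return The data frame with rounded metric columns.
#' @export
format_metrics <- function(metrics, digits = 3) {
  cols <- intersect(c("accuracy", "sensitivity", "specificity", "f1", "ppv",
                      "npv", "auc", "ci_low", "ci_high"), names(metrics))
  metrics[cols] <- lapply(metrics[cols], round_half_up, digits = digits)
  metrics
}

#' Chi-square comparison of two models' per-label correctness
#'
#' For every size code, cross-tabulates model (before/after tuning) against
#' one-vs-rest correctness (a record is "correct" for a code when
#' membership in that code is judged the same way by prediction and truth)
#' and applies Pearson's chi-square test without continuity correction at
#' significance level 0.05. A degenerate table (zero margin, e.g. both
#' models fully correct) yields statistic 0 and p 1 with a warning. The
#' construction used is reported in the `construction` attribute since
#' several defensible 2x2 layouts exist.
#'
#' @param truth True codes.
#' @param pred_before,pred_after Predictions of the two models on the same
#'   records.
#' @param alpha Significance level.
#' @return Data frame with columns `code`, `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_before_after <- function(truth, pred_before, pred_after, alpha = 0.05) {
  n <- length(truth)
  if (length(pred_before) != n || length(pred_after) != n) {
    isz_error("all three code vectors must have equal length",
              "implant_cardinality_error")
  }
  rows <- lapply(size_codes(), function(code) {
    correct_b <- (truth == code) == (pred_before == code)
    correct_a <- (truth == code) == (pred_after == code)
    tab <- rbind(before = c(correct = sum(correct_b), incorrect = sum(!correct_b)),
                 after = c(correct = sum(correct_a), incorrect = sum(!correct_a)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      isz_warning(sprintf("degenerate before/after table for code %s; statistic set to 0",
                          code), "implant_degenerate_warning")
      stat <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- unname(ct$p.value)
    }
    data.frame(code = code, statistic = stat, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "construction") <-
    "per-label one-vs-rest correctness x model, Pearson chi-square, no continuity correction"
  out
}

#' Reconstruct prediction vectors consistent with one-vs-rest counts
#'
#' Builds `truth`/`pred` vectors whose confusion matrix reproduces the
#' given per-label TP/TN/FP/FN exactly (possible when the counts are
#' mutually consistent, i.e. total FN equals total FP and the implied
#' totals agree). Off-diagonal placement of errors is not determined by
#' one-vs-rest counts; any consistent placement leaves every per-label
#' count and the total error count unchanged.
#'
#' @param counts_df Data frame with columns `code`, `TP`, `TN`, `FP`, `FN`.
#' @return List with character vectors `truth` and `pred`.
#' @export
reconstruct_predictions <- function(counts_df) {
  need <- c("code", "TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts_df))) {
    isz_error("counts_df needs columns code, TP, TN, FP, FN",
              "implant_format_error")
  }
  if (sum(counts_df$FN) != sum(counts_df$FP)) {
    isz_error("inconsistent counts: total FN must equal total FP",
              "implant_value_error")
  }
  truth <- character(0); pred <- character(0)
  fp_left <- stats::setNames(counts_df$FP, counts_df$code)
  for (i in seq_len(nrow(counts_df))) {
    code <- counts_df$code[i]
    truth <- c(truth, rep(code, counts_df$TP[i]))
    pred <- c(pred, rep(code, counts_df$TP[i]))
    for (dummy in seq_len(counts_df$FN[i])) {
      cand <- names(fp_left)[fp_left > 0 & names(fp_left) != code]
      if (!length(cand)) {
        isz_error("counts admit no consistent error placement",
                  "implant_value_error")
      }
      j <- cand[which.max(fp_left[cand])]
      fp_left[j] <- fp_left[j] - 1L
      truth <- c(truth, code)
      pred <- c(pred, j)
    }
  }
  list(truth = truth, pred = pred)
}
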