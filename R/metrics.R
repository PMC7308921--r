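#' Multiclass confusion matrix
#'
#' Entry (i, j) counts instances of true class i predicted as class j.
#'
#' @param truth,predicted Vectors of equal length; every value must belong to
#'   `class_order`.
#' @param class_order Character vector fixing row/column order.
#' @return An integer matrix with named rows (truth) and columns (predicted).
#' @export
confusion_matrix <- function(truth, predicted, class_order = beat_classes()) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad) > 0) {
    abort(sprintf("Labels not in `class_order`: %s.", paste(bad, collapse = ", ")))
  }
  tab <- table(
    factor(truth, levels = class_order),
    factor(predicted, levels = class_order)
  )
  m <- matrix(as.integer(tab), nrow = length(class_order),
              dimnames = list(truth = class_order, predicted = class_order))
  m
}

#' Per-class TP/FP/FN/TN from a confusion matrix
#'
#' For each class: TP is the diagonal entry, FP the column sum minus TP, FN
#' the row sum minus TP, and TN the remainder of the total.
#'
#' @param matrix Square confusion matrix (true rows, predicted columns).
#' @return Tibble with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
per_class_counts <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  total <- sum(matrix)
  tp <- diag(matrix)
  fp <- colSums(matrix) - tp
  fn <- rowSums(matrix) - tp
  tibble(
    class = if (!is.null(rownames(matrix))) rownames(matrix) else as.character(seq_len(nrow(matrix))),
    tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn),
    tn = total - as.numeric(tp) - as.numeric(fp) - as.numeric(fn)
  )
}

safe_ratio <- function(num, den, what) {
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0)) {
    warn(sprintf("Undefined %s (0/0) returned as 0 for %d class(es).", what, sum(den == 0)))
  }
  out
}

#' Per-class metrics from TP/FP/FN/TN, in percent
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2*Pre*Sen/(Pre+Sen)`, each multiplied by 100. An undefined 0/0 ratio is
#' returned as 0 with a warning.
#'
#' @param counts A tibble as returned by [per_class_counts()], or four
#'   numeric vectors `tp`, `fp`, `fn`, `tn`.
#' @param tp,fp,fn,tn Used only when `counts` is missing.
#' @return `counts` with columns `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1` appended (percent).
#' @export
class_metrics <- function(counts, tp, fp, fn, tn) {
  if (missing(counts)) {
    counts <- tibble(class = seq_along(tp), tp = tp, fp = fp, fn = fn, tn = tn)
  }
  counts |>
    mutate(
      accuracy = 100 * (.data$tp + .data$tn) /
        (.data$tp + .data$tn + .data$fp + .data$fn),
      sensitivity = 100 * safe_ratio(.data$tp, .data$tp + .data$fn, "sensitivity"),
      specificity = 100 * safe_ratio(.data$tn, .data$tn + .data$fp, "specificity"),
      precision = 100 * safe_ratio(.data$tp, .data$tp + .data$fp, "precision"),
      f1 = safe_ratio(
        2 * .data$precision * .data$sensitivity,
        .data$precision + .data$sensitivity, "F1"
      )
    )
}

#' Full confusion report with macro-averaged metrics
#'
#' Builds the confusion matrix (or accepts one), the per-class counts and
#' metrics, and the overall row: overall accuracy is micro (trace / total)
#' while sensitivity, specificity, precision and F1 are macro averaged
#' (unweighted mean over classes), so minority arrhythmias weigh equally.
#'
#' @param truth True labels, or a square confusion matrix (then leave
#'   `predicted` missing).
#' @param predicted Predicted labels.
#' @param class_order Class ordering for the matrix.
#' @return An object of class `confusion_report`: list with `matrix`,
#'   `per_class` (tibble) and `overall` (one-row tibble).
#' @examples
#' rep <- confusion_report(c("N", "N", "V"), c("N", "V", "V"), c("N", "V"))
#' glance(rep)
#' @export
confusion_report <- function(truth, predicted, class_order = beat_classes()) {
  m <- if (is.matrix(truth) && missing(predicted)) {
    truth
  } else {
    confusion_matrix(truth, predicted, class_order)
  }
  per_class <- class_metrics(per_class_counts(m))
  overall <- tibble(
    accuracy = 100 * sum(diag(m)) / sum(m),
    macro_sensitivity = mean(per_class$sensitivity),
    macro_specificity = mean(per_class$specificity),
    macro_precision = mean(per_class$precision),
    macro_f1 = mean(per_class$f1),
    n = sum(m)
  )
  structure(
    list(matrix = m, per_class = per_class, overall = overall),
    class = "confusion_report"
  )
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf(
    "<confusion_report> %d classes, n = %d, accuracy %.2f%%, macro F1 %.2f%%\n",
    nrow(x$matrix), sum(x$matrix), x$overall$accuracy, x$overall$macro_f1
  ))
  invisible(x)
}

#' @rdname confusion_report
#' @param x A `confusion_report`.
#' @param ... Unused.
#' @export
tidy.confusion_report <- function(x, ...) x$per_class

#' @rdname confusion_report
#' @export
glance.confusion_report <- function(x, ...) x$overall

#' Imbalance ratio between a majority and a minority class
#'
#' `IR = N_majority / N_minority`; a ratio above 1.5 conventionally marks a
#' dataset as unbalanced.
#'
#' @param n_major,n_minor Class counts; `n_minor` must be positive.
#' @return The ratio (reported to one decimal in the standard tables).
#' @examples
#' imbalance_ratio(74758, 472) # 158.4
#' @export
imbalance_ratio <- function(n_major, n_minor) {
  if (any(n_minor <= 0)) abort("Minority count must be positive.")
  n_major / n_minor
}

#' Pairwise imbalance-ratio table
#'
#' One row per minority class, one column per majority class, each cell the
#' majority/minority count ratio.
#'
#' @param class_counts Named vector of class counts.
#' @param majority,minority Class symbols (defaults: the standard split).
#' @return Tibble with a `minority` column and one numeric column per
#'   majority class, ordered N, L, R, V.
#' @export
imbalance_table <- function(class_counts,
                            majority = c("N", "L", "R", "V"),
                            minority = minority_classes()) {
  stopifnot(all(c(majority, minority) %in% names(class_counts)))
  rows <- purrr::map(minority, function(mi) {
    vals <- purrr::map_dbl(majority, function(ma) {
      imbalance_ratio(class_counts[[ma]], class_counts[[mi]])
    })
    tibble(minority = mi, !!!stats::setNames(as.list(vals), majority))
  })
  bind_rows(rows)
}

#' One-sample t statistic for repeated F1 scores
#'
#' Tests whether the mean of repeated performance runs exceeds a reference
#' value: `t = (mean(x) - mu0) / (S / sqrt(n))` with the sample standard
#' deviation (n - 1 denominator) and `n - 1` degrees of freedom.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @param mu0 Reference mean under the null hypothesis.
#' @return An object of class `one_sample_t` with fields `mean`, `sd`, `n`,
#'   `mu0`, `statistic`, `df`, `p_value` (one-sided, greater).
#' @examples
#' one_sample_t(c(99.7, 99.8, 99.75), mu0 = 98)
#' @export
one_sample_t <- function(values, mu0) {
  if (length(values) < 2) abort("Need at least 2 values.")
  assert_scalar_number(mu0, "mu0")
  s <- sd(values)
  if (s == 0) abort("Zero standard deviation: t statistic undefined.")
  n <- length(values)
  stat <- (mean(values) - mu0) / (s / sqrt(n))
  structure(
    list(
      mean = mean(values), sd = s, n = n, mu0 = mu0,
      statistic = stat, df = n - 1L,
      p_value = stats::pt(stat, df = n - 1, lower.tail = FALSE)
    ),
    class = "one_sample_t"
  )
}

#' @export
print.one_sample_t <- function(x, ...) {
  cat(sprintf(
    "One-sample t: mean %.4g vs mu0 %.4g, t = %.4g (df %d), one-sided p = %.3g\n",
    x$mean, x$mu0, x$statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname one_sample_t
#' @param x A `one_sample_t` object.
#' @param ... Unused.
#' @export
glance.one_sample_t <- function(x, ...) {
  tibble(
    mean = x$mean, sd = x$sd, n = x$n, mu0 = x$mu0,
    statistic = x$statistic, df = x$df, p_value = x$p_value
  )
}

#' @rdname one_sample_t
#' @export
tidy.one_sample_t <- function(x, ...) glance(x)
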