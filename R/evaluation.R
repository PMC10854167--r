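#' Stratified train/validation split
#'
#' Splits samples into a training and a validation partition at the given
#' training fraction, stratified by class: per class, `ceiling(frac * n_c)`
#' samples (clamped so both partitions keep at least one sample when a
#' class has >= 2) go to training. Stratification is the minimal assumption
#' guaranteeing every class appears in the training partition of a
#' many-class model. Seeded and reproducible.
#'
#' @param labels Labels tibble (`sample_id`, `class`).
#' @param train_frac Training fraction, in (0, 1); default 0.30.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `valid` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_frac = 0.30, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  sizes <- table(labels$class)
  if (any(sizes < 2)) {
    stop("classes with a single sample cannot be split: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  train <- unlist(lapply(split(labels$sample_id, labels$class), function(ids) {
    n_train <- min(max(ceiling(train_frac * length(ids)), 1L),
                   length(ids) - 1L)
    sample(ids, n_train)
  }), use.names = FALSE)
  list(train = sort(train),
       valid = sort(setdiff(labels$sample_id, train)))
}

#' Confusion matrix of class predictions
#'
#' Tallies counts of (true class, predicted class) over an ordered class
#' list; rows are true classes, columns predictions. The row-percent view
#' (100 * count / row sum, zero rows flagged) is available via
#' [row_percent()] and [tidy()].
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels; must be within `classes`.
#' @param classes Ordered class list; defaults to the sorted union of the
#'   observed labels.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown) > 0) {
    stop("labels outside the class list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  structure(list(counts = counts, classes = classes),
            class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param cm A `confusion_matrix`.
#' @return `row_percent()`: a matrix of row percentages (rows sum to 100;
#'   all-zero rows stay zero, with the `"empty_rows"` attribute naming them).
#' @export
row_percent <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm$counts)
  pct <- 100 * cm$counts / ifelse(rs == 0, 1, rs)
  attr(pct, "empty_rows") <- cm$classes[rs == 0]
  pct
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d samples, accuracy %.3f\n",
              length(x$classes), sum(x$counts),
              sum(diag(x$counts)) / sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  pct <- row_percent(x)
  tibble::tibble(
    true = rep(x$classes, times = length(x$classes)),
    predicted = rep(x$classes, each = length(x$classes)),
    n = c(x$counts),
    row_pct = c(pct)
  )
}

#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(n = sum(x$counts),
                 accuracy = sum(diag(x$counts)) / sum(x$counts))
}

#' Per-class one-vs-rest performance metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and negative
#' predictive values TP/(TP+FP) and TN/(TN+FN) for each class, plus overall
#' accuracy. Undefined 0/0 ratios (e.g. PPV of a never-predicted class) are
#' reported as `NA`, never as 0, so summaries are not silently deflated.
#'
#' @param cm A [confusion_matrix()].
#' @return A `class_metrics` tibble with one row per class and the overall
#'   accuracy in the `"accuracy"` attribute.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) {
    unname(ifelse(den == 0, NA_real_, num / den))
  }
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- total - tp - fn - fp
  res <- tibble::tibble(
    class = cm$classes,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn)
  )
  attr(res, "accuracy") <- sum(tp) / total
  class(res) <- c("class_metrics", class(res))
  res
}

#' Evaluate predictions against true labels
#'
#' Bundles the confusion matrix, per-class metrics and overall accuracy
#' into one report, as printed for each validation cohort.
#'
#' @inheritParams confusion_matrix
#' @return An `eval_report` list: `confusion`, `metrics`, `accuracy`.
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  cm <- confusion_matrix(truth, predicted, classes)
  metrics <- per_class_metrics(cm)
  structure(list(confusion = cm, metrics = metrics,
                 accuracy = attr(metrics, "accuracy")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f over %d samples\n",
              x$accuracy, sum(x$confusion$counts)))
  print(x$metrics)
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) tibble::as_tibble(x$metrics)

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = sum(x$confusion$counts), accuracy = x$accuracy,
                 n_classes = length(x$confusion$classes))
}
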