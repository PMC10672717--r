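# Dataset splitting and the evaluation report: confusion matrix plus
# accuracy / precision / recall / F1 in both weighted and macro averages.
# Support-weighted recall equals accuracy by construction; both averaging
# conventions are reported because published tables rarely say which one
# they use.

#' Stratified train/test split
#'
#' Splits a sample table into train and test sets stratified by the label
#' column: within each class, `round(train_fraction * n_class)` samples go
#' to training.  Deterministic for a given seed.
#'
#' @param samples A data frame with a `label` column (factor or character).
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Optional integer seed.
#' @return A list with tibbles `train` and `test`; disjoint, union the
#'   input.
#' @examples
#' df <- tibble::tibble(id = 1:100,
#'                      label = rep(c("a", "b", "c"), c(60, 30, 10)))
#' sp <- split_dataset(df, 0.8, seed = 1)
#' table(sp$test$label)
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = NULL) {
  if (!"label" %in% names(samples)) abort("`samples` needs a `label` column.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  counts <- table(as.character(samples$label))
  if (any(counts < 2L)) {
    abort(sprintf("Cannot stratify: class '%s' has fewer than 2 samples.",
                  names(counts)[which.min(counts)]))
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- as_tibble(samples)
  idx_train <- unlist(lapply(split(seq_len(nrow(samples)),
                                   as.character(samples$label)), function(ix) {
    n_tr <- max(1L, min(length(ix) - 1L, round(train_fraction * length(ix))))
    sample(ix, n_tr)
  }), use.names = FALSE)
  list(train = samples[sort(idx_train), , drop = FALSE],
       test = samples[setdiff(seq_len(nrow(samples)), idx_train), , drop = FALSE])
}

#' Resize an image with bilinear interpolation
#'
#' @param image Matrix or `height x width x 3` array.
#' @param height,width Target size in pixels.
#' @return Resized array on the same value scale.
#' @export
resize_image <- function(image, height, width) {
  is_mat <- is.matrix(image)
  if (is_mat) image <- array(image, dim = c(dim(image), 1))
  d <- dim(image)
  xs <- ((seq_len(width) - 0.5) * d[2] / width) - 0.5
  ys <- ((seq_len(height) - 0.5) * d[1] / height) - 0.5
  grid_x <- rep(xs, each = height)
  grid_y <- rep(ys, times = width)
  out <- array(0, dim = c(height, width, d[3]))
  for (c in seq_len(d[3])) {
    v <- bilinear_sample(image[, , c], grid_x, grid_y, "nearest", 0)
    out[, , c] <- matrix(v, nrow = height, ncol = width)
  }
  if (is_mat) out <- out[, , 1]
  out
}

#' Evaluation report from truth and predictions
#'
#' Builds the confusion matrix (rows = true class, columns = predicted) and
#' the standard multiclass metrics.  Per-class precision is the column-wise
#' and recall the row-wise diagonal fraction; F1 their harmonic mean;
#' `weighted` averages weight classes by their support and `macro` averages
#' them equally.  Support-weighted recall is algebraically identical to
#' accuracy.
#'
#' @param truth,predicted Vectors of class labels of equal length.
#' @param classes Class order for the matrix (default: three-class severity).
#' @return An `eval_report` object.
#' @examples
#' eval_report(c("a", "a", "b"), c("a", "b", "b"), classes = c("a", "b"))
#' @export
eval_report <- function(truth, predicted, classes = severity_levels3) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (!length(truth)) abort("Empty test set.")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) abort(sprintf("Label outside the class set: %s", bad[1]))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  eval_report_from_confusion(cm)
}

#' @rdname eval_report
#' @param cm A square confusion matrix of counts, rows = true class.
#' @export
eval_report_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  n <- sum(cm)
  support <- rowSums(cm)
  tp <- diag(cm)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  recall <- unname(safe_div(tp, support))
  precision <- unname(safe_div(tp, colSums(cm)))
  f1 <- safe_div(2 * precision * recall, precision + recall)
  wt <- support / n
  per_class <- tibble(class = classes, support = as.integer(support),
                      precision = precision, recall = recall, f1 = f1)
  metrics <- tibble(
    average = c("weighted", "macro"),
    accuracy = sum(tp) / n,
    precision = c(sum(wt * precision), mean(precision)),
    recall = c(sum(wt * recall), mean(recall)),
    f1 = c(sum(wt * f1), mean(f1))
  )
  structure(
    list(confusion = cm, per_class = per_class, metrics = metrics,
         n_test = as.integer(n)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples (accuracy %.4f)\n", x$n_test,
              x$metrics$accuracy[1]))
  print(x$confusion)
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  w <- x$metrics[x$metrics$average == "weighted", ]
  tibble(n_test = x$n_test, accuracy = w$accuracy, precision = w$precision,
         recall = w$recall, f1 = w$f1)
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix", x = "predicted", y = "true")
}

#' Write an evaluation report to disk
#'
#' @param report An `eval_report`.
#' @param json_path Metrics bundle as JSON (or `NULL`).
#' @param csv_path Confusion matrix as CSV (or `NULL`).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_test = report$n_test,
           confusion = unname(apply(report$confusion, 1L, as.list)),
           classes = rownames(report$confusion),
           per_class = report$per_class, metrics = report$metrics),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    df <- as_tibble(report$confusion, rownames = "truth")
    readr::write_csv(df, csv_path)
  }
  invisible(report)
}
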