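#' Confusion matrix of true versus predicted roasting degrees
#'
#' Rows are true classes, columns predicted classes, in the fixed
#' roasting order supplied by `class_order`; correctly classified
#' samples sit on the diagonal.
#'
#' @param truth,predicted Label vectors of equal length, drawn from
#'   `class_order`.
#' @param class_order Character vector fixing the class ordering
#'   (default the seven roasting degrees RD-U ... RD-D).
#' @return An object of class `confusion_matrix`: integer `counts`
#'   (k x k, dimnames = classes) and `n_total`.
#' @examples
#' cm <- confusion(c("RD-U", "RD-D"), c("RD-U", "RD-D"))
#' overall_accuracy(cm)
#' @export
confusion <- function(truth, predicted, class_order = roast_labels(7)) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  unknown <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(unknown))
    stop("labels outside class_order: ", paste(unknown, collapse = ", "))
  tt <- table(factor(truth, levels = class_order),
              factor(predicted, levels = class_order))
  counts <- matrix(as.integer(tt), nrow(tt),
                   dimnames = dimnames(tt))
  new_confusion(counts)
}

new_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, n_total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d samples, accuracy %.2f%%\n",
              x$n_total, 100 * overall_accuracy(x)))
  print(x$counts)
  invisible(x)
}

#' Overall classification accuracy
#'
#' The trace of the confusion matrix divided by the total sample count.
#'
#' @param cm A [confusion()] matrix.
#' @return Accuracy fraction in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n_total == 0) stop("empty confusion matrix")
  sum(diag(cm$counts)) / cm$n_total
}

#' Number of misclassified samples
#'
#' @param cm A [confusion()] matrix.
#' @return `n_total` minus the diagonal sum.
#' @export
misclassified_count <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cm$n_total - sum(diag(cm$counts))
}

#' Read / write a confusion matrix as labelled CSV
#'
#' The CSV has a `truth` column of class names and one column per
#' predicted class.
#'
#' @param cm A `confusion_matrix`.
#' @param path File path.
#' @return `write_confusion_csv` returns `path` invisibly;
#'   `read_confusion_csv` returns a `confusion_matrix`.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(truth = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1])
  rownames(counts) <- df$truth
  storage.mode(counts) <- "integer"
  new_confusion(counts)
}

#' Published reference confusion matrices
#'
#' Loads one of the three reference 7 x 7 confusion matrices reported
#' for LS-SVM roasting-degree models on a 175-sample prediction set,
#' one per wavelength-selection method. They ship with the package as
#' plain CSV and serve as worked-example fixtures for the evaluation
#' statistics.
#'
#' @param method `"xloading"`, `"spa"` or `"rf"`.
#' @return A `confusion_matrix`.
#' @examples
#' misclassified_count(reference_confusion("rf"))
#' @export
reference_confusion <- function(method = c("xloading", "spa", "rf")) {
  method <- match.arg(method)
  path <- system.file("extdata",
                      sprintf("confusion_%s.csv", method),
                      package = "roastspec", mustWork = TRUE)
  read_confusion_csv(path)
}
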