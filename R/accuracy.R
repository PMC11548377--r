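# Confusion-matrix accuracy assessment: overall accuracy and Cohen's kappa,
# plus per-class producer's and user's accuracy.  Convention: rows are the
# reference labels, columns the predicted labels.  Both summary statistics
# are invariant under transposition, so the convention only matters for the
# per-class accuracies.

#' Default class order for accuracy reports
#' @export
VBI_CLASS_ORDER <- c("FEAV", "SAV", "AB", "OW")

#' Build a confusion matrix from paired label vectors
#'
#' @param reference Character vector of reference (ground-truth) labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param class_order Class labels fixing row/column order.
#' @return A `confusion_matrix`: integer matrix with rows = reference,
#'   columns = predicted.
#' @export
build_confusion <- function(reference, predicted,
                            class_order = VBI_CLASS_ORDER) {
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length (",
         length(reference), " vs ", length(predicted), ")")
  bad <- setdiff(unique(c(reference, predicted)), c(class_order, NA))
  if (length(bad))
    stop("labels not in class_order: ", paste(bad, collapse = ", "))
  keep <- !is.na(reference) & !is.na(predicted)
  cm <- table(factor(reference[keep], levels = class_order),
              factor(predicted[keep], levels = class_order))
  cm <- unclass(cm)
  dimnames(cm) <- list(reference = class_order, predicted = class_order)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Assemble a confusion matrix directly from counts
#'
#' @param counts Square non-negative integer matrix (rows = reference).
#' @param class_order Class labels for both axes.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, class_order = VBI_CLASS_ORDER) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("confusion matrix must be square")
  if (nrow(counts) != length(class_order))
    stop("counts shape does not match class_order length")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(reference = class_order, predicted = class_order)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  if (sum(cm) <= 0) stop("confusion matrix is empty (grand total 0)")
}

#' Overall accuracy of a confusion matrix
#'
#' Fraction of samples on the diagonal: trace / grand total.
#'
#' @param cm A confusion matrix (any square count matrix works).
#' @return Fraction in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(as.matrix(cm))) / sum(cm)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = trace/total` and `p_e = sum_i rowSum_i * colSum_i / total^2`.
#'
#' @param cm A confusion matrix.
#' @return Kappa (real, at most 1).
#' @export
cohen_kappa <- function(cm) {
  check_cm(cm)
  cm <- as.matrix(cm)
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5)
    stop("kappa undefined: expected agreement is 1 ",
         "(all mass in a single class on both axes)")
  (p_o - p_e) / (1 - p_e)
}

#' Full accuracy report
#'
#' @param cm A confusion matrix (rows = reference, columns = predicted).
#' @return An `accuracy_report`: list with `confusion`, `overall_accuracy`,
#'   `kappa`, `producers_accuracy` (diagonal / row sums; omission view),
#'   `users_accuracy` (diagonal / column sums; commission view) and `n`.
#' @export
accuracy_report <- function(cm) {
  check_cm(cm)
  m <- as.matrix(cm)
  prod_acc <- ifelse(rowSums(m) > 0, diag(m) / rowSums(m), NA_real_)
  user_acc <- ifelse(colSums(m) > 0, diag(m) / colSums(m), NA_real_)
  names(prod_acc) <- names(user_acc) <- rownames(m)
  structure(list(confusion = cm,
                 overall_accuracy = overall_accuracy(cm),
                 kappa = cohen_kappa(cm),
                 producers_accuracy = prod_acc,
                 users_accuracy = user_acc,
                 n = sum(m)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report (n =", x$n, ")\n")
  print(unclass(x$confusion))
  cat(sprintf("overall accuracy: %.2f%%   kappa: %.2f\n",
              100 * x$overall_accuracy, x$kappa))
  invisible(x)
}

#' Sample a class map at reference points
#'
#' Looks up the predicted class at each (x, y) location by nearest pixel
#' centre, then pairs it with the reference label for [build_confusion()].
#'
#' @param cm A [class_map()].
#' @param points Data frame with columns `x`, `y`, `class` (coordinates in
#'   the map's CRS).
#' @return Data frame with columns `reference` and `predicted`; points
#'   falling outside the grid or on nodata pixels get NA predicted.
#' @export
sample_classmap <- function(cm, points) {
  stopifnot(all(c("x", "y", "class") %in% names(points)))
  cell <- point_to_cell(cm$geo, points$x, points$y)
  lab <- class_labels(cm)
  pred <- rep(NA_character_, nrow(points))
  ok <- !is.na(cell$row)
  pred[ok] <- lab[cbind(cell$row[ok], cell$col[ok])]
  data.frame(reference = as.character(points$class), predicted = pred,
             stringsAsFactors = FALSE)
}

#' Published validation counts for the Bao'an Lake VBI classification
#'
#' The 4x4 confusion-matrix counts from the Bao'an Lake accuracy-verification
#' campaign (reference samples vs decision-tree predictions over the classes
#' FEAV, SAV, AB, OW), shipped as the package's worked accuracy example.
#'
#' @return A `confusion_matrix` with class order FEAV, SAV, AB, OW.
#' @export
baoan_reference_confusion <- function() {
  path <- system.file("extdata", "baoan_validation_counts.csv",
                      package = "vbimap", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  confusion_from_counts(as.matrix(df), class_order = rownames(df))
}
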