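#' Confusion-matrix accuracy assessment
#'
#' Rows are the reference class, columns the predicted class; producer's
#' accuracy (PA) is therefore row-wise recall, user's accuracy (UA) is
#' column-wise precision, overall accuracy (OA) is trace/total and kappa
#' is the chance-corrected agreement (p_o - p_e) / (1 - p_e) with
#' p_e = sum(row_i * col_i) / total^2.
#'
#' @name accuracy_doc
NULL

# Tally a confusion matrix from two aligned factors.
confusion_counts <- function(truth, pred, legend) {
  truth <- factor(truth, levels = legend)
  pred <- factor(pred, levels = legend)
  table(reference = truth, prediction = pred)
}

#' Confusion matrix of a class map against validation samples
#'
#' One count per validation pixel; samples falling off-grid or on nodata
#' are excluded and reported in the `excluded` attribute.
#'
#' @param map a [class_map].
#' @param samples data.frame with `row`, `col`, `class` (and optionally
#'   `role`; only rows with `role == "validate"` are used if present).
#' @return `confusion` table (reference rows x prediction columns) with
#'   attribute `excluded` (count of unusable samples).
#' @export
confusion <- function(map, samples) {
  if ("role" %in% names(samples))
    samples <- samples[samples$role == "validate", , drop = FALSE]
  H <- nrow(map$labels); W <- ncol(map$labels)
  on_grid <- samples$row >= 1 & samples$row <= H &
    samples$col >= 1 & samples$col <= W
  lab <- rep(NA_integer_, nrow(samples))
  lab[on_grid] <- map$labels[cbind(samples$row[on_grid],
                                   samples$col[on_grid])]
  usable <- !is.na(lab)
  if (!any(usable)) stop("no usable validation pixels on the map")
  cm <- confusion_counts(samples$class[usable], map$legend[lab[usable]],
                         map$legend)
  attr(cm, "excluded") <- sum(!usable)
  cm
}

#' Accuracy metrics from a confusion matrix
#'
#' @param cm square contingency table / matrix, reference rows x
#'   prediction columns.
#' @return list of class `accuracy_report`: `OA`, per-class `PA` and `UA`
#'   (proportions; NaN with a warning where a reference row or prediction
#'   column is empty), `kappa`, `ground_truth` (per-class reference pixel
#'   tallies), `total` and the matrix itself.
#' @export
accuracy_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  rows <- rowSums(cm); cols <- colSums(cm); diagc <- diag(cm)
  if (any(rows == 0))
    warning("empty reference row(s): ",
            paste(rownames(cm)[rows == 0], collapse = ", "),
            "; PA undefined there")
  PA <- diagc / rows
  UA <- diagc / cols
  OA <- sum(diagc) / total
  pe <- sum(rows * cols) / total^2
  kappa <- if (pe < 1) (OA - pe) / (1 - pe) else 1
  structure(list(OA = OA, PA = PA, UA = UA, kappa = kappa,
                 ground_truth = rows, total = total, matrix = cm),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.2f%%   kappa: %.4f   (n = %d)\n",
              100 * x$OA, x$kappa, x$total))
  tab <- data.frame(class = names(x$PA),
                    PA = sprintf("%.2f%%", 100 * x$PA),
                    UA = sprintf("%.2f%%", 100 * x$UA),
                    reference_pixels = as.integer(x$ground_truth))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Binary cultivated / non-cultivated evaluation
#'
#' Merges every non-cultivated class of the map before tallying, then
#' evaluates the 2 x 2 matrix against samples labelled 1 (cultivated) or
#' 0 (non-cultivated). Merging before or after counting is equivalent;
#' this implementation merges first.
#'
#' @param map a [class_map] whose legend contains `cultivated_class`.
#' @param samples data.frame with `row`, `col` and `label` in `c(0, 1)`
#'   (or a `class` column, binarized against `cultivated_class`).
#' @param cultivated_class legend entry treated as the positive class.
#' @return [accuracy_metrics()] report on the 2 x 2 matrix with classes
#'   `c("non-cultivated", "cultivated")`.
#' @export
binarize_and_evaluate <- function(map, samples,
                                  cultivated_class = "cultivated") {
  ci <- match(cultivated_class, map$legend)
  if (is.na(ci)) stop("map legend lacks class '", cultivated_class, "'")
  bin <- map
  bin$labels <- ifelse(is.na(map$labels), NA_integer_,
                       ifelse(map$labels == ci, 2L, 1L))
  bin$legend <- c("non-cultivated", "cultivated")
  s <- samples
  if (!"label" %in% names(s)) {
    if (!"class" %in% names(s)) stop("samples need a 'label' or 'class'")
    s$label <- as.integer(as.character(s$class) == cultivated_class)
  }
  s$class <- factor(ifelse(s$label == 1, "cultivated", "non-cultivated"),
                    levels = bin$legend)
  s$role <- NULL
  cm <- confusion(class_map(bin$labels, bin$legend), s)
  rep <- accuracy_metrics(cm)
  attr(rep, "excluded") <- attr(cm, "excluded")
  rep
}

#' Write an accuracy report to JSON or CSV
#' @param report an `accuracy_report`; `path` output ending `.json` or
#'   `.csv`.
#' @export
write_accuracy_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(OA = report$OA, kappa = report$kappa,
           PA = as.list(report$PA), UA = as.list(report$UA),
           ground_truth = as.list(report$ground_truth),
           total = report$total,
           confusion = as.data.frame.matrix(report$matrix)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(
      class = names(report$PA), PA = report$PA, UA = report$UA,
      ground_truth = as.integer(report$ground_truth),
      OA = report$OA, kappa = report$kappa), path, row.names = FALSE)
  }
  invisible(path)
}
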