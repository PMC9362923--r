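#' Fit a time-series-vector-feature land-cover classifier
#'
#' The full MTVF fit: ranks the feature columns by normalized Gini
#' importance, forms nested importance groups at descending score
#' thresholds, traces each group's out-of-bag error and hold-out
#' prediction accuracy over a grid of tree counts, selects the group with
#' the highest accuracy and smallest OOB error together with the smallest
#' plateau tree count, and trains the final random forest on the selected
#' features.
#'
#' @param features labelled feature table: numeric feature columns (see
#'   [build_feature_table()] / [label_features()]) plus a `class` factor.
#' @param thresholds strictly decreasing importance-score thresholds
#'   defining the groups (default `c(0.1, 0.04, 0.02, 0)`).
#' @param tree_grid tree counts scanned during selection (default
#'   `seq(50, 1000, by = 50)`).
#' @param n_rank_trees trees in the ranking forest (default 500).
#' @param n_trees final forest size; `NULL` (default) uses the selected
#'   plateau tree count.
#' @param holdout fraction of training samples held out (stratified) for
#'   the selection curves' prediction accuracy (default 0.3).
#' @param plateau_tol accuracy tolerance defining the tree-count plateau.
#' @param seed integer; fixes ranking, splits and every forest.
#' @return object of class `mtvf` with components `importance` (score
#'   table), `groups`, `selection` (chosen group, features, n_trees,
#'   curves), `forest` (final [train_rf()] model), `levels`, `call`.
#' @seealso [predict.mtvf()], [predict_map()], [compare_models()]
#' @export
#' @examples
#' scene <- generate_scene(scene_config(width = 48, height = 48, seed = 7))
#' sam <- draw_samples(scene, n_train = 40, n_validate = 40, seed = 7)
#' idx <- evaluate_indices(scene$cube)
#' tr <- label_features(
#'   build_feature_table(scene$cube, idx,
#'                       sam[sam$role == "train", c("row", "col")]),
#'   sam[sam$role == "train", ])
#' fit <- mtvf(tr, tree_grid = c(50, 100), seed = 7)
#' print(fit)
mtvf <- function(features, thresholds = c(0.1, 0.04, 0.02, 0),
                 tree_grid = seq(50, 1000, by = 50),
                 n_rank_trees = 500, n_trees = NULL, holdout = 0.3,
                 plateau_tol = 0.002, seed = 1) {
  cl <- match.call()
  imp <- importance_scores(features, n_trees = n_rank_trees, seed = seed)
  groups <- group_by_thresholds(imp, thresholds)
  curves <- selection_curves(features, groups, tree_grid,
                             seed = seed, holdout = holdout)
  sel <- select_group(curves, groups, plateau_tol)
  final_trees <- if (is.null(n_trees)) sel$n_trees else n_trees
  forest <- train_rf(features, sel$features, n_trees = final_trees,
                     seed = seed)
  structure(list(importance = imp, groups = groups, selection = sel,
                 forest = forest, levels = forest$levels,
                 thresholds = thresholds, seed = seed, call = cl),
            class = "mtvf")
}

#' @export
print.mtvf <- function(x, ...) {
  cat("Time-series vector feature classifier (random forest core)\n")
  cat(sprintf("  features ranked: %d; groups: %s\n",
              nrow(x$importance),
              paste(sprintf("%s(%d)", names(x$groups),
                            lengths(x$groups)), collapse = " ")))
  cat(sprintf("  selected: group %s, %d features, %d trees\n",
              x$selection$group, length(x$selection$features),
              x$forest$n_trees))
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
summary.mtvf <- function(object, n_top = 10, ...) {
  sel_curve <- object$selection$curves
  sel_curve <- sel_curve[sel_curve$group == object$selection$group, ]
  out <- list(
    top_features = utils::head(object$importance, n_top),
    group_sizes = lengths(object$groups),
    selected = list(group = object$selection$group,
                    n_features = length(object$selection$features),
                    n_trees = object$forest$n_trees),
    oob_error = unname(
      object$forest$fit$err.rate[object$forest$fit$ntree, "OOB"]),
    peak_prediction_accuracy = max(sel_curve$prediction_accuracy))
  class(out) <- "summary.mtvf"
  out
}

#' @export
print.summary.mtvf <- function(x, ...) {
  cat("MTVF fit summary\n----------------\n")
  cat("Top features by importance score:\n")
  print(x$top_features, row.names = FALSE)
  cat(sprintf("\nGroup sizes: %s\n",
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  cat(sprintf("Selected group %s: %d features, %d trees\n",
              x$selected$group, x$selected$n_features, x$selected$n_trees))
  cat(sprintf("Final forest OOB error: %.4f\n", x$oob_error))
  cat(sprintf("Peak hold-out prediction accuracy: %.4f\n",
              x$peak_prediction_accuracy))
  invisible(x)
}

#' Predict classes for new feature rows
#'
#' @param object fitted [mtvf()] model.
#' @param newdata data.frame containing at least the selected feature
#'   columns (names are checked against the training contract).
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.mtvf <- function(object, newdata, ...) {
  check_feature_contract(object$selection$features, names(newdata))
  rf_vote(object$forest$fit, newdata[object$selection$features])
}

#' Importance scores of a fitted MTVF model
#' @param object fitted [mtvf()] model; `...` unused.
#' @return the importance score table (feature, importance, score, rank).
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @export
importance.mtvf <- function(object, ...) object$importance

#' Plot an MTVF fit
#'
#' `which = 1`: bar chart of the top feature importance scores with the
#' group thresholds; `which = 2`: prediction-accuracy and OOB-error curves
#' against the number of trees, one line per group.
#'
#' @param x fitted [mtvf()] model; `which` plots to draw; `n_top` bars;
#'   `...` unused.
#' @export
plot.mtvf <- function(x, which = c(1, 2), n_top = 30, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (all(c(1, 2) %in% which)) graphics::par(mfrow = c(1, 2))
  if (1 %in% which) {
    top <- utils::head(x$importance, n_top)
    graphics::barplot(rev(top$score), names.arg = rev(top$feature),
                      horiz = TRUE, las = 1, cex.names = 0.55,
                      col = "forestgreen", border = NA,
                      xlab = "importance score",
                      main = sprintf("Top %d features", nrow(top)))
    graphics::abline(v = x$thresholds, lty = 3, col = "grey40")
  }
  if (2 %in% which) {
    cv <- x$selection$curves
    cols <- stats::setNames(
      grDevices::hcl.colors(length(x$groups), "Dark 2"), names(x$groups))
    graphics::plot(range(cv$n_trees), range(cv$prediction_accuracy),
                   type = "n", xlab = "number of trees",
                   ylab = "hold-out accuracy",
                   main = "Group selection curves")
    for (g in names(x$groups)) {
      d <- cv[cv$group == g, ]
      graphics::lines(d$n_trees, d$prediction_accuracy, col = cols[g],
                      lwd = 2)
      graphics::lines(d$n_trees, 1 - d$oob_error, col = cols[g], lty = 2)
    }
    graphics::legend("bottomright", legend = names(x$groups),
                     col = cols, lwd = 2, bty = "n",
                     title = "group (solid acc / dashed 1-OOB)")
  }
  invisible(x)
}
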