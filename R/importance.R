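#' Gini importance ranking and importance-group selection
#'
#' A random forest accumulates, for every feature f, the total Gini
#' impurity decrease over all splits of all trees that use f (mean
#' decrease in impurity, I_f). The importance score is the normalized
#' value S_f = I_f / sum_f I_f, so scores sum to one and average 1/#features.
#' Features are then grouped by descending score thresholds, and the group
#' with the best hold-out prediction accuracy and smallest out-of-bag (OOB)
#' error — together with a tree count on the accuracy plateau — is selected.
#'
#' @name feature_selection_doc
NULL

#' Normalized Gini importance scores
#'
#' Fits a random forest on the labelled feature table and normalizes the
#' per-feature impurity decreases to scores summing to 1.
#'
#' @param features data.frame of numeric feature columns plus a `class`
#'   factor column (see [label_features()]).
#' @param n_trees number of trees for the ranking forest (default 500).
#' @param seed integer; fixes the forest.
#' @return data.frame `feature`, `importance` (raw I_f), `score` (S_f),
#'   `rank`, sorted by descending score.
#' @export
importance_scores <- function(features, n_trees = 500, seed = 1) {
  y <- features$class
  if (is.null(y)) stop("features must carry a 'class' column")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("importance ranking needs at least 2 classes")
  x <- features[setdiff(names(features), "class")]
  if (!ncol(x) || !nrow(x)) stop("empty feature table")
  if (any(!stats::complete.cases(x))) stop("feature table contains NA rows")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  raw <- rf$importance[, "MeanDecreaseGini"]
  total <- sum(raw)
  score <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  o <- order(score, decreasing = TRUE)
  data.frame(feature = names(raw)[o], importance = unname(raw[o]),
             score = unname(score[o]), rank = seq_along(raw),
             stringsAsFactors = FALSE)
}

#' Group features by descending importance-score thresholds
#'
#' Group g keeps every feature with score strictly above threshold_g, so
#' strictly decreasing thresholds give nested groups A <= B <= C <= D.
#'
#' @param table importance table from [importance_scores()].
#' @param thresholds strictly decreasing numeric vector; default the
#'   visually chosen score nodes `c(0.1, 0.04, 0.02, 0)`.
#' @return named list of feature-name character vectors, labelled
#'   `A`, `B`, `C`, ... An empty leading group is dropped with a warning.
#' @export
group_by_thresholds <- function(table, thresholds = c(0.1, 0.04, 0.02, 0)) {
  if (any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing")
  groups <- lapply(thresholds, function(th)
    table$feature[table$score > th])
  names(groups) <- LETTERS[seq_along(groups)]
  empty <- lengths(groups) == 0
  if (empty[length(empty)])
    stop("smallest-threshold group is empty; lower the last threshold")
  if (any(empty)) {
    warning("dropping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
    names(groups) <- LETTERS[seq_along(groups)]
  }
  attr(groups, "thresholds") <- thresholds[!empty]
  groups
}

#' Out-of-bag error / prediction-accuracy curve for one feature group
#'
#' For each tree count, fits a forest restricted to the group's features on
#' a stratified 70% training portion, records the forest's internal OOB
#' error (estimated on the ~36.8% per-tree held-out samples) and the
#' prediction accuracy on the stratified 30% hold-out.
#'
#' @param features labelled feature table.
#' @param group character vector of feature names.
#' @param tree_grid tree counts (default `seq(50, 1000, by = 50)`).
#' @param seed integer seed; the stratified split and all forests derive
#'   from it.
#' @param holdout fraction held out for prediction accuracy (default 0.3).
#' @return data.frame `n_trees`, `oob_error`, `prediction_accuracy`.
#' @export
oob_curve <- function(features, group, tree_grid = seq(50, 1000, by = 50),
                      seed = 1, holdout = 0.3) {
  if (!length(tree_grid)) stop("tree_grid must be nonempty")
  y <- droplevels(factor(features$class))
  x <- features[group]
  split <- stratified_split(y, holdout, seed)
  if (any(table(y[split$train]) < 2) || any(table(y[split$test]) < 1))
    stop("sample too small for a stratified hold-out split")
  res <- lapply(seq_along(tree_grid), function(i) {
    set.seed(seed + i)
    rf <- randomForest::randomForest(
      x = x[split$train, , drop = FALSE], y = y[split$train],
      ntree = tree_grid[i])
    pred <- stats::predict(rf, x[split$test, , drop = FALSE])
    data.frame(n_trees = tree_grid[i],
               oob_error = unname(rf$err.rate[rf$ntree, "OOB"]),
               prediction_accuracy = mean(pred == y[split$test]))
  })
  do.call(rbind, res)
}

# Stratified split: per class, floor((1 - holdout) * n) to train.
stratified_split <- function(y, holdout, seed) {
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- max(1L, floor((1 - holdout) * length(idx)))
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), test = setdiff(seq_along(y), train))
}

#' Selection curves for several feature groups
#'
#' @param features labelled feature table; `groups` list from
#'   [group_by_thresholds()]; other arguments as [oob_curve()].
#' @return data.frame with a `group` column stacked over groups.
#' @export
selection_curves <- function(features, groups,
                             tree_grid = seq(50, 1000, by = 50),
                             seed = 1, holdout = 0.3) {
  do.call(rbind, lapply(names(groups), function(g) {
    cbind(group = g, oob_curve(features, groups[[g]], tree_grid,
                               seed = seed, holdout = holdout))
  }))
}

#' Select the best feature group and tree count from selection curves
#'
#' Picks the group whose curve attains the highest peak prediction
#' accuracy; ties are broken by lower OOB error at the peak, then by fewer
#' features. The tree count is the smallest on the grid whose accuracy is
#' within `plateau_tol` of that group's peak.
#'
#' @param curves data.frame from [selection_curves()].
#' @param groups the group list the curves were computed for.
#' @param plateau_tol absolute accuracy tolerance defining the plateau
#'   (default 0.002).
#' @return list `group` (label), `features`, `n_trees`, `curves`.
#' @export
select_group <- function(curves, groups, plateau_tol = 0.002) {
  if (any(!is.finite(curves$oob_error)) ||
      any(!is.finite(curves$prediction_accuracy)))
    stop("selection curves contain non-finite values")
  stats_by <- lapply(split(curves, curves$group), function(d) {
    peak <- max(d$prediction_accuracy)
    c(peak = peak, oob = min(d$oob_error[d$prediction_accuracy == peak]))
  })
  labels <- names(stats_by)
  peak <- vapply(stats_by, `[[`, 0, "peak")
  oob <- vapply(stats_by, `[[`, 0, "oob")
  sizes <- lengths(groups)[labels]
  best <- labels[order(-peak, oob, sizes)][1]
  d <- curves[curves$group == best, ]
  plateau <- d$prediction_accuracy >= max(d$prediction_accuracy) - plateau_tol
  n_trees <- min(d$n_trees[plateau])
  list(group = best, features = groups[[best]], n_trees = n_trees,
       curves = curves)
}

#' Bootstrap in-bag / out-of-bag fractions by simulation
#'
#' Draws `reps` bootstrap resamples of size n with replacement from 1..n
#' and reports the mean percentage of distinct original samples present in
#' a resample (in-bag) and absent from it (out-of-bag). For large n these
#' approach 100(1 - 1/e) ~ 63.2% and 100/e ~ 36.8%.
#'
#' @param n sample size (default 10000); `reps` number of resamples
#'   (default 200); `seed` integer.
#' @return list `in_bag_pct`, `oob_pct`, `n`, `reps`.
#' @export
bootstrap_fractions <- function(n = 10000, reps = 200, seed = 1) {
  set.seed(seed)
  distinct <- vapply(seq_len(reps), function(i) {
    length(unique(sample.int(n, n, replace = TRUE)))
  }, 0L)
  in_bag <- mean(distinct) / n * 100
  list(in_bag_pct = in_bag, oob_pct = 100 - in_bag, n = n, reps = reps)
}
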