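#' Land-cover classes and class maps
#'
#' The fixed six-class legend: cultivated, woodland, grassland, water,
#' artificial, bare — integer codes 1..6 in that order, for stable rasters.
#' @export
LAND_CLASSES <- c("cultivated", "woodland", "grassland",
                  "water", "artificial", "bare")

#' Construct a class map
#' @param labels integer H x W matrix of class codes (NA = nodata).
#' @param legend character vector naming codes 1..C.
#' @return object of class `class_map`.
#' @export
class_map <- function(labels, legend = LAND_CLASSES) {
  stopifnot(is.matrix(labels))
  ok <- labels[!is.na(labels)]
  if (length(ok) && (any(ok < 1) || any(ok > length(legend))))
    stop("class codes outside the legend")
  structure(list(labels = labels, legend = legend), class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$legend[x$labels], levels = x$legend))
  cat(sprintf("<class_map> %d x %d px, %d nodata\n", nrow(x$labels),
              ncol(x$labels), sum(is.na(x$labels))))
  print(tab)
  invisible(x)
}

#' Train a random forest on selected feature columns
#'
#' Thin, seeded wrapper storing the feature-name contract; prediction
#' refuses mismatched columns. (The full selection procedure lives in
#' [mtvf()]; this is the bare classification core.)
#'
#' @param features labelled feature table; `feature_names` columns to use
#'   (default all non-class columns); `n_trees` trees (>= 1); `seed` integer.
#' @return object of class `rf_model`.
#' @export
train_rf <- function(features, feature_names = NULL, n_trees = 400,
                     seed = 1) {
  stopifnot(n_trees >= 1)
  y <- droplevels(factor(features$class))
  if (nlevels(y) < 2) stop("training requires at least 2 classes present")
  if (is.null(feature_names))
    feature_names <- setdiff(names(features), "class")
  x <- features[feature_names]
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  structure(list(fit = fit, feature_names = feature_names,
                 levels = levels(y), n_trees = n_trees, seed = seed),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  check_feature_contract(object$feature_names, names(newdata))
  rf_vote(object$fit, newdata[object$feature_names])
}

# Deterministic per-row argmax of tree votes (first level wins a tie), so
# tiled full-scene prediction is output-invariant.
rf_vote <- function(fit, x) {
  v <- stats::predict(fit, x, type = "vote", norm.votes = FALSE)
  factor(colnames(v)[max.col(v, ties.method = "first")],
         levels = colnames(v))
}

check_feature_contract <- function(expected, got) {
  miss <- setdiff(expected, got)
  if (length(miss))
    stop("prediction input lacks feature column(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Predict a full-scene class map from cubes
#'
#' Builds the model's features for every valid pixel (in tiles, so memory
#' stays bounded and results are tile-size invariant) and predicts the
#' per-pixel class by majority vote of the forest's trees; nodata is
#' preserved.
#'
#' @param model an [mtvf()] fit, [rf_model], `mlc_model`, `svm_model` or
#'   `ann_model`.
#' @param band_cube,index_cube cubes as in [build_feature_table()].
#' @param tile_rows number of feature rows per prediction tile.
#' @param cosine_form,distance_form passed to the feature builder.
#' @return [class_map]
#' @export
predict_map <- function(model, band_cube, index_cube = NULL,
                        tile_rows = 20000,
                        cosine_form = "normalized",
                        distance_form = "squared") {
  d <- dim(band_cube$values)
  labels <- matrix(NA_integer_, d[1], d[2])
  idx <- which(band_cube$valid_mask)
  if (!length(idx)) return(class_map(labels, model_levels(model)))
  pixels <- data.frame(row = ((idx - 1) %% d[1]) + 1,
                       col = ((idx - 1) %/% d[1]) + 1)
  lv <- model_levels(model)
  for (start in seq(1, nrow(pixels), by = tile_rows)) {
    sel <- start:min(start + tile_rows - 1, nrow(pixels))
    ft <- build_feature_table(band_cube, index_cube, pixels[sel, ],
                              cosine_form, distance_form)
    ok <- stats::complete.cases(ft[model_features(model)])
    if (!any(ok)) next
    pred <- predict(model, ft[ok, , drop = FALSE])
    labels[idx[sel][ok]] <- match(as.character(pred), lv)
  }
  class_map(labels, lv)
}

model_levels <- function(model) {
  if (inherits(model, "mtvf")) model$levels else model$levels
}
model_features <- function(model) {
  if (inherits(model, "mtvf")) model$selection$features else
    model$feature_names
}

# ---------------------------------------------------------------------------
# Gaussian maximum-likelihood classifier (from first principles)

#' Train a Gaussian maximum-likelihood classifier
#'
#' Per class, estimates a mean vector and covariance matrix of the feature
#' distribution and classifies by the largest Gaussian discriminant
#' g_i(x) = ln pi_i - 0.5 ln|Sigma_i| - 0.5 (x - mu_i)' Sigma_i^{-1}
#' (x - mu_i). Ties break to the earlier class in the legend order (logged
#' as an attribute of the prediction).
#'
#' @param features labelled feature table; `feature_names` columns to use.
#' @param priors `"proportional"` (training frequencies), `"equal"`, or a
#'   named numeric vector summing to 1.
#' @param epsilon ridge added to each covariance diagonal (default 1e-6)
#'   so classes with few samples relative to the dimension stay usable.
#' @return object of class `mlc_model`.
#' @export
train_mlc <- function(features, feature_names = NULL,
                      priors = "proportional", epsilon = 1e-6) {
  y <- droplevels(factor(features$class))
  if (is.null(feature_names))
    feature_names <- setdiff(names(features), "class")
  x <- as.matrix(features[feature_names])
  lv <- levels(y)
  if (is.character(priors)) {
    pr <- switch(priors,
                 proportional = as.numeric(table(y)) / length(y),
                 equal = rep(1 / length(lv), length(lv)),
                 stop("unknown priors spec: ", priors))
    names(pr) <- lv
  } else {
    pr <- priors[lv] / sum(priors[lv])
  }
  models <- lapply(lv, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    S <- if (nrow(xi) > 1) stats::cov(xi) else
      diag(0, ncol(xi))
    # ridge scaled to the average feature variance, escalated until the
    # Cholesky factorization succeeds (classes with fewer samples than
    # dimensions have rank-deficient covariance)
    scale_d <- mean(diag(S)); if (!is.finite(scale_d) || scale_d <= 0)
      scale_d <- 1
    ch <- NULL
    for (k in 0:6) {
      Sr <- S + diag(epsilon * scale_d * 10^k, ncol(xi))
      ch <- tryCatch(chol(Sr), error = function(e) NULL)
      if (!is.null(ch)) break
    }
    if (is.null(ch))
      stop("singular covariance for class '", cl,
           "'; increase epsilon or sample size")
    list(mu = mu, chol = ch,
         logdet = 2 * sum(log(diag(ch))), prior = pr[[cl]])
  })
  names(models) <- lv
  structure(list(models = models, feature_names = feature_names,
                 levels = lv, epsilon = epsilon),
            class = "mlc_model")
}

#' @export
predict.mlc_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  check_feature_contract(object$feature_names, names(newdata))
  x <- as.matrix(newdata[object$feature_names])
  g <- vapply(object$models, function(m) {
    z <- backsolve(m$chol, t(x) - m$mu, transpose = TRUE)
    log(m$prior) - 0.5 * m$logdet - 0.5 * colSums(z^2)
  }, numeric(nrow(x)))
  g <- matrix(g, nrow = nrow(x),
              dimnames = list(NULL, object$levels))
  if (type == "score") return(g)
  # which.max takes the first maximum: ties break to the earlier class
  best <- apply(g, 1, which.max)
  ties <- apply(g, 1, function(r) sum(r == max(r)) > 1)
  out <- factor(object$levels[best], levels = object$levels)
  attr(out, "n_ties") <- sum(ties)
  out
}

# ---------------------------------------------------------------------------
# Comparator adapters (developer-recommended defaults, thin wrappers)

#' Train the support-vector-machine comparator
#'
#' Thin adapter over `e1071::svm` with the developer defaults (C-support
#' vector classification, radial kernel); any `...` is passed through.
#' @inheritParams train_rf
#' @export
train_svm <- function(features, feature_names = NULL, seed = 1, ...) {
  y <- droplevels(factor(features$class))
  if (is.null(feature_names))
    feature_names <- setdiff(names(features), "class")
  set.seed(seed)
  fit <- e1071::svm(x = features[feature_names], y = y, ...)
  structure(list(fit = fit, feature_names = feature_names,
                 levels = levels(y), seed = seed), class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  check_feature_contract(object$feature_names, names(newdata))
  stats::predict(object$fit, newdata[object$feature_names])
}

#' Train the artificial-neural-network comparator
#'
#' Thin adapter over `nnet::nnet` (single-hidden-layer perceptron,
#' developer defaults except a seeded start; `size` and `decay`
#' overridable). Non-convergence produces a warning with diagnostics, not
#' a failure.
#' @inheritParams train_rf
#' @param size hidden units (default 8); `decay` weight decay (default
#'   5e-4); `maxit` iterations (default 500).
#' @export
train_ann <- function(features, feature_names = NULL, seed = 1,
                      size = 8, decay = 5e-4, maxit = 500, ...) {
  y <- droplevels(factor(features$class))
  if (is.null(feature_names))
    feature_names <- setdiff(names(features), "class")
  x <- scale(as.matrix(features[feature_names]))
  ctr <- attr(x, "scaled:center"); scl <- attr(x, "scaled:scale")
  scl[scl == 0] <- 1
  set.seed(seed)
  fit <- nnet::nnet(x = x, y = nnet::class.ind(y), size = size,
                    decay = decay, maxit = maxit, softmax = TRUE,
                    trace = FALSE, MaxNWts = 1e5, ...)
  if (fit$convergence != 0)
    warning("ANN did not converge in ", maxit,
            " iterations (final value ", signif(fit$value, 6), ")")
  structure(list(fit = fit, feature_names = feature_names,
                 levels = levels(y), center = ctr, scale = scl,
                 seed = seed), class = "ann_model")
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  check_feature_contract(object$feature_names, names(newdata))
  x <- as.matrix(newdata[object$feature_names])
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- stats::predict(object$fit, x)
  factor(colnames(p)[max.col(p, ties.method = "first")],
         levels = object$levels)
}

#' Benchmark MTVF against the comparator models
#'
#' Trains the maximum-likelihood, SVM and ANN comparators on byte-identical
#' train/validation splits (the split checksum is recorded) and the same
#' selected features as a fitted MTVF model, and evaluates all four on the
#' validation features.
#'
#' @param model a fitted [mtvf()] object.
#' @param train labelled feature table used to fit `model`.
#' @param validate labelled feature table of validation samples.
#' @param seed integer seed for the comparators.
#' @return data.frame: one row per model with OA, cultivated-class UA/PA
#'   and kappa (percent / unitless), plus attribute `split_checksum`.
#' @export
compare_models <- function(model, train, validate, seed = 1) {
  stopifnot(inherits(model, "mtvf"))
  feats <- model$selection$features
  models <- list(
    MTVF = model,
    MLC = train_mlc(train, feats),
    SVM = train_svm(train, feats, seed = seed),
    ANN = train_ann(train, feats, seed = seed))
  truth <- factor(validate$class, levels = model$levels)
  rows <- lapply(names(models), function(nm) {
    pred <- factor(as.character(predict(models[[nm]], validate)),
                   levels = model$levels)
    cm <- confusion_counts(truth, pred, model$levels)
    rep <- accuracy_metrics(cm)
    cult <- if ("cultivated" %in% model$levels) "cultivated" else
      model$levels[1]
    data.frame(model = nm, OA = 100 * rep$OA,
               UA = 100 * rep$UA[[cult]], PA = 100 * rep$PA[[cult]],
               kappa = rep$kappa)
  })
  out <- do.call(rbind, rows)
  key <- paste(c(format(train$class), format(validate$class)),
               collapse = ";")
  attr(out, "split_checksum") <- sprintf("%08x", crc32_string(key))
  out
}

# Polynomial rolling hash over a string; enough to fingerprint a split.
crc32_string <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
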