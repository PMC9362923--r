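#' End-to-end workflow
#'
#' `run_pipeline()` drives the full chain in memory: simulate (or load) a
#' scene, evaluate the vegetation indices, build the feature table at the
#' sample pixels, fit the [mtvf()] classifier, classify the scene, and
#' assess accuracy on the validation samples; optionally benchmark the
#' comparator models on the identical split. The same stages are exposed
#' individually (artifacts on disk, plain CSV/TIFF/JSON) through the
#' `inst/cli/mtvf` command-line script.
#'
#' @param scene a `synthetic_scene` (default: generated from
#'   `scene_config(seed = seed)`); alternatively pass `manifest` to read
#'   rasters from disk.
#' @param manifest optional manifest path; overrides `scene`'s cube and
#'   applies `normalization`.
#' @param samples sample data.frame (`row`, `col`, `class`, `role`);
#'   default drawn from the scene.
#' @param normalization method for disk input (see [normalize_bands()]).
#' @param registry index registry (default the 23-index bank).
#' @param thresholds,tree_grid,n_rank_trees,holdout passed to [mtvf()].
#' @param compare also run the MLC / SVM / ANN comparators (default FALSE).
#' @param map classify the full scene and evaluate the map (default TRUE);
#'   with `FALSE` the evaluation uses validation-pixel predictions only.
#' @param seed root seed for every stage.
#' @param out optional directory; when set, importance, curves, selection,
#'   report (and comparison) are written there as CSV/JSON along with the
#'   resolved seed.
#' @return list of class `mtvf_run`: `fit`, `map` ([class_map] or NULL),
#'   `report` ([accuracy_metrics()] result), `binary_report`,
#'   `comparison` (or NULL), `samples`, `seed`.
#' @export
run_pipeline <- function(scene = NULL, manifest = NULL, samples = NULL,
                         normalization = "scale10000",
                         registry = register_default_indices(),
                         thresholds = c(0.1, 0.04, 0.02, 0),
                         tree_grid = seq(50, 1000, by = 50),
                         n_rank_trees = 500, holdout = 0.3,
                         compare = FALSE, map = TRUE, seed = 1,
                         out = NULL) {
  if (is.null(scene) && is.null(manifest))
    scene <- generate_scene(scene_config(seed = seed))
  if (!is.null(manifest)) {
    man <- read_manifest(manifest)
    cube <- normalize_bands(
      assemble_cube(man, DEFAULT_BANDS), normalization)
    truth <- NULL
    if (is.null(samples))
      stop("samples are required when reading a scene from a manifest")
  } else {
    cube <- scene$cube
    truth <- scene$truth
    if (is.null(samples))
      samples <- draw_samples(scene, seed = seed)
  }
  index_cube <- evaluate_indices(cube, registry)

  tr_px <- samples[samples$role == "train", ]
  va_px <- samples[samples$role == "validate", ]
  train <- label_features(
    build_feature_table(cube, index_cube, tr_px[c("row", "col")]), tr_px)
  validate <- label_features(
    build_feature_table(cube, index_cube, va_px[c("row", "col")]), va_px)

  fit <- mtvf(train, thresholds = thresholds, tree_grid = tree_grid,
              n_rank_trees = n_rank_trees, holdout = holdout, seed = seed)

  cmap <- NULL
  if (map) {
    cmap <- predict_map(fit, cube, index_cube)
    cm <- confusion(cmap, samples)
  } else {
    pred <- predict(fit, validate)
    cm <- confusion_counts(validate$class, pred, fit$levels)
  }
  report <- accuracy_metrics(cm)
  binary <- if (!is.null(cmap) && "cultivated" %in% fit$levels)
    binarize_and_evaluate(cmap, va_px) else NULL

  comparison <- if (compare)
    compare_models(fit, train, validate, seed = seed) else NULL

  res <- structure(list(fit = fit, map = cmap, report = report,
                        binary_report = binary, comparison = comparison,
                        samples = samples, train = train,
                        validate = validate, seed = seed),
                   class = "mtvf_run")
  if (!is.null(out)) write_run_artifacts(res, out)
  res
}

#' @export
print.mtvf_run <- function(x, ...) {
  cat("MTVF pipeline run (seed ", x$seed, ")\n", sep = "")
  print(x$fit)
  cat("\nValidation accuracy:\n")
  print(x$report)
  if (!is.null(x$comparison)) {
    cat("\nModel comparison (cultivated-class UA/PA, %):\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}

#' Write a run's artifacts as plain CSV/JSON files
#' @param run an `mtvf_run`; `dir` output directory.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$fit$importance,
                   file.path(dir, "importance.csv"), row.names = FALSE)
  utils::write.csv(run$fit$selection$curves,
                   file.path(dir, "selection_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(group = run$fit$selection$group,
         n_features = length(run$fit$selection$features),
         features = run$fit$selection$features,
         n_trees = run$fit$forest$n_trees, seed = run$seed),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  write_accuracy_report(run$report, file.path(dir, "report.json"))
  if (!is.null(run$comparison))
    utils::write.csv(run$comparison, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
  if (!is.null(run$map))
    write_raster_dn(run$map$labels, file.path(dir, "classmap.tif"))
  invisible(dir)
}

#' Single-date spectral baseline
#'
#' Trains a random forest on the band values of one acquisition date only
#' (no temporal features) using the identical samples, and returns its
#' validation accuracy report. The natural reference date is the first
#' acquisition: at the annual time node (October, winter-wheat sowing)
#' cultivated land is spectrally bare soil, the hard case temporal
#' features are designed to resolve.
#'
#' @param cube band [ts_cube]; `samples` as in [run_pipeline()];
#'   `date_index` which acquisition to use (default 1); `n_trees` forest
#'   size (default 400); `seed` integer.
#' @return [accuracy_metrics()] report.
#' @export
single_date_baseline <- function(cube, samples, date_index = 1,
                                 n_trees = 400, seed = 1) {
  d <- dim(cube$values)
  flat <- matrix(cube$values[, , date_index, ], nrow = d[1] * d[2])
  colnames(flat) <- cube$band_names
  lin <- (samples$col - 1) * d[1] + samples$row
  x <- as.data.frame(flat[lin, , drop = FALSE])
  x$class <- samples$class
  tr <- samples$role == "train"
  model <- train_rf(x[tr, ], n_trees = n_trees, seed = seed)
  pred <- predict(model, x[!tr, ])
  cm <- confusion_counts(x$class[!tr], pred, model$levels)
  accuracy_metrics(cm)
}
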