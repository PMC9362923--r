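test_that("the forest memorizes a pure training set and enforces its contract", {
  # one perfectly separating feature: a single tree reaches accuracy 1
  pure <- data.frame(f = rep(c(0, 10, 20), each = 10),
                     class = factor(rep(c("a", "b", "c"), each = 10)))
  mp <- train_rf(pure, n_trees = 1, seed = 1)
  expect_equal(mean(predict(mp, pure) == pure$class), 1)

  feats <- toy_features(n = 30, seed = 1)
  m <- train_rf(feats, n_trees = 25, seed = 1)
  expect_error(predict(m, feats[c("f_signal", "f_weak")]),
               "lacks feature column")
  # column permutation does not change predictions (name contract)
  shuffled <- feats[rev(names(feats))]
  expect_identical(predict(m, shuffled), predict(m, feats))
  one <- feats; one$class <- factor("a", levels = "a")
  expect_error(train_rf(one), "2 classes")
})

test_that("the Gaussian discriminant reproduces hand-computed decisions", {
  # class 1 ~ N(0,1), class 2 ~ N(3,4), equal priors: at x = 1,
  # g1 = ln(1/2) - 0.5, g2 = ln(1/2) - ln 2 - 0.5  =>  class 1
  tr <- data.frame(x = c(-1, 0, 1, 1, 3, 5), class = factor(
    c("c1", "c1", "c1", "c2", "c2", "c2")))
  m <- train_mlc(tr, priors = "equal", epsilon = 0)
  # overwrite estimated moments with the exact ones
  m$models$c1$mu <- c(x = 0); m$models$c2$mu <- c(x = 3)
  m$models$c1$chol <- matrix(1); m$models$c1$logdet <- 0
  m$models$c2$chol <- matrix(2); m$models$c2$logdet <- log(4)
  g <- predict(m, data.frame(x = 1), type = "score")
  expect_equal(unname(g[1, "c1"]), log(0.5) - 0.5)
  expect_equal(unname(g[1, "c2"]), log(0.5) - log(2) - 0.5)
  expect_equal(as.character(predict(m, data.frame(x = 1))), "c1")

  # equidistant tie between N(0,1) and N(2,1) breaks to the first class
  m$models$c2$mu <- c(x = 2)
  m$models$c2$chol <- matrix(1); m$models$c2$logdet <- 0
  p <- predict(m, data.frame(x = 1))
  expect_equal(as.character(p), "c1")
  expect_equal(attr(p, "n_ties"), 1)
})

test_that("equal isotropic covariances reduce MLC to nearest-mean", {
  set.seed(8)
  mu <- list(a = c(0, 0), b = c(3, 0), c = c(0, 3))
  tr <- do.call(rbind, lapply(names(mu), function(cl)
    data.frame(x = stats::rnorm(80) + mu[[cl]][1],
               y = stats::rnorm(80) + mu[[cl]][2], class = cl)))
  tr$class <- factor(tr$class)
  m <- train_mlc(tr, priors = "equal")
  # force the shared covariance so the reduction is exact
  shared <- chol(diag(2) + diag(1e-6, 2))
  for (cl in names(mu)) {
    m$models[[cl]]$chol <- shared
    m$models[[cl]]$logdet <- 2 * sum(log(diag(shared)))
    m$models[[cl]]$mu <- stats::setNames(mu[[cl]], c("x", "y"))
  }
  te <- data.frame(x = stats::runif(200, -2, 5),
                   y = stats::runif(200, -2, 5))
  pred <- predict(m, te)
  nearest <- names(mu)[apply(vapply(mu, function(u)
    (te$x - u[1])^2 + (te$y - u[2])^2, numeric(200)), 1, which.min)]
  expect_equal(as.character(pred), nearest)
})

test_that("scene prediction preserves nodata and is tile-invariant", {
  sc <- small_scene()
  sam <- small_samples()
  tr <- sam[sam$role == "train", ]
  ft <- label_features(build_feature_table(sc$cube, pixels = tr[c("row", "col")]), tr)
  m <- train_rf(ft, n_trees = 50, seed = 4)

  map1 <- predict_map(m, sc$cube)
  map2 <- predict_map(m, sc$cube, tile_rows = 997)
  expect_identical(map1$labels, map2$labels)
  expect_identical(map1$labels,
                   predict_map(m, sc$cube)$labels)  # determinism

  empty <- sc$cube
  empty$valid_mask[] <- FALSE
  expect_true(all(is.na(predict_map(m, empty)$labels)))

  # nodata pixels stay nodata, valid pixels are all labelled
  holey <- sc$cube
  holey$valid_mask[1:5, 1:5] <- FALSE
  mh <- predict_map(m, holey)
  expect_true(all(is.na(mh$labels[1:5, 1:5])))
  expect_false(anyNA(mh$labels[10:20, 10:20]))
})

test_that("comparators train on separable data and are seeded", {
  feats <- toy_features(n = 90, seed = 3)
  svm <- train_svm(feats, seed = 1)
  expect_equal(mean(predict(svm, feats) == feats$class), 1)
  a1 <- train_ann(feats, seed = 6)
  a2 <- train_ann(feats, seed = 6)
  expect_identical(a1$fit$wts, a2$fit$wts)
  expect_identical(predict(a1, feats), predict(a2, feats))
})

test_that("the model benchmark runs all four models on one split", {
  sc <- small_scene()
  sam <- small_samples()
  idx <- evaluate_indices(sc$cube)
  tr <- label_features(build_feature_table(
    sc$cube, idx, sam[sam$role == "train", c("row", "col")]),
    sam[sam$role == "train", ])
  va <- label_features(build_feature_table(
    sc$cube, idx, sam[sam$role == "validate", c("row", "col")]),
    sam[sam$role == "validate", ])
  fit <- suppressWarnings(
    mtvf(tr, tree_grid = c(50, 100), n_rank_trees = 200, seed = 5))
  # the ANN may emit its non-convergence diagnostic here; that is its
  # documented behaviour, not a failure
  cmp <- suppressWarnings(compare_models(fit, tr, va, seed = 5))
  expect_equal(cmp$model, c("MTVF", "MLC", "SVM", "ANN"))
  expect_named(cmp, c("model", "OA", "UA", "PA", "kappa"))
  expect_true(all(cmp$OA >= 0 & cmp$OA <= 100))
  expect_true(all(cmp$kappa >= -1 & cmp$kappa <= 1))
  expect_match(attr(cmp, "split_checksum"), "^[0-9a-f]{8}$")
})
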