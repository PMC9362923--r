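test_that("vector features match hand evaluation", {
  v <- c(1, rep(0, 11))
  f <- vector_features(v)
  expect_equal(f[["Cos"]], 1 / sqrt(12))
  expect_equal(f[["Dis"]], 11)           # 0^2 + 11 * 1^2
  expect_equal(f[["Max"]], 1)
  expect_equal(f[["Min"]], 0)
  expect_equal(f[["Ran"]], 1)

  # constant positive vector is parallel to the reference
  fc <- vector_features(rep(0.3, 12))
  expect_equal(fc[["Cos"]], 1)
  expect_equal(fc[["Ran"]], 0)

  # the reference vector itself is at distance zero
  expect_equal(vector_features(rep(1, 12))[["Dis"]], 0)
})

test_that("degenerate vectors are rejected", {
  expect_error(vector_features(rep(0, 5)), "all-zero")
  expect_error(extract_vector(1), "at least 2")
  expect_error(extract_vector(c(1, NaN, 2)), "invalid")
})

test_that("alternate cosine and distance forms are available", {
  v <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(vector_features(v, cosine_form = "printed")[["Cos"]],
               sum(v) / (4 * sum(v^2)))
  expect_equal(vector_features(v, distance_form = "euclidean")[["Dis"]],
               sqrt(sum((1 - v)^2)))
})

test_that("matrix features agree with a naive per-vector oracle", {
  set.seed(99)
  n <- 1000; Tn <- 12
  M <- matrix(stats::runif(n * Tn, 0.01, 1.5), n, Tn)
  fast <- mtvf:::features_of_matrix(M)
  naive <- t(apply(M, 1, function(v) {
    c(Cos = sum(v) / sqrt(sum(rep(1, Tn)^2) * sum(v^2)),
      Dis = sum((1 - v)^2), Max = max(v), Min = min(v),
      Ran = max(v) - min(v))
  }))
  expect_lt(max(abs(fast - naive)), 1e-10)
  # and with the loop-based single-vector entry point
  for (i in sample(n, 25))
    expect_equal(unname(vector_features(M[i, ])), unname(naive[i, ]),
                 tolerance = 1e-10)
})

test_that("scaling and time-permutation behave as the geometry dictates", {
  set.seed(7)
  for (i in 1:20) {
    v <- stats::runif(12, 0.05, 1)
    s <- stats::runif(1, 0.5, 3)
    f <- vector_features(v); fs <- vector_features(s * v)
    expect_equal(fs[["Cos"]], f[["Cos"]], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(fs[["Dis"]], f[["Dis"]])))
    expect_false(isTRUE(all.equal(fs[["Ran"]], f[["Ran"]])))
    # constant reference: permuting acquisition order changes nothing
    fp <- vector_features(sample(v))
    expect_equal(fp, f, tolerance = 1e-12)
  }
})

test_that("the feature table has 5 columns per parameter in fixed order", {
  sc <- small_scene()
  idx <- evaluate_indices(sc$cube)
  px <- data.frame(row = c(1, 5, 10), col = c(2, 3, 4))
  full <- build_feature_table(sc$cube, idx, px)
  expect_equal(ncol(full), 180)        # (13 bands + 23 indices) x 5
  expect_equal(names(full)[1:5],
               c("B1_Cos", "B1_Dis", "B1_Max", "B1_Min", "B1_Ran"))
  expect_equal(names(full)[66:70],
               c("SAVI_Cos", "SAVI_Dis", "SAVI_Max", "SAVI_Min",
                 "SAVI_Ran"))
  expect_true(all(grepl("_(Cos|Dis|Max|Min|Ran)$", names(full))))

  bands_only <- build_feature_table(sc$cube, pixels = px)
  expect_equal(ncol(bands_only), 65)   # 13 x 5

  one_band <- sc$cube
  one_band$values <- one_band$values[, , , 4, drop = FALSE]
  one_band$band_names <- "B4"
  expect_equal(ncol(build_feature_table(one_band, pixels = px)), 5)

  reg3 <- register_default_indices()[c("NDVI", "EVI2", "SAVI")]
  two_band <- sc$cube
  two_band$values <- two_band$values[, , , c(4, 8), drop = FALSE]
  two_band$band_names <- c("B4", "B8")
  idx3 <- evaluate_indices(two_band, reg3)
  expect_equal(ncol(build_feature_table(two_band, idx3, px)), 25)

  # date mismatch between cubes is an error
  idx_bad <- idx
  idx_bad$dates <- idx$dates + 1
  expect_error(build_feature_table(sc$cube, idx_bad, px), "dates")
})

test_that("labelling drops rows with undefined features", {
  ft <- data.frame(B4_Cos = c(1, NA, 3), B4_Dis = c(1, 2, 3))
  attr(ft, "pixels") <- data.frame(row = 1:3, col = 1L)
  sam <- data.frame(row = 1:3, col = 1L,
                    class = c("cultivated", "water", "bare"))
  lf <- label_features(ft, sam)
  expect_equal(nrow(lf), 2)
  expect_s3_class(lf$class, "factor")
  expect_error(label_features(ft, data.frame(row = 9, col = 9,
                                             class = "bare")),
               "missing from the feature table")
})
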