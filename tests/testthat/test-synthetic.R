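test_that("the generator is deterministic in its seed", {
  cfg <- scene_config(width = 32, height = 32, mean_patch_area = 128,
                      seed = 9)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$cube$values, s2$cube$values)
  expect_identical(s1$truth$labels, s2$truth$labels)
  s3 <- generate_scene(scene_config(width = 32, height = 32,
                                    mean_patch_area = 128, seed = 10))
  expect_false(identical(s1$cube$values, s3$cube$values))
})

test_that("the noiseless limit reproduces class profiles exactly", {
  cfg <- scene_config(width = 24, height = 24, mean_patch_area = 96,
                      noise_sd = 0, brightness_sd = 0, boundary_width = 0,
                      seed = 2)
  sc <- generate_scene(cfg)
  profs <- lapply(stats::setNames(LAND_CLASSES, LAND_CLASSES),
                  class_profile)
  for (px in list(c(3, 3), c(12, 20), c(22, 7))) {
    cl <- LAND_CLASSES[sc$truth$labels[px[1], px[2]]]
    expect_equal(sc$cube$values[px[1], px[2], , ],
                 unname(profs[[cl]]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(sum(sc$mixed_mask), 0)
})

test_that("class phenologies carry the designed temporal signatures", {
  # cultivated NDVI: exactly two interior local maxima (double cropping)
  p <- class_profile("cultivated")
  ndvi <- (p[, "B8"] - p[, "B4"]) / (p[, "B8"] + p[, "B4"])
  interior <- 2:(length(ndvi) - 1)
  n_peaks <- sum(ndvi[interior] > ndvi[interior - 1] &
                   ndvi[interior] > ndvi[interior + 1])
  expect_equal(n_peaks, 2)
  # woodland and grassland: single broad peak, grassland lower amplitude
  for (cl in c("woodland", "grassland")) {
    pg <- class_profile(cl)
    nd <- (pg[, "B8"] - pg[, "B4"]) / (pg[, "B8"] + pg[, "B4"])
    expect_equal(sum(nd[interior] > nd[interior - 1] &
                       nd[interior] > nd[interior + 1]), 1, label = cl)
  }
  expect_lt(diff(range(class_profile("grassland")[, "B8"])),
            diff(range(class_profile("woodland")[, "B8"])))
  # water: persistently dark in the near infrared
  expect_lt(mean(class_profile("water")[, "B8"]), 0.1)
  # all profiles are valid reflectance
  for (cl in LAND_CLASSES) {
    pr <- class_profile(cl)
    expect_true(all(pr > 0 & pr < 1), label = cl)
  }
})

test_that("oversized patches and undersized classes are rejected", {
  expect_error(scene_config(width = 16, height = 16,
                            mean_patch_area = 1e5), "patch size")
  sc <- generate_scene(scene_config(width = 24, height = 24,
                                    mean_patch_area = 96, seed = 2))
  expect_error(draw_samples(sc, n_train = 500, n_validate = 500),
               "has only")
})

test_that("sample draws are stratified, capped and disjoint", {
  sc <- cached("sample_scene", generate_scene(
    scene_config(width = 128, height = 128, mean_patch_area = 1000,
                 seed = 5)))
  sam <- draw_samples(sc, seed = 11)
  tab <- table(sam$class, sam$role)
  expect_equal(unname(tab[, "train"]),
               c(130, 130, 130, 70, 130, 70))    # 10 x 13 bands; caps
  expect_true(all(tab[, "validate"] == 300))
  key <- paste(sam$row, sam$col)
  expect_false(any(duplicated(key)))             # train and validate disjoint
  # samples carry their true class
  got <- sc$truth$labels[cbind(sam$row, sam$col)]
  expect_equal(LAND_CLASSES[got], as.character(sam$class))
})

test_that("widening the boundary strictly increases mixed-pixel counts", {
  counts <- vapply(c(0, 1, 3), function(w) {
    sum(generate_scene(scene_config(width = 48, height = 48,
                                    mean_patch_area = 230,
                                    boundary_width = w,
                                    seed = 6))$mixed_mask)
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("accuracy degrades monotonically with sensor noise", {
  oas <- vapply(c(0, 0.02, 0.05, 0.1), function(sd) {
    sc <- generate_scene(scene_config(width = 96, height = 96,
                                      mean_patch_area = 900,
                                      noise_sd = sd, seed = 13))
    sam <- draw_samples(sc, n_train = 60, n_validate = 100, seed = 13)
    run <- suppressWarnings(run_pipeline(
      scene = sc, samples = sam, tree_grid = 100, n_rank_trees = 200,
      map = FALSE, seed = 13))
    run$report$OA
  }, 0)
  expect_true(all(diff(oas) <= 0.005))  # non-increasing within noise jitter
  expect_lt(oas[4], oas[1])
})
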