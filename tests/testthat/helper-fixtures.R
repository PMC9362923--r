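# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small 6-class scene with the default band set (fast, all stages work).
small_scene <- function() cached("small_scene", {
  generate_scene(scene_config(width = 64, height = 64,
                              mean_patch_area = 600, seed = 3))
})

small_samples <- function() cached("small_samples", {
  draw_samples(small_scene(), n_train = 60, n_validate = 60, seed = 3)
})

# Labelled 180-column training table on the small scene.
small_train_features <- function() cached("small_train", {
  sc <- small_scene()
  idx <- evaluate_indices(sc$cube)
  tr <- small_samples()[small_samples()$role == "train", ]
  label_features(build_feature_table(sc$cube, idx, tr[c("row", "col")]),
                 tr)
})

# Tiny labelled table with two informative and two noise features.
toy_features <- function(n = 60, seed = 42) {
  set.seed(seed)
  cls <- factor(rep(c("a", "b", "c"), length.out = n))
  data.frame(
    f_signal = as.integer(cls) + stats::rnorm(n, 0, 0.05),
    f_weak = as.integer(cls) + stats::rnorm(n, 0, 1.5),
    f_noise1 = stats::rnorm(n),
    f_noise2 = stats::rnorm(n),
    class = cls)
}

# Reflectance-like random band list for index purity checks.
random_bands <- function(n, seed) {
  set.seed(seed)
  lapply(stats::setNames(DEFAULT_BANDS, DEFAULT_BANDS),
         function(b) stats::runif(n, 0.01, 0.6))
}
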