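#' Synthetic multi-date multispectral scenes
#'
#' Seeded generator of scenes with a known class map and class-specific
#' seasonal (phenology) reflectance profiles, so the whole pipeline can be
#' exercised and validated without external imagery. The landscape is a
#' Voronoi patch mosaic; per-pixel reflectance is the class profile at each
#' date plus i.i.d. Gaussian noise, and pixels near a patch boundary mix
#' the two adjacent class profiles linearly (mixed pixels).
#'
#' Class temporal signatures (months indexed October..September):
#' cultivated land follows a double-peaked greenness curve (winter wheat
#' peaking in spring, summer corn peaking in late summer); woodland a
#' single broad summer peak; grassland a lower-amplitude single peak;
#' water has persistently low near-infrared reflectance; artificial and
#' bare surfaces are temporally flat with different brightness.
#'
#' @name synthetic_scene_doc
NULL

#' Default 13-band Sentinel-2-style band set
#' @export
DEFAULT_BANDS <- c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8",
                   "B8A", "B9", "B10", "B11", "B12")

# End-member spectra (surface reflectance) over DEFAULT_BANDS.
ENDMEMBERS <- list(
  veg   = c(0.03, 0.04, 0.08, 0.04, 0.14, 0.32, 0.42, 0.46, 0.47, 0.25,
            0.010, 0.22, 0.10),
  soil  = c(0.10, 0.12, 0.16, 0.20, 0.23, 0.25, 0.27, 0.28, 0.29, 0.20,
            0.010, 0.36, 0.31),
  water = c(0.080, 0.070, 0.060, 0.030, 0.020, 0.015, 0.012, 0.010,
            0.010, 0.008, 0.005, 0.006, 0.005),
  urban = c(0.18, 0.20, 0.22, 0.24, 0.25, 0.26, 0.27, 0.28, 0.28, 0.22,
            0.010, 0.32, 0.30))
names(ENDMEMBERS$veg) <- names(ENDMEMBERS$soil) <-
  names(ENDMEMBERS$water) <- names(ENDMEMBERS$urban) <- DEFAULT_BANDS

# Greenness (vegetation fraction) curves on month index 1..12 = Oct..Sep.
greenness <- function(class, t) {
  switch(class,
    cultivated = 0.05 + 0.90 * exp(-((t - 7) / 1.4)^2) +
      0.80 * exp(-((t - 11) / 1.2)^2),
    woodland = 0.15 + 0.75 * exp(-((t - 9.4) / 2.6)^2),
    grassland = 0.10 + 0.45 * exp(-((t - 9.2) / 2.2)^2),
    rep(0, length(t)))
}

#' Noise-free reflectance profile of one class
#'
#' @param class one of [LAND_CLASSES].
#' @param bands band names (subset of [DEFAULT_BANDS]).
#' @param n_dates number of equally spaced dates across the season.
#' @return `n_dates` x `length(bands)` matrix of reflectance in (0, 1).
#' @export
class_profile <- function(class, bands = DEFAULT_BANDS, n_dates = 12) {
  class <- match.arg(class, LAND_CLASSES)
  t <- seq(1, 12, length.out = n_dates)
  veg <- ENDMEMBERS$veg[bands]; soil <- ENDMEMBERS$soil[bands]
  prof <- switch(class,
    cultivated = outer(1 - greenness("cultivated", t), soil) +
      outer(greenness("cultivated", t), veg),
    woodland = outer(1 - greenness("woodland", t), 0.60 * soil) +
      outer(greenness("woodland", t), veg),
    grassland = outer(1 - greenness("grassland", t), 0.85 * soil) +
      outer(greenness("grassland", t), veg),
    water = matrix(ENDMEMBERS$water[bands], n_dates, length(bands),
                   byrow = TRUE),
    artificial = matrix(ENDMEMBERS$urban[bands], n_dates, length(bands),
                        byrow = TRUE),
    bare = matrix(pmin(1.15 * soil, 0.95), n_dates, length(bands),
                  byrow = TRUE))
  colnames(prof) <- bands
  pmin(pmax(prof, 1e-3), 0.999)
}

#' Scene configuration
#'
#' @param width,height scene size in pixels (default 256 x 256).
#' @param dates acquisition dates; default 12 monthly dates spanning one
#'   agricultural year (mid-October through mid-September).
#' @param bands band names (default the 13-band set).
#' @param noise_sd additive Gaussian reflectance noise sd (default 0.02).
#' @param brightness_sd sd of the per-pixel log-normal brightness factor
#'   (default 0.15). The factor multiplies a pixel's whole reflectance
#'   series and is constant over time: it emulates albedo and illumination
#'   variability (soil moisture, tillage, topography), the source of the
#'   single-date spectral overlap between land-cover classes that temporal
#'   features are designed to resolve.
#' @param boundary_width mixed-pixel boundary width in pixels (default 1).
#' @param mean_patch_area mean Voronoi patch area in pixels (default 2500,
#'   i.e. roughly 500 m fields at 10 m resolution).
#' @param proportions named class proportions, summing to 1.
#' @param seed root seed; mosaic and noise use named substreams of it.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(width = 256, height = 256,
                         dates = seq(as.Date("2019-10-15"), by = "month",
                                     length.out = 12),
                         bands = DEFAULT_BANDS,
                         noise_sd = 0.02, brightness_sd = 0.15,
                         boundary_width = 1,
                         mean_patch_area = 2500,
                         proportions = c(cultivated = 0.45,
                                         woodland = 0.15,
                                         grassland = 0.12, water = 0.08,
                                         artificial = 0.12, bare = 0.08),
                         seed = 1) {
  stopifnot(width >= 4, height >= 4, noise_sd >= 0, brightness_sd >= 0,
            boundary_width >= 0, length(dates) >= 2,
            length(proportions) >= 2)
  if (mean_patch_area > width * height)
    stop("mean patch size larger than the scene")
  proportions <- proportions / sum(proportions)
  structure(list(width = width, height = height, dates = as.Date(dates),
                 bands = bands, noise_sd = noise_sd,
                 brightness_sd = brightness_sd,
                 boundary_width = boundary_width,
                 mean_patch_area = mean_patch_area,
                 proportions = proportions, seed = seed),
            class = "scene_config")
}

#' Generate a synthetic scene
#'
#' @param config a [scene_config()].
#' @return list of class `synthetic_scene`: `cube` ([ts_cube] of
#'   reflectance), `truth` ([class_map]), `mixed_mask` (logical H x W,
#'   pixels whose spectra mix two classes), `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  H <- config$height; W <- config$width
  classes <- names(config$proportions)
  n_dates <- length(config$dates)
  bands <- config$bands

  # --- mosaic substream
  set.seed(config$seed)
  n_sites <- max(length(classes), round(H * W / config$mean_patch_area))
  sr <- stats::runif(n_sites, 0.5, H + 0.5)
  sc <- stats::runif(n_sites, 0.5, W + 0.5)
  # class per site, matching proportions (largest remainder), shuffled
  quota <- floor(config$proportions * n_sites)
  rem <- config$proportions * n_sites - quota
  short <- n_sites - sum(quota)
  if (short > 0) {
    up <- order(rem, decreasing = TRUE)[seq_len(short)]
    quota[up] <- quota[up] + 1
  }
  quota[quota == 0] <- 1                      # every class present
  while (sum(quota) > n_sites)                # rebalance from the largest
    quota[which.max(quota)] <- quota[which.max(quota)] - 1
  site_class <- sample(rep(seq_along(classes), quota))

  px_r <- rep(seq_len(H), times = W)
  px_c <- rep(seq_len(W), each = H)
  # per-class minimum distance to a site of that class
  dmin <- matrix(Inf, H * W, length(classes))
  for (s in seq_len(n_sites)) {
    ds <- sqrt((px_r - sr[s])^2 + (px_c - sc[s])^2)
    k <- site_class[s]
    dmin[, k] <- pmin(dmin[, k], ds)
  }
  truth_k <- max.col(-dmin, ties.method = "first")
  d1 <- dmin[cbind(seq_len(H * W), truth_k)]
  dmin2 <- dmin
  dmin2[cbind(seq_len(H * W), truth_k)] <- Inf
  second_k <- max.col(-dmin2, ties.method = "first")
  d2 <- dmin2[cbind(seq_len(H * W), second_k)]
  gap <- d2 - d1
  alpha <- ifelse(config$boundary_width > 0 & gap < config$boundary_width,
                  0.5 * (1 - gap / config$boundary_width), 0)

  # --- brightness substream (per-pixel albedo factor, constant in time)
  set.seed(config$seed + 2000003L)
  bright <- if (config$brightness_sd > 0)
    exp(stats::rnorm(H * W, 0, config$brightness_sd)) else rep(1, H * W)

  profiles <- lapply(stats::setNames(classes, classes), class_profile,
                     bands = bands, n_dates = n_dates)
  values <- array(NA_real_, c(H, W, n_dates, length(bands)))
  for (t in seq_len(n_dates)) {
    for (b in seq_along(bands)) {
      p1 <- vapply(classes, function(cl) profiles[[cl]][t, b], 0)
      v <- ((1 - alpha) * p1[truth_k] + alpha * p1[second_k]) * bright
      values[, , t, b] <- matrix(v, H, W)
    }
  }
  # --- noise substream
  set.seed(config$seed + 1000003L)
  if (config$noise_sd > 0)
    values <- values + stats::rnorm(length(values), 0, config$noise_sd)
  values <- soft_clip(values)

  truth <- class_map(matrix(match(classes[truth_k], LAND_CLASSES), H, W),
                     LAND_CLASSES)
  cube <- ts_cube(values, config$dates, bands,
                  grid = default_grid(), kind = "band")
  structure(list(cube = cube, truth = truth,
                 mixed_mask = matrix(alpha > 0, H, W), config = config),
            class = "synthetic_scene")
}

# Monotone soft saturation into (0, 1): values beyond [lo, hi] are
# compressed exponentially instead of truncated, so distinct inputs stay
# distinct (a hard clamp would create exact ties between bands and hence
# zero denominators in ratio indices, which real reflectance never shows).
soft_clip <- function(x, lo = 1e-3, hi = 0.999) {
  low <- x < lo
  x[low] <- lo * exp((x[low] - lo) / lo)
  high <- x > hi
  x[high] <- 1 - (1 - hi) * exp(-(x[high] - hi) / (1 - hi))
  x
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d dates, %d bands, noise sd %.3g\n",
              x$config$height, x$config$width, length(x$config$dates),
              length(x$config$bands), x$config$noise_sd))
  cat(sprintf("  mixed pixels: %d (%.1f%%)\n", sum(x$mixed_mask),
              100 * mean(x$mixed_mask)))
  invisible(x)
}

#' Draw stratified, disjoint training and validation samples
#'
#' Training defaults to ten times the number of bands per class (the
#' supervised-classification rule of thumb), with the sparse water and
#' bare classes capped at 70 pixels.
#'
#' @param scene a [generate_scene()] result.
#' @param n_train training pixels per class; default `10 * #bands`.
#' @param n_validate validation pixels per class (default 300).
#' @param caps named per-class training caps
#'   (default `c(water = 70, bare = 70)`).
#' @param seed sampling seed.
#' @return data.frame `row`, `col`, `class` (factor), `role`
#'   (`train` / `validate`), train and validate disjoint.
#' @export
draw_samples <- function(scene, n_train = 10 * length(scene$config$bands),
                         n_validate = 300,
                         caps = c(water = 70, bare = 70), seed = 1) {
  set.seed(seed)
  truth <- scene$truth$labels
  legend <- scene$truth$legend
  out <- list()
  for (k in sort(unique(as.vector(truth)))) {
    cl <- legend[k]
    n_tr <- n_train
    if (cl %in% names(caps)) n_tr <- min(n_tr, caps[[cl]])
    idx <- which(truth == k)
    if (length(idx) < n_tr + n_validate)
      stop("class '", cl, "' has only ", length(idx),
           " pixels; needs ", n_tr + n_validate)
    pick <- sample(idx, n_tr + n_validate)
    out[[cl]] <- data.frame(
      row = ((pick - 1) %% nrow(truth)) + 1,
      col = ((pick - 1) %/% nrow(truth)) + 1,
      class = cl,
      role = rep(c("train", "validate"), c(n_tr, n_validate)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$class <- factor(res$class, levels = legend)
  res
}

#' Write a scene to disk in the pipeline's input format
#'
#' Per-date 16-bit TIFF rasters of digital numbers plus a JSON manifest,
#' the ground-truth class raster, and the samples CSV.
#' @param scene a `synthetic_scene`; `samples` optional data.frame from
#'   [draw_samples()]; `dir` output directory.
#' @return the manifest path.
#' @export
write_scene <- function(scene, dir, samples = NULL) {
  manifest <- write_cube(scene$cube, dir)
  write_raster_dn(scene$truth$labels, file.path(dir, "truth.tif"))
  if (!is.null(samples))
    utils::write.csv(samples, file.path(dir, "samples.csv"),
                     row.names = FALSE)
  manifest
}
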