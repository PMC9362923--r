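#' Time-series reflectance cubes
#'
#' A `ts_cube` holds a T-date x B-parameter x H x W stack of surface
#' reflectance (or vegetation-index) values together with the acquisition
#' dates, parameter names, a validity mask and a minimal grid description.
#' It is the container every downstream stage (index evaluation, vector
#' feature extraction, classification) consumes.
#'
#' Values are stored as a 4-d array indexed `[row, col, date, parameter]`
#' so that one date/parameter slice is an H x W matrix in image orientation.
#'
#' @param values numeric array of dimension `c(H, W, T, B)`.
#' @param dates `Date` vector of length T, strictly increasing.
#' @param band_names character vector of length B, unique.
#' @param valid_mask logical H x W matrix; `TRUE` where the pixel is usable
#'   at every date. Defaults to all-`TRUE`.
#' @param grid list with elements `origin` (map coordinates of the center of
#'   the top-left pixel), `pixel` (pixel size, map units, `c(dx, dy)`) and
#'   `crs` (free-form string). Pixel centers; rasters are north-up.
#' @param kind `"band"` or `"index"`; informational.
#' @return An object of class `ts_cube`.
#' @export
ts_cube <- function(values, dates, band_names, valid_mask = NULL,
                    grid = default_grid(), kind = "band") {
  stopifnot(is.array(values), length(dim(values)) == 4)
  d <- dim(values)
  dates <- as.Date(dates)
  if (length(dates) != d[3])
    stop("length(dates) must equal the third array dimension")
  if (length(dates) < 2)
    stop("a time series cube requires at least 2 dates")
  if (any(diff(as.numeric(dates)) <= 0))
    stop("dates must be distinct and strictly increasing")
  if (length(band_names) != d[4])
    stop("length(band_names) must equal the fourth array dimension")
  if (anyDuplicated(band_names))
    stop("band_names must be unique")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1], d[2])
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == d[1:2]))
  structure(list(values = values, dates = dates, band_names = band_names,
                 valid_mask = valid_mask, grid = grid, kind = kind),
            class = "ts_cube")
}

default_grid <- function(origin = c(0, 0), pixel = c(10, -10),
                         crs = "local-metric") {
  list(origin = origin, pixel = pixel, crs = crs)
}

#' @export
dim.ts_cube <- function(x) dim(x$values)

#' @export
print.ts_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ts_cube> %d x %d px, %d dates (%s .. %s), %d %s parameters\n",
              d[1], d[2], d[3], format(min(x$dates)), format(max(x$dates)),
              d[4], x$kind))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid_mask), d[1] * d[2]))
  invisible(x)
}

#' Read an acquisition manifest
#'
#' The manifest pairs acquisition dates with raster file paths, one row per
#' scene, and optionally carries the grid metadata. CSV needs columns
#' `date,path`; JSON needs fields `entries` (list of `{date, path}`) and an
#' optional `grid`.
#'
#' @param path CSV or JSON manifest file.
#' @return list with `dates` (Date), `paths` (character, resolved relative
#'   to the manifest directory) and `grid`.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    dates <- as.Date(m$entries$date)
    paths <- m$entries$path
    grid <- if (!is.null(m$grid)) {
      list(origin = as.numeric(m$grid$origin), pixel = as.numeric(m$grid$pixel),
           crs = as.character(m$grid$crs))
    } else default_grid()
  } else {
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("date", "path") %in% names(m)))
      stop("manifest CSV must have columns 'date' and 'path'")
    dates <- as.Date(m$date)
    paths <- m$path
    grid <- default_grid()
  }
  if (length(dates) < 2) stop("manifest must list at least 2 acquisitions")
  if (anyDuplicated(dates)) stop("manifest dates must be distinct")
  o <- order(dates)
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  list(dates = dates[o], paths = paths[o], grid = grid)
}

#' Write an acquisition manifest (JSON, with grid metadata)
#' @param dates Date vector; `paths` file paths; `grid` grid list;
#'   `path` output file.
#' @export
write_manifest <- function(dates, paths, grid, path) {
  jsonlite::write_json(
    list(entries = data.frame(date = format(as.Date(dates)), path = paths),
         grid = grid),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Raster I/O. Values on disk are 16-bit digital numbers (DN); surface
# reflectance maps to DN = reflectance * 10000, the L2A convention, so a
# write/read round trip is bit-exact. A slice is H x W (one band) or
# H x W x B.
#' Write a raster of digital numbers to TIFF
#' @param dn integer-valued matrix or 3-d array, range 0..65535.
#' @param path output file.
#' @export
write_raster_dn <- function(dn, path) {
  if (any(!is.finite(dn)) || any(dn < 0) || any(dn > 65535))
    stop("digital numbers must be finite and in 0..65535")
  if (length(dim(dn)) == 2) dn <- array(dn, c(dim(dn), 1))
  # one greyscale page per band (baseline TIFF caps samples per pixel)
  pages <- lapply(seq_len(dim(dn)[3]), function(b) dn[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a raster of digital numbers from TIFF
#' @param path TIFF file written by [write_raster_dn()].
#' @return matrix (single band) or H x W x B array of integers.
#' @export
read_raster_dn <- function(path) {
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  if (length(pages) == 1) return(round(pages[[1]] * 65535))
  out <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) out[, , b] <- pages[[b]]
  round(out * 65535)
}

#' Assemble a time-series cube from a date manifest
#'
#' Reads one multiband raster per acquisition date and stacks them into a
#' [ts_cube] of digital numbers. All rasters must share a grid; a band at a
#' coarser resolution (integer factor of the finest grid) is resampled to
#' the finest grid.
#'
#' @param manifest list as returned by [read_manifest()].
#' @param band_selection character vector naming the bands to keep; band
#'   order in each file must follow the manifest's band list.
#' @param band_names names of the layers stored in each raster file.
#' @param resample `"bilinear"` (default) or `"nearest"` for coarser bands.
#' @return [ts_cube] of digital numbers (call [normalize_bands()] next).
#' @export
assemble_cube <- function(manifest, band_selection,
                          band_names = band_selection,
                          resample = c("bilinear", "nearest")) {
  resample <- match.arg(resample)
  missing_b <- setdiff(band_selection, band_names)
  if (length(missing_b))
    stop("requested bands absent from rasters: ",
         paste(missing_b, collapse = ", "))
  Tn <- length(manifest$dates)
  slices <- vector("list", Tn)
  ref_dim <- NULL
  for (t in seq_len(Tn)) {
    a <- read_raster_dn(manifest$paths[[t]])
    if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
    if (dim(a)[3] != length(band_names))
      stop("raster ", manifest$paths[[t]], " has ", dim(a)[3],
           " layers, expected ", length(band_names))
    if (is.null(ref_dim)) ref_dim <- dim(a)[1:2]
    if (!all(dim(a)[1:2] == ref_dim)) {
      if (any(ref_dim %% dim(a)[1:2] != 0))
        stop("grid mismatch beyond resampling for ", manifest$paths[[t]])
      a <- array(apply(a, 3, resample_grid, out_dim = ref_dim,
                       method = resample), c(ref_dim, dim(a)[3]))
    }
    slices[[t]] <- a[, , match(band_selection, band_names), drop = FALSE]
  }
  values <- array(NA_real_, c(ref_dim, Tn, length(band_selection)))
  for (t in seq_len(Tn)) values[, , t, ] <- slices[[t]]
  # nodata (DN 0 in every layer of a date) invalidates the pixel everywhere
  valid <- matrix(TRUE, ref_dim[1], ref_dim[2])
  for (t in seq_len(Tn))
    valid <- valid & apply(values[, , t, , drop = FALSE] > 0, c(1, 2), any)
  ts_cube(values, manifest$dates, band_selection, valid, manifest$grid)
}

# Bilinear / nearest-neighbour resampling of a single matrix to out_dim,
# pixel-center aligned.
resample_grid <- function(m, out_dim, method = "bilinear") {
  hi <- dim(m); ho <- out_dim
  # source pixel-center coordinates of each output pixel center
  ri <- (seq_len(ho[1]) - 0.5) * hi[1] / ho[1] + 0.5 - 0.5
  ci <- (seq_len(ho[2]) - 0.5) * hi[2] / ho[2] + 0.5 - 0.5
  if (method == "nearest") {
    r <- pmin(pmax(round(ri), 1), hi[1])
    cc <- pmin(pmax(round(ci), 1), hi[2])
    return(m[r, cc, drop = FALSE])
  }
  ri <- pmin(pmax(ri, 1), hi[1]); ci <- pmin(pmax(ci, 1), hi[2])
  z <- pracma::interp2(x = seq_len(hi[2]), y = seq_len(hi[1]), Z = m,
                       xp = rep(ci, each = ho[1]),
                       yp = rep(ri, times = ho[2]), method = "linear")
  matrix(z, nrow = ho[1], ncol = ho[2])
}

#' Normalize cube bands to reflectance
#'
#' `scale10000` divides stored digital numbers by 10,000 (the L2A surface
#' reflectance convention). `minmax_per_band` maps each band's valid values
#' to \[0, 1\] using the band-wide minimum/maximum pooled over all dates.
#' Nodata pixels are untouched.
#'
#' @param cube a [ts_cube].
#' @param method `"scale10000"` (default) or `"minmax_per_band"`.
#' @return normalized [ts_cube].
#' @export
normalize_bands <- function(cube, method = c("scale10000", "minmax_per_band")) {
  method <- match.arg(method)
  v <- cube$values
  if (method == "scale10000") {
    v <- v / 10000
  } else {
    mask <- cube$valid_mask
    for (b in seq_along(cube$band_names)) {
      band <- v[, , , b, drop = FALSE]
      sel <- rep(mask, times = dim(v)[3])
      rng <- range(band[sel], finite = TRUE)
      if (rng[2] == rng[1])
        stop("band '", cube$band_names[b],
             "' is constant; min-max normalization undefined")
      v[, , , b] <- (band - rng[1]) / (rng[2] - rng[1])
    }
  }
  out <- cube
  out$values <- v
  out
}

#' Write one date of a cube to a TIFF raster (digital numbers)
#'
#' Reflectance is quantized to DN = round(x * 10000); see [write_raster_dn()].
#' @param cube [ts_cube] of reflectance; `date_index` which date; `path`
#'   output file.
#' @export
write_cube_slice <- function(cube, date_index, path) {
  sl <- cube$values[, , date_index, , drop = TRUE]
  if (length(dim(sl)) == 2) sl <- array(sl, c(dim(sl), 1))
  write_raster_dn(round(sl * 10000), path)
}

#' Export a cube as per-date rasters plus a JSON manifest
#' @param cube [ts_cube] of reflectance; `dir` output directory.
#' @return manifest path.
#' @export
write_cube <- function(cube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("scene_%s.tif", format(cube$dates)))
  for (t in seq_along(cube$dates)) write_cube_slice(cube, t, paths[t])
  write_manifest(cube$dates, basename(paths), cube$grid,
                 file.path(dir, "manifest.json"))
  file.path(dir, "manifest.json")
}
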