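#' Time-series vector features
#'
#' Every parameter p (a spectral band or a vegetation index) observed at T
#' acquisition dates forms, per pixel, an ordered time-series vector
#' V_p = (p_1, ..., p_T). Five features summarise each vector: its maximum,
#' minimum and range, and the cosine of the angle and the distance between
#' V_p and an all-ones reference vector V_0 of the same length:
#'
#'   Cos_p = sum(V_0 V_p) / sqrt(sum(V_0^2) sum(V_p^2))
#'   Dis_p = sum((V_0 - V_p)^2)
#'
#' `Cos` defaults to the true cosine similarity (the radical in the
#' denominator); `cosine_form = "printed"` drops the square root, matching
#' the literal transcription some reports use. `Dis` defaults to the squared
#' Euclidean distance (a monotone transform, immaterial to tree-based
#' classifiers); `distance_form = "euclidean"` takes the root.
#'
#' @name vector_features_doc
NULL

FEATURE_KINDS <- c("Cos", "Dis", "Max", "Min", "Ran")

#' Extract the per-pixel time-series vector of one parameter
#'
#' @param series numeric vector, the parameter's values ordered by
#'   acquisition date ascending.
#' @return the series, validated (length >= 2, all finite); a series with
#'   any non-finite component is rejected so the pixel can be flagged
#'   invalid for this parameter.
#' @export
extract_vector <- function(series) {
  if (length(series) < 2)
    stop("a time series vector requires at least 2 dates")
  if (any(!is.finite(series)))
    stop("time series vector has non-finite components; pixel invalid")
  as.numeric(series)
}

#' Five vector features of one time-series vector
#'
#' @param v numeric time-series vector (length T >= 2, finite).
#' @param cosine_form `"normalized"` (true cosine, default) or `"printed"`
#'   (no radical in the denominator).
#' @param distance_form `"squared"` (default) or `"euclidean"`.
#' @return named numeric vector `c(Cos, Dis, Max, Min, Ran)`.
#' @export
vector_features <- function(v, cosine_form = c("normalized", "printed"),
                            distance_form = c("squared", "euclidean")) {
  cosine_form <- match.arg(cosine_form)
  distance_form <- match.arg(distance_form)
  v <- extract_vector(v)
  ss <- sum(v^2)
  if (ss == 0)
    stop("all-zero vector: cosine against the reference is undefined")
  Tn <- length(v)
  cos_p <- if (cosine_form == "normalized")
    sum(v) / sqrt(Tn * ss) else sum(v) / (Tn * ss)
  dis_p <- sum((1 - v)^2)
  if (distance_form == "euclidean") dis_p <- sqrt(dis_p)
  mx <- max(v); mn <- min(v)
  c(Cos = cos_p, Dis = dis_p, Max = mx, Min = mn, Ran = mx - mn)
}

# Vectorized feature computation on an n_pixel x T matrix of one
# parameter's series. Rows with any non-finite entry come back NA.
features_of_matrix <- function(M, cosine_form = "normalized",
                               distance_form = "squared") {
  Tn <- ncol(M)
  bad <- rowSums(!is.finite(M)) > 0
  M[bad, ] <- 0
  ss <- rowSums(M^2)
  s1 <- rowSums(M)
  cos_p <- if (cosine_form == "normalized")
    s1 / sqrt(Tn * ss) else s1 / (Tn * ss)
  cos_p[ss == 0] <- NA_real_
  dis_p <- rowSums((1 - M)^2)
  if (distance_form == "euclidean") dis_p <- sqrt(dis_p)
  mx <- do.call(pmax, as.data.frame(M))
  mn <- do.call(pmin, as.data.frame(M))
  out <- cbind(Cos = cos_p, Dis = dis_p, Max = mx, Min = mn, Ran = mx - mn)
  out[bad, ] <- NA_real_
  out
}

#' Build the per-pixel feature table
#'
#' Computes the five vector features of every band and every index and
#' binds them into one table. With the default 13-band set and the 23-index
#' registry this is the 180-column feature matrix. Column order is
#' deterministic: bands first (cube order), indices second (registry
#' order); within a parameter: Cos, Dis, Max, Min, Ran. Names follow the
#' `{parameter}_{feature}` scheme, e.g. `B12_Cos`, `NDVI705_Min`.
#'
#' @param band_cube [ts_cube] of band reflectance.
#' @param index_cube optional [ts_cube] of indices on the same grid/dates.
#' @param pixels optional data.frame with columns `row`, `col` restricting
#'   the table to those pixels; default all valid pixels.
#' @param cosine_form,distance_form see [vector_features()].
#' @return data.frame of features with attributes `pixels` (row/col of each
#'   table row) and `params`; rows with any undefined feature carry NA.
#' @export
build_feature_table <- function(band_cube, index_cube = NULL, pixels = NULL,
                                cosine_form = "normalized",
                                distance_form = "squared") {
  cubes <- list(band_cube)
  if (!is.null(index_cube)) {
    if (!identical(band_cube$dates, index_cube$dates))
      stop("band and index cubes disagree on acquisition dates")
    if (!all(dim(band_cube$values)[1:2] == dim(index_cube$values)[1:2]))
      stop("band and index cubes disagree on grid size")
    cubes <- c(cubes, list(index_cube))
  }
  d <- dim(band_cube$values)
  if (is.null(pixels)) {
    idx <- which(band_cube$valid_mask)
    pixels <- data.frame(row = ((idx - 1) %% d[1]) + 1,
                         col = ((idx - 1) %/% d[1]) + 1)
  }
  lin <- (pixels$col - 1) * d[1] + pixels$row
  blocks <- list()
  params <- character(0)
  for (cube in cubes) {
    dv <- dim(cube$values)
    npix <- dv[1] * dv[2]
    flat <- matrix(cube$values, nrow = npix)  # npix x (T*B), t fastest
    for (b in seq_len(dv[4])) {
      M <- flat[lin, (b - 1) * dv[3] + seq_len(dv[3]), drop = FALSE]
      F <- features_of_matrix(M, cosine_form, distance_form)
      colnames(F) <- paste(cube$band_names[b], FEATURE_KINDS, sep = "_")
      blocks[[length(blocks) + 1L]] <- F
      params <- c(params, cube$band_names[b])
    }
  }
  out <- as.data.frame(do.call(cbind, blocks))
  attr(out, "pixels") <- pixels
  attr(out, "params") <- params
  out
}

#' Attach class labels to a feature table at sample pixels
#'
#' @param features feature table from [build_feature_table()] built over
#'   `samples`' pixels, or over all pixels of the cube.
#' @param samples data.frame with `row`, `col`, `class` (factor) columns.
#' @return feature data.frame with a `class` column; rows containing NA
#'   features are dropped (they cannot enter training).
#' @export
label_features <- function(features, samples) {
  px <- attr(features, "pixels")
  key <- paste(px$row, px$col)
  skey <- paste(samples$row, samples$col)
  m <- match(skey, key)
  if (anyNA(m))
    stop(sum(is.na(m)), " sample pixel(s) missing from the feature table")
  out <- features[m, , drop = FALSE]
  out$class <- factor(samples$class)
  keep <- stats::complete.cases(out)
  out <- out[keep, , drop = FALSE]
  attr(out, "pixels") <- samples[keep, c("row", "col")]
  rownames(out) <- NULL
  out
}
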