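#' Vegetation index registry
#'
#' The default registry holds the 23 vegetation indices computable from
#' Sentinel-2-style bands that the classifier uses as temporal parameters
#' alongside the raw bands. Formulas follow the standard Sentinel-2 toolbox
#' conventions; every empirical constant (SAVI soil factor L, soil-line
#' slope/intercept, WDVI slope g, ARVI gamma) is exposed and overridable.
#'
#' Each definition is a list with `name`, `required_bands`, `constants`
#' (named scalars) and `formula`, a pure function `f(bands, constants)`
#' where `bands` is a named list of equally-shaped numeric arrays of
#' reflectance. All indices are unitless except S2REP (nanometres).
#'
#' @name index_registry
NULL

index_definition <- function(name, required_bands, formula,
                             constants = list()) {
  stopifnot(is.character(name), is.function(formula))
  if (length(constants) && any(!vapply(constants, is.finite, TRUE)))
    stop("constants must be finite")
  list(name = name, required_bands = required_bands,
       constants = constants, formula = formula)
}

#' Register the default 23 vegetation indices
#'
#' @param constants named list overriding default constants, e.g.
#'   `list(soil_slope = 1.2)`. Shared constants: `L` (SAVI, 0.5),
#'   `soil_slope` / `soil_intercept` (TSAVI, PVI, MSAVI, WDVI; 0.5 / 0.5),
#'   `X` (TSAVI adjustment, 0.08), `g` (WDVI slope, alias of soil_slope),
#'   `gamma` (ARVI, 1.0).
#' @return named list of 23 index definitions, in canonical order.
#' @export
register_default_indices <- function(constants = list()) {
  k <- utils::modifyList(
    list(L = 0.5, soil_slope = 0.5, soil_intercept = 0.5, X = 0.08,
         gamma = 1.0),
    constants)
  defs <- list(
    index_definition("SAVI", c("B8", "B4"), function(b, k)
      (1 + k$L) * (b$B8 - b$B4) / (b$B8 + b$B4 + k$L), k["L"]),
    index_definition("TSAVI", c("B8", "B4"), function(b, k) {
      s <- k$soil_slope; a <- k$soil_intercept
      s * (b$B8 - s * b$B4 - a) /
        (a * b$B8 + b$B4 - a * s + k$X * (1 + s^2))
    }, k[c("soil_slope", "soil_intercept", "X")]),
    index_definition("MSAVI", c("B8", "B4"), function(b, k) {
      s <- k$soil_slope
      ndvi <- (b$B8 - b$B4) / (b$B8 + b$B4)
      wdvi <- b$B8 - s * b$B4
      L <- 1 - 2 * s * ndvi * wdvi
      (1 + L) * (b$B8 - b$B4) / (b$B8 + b$B4 + L)
    }, k["soil_slope"]),
    index_definition("MSAVI2", c("B8", "B4"), function(b, k)
      0.5 * (2 * b$B8 + 1 - sqrt((2 * b$B8 + 1)^2 - 8 * (b$B8 - b$B4)))),
    index_definition("DVI", c("B8", "B4"), function(b, k) b$B8 - b$B4),
    index_definition("RVI", c("B8", "B4"), function(b, k) b$B8 / b$B4),
    index_definition("PVI", c("B8", "B4"), function(b, k) {
      s <- k$soil_slope
      (b$B8 - s * b$B4 - k$soil_intercept) / sqrt(1 + s^2)
    }, k[c("soil_slope", "soil_intercept")]),
    index_definition("IPVI", c("B8", "B4"), function(b, k)
      b$B8 / (b$B8 + b$B4)),
    index_definition("WDVI", c("B8", "B4"), function(b, k)
      b$B8 - k$soil_slope * b$B4, k["soil_slope"]),
    # radicand clamped at 0: NDVI < -0.5 (open water) would otherwise make
    # the index undefined over a whole class
    index_definition("TNDVI", c("B8", "B4"), function(b, k)
      sqrt(pmax((b$B8 - b$B4) / (b$B8 + b$B4) + 0.5, 0))),
    index_definition("GNDVI", c("B8", "B3"), function(b, k)
      (b$B8 - b$B3) / (b$B8 + b$B3)),
    index_definition("GEMI", c("B8", "B4"), function(b, k) {
      eta <- (2 * (b$B8^2 - b$B4^2) + 1.5 * b$B8 + 0.5 * b$B4) /
        (b$B8 + b$B4 + 0.5)
      eta * (1 - 0.25 * eta) - (b$B4 - 0.125) / (1 - b$B4)
    }),
    index_definition("ARVI", c("B8", "B4", "B2"), function(b, k) {
      rb <- b$B4 - k$gamma * (b$B2 - b$B4)
      (b$B8 - rb) / (b$B8 + rb)
    }, k["gamma"]),
    index_definition("NDI45", c("B5", "B4"), function(b, k)
      (b$B5 - b$B4) / (b$B5 + b$B4)),
    index_definition("MTCI", c("B6", "B5", "B4"), function(b, k)
      (b$B6 - b$B5) / (b$B5 - b$B4)),
    index_definition("MCARI", c("B5", "B4", "B3"), function(b, k)
      ((b$B5 - b$B4) - 0.2 * (b$B5 - b$B3)) * (b$B5 / b$B4)),
    index_definition("S2REP", c("B7", "B6", "B5", "B4"), function(b, k)
      705 + 35 * ((b$B4 + b$B7) / 2 - b$B5) / (b$B6 - b$B5)),
    index_definition("IRECI", c("B7", "B6", "B5", "B4"), function(b, k)
      (b$B7 - b$B4) / (b$B5 / b$B6)),
    index_definition("PSSR", c("B7", "B4"), function(b, k) b$B7 / b$B4),
    index_definition("NDVI", c("B8", "B4"), function(b, k)
      (b$B8 - b$B4) / (b$B8 + b$B4)),
    index_definition("NDVI705", c("B6", "B5"), function(b, k)
      (b$B6 - b$B5) / (b$B6 + b$B5)),
    index_definition("EVI", c("B8", "B4", "B2"), function(b, k)
      2.5 * (b$B8 - b$B4) / (b$B8 + 6 * b$B4 - 7.5 * b$B2 + 1)),
    index_definition("EVI2", c("B8", "B4"), function(b, k)
      2.5 * (b$B8 - b$B4) / (b$B8 + 2.4 * b$B4 + 1))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(names(defs))) stop("duplicate index name in registry")
  defs
}

# Historical / report-name aliases for registry lookup.
INDEX_ALIASES <- c(IECI = "IRECI", PSSRA = "PSSR", REIP = "S2REP",
                   NDVI_705 = "NDVI705")

#' Look up an index definition by name or alias
#' @param registry list from [register_default_indices()]; `name` canonical
#'   name or alias (IECI, PSSRA, REIP, NDVI_705).
#' @export
get_index <- function(registry, name) {
  if (name %in% names(INDEX_ALIASES)) name <- INDEX_ALIASES[[name]]
  if (!name %in% names(registry)) stop("unknown index: ", name)
  registry[[name]]
}

#' Evaluate a single index definition on named band values
#'
#' Pure evaluation; division by zero or a domain violation (e.g. a negative
#' TNDVI radicand) yields NaN at the affected entries.
#' @param def index definition; `bands` named list of numeric arrays of
#'   identical shape (scalars allowed).
#' @export
evaluate_index <- function(def, bands) {
  miss <- setdiff(def$required_bands, names(bands))
  if (length(miss))
    stop("index ", def$name, " requires missing band(s): ",
         paste(miss, collapse = ", "))
  out <- def$formula(bands, def$constants)
  out[!is.finite(out)] <- NaN
  out
}

#' Evaluate a registry of indices over a time-series cube
#'
#' Each index is evaluated independently per date and per pixel on the
#' cube's (normalized) reflectance. NaNs are recorded in a per-index count
#' attached as attribute `nan_counts`.
#'
#' @param cube [ts_cube] of band reflectance.
#' @param registry list of index definitions (default full registry).
#' @return [ts_cube] with `kind = "index"`, parameters = index names, plus
#'   attribute `nan_counts`.
#' @export
evaluate_indices <- function(cube, registry = register_default_indices()) {
  need <- unique(unlist(lapply(registry, `[[`, "required_bands")))
  miss <- setdiff(need, cube$band_names)
  if (length(miss)) {
    who <- names(registry)[vapply(registry, function(d)
      any(d$required_bands %in% miss), TRUE)]
    stop("cube lacks band(s) ", paste(miss, collapse = ", "),
         " required by index(es) ", paste(who, collapse = ", "))
  }
  d <- dim(cube$values)
  K <- length(registry)
  out <- array(NA_real_, c(d[1], d[2], d[3], K))
  nan_counts <- stats::setNames(integer(K), names(registry))
  for (t in seq_len(d[3])) {
    bands <- lapply(stats::setNames(seq_len(d[4]), cube$band_names),
                    function(b) cube$values[, , t, b])
    for (ki in seq_len(K)) {
      v <- evaluate_index(registry[[ki]], bands)
      nan_counts[ki] <- nan_counts[ki] + sum(is.nan(v) & cube$valid_mask)
      out[, , t, ki] <- v
    }
  }
  res <- ts_cube(out, cube$dates, names(registry), cube$valid_mask,
                 cube$grid, kind = "index")
  attr(res, "nan_counts") <- nan_counts
  res
}
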