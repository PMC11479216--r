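#' Extract raster values at point locations
#'
#' Samples the cell containing each point (nearest-cell lookup, no
#' interpolation). Cell footprints are half-open, `[x, x + px) x
#' (y - px, y]`, so a point on a shared edge resolves to the right/lower
#' cell. Points falling on nodata cells are kept in the output but flagged;
#' points outside the raster extent are an error listing the offending rows.
#'
#' @param layer a [grid_layer()].
#' @param points data frame with columns `x`, `y` (other columns are carried
#'   through).
#' @return the input tibble with added columns `value` and `nodata`.
#' @export
extract_values_at_points <- function(layer, points) {
  points <- tibble::as_tibble(points)
  idx <- cell_index(layer, points$x, points$y)
  outside <- is.na(idx[, "row"])
  if (any(outside)) {
    abort_fmt(
      "%d point(s) outside the raster extent (first: x = %g, y = %g)",
      sum(outside), points$x[which(outside)[1]], points$y[which(outside)[1]]
    )
  }
  vals <- layer$values[idx]
  dplyr::mutate(points, value = vals, nodata = is.na(vals))
}

#' Derive a backscatter threshold interval from ground-truth samples
#'
#' Takes the dB values observed at ground-truth coffee locations and returns
#' the interval used to threshold the scene. By default (`trim_fraction =
#' 0`) the interval is the exact sample minimum and maximum; a positive trim
#' uses the corresponding lower/upper order statistics (inverse-ECDF
#' quantiles), discarding possible outliers symmetrically.
#'
#' @param values numeric dB values (NAs dropped).
#' @param trim_fraction fraction in `[0, 0.5)` trimmed from each tail.
#' @return an object of class `threshold_interval`: list with `low_db`,
#'   `high_db`, `n_points`.
#' @export
#' @examples
#' derive_threshold(c(-18, -15, -12.5))
derive_threshold <- function(values, trim_fraction = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 1) abort_fmt("derive_threshold: no finite values")
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort_fmt("trim_fraction must be in [0, 0.5)")
  }
  if (trim_fraction == 0) {
    lo <- min(values); hi <- max(values)
  } else {
    lo <- unname(stats::quantile(values, trim_fraction, type = 1))
    hi <- unname(stats::quantile(values, 1 - trim_fraction, type = 1))
  }
  structure(list(low_db = lo, high_db = hi, n_points = length(values)),
            class = "threshold_interval")
}

#' @export
print.threshold_interval <- function(x, ...) {
  cat(sprintf("<threshold_interval> [%.6f, %.6f] dB from %d points\n",
              x$low_db, x$high_db, x$n_points))
  invisible(x)
}

#' Threshold a backscatter scene into a coffee mask
#'
#' Marks cells whose dB value lies inside the closed interval
#' `[low_db, high_db]` as coffee (1), others 0; nodata is preserved. The
#' mapped area follows from the pixel size.
#'
#' @param layer dB [grid_layer()].
#' @param interval a [derive_threshold()] result, or numeric `c(low, high)`.
#' @return an object of class `coffee_mask`: list with `mask` (0/1
#'   `grid_layer`), `area_km2`, `interval`. Supports `tidy()` and
#'   `autoplot()`.
#' @export
threshold_mask <- function(layer, interval) {
  if (is.numeric(interval) && length(interval) == 2) {
    interval <- structure(list(low_db = interval[1], high_db = interval[2],
                               n_points = NA_integer_),
                          class = "threshold_interval")
  }
  stopifnot(inherits(interval, "threshold_interval"),
            interval$low_db <= interval$high_db)
  v <- layer$values
  m <- ifelse(is.na(v), NA_real_,
              as.numeric(v >= interval$low_db & v <= interval$high_db))
  mask <- grid_layer(m, layer$pixel_size, layer$origin, units = "mask",
                     crs = layer$crs)
  area <- sum(m == 1, na.rm = TRUE) * layer$pixel_size^2 / 1e6
  structure(list(mask = mask, area_km2 = area, interval = interval),
            class = "coffee_mask")
}

#' @export
print.coffee_mask <- function(x, ...) {
  cat(sprintf("<coffee_mask> %.4f km2 inside [%.3f, %.3f] dB\n",
              x$area_km2, x$interval$low_db, x$interval$high_db))
  invisible(x)
}

#' @rdname threshold_mask
#' @param x a `coffee_mask`.
#' @param ... unused.
#' @method tidy coffee_mask
#' @export
tidy.coffee_mask <- function(x, ...) {
  tibble::tibble(
    low_db = x$interval$low_db, high_db = x$interval$high_db,
    n_points = x$interval$n_points, area_km2 = x$area_km2
  )
}

#' @rdname threshold_mask
#' @param object a `coffee_mask`.
#' @method autoplot coffee_mask
#' @export
autoplot.coffee_mask <- function(object, ...) {
  autoplot(object$mask) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "coffee")
}

#' Jaccard index of two binary masks
#'
#' Intersection over union of the `1` cells of two co-registered 0/1 layers;
#' used to quantify recovery of a known planting stencil.
#'
#' @param a,b 0/1 [grid_layer()] objects (NAs ignored).
#' @return scalar in `[0, 1]` (1 when both masks are empty).
#' @export
jaccard_index <- function(a, b) {
  check_coregistered(a, b, "jaccard mask")
  av <- a$values == 1 & !is.na(a$values)
  bv <- b$values == 1 & !is.na(b$values)
  un <- sum(av | bv)
  if (un == 0) return(1)
  sum(av & bv) / un
}
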