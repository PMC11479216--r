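#' Inverse-distance-weighted interpolation of station data
#'
#' Interpolates a station variable onto a target grid with IDW:
#' \eqn{z(c) = \sum_s v_s d_{cs}^{-p} / \sum_s d_{cs}^{-p}} over all
#' stations. A cell whose centre coincides with a station (distance below
#' `eps`) takes that station's value exactly, so the surface is an exact
#' interpolator; every output lies within the range of the station values.
#'
#' @param stations data frame with planar coordinate columns `x`, `y` (in
#'   the grid's frame; project geographic coordinates first) and the value
#'   column named by `value`.
#' @param value name of the station column to interpolate.
#' @param grid a [grid_layer()] defining the target geometry (its values are
#'   ignored; its `NA` pattern is preserved).
#' @param power IDW exponent p > 0 (default 2). Larger powers converge to
#'   nearest-neighbour assignment.
#' @param eps snap distance (m) below which a cell is treated as on-station.
#' @param units units tag of the result.
#' @return a `grid_layer` of interpolated values.
#' @export
#' @examples
#' g <- grid_layer(matrix(0, 8, 8), pixel_size = 10)
#' st <- tibble::tibble(x = c(15, 65), y = c(15, 65), t = c(10, 20))
#' idw_interpolate(st, "t", g)
idw_interpolate <- function(stations, value, grid, power = 2, eps = 1e-9,
                            units = "") {
  stations <- tibble::as_tibble(stations)
  if (nrow(stations) == 0) abort_fmt("idw_interpolate: empty station list")
  stopifnot(power > 0, all(c("x", "y", value) %in% names(stations)))
  v <- stations[[value]]
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  X <- matrix(rep(cc$x, each = nr), nr, nc)
  Y <- matrix(rep(cc$y, times = nc), nr, nc)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  snap <- matrix(NA_real_, nr, nc)
  for (s in seq_len(nrow(stations))) {
    d <- sqrt((X - stations$x[s])^2 + (Y - stations$y[s])^2)
    on_station <- d < eps
    snap[on_station] <- v[s]
    w <- d^(-power)
    w[on_station] <- 0
    num <- num + w * v[s]
    den <- den + w
  }
  out <- num / den
  out[!is.na(snap)] <- snap[!is.na(snap)]
  out[is.na(grid$values)] <- NA
  grid_layer(out, grid$pixel_size, grid$origin, units = units, crs = grid$crs)
}

#' Cellwise mean of two co-registered temperature layers
#'
#' Average annual temperature derived as the arithmetic mean of the annual
#' mean minimum and maximum temperature surfaces. Nodata in either input
#' propagates.
#'
#' @param min_layer,max_layer co-registered [grid_layer()] objects.
#' @return a `grid_layer`.
#' @export
mean_temperature <- function(min_layer, max_layer) {
  grid_map(min_layer, max_layer, f = function(a, b) (a + b) / 2,
           units = min_layer$units)
}

# internal: Horn 3x3 gradient with replicated borders.
# Returns list(gx = dz/dx eastward, gy = dz/dy northward), per metre.
horn_gradient <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  px <- dem$pixel_size
  # replicate-pad one cell on each side
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) zp[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  a <- sh(-1, -1); b <- sh(-1, 0); c_ <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1); h <- sh(1, 0);  i <- sh(1, 1)
  gx <- ((c_ + 2 * f + i) - (a + 2 * d + g)) / (8 * px)
  gy <- ((a + 2 * b + c_) - (g + 2 * h + i)) / (8 * px)  # row 1 is north
  list(gx = gx, gy = gy)
}

#' Terrain slope in percent from a DEM
#'
#' Horn 3x3 finite-difference gradient on a square grid with replicated
#' borders; slope = 100 * sqrt(gx^2 + gy^2).
#'
#' @param dem elevation [grid_layer()] in metres.
#' @return slope `grid_layer` in percent.
#' @export
slope_percent <- function(dem) {
  gr <- horn_gradient(dem)
  out <- 100 * sqrt(gr$gx^2 + gr$gy^2)
  out[is.na(dem$values)] <- NA
  grid_layer(out, dem$pixel_size, dem$origin, units = "%", crs = dem$crs)
}

#' Terrain aspect from a DEM
#'
#' Direction of steepest *descent* (the downhill-facing direction), in
#' degrees clockwise from north, from the Horn 3x3 gradient. Cells whose
#' gradient magnitude is below `flat_tol` are flagged `-1` (flat, undefined
#' aspect).
#'
#' @param dem elevation [grid_layer()] in metres.
#' @param flat_tol gradient magnitude below which a cell is flat.
#' @return aspect `grid_layer` in degrees, flat cells `-1`.
#' @export
aspect_degrees <- function(dem, flat_tol = 1e-12) {
  gr <- horn_gradient(dem)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  # steepest descent direction = -(gx, gy); azimuth measured from north, CW
  az <- (atan2(-gr$gx, -gr$gy) * 180 / pi) %% 360
  az[mag < flat_tol] <- -1
  az[is.na(dem$values)] <- NA
  grid_layer(az, dem$pixel_size, dem$origin, units = "degrees", crs = dem$crs)
}

#' Euclidean distance from each cell to the nearest feature
#'
#' Exact point-to-segment distance from every cell centre to a set of
#' polyline or point features; cells touching a feature get distance 0.
#'
#' @param grid a [grid_layer()] defining the target geometry.
#' @param features data frame of feature vertices with columns `feature_id`,
#'   `x`, `y`; consecutive vertices within a `feature_id` form segments, a
#'   single-vertex feature is a point. (The tidy form returned by
#'   [read_features_geojson()].)
#' @return distance `grid_layer` in metres.
#' @export
euclidean_distance <- function(grid, features) {
  features <- tibble::as_tibble(features)
  if (nrow(features) == 0) abort_fmt("euclidean_distance: empty feature set")
  if (!"feature_id" %in% names(features)) features$feature_id <- 1L
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  X <- matrix(rep(cc$x, each = nr), nr, nc)
  Y <- matrix(rep(cc$y, times = nc), nr, nc)
  dmin <- matrix(Inf, nr, nc)
  for (fid in unique(features$feature_id)) {
    pts <- features[features$feature_id == fid, ]
    n <- nrow(pts)
    if (n == 1) {
      d <- sqrt((X - pts$x)^2 + (Y - pts$y)^2)
      dmin <- pmin(dmin, d)
    } else {
      for (k in seq_len(n - 1)) {
        dmin <- pmin(dmin, dist_to_segment(X, Y, pts$x[k], pts$y[k],
                                           pts$x[k + 1], pts$y[k + 1]))
      }
    }
  }
  dmin[is.na(grid$values)] <- NA
  grid_layer(dmin, grid$pixel_size, grid$origin, units = "m", crs = grid$crs)
}

# internal: distance from points (X, Y) to segment (x1,y1)-(x2,y2)
dist_to_segment <- function(X, Y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    return(sqrt((X - x1)^2 + (Y - y1)^2))
  }
  t <- pmin(1, pmax(0, ((X - x1) * dx + (Y - y1) * dy) / len2))
  sqrt((X - (x1 + t * dx))^2 + (Y - (y1 + t * dy))^2)
}
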