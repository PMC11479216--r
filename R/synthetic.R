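#' Configuration for the synthetic landscape generator
#'
#' Defines the statistical structure of a generated highland landscape:
#' layer value ranges matching the Gedeo study region (elevation 1329-3088 m,
#' rainfall 1093.02-1667 mm, SOM 0-6 %, CEC 0-43 cmol+/kg, pH 4-7.5),
#' land-cover class proportions from the 2021 reference mapping (farmland
#' 41.34 %, agroforestry 44.54 %, forest 7.33 %, grassland 0.72 %,
#' settlement 4.85 %, wetland 1.22 %), a coffee backscatter interval of
#' [-19.034781, -10.773612] dB disjoint from the background interval, and an
#' elevation-temperature coupling through a lapse rate.
#'
#' @param shape grid dimensions `c(rows, cols)`.
#' @param pixel_size cell size in metres.
#' @param seed integer seed; a fixed seed makes the landscape byte-identical.
#' @param elevation_range,rainfall_range,som_range,cec_range,ph_range value
#'   ranges the smoothed fields are rescaled to (endpoints attained).
#' @param lulc_props named land-cover proportions summing to 1 (+- 1e-6).
#' @param texture_props named soil-texture proportions summing to 1; the
#'   defaults follow the study area's clay/loam/sandy-loam area shares.
#' @param coffee_db,background_db dB intervals for coffee patches and
#'   background; must be disjoint.
#' @param db_noise_sd sd of truncated (+-2 sd) Gaussian dB noise. Patch and
#'   background values are drawn with a 2-sd interior margin so noise never
#'   moves a cell across the threshold.
#' @param coffee_fraction fraction of agroforestry cells planted with coffee.
#' @param n_stations number of synthetic meteorological stations.
#' @param lapse_rate temperature decrease per metre of elevation (deg C/m).
#' @param temp_noise_sd sd of the smoothed temperature noise (deg C).
#' @param n_points number of ground-truth coffee points.
#' @param n_roads,n_rivers number of random polyline features.
#' @param smoothness Gaussian blur sd, in cells, of the random fields.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(shape = c(128, 128), pixel_size = 10, seed = 1,
                             elevation_range = c(1329, 3088),
                             rainfall_range = c(1093.02, 1667),
                             som_range = c(0, 6), cec_range = c(0, 43),
                             ph_range = c(4, 7.5),
                             lulc_props = c(farmland = 0.4134,
                                            agroforestry = 0.4454,
                                            forest = 0.0733,
                                            grassland = 0.0072,
                                            settlement = 0.0485,
                                            wetland = 0.0122),
                             texture_props = c(L = 0.2823, SL = 0.6647,
                                               C = 0.053),
                             coffee_db = c(-19.034781, -10.773612),
                             background_db = c(-26, -21),
                             db_noise_sd = 0, coffee_fraction = 0.5,
                             n_stations = 6, lapse_rate = 0.0065,
                             temp_noise_sd = 0.2, n_points = 50,
                             n_roads = 2, n_rivers = 2, smoothness = 8) {
  if (abs(sum(lulc_props) - 1) > 1e-6) {
    abort_fmt("lulc_props must sum to 1 (got %.8f)", sum(lulc_props))
  }
  if (abs(sum(texture_props) - 1) > 1e-6) {
    abort_fmt("texture_props must sum to 1 (got %.8f)", sum(texture_props))
  }
  if (background_db[2] >= coffee_db[1] && background_db[1] <= coffee_db[2]) {
    abort_fmt("background dB interval must be disjoint from the coffee interval")
  }
  cfg <- list(
    shape = as.integer(shape), pixel_size = pixel_size, seed = as.integer(seed),
    elevation_range = elevation_range, rainfall_range = rainfall_range,
    som_range = som_range, cec_range = cec_range, ph_range = ph_range,
    lulc_props = lulc_props, texture_props = texture_props,
    coffee_db = coffee_db, background_db = background_db,
    db_noise_sd = db_noise_sd, coffee_fraction = coffee_fraction,
    n_stations = n_stations, lapse_rate = lapse_rate,
    temp_noise_sd = temp_noise_sd, n_points = n_points,
    n_roads = n_roads, n_rivers = n_rivers, smoothness = smoothness
  )
  structure(cfg, class = "landscape_config")
}

# internal: Gaussian-blurred white noise, replicate-padded, in [0, 1]
smooth_field <- function(nr, nc, smoothness) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (smoothness > 0) {
    half <- ceiling(3 * smoothness)
    k <- stats::dnorm(seq(-half, half), sd = smoothness)
    k <- k / sum(k)
    z <- blur_1d(z, k)        # along rows (within columns)
    z <- t(blur_1d(t(z), k))  # along columns (within rows)
  }
  (z - min(z)) / (max(z) - min(z))
}

# internal: convolve each column of M with kernel k, replicated borders
blur_1d <- function(M, k) {
  half <- (length(k) - 1) / 2
  n <- nrow(M)
  Mp <- M[c(rep(1, half), seq_len(n), rep(n, half)), , drop = FALSE]
  out <- apply(Mp, 2, function(col) {
    as.numeric(stats::filter(col, k, sides = 2))[(half + 1):(half + n)]
  })
  matrix(out, nrow = n)
}

rescale_to <- function(x, lo, hi) {
  r <- range(x)
  if (r[1] == r[2]) return(x * 0 + (lo + hi) / 2)
  (x - r[1]) / (r[2] - r[1]) * (hi - lo) + lo
}

# internal: categorical field hitting target proportions by rank assignment
# on a smoothed field (spatially coherent classes, proportions exact up to
# integer rounding)
categorical_field <- function(nr, nc, props, smoothness) {
  f <- smooth_field(nr, nc, smoothness)
  n <- nr * nc
  cuts <- round(cumsum(props) * n)
  cuts[length(cuts)] <- n
  codes <- integer(n)
  ord <- order(f)
  lo <- 1
  for (i in seq_along(props)) {
    if (cuts[i] >= lo) codes[ord[lo:cuts[i]]] <- i
    lo <- cuts[i] + 1
  }
  matrix(codes, nr, nc)
}

# internal: random edge-to-edge polyline in grid coordinates
random_polyline <- function(extent_x, extent_y, n_waypoints = 3) {
  side <- sample(1:4, 2)
  pick <- function(s) {
    switch(s,
      c(stats::runif(1, 0, extent_x), extent_y),   # north
      c(extent_x, stats::runif(1, 0, extent_y)),   # east
      c(stats::runif(1, 0, extent_x), 0),          # south
      c(0, stats::runif(1, 0, extent_y))           # west
    )
  }
  p0 <- pick(side[1]); p1 <- pick(side[2])
  t <- seq(0, 1, length.out = n_waypoints + 2)
  x <- p0[1] + t * (p1[1] - p0[1])
  y <- p0[2] + t * (p1[2] - p0[2])
  jit <- 0.1 * min(extent_x, extent_y)
  mid <- seq(2, n_waypoints + 1)
  x[mid] <- pmin(extent_x, pmax(0, x[mid] + stats::runif(n_waypoints, -jit, jit)))
  y[mid] <- pmin(extent_y, pmax(0, y[mid] + stats::runif(n_waypoints, -jit, jit)))
  tibble::tibble(x = x, y = y)
}

# internal: truncated (+-2 sd) centred Gaussian noise
truncated_noise <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

#' Generate a seeded synthetic landscape
#'
#' Produces a fully self-contained layer stack with the statistical
#' structure the suitability analysis assumes: a smoothed random-field DEM
#' rescaled to the configured elevation range; minimum/maximum temperature
#' surfaces coupled to the DEM through the lapse rate (plus smooth noise);
#' independent smoothed rainfall, pH, SOM and CEC fields; spatially coherent
#' categorical land-cover and soil-texture fields hitting the target
#' proportions; random road and river polylines; a SAR backscatter scene
#' whose coffee patches (grown inside agroforestry) carry dB values in the
#' coffee interval while the background stays outside it; ground-truth
#' points sampled inside the patches; and stations placed on grid cells with
#' the exact local temperatures (so interpolation tests have ground truth).
#'
#' @param config a [landscape_config()].
#' @return an object of class `landscape`: list with `layers` (named
#'   [grid_layer()] stack: `elevation`, `rainfall`, `min_temp`, `max_temp`,
#'   `ph`, `som`, `cec`, `texture`, `lulc`, `sar`), `features` (road/river
#'   vertices), `stations`, `coffee_points`, `patch_mask` (0/1 stencil) and
#'   `config`.
#' @export
#' @examples
#' ls <- generate_landscape(landscape_config(shape = c(32, 32), seed = 7))
#' range(ls$layers$elevation$values)
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  withr::with_seed(config$seed, generate_landscape_impl(config))
}

generate_landscape_impl <- function(cfg) {
  nr <- cfg$shape[1]; nc <- cfg$shape[2]; px <- cfg$pixel_size
  origin <- c(0, nr * px)
  gl <- function(values, units) grid_layer(values, px, origin, units = units)

  dem_v <- rescale_to(smooth_field(nr, nc, cfg$smoothness),
                      cfg$elevation_range[1], cfg$elevation_range[2])
  elevation <- gl(dem_v, "m")

  # temperatures: affine in elevation via the lapse rate, plus smooth noise.
  # Intercepts place the surfaces in the observed highland range
  # (~13 deg C min / ~29 deg C max at the low end of the elevation range).
  tnoise <- function() {
    if (cfg$temp_noise_sd > 0) {
      rescale_to(smooth_field(nr, nc, cfg$smoothness / 2), -1, 1) * cfg$temp_noise_sd
    } else {
      matrix(0, nr, nc)
    }
  }
  min_temp <- gl(22.5 - cfg$lapse_rate * dem_v + tnoise(), "degC")
  max_temp <- gl(37.8 - cfg$lapse_rate * dem_v + tnoise(), "degC")

  rainfall <- gl(rescale_to(smooth_field(nr, nc, cfg$smoothness),
                            cfg$rainfall_range[1], cfg$rainfall_range[2]), "mm")
  ph <- gl(rescale_to(smooth_field(nr, nc, cfg$smoothness),
                      cfg$ph_range[1], cfg$ph_range[2]), "pH")
  som <- gl(rescale_to(smooth_field(nr, nc, cfg$smoothness),
                       cfg$som_range[1], cfg$som_range[2]), "%")
  cec <- gl(rescale_to(smooth_field(nr, nc, cfg$smoothness),
                       cfg$cec_range[1], cfg$cec_range[2]), "cmol+/kg")

  lulc_codes <- categorical_field(nr, nc, cfg$lulc_props, cfg$smoothness)
  lulc <- gl(lulc_codes, "category")
  attr(lulc, "legend") <- tibble::tibble(code = seq_along(cfg$lulc_props),
                                         category = names(cfg$lulc_props))
  tex_codes <- categorical_field(nr, nc, cfg$texture_props, cfg$smoothness)
  texture <- gl(tex_codes, "category")
  attr(texture, "legend") <- tibble::tibble(code = seq_along(cfg$texture_props),
                                            category = names(cfg$texture_props))

  # coffee patches: the top coffee_fraction of an independent smooth field,
  # restricted to agroforestry cells -> coherent patches inside agroforestry
  agro_code <- which(names(cfg$lulc_props) == "agroforestry")
  agro <- lulc_codes == agro_code
  pf <- smooth_field(nr, nc, cfg$smoothness / 2)
  patch <- matrix(FALSE, nr, nc)
  if (any(agro) && cfg$coffee_fraction > 0) {
    thr <- stats::quantile(pf[agro], 1 - cfg$coffee_fraction, type = 1)
    patch <- agro & pf >= thr
  }
  patch_mask <- gl(patch + 0, "mask")

  margin <- 2 * cfg$db_noise_sd
  sar_v <- matrix(stats::runif(nr * nc, cfg$background_db[1] + margin,
                               cfg$background_db[2] - margin), nr, nc)
  n_patch <- sum(patch)
  if (n_patch > 0) {
    sar_v[patch] <- stats::runif(n_patch, cfg$coffee_db[1] + margin,
                                 cfg$coffee_db[2] - margin)
  }
  sar_v <- sar_v + matrix(truncated_noise(nr * nc, cfg$db_noise_sd), nr, nc)
  sar <- gl(sar_v, "dB")

  extent_x <- nc * px; extent_y <- nr * px
  mk_features <- function(n, kind, id0) {
    purrr::map(seq_len(n), function(i) {
      dplyr::mutate(random_polyline(extent_x, extent_y),
                    feature_id = id0 + i, kind = kind)
    }) |> purrr::list_rbind()
  }
  features <- dplyr::bind_rows(mk_features(cfg$n_roads, "road", 0L),
                               mk_features(cfg$n_rivers, "river", cfg$n_roads))

  cc <- cell_centers(elevation)
  st_cells <- sample(nr * nc, cfg$n_stations)
  st_row <- (st_cells - 1) %% nr + 1
  st_col <- (st_cells - 1) %/% nr + 1
  stations <- tibble::tibble(
    station = paste0("S", seq_len(cfg$n_stations)),
    x = cc$x[st_col], y = cc$y[st_row],
    elevation = dem_v[cbind(st_row, st_col)],
    min_temp = min_temp$values[cbind(st_row, st_col)],
    max_temp = max_temp$values[cbind(st_row, st_col)]
  )

  coffee_points <- tibble::tibble(x = numeric(0), y = numeric(0),
                                  label = character(0))
  if (n_patch > 0) {
    # the sample always includes the patch cells with the lowest and highest
    # backscatter, so the derived min/max threshold spans the whole planting
    idx <- which(patch)
    extremes <- c(idx[which.min(sar_v[idx])], idx[which.max(sar_v[idx])])
    pk <- unique(c(extremes, sample(idx, min(cfg$n_points, n_patch))))
    pk <- pk[seq_len(min(length(pk), max(cfg$n_points, 2)))]
    pr <- (pk - 1) %% nr + 1
    pc <- (pk - 1) %/% nr + 1
    coffee_points <- tibble::tibble(x = cc$x[pc], y = cc$y[pr],
                                    label = "coffee")
  }

  structure(
    list(
      layers = list(elevation = elevation, rainfall = rainfall,
                    min_temp = min_temp, max_temp = max_temp, ph = ph,
                    som = som, cec = cec, texture = texture, lulc = lulc,
                    sar = sar),
      features = features, stations = stations,
      coffee_points = coffee_points, patch_mask = patch_mask, config = cfg
    ),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d @ %g m, seed %d | %d layers, %d stations, %d coffee points\n",
              x$config$shape[1], x$config$shape[2], x$config$pixel_size,
              x$config$seed, length(x$layers), nrow(x$stations),
              nrow(x$coffee_points)))
  invisible(x)
}
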