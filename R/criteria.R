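#' Declarative suitability-scoring rule for one criterion
#'
#' A criterion spec maps raw layer values to ordinal suitability scores
#' (3 = suitable, 2 = sub-suitable, 1 = unsuitable). Continuous criteria use
#' non-overlapping lower-closed, upper-open intervals `[min, max)`;
#' categorical criteria map category names to scores via an integer-coded
#' legend on the layer.
#'
#' @param name criterion name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param rules for continuous: a data frame with columns `min`, `max`,
#'   `score` (use `-Inf`/`Inf` for open ends); for categorical: a data frame
#'   with columns `category`, `score`.
#' @param default_score score for values matching no rule; `NA` (default)
#'   makes unmatched values an error, naming the value.
#' @param weight optional composite criterion weight (from
#'   [compose_weights()]).
#' @param units expected units of the input layer (informational).
#' @return an object of class `criterion_spec`.
#' @export
criterion_spec <- function(name, kind = c("continuous", "categorical"),
                           rules, default_score = NA, weight = NA_real_,
                           units = "") {
  kind <- match.arg(kind)
  rules <- tibble::as_tibble(rules)
  if (!all(rules$score %in% c(1, 2, 3))) {
    abort_fmt("criterion '%s': rule scores must be in {1, 2, 3}", name)
  }
  if (kind == "continuous") {
    stopifnot(all(c("min", "max") %in% names(rules)))
    if (any(rules$min >= rules$max)) {
      abort_fmt("criterion '%s': empty interval (min >= max)", name)
    }
    o <- order(rules$min)
    if (any(rules$max[o][-nrow(rules)] > rules$min[o][-1] + 1e-12)) {
      abort_fmt("criterion '%s': overlapping intervals", name)
    }
  } else {
    stopifnot("category" %in% names(rules))
    if (anyDuplicated(rules$category)) {
      abort_fmt("criterion '%s': category listed twice", name)
    }
  }
  structure(list(name = name, kind = kind, rules = rules,
                 default_score = default_score, weight = weight,
                 units = units),
            class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat(sprintf("<criterion_spec> %s (%s%s)\n", x$name, x$kind,
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  print(x$rules)
  invisible(x)
}

#' Reclassify a layer into suitability scores
#'
#' Applies a [criterion_spec()] to a [grid_layer()], producing a score layer
#' whose valid cells are in `{1, 2, 3}`. Nodata cells are preserved. Values
#' matching no rule use the rule set's `default_score`, or raise an error naming
#' the value when no default is set (unknown categories always fail loudly
#' unless a default is given).
#'
#' @param layer a [grid_layer()]. For categorical criteria the layer must
#'   carry a `legend` attribute: a data frame with columns `code`,
#'   `category`.
#' @param spec a [criterion_spec()].
#' @return a score `grid_layer` (units `"score"`).
#' @export
#' @examples
#' rules <- data.frame(min = c(1600, 1100, 1800, -Inf, 2000),
#'                     max = c(1800, 1600, 2000, 1100, Inf),
#'                     score = c(3, 2, 2, 1, 1))
#' spec <- criterion_spec("rainfall", "continuous", rules, units = "mm")
#' g <- grid_layer(matrix(c(1650, 1200, 900, NA), 2, 2), 10)
#' reclassify(g, spec)$values
reclassify <- function(layer, spec) {
  stopifnot(inherits(layer, "grid_layer"), inherits(spec, "criterion_spec"))
  if (spec$kind == "continuous") {
    reclassify_continuous(layer, spec)
  } else {
    reclassify_categorical(layer, spec)
  }
}

#' @rdname reclassify
#' @export
reclassify_continuous <- function(layer, spec) {
  v <- layer$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  matched <- is.na(v)  # nodata counts as handled
  for (k in seq_len(nrow(spec$rules))) {
    r <- spec$rules[k, ]
    hit <- !is.na(v) & v >= r$min & v < r$max
    out[hit] <- r$score
    matched <- matched | hit
  }
  if (!all(matched)) {
    if (is.na(spec$default_score)) {
      bad <- v[!matched][1]
      abort_fmt("criterion '%s': value %g matches no rule and no default score is set",
                spec$name, bad)
    }
    out[!matched] <- spec$default_score
  }
  grid_layer(out, layer$pixel_size, layer$origin, units = "score", crs = layer$crs)
}

#' @rdname reclassify
#' @export
reclassify_categorical <- function(layer, spec) {
  legend <- attr(layer, "legend")
  if (is.null(legend)) {
    abort_fmt("criterion '%s': categorical layer lacks a legend attribute", spec$name)
  }
  legend <- tibble::as_tibble(legend)
  lut <- stats::setNames(spec$rules$score, spec$rules$category)
  v <- layer$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  valid <- !is.na(v)
  codes <- sort(unique(v[valid]))
  for (code in codes) {
    cat_name <- legend$category[legend$code == code]
    if (length(cat_name) != 1) {
      abort_fmt("criterion '%s': layer code %g missing from legend", spec$name, code)
    }
    sc <- if (cat_name %in% names(lut)) lut[[cat_name]] else NA_real_
    if (is.na(sc)) {
      if (is.na(spec$default_score)) {
        abort_fmt("criterion '%s': category '%s' has no scoring rule and no default",
                  spec$name, cat_name)
      }
      sc <- spec$default_score
    }
    out[valid & v == code] <- sc
  }
  grid_layer(out, layer$pixel_size, layer$origin, units = "score", crs = layer$crs)
}

#' Published suitability thresholds for the 14 coffee criteria
#'
#' The shipped rule set scoring each thematic layer 3 (suitable),
#' 2 (sub-suitable) or 1 (unsuitable) for Arabica coffee: rainfall (mm),
#' average/min/max annual temperature (deg C), soil pH, SOM (%), CEC
#' (cmol+/kg), soil texture class, elevation (m), slope (%), aspect
#' (scored via [aspect_to_score()]), LULC, and distance to road/river
#' (expressed in metres here; the published thresholds are 0-2/2-5/>5 km for
#' roads and 0-1/1-5/>5 km for rivers). Continuous intervals are
#' lower-closed, upper-open, so a boundary value shared between two classes
#' takes the class whose interval starts there.
#'
#' @param weights optional weight table from [compose_weights()]; when given,
#'   composite weights are attached to the matching specs.
#' @return named list of 14 [criterion_spec()] objects.
#' @export
coffee_criteria <- function(weights = NULL) {
  cont <- function(name, units, suit, sub, unsuit) {
    mk <- function(iv, score) {
      if (is.null(iv)) return(NULL)
      tibble::tibble(min = vapply(iv, `[`, 1, 1),
                     max = vapply(iv, `[`, 1, 2), score = score)
    }
    rules <- dplyr::bind_rows(mk(suit, 3), mk(sub, 2), mk(unsuit, 1))
    criterion_spec(name, "continuous", rules, units = units)
  }
  catg <- function(name, suit, sub, unsuit) {
    rules <- tibble::tibble(
      category = c(suit, sub, unsuit),
      score = rep(c(3, 2, 1), c(length(suit), length(sub), length(unsuit)))
    )
    criterion_spec(name, "categorical", rules)
  }
  specs <- list(
    rainfall = cont("rainfall", "mm",
                    list(c(1600, 1800)), list(c(1100, 1600), c(1800, 2000)),
                    list(c(-Inf, 1100), c(2000, Inf))),
    avg_temp = cont("avg_temp", "degC",
                    list(c(18, 23)), list(c(15, 18), c(23, 26)),
                    list(c(-Inf, 15), c(26, Inf))),
    min_temp = cont("min_temp", "degC",
                    list(c(18, Inf)), list(c(10, 18)), list(c(-Inf, 10))),
    max_temp = cont("max_temp", "degC",
                    list(c(-Inf, 25)), list(c(25, 30)), list(c(30, Inf))),
    ph = cont("ph", "pH",
              list(c(5, 6.5)), list(c(4.5, 5), c(6.5, 7.5)),
              list(c(-Inf, 4.5), c(7.5, Inf))),
    texture = catg("texture",
                   c("L", "SCL", "SiCL"),
                   c("CL", "SL", "SC", "SiL", "SiC"),
                   c("S", "C", "Si", "LS")),
    cec = cont("cec", "cmol+/kg",
               list(c(25, Inf)), list(c(15, 25)), list(c(-Inf, 15))),
    som = cont("som", "%",
               list(c(3, Inf)), list(c(2, 3)), list(c(-Inf, 2))),
    elevation = cont("elevation", "m",
                     list(c(1400, 1800)), list(c(900, 1400), c(1800, 2500)),
                     list(c(-Inf, 900), c(2500, Inf))),
    slope = cont("slope", "%",
                 list(c(-Inf, 12)), list(c(12, 25)), list(c(25, Inf))),
    # aspect sectors as degree intervals (N/NE/NW suitable, E/W sub, S/SW/SE
    # unsuitable); flat cells are flagged -1 and carry no aspect penalty
    aspect = cont("aspect", "degrees",
                  list(c(-Inf, 0), c(337.5, 360), c(0, 22.5), c(22.5, 67.5),
                       c(292.5, 337.5)),
                  list(c(67.5, 112.5), c(247.5, 292.5)),
                  list(c(112.5, 247.5))),
    lulc = catg("lulc",
                "agroforestry",
                c("farmland", "grassland"),
                c("forest", "settlement", "wetland")),
    dist_road = cont("dist_road", "m",
                     list(c(0, 2000)), list(c(2000, 5000)), list(c(5000, Inf))),
    dist_river = cont("dist_river", "m",
                      list(c(0, 1000)), list(c(1000, 5000)), list(c(5000, Inf)))
  )
  if (!is.null(weights)) {
    for (i in seq_len(nrow(weights))) {
      nm <- weights$criterion[i]
      if (nm %in% names(specs)) specs[[nm]]$weight <- weights$weight[i]
    }
  }
  specs
}

#' Ethiopian agro-ecological zone legend
#'
#' @return tibble with columns `code`, `zone`, `min_elev`, `max_elev` (m,
#'   lower-closed upper-open bands).
#' @export
agroecology_legend <- function() {
  tibble::tribble(
    ~code, ~zone,         ~min_elev, ~max_elev,
    1,     "Berha",       -Inf,      500,
    2,     "Kolla",       500,       1500,
    3,     "Weyina Dega", 1500,      2300,
    4,     "Dega",        2300,      3200,
    5,     "Wurch",       3200,      3700,
    6,     "High Wurch",  3700,      Inf
  )
}

#' Classify elevation into Ethiopian agro-ecological zones
#'
#' Maps a DEM (metres above sea level) into the six traditional zones:
#' Berha (< 500 m), Kolla (500-1500), Weyina Dega (1500-2300), Dega
#' (2300-3200), Wurch (3200-3700), High Wurch (> 3700). Every finite
#' elevation receives exactly one zone.
#'
#' @param dem elevation [grid_layer()] in metres.
#' @return a `grid_layer` of zone codes 1-6, carrying the zone legend in
#'   `attr(, "legend")`.
#' @export
classify_agroecology <- function(dem) {
  lg <- agroecology_legend()
  v <- dem$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(lg))) {
    hit <- !is.na(v) & v >= lg$min_elev[i] & v < lg$max_elev[i]
    out[hit] <- lg$code[i]
  }
  res <- grid_layer(out, dem$pixel_size, dem$origin, units = "zone", crs = dem$crs)
  attr(res, "legend") <- tibble::tibble(code = lg$code, category = lg$zone)
  res
}

#' Score terrain aspect for coffee suitability
#'
#' Bins aspect (degrees clockwise from north, the downhill direction) into
#' eight 45-degree compass sectors centred on the cardinal and intercardinal
#' bearings (N = \[337.5, 22.5)), then scores the cool, shaded sectors
#' N/NE/NW as suitable (3), E/W as sub-suitable (2) and the sun-exposed
#' S/SW/SE as unsuitable (1). Flat cells (aspect `-1`, undefined direction)
#' default to 3 on the rationale that flat ground imposes no aspect penalty.
#'
#' @param aspect_layer aspect [grid_layer()] in degrees, flat cells `-1`.
#' @param flat_score score assigned to flat cells.
#' @return a score `grid_layer`.
#' @export
aspect_to_score <- function(aspect_layer, flat_score = 3) {
  v <- aspect_layer$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v) & v >= 0
  sector <- compass_sector(v[ok])
  score_by_sector <- c(N = 3, NE = 3, NW = 3, E = 2, W = 2, S = 1, SW = 1, SE = 1)
  out[ok] <- unname(score_by_sector[sector])
  out[!is.na(v) & v < 0] <- flat_score
  grid_layer(out, aspect_layer$pixel_size, aspect_layer$origin,
             units = "score", crs = aspect_layer$crs)
}

#' Compass sector of an azimuth
#'
#' @param azimuth degrees clockwise from north.
#' @return character vector in N, NE, E, SE, S, SW, W, NW.
#' @export
compass_sector <- function(azimuth) {
  sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  idx <- (floor(((azimuth %% 360) + 22.5) / 45) %% 8) + 1
  sectors[idx]
}
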