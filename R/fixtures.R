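#' Worked judgment matrices for the Gedeo coffee suitability hierarchy
#'
#' Returns the published two-level hierarchy used for coffee-plantation
#' suitability in the Gedeo zone: a 4x4 main-factor matrix (climatology,
#' edaphic, physiographic, socioeconomic) and one sub-factor matrix per main
#' factor covering the 14 thematic criteria. Judgments are encoded as exact
#' rationals (e.g. 2/3), so reciprocity holds to machine precision.
#'
#' @return an [ahp_hierarchy()] whose leaves are the 14 criterion names used
#'   throughout the package: `rainfall`, `avg_temp`, `min_temp`, `max_temp`,
#'   `ph`, `texture`, `cec`, `som`, `elevation`, `slope`, `aspect`, `lulc`,
#'   `dist_road`, `dist_river`.
#' @export
#' @examples
#' h <- coffee_hierarchy()
#' compose_weights(h)
coffee_hierarchy <- function() {
  main <- pairwise_matrix(rbind(
    c(1,     5,     4,     5),
    c(1 / 5, 1,     3 / 2, 3 / 2),
    c(1 / 4, 2 / 3, 1,     2),
    c(1 / 5, 2 / 3, 1 / 2, 1)
  ), labels = c("climatology", "edaphic", "physiographic", "socioeconomic"))

  # kept verbatim from the published table: the avg-temp/max-temp pair is
  # recorded as 2 and 2/3 (not exactly reciprocal); the loose tolerance
  # admits it so the printed priority weights are reproduced exactly
  meteorological <- pairwise_matrix(rbind(
    c(1,     2 / 3, 2,     3 / 2),
    c(3 / 2, 1,     3,     2),
    c(1 / 2, 1 / 3, 1,     2 / 3),
    c(2 / 3, 2 / 3, 3 / 2, 1)
  ), labels = c("rainfall", "avg_temp", "min_temp", "max_temp"),
  reciprocal_tol = 0.34)

  edaphic <- pairwise_matrix(rbind(
    c(1,     3 / 2, 2,     2),
    c(2 / 3, 1,     3 / 2, 2),
    c(1 / 2, 2 / 3, 1,     3 / 2),
    c(1 / 2, 1 / 2, 2 / 3, 1)
  ), labels = c("ph", "texture", "cec", "som"))

  physiographic <- pairwise_matrix(rbind(
    c(1,     3,     5),
    c(1 / 3, 1,     3 / 2),
    c(1 / 5, 2 / 3, 1)
  ), labels = c("elevation", "slope", "aspect"))

  socioeconomic <- pairwise_matrix(rbind(
    c(1,     3,     3),
    c(1 / 3, 1,     3 / 2),
    c(1 / 3, 2 / 3, 1)
  ), labels = c("lulc", "dist_road", "dist_river"))

  ahp_hierarchy(main, list(
    climatology = meteorological,
    edaphic = edaphic,
    physiographic = physiographic,
    socioeconomic = socioeconomic
  ))
}

#' Meteorological stations of the Gedeo zone
#'
#' The five published stations with elevation (m), geographic coordinates
#' (decimal degrees) and annual mean minimum/maximum temperature (deg C),
#' used as input to inverse-distance-weighted temperature surfaces.
#'
#' @return a tibble with columns `station`, `elevation`, `lat`, `lon`,
#'   `min_temp`, `max_temp`.
#' @export
gedeo_stations <- function() {
  tibble::tribble(
    ~station,       ~elevation, ~lat,     ~lon,     ~min_temp, ~max_temp,
    "Dilla",        1515,       6.380556, 38.30694, 12.7,      28,
    "Fiseha Genet", 2240,       6.0667,   38.18333, 12.1,      22,
    "Yirga Chefe",  1856,       6.150667, 38.202,   10.4,      24.5,
    "Hagere Selam", 2809,       6.49,     38.52,    7,         19.2,
    "Gedebe",       2245,       5.905667, 38.2395,  11.9,      22.02
  )
}
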