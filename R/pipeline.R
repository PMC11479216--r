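#' Run the full suitability pipeline on a landscape
#'
#' Executes the complete analysis: derive composite criterion weights from
#' the AHP hierarchy (refusing matrices whose consistency ratio exceeds the
#' threshold), build the derived surfaces (average temperature, slope,
#' aspect, distance to roads/rivers), reclassify all 14 thematic layers into
#' suitability scores, combine them by weighted overlay, classify the score
#' into three suitability classes, and tabulate class areas.
#'
#' @param landscape a [generate_landscape()] result, or a compatible list
#'   with `layers`, `features` and optionally `coffee_points`.
#' @param hierarchy an [ahp_hierarchy()]; defaults to [coffee_hierarchy()].
#' @param criteria named list of [criterion_spec()]s; defaults to
#'   [coffee_criteria()].
#' @param breaks suitability class breaks, see [classify_suitability()].
#' @param cr_threshold,force consistency gate, see [compose_weights()].
#' @return an object of class `suitability_result`: list with `pacp`
#'   (score [grid_layer()]), `classes`, `area_table`, `weights`, `breaks`,
#'   `consistency`, `score_layers`. Supports `tidy()`, `glance()` and
#'   `autoplot()`.
#' @export
#' @examples
#' ls <- generate_landscape(landscape_config(shape = c(48, 48), seed = 3))
#' res <- run_pipeline(ls)
#' tidy(res)
run_pipeline <- function(landscape, hierarchy = coffee_hierarchy(),
                         criteria = coffee_criteria(),
                         breaks = c(5 / 3, 7 / 3), cr_threshold = 0.1,
                         force = FALSE) {
  weights <- tryCatch(
    compose_weights(hierarchy, cr_threshold = cr_threshold, force = force),
    error = function(e) stop("stage ahp: ", conditionMessage(e), call. = FALSE)
  )
  lyr <- landscape$layers

  derived <- tryCatch({
    dem <- lyr$elevation
    feats <- landscape$features
    list(
      avg_temp = mean_temperature(lyr$min_temp, lyr$max_temp),
      slope = slope_percent(dem),
      aspect = aspect_degrees(dem),
      dist_road = euclidean_distance(dem, feats[feats$kind == "road", ]),
      dist_river = euclidean_distance(dem, feats[feats$kind == "river", ])
    )
  }, error = function(e) stop("stage surfaces: ", conditionMessage(e), call. = FALSE))

  raw <- c(lyr[c("rainfall", "min_temp", "max_temp", "ph", "som", "cec",
                 "texture", "lulc", "elevation")], derived)
  score_layers <- tryCatch(
    purrr::imap(raw, function(l, nm) reclassify(l, criteria[[nm]])),
    error = function(e) stop("stage reclassify: ", conditionMessage(e), call. = FALSE)
  )

  result <- tryCatch({
    pacp <- weighted_overlay(score_layers, weights)
    classes <- classify_suitability(pacp, breaks = breaks)
    area_table <- tabulate_areas(classes)
    list(pacp = pacp, classes = classes, area_table = area_table)
  }, error = function(e) stop("stage overlay: ", conditionMessage(e), call. = FALSE))

  structure(
    c(result, list(weights = weights, breaks = breaks,
                   consistency = attr(weights, "consistency"),
                   score_layers = score_layers)),
    class = "suitability_result"
  )
}

#' @export
print.suitability_result <- function(x, ...) {
  cat("Coffee land-suitability result\n")
  cat(sprintf("  class breaks: %.4f, %.4f\n", x$breaks[1], x$breaks[2]))
  print(x$area_table)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object a `suitability_result`.
#' @param ... unused.
#' @method tidy suitability_result
#' @export
tidy.suitability_result <- function(x, ...) x$area_table

#' @rdname run_pipeline
#' @method glance suitability_result
#' @export
glance.suitability_result <- function(x, ...) {
  v <- x$pacp$values
  tibble::tibble(
    n_criteria = nrow(x$weights),
    mean_score = mean(v, na.rm = TRUE),
    pct_suitable = x$area_table$pct[x$area_table$class == "3"],
    max_cr = max(x$consistency$cr),
    break_low = x$breaks[1], break_high = x$breaks[2]
  )
}

#' @rdname run_pipeline
#' @method autoplot suitability_result
#' @export
autoplot.suitability_result <- function(object, ...) {
  df <- as_tibble(object$classes)
  df$class <- factor(df$value, levels = c(1, 2, 3),
                     labels = c("unsuitable", "sub-suitable", "suitable"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(unsuitable = "#d73027", `sub-suitable` = "#fee08b",
                 suitable = "#1a9850"),
      na.value = "grey90", na.translate = FALSE, name = NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' Write the artifacts of a suitability run
#'
#' Writes the score and class rasters (ASCII grid), the area table (CSV) and
#' a JSON run report recording weights, per-matrix consistency diagnostics
#' and the class breaks used.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grid(result$pacp, file.path(dir, "pacp.asc"))
  write_grid(result$classes, file.path(dir, "classes.asc"))
  readr::write_csv(result$area_table, file.path(dir, "areas.csv"))
  report <- list(
    package_version = as.character(utils::packageVersion("agrisuit")),
    breaks = result$breaks,
    weights = stats::setNames(as.list(result$weights$weight),
                              result$weights$criterion),
    consistency = result$consistency,
    areas = result$area_table
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
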