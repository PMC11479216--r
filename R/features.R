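#' Read and write simple GeoJSON feature sets
#'
#' Supports `FeatureCollection`s of `Point` and `LineString` geometries in a
#' planar coordinate frame — the vocabulary needed for road/river features
#' and ground points. Coordinates are taken as-is (no reprojection).
#'
#' @param path file path.
#' @return `read_features_geojson()` returns a tibble with columns
#'   `feature_id`, `x`, `y` plus any scalar properties (e.g. `kind`).
#' @export
read_features_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_fmt("expected a GeoJSON FeatureCollection: %s", path)
  }
  purrr::imap(gj$features, function(ft, i) {
    geom <- ft$geometry
    coords <- switch(geom$type,
      Point = list(geom$coordinates),
      LineString = geom$coordinates,
      abort_fmt("unsupported geometry type '%s'", geom$type)
    )
    out <- tibble::tibble(
      feature_id = i,
      x = vapply(coords, function(p) as.numeric(p[[1]]), 1),
      y = vapply(coords, function(p) as.numeric(p[[2]]), 1)
    )
    for (nm in names(ft$properties)) {
      val <- ft$properties[[nm]]
      if (length(val) == 1 && is.atomic(val)) out[[nm]] <- val
    }
    out
  }) |> purrr::list_rbind()
}

#' @rdname read_features_geojson
#' @param features tibble with `feature_id`, `x`, `y` and optional scalar
#'   property columns; multi-vertex features become `LineString`s.
#' @export
write_features_geojson <- function(features, path) {
  features <- tibble::as_tibble(features)
  prop_cols <- setdiff(names(features), c("feature_id", "x", "y"))
  feats <- lapply(split(features, features$feature_id), function(pts) {
    geom <- if (nrow(pts) == 1) {
      list(type = "Point", coordinates = c(pts$x, pts$y))
    } else {
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(pts)),
                                function(k) c(pts$x[k], pts$y[k])))
    }
    props <- lapply(pts[1, prop_cols, drop = FALSE], identity)
    list(type = "Feature", geometry = geom, properties = props)
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(feats)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write point tables
#'
#' Plain CSV with `x`, `y` and optional `label` columns.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_points_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_points_csv
#' @param points data frame with columns `x`, `y` and optional extras.
#' @export
write_points_csv <- function(points, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(points, path)
  invisible(path)
}
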