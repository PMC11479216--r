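#' Single-band raster layer
#'
#' A minimal in-memory raster: a numeric matrix on a square grid with a
#' pixel size in metres and the coordinate of the top-left corner. Row 1 is
#' the northernmost row; missing cells are `NA` internally and mapped to a
#' nodata sentinel on write. Geo-coordinates refer to cell centres when
#' sampling points and to cell edges for the extent.
#'
#' @param values numeric matrix (`NA` = nodata). Row 1 = north.
#' @param pixel_size cell edge length in metres (> 0).
#' @param origin numeric `c(x, y)` of the top-left corner of cell (1,1).
#' @param units free-text units tag (e.g. "m", "mm", "dB").
#' @param crs identifier of the (planar) coordinate frame; purely a tag.
#' @return an object of class `grid_layer`.
#' @export
#' @examples
#' g <- grid_layer(matrix(1:6, 2, 3), pixel_size = 10)
#' cell_centers(g)
grid_layer <- function(values, pixel_size = 10, origin = c(0, nrow(values) * pixel_size),
                       units = "", crs = "local") {
  if (!is.matrix(values)) abort_fmt("values must be a matrix")
  if (length(values) == 0) abort_fmt("raster must be non-empty")
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort_fmt("pixel_size must be > 0")
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), units = units, crs = crs),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<grid_layer> %d x %d @ %g m%s | %d valid cells | range [%s, %s]\n",
    nrow(x$values), ncol(x$values), x$pixel_size,
    if (nzchar(x$units)) paste0(", units: ", x$units) else "",
    length(v),
    if (length(v)) format(min(v)) else "-",
    if (length(v)) format(max(v)) else "-"
  ))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Cell-centre coordinates of a grid layer
#'
#' @param layer a [grid_layer()].
#' @return list of `x` (per column) and `y` (per row) centre coordinates.
#' @export
cell_centers <- function(layer) {
  px <- layer$pixel_size
  list(
    x = layer$origin[1] + (seq_len(ncol(layer$values)) - 0.5) * px,
    y = layer$origin[2] - (seq_len(nrow(layer$values)) - 0.5) * px
  )
}

#' Locate the cell containing a point
#'
#' Uses half-open cell footprints `[x, x + px) x (y - px, y]`; points on a
#' shared edge resolve to the right/lower cell. Points outside the raster
#' extent return `NA` indices.
#'
#' @param layer a [grid_layer()].
#' @param x,y point coordinates in the layer's frame.
#' @return integer matrix with columns `row`, `col` (`NA` outside extent).
#' @export
cell_index <- function(layer, x, y) {
  px <- layer$pixel_size
  col <- floor((x - layer$origin[1]) / px) + 1L
  row <- floor((layer$origin[2] - y) / px) + 1L
  # top edge belongs to row 1, left edge to col 1
  row[layer$origin[2] - y == 0] <- 1L
  bad <- col < 1L | col > ncol(layer$values) | row < 1L | row > nrow(layer$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @param x a `grid_layer`.
#' @param ... unused.
#' @rdname grid_layer
#' @method as_tibble grid_layer
#' @export
as_tibble.grid_layer <- function(x, ...) {
  cc <- cell_centers(x)
  tibble::tibble(
    x = rep(cc$x, each = nrow(x$values)),
    y = rep(cc$y, times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Map a function over co-registered grids
#'
#' @param ... one or more co-registered [grid_layer()] objects.
#' @param f function applied elementwise to the value matrices.
#' @param units units tag of the result.
#' @return a `grid_layer` on the shared grid.
#' @export
grid_map <- function(..., f, units = "") {
  layers <- list(...)
  ref <- layers[[1]]
  for (l in layers[-1]) check_coregistered(ref, l, "grid_map input")
  vals <- do.call(f, lapply(layers, function(l) l$values))
  grid_layer(vals, ref$pixel_size, ref$origin, units = units, crs = ref$crs)
}

# internal: error unless two layers share shape, pixel size and origin
check_coregistered <- function(a, b, what = "layer", tol = 1e-6) {
  if (!all(dim(a$values) == dim(b$values)) ||
      abs(a$pixel_size - b$pixel_size) > tol ||
      any(abs(a$origin - b$origin) > tol)) {
    abort_fmt(
      "%s is not co-registered with the reference grid (%d x %d @ %g m, origin %g,%g)",
      what, nrow(a$values), ncol(a$values), a$pixel_size, a$origin[1], a$origin[2]
    )
  }
  invisible(TRUE)
}

#' Read / write a grid layer as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south).
#' A write/read round trip preserves values, nodata cells, pixel size and
#' origin to full double precision.
#'
#' @param path file path (conventionally `.asc`).
#' @param units,crs tags attached on read (the format stores neither).
#' @return `read_grid()` returns a [grid_layer()]; `write_grid()` returns
#'   `path` invisibly.
#' @export
read_grid <- function(path, units = "", crs = "local") {
  lines <- readLines(path, n = 6)
  is_hdr <- grepl("^\\s*[A-Za-z]", lines)
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  hdr <- list()
  for (ln in lines[seq_len(n_hdr)]) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort_fmt("not an ASCII grid (missing header keys) or missing georeferencing: %s", path)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort_fmt("cell count %d does not match header %d x %d",
              length(vals), hdr$nrows, hdr$ncols)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  grid_layer(
    m, pixel_size = hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    units = units, crs = crs
  )
}

#' @rdname read_grid
#' @param layer a [grid_layer()].
#' @param nodata sentinel written for `NA` cells.
#' @export
write_grid <- function(layer, path, nodata = -9999) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  m <- layer$values
  if (any(m == nodata, na.rm = TRUE)) {
    abort_fmt("nodata sentinel %g collides with data values", nodata)
  }
  m[is.na(m)] <- nodata
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", layer$origin[1]),
    sprintf("yllcorner %.10g", layer$origin[2] - nr * layer$pixel_size),
    sprintf("cellsize %.10g", layer$pixel_size),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Heat-map plot of a grid layer
#'
#' @param object a [grid_layer()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot grid_layer
#' @export
autoplot.grid_layer <- function(object, ...) {
  df <- as_tibble.grid_layer(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = object$units) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}
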