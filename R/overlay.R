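#' Weighted linear overlay of score layers
#'
#' Combines co-registered suitability score layers into the continuous
#' suitability score \eqn{\sum_i w_i x_i}, where \eqn{x_i} is criterion
#' *i*'s score (1/2/3) at the cell and \eqn{w_i} its composite weight.
#' Weights must sum to 1, so the result lies in `[1, 3]` for valid score
#' inputs. Any nodata input cell voids the output cell (strict propagation);
#' set `reweight_missing = TRUE` to instead renormalise the weights over the
#' layers present at each cell.
#'
#' @param score_layers named list of score [grid_layer()] objects.
#' @param weights weight table with columns `criterion`, `weight` (as from
#'   [compose_weights()]) or a named numeric vector. Names must match
#'   `names(score_layers)`.
#' @param reweight_missing logical; renormalise weights over non-missing
#'   layers per cell instead of propagating nodata.
#' @return the continuous suitability score as a `grid_layer`.
#' @export
#' @examples
#' g3 <- grid_layer(matrix(3, 2, 2), 10)
#' g1 <- grid_layer(matrix(1, 2, 2), 10)
#' weighted_overlay(list(a = g3, b = g1), c(a = 0.75, b = 0.25))$values
weighted_overlay <- function(score_layers, weights, reweight_missing = FALSE) {
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$weight, weights$criterion)
  }
  if (is.null(names(score_layers)) || is.null(names(weights))) {
    abort_fmt("score_layers and weights must both be named")
  }
  if (!setequal(names(score_layers), names(weights))) {
    missing_w <- setdiff(names(score_layers), names(weights))
    missing_l <- setdiff(names(weights), names(score_layers))
    abort_fmt("layer/weight name mismatch (no weight: %s; no layer: %s)",
              paste(missing_w, collapse = ","), paste(missing_l, collapse = ","))
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    abort_fmt("weights must sum to 1 (got %.8f)", sum(weights))
  }
  ref <- score_layers[[1]]
  for (nm in names(score_layers)[-1]) {
    check_coregistered(ref, score_layers[[nm]], paste0("layer '", nm, "'"))
  }
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  acc <- matrix(0, nr, nc)
  wsum <- matrix(0, nr, nc)
  anyna <- matrix(FALSE, nr, nc)
  for (nm in names(score_layers)) {
    v <- score_layers[[nm]]$values
    na <- is.na(v)
    anyna <- anyna | na
    v[na] <- 0
    acc <- acc + weights[[nm]] * v
    wsum <- wsum + weights[[nm]] * !na
  }
  if (reweight_missing) {
    out <- acc / wsum
    out[wsum == 0] <- NA
  } else {
    out <- acc
    out[anyna] <- NA
  }
  grid_layer(out, ref$pixel_size, ref$origin, units = "score", crs = ref$crs)
}

#' Classify a continuous suitability score into three classes
#'
#' Cuts the `[1, 3]` suitability score at two breaks into classes
#' 1 = unsuitable (score < b1), 2 = sub-suitable (b1 <= score < b2) and
#' 3 = suitable (score >= b2). The default breaks are the equal-width thirds
#' of `[1, 3]`: 5/3 and 7/3.
#'
#' @param pacp suitability-score [grid_layer()].
#' @param breaks numeric `c(b1, b2)` with `1 < b1 < b2 < 3`.
#' @return a class `grid_layer` with codes 1/2/3.
#' @export
classify_suitability <- function(pacp, breaks = c(5 / 3, 7 / 3)) {
  if (length(breaks) != 2 || !(1 < breaks[1] && breaks[1] < breaks[2] && breaks[2] < 3)) {
    abort_fmt("breaks must satisfy 1 < b1 < b2 < 3")
  }
  v <- pacp$values
  out <- ifelse(is.na(v), NA_real_,
                ifelse(v < breaks[1], 1, ifelse(v < breaks[2], 2, 3)))
  res <- grid_layer(out, pacp$pixel_size, pacp$origin, units = "class",
                    crs = pacp$crs)
  attr(res, "breaks") <- breaks
  res
}

#' Tabulate class areas
#'
#' Per-class area in km2 and percentage of the valid area, plus a total row,
#' for a 1/2/3 class raster.
#'
#' @param classes class [grid_layer()].
#' @param pixel_size cell size in metres; defaults to the layer's.
#' @return a tibble with columns `class`, `label`, `cells`, `area_km2`,
#'   `pct`; the final row is the total over valid cells.
#' @export
tabulate_areas <- function(classes, pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- classes$pixel_size
  labels <- c(`1` = "unsuitable", `2` = "sub-suitable", `3` = "suitable")
  v <- classes$values
  valid <- sum(!is.na(v))
  cell_km2 <- pixel_size^2 / 1e6
  rows <- purrr::map(c(1, 2, 3), function(k) {
    n <- sum(v == k, na.rm = TRUE)
    tibble::tibble(
      class = as.character(k), label = labels[[as.character(k)]], cells = n,
      area_km2 = n * cell_km2,
      pct = if (valid > 0) 100 * n / valid else 0
    )
  }) |> purrr::list_rbind()
  dplyr::bind_rows(rows, tibble::tibble(
    class = "total", label = "total", cells = valid,
    area_km2 = valid * cell_km2, pct = if (valid > 0) 100 else 0
  ))
}

#' Confusion-matrix accuracy metrics
#'
#' Overall accuracy (trace over total) and Cohen's kappa
#' \eqn{(p_o - p_e)/(1 - p_e)}, with expected agreement \eqn{p_e} from the
#' row/column marginals. Kappa is undefined (returned `NA` with a warning)
#' when all marginal mass sits in one cell (\eqn{p_e = 1}).
#'
#' @param data either a square count matrix/table (reference in rows,
#'   predicted in columns) or a data frame with columns `reference` and
#'   `predicted` (one row per validation sample).
#' @return a one-row tibble with `n`, `overall_accuracy`, `kappa`.
#' @export
#' @examples
#' accuracy_metrics(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
accuracy_metrics <- function(data) {
  if (is.data.frame(data) && all(c("reference", "predicted") %in% names(data))) {
    lv <- sort(unique(c(data$reference, data$predicted)))
    m <- table(factor(data$reference, lv), factor(data$predicted, lv))
    m <- unclass(m)
  } else {
    m <- as.matrix(data)
  }
  if (nrow(m) != ncol(m)) abort_fmt("confusion matrix must be square")
  if (any(m < 0)) abort_fmt("confusion matrix counts must be >= 0")
  total <- sum(m)
  if (total == 0) abort_fmt("confusion matrix is empty")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: expected agreement is 1 (all mass in one marginal cell)",
            call. = FALSE)
    NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  tibble::tibble(n = total, overall_accuracy = po, kappa = kappa)
}

#' Overlay validation points on a class raster
#'
#' Looks up the predicted suitability class under each ground point,
#' mirroring a field-validation overlay. Points on nodata cells are flagged
#' unscored.
#'
#' @param classes class [grid_layer()].
#' @param labelled_points data frame with columns `x`, `y` and optionally a
#'   reference `label`.
#' @return the input tibble with columns `predicted_class`,
#'   `predicted_label`, `scored`; per-class counts in `attr(, "summary")`.
#' @export
validate_points <- function(classes, labelled_points) {
  out <- extract_values_at_points(classes, labelled_points)
  labels <- c(`1` = "unsuitable", `2` = "sub-suitable", `3` = "suitable")
  out <- dplyr::mutate(
    out,
    predicted_class = .data$value,
    predicted_label = ifelse(is.na(.data$value), NA_character_,
                             labels[as.character(.data$value)]),
    scored = !.data$nodata
  )
  out$value <- NULL
  out$nodata <- NULL
  smry <- dplyr::count(dplyr::filter(out, .data$scored),
                       .data$predicted_label, name = "points")
  attr(out, "summary") <- smry
  out
}
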