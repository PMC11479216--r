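#' Saaty's random consistency index table
#'
#' Expected consistency index of random reciprocal matrices of order 1--10,
#' used to normalise CI into the consistency ratio CR = CI/RI.
#'
#' @format named numeric vector, names `"1"` to `"10"`.
#' @export
ri_saaty <- c(
  "1" = 0, "2" = 0, "3" = 0.58, "4" = 0.90, "5" = 1.12,
  "6" = 1.24, "7" = 1.32, "8" = 1.41, "9" = 1.45, "10" = 1.49
)

#' Column-normalise a pairwise comparison matrix
#'
#' Divides each judgment by its column sum, so every column of the result
#' sums to 1. This is the first step of the approximate priority-weight
#' method (normalise columns, then average rows).
#'
#' @param matrix a [pairwise_matrix()].
#' @return a tibble with a `criterion` column followed by one column per
#'   criterion holding the normalised judgments.
#' @export
normalize_columns <- function(matrix) {
  m <- as_judgment_matrix(matrix)
  norm <- sweep(m, 2, colSums(m), "/")
  tibble::as_tibble(norm, rownames = "criterion")
}

#' Priority weights by column-normalise-and-row-average
#'
#' The weight of criterion *i* is the mean over columns of the
#' column-normalised judgments in row *i*; weights sum to 1. This is the
#' approximate (arithmetic) eigenvector method conventionally used when AHP
#' tables are computed by hand; the principal eigenvector agrees with it to
#' well under a printed unit for near-consistent matrices.
#'
#' @inheritParams normalize_columns
#' @return a tibble with columns `criterion` and `weight`.
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 3), c(1 / 3, 1)), c("a", "b"))
#' priority_weights(m)
priority_weights <- function(matrix) {
  m <- as_judgment_matrix(matrix)
  norm <- sweep(m, 2, colSums(m), "/")
  tibble::tibble(criterion = rownames(m), weight = unname(rowMeans(norm)))
}

#' Principal-eigenvalue estimate of a judgment matrix
#'
#' Estimates \eqn{\lambda_{max}} as the mean over rows of
#' \eqn{(A w)_i / w_i}, the "weighted sum and priority" estimate. For a
#' perfectly consistent matrix this equals the order *n* exactly; judgment
#' inconsistency inflates it.
#'
#' @inheritParams normalize_columns
#' @param weights optional numeric weight vector (or tibble from
#'   [priority_weights()]); computed from `matrix` when omitted.
#' @return scalar \eqn{\lambda_{max}} estimate.
#' @export
lambda_max <- function(matrix, weights = NULL) {
  m <- as_judgment_matrix(matrix)
  if (is.null(weights)) weights <- priority_weights(matrix)
  if (is.data.frame(weights)) weights <- weights$weight
  if (any(weights <= 0)) abort_fmt("weights must be strictly positive")
  mean(as.vector(m %*% weights) / weights)
}

#' AHP consistency diagnostics
#'
#' Computes priority weights, \eqn{\lambda_{max}}, the consistency index
#' CI = (\eqn{\lambda_{max}} - n)/(n - 1) and the consistency ratio
#' CR = CI/RI(n). Judgment sets with CR below 0.1 are conventionally
#' considered acceptably consistent.
#'
#' @inheritParams normalize_columns
#' @param ri random consistency index table, a numeric vector indexed by
#'   matrix order as in [ri_saaty]. The source of RI values is a modelling
#'   choice (tables differ slightly between authors), so it is exposed here.
#' @return an object of class `ahp_priority` with fields `labels`, `weights`,
#'   `lambda_max`, `ci`, `cr`, `ri_used`, `n`. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(
#'   c(1, 5, 4, 5), c(1 / 5, 1, 3 / 2, 3 / 2),
#'   c(1 / 4, 2 / 3, 1, 2), c(1 / 5, 2 / 3, 1 / 2, 1)
#' ), c("climatology", "edaphic", "physiographic", "socioeconomic"))
#' ahp_consistency(m)
ahp_consistency <- function(matrix, ri = ri_saaty) {
  m <- as_judgment_matrix(matrix)
  n <- nrow(m)
  if (!as.character(n) %in% names(ri)) {
    abort_fmt("matrix order %d is outside the supplied RI table (orders %s)",
              n, paste(names(ri), collapse = ", "))
  }
  w <- priority_weights(matrix)
  lm <- lambda_max(matrix, w)
  ci <- if (n > 1) (lm - n) / (n - 1) else 0
  ri_n <- unname(ri[as.character(n)])
  cr <- if (ri_n > 0) ci / ri_n else 0
  structure(
    list(labels = rownames(m), weights = stats::setNames(w$weight, w$criterion),
         lambda_max = lm, ci = ci, cr = cr, ri_used = ri_n, n = n),
    class = "ahp_priority"
  )
}

#' @export
print.ahp_priority <- function(x, ...) {
  cat(sprintf("AHP priorities (n = %d)\n", x$n))
  print(tibble::tibble(criterion = x$labels, weight = round(unname(x$weights), 4)))
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (RI = %.2f)\n",
              x$lambda_max, x$ci, x$cr, x$ri_used))
  invisible(x)
}

#' @rdname ahp_consistency
#' @param x an `ahp_priority` object.
#' @param ... unused.
#' @method tidy ahp_priority
#' @export
tidy.ahp_priority <- function(x, ...) {
  tibble::tibble(criterion = x$labels, weight = unname(x$weights))
}

#' @rdname ahp_consistency
#' @method glance ahp_priority
#' @export
glance.ahp_priority <- function(x, ...) {
  tibble::tibble(
    n = x$n, lambda_max = x$lambda_max, ci = x$ci, cr = x$cr,
    ri_used = x$ri_used
  )
}

#' Two-level AHP hierarchy
#'
#' Bundles the main-criteria judgment matrix with one sub-criteria matrix per
#' main criterion. Every leaf (sub-criterion) belongs to exactly one main
#' criterion; composed leaf weights multiply through the levels and sum to 1.
#'
#' @param main a `pairwise_matrix` over the main criteria.
#' @param subs named list of `pairwise_matrix` objects; names must match the
#'   labels of `main` exactly.
#' @return an object of class `ahp_hierarchy`.
#' @export
ahp_hierarchy <- function(main, subs) {
  stopifnot(inherits(main, "pairwise_matrix"))
  main_labels <- rownames(main)
  if (!setequal(names(subs), main_labels)) {
    abort_fmt("sub-matrix names {%s} must match main criteria {%s}",
              paste(names(subs), collapse = ", "),
              paste(main_labels, collapse = ", "))
  }
  leaf_labels <- unlist(lapply(subs, rownames), use.names = FALSE)
  if (anyDuplicated(leaf_labels)) {
    abort_fmt("sub-criterion '%s' appears under more than one main criterion",
              leaf_labels[duplicated(leaf_labels)][1])
  }
  structure(list(main = main, subs = subs[main_labels]),
            class = "ahp_hierarchy")
}

#' @export
print.ahp_hierarchy <- function(x, ...) {
  cat(sprintf("<ahp_hierarchy> %d main criteria, %d leaves\n",
              nrow(x$main), sum(vapply(x$subs, nrow, 1L))))
  invisible(x)
}

#' Compose hierarchical weights into a flat criterion weight table
#'
#' Multiplies each sub-criterion weight by its main criterion's weight,
#' yielding the composite weight of each leaf; composites sum to 1. Matrices
#' whose consistency ratio exceeds `cr_threshold` cause a refusal (naming the
#' offending matrix) unless `force = TRUE`.
#'
#' @param hierarchy an [ahp_hierarchy()].
#' @param cr_threshold maximum acceptable CR (conventional 0.1).
#' @param force logical; proceed despite CR violations.
#' @param ri RI table, see [ahp_consistency()].
#' @return a tibble with columns `criterion`, `main_criterion`, `main_weight`,
#'   `sub_weight`, `weight`, plus per-matrix diagnostics in
#'   `attr(, "consistency")`.
#' @export
compose_weights <- function(hierarchy, cr_threshold = 0.1, force = FALSE,
                            ri = ri_saaty) {
  stopifnot(inherits(hierarchy, "ahp_hierarchy"))
  main_res <- ahp_consistency(hierarchy$main, ri = ri)
  sub_res <- lapply(hierarchy$subs, ahp_consistency, ri = ri)

  diag_tbl <- dplyr::bind_rows(
    dplyr::mutate(glance.ahp_priority(main_res), matrix = "main", .before = 1),
    purrr::imap(sub_res, \(r, nm) {
      dplyr::mutate(glance.ahp_priority(r), matrix = nm, .before = 1)
    }) |> purrr::list_rbind()
  )
  bad <- diag_tbl$matrix[diag_tbl$cr > cr_threshold]
  if (length(bad) > 0 && !force) {
    abort_fmt(
      "consistency ratio above %.2f for matrix '%s' (CR = %.3f); revise judgments or set force = TRUE",
      cr_threshold, bad[1], diag_tbl$cr[diag_tbl$matrix == bad[1]][1]
    )
  }

  out <- purrr::imap(sub_res, function(r, nm) {
    tibble::tibble(
      criterion = r$labels,
      main_criterion = nm,
      main_weight = unname(main_res$weights[nm]),
      sub_weight = unname(r$weights),
      weight = main_weight * sub_weight
    )
  }) |> purrr::list_rbind()
  attr(out, "consistency") <- diag_tbl
  out
}

# coerce pairwise_matrix / plain matrix to a validated judgment matrix
as_judgment_matrix <- function(matrix) {
  if (inherits(matrix, "pairwise_matrix")) {
    m <- unclass(matrix)
  } else {
    m <- unclass(pairwise_matrix(matrix))
  }
  m
}
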