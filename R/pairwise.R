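#' Construct and validate a pairwise comparison matrix
#'
#' A pairwise comparison matrix records relative-importance judgments
#' \eqn{a_{ij} > 0} between criteria on the Saaty 1--9 scale (fractional
#' judgments such as 3/2 are permitted). The matrix must have unit diagonal
#' and be reciprocal, \eqn{a_{ji} = 1/a_{ij}}. If only the upper triangle is
#' supplied (lower triangle `NA`), the lower triangle is completed from the
#' reciprocity condition.
#'
#' @param entries square numeric or character matrix (or data.frame) of
#'   judgments; character cells may be fractions like `"3/2"`. `NA` below the
#'   diagonal is filled with the reciprocal of the mirror cell.
#' @param labels criterion names, one per row. Defaults to the rownames of
#'   `entries`, then to `"C1"`, `"C2"`, ...
#' @param reciprocal_tol relative tolerance on \eqn{a_{ij} a_{ji} = 1}.
#' @return an object of class `pairwise_matrix`: the numeric judgment matrix
#'   with row/column names set to `labels`.
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(
#'   c(1, 5, 4, 5),
#'   c(1 / 5, 1, 3 / 2, 3 / 2),
#'   c(1 / 4, 2 / 3, 1, 2),
#'   c(1 / 5, 2 / 3, 1 / 2, 1)
#' ), labels = c("climatology", "edaphic", "physiographic", "socioeconomic"))
#' priority_weights(m)
pairwise_matrix <- function(entries, labels = NULL, reciprocal_tol = 1e-9) {
  if (is.data.frame(entries)) entries <- as.matrix(entries)
  if (is.character(entries)) {
    entries <- matrix(parse_judgment(entries), nrow = nrow(entries))
  }
  if (!is.matrix(entries) || nrow(entries) != ncol(entries)) {
    abort_fmt("pairwise matrix must be square (got %d x %d)",
              NROW(entries), NCOL(entries))
  }
  n <- nrow(entries)
  if (n < 2) abort_fmt("pairwise matrix needs at least 2 criteria")
  if (is.null(labels)) labels <- rownames(entries)
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  if (length(labels) != n) {
    abort_fmt("length(labels) (%d) != matrix order (%d)", length(labels), n)
  }
  storage.mode(entries) <- "double"

  # complete the lower triangle from the upper when it was left NA
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i > j && is.na(entries[i, j]) && !is.na(entries[j, i])) {
        entries[i, j] <- 1 / entries[j, i]
      }
    }
  }
  if (anyNA(entries)) {
    idx <- which(is.na(entries), arr.ind = TRUE)[1, ]
    abort_fmt("missing judgment at cell (%d,%d)", idx[1], idx[2])
  }
  bad <- which(entries <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_fmt("nonpositive judgment %g at cell (%d,%d)",
              entries[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2])
  }
  for (i in seq_len(n)) {
    if (abs(entries[i, i] - 1) > reciprocal_tol) {
      abort_fmt("diagonal entry at cell (%d,%d) must be 1, got %g",
                i, i, entries[i, i])
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i > j) {
        prod_ij <- entries[i, j] * entries[j, i]
        if (abs(prod_ij - 1) > reciprocal_tol) {
          abort_fmt(
            "reciprocity violated at cell (%d,%d): a[%d,%d]*a[%d,%d] = %g != 1",
            i, j, i, j, j, i, prod_ij
          )
        }
      }
    }
  }
  dimnames(entries) <- list(labels, labels)
  structure(entries, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<pairwise_matrix> %d criteria\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Read a pairwise comparison matrix from CSV
#'
#' Expects a header row and a first column of criterion labels; cells may be
#' decimals or `"p/q"` fractions. Cells below the diagonal may be left empty
#' and are completed by reciprocity.
#'
#' @param path file path.
#' @param reciprocal_tol passed to [pairwise_matrix()].
#' @return a `pairwise_matrix`.
#' @export
read_pairwise_csv <- function(path, reciprocal_tol = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  labels <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells == ""] <- NA
  num <- matrix(NA_real_, nrow(cells), ncol(cells))
  num[!is.na(cells)] <- parse_judgment(cells[!is.na(cells)])
  pairwise_matrix(num, labels = labels, reciprocal_tol = reciprocal_tol)
}
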