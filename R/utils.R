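#' Round half away from zero
#'
#' Printed decision-analysis tables conventionally round 0.145 up to 0.15,
#' whereas [base::round()] rounds half to even. Used whenever values are
#' compared against a table printed at fixed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Parse judgment values given as decimals or "p/q" fractions
#'
#' Pairwise judgments on the Saaty scale are often recorded as vulgar
#' fractions ("3/2", "2/3"). These are parsed exactly as rationals before
#' conversion to double, so that reciprocity holds to machine precision.
#'
#' @param x character or numeric vector.
#' @return numeric vector.
#' @export
#' @examples
#' parse_judgment(c("3/2", "1", "0.5"))
parse_judgment <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  # tolerate a stray trailing slash as seen in hand-typed tables ("1/3/")
  x <- sub("/+$", "", x)
  vapply(x, function(s) {
    if (grepl("^[+-]?[0-9.]+\\s*/\\s*[0-9.]+$", s)) {
      parts <- strsplit(s, "/")[[1]]
      as.numeric(parts[1]) / as.numeric(parts[2])
    } else {
      as.numeric(s)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

# internal: stop() with a sprintf-style message
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
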