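#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published composition tables in
#' this field round half up (55.6% prints as 56%), so reports use this
#' convention.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(55.5)  # 56, where round(55.5) gives 56 but round(0.5) gives 0
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_musadiv <- function(...) stop(..., call. = FALSE)

#  Validate a square distance/similarity-style matrix.
check_square <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_musadiv(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop_musadiv(what, " must be symmetric")
  invisible(m)
}

#  Format numerics for deterministic CSV output.
fmt_num <- function(x, fmt = "%.4f") {
  ifelse(is.na(x), "NA", sprintf(fmt, x))
}
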