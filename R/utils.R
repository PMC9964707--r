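`%||%` <- function(x, y) if (is.null(x)) y else x

# linear interpolation on a strictly increasing grid; errors outside the span
# (no extrapolation anywhere in this package)
interp_within <- function(x, y, xout, what = "value") {
  if (any(xout < x[1] | xout > x[length(x)])) {
    stop(sprintf("%s requested outside the supported span [%g, %g] nm",
                 what, x[1], x[length(x)]), call. = FALSE)
  }
  stats::approx(x, y, xout = xout, method = "linear", ties = "ordered")$y
}

check_grid <- function(grid, lo = 650, hi = 1050) {
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid)) {
    stop("wavelength grid must be numeric with no missing values", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (!is.null(lo) && (grid[1] < lo || grid[length(grid)] > hi)) {
    stop(sprintf("wavelength grid must lie within %g-%g nm", lo, hi), call. = FALSE)
  }
  invisible(grid)
}

same_grid <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) < 1e-9)
}
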