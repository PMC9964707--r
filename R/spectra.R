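#' Diffuse-reflectance acquisition
#'
#' One detected spectrum: a strictly increasing wavelength grid within the
#' probe's 650-1050 nm operating band, positive intensities in arbitrary
#' counts, and acquisition metadata (subject, group, limb, timepoint in days,
#' skin condition, role).
#'
#' @param grid wavelengths in nm.
#' @param intensity detected counts, all > 0, same length as `grid`.
#' @param meta named list of acquisition metadata; free-form, but the
#'   synthetic generator and pipeline use `subject`, `group`, `limb`,
#'   `timepoint`, `skin`, `role` and `id`.
#' @return An object of class `nirs_spectrum`.
#' @export
nirs_spectrum <- function(grid, intensity, meta = list()) {
  check_grid(grid)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(grid)) {
    stop("intensity and grid lengths differ", call. = FALSE)
  }
  if (anyNA(intensity) || any(intensity <= 0)) {
    stop("all intensities must be positive", call. = FALSE)
  }
  structure(list(grid = as.numeric(grid), intensity = intensity,
                 meta = as.list(meta)),
            class = "nirs_spectrum")
}

#' Incident (reference) spectrum
#'
#' The incident light \eqn{I_0(\lambda)} against which optical density is
#' computed; same grid and positivity contract as [nirs_spectrum()].
#'
#' @inheritParams nirs_spectrum
#' @return An object of class `nirs_reference`.
#' @export
reference_spectrum <- function(grid, intensity) {
  x <- nirs_spectrum(grid, intensity)
  class(x) <- c("nirs_reference", "nirs_spectrum")
  x
}

#' @export
print.nirs_spectrum <- function(x, ...) {
  m <- x$meta
  tag <- if (length(m)) paste0(" [", paste(sprintf("%s=%s", names(m),
                                                  vapply(m, format, "")),
                                           collapse = ", "), "]") else ""
  cat(sprintf("<%s> %d points, %g-%g nm%s\n", class(x)[1], length(x$grid),
              x$grid[1], x$grid[length(x$grid)], tag))
  invisible(x)
}
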