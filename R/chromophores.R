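#' Chromophore extinction-coefficient set
#'
#' Container for named absorbers with extinction coefficient curves
#' \eqn{\epsilon_i(\lambda)} on a shared wavelength grid. Values are in
#' natural-log (Napierian) basis, units mM^-1 cm^-1, so that
#' \eqn{OD = -\ln(I/I_0) = \sum_i \epsilon_i C_i \cdot DPF \cdot d + G}
#' holds without hidden log-base factors. A total-hemoglobin curve (`THb`)
#' is always derived as the pointwise sum of `HbO2` and `Hb` when both are
#' present.
#'
#' @param grid numeric vector of wavelengths in nm, strictly increasing.
#' @param epsilon numeric matrix, one column per chromophore (named), one row
#'   per grid point; all values must be >= 0.
#' @return An object of class `chromophore_set` with fields `names`, `grid`
#'   and `epsilon`.
#' @seealso [default_chromophores()], [extinction_at()]
#' @export
chromophore_set <- function(grid, epsilon) {
  check_grid(grid, lo = NULL)
  epsilon <- as.matrix(epsilon)
  if (is.null(colnames(epsilon)) || anyNA(colnames(epsilon))) {
    stop("epsilon must have one named column per chromophore", call. = FALSE)
  }
  if (nrow(epsilon) != length(grid)) {
    stop("epsilon must have one row per grid wavelength", call. = FALSE)
  }
  if (anyNA(epsilon) || any(epsilon < 0)) {
    stop("extinction coefficients must be defined and >= 0 on the full grid",
         call. = FALSE)
  }
  if (all(c("HbO2", "Hb") %in% colnames(epsilon)) &&
      !("THb" %in% colnames(epsilon))) {
    epsilon <- cbind(epsilon, THb = epsilon[, "HbO2"] + epsilon[, "Hb"])
  }
  structure(list(names = colnames(epsilon), grid = as.numeric(grid),
                 epsilon = epsilon),
            class = "chromophore_set")
}

#' Bundled hemoglobin extinction table
#'
#' Loads the packaged HbO2/Hb molar extinction table (650-1000 nm, natural-log
#' basis, mM^-1 cm^-1; provenance and basis are documented in the file
#' header). A custom table in the same format (one comment/header block, then
#' tab-separated `wavelength_nm`, one column per chromophore) can be
#' substituted via `path`.
#'
#' @param path optional path to an alternative extinction table.
#' @return A [chromophore_set()].
#' @export
default_chromophores <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hb_extinction.tsv",
                                package = "nirsox", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"wavelength_nm" %in% names(tab) || ncol(tab) < 2L) {
    stop("extinction table must have a 'wavelength_nm' column plus one column ",
         "per chromophore: ", path, call. = FALSE)
  }
  grid <- tab$wavelength_nm
  eps <- as.matrix(tab[setdiff(names(tab), "wavelength_nm")])
  chromophore_set(grid, eps)
}

#' Extinction coefficient of one chromophore at one wavelength
#'
#' Linear interpolation between bracketing grid points; exact on grid points.
#' No extrapolation: wavelengths outside the table span raise an error.
#'
#' @param set a [chromophore_set()].
#' @param name chromophore identifier (e.g. `"HbO2"`, `"Hb"`, `"THb"`).
#' @param wavelength wavelength(s) in nm, within the grid span.
#' @return Extinction coefficient(s) in mM^-1 cm^-1 (natural-log basis).
#' @export
extinction_at <- function(set, name, wavelength) {
  stopifnot(inherits(set, "chromophore_set"))
  if (length(name) != 1L || !name %in% set$names) {
    stop("unknown chromophore: ", paste(name, collapse = ", "),
         " (have: ", paste(set$names, collapse = ", "), ")", call. = FALSE)
  }
  interp_within(set$grid, set$epsilon[, name], wavelength,
                what = paste0("extinction of ", name))
}

#' @export
print.chromophore_set <- function(x, ...) {
  cat(sprintf("<chromophore_set> %s on %d wavelengths (%g-%g nm), mM^-1 cm^-1 (ln basis)\n",
              paste(x$names, collapse = ", "), length(x$grid),
              x$grid[1], x$grid[length(x$grid)]))
  invisible(x)
}
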