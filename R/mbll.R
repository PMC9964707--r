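#' Optical density of an acquisition
#'
#' \eqn{OD(\lambda) = -\ln(I(\lambda)/I_0(\lambda))}, pointwise on the shared
#' grid. Under the modified Beer-Lambert model this equals
#' \eqn{\mu_a(\lambda)\, DPF(\lambda)\, d + G}.
#'
#' @param spectrum a [nirs_spectrum()].
#' @param reference a [reference_spectrum()] on the same grid.
#' @return An object of class `od_spectrum` (`grid`, `od`, `meta`).
#' @export
compute_od <- function(spectrum, reference) {
  stopifnot(inherits(spectrum, "nirs_spectrum"), inherits(reference, "nirs_spectrum"))
  if (!same_grid(spectrum$grid, reference$grid)) {
    stop("spectrum and reference are on different wavelength grids", call. = FALSE)
  }
  if (any(spectrum$intensity <= 0) || any(reference$intensity <= 0)) {
    stop("optical density requires strictly positive intensities", call. = FALSE)
  }
  structure(list(grid = spectrum$grid,
                 od = log(reference$intensity) - log(spectrum$intensity),
                 meta = spectrum$meta),
            class = "od_spectrum")
}

snap_wavelengths <- function(grid, wavelengths, snap_tol) {
  idx <- vapply(wavelengths, function(w) which.min(abs(grid - w)), integer(1))
  off <- abs(grid[idx] - wavelengths)
  if (any(off > snap_tol)) {
    bad <- wavelengths[off > snap_tol][1]
    stop(sprintf("requested wavelength %g nm is farther than %g nm from any grid point",
                 bad, snap_tol), call. = FALSE)
  }
  idx
}

band_value <- function(grid, values, idx, band_halfwidth) {
  vapply(idx, function(i) {
    sel <- max(1L, i - band_halfwidth):min(length(grid), i + band_halfwidth)
    mean(values[sel])
  }, numeric(1))
}

#' Differential optical density between two timepoints
#'
#' \eqn{\Delta OD(\lambda) = OD(t_2,\lambda) - OD(t_1,\lambda)} at selected
#' analysis wavelengths. The differential removes the unknown geometry
#' constant G (assumed constant across the two acquisitions). Requested
#' wavelengths are snapped to the nearest spectrometer grid point within
#' `snap_tol`; optionally a boxcar band mean of `2*band_halfwidth + 1` grid
#' points around each snapped point is used instead of the single pixel.
#'
#' @param od_t1,od_t2 `od_spectrum` objects on the same grid (t1 = baseline).
#' @param wavelengths analysis wavelengths in nm (>= 2 for inversion;
#'   default 740 and 840 nm).
#' @param snap_tol maximum snap distance in nm.
#' @param band_halfwidth boxcar half-width in grid points (0 = single pixel).
#' @return An object of class `delta_od` recording the requested and the
#'   actually used grid wavelengths, the \eqn{\Delta OD} values, and the
#'   timepoint pair.
#' @export
delta_od <- function(od_t1, od_t2, wavelengths = c(740, 840),
                     snap_tol = 2, band_halfwidth = 0) {
  stopifnot(inherits(od_t1, "od_spectrum"), inherits(od_t2, "od_spectrum"))
  if (!same_grid(od_t1$grid, od_t2$grid)) {
    stop("the two OD spectra are on different wavelength grids", call. = FALSE)
  }
  t1 <- od_t1$meta$timepoint %||% NA
  t2 <- od_t2$meta$timepoint %||% NA
  r1 <- od_t1$meta$role %||% NA
  r2 <- od_t2$meta$role %||% NA
  if (!is.na(t1) && !is.na(t2) && identical(t1, t2) && identical(r1, r2) &&
      !is.na(r1)) {
    stop("differential measurement requires two distinct acquisitions", call. = FALSE)
  }
  idx <- snap_wavelengths(od_t1$grid, wavelengths, snap_tol)
  d1 <- band_value(od_t1$grid, od_t1$od, idx, band_halfwidth)
  d2 <- band_value(od_t2$grid, od_t2$od, idx, band_halfwidth)
  bands <- lapply(idx, function(i) {
    od_t1$grid[max(1L, i - band_halfwidth):min(length(od_t1$grid),
                                               i + band_halfwidth)]
  })
  structure(list(requested = wavelengths, wavelengths = od_t1$grid[idx],
                 dod = d2 - d1, t1 = t1, t2 = t2,
                 band_halfwidth = band_halfwidth, bands = bands),
            class = "delta_od")
}

#' Invert differential optical densities to concentration changes
#'
#' Solves \eqn{\Delta OD(\lambda_j) = \sum_i \epsilon_i(\lambda_j)\,
#' \Delta C_i \cdot DPF(\lambda_j)\, d} for the chromophore concentration
#' changes. Each row is first divided by its own \eqn{DPF(\lambda_j)\, d}
#' (d converted mm to cm), leaving the plain extinction system
#' \eqn{E\,\Delta C = y}. With exactly two wavelengths and two chromophores
#' the 2x2 system is solved in closed form via the adjugate; with more
#' wavelengths an ordinary least-squares solution is returned. The condition
#' number of E is reported and a conditioning error raised above `cond_cap`.
#'
#' @param dod a [delta_od()] with at least two wavelengths.
#' @param geom a [probe_geometry()] whose DPF table covers the wavelengths.
#' @param chrom a [chromophore_set()].
#' @param chromophores chromophores to unmix (default oxy/deoxyhemoglobin).
#' @param method `"auto"` (closed form when square, else least squares),
#'   `"closed_form"`, or `"least_squares"`.
#' @param cond_cap maximum tolerated condition number.
#' @return An object of class `mbll_fit` with the concentration changes in
#'   mM (`coef()`), the wavelengths used, the condition number, and the
#'   scaled system for `fitted()`/`residuals()` (on the \eqn{\Delta OD}
#'   scale).
#' @export
solve_concentration_changes <- function(dod, geom, chrom,
                                        chromophores = c("HbO2", "Hb"),
                                        method = c("auto", "closed_form",
                                                   "least_squares"),
                                        cond_cap = 1e8) {
  stopifnot(inherits(dod, "delta_od"))
  method <- match.arg(method)
  wl <- dod$wavelengths
  if (length(wl) < 2L) {
    stop("at least two wavelengths are needed for the inversion", call. = FALSE)
  }
  # with band extraction the extinction and DPF entering each row are band
  # means, matching the band-averaged delta-OD (DPF is extended flat at the
  # edges of its table across the few-nm band)
  banded <- (dod$band_halfwidth %||% 0) > 0 && !is.null(dod$bands)
  eps_row <- function(nm) {
    if (banded) {
      vapply(dod$bands, function(b) mean(extinction_at(chrom, nm, b)),
             numeric(1))
    } else {
      extinction_at(chrom, nm, wl)
    }
  }
  E <- vapply(chromophores, eps_row, numeric(length(wl)))
  E <- matrix(E, nrow = length(wl),
              dimnames = list(NULL, chromophores))
  dpf_row <- if (banded && length(geom$dpf) > 1L) {
    vapply(dod$bands, function(b) {
      mean(stats::approx(geom$dpf_wavelength, geom$dpf, xout = b,
                         rule = 2, ties = "ordered")$y)
    }, numeric(1))
  } else {
    dpf_at(geom, wl)
  }
  path <- dpf_row * (geom$d / 10)   # DPF * d in cm
  y <- dod$dod / path
  sv <- svd(E, nu = 0, nv = 0)$d
  cond <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > cond_cap) {
    stop(sprintf("ill-conditioned extinction matrix at wavelengths %s (condition number %.3g)",
                 paste(signif(wl, 6), collapse = ", "), cond), call. = FALSE)
  }
  if (method == "closed_form" &&
      !(length(wl) == 2L && length(chromophores) == 2L)) {
    stop("closed_form requires exactly two wavelengths and two chromophores",
         call. = FALSE)
  }
  if (method %in% c("auto", "closed_form") &&
      length(wl) == 2L && length(chromophores) == 2L) {
    det2 <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
    coefs <- c(E[2, 2] * y[1] - E[1, 2] * y[2],
               -E[2, 1] * y[1] + E[1, 1] * y[2]) / det2
    used <- "closed_form"
  } else {
    coefs <- qr.coef(qr(E), y)
    used <- "least_squares"
  }
  coefs <- stats::setNames(as.numeric(coefs), chromophores)
  structure(list(coefficients = coefs, wavelengths = wl,
                 condition_number = cond, method = used,
                 t1 = dod$t1, t2 = dod$t2,
                 E = E, path = path, dod = dod$dod),
            class = "mbll_fit")
}

#' @export
coef.mbll_fit <- function(object, ...) object$coefficients

#' @export
fitted.mbll_fit <- function(object, ...) {
  as.numeric(object$E %*% object$coefficients) * object$path
}

#' @export
residuals.mbll_fit <- function(object, ...) object$dod - fitted(object)

#' @export
print.mbll_fit <- function(x, ...) {
  cat(sprintf("<mbll_fit> %s at %s nm (condition number %.3g)\n", x$method,
              paste(signif(x$wavelengths, 6), collapse = "/"),
              x$condition_number))
  print(signif(x$coefficients, 6))
  cat("  (concentration changes in mM)\n")
  invisible(x)
}

#' Semi-quantitative tissue oxygen saturation
#'
#' CW-NIRS measures only concentration *changes*; an absolute saturation
#' requires an assumed baseline state. Given baseline saturation and total
#' hemoglobin, the reconstructed concentrations are
#' \eqn{HbO_2 = s_0\,THb_0 + \Delta HbO_2} and
#' \eqn{Hb = (1-s_0)\,THb_0 + \Delta Hb}, and
#' \eqn{StO_2 = 100\, HbO_2 / (HbO_2 + Hb)}. Negative reconstructed
#' concentrations (possible under noise) are clamped to zero and flagged.
#' The estimate is flagged semi-quantitative: it is exact only insofar as the
#' baseline assumption holds.
#'
#' @param dc an [solve_concentration_changes()] fit, or a named vector with
#'   `HbO2` and `Hb` concentration changes in mM.
#' @param baseline_sto2 assumed baseline saturation, fraction in [0, 1].
#' @param baseline_thb assumed baseline total hemoglobin in mM (> 0).
#' @return An object of class `sto2_estimate` with `sto2` in percent, the
#'   reconstructed concentrations, the baseline assumption, and flags.
#' @export
compute_sto2 <- function(dc, baseline_sto2 = 0.70, baseline_thb = 0.1) {
  if (inherits(dc, "mbll_fit")) dc <- coef(dc)
  if (!all(c("HbO2", "Hb") %in% names(dc))) {
    stop("dc must provide HbO2 and Hb concentration changes", call. = FALSE)
  }
  if (baseline_thb <= 0) stop("baseline_thb must be > 0", call. = FALSE)
  if (baseline_sto2 < 0 || baseline_sto2 > 1) {
    stop("baseline_sto2 must lie in [0, 1]", call. = FALSE)
  }
  hbo2 <- baseline_sto2 * baseline_thb + dc[["HbO2"]]
  hb <- (1 - baseline_sto2) * baseline_thb + dc[["Hb"]]
  clamped <- hbo2 < 0 || hb < 0
  hbo2 <- max(hbo2, 0)
  hb <- max(hb, 0)
  if (hbo2 + hb <= 1e-9 * baseline_thb) {
    stop("saturation undefined: total hemoglobin is zero after clamping",
         call. = FALSE)
  }
  structure(list(sto2 = 100 * hbo2 / (hbo2 + hb),
                 hbo2 = hbo2, hb = hb,
                 baseline_sto2 = baseline_sto2, baseline_thb = baseline_thb,
                 delta = c(HbO2 = dc[["HbO2"]], Hb = dc[["Hb"]]),
                 clamped = clamped, semi_quantitative = TRUE),
            class = "sto2_estimate")
}

#' @export
print.sto2_estimate <- function(x, ...) {
  cat(sprintf("StO2 = %.2f%% (semi-quantitative; baseline %.0f%% / %.3g mM%s)\n",
              x$sto2, 100 * x$baseline_sto2, x$baseline_thb,
              if (x$clamped) "; clamped" else ""))
  invisible(x)
}

#' Saturation time series for one subject and limb
#'
#' Runs the differential chain for every timepoint of one subject/limb:
#' OD against the study reference, \eqn{\Delta OD} from the pre-surgery
#' baseline acquisition to the timepoint, inversion to concentration
#' changes, and conversion to semi-quantitative saturation under the
#' configured baseline assumption. When the study carries a dedicated
#' baseline acquisition (role `"baseline"`) it is the differential
#' reference; otherwise the day-0 record serves as its own baseline, in
#' which case day 0 maps to the baseline saturation exactly.
#'
#' @param study a `nirs_study` (simulated or read from disk).
#' @param subject,limb which series to extract.
#' @param geom analysis [probe_geometry()]; defaults to the study's.
#' @param chrom a [chromophore_set()].
#' @param wavelengths analysis wavelength pair in nm.
#' @param baseline_sto2,baseline_thb baseline assumption for [compute_sto2()].
#' @param band_halfwidth boxcar half-width in grid points for the band mean
#'   around each analysis wavelength (default 2, i.e. a 5-point band).
#' @param snap_tol wavelength snap tolerance in nm.
#' @return data.frame with one row per timepoint: metadata, concentration
#'   changes in mM, `sto2` percent, condition number and clamp flag.
#' @export
sto2_timeseries <- function(study, subject, limb,
                            geom = NULL, chrom = default_chromophores(),
                            wavelengths = c(740, 840),
                            baseline_sto2 = 0.70, baseline_thb = 0.1,
                            band_halfwidth = 2, snap_tol = 2) {
  stopifnot(inherits(study, "nirs_study"))
  geom <- geom %||% study$geometry
  recs <- Filter(function(r) identical(r$spectrum$meta$subject, subject) &&
                   identical(r$spectrum$meta$limb, limb), study$records)
  if (!length(recs)) stop("no acquisitions for ", subject, "/", limb, call. = FALSE)
  roles <- vapply(recs, function(r) r$spectrum$meta$role %||% "measure", "")
  tps <- vapply(recs, function(r) as.numeric(r$spectrum$meta$timepoint), 0)
  base_rec <- NULL
  if (any(roles == "baseline")) {
    base_rec <- recs[[which(roles == "baseline")[1]]]
  } else if (any(tps == min(tps) & tps == 0)) {
    base_rec <- recs[[which(tps == 0)[1]]]
  }
  if (is.null(base_rec)) {
    stop("baseline missing: no pre-surgery (day 0) acquisition for ",
         subject, "/", limb, call. = FALSE)
  }
  od_base <- compute_od(base_rec$spectrum, study$reference)
  meas <- recs[roles == "measure"]
  meas <- meas[order(vapply(meas, function(r)
    as.numeric(r$spectrum$meta$timepoint), 0))]
  rows <- lapply(meas, function(r) {
    m <- r$spectrum$meta
    if (identical(m$id, base_rec$spectrum$meta$id)) {
      est <- compute_sto2(c(HbO2 = 0, Hb = 0), baseline_sto2, baseline_thb)
      dc <- c(HbO2 = 0, Hb = 0); cond <- NA_real_
    } else {
      od_t <- compute_od(r$spectrum, study$reference)
      dod <- delta_od(od_base, od_t, wavelengths = wavelengths,
                      snap_tol = snap_tol, band_halfwidth = band_halfwidth)
      fit <- solve_concentration_changes(dod, geom, chrom)
      dc <- coef(fit); cond <- fit$condition_number
      est <- compute_sto2(fit, baseline_sto2, baseline_thb)
    }
    data.frame(subject = m$subject, group = m$group %||% NA_character_,
               limb = m$limb, timepoint = as.numeric(m$timepoint),
               skin = m$skin %||% NA_character_,
               dHbO2_mM = dc[["HbO2"]], dHb_mM = dc[["Hb"]],
               sto2 = est$sto2, condition_number = cond,
               clamped = est$clamped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
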