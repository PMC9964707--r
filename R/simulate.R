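#' Forward-simulate one diffuse-reflectance spectrum
#'
#' Evaluates the modified Beer-Lambert forward model
#' \deqn{I(\lambda) = I_0(\lambda)\, e^{-(\mu_a(\lambda)\, DPF(\lambda)\, d + G)}}
#' with \eqn{\mu_a(\lambda) = \sum_i \epsilon_i(\lambda) C_i} over the
#' chromophores present in `state`. `d` is taken from the geometry in mm and
#' converted to cm to match the mM^-1 cm^-1 extinction units. Instrument
#' noise, when requested, multiplies each intensity by an independent
#' Gaussian factor `1 + N(0, noise_rel)` truncated to stay positive.
#'
#' @param state named numeric vector of chromophore concentrations in mM
#'   (e.g. `c(HbO2 = 0.07, Hb = 0.03)`), all >= 0.
#' @param geom a [probe_geometry()] whose DPF table covers the reference
#'   grid (see [broadband_dpf()]).
#' @param chrom a [chromophore_set()] covering the reference grid.
#' @param ref a [reference_spectrum()] giving \eqn{I_0(\lambda)}.
#' @param noise_rel relative noise scale (fraction, >= 0; 0 = noise-free).
#' @param seed optional integer; if given, the RNG is seeded for this draw.
#' @param meta metadata list attached to the returned spectrum.
#' @return A [nirs_spectrum()] on the reference grid.
#' @export
simulate_spectrum <- function(state, geom, chrom, ref, noise_rel = 0,
                              seed = NULL, meta = list()) {
  stopifnot(inherits(geom, "probe_geometry"), inherits(chrom, "chromophore_set"),
            inherits(ref, "nirs_reference"))
  if (is.null(names(state)) || anyNA(names(state))) {
    stop("state must be a named concentration vector (mM)", call. = FALSE)
  }
  if (any(state < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  grid <- ref$grid
  if (grid[1] < chrom$grid[1] || grid[length(grid)] > chrom$grid[length(chrom$grid)]) {
    stop("reference grid extends beyond the chromophore table span", call. = FALSE)
  }
  mu_a <- rep(0, length(grid))
  for (nm in names(state)) {
    mu_a <- mu_a + extinction_at(chrom, nm, grid) * state[[nm]]
  }
  att <- mu_a * dpf_at(geom, grid) * (geom$d / 10) + geom$g
  intensity <- ref$intensity * exp(-att)
  if (noise_rel > 0) {
    if (!is.null(seed)) set.seed(seed)
    fac <- pmax(1 + stats::rnorm(length(grid), 0, noise_rel), 1e-8)
    intensity <- intensity * fac
  }
  nirs_spectrum(grid, intensity, meta = meta)
}

#' Default per-group saturation trajectories
#'
#' The planted group effects used by [study_design()] when none are given:
#' per-timepoint saturation offsets from baseline and between-subject
#' standard deviations for the Mg, Ti and sham groups.  The Mg group
#' carries strongly inflated between-subject spread at days 1 and 3 (the
#' early gas-cavity phase of magnesium corrosion); Ti and sham carry a
#' modest post-surgical dip with small, constant spread.
#'
#' @param timepoints numeric vector of study days.
#' @return Named list (one element per group) of lists with `sto2_offset`
#'   and `sto2_sd`, each a named vector over `timepoints`.
#' @export
default_group_effects <- function(timepoints) {
  tp <- as.character(timepoints)
  eff <- list(
    Mg = list(
      sto2_offset = c("0" = 0, "1" = -0.02, "3" = -0.015, "7" = -0.01,
                      "14" = -0.005, "45" = 0),
      sto2_sd = c("0" = 0, "1" = 0.12, "3" = 0.12, "7" = 0.03,
                  "14" = 0.02, "45" = 0.01)),
    Ti = list(
      sto2_offset = c("0" = 0, "1" = -0.05, "3" = -0.06, "7" = -0.06,
                      "14" = -0.055, "45" = -0.05),
      sto2_sd = c("0" = 0, "1" = 0.01, "3" = 0.01, "7" = 0.01,
                  "14" = 0.01, "45" = 0.01)),
    sham = list(
      sto2_offset = c("0" = 0, "1" = -0.04, "3" = -0.045, "7" = -0.04,
                      "14" = -0.04, "45" = -0.035),
      sto2_sd = c("0" = 0, "1" = 0.01, "3" = 0.01, "7" = 0.01,
                  "14" = 0.01, "45" = 0.01)))
  lapply(eff, function(e) lapply(e, function(v) {
    if (!all(tp %in% names(v))) stop("effect trajectory must cover every timepoint",
                                     call. = FALSE)
    v[tp]
  }))
}

#' Longitudinal study design
#'
#' Parameters of the synthetic implant study: three groups (Mg alloy,
#' titanium, sham surgery), both hindlimbs implanted per animal, acquisitions
#' pre-operatively (day 0) and on days 1, 3, 7, 14 and 45. Per-group
#' hemodynamic trajectories are expressed as a tissue-saturation offset and a
#' between-animal standard deviation per timepoint; the defaults plant the
#' qualitative study pattern — strongly inflated early (days 1-3) variability
#' in the Mg group that resolves by day 45, a moderate persistent saturation
#' deficit in Ti and sham animals, and one Ti animal developing a skin rash
#' from day 3 with persistently elevated saturation. Baseline saturation
#' (0.70) and total hemoglobin (0.1 mM) for rat hindlimb tissue are
#' configuration defaults, not measured facts.
#'
#' @param subjects_per_group named integer vector of animals per group.
#' @param timepoints acquisition days, non-negative and sorted.
#' @param baseline_sto2 baseline tissue oxygen saturation, fraction in [0,1].
#' @param baseline_thb baseline total hemoglobin in mM (> 0).
#' @param effects per-group list with `sto2_offset` and `sto2_sd`, each a
#'   vector named by timepoint (fractions); defaults as described above.
#' @param rash_subject logical: plant the skin-rash case.
#' @param rash_group,rash_effect,rash_onset group hosting the rash animal,
#'   saturation elevation (fraction), and onset day.
#' @param noise_rel relative instrument noise per wavelength (default 1%).
#' @param grid spectrometer wavelength grid in nm.
#' @param g_range range of the per-limb geometry constant G, drawn uniformly.
#' @param g_jitter_sd optional per-timepoint jitter of G (default 0,
#'   matching the differential-measurement assumption that G is constant);
#'   set > 0 to probe violations of that assumption.
#' @param baseline_replicate logical: emit a separate pre-surgery baseline
#'   acquisition per limb in addition to the day-0 measurement record (the
#'   study protocol took two day-0 measurements).
#' @param seed integer RNG seed for the whole simulated study.
#' @return An object of class `study_design`.
#' @export
study_design <- function(subjects_per_group = c(Mg = 7L, Ti = 4L, sham = 4L),
                         timepoints = c(0, 1, 3, 7, 14, 45),
                         baseline_sto2 = 0.70,
                         baseline_thb = 0.1,
                         effects = NULL,
                         rash_subject = TRUE,
                         rash_group = "Ti",
                         rash_effect = 0.10,
                         rash_onset = 3,
                         noise_rel = 0.01,
                         grid = seq(650, 1000, by = 2),
                         g_range = c(0.5, 2.5),
                         g_jitter_sd = 0,
                         baseline_replicate = TRUE,
                         seed = 1L) {
  if (is.unsorted(timepoints, strictly = TRUE) || any(timepoints < 0)) {
    stop("timepoints must be sorted, distinct and non-negative", call. = FALSE)
  }
  if (baseline_sto2 < 0 || baseline_sto2 > 1) {
    stop("baseline_sto2 must lie in [0, 1]", call. = FALSE)
  }
  if (baseline_thb <= 0) stop("baseline_thb must be > 0", call. = FALSE)
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  check_grid(grid)
  effects <- effects %||% default_group_effects(timepoints)
  if (!setequal(names(effects), names(subjects_per_group))) {
    stop("effects must name exactly the study groups", call. = FALSE)
  }
  if (rash_subject && !rash_group %in% names(subjects_per_group)) {
    stop("rash_group must be one of the study groups", call. = FALSE)
  }
  structure(list(subjects_per_group = subjects_per_group,
                 groups = names(subjects_per_group),
                 timepoints = timepoints,
                 baseline_sto2 = baseline_sto2, baseline_thb = baseline_thb,
                 effects = effects,
                 rash_subject = rash_subject, rash_group = rash_group,
                 rash_effect = rash_effect, rash_onset = rash_onset,
                 noise_rel = noise_rel, grid = grid,
                 g_range = g_range, g_jitter_sd = g_jitter_sd,
                 baseline_replicate = baseline_replicate,
                 seed = as.integer(seed)),
            class = "study_design")
}

# smooth halogen-like lamp shape in arbitrary counts
default_reference <- function(grid) {
  reference_spectrum(grid, 5e4 * exp(-((grid - 880) / 260)^2) + 5e3)
}

#' Simulate a full longitudinal study
#'
#' Draws, for each animal and timepoint, a true hemodynamic state from the
#' group trajectory (baseline saturation + group/timepoint offset + a random
#' effect with the group/timepoint standard deviation, shared by both limbs),
#' then forward-simulates one acquisition per limb with a per-limb geometry
#' constant G held fixed across timepoints. The day-0 state is the subject's
#' baseline; with `baseline_replicate = TRUE` each limb also gets a separate
#' pre-surgery baseline acquisition of that same state (independent noise),
#' which the analysis pipeline uses as the differential reference. Ground
#' truth (concentrations and saturation) is stored alongside every record.
#'
#' @param design a [study_design()].
#' @param geom analysis [probe_geometry()]; its DPF table is extended over
#'   the spectrometer grid via [broadband_dpf()] for forward simulation.
#' @param chrom a [chromophore_set()]; defaults to the bundled table.
#' @return An object of class `nirs_study`: list with `design`, `geometry`
#'   (analysis geometry), `reference`, and `records` (each a list with
#'   `spectrum`, `truth` = named concentrations in mM, `sto2_true` in
#'   percent).
#' @export
simulate_study <- function(design = study_design(),
                           geom = probe_geometry(),
                           chrom = default_chromophores()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  ref <- default_reference(design$grid)
  sim_geom <- broadband_dpf(geom, design$grid)
  thb <- design$baseline_thb
  rash_id <- if (design$rash_subject) paste0(design$rash_group, 1) else NA_character_
  records <- list()
  for (grp in design$groups) {
    eff <- design$effects[[grp]]
    for (s in seq_len(design$subjects_per_group[[grp]])) {
      subj <- paste0(grp, s)
      g_limb <- stats::setNames(stats::runif(2, design$g_range[1], design$g_range[2]),
                                c("left", "right"))
      base_sto2 <- design$baseline_sto2
      for (tp in design$timepoints) {
        key <- as.character(tp)
        sto2 <- base_sto2 + eff$sto2_offset[[key]] +
          stats::rnorm(1, 0, eff$sto2_sd[[key]])
        if (!is.na(rash_id) && subj == rash_id && tp >= design$rash_onset) {
          sto2 <- sto2 + design$rash_effect
        }
        sto2 <- min(max(sto2, 0.02), 0.98)
        state <- c(HbO2 = sto2 * thb, Hb = (1 - sto2) * thb)
        skin <- if (!is.na(rash_id) && subj == rash_id && tp >= design$rash_onset)
          "rash" else "normal"
        for (limb in c("left", "right")) {
          g_now <- g_limb[[limb]] +
            if (design$g_jitter_sd > 0) stats::rnorm(1, 0, design$g_jitter_sd) else 0
          geom_now <- probe_geometry(sim_geom$d,
                                     stats::setNames(sim_geom$dpf,
                                                     sim_geom$dpf_wavelength),
                                     g = g_now)
          if (tp == design$timepoints[1] && design$baseline_replicate) {
            id0 <- sprintf("%s_%s_baseline", subj, limb)
            sp0 <- simulate_spectrum(state, geom_now, chrom, ref,
                                     noise_rel = design$noise_rel,
                                     meta = list(id = id0, subject = subj,
                                                 group = grp, limb = limb,
                                                 timepoint = tp, skin = skin,
                                                 role = "baseline"))
            records[[id0]] <- list(spectrum = sp0, truth = state,
                                   sto2_true = 100 * sto2)
          }
          id <- sprintf("%s_%s_t%g", subj, limb, tp)
          sp <- simulate_spectrum(state, geom_now, chrom, ref,
                                  noise_rel = design$noise_rel,
                                  meta = list(id = id, subject = subj,
                                              group = grp, limb = limb,
                                              timepoint = tp, skin = skin,
                                              role = "measure"))
          records[[id]] <- list(spectrum = sp, truth = state,
                                sto2_true = 100 * sto2)
        }
      }
    }
  }
  structure(list(design = design, geometry = geom, reference = ref,
                 records = records),
            class = "nirs_study")
}

#' Acquisition manifest of a study
#'
#' @param study a `nirs_study`.
#' @return data.frame with one row per acquisition (id, subject, group, limb,
#'   timepoint, skin, role) plus the true saturation when truth is present.
#' @export
study_manifest <- function(study) {
  stopifnot(inherits(study, "nirs_study"))
  rows <- lapply(study$records, function(r) {
    m <- r$spectrum$meta
    data.frame(id = m$id, subject = m$subject, group = m$group, limb = m$limb,
               timepoint = m$timepoint, skin = m$skin, role = m$role,
               sto2_true = if (is.null(r$sto2_true)) NA_real_ else r$sto2_true,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.nirs_study <- function(x, ...) {
  man <- study_manifest(x)
  cat(sprintf("<nirs_study> %d acquisitions: %d subjects, groups {%s}, days {%s}\n",
              nrow(man), length(unique(man$subject)),
              paste(unique(man$group), collapse = ", "),
              paste(sort(unique(man$timepoint)), collapse = ", ")))
  if (all(is.na(man$sto2_true))) cat("  blinded: no ground truth attached\n")
  invisible(x)
}
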