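grid_ <- seq(700, 900, by = 2)
chrom_ <- tiny_chrom()
ref_ <- flat_ref(grid_)
geom_ <- probe_geometry()
bb_ <- broadband_dpf(geom_, grid_)

sim_pair <- function(c1, c2, g = 0, g2 = g) {
  ga <- bb_; ga$g <- g
  gb <- bb_; gb$g <- g2
  list(od1 = compute_od(simulate_spectrum(c1, ga, chrom_, ref_), ref_),
       od2 = compute_od(simulate_spectrum(c2, gb, chrom_, ref_), ref_))
}

test_that("optical density identities hold", {
  sp <- nirs_spectrum(grid_, ref_$intensity)
  expect_equal(compute_od(sp, ref_)$od, rep(0, length(grid_)))
  sp2 <- nirs_spectrum(grid_, ref_$intensity * exp(-2))
  expect_equal(compute_od(sp2, ref_)$od, rep(2, length(grid_)), tolerance = 1e-12)
  expect_error(compute_od(nirs_spectrum(grid_ + 1, ref_$intensity), ref_),
               "different wavelength grids")
})

test_that("noise-free OD equals the forward attenuation term by term", {
  ga <- bb_; ga$g <- 1.3
  state <- c(HbO2 = 0.06, Hb = 0.04)
  od <- compute_od(simulate_spectrum(state, ga, chrom_, ref_), ref_)
  mu_a <- extinction_at(chrom_, "HbO2", grid_) * 0.06 +
    extinction_at(chrom_, "Hb", grid_) * 0.04
  expect_equal(od$od, mu_a * dpf_at(bb_, grid_) * 0.8 + 1.3, tolerance = 1e-12)
})

test_that("delta-OD is zero for identical acquisitions and invariant to the shared G", {
  p <- sim_pair(c(HbO2 = 0.07, Hb = 0.03), c(HbO2 = 0.07, Hb = 0.03))
  expect_equal(delta_od(p$od1, p$od2, c(740, 840))$dod, c(0, 0))
  # the geometry constant shared by both acquisitions drops out entirely:
  # a pair measured with G = 0 and a pair measured with G = 5 give the same
  # delta-OD, and zero for equal concentrations
  c1 <- c(HbO2 = 0.07, Hb = 0.03); c2 <- c(HbO2 = 0.08, Hb = 0.025)
  d_g0 <- delta_od(sim_pair(c1, c2, g = 0)$od1, sim_pair(c1, c2, g = 0)$od2,
                   c(740, 840))
  d_g5 <- delta_od(sim_pair(c1, c2, g = 5)$od1, sim_pair(c1, c2, g = 5)$od2,
                   c(740, 840))
  expect_equal(d_g0$dod, d_g5$dod, tolerance = 1e-12)
  p2 <- sim_pair(c1, c1, g = 5)
  expect_equal(delta_od(p2$od1, p2$od2, c(740, 840))$dod, c(0, 0),
               tolerance = 1e-12)
})

test_that("delta-OD matches the extinction-weighted concentration change", {
  c1 <- c(HbO2 = 0.065, Hb = 0.035)
  c2 <- c(HbO2 = 0.072, Hb = 0.031)
  p <- sim_pair(c1, c2, g = 2.2)
  wl <- c(740, 780, 840)
  dod <- delta_od(p$od1, p$od2, wl)
  expected <- (extinction_at(chrom_, "HbO2", wl) * (c2[["HbO2"]] - c1[["HbO2"]]) +
                 extinction_at(chrom_, "Hb", wl) * (c2[["Hb"]] - c1[["Hb"]])) *
    dpf_at(bb_, wl) * 0.8
  expect_equal(dod$dod, unname(expected), tolerance = 1e-12)
})

test_that("wavelength snapping records grid points and enforces the tolerance", {
  p <- sim_pair(c(HbO2 = 0.07, Hb = 0.03), c(HbO2 = 0.08, Hb = 0.02))
  dod <- delta_od(p$od1, p$od2, c(740.6, 840.8))
  expect_equal(dod$wavelengths, c(740, 840))   # snapped to nearest grid point
  expect_error(delta_od(p$od1, p$od2, c(745, 840), snap_tol = 0.5),
               "farther than")
})

test_that("inversion recovers planted concentration changes exactly", {
  dc <- c(HbO2 = 0.005, Hb = -0.003)
  c1 <- c(HbO2 = 0.07, Hb = 0.03)
  p <- sim_pair(c1, c1 + dc, g = 1.1)
  fit <- solve_concentration_changes(delta_od(p$od1, p$od2, c(740, 840)),
                                     geom_, chrom_)
  expect_lt(max(abs(coef(fit) - dc)), 1e-9)
  expect_equal(fit$method, "closed_form")
  expect_gt(fit$condition_number, 0)
  # residuals of an exactly determined system vanish
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("homogeneous system gives zero changes and linearity holds", {
  p <- sim_pair(c(HbO2 = 0.07, Hb = 0.03), c(HbO2 = 0.07, Hb = 0.03))
  dod <- delta_od(p$od1, p$od2, c(740, 840))
  expect_equal(unname(coef(solve_concentration_changes(dod, geom_, chrom_))),
               c(0, 0))
  # doubling delta-OD doubles both concentration changes
  dc <- c(HbO2 = 0.004, Hb = -0.002)
  p2 <- sim_pair(c(HbO2 = 0.07, Hb = 0.03), c(HbO2 = 0.07, Hb = 0.03) + dc)
  dod1 <- delta_od(p2$od1, p2$od2, c(740, 840))
  dod2 <- dod1; dod2$dod <- 2 * dod1$dod
  f1 <- solve_concentration_changes(dod1, geom_, chrom_)
  f2 <- solve_concentration_changes(dod2, geom_, chrom_)
  expect_equal(coef(f2), 2 * coef(f1), tolerance = 1e-12)
})

test_that("closed-form and least-squares solutions agree, and wavelength order is irrelevant", {
  set.seed(10)
  for (i in 1:25) {
    dod <- structure(list(requested = c(740, 840), wavelengths = c(740, 840),
                          dod = rnorm(2, 0, 0.1), t1 = NA, t2 = NA,
                          band_halfwidth = 0, bands = NULL),
                     class = "delta_od")
    f_cf <- solve_concentration_changes(dod, geom_, chrom_,
                                        method = "closed_form")
    f_ls <- solve_concentration_changes(dod, geom_, chrom_,
                                        method = "least_squares")
    expect_equal(coef(f_cf), coef(f_ls), tolerance = 1e-12)
    dod_r <- dod
    dod_r$wavelengths <- rev(dod$wavelengths)
    dod_r$dod <- rev(dod$dod)
    f_r <- solve_concentration_changes(dod_r, geom_, chrom_)
    expect_equal(coef(f_r), coef(f_cf), tolerance = 1e-12)
  }
})

test_that("overdetermined inversion matches the planted truth on noise-free data", {
  dc <- c(HbO2 = 0.005, Hb = -0.003)
  c1 <- c(HbO2 = 0.07, Hb = 0.03)
  p <- sim_pair(c1, c1 + dc, g = 0.4)
  wl <- seq(710, 890, by = 6)   # 31 wavelengths
  fit <- solve_concentration_changes(delta_od(p$od1, p$od2, wl), bb_, chrom_)
  expect_equal(fit$method, "least_squares")
  expect_lt(max(abs(coef(fit) - dc)), 1e-9)
})

test_that("near-singular extinction systems raise a conditioning error", {
  p <- sim_pair(c(HbO2 = 0.07, Hb = 0.03), c(HbO2 = 0.08, Hb = 0.02))
  dod <- delta_od(p$od1, p$od2, c(800, 800.4), snap_tol = 2)
  # both requested wavelengths snap to neighbouring points: nearly collinear rows
  expect_error(solve_concentration_changes(dod, geom_, chrom_, cond_cap = 100),
               "ill-conditioned")
})

test_that("saturation anchors and baseline arithmetic are exact", {
  est0 <- compute_sto2(c(HbO2 = 0, Hb = 0), 0.70, 0.1)
  expect_equal(est0$sto2, 70)
  expect_true(est0$semi_quantitative)
  est <- compute_sto2(c(HbO2 = 0.01, Hb = -0.01), 0.70, 0.1)
  expect_equal(est$sto2, 80)
  for (x in c(0.01, 0.05, 0.2)) {
    expect_equal(compute_sto2(c(HbO2 = x - 0.07, Hb = x - 0.03), 0.7, 0.1)$sto2, 50)
    expect_equal(compute_sto2(c(HbO2 = x - 0.07, Hb = -0.03), 0.7, 0.1)$sto2, 100)
    expect_equal(compute_sto2(c(HbO2 = -0.07, Hb = x - 0.03), 0.7, 0.1)$sto2, 0)
  }
})

test_that("negative reconstructed concentrations are clamped and flagged", {
  est <- compute_sto2(c(HbO2 = -0.5, Hb = 0.01), 0.70, 0.1)
  expect_true(est$clamped)
  expect_equal(est$sto2, 0)
  expect_error(compute_sto2(c(HbO2 = -0.07, Hb = -0.03), 0.70, 0.1),
               "undefined")
})

test_that("a constant noise-free series recovers the baseline at every timepoint", {
  st <- simulate_study(null_design(noise_rel = 0, seed = 12,
                                   subjects = c(Mg = 1L),
                                   timepoints = c(0, 1, 3, 7)))
  ts <- sto2_timeseries(st, "Mg1", "left", chrom = default_chrom)
  expect_equal(ts$sto2, rep(70, 4), tolerance = 1e-9)
  expect_equal(ts$dHbO2_mM, rep(0, 4), tolerance = 1e-12)
})

test_that("noise-free planted trajectories are recovered through the full chain", {
  des <- study_design(subjects_per_group = c(Mg = 2L), rash_subject = FALSE,
                      effects = list(Mg = list(
                        sto2_offset = c("0" = 0, "1" = -0.1, "3" = 0.05,
                                        "7" = -0.02, "14" = 0.01, "45" = 0),
                        sto2_sd = c("0" = 0, "1" = 0.05, "3" = 0.05,
                                    "7" = 0.02, "14" = 0.01, "45" = 0.01))),
                      noise_rel = 0, seed = 13)
  st <- simulate_study(des)
  for (limb in c("left", "right")) {
    # single-pixel extraction: exact
    ts0 <- sto2_timeseries(st, "Mg1", limb, chrom = default_chrom,
                           band_halfwidth = 0)
    truth <- vapply(sprintf("Mg1_%s_t%g", limb, ts0$timepoint),
                    function(id) st$records[[id]]$sto2_true, 0)
    expect_lt(max(abs(ts0$sto2 - truth)), 1e-6)
    # default band extraction: within a hundredth of a percentage point
    ts2 <- sto2_timeseries(st, "Mg1", limb, chrom = default_chrom)
    expect_lt(max(abs(ts2$sto2 - truth)), 0.01)
  }
})

test_that("a missing day-0 acquisition is a baseline error", {
  st <- simulate_study(null_design(noise_rel = 0, seed = 14,
                                   subjects = c(Mg = 1L)))
  st$records <- Filter(function(r)
    !(r$spectrum$meta$role == "baseline" ||
        r$spectrum$meta$timepoint == 0), st$records)
  expect_error(sto2_timeseries(st, "Mg1", "left", chrom = default_chrom),
               "baseline missing")
})

test_that("saturation estimates are invariant to a shared geometry-constant shift", {
  # per-limb G is drawn randomly in the generator; shifting it must not matter
  des <- null_design(noise_rel = 0, seed = 15, subjects = c(Mg = 1L),
                     timepoints = c(0, 1, 3), g_range = c(0, 0))
  st_a <- simulate_study(des)
  des$g_range <- c(4, 4)
  st_b <- simulate_study(des)
  ts_a <- sto2_timeseries(st_a, "Mg1", "left", chrom = default_chrom)
  ts_b <- sto2_timeseries(st_b, "Mg1", "left", chrom = default_chrom)
  expect_equal(ts_a$sto2, ts_b$sto2, tolerance = 1e-9)
})
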