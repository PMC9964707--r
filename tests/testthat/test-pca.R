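test_that("SNV rows have mean 0 and unit standard deviation", {
  set.seed(20)
  m <- matrix_fixture(matrix(rnorm(8 * 30, 5, 2), 8))
  s <- normalize_spectra(m, "snv")
  expect_equal(unname(rowMeans(s$values)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(s$values, 1, sd)), rep(1, 8), tolerance = 1e-12)
})

test_that("SNV is invariant to per-spectrum affine gain and offset", {
  set.seed(21)
  x <- matrix(rnorm(5 * 40), 5)
  a <- runif(5, 0.5, 3); b <- rnorm(5, 0, 10)
  s1 <- normalize_spectra(matrix_fixture(x), "snv")$values
  s2 <- normalize_spectra(matrix_fixture(x * a + b), "snv")$values
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("degenerate rows are rejected or normalized as defined", {
  x <- matrix(rnorm(4 * 10), 4)
  x[2, ] <- 3
  expect_error(normalize_spectra(matrix_fixture(x), "snv"), "row02")
  mx <- normalize_spectra(matrix_fixture(x), "max")
  expect_equal(unname(mx$values[2, ]), rep(1, 10))
})

test_that("rank-2 data is fully explained by two components", {
  set.seed(22)
  p1 <- sin(seq(0, 3, length.out = 50)); p2 <- seq(-1, 1, length.out = 50)
  sc <- matrix(rnorm(24), 12)
  x <- sc %*% rbind(p1, p2) + matrix(5, 12, 50)
  fit <- fit_spectra_pca(matrix_fixture(x), n_components = 2)
  expect_equal(sum(fit$explained[1:2]), 1, tolerance = 1e-9)
})

test_that("full reconstruction returns the centered data to machine precision", {
  set.seed(23)
  x <- matrix(rnorm(10 * 25), 10)
  fit <- fit_spectra_pca(matrix_fixture(x), n_components = 2)
  recon <- fit$scores %*% t(fit$loadings)
  expect_equal(recon, unname(scale(x, center = TRUE, scale = FALSE)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("scores are deterministic, sign-fixed, and centering-invariant", {
  set.seed(24)
  x <- matrix(rnorm(9 * 30), 9)
  f1 <- fit_spectra_pca(matrix_fixture(x))
  f2 <- fit_spectra_pca(matrix_fixture(x))
  expect_identical(f1$scores, f2$scores)
  # each loading's largest-magnitude element is positive
  for (k in seq_len(ncol(f1$loadings))) {
    expect_gt(f1$loadings[which.max(abs(f1$loadings[, k])), k], 0)
  }
  # adding one constant spectrum to every row changes nothing
  f3 <- fit_spectra_pca(matrix_fixture(x + rep(1, 9) %o% rnorm(30)))
  expect_equal(f1$scores, f3$scores, tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated acquisitions get identical score coordinates
  fd <- fit_spectra_pca(matrix_fixture(x[c(1:9, 3), ]))
  expect_equal(unname(fd$scores[3, ]), unname(fd$scores[10, ]), tolerance = 1e-10)
})

test_that("explained variance is non-increasing and eigenvalues non-negative", {
  set.seed(25)
  fit <- fit_spectra_pca(matrix_fixture(matrix(rnorm(15 * 20), 15)))
  expect_true(all(diff(fit$explained) <= 1e-12))
  expect_true(all(fit$eigenvalues >= 0))
  expect_lte(sum(fit$explained), 1 + 1e-12)
})

test_that("a planted spectral artifact is flagged as an outlier", {
  set.seed(26)
  x <- matrix(rnorm(20 * 40), 20)
  x[7, ] <- x[7, ] + 10   # 10-standard-deviation artifact
  fit <- fit_spectra_pca(matrix_fixture(x))
  rep <- detect_outliers(fit, alpha = 0.01)
  expect_true(rep$rows$flagged[7])
  expect_equal(sum(rep$rows$flagged), 1)
})

test_that("outlier flagging is calibrated under a homogeneous null", {
  set.seed(27)
  flags <- n_rows <- 0
  # study-sized batches; the MAD-based scale mildly inflates the rate for
  # very small batches, so calibration is asserted at realistic n
  for (i in 1:30) {
    fit <- fit_spectra_pca(matrix_fixture(matrix(rnorm(150 * 25), 150)))
    rep <- detect_outliers(fit, alpha = 0.01)
    flags <- flags + sum(rep$rows$flagged)
    n_rows <- n_rows + nrow(rep$rows)
  }
  expect_lte(flags / n_rows, 0.025)   # ~1% nominal, Monte Carlo slack
})

test_that("alpha = 1 flags every acquisition and small batches error", {
  set.seed(28)
  fit <- fit_spectra_pca(matrix_fixture(matrix(rnorm(10 * 12), 10)))
  expect_true(all(detect_outliers(fit, alpha = 1)$rows$flagged))
  fit3 <- fit_spectra_pca(matrix_fixture(matrix(rnorm(3 * 12), 3)))
  expect_error(detect_outliers(fit3), "at least 4")
})

test_that("identical groups have zero centroid distance and a null p-value", {
  set.seed(29)
  x <- matrix(rnorm(6 * 20), 6)
  fit <- fit_spectra_pca(matrix_fixture(x[c(1:6, 1:6), ]))
  labels <- rep(c("a", "b"), each = 6)
  sep <- score_group_separation(fit, labels, "a", "b", n_perm = 199, seed = 1)
  expect_equal(sep$distance, 0, tolerance = 1e-10)
  expect_gt(sep$p_value, 0.5)
})

test_that("the permutation test holds its level under a one-distribution null", {
  set.seed(30)
  rejections <- 0
  for (i in 1:60) {
    x <- matrix(rnorm(16 * 15), 16)
    fit <- fit_spectra_pca(matrix_fixture(x))
    labels <- sample(rep(c("a", "b"), each = 8))
    sep <- score_group_separation(fit, labels, "a", "b", n_perm = 99)
    rejections <- rejections + (sep$p_value <= 0.1)
  }
  expect_gte(rejections / 60, 0.01)
  expect_lte(rejections / 60, 0.25)
})

test_that("timepoint similarity is zero for identical timepoints and errors when missing", {
  st <- simulate_study(study_design(subjects_per_group = c(Mg = 2L, Ti = 2L,
                                                           sham = 2L), seed = 31))
  mat <- normalize_spectra(assemble_spectra_matrix(st))
  fit <- fit_spectra_pca(mat)
  s <- timepoint_similarity(fit, "Mg", 3, 3)
  expect_equal(s$distance, 0)
  expect_error(timepoint_similarity(fit, "Mg", 0, 99), "missing")
  tab <- timepoint_similarity_table(fit, 0, 45)
  expect_setequal(tab$group, c("Mg", "Ti", "sham"))
  expect_true(all(tab$distance >= 0))
})
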