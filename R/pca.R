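#' Assemble acquisitions into a spectra matrix
#'
#' Stacks the measurement acquisitions of a study into one matrix (rows =
#' acquisitions, columns = wavelengths) for multivariate exploration, either
#' as optical density against the study reference (default) or as raw
#' intensity. Row metadata travels with the matrix.
#'
#' @param study a `nirs_study`.
#' @param mode `"od"` or `"intensity"`.
#' @param include_baseline include dedicated baseline acquisitions as rows.
#' @return An object of class `spectra_matrix`: `values` (n x p), `grid`,
#'   `meta` (data.frame, one row per acquisition), `mode`, `normalization`.
#' @export
assemble_spectra_matrix <- function(study, mode = c("od", "intensity"),
                                    include_baseline = FALSE) {
  stopifnot(inherits(study, "nirs_study"))
  mode <- match.arg(mode)
  recs <- Filter(function(r) include_baseline ||
                   identical(r$spectrum$meta$role %||% "measure", "measure"),
                 study$records)
  if (!length(recs)) stop("study has no acquisitions to assemble", call. = FALSE)
  grid <- recs[[1]]$spectrum$grid
  vals <- t(vapply(recs, function(r) {
    sp <- r$spectrum
    if (!same_grid(sp$grid, grid)) {
      stop("acquisition ", sp$meta$id, " is on a different grid", call. = FALSE)
    }
    if (mode == "od") compute_od(sp, study$reference)$od else sp$intensity
  }, numeric(length(grid))))
  meta <- do.call(rbind, lapply(recs, function(r) {
    m <- r$spectrum$meta
    data.frame(id = m$id, subject = m$subject %||% NA_character_,
               group = m$group %||% NA_character_,
               limb = m$limb %||% NA_character_,
               timepoint = as.numeric(m$timepoint %||% NA),
               skin = m$skin %||% NA_character_,
               role = m$role %||% "measure", stringsAsFactors = FALSE)
  }))
  rownames(vals) <- meta$id
  rownames(meta) <- NULL
  if (anyNA(vals)) stop("missing values in assembled spectra", call. = FALSE)
  structure(list(values = vals, grid = grid, meta = meta, mode = mode,
                 normalization = "none"),
            class = "spectra_matrix")
}

#' Subset rows of a spectra matrix
#'
#' @param m a `spectra_matrix`.
#' @param keep logical or integer row index.
#' @return The subset `spectra_matrix`.
#' @export
subset_spectra <- function(m, keep) {
  stopifnot(inherits(m, "spectra_matrix"))
  m$values <- m$values[keep, , drop = FALSE]
  m$meta <- m$meta[keep, , drop = FALSE]
  rownames(m$meta) <- NULL
  if (nrow(m$values) == 0L) stop("subset removed every acquisition", call. = FALSE)
  m
}

#' Per-spectrum normalization
#'
#' Default is the standard normal variate (SNV): each spectrum is centered
#' to mean 0 and scaled to standard deviation 1, which removes per-spectrum
#' additive offsets (such as the geometry constant G in OD space) and
#' multiplicative gain. Alternatives: `"unit"` (Euclidean length 1) and
#' `"max"` (divide by the row maximum).
#'
#' @param m a `spectra_matrix`.
#' @param method `"snv"`, `"unit"`, or `"max"`.
#' @return The normalized `spectra_matrix` (metadata untouched).
#' @export
normalize_spectra <- function(m, method = c("snv", "unit", "max")) {
  stopifnot(inherits(m, "spectra_matrix"))
  method <- match.arg(method)
  x <- m$values
  m$values <- switch(method,
    snv = {
      s <- apply(x, 1, stats::sd)
      if (any(s == 0)) {
        stop("SNV undefined for zero-variance acquisition: ",
             m$meta$id[which(s == 0)[1]], call. = FALSE)
      }
      (x - rowMeans(x)) / s
    },
    unit = {
      n <- sqrt(rowSums(x^2))
      if (any(n == 0)) {
        stop("unit normalization undefined for all-zero acquisition: ",
             m$meta$id[which(n == 0)[1]], call. = FALSE)
      }
      x / n
    },
    max = {
      mx <- apply(x, 1, max)
      if (any(mx == 0)) {
        stop("max normalization undefined for acquisition with zero maximum: ",
             m$meta$id[which(mx == 0)[1]], call. = FALSE)
      }
      x / mx
    })
  m$normalization <- method
  m
}

#' Principal component analysis of spectra
#'
#' Column-mean-centered PCA (no column scaling) of a spectra matrix. All
#' attainable components are computed so a scree display can justify the
#' retained number; `n_components` (default 2, the usual choice for score
#' plots) marks how many are used by downstream score-space summaries.
#' Signs are fixed by the convention that each loading's largest-magnitude
#' element is positive, making repeated fits bit-reproducible.
#'
#' @param m a `spectra_matrix` (normalize first; the preprocessing applied
#'   is recorded in the model).
#' @param n_components number of retained components,
#'   `<= min(nrow - 1, ncol)`.
#' @return An object of class `spectra_pca`: full `loadings` (p x K),
#'   `scores` (n x K), `eigenvalues`, `explained` variance fractions,
#'   `center`, `retained`, `meta`, `grid`, `preprocessing`.
#' @export
fit_spectra_pca <- function(m, n_components = 2) {
  stopifnot(inherits(m, "spectra_matrix"))
  n <- nrow(m$values); p <- ncol(m$values)
  if (n < 2L) stop("PCA needs at least two acquisitions", call. = FALSE)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop(sprintf("n_components must lie in [1, %d]", min(n - 1L, p)),
         call. = FALSE)
  }
  pc <- stats::prcomp(m$values, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  sco <- pc$x
  for (k in seq_len(ncol(load))) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      sco[, k] <- -sco[, k]
    }
  }
  eig <- pc$sdev^2
  structure(list(loadings = load, scores = sco, eigenvalues = eig,
                 explained = eig / sum(eig), center = pc$center,
                 retained = as.integer(n_components),
                 meta = m$meta, grid = m$grid,
                 preprocessing = list(mode = m$mode,
                                      normalization = m$normalization)),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca> %d acquisitions x %d wavelengths (%s, %s), %d of %d PCs retained\n",
              nrow(x$scores), length(x$grid), x$preprocessing$mode,
              x$preprocessing$normalization, x$retained, ncol(x$scores)))
  ev <- 100 * x$explained[seq_len(min(4, length(x$explained)))]
  cat("  explained variance:", paste(sprintf("PC%d %.1f%%", seq_along(ev), ev),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spectra_pca <- function(object, ...) {
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             explained = object$explained,
             cumulative = cumsum(object$explained))
}

#' Score plot
#'
#' PC1 vs PC2 score plot colored by a metadata field, the standard display
#' for group/timepoint comparisons of spectra.
#'
#' @param x a `spectra_pca`.
#' @param color_by metadata column used for colors (default `"group"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.spectra_pca <- function(x, color_by = "group", ...) {
  fac <- factor(x$meta[[color_by]])
  cols <- seq_len(nlevels(fac)) + 1L
  graphics::plot(x$scores[, 1], x$scores[, 2], col = cols[as.integer(fac)],
                 pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  graphics::legend("topright", legend = levels(fac), col = cols, pch = 19,
                   bty = "n", title = color_by)
  invisible(x)
}

#' Robust score-space outlier detection
#'
#' Flags acquisitions whose retained-component scores deviate from the
#' component median by more than a robust z-score threshold (median/MAD
#' scaling). The per-component threshold is Sidak-adjusted so the overall
#' false-flag probability under a homogeneous batch is about `alpha`.
#' Removal is left to the caller: the report lists distances for every row.
#'
#' @param model a `spectra_pca`.
#' @param alpha nominal false-flag probability per acquisition (default 0.01).
#' @return An object of class `outlier_report`: data.frame `rows` (id,
#'   per-component z, max z, flagged), `threshold`, `alpha`.
#' @export
detect_outliers <- function(model, alpha = 0.01) {
  stopifnot(inherits(model, "spectra_pca"))
  k <- model$retained
  sco <- model$scores[, seq_len(k), drop = FALSE]
  if (nrow(sco) < 4L) {
    stop("outlier detection needs at least 4 acquisitions for a robust scale",
         call. = FALSE)
  }
  z <- vapply(seq_len(k), function(j) {
    med <- stats::median(sco[, j])
    s <- stats::mad(sco[, j])
    dev <- abs(sco[, j] - med)
    # degenerate batch (zero robust scale): rows at the median are not
    # outliers, anything off it is
    if (s == 0) ifelse(dev <= 1e-12, 0, Inf) else dev / s
  }, numeric(nrow(sco)))
  z <- matrix(z, nrow = nrow(sco))
  alpha_c <- 1 - (1 - alpha)^(1 / k)
  threshold <- stats::qnorm(1 - alpha_c / 2)
  zmax <- apply(z, 1, max)
  rows <- data.frame(id = model$meta$id, distance = zmax,
                     flagged = zmax >= threshold, stringsAsFactors = FALSE)
  structure(list(rows = rows, threshold = threshold, alpha = alpha,
                 n_components = k),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d of %d acquisitions flagged (alpha %.3g, robust z >= %.2f on %d PCs)\n",
              sum(x$rows$flagged), nrow(x$rows), x$alpha, x$threshold,
              x$n_components))
  if (any(x$rows$flagged)) print(x$rows[x$rows$flagged, ], row.names = FALSE)
  invisible(x)
}

centroid_distance <- function(sa, sb) {
  sqrt(sum((colMeans(sa) - colMeans(sb))^2))
}

#' Group separation in score space
#'
#' Euclidean distance between two groups' centroids in the retained score
#' space, with a label-permutation p-value (how often a random relabeling of
#' the same rows yields at least that distance).
#'
#' @param model a `spectra_pca`.
#' @param key metadata column holding the labels, or a label vector with one
#'   entry per acquisition.
#' @param a,b the two label values to compare.
#' @param n_perm number of permutations (default 999).
#' @param seed optional RNG seed for the permutations.
#' @return list with `distance`, `p_value`, group sizes and `n_perm`.
#' @export
score_group_separation <- function(model, key, a, b, n_perm = 999, seed = NULL) {
  stopifnot(inherits(model, "spectra_pca"))
  labels <- if (length(key) == 1L && is.character(key)) model$meta[[key]] else key
  if (length(labels) != nrow(model$scores)) {
    stop("labels must match the number of acquisitions", call. = FALSE)
  }
  sel <- labels %in% c(a, b)
  lab <- labels[sel]
  if (!any(lab == a) || !any(lab == b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  sco <- model$scores[sel, seq_len(model$retained), drop = FALSE]
  obs <- centroid_distance(sco[lab == a, , drop = FALSE],
                           sco[lab == b, , drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  n_a <- sum(lab == a)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(lab), n_a)
    centroid_distance(sco[idx, , drop = FALSE], sco[-idx, , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(distance = obs, p_value = p, n_a = n_a, n_b = sum(lab == b),
       n_perm = n_perm)
}

#' Timepoint similarity in score space
#'
#' Centroid distance between one group's acquisitions at two timepoints, the
#' quantitative surrogate for "how close has the tissue returned to its
#' pre-implantation spectral state". Smaller distance = more similar.
#'
#' @param model a `spectra_pca`.
#' @param group group label.
#' @param t_a,t_b the two timepoints (days).
#' @return list with `group`, `t_a`, `t_b`, `distance`, and group sizes.
#' @export
timepoint_similarity <- function(model, group, t_a, t_b) {
  stopifnot(inherits(model, "spectra_pca"))
  sel_g <- model$meta$group == group
  ia <- sel_g & model$meta$timepoint == t_a
  ib <- sel_g & model$meta$timepoint == t_b
  if (!any(ia) || !any(ib)) {
    stop(sprintf("group %s is missing acquisitions at day %g or %g",
                 group, t_a, t_b), call. = FALSE)
  }
  k <- seq_len(model$retained)
  d <- if (t_a == t_b) 0 else
    centroid_distance(model$scores[ia, k, drop = FALSE],
                      model$scores[ib, k, drop = FALSE])
  list(group = group, t_a = t_a, t_b = t_b, distance = d,
       n_a = sum(ia), n_b = sum(ib))
}

#' Timepoint similarity for every group
#'
#' @inheritParams timepoint_similarity
#' @return data.frame with one row per group.
#' @export
timepoint_similarity_table <- function(model, t_a, t_b) {
  groups <- unique(model$meta$group)
  do.call(rbind, lapply(groups, function(g) {
    s <- timepoint_similarity(model, g, t_a, t_b)
    data.frame(group = g, t_a = t_a, t_b = t_b, distance = s$distance,
               n_a = s$n_a, n_b = s$n_b, stringsAsFactors = FALSE)
  }))
}
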