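#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: input mode (simulate a
#' synthetic study or load one from disk), the study design, probe geometry,
#' analysis wavelength pair, baseline assumption, PCA settings, and the
#' global seed.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param design a [study_design()] (simulate mode).
#' @param study_dir directory written by [write_study()] (load mode).
#' @param geom analysis [probe_geometry()].
#' @param wavelengths analysis wavelength pair in nm.
#' @param baseline_sto2,baseline_thb baseline assumption for the saturation
#'   estimates.
#' @param band_halfwidth boxcar half-width (grid points) for band extraction.
#' @param n_components,normalization,outlier_alpha PCA settings.
#' @param n_perm permutations for score-space tests.
#' @param seed global RNG seed; in simulate mode it overrides the design seed.
#' @param out_dir optional output directory for [write_report()].
#' @param verbose log stage progress to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       design = study_design(), study_dir = NULL,
                       geom = probe_geometry(),
                       wavelengths = c(740, 840),
                       baseline_sto2 = 0.70, baseline_thb = 0.1,
                       band_halfwidth = 2,
                       n_components = 2, normalization = "snv",
                       outlier_alpha = 0.01, n_perm = 999,
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(study_dir) || !dir.exists(study_dir)) {
      stop("load mode requires an existing study_dir", call. = FALSE)
    }
  } else if (is.null(seed)) {
    stop("simulate mode requires a seed", call. = FALSE)
  }
  structure(list(mode = mode, design = design, study_dir = study_dir,
                 geom = geom, wavelengths = wavelengths,
                 baseline_sto2 = baseline_sto2, baseline_thb = baseline_thb,
                 band_halfwidth = band_halfwidth,
                 n_components = n_components, normalization = normalization,
                 outlier_alpha = outlier_alpha, n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

pipeline_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(paste0("[nirsox] ", fmt), ...))
}

#' Per-group, per-timepoint saturation summary
#'
#' @param series data.frame of saturation series as returned by
#'   [sto2_timeseries()] (rows from several subjects row-bound together).
#' @return data.frame with mean, sd, median, min, max and n of `sto2` per
#'   group x timepoint.
#' @export
summarize_groups <- function(series) {
  if (is.null(series) || !nrow(series)) stop("empty series collection", call. = FALSE)
  agg <- function(f) stats::aggregate(sto2 ~ group + timepoint, series, f)
  out <- agg(mean)
  names(out)[3] <- "mean"
  out$sd <- agg(function(v) if (length(v) < 2L) 0 else stats::sd(v))$sto2
  out$median <- agg(stats::median)$sto2
  out$min <- agg(min)$sto2
  out$max <- agg(max)$sto2
  out$n <- agg(length)$sto2
  out[order(out$group, out$timepoint), ]
}

#' Run the full analysis pipeline
#'
#' Executes the whole workflow on one study: simulate or load the
#' acquisitions, compute each subject/limb saturation time series through
#' the differential Beer-Lambert chain, summarize groups over timepoints,
#' and run the PCA exploration (normalization, fit, outlier flagging with
#' explicit exclusion, skin-condition separation at days 3-14 when a rash
#' case is present, and first-vs-last timepoint similarity per group).
#' Fully deterministic under the configured seed.
#'
#' @param config a [run_config()].
#' @return An object of class `study_report`; see the fields in the
#'   examples of [print.study_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    design <- config$design
    design$seed <- config$seed %||% design$seed
    pipeline_log(config, "simulating study (seed %d)", design$seed)
    study <- simulate_study(design, geom = config$geom)
  } else {
    pipeline_log(config, "loading study from %s", config$study_dir)
    study <- read_study(config$study_dir)
    if (!is.null(config$seed)) set.seed(config$seed)
  }
  chrom <- default_chromophores()
  man <- study_manifest(study)
  meas <- man[man$role == "measure", ]
  pipeline_log(config, "acquisitions in: %d (%d measurement, %d baseline)",
               nrow(man), nrow(meas), sum(man$role == "baseline"))

  units <- unique(meas[c("subject", "limb")])
  series <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    sto2_timeseries(study, units$subject[i], units$limb[i],
                    geom = config$geom, chrom = chrom,
                    wavelengths = config$wavelengths,
                    baseline_sto2 = config$baseline_sto2,
                    baseline_thb = config$baseline_thb,
                    band_halfwidth = config$band_halfwidth)
  }))
  group_summary <- summarize_groups(series)
  pipeline_log(config, "saturation series: %d rows over %d subject/limb units",
               nrow(series), nrow(units))

  mat <- normalize_spectra(assemble_spectra_matrix(study, mode = "od"),
                           method = config$normalization)
  pca_all <- fit_spectra_pca(mat, n_components = config$n_components)
  outliers <- detect_outliers(pca_all, alpha = config$outlier_alpha)
  excluded <- outliers$rows$id[outliers$rows$flagged]
  pca <- pca_all
  if (length(excluded)) {
    pipeline_log(config, "excluding %d flagged outlier(s): %s",
                 length(excluded), paste(excluded, collapse = ", "))
    pca <- fit_spectra_pca(subset_spectra(mat, !mat$meta$id %in% excluded),
                           n_components = config$n_components)
  }

  rash_separation <- NULL
  if (any(pca$meta$skin == "rash")) {
    mid <- pca$meta$timepoint >= 3 & pca$meta$timepoint <= 14
    sub <- subset_spectra(mat, mat$meta$id %in% pca$meta$id[mid])
    pca_mid <- fit_spectra_pca(sub, n_components = config$n_components)
    rash_separation <- score_group_separation(pca_mid, "skin", "rash", "normal",
                                              n_perm = config$n_perm,
                                              seed = config$seed)
    pipeline_log(config, "rash separation: distance %.3g, p = %.4g",
                 rash_separation$distance, rash_separation$p_value)
  }

  tps <- sort(unique(pca$meta$timepoint))
  similarity <- timepoint_similarity_table(pca, tps[1], tps[length(tps)])

  structure(list(config = config, seed = config$seed,
                 version = as.character(utils::packageVersion("nirsox")),
                 study = study, series = series,
                 group_summary = group_summary,
                 pca = pca, outliers = outliers, excluded = excluded,
                 rash_separation = rash_separation,
                 similarity = similarity,
                 counts = c(acquisitions = nrow(man),
                            measurements = nrow(meas),
                            analyzed = nrow(meas) - length(excluded),
                            excluded = length(excluded))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> nirsox %s, seed %s\n", x$version,
              format(x$seed)))
  cat(sprintf("  acquisitions: %d in, %d analyzed, %d excluded as outliers\n",
              x$counts[["measurements"]], x$counts[["analyzed"]],
              x$counts[["excluded"]]))
  cat("  group StO2 summary (mean +/- sd, %):\n")
  gs <- x$group_summary
  for (g in unique(gs$group)) {
    r <- gs[gs$group == g, ]
    cat(sprintf("    %-5s %s\n", g,
                paste(sprintf("d%g: %.1f+/-%.1f", r$timepoint, r$mean, r$sd),
                      collapse = "  ")))
  }
  if (!is.null(x$rash_separation)) {
    cat(sprintf("  skin-rash separation (days 3-14): distance %.3g, permutation p = %.4g\n",
                x$rash_separation$distance, x$rash_separation$p_value))
  }
  cat(sprintf("  day %g vs day %g score-space distance: %s\n",
              x$similarity$t_a[1], x$similarity$t_b[1],
              paste(sprintf("%s %.3g", x$similarity$group,
                            x$similarity$distance), collapse = ", ")))
  invisible(x)
}

#' Write report tables and figures to disk
#'
#' Emits the per-subject saturation series, group summary, PCA scores and
#' loadings, outlier report, timepoint-similarity table, a provenance block
#' (config echo, seed, version), and a PC1/PC2 score-plot image.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(report$series, "sto2_series.tsv")
  wt(report$group_summary, "group_summary.tsv")
  sco <- data.frame(report$pca$meta,
                    report$pca$scores[, seq_len(report$pca$retained),
                                      drop = FALSE])
  wt(sco, "pca_scores.tsv")
  wt(data.frame(wavelength_nm = report$pca$grid,
                report$pca$loadings[, seq_len(report$pca$retained),
                                    drop = FALSE]),
     "pca_loadings.tsv")
  wt(report$outliers$rows, "outliers.tsv")
  wt(report$similarity, "timepoint_similarity.tsv")
  cfg <- report$config
  prov <- list(version = report$version, seed = report$seed,
               mode = cfg$mode, wavelengths = cfg$wavelengths,
               baseline_sto2 = cfg$baseline_sto2,
               baseline_thb = cfg$baseline_thb,
               band_halfwidth = cfg$band_halfwidth,
               normalization = cfg$normalization,
               n_components = cfg$n_components,
               outlier_alpha = cfg$outlier_alpha, n_perm = cfg$n_perm,
               excluded = as.list(report$excluded))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  grDevices::png(file.path(dir, "score_plot.png"), width = 900, height = 700)
  plot(report$pca, color_by = "group", main = "PCA score plot")
  grDevices::dev.off()
  invisible(dir)
}
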