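fmt_num <- function(x) sprintf("%.17g", x)

write_two_col <- function(grid, intensity, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavelength_nm\tintensity", con)
  writeLines(paste(fmt_num(grid), fmt_num(intensity), sep = "\t"), con)
}

read_two_col <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !identical(lines[1], "wavelength_nm\tintensity")) {
    stop(sprintf("parse error in %s, line 1: expected header 'wavelength_nm\\tintensity'",
                 path), call. = FALSE)
  }
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("parse error in %s, line %d: expected two tab-separated fields",
                 path, bad[1] + 1L), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(matrix(is.na(m), ncol = 2), 1, any))[1]
    stop(sprintf("parse error in %s, line %d: non-numeric value", path, bad + 1L),
         call. = FALSE)
  }
  list(grid = m[, 1], intensity = m[, 2])
}

#' Write a study to a directory of plain-text files
#'
#' Layout: `reference.tsv` (incident spectrum), one `spectra/<id>.tsv` per
#' acquisition, `manifest.tsv` (acquisition metadata), `design.yaml` (the
#' study design), and the ground truth in a separate `truth.tsv` sidecar so
#' the analysis pipeline can be run blinded.
#'
#' @param study a `nirs_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "nirs_study"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  write_two_col(study$reference$grid, study$reference$intensity,
                file.path(dir, "reference.tsv"))
  man <- study_manifest(study)
  man$file <- file.path("spectra", paste0(man$id, ".tsv"))
  for (i in seq_len(nrow(man))) {
    sp <- study$records[[man$id[i]]]$spectrum
    write_two_col(sp$grid, sp$intensity, file.path(dir, man$file[i]))
  }
  utils::write.table(man[c("id", "file", "subject", "group", "limb",
                           "timepoint", "skin", "role")],
                     file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- do.call(rbind, lapply(man$id, function(id) {
    r <- study$records[[id]]
    data.frame(id = id, HbO2_mM = fmt_num(r$truth[["HbO2"]]),
               Hb_mM = fmt_num(r$truth[["Hb"]]),
               sto2_true = fmt_num(r$sto2_true), stringsAsFactors = FALSE)
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  d <- unclass(study$design)
  d$subjects_per_group <- as.list(d$subjects_per_group)
  d$effects <- lapply(d$effects, function(e) lapply(e, as.list))
  yaml::write_yaml(d, file.path(dir, "design.yaml"), precision = 15)
  geo <- list(d = study$geometry$d,
              dpf = as.list(stats::setNames(study$geometry$dpf,
                                            study$geometry$dpf_wavelength)),
              g = study$geometry$g)
  yaml::write_yaml(geo, file.path(dir, "geometry.yaml"), precision = 15)
  invisible(dir)
}

#' Read a study back from a directory
#'
#' Inverse of [write_study()]. With `blinded = TRUE` the truth sidecar is
#' ignored and the returned study carries no ground truth.
#'
#' @param dir directory written by [write_study()].
#' @param blinded ignore `truth.tsv`.
#' @return A `nirs_study`.
#' @export
read_study <- function(dir, blinded = FALSE) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("no manifest.tsv in ", dir, call. = FALSE)
  first <- readLines(man_path, n = 1L)
  need <- c("id", "file", "subject", "group", "limb", "timepoint", "skin", "role")
  if (!identical(strsplit(first, "\t")[[1]], need)) {
    stop(sprintf("parse error in %s, line 1: malformed manifest header", man_path),
         call. = FALSE)
  }
  man <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  refd <- read_two_col(file.path(dir, "reference.tsv"))
  ref <- reference_spectrum(refd$grid, refd$intensity)
  truth <- NULL
  if (!blinded && file.exists(file.path(dir, "truth.tsv"))) {
    truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                               stringsAsFactors = FALSE)
    rownames(truth) <- truth$id
  }
  records <- vector("list", nrow(man))
  names(records) <- man$id
  for (i in seq_len(nrow(man))) {
    sp <- read_two_col(file.path(dir, man$file[i]))
    meta <- list(id = man$id[i], subject = man$subject[i], group = man$group[i],
                 limb = man$limb[i], timepoint = man$timepoint[i],
                 skin = man$skin[i], role = man$role[i])
    rec <- list(spectrum = nirs_spectrum(sp$grid, sp$intensity, meta = meta),
                truth = NULL, sto2_true = NULL)
    if (!is.null(truth)) {
      tr <- truth[man$id[i], ]
      rec$truth <- c(HbO2 = as.numeric(tr$HbO2_mM), Hb = as.numeric(tr$Hb_mM))
      rec$sto2_true <- as.numeric(tr$sto2_true)
    }
    records[[i]] <- rec
  }
  design <- NULL
  if (file.exists(file.path(dir, "design.yaml"))) {
    d <- yaml::read_yaml(file.path(dir, "design.yaml"))
    d$groups <- NULL
    d$subjects_per_group <- unlist(d$subjects_per_group)
    d$effects <- lapply(d$effects, function(e) lapply(e, unlist))
    d$timepoints <- as.numeric(d$timepoints)
    d$grid <- as.numeric(d$grid)
    d$g_range <- as.numeric(d$g_range)
    design <- do.call(study_design, d)
  }
  geom <- probe_geometry()
  if (file.exists(file.path(dir, "geometry.yaml"))) {
    g <- yaml::read_yaml(file.path(dir, "geometry.yaml"))
    geom <- probe_geometry(g$d, unlist(g$dpf), g = g$g)
  }
  structure(list(design = design, geometry = geom, reference = ref,
                 records = records),
            class = "nirs_study")
}
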