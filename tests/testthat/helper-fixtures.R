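# shared fixtures, all generated in code

default_chrom <- default_chromophores()

# small two-chromophore table with hand-picked values for oracle arithmetic
tiny_chrom <- function() {
  chromophore_set(grid = c(700, 750, 800, 850, 900),
                  epsilon = cbind(HbO2 = c(0.6, 1.2, 1.9, 2.4, 2.8),
                                  Hb = c(4.0, 3.2, 1.8, 1.6, 1.7)))
}

flat_ref <- function(grid, level = 1e4) reference_spectrum(grid, rep(level, length(grid)))

null_effects <- function(timepoints) {
  z <- stats::setNames(rep(0, length(timepoints)), as.character(timepoints))
  list(sto2_offset = z, sto2_sd = z)
}

# a design with no planted effects and configurable noise
null_design <- function(noise_rel = 0, seed = 1L, subjects = c(Mg = 2L),
                        timepoints = c(0, 1, 3), ...) {
  study_design(subjects_per_group = subjects, timepoints = timepoints,
               effects = stats::setNames(
                 rep(list(null_effects(timepoints)), length(subjects)),
                 names(subjects)),
               rash_subject = FALSE, noise_rel = noise_rel, seed = seed, ...)
}

# spectra_matrix built directly from a numeric matrix, for PCA unit tests
matrix_fixture <- function(x, grid = NULL) {
  grid <- grid %||% seq(650, by = 2, length.out = ncol(x))
  n <- nrow(x)
  meta <- data.frame(id = sprintf("row%02d", seq_len(n)),
                     subject = sprintf("s%d", seq_len(n)),
                     group = rep_len(c("A", "B"), n),
                     limb = "left", timepoint = rep_len(c(0, 45), n),
                     skin = "normal", role = "measure",
                     stringsAsFactors = FALSE)
  structure(list(values = x, grid = grid, meta = meta, mode = "od",
                 normalization = "none"),
            class = "spectra_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
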