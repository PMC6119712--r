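# fixed column layouts for the on-disk interchange files
patients_columns <- c("patient_id", "group", "sex", "age", "education",
                      "mmse", "disease_duration", "ast_imitation",
                      "ast_gesture", "ast_total")
trials_columns <- c("patient_id", "condition", "delay_ms", "set_index",
                    "response")
fits_columns <- c("patient_id", "condition", "steepness", "ddt", "rss",
                  "converged", "boundary_hit")

#' Read and write the cohort interchange files
#'
#' `patients.csv`, `trials.csv` and `fits.csv` carry one row per
#' patient, trial and psychometric fit respectively, with fixed
#' headers. `truth.json` stores generator ground truth for recovery
#' tests.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the data.frame (readers) or the path, invisibly (writers).
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_patients_csv <- function(x, path) {
  stopifnot(all(patients_columns %in% names(x)))
  write.csv(x[, patients_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_patients_csv <- function(path) {
  x <- read.csv(path)
  stopifnot(identical(names(x), patients_columns))
  x$group <- factor(x$group, levels = vmti_groups())
  x
}

#' @rdname cohort_io
#' @export
write_trials_csv <- function(x, path) {
  stopifnot(all(trials_columns %in% names(x)))
  write.csv(x[, trials_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_trials_csv <- function(path) {
  x <- read.csv(path)
  stopifnot(identical(names(x), trials_columns))
  x
}

#' @rdname cohort_io
#' @export
write_fits_csv <- function(x, path) {
  stopifnot(all(fits_columns %in% names(x)))
  write.csv(x[, fits_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_fits_csv <- function(path) {
  x <- read.csv(path)
  stopifnot(identical(names(x), fits_columns))
  x
}

#' Write lesion masks to a directory of NIfTI files
#'
#' @param masks named list of binary arrays.
#' @param dir output directory (created if absent).
#' @param gzip write .nii.gz (default) or plain .nii.
#' @return named character vector of paths, invisibly.
#' @export
write_lesion_masks <- function(masks, dir, gzip = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- setNames(file.path(dir, paste0(names(masks), ext)), names(masks))
  for (id in names(masks)) write_lesion_volume(masks[[id]], paths[[id]])
  invisible(paths)
}
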