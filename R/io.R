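trial_schema <- c("trial_idx", "trial_type", "amplitude_um", "freq_hz",
                  "stim_onset_s", "stim_offset_s", "first_lick_s",
                  "outcome", "timeout")

#' Write a trial table to CSV
#'
#' @param trials trial table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Enforces the trial-table schema: required columns present, outcome
#' codes known, Go rows carry amplitudes, onset times monotone (rows in
#' nonmonotone order are sorted by onset with a message). Schema
#' violations report the offending row numbers.
#'
#' @param path CSV path written by [write_trials()] (or any file
#'   matching the schema; extra columns such as `mouse_id` are kept).
#' @return a validated trial tibble ordered by stimulus onset.
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trial_schema, names(tr))
  assert_that(length(missing) == 0, "trial table missing columns: %s",
              paste(missing, collapse = ", "))
  bad_type <- which(!tr$trial_type %in% c("go", "nogo"))
  assert_that(length(bad_type) == 0, "unknown trial_type at rows: %s",
              paste(utils::head(bad_type, 5), collapse = ", "))
  bad_out <- which(!(is.na(tr$outcome) & tr$timeout) &
                     !tr$outcome %in% c("hit", "miss", "cr", "fa"))
  assert_that(length(bad_out) == 0, "unknown outcome codes at rows: %s",
              paste(utils::head(bad_out, 5), collapse = ", "))
  bad_amp <- which(tr$trial_type == "go" & !tr$timeout & is.na(tr$amplitude_um))
  assert_that(length(bad_amp) == 0,
              "Go rows without amplitude at rows: %s",
              paste(utils::head(bad_amp, 5), collapse = ", "))
  if (is.unsorted(tr$stim_onset_s)) {
    message("read_trials: rows not in onset order; sorting by stim_onset_s")
    tr <- dplyr::arrange(tr, .data$stim_onset_s)
  }
  tr$timeout <- as.logical(tr$timeout)
  tr
}

#' Write a trace set to a plain-text container
#'
#' Serializes a [trace_set()] as a directory holding `F.csv` and
#' `Fneu.csv` (neurons x frames, no header), and `meta.json` with the
#' cell-type labels (0 = pyramidal, 1 = interneuron) and the frame rate.
#'
#' @param ts a `trace_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_traces <- function(ts, dir) {
  assert_that(inherits(ts, "trace_set"), "ts must be a trace_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ts$F, file.path(dir, "F.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ts$Fneu, file.path(dir, "Fneu.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(celltype = as.integer(ts$celltype == "inh"),
         frame_rate_hz = ts$frame_rate_hz),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trace set from its plain-text container
#'
#' @param dir directory written by [write_traces()].
#' @return a validated [trace_set()].
#' @export
read_traces <- function(dir) {
  fpath <- file.path(dir, "F.csv")
  assert_that(file.exists(fpath), "no F.csv under %s", dir)
  F <- as.matrix(utils::read.table(fpath, sep = ","))
  Fneu <- as.matrix(utils::read.table(file.path(dir, "Fneu.csv"), sep = ","))
  dimnames(F) <- dimnames(Fneu) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  assert_that(!is.null(meta$frame_rate_hz), "meta.json lacks frame_rate_hz")
  assert_that(all(meta$celltype %in% c(0, 1)),
              "celltype codes must be 0 (pyr) or 1 (inh)")
  trace_set(F, Fneu, ifelse(meta$celltype == 1, "inh", "pyr"),
            meta$frame_rate_hz)
}

#' Write / read a run configuration
#'
#' Run configurations are fully serializable JSON; a run is reproducible
#' from the configuration plus its seed alone.
#'
#' @param config named list of configuration blocks.
#' @param path JSON path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
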