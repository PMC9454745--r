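#' Paired head/eye velocity time series
#'
#' The canonical input of the gaze pipeline: one horizontal velocity channel
#' for the eye and one for the head (or visual surround, for OKR), on a
#' uniform time grid.
#'
#' @param time time stamps in s, uniform grid starting near 0.
#' @param head_vel head (or surround) velocity in deg/s.
#' @param eye_vel eye velocity in deg/s.
#' @param sampling_rate sampling rate in Hz.
#' @param stimulus_frequency stimulus frequency in Hz.
#' @param metadata named list (animal, genotype, condition, ...).
#' @return an object of class \code{velocity_recording}.
#' @export
velocity_recording <- function(time, head_vel, eye_vel, sampling_rate,
                               stimulus_frequency, metadata = list()) {
  n <- length(time)
  check_that(length(head_vel) == n && length(eye_vel) == n, "head_vel/eye_vel",
             "must have the same length as `time`")
  check_that(n >= 2, "time", "must contain at least two samples")
  dt <- diff(time)
  check_that(all(abs(dt - 1 / sampling_rate) < 1e-9), "time",
             "must be a uniform grid with step 1/sampling_rate")
  check_that(!anyNA(head_vel) && !anyNA(eye_vel), "head_vel/eye_vel",
             "must contain no missing samples")
  check_that(is.numeric(stimulus_frequency) && stimulus_frequency > 0,
             "stimulus_frequency", "must be > 0")
  structure(list(time = time, head_vel = head_vel, eye_vel = eye_vel,
                 sampling_rate = sampling_rate,
                 stimulus_frequency = stimulus_frequency,
                 metadata = metadata),
            class = "velocity_recording")
}

#' @export
print.velocity_recording <- function(x, ...) {
  cat(sprintf("<velocity_recording> %d samples @ %g Hz, stimulus %g Hz\n",
              length(x$time), x$sampling_rate, x$stimulus_frequency))
  if (length(x$metadata))
    cat("  ", paste(names(x$metadata), unlist(x$metadata),
                    sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sorted spike-time container
#'
#' @param times spike times in s, strictly increasing, within [0, duration].
#' @param duration recording duration in s.
#' @param metadata named list (cell id, genotype, state).
#' @return an object of class \code{spike_train}.
#' @export
spike_train <- function(times, duration, metadata = list()) {
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop(sprintf("spike times must be strictly increasing; violated at index %d",
                   i + 1L), call. = FALSE)
    }
  }
  check_that(length(times) == 0 ||
               (min(times) >= 0 && max(times) <= duration + 1e-9),
             "times", "must lie within [0, duration]")
  structure(list(times = as.numeric(times), duration = duration,
                 metadata = metadata),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s\n", length(x$times), x$duration))
  invisible(x)
}

#' Read / write a velocity trace CSV
#'
#' Trace files have the header \code{time_s,head_vel_dps,eye_vel_dps}, one row
#' per sample, '.' decimal separator.
#'
#' @param path file path.
#' @param stimulus_frequency stimulus frequency in Hz (stored in metadata by
#'   the manifest, not in the CSV).
#' @param metadata named list attached to the recording.
#' @return \code{read_trace_csv}: a \code{\link{velocity_recording}}.
#' @export
read_trace_csv <- function(path, stimulus_frequency, metadata = list()) {
  d <- utils::read.csv(path)
  check_that(all(c("time_s", "head_vel_dps", "eye_vel_dps") %in% names(d)),
             "path", "trace CSV must have columns time_s,head_vel_dps,eye_vel_dps")
  fs <- 1 / stats::median(diff(d$time_s))
  velocity_recording(d$time_s, d$head_vel_dps, d$eye_vel_dps,
                     sampling_rate = round(fs),
                     stimulus_frequency = stimulus_frequency,
                     metadata = metadata)
}

#' @rdname read_trace_csv
#' @param rec a \code{\link{velocity_recording}}.
#' @export
write_trace_csv <- function(rec, path) {
  con <- file(path, open = "wb")  # binary: LF line endings on all platforms
  on.exit(close(con))
  writeLines("time_s,head_vel_dps,eye_vel_dps", con)
  writeLines(sprintf("%.6f,%.6f,%.6f", rec$time, rec$head_vel, rec$eye_vel), con)
  invisible(path)
}

#' Read / write a plain-text spike-time file (one ascending time in s per line)
#'
#' @param path file path.
#' @param duration recording duration in s; if \code{NULL}, the last spike
#'   time is used.
#' @param metadata named list attached to the train.
#' @return \code{read_spike_file}: a \code{\link{spike_train}}.
#' @export
read_spike_file <- function(path, duration = NULL, metadata = list()) {
  times <- as.numeric(readLines(path))
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  spike_train(times, duration, metadata)
}

#' @rdname read_spike_file
#' @param train a \code{\link{spike_train}}.
#' @export
write_spike_file <- function(train, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%.6f", train$times), con)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' The manifest is a JSON array of records with fields \code{file},
#' \code{animal_id} (or \code{cell_id} for spike files), \code{genotype}
#' (WT/SCA6), \code{condition} (VORd/OKR/VORl/pre/post for traces),
#' \code{state} (anesthetized/awake, spike files only) and
#' \code{frequency_hz} (traces only).
#'
#' @param path manifest path.
#' @return a data.frame, one row per file.
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' @rdname read_manifest
#' @param manifest a data.frame of manifest records.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
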