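#' Least-squares sinusoid fit at a known frequency
#'
#' Fits \code{s(t) = a*sin(2*pi*f*t) + b*cos(2*pi*f*t) + c} by the closed-form
#' normal-equations (QR) solution over the unmasked samples, the standard
#' estimator for gain/phase extraction from steady-state sinusoidal reflex
#' responses.
#'
#' @param x signal samples (deg/s).
#' @param frequency stimulus frequency in Hz (> 0).
#' @param sampling_rate sampling rate in Hz (used when \code{time} is NULL).
#' @param mask optional logical vector, TRUE = excluded from the fit.
#' @param time optional explicit time grid in s.
#' @return list with \code{amplitude} (\code{sqrt(a^2+b^2)}, deg/s),
#'   \code{phase} (\code{atan2(b, a)}, degrees), \code{offset} (c, deg/s) and
#'   the raw coefficients \code{a}, \code{b}.
#' @export
fit_sinusoid <- function(x, frequency, sampling_rate = NULL, mask = NULL,
                         time = NULL) {
  check_that(is.numeric(frequency) && frequency > 0, "frequency", "must be > 0")
  if (is.null(time)) {
    check_that(!is.null(sampling_rate), "sampling_rate",
               "must be given when `time` is not")
    time <- (seq_along(x) - 1) / sampling_rate
  }
  keep <- if (is.null(mask)) rep(TRUE, length(x)) else !mask
  if (sum(keep) < 3)
    stop("sinusoid fit needs at least 3 unmasked samples", call. = FALSE)
  w <- 2 * pi * frequency * time[keep]
  X <- cbind(sin(w), cos(w), 1)
  cf <- qr.coef(qr(X), x[keep])
  a <- cf[1]; b <- cf[2]; c0 <- cf[3]
  list(amplitude = sqrt(a^2 + b^2),
       phase = atan2(b, a) * 180 / pi,
       offset = unname(c0), a = unname(a), b = unname(b))
}

# model prediction of a fit_sinusoid() result on a time grid
predict_sinusoid <- function(fit, frequency, time) {
  w <- 2 * pi * frequency * time
  fit$a * sin(w) + fit$b * cos(w) + fit$offset
}

#' Options for the iterative quick-phase detector
#'
#' @param k threshold in robust SDs of the residual (default 3).
#' @param velocity_floor minimum absolute residual velocity in deg/s that a
#'   sample must exceed to be marked (default 10), so the threshold never
#'   collapses onto the noise floor of clean traces.
#' @param margin_before,margin_after dilation margins in s applied to each
#'   detected run (defaults 20 ms and 40 ms), so the accelerating and
#'   decelerating tails of a quick phase are excluded with its core.
#' @param min_duration minimum core duration in s of a candidate run before
#'   dilation (default 5 ms); shorter supra-threshold excursions are treated
#'   as noise crossings.
#' @param max_iter maximum fit/mask iterations (default 10).
#' @return list of options for \code{\link{detect_quick_phases}}.
#' @export
desaccade_options <- function(k = 3, velocity_floor = 10, margin_before = 0.02,
                              margin_after = 0.04, min_duration = 0.005,
                              max_iter = 10) {
  list(k = k, velocity_floor = velocity_floor, margin_before = margin_before,
       margin_after = margin_after, min_duration = min_duration,
       max_iter = max_iter)
}

#' Detect and mask quick phases in an eye-velocity trace
#'
#' Iterates: (1) fit a sinusoid at the stimulus frequency to the eye velocity
#' using the current mask (initially empty); (2) form the residual; (3) mark
#' samples whose absolute residual exceeds
#' \code{max(velocity_floor, k * robust_SD)} where the robust SD is
#' \code{1.4826 * median(|r - median(r)|)}; (4) drop marked runs shorter than
#' \code{min_duration}, dilate the rest by the margins; (5) repeat until the
#' mask is stable or \code{max_iter}. Contiguous masked runs become quick
#' phase events; each event's amplitude is the time integral of the residual
#' over the run (degrees) and its peak velocity the maximum absolute residual.
#'
#' @param rec a \code{\link{velocity_recording}}.
#' @param opts options from \code{\link{desaccade_options}}.
#' @return list with \code{events} (data.frame: onset, offset, amplitude,
#'   peak_velocity, direction), \code{mask} (logical, TRUE = excluded) and
#'   \code{iterations}.
#' @export
detect_quick_phases <- function(rec, opts = desaccade_options()) {
  stopifnot(inherits(rec, "velocity_recording"))
  n <- length(rec$eye_vel)
  fs <- rec$sampling_rate
  min_run <- max(1L, round(opts$min_duration * fs))
  m_before <- round(opts$margin_before * fs)
  m_after <- round(opts$margin_after * fs)
  mask <- rep(FALSE, n)
  fit <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- fit_sinusoid(rec$eye_vel, rec$stimulus_frequency, fs, mask)
    r <- rec$eye_vel - predict_sinusoid(fit, rec$stimulus_frequency, rec$time)
    thr <- max(opts$velocity_floor, opts$k * stats::mad(r))
    core <- abs(r) > thr
    new_mask <- rep(FALSE, n)
    if (any(core)) {
      runs <- true_runs(core)
      runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_run, ,
                   drop = FALSE]
      for (j in seq_len(nrow(runs))) {
        i0 <- max(1L, runs[j, "start"] - m_before)
        i1 <- min(n, runs[j, "end"] + m_after)
        new_mask[i0:i1] <- TRUE
      }
    }
    if (mean(new_mask) > 0.8)
      stop("quick-phase mask covers > 80% of samples; trace is dominated by ",
           "saccades or the detection threshold is mis-set", call. = FALSE)
    if (identical(new_mask, mask) || iter >= opts$max_iter) {
      mask <- new_mask
      break
    }
    mask <- new_mask
  }
  fit <- fit_sinusoid(rec$eye_vel, rec$stimulus_frequency, fs, mask)
  r <- rec$eye_vel - predict_sinusoid(fit, rec$stimulus_frequency, rec$time)
  events <- data.frame(onset = numeric(0), offset = numeric(0),
                       amplitude = numeric(0), peak_velocity = numeric(0),
                       direction = numeric(0))
  if (any(mask)) {
    runs <- true_runs(mask)
    events <- do.call(rbind, lapply(seq_len(nrow(runs)), function(j) {
      idx <- runs[j, "start"]:runs[j, "end"]
      ipk <- idx[which.max(abs(r[idx]))]
      data.frame(onset = rec$time[idx[1]],
                 offset = rec$time[idx[length(idx)]],
                 amplitude = sum(r[idx]) / fs,
                 peak_velocity = max(abs(r[idx])),
                 direction = sign(r[ipk]))
    }))
  }
  list(events = events, mask = mask, iterations = iter)
}

#' Estimate slow-phase gain and phase of a recording
#'
#' The head channel is fitted with no mask; the eye channel is fitted after
#' quick phases are excluded. Gain is the ratio of eye to head fitted
#' amplitudes. Phase is reported relative to the ideal response: for
#' compensatory conditions (VORd/VORl and pre/post learning recordings) the
#' ideal eye equals minus the head, so phase = eye phase - head phase - 180
#' degrees (wrapped); for the OKR the ideal eye follows the surround, so
#' phase = eye phase - head phase. Positive phase means the eye leads the
#' ideal response.
#'
#' @param rec a \code{\link{velocity_recording}}; \code{metadata$condition ==
#'   "OKR"} selects the following-response convention.
#' @param desaccade exclude quick phases before fitting (default TRUE).
#' @param opts detector options, see \code{\link{desaccade_options}}.
#' @return an object of class \code{slow_phase_fit}: list with
#'   \code{frequency}, \code{gain}, \code{phase} (degrees, in (-180, 180]),
#'   \code{eye_amplitude}, \code{head_amplitude}, \code{offset},
#'   \code{fraction_retained}, \code{vaf} (variance accounted for) and the
#'   detected \code{quick_phases}.
#' @export
estimate_gain_phase <- function(rec, desaccade = TRUE,
                                opts = desaccade_options()) {
  stopifnot(inherits(rec, "velocity_recording"))
  head_fit <- fit_sinusoid(rec$head_vel, rec$stimulus_frequency,
                           rec$sampling_rate)
  if (head_fit$amplitude < 1)
    stop("head (stimulus) amplitude < 1 deg/s: no stimulus present",
         call. = FALSE)
  qp <- list(events = NULL, mask = rep(FALSE, length(rec$eye_vel)))
  if (desaccade) qp <- detect_quick_phases(rec, opts)
  eye_fit <- fit_sinusoid(rec$eye_vel, rec$stimulus_frequency,
                          rec$sampling_rate, qp$mask)
  following <- identical(rec$metadata$condition, "OKR")
  raw <- eye_fit$phase - head_fit$phase - if (following) 0 else 180
  pred <- predict_sinusoid(eye_fit, rec$stimulus_frequency, rec$time)
  keep <- !qp$mask
  resid_var <- stats::var(rec$eye_vel[keep] - pred[keep])
  tot_var <- stats::var(rec$eye_vel[keep])
  structure(list(frequency = rec$stimulus_frequency,
                 gain = eye_fit$amplitude / head_fit$amplitude,
                 phase = wrap_degrees(raw),
                 eye_amplitude = eye_fit$amplitude,
                 head_amplitude = head_fit$amplitude,
                 offset = eye_fit$offset,
                 fraction_retained = mean(keep),
                 vaf = if (tot_var > 0) max(0, 1 - resid_var / tot_var) else 1,
                 quick_phases = qp$events,
                 metadata = rec$metadata),
            class = "slow_phase_fit")
}

#' @export
print.slow_phase_fit <- function(x, ...) {
  cat(sprintf("<slow_phase_fit> f = %g Hz: gain %.3f, phase %.1f deg (VAF %.3f, %.0f%% retained)\n",
              x$frequency, x$gain, x$phase, x$vaf, 100 * x$fraction_retained))
  invisible(x)
}

#' Frequency response of a cohort: per-recording gains/phases and group summary
#'
#' Runs \code{\link{estimate_gain_phase}} on every trace listed in the
#' manifest, averaging repeats of the same (animal, condition, frequency),
#' and summarises per genotype x condition x frequency as mean +/- SEM
#' (SEM = SD / sqrt(n animals)).
#'
#' @param manifest manifest data.frame (see \code{\link{read_manifest}}) or
#'   path to a manifest JSON; only rows with a \code{frequency_hz} are used.
#' @param dir directory containing the trace files.
#' @param desaccade,opts passed to \code{\link{estimate_gain_phase}}.
#' @param collect_quick_phases also return the pooled quick-phase event table.
#' @return list with \code{table} (animal, genotype, condition, frequency_hz,
#'   gain, phase_deg, vaf, fraction_retained), \code{summary} (genotype,
#'   condition, frequency_hz, n, mean_gain, sem_gain, mean_phase, sem_phase)
#'   and, if requested, \code{quick_phases}.
#' @export
frequency_response <- function(manifest, dir = ".", desaccade = TRUE,
                               opts = desaccade_options(),
                               collect_quick_phases = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  m <- manifest[!is.na(manifest$frequency_hz) &
                  manifest$condition %in% c("VORd", "OKR", "VORl", "pre", "post"), ,
                drop = FALSE]
  if (nrow(m) == 0) stop("manifest lists no velocity traces", call. = FALSE)
  rows <- vector("list", nrow(m))
  qps <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    rec <- read_trace_csv(file.path(dir, m$file[i]), m$frequency_hz[i],
                          metadata = list(animal = m$animal_id[i],
                                          genotype = m$genotype[i],
                                          condition = m$condition[i]))
    fit <- estimate_gain_phase(rec, desaccade = desaccade, opts = opts)
    rows[[i]] <- data.frame(animal = m$animal_id[i], genotype = m$genotype[i],
                            condition = m$condition[i],
                            frequency_hz = m$frequency_hz[i],
                            gain = fit$gain, phase_deg = fit$phase,
                            vaf = fit$vaf,
                            fraction_retained = fit$fraction_retained)
    if (collect_quick_phases && nrow(fit$quick_phases) > 0)
      qps[[i]] <- cbind(animal = m$animal_id[i], genotype = m$genotype[i],
                        condition = m$condition[i],
                        frequency_hz = m$frequency_hz[i], fit$quick_phases)
  }
  tab <- do.call(rbind, rows)
  key <- interaction(tab$animal, tab$condition, tab$frequency_hz, drop = TRUE)
  if (anyDuplicated(key)) {  # average repeats per animal/condition/frequency
    agg <- stats::aggregate(cbind(gain, phase_deg, vaf, fraction_retained) ~
                              animal + genotype + condition + frequency_hz,
                            data = tab, FUN = mean)
    tab <- agg[order(agg$genotype, agg$condition, agg$frequency_hz, agg$animal), ]
    rownames(tab) <- NULL
  }
  grp <- split(tab, interaction(tab$genotype, tab$condition, tab$frequency_hz,
                                drop = TRUE))
  summ <- do.call(rbind, lapply(grp, function(g) {
    data.frame(genotype = g$genotype[1], condition = g$condition[1],
               frequency_hz = g$frequency_hz[1], n = nrow(g),
               mean_gain = mean(g$gain), sem_gain = sem(g$gain),
               mean_phase = mean(g$phase_deg), sem_phase = sem(g$phase_deg))
  }))
  summ <- summ[order(summ$condition, summ$genotype, summ$frequency_hz), ]
  rownames(summ) <- NULL
  out <- list(table = tab, summary = summ)
  if (collect_quick_phases)
    out$quick_phases <- do.call(rbind, qps[!vapply(qps, is.null, TRUE)])
  out
}
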