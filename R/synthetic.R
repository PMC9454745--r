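#' Specification of a sinusoidal head (or surround) velocity stimulus
#'
#' The study conditions are sinusoidal table rotation at 0.2-2 Hz with a peak
#' velocity of 16 deg/s, acquired at 1 kHz.
#'
#' @param frequency stimulus frequency in Hz (> 0).
#' @param peak_velocity peak velocity in deg/s (> 0; 0 allowed for a null trace).
#' @param duration trace duration in s; must cover at least two full cycles.
#' @param sampling_rate sampling rate in Hz (>= 100).
#' @return an object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(frequency, peak_velocity = 16, duration = 60,
                          sampling_rate = 1000) {
  check_that(is.numeric(frequency) && frequency > 0, "frequency", "must be > 0")
  check_that(is.numeric(peak_velocity) && peak_velocity >= 0, "peak_velocity",
             "must be >= 0")
  check_that(is.numeric(duration) && duration >= 2 / frequency, "duration",
             "must cover at least two full stimulus cycles")
  check_that(is.numeric(sampling_rate) && sampling_rate >= 100, "sampling_rate",
             "must be >= 100 Hz")
  structure(list(frequency = frequency, peak_velocity = peak_velocity,
                 duration = duration, sampling_rate = sampling_rate),
            class = "stimulus_spec")
}

#' Generate a sinusoidal head-velocity trace
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @return a \code{head_stimulus}: list with \code{time} (s), \code{velocity}
#'   (deg/s, \code{A * sin(2*pi*f*t)}) and the \code{spec}.
#' @export
gen_head_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  structure(list(time = t,
                 velocity = spec$peak_velocity * sin(2 * pi * spec$frequency * t),
                 spec = spec),
            class = "head_stimulus")
}

#' Eye-response model for synthetic recordings
#'
#' Describes the slow-phase response (gain and phase relative to the ideal
#' compensatory response), additive band-limited noise, and superimposed quick
#' phases obeying a linear amplitude/peak-velocity main sequence.
#'
#' @param gain slow-phase gain (>= 0, dimensionless).
#' @param phase slow-phase phase in degrees; 0 means perfectly compensatory
#'   (eye velocity = -gain * head velocity).
#' @param noise_sd SD in deg/s of additive Gaussian noise after low-pass
#'   filtering at 125 Hz (mirrors the acquisition chain).
#' @param qp_rate quick-phase rate in events/s (Poisson, with refractory gap).
#' @param ms_slope main-sequence slope in 1/s (peak velocity per degree).
#' @param ms_intercept main-sequence intercept in deg/s.
#' @param qp_duration nominal quick-phase width in s; the refractory gap
#'   between consecutive quick phases is at least \code{2 * qp_duration}.
#'   Each pulse's actual width is \code{2 * amplitude / peak_velocity} so the
#'   raised-cosine waveform carries both its amplitude (time integral) and its
#'   main-sequence peak velocity exactly.
#' @param qp_amp_range amplitude range in degrees; amplitudes drawn uniformly.
#' @param alternate_direction if TRUE (default) quick phases reset against the
#'   ongoing slow phase (direction = -sign of slow-phase eye velocity at
#'   onset), as in physiological nystagmus; if FALSE directions are random.
#' @return an object of class \code{eye_model_spec}.
#' @export
eye_model_spec <- function(gain, phase = 0, noise_sd = 0, qp_rate = 0,
                           ms_slope = 35, ms_intercept = 10,
                           qp_duration = 0.05, qp_amp_range = c(2, 10),
                           alternate_direction = TRUE) {
  check_that(is.numeric(gain) && gain >= 0, "gain", "must be >= 0")
  check_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(is.numeric(qp_rate) && qp_rate >= 0, "qp_rate", "must be >= 0")
  if (qp_rate > 0)
    check_that(ms_slope > 0, "ms_slope", "must be > 0 when qp_rate > 0")
  check_that(qp_duration > 0, "qp_duration", "must be > 0")
  check_that(length(qp_amp_range) == 2 && qp_amp_range[1] > 0 &&
               diff(qp_amp_range) >= 0, "qp_amp_range",
             "must be an increasing positive pair")
  structure(list(gain = gain, phase = phase, noise_sd = noise_sd,
                 qp_rate = qp_rate, ms_slope = ms_slope,
                 ms_intercept = ms_intercept, qp_duration = qp_duration,
                 qp_amp_range = qp_amp_range,
                 alternate_direction = alternate_direction),
            class = "eye_model_spec")
}

# Gaussian noise band-limited to `cutoff` Hz (4th-order zero-phase Butterworth),
# rescaled so the SD *after* filtering equals `sd`.
bandlimited_noise <- function(n, sd, sampling_rate, cutoff = 125) {
  if (sd <= 0 || n == 0) return(numeric(n))
  z <- stats::rnorm(n)
  if (cutoff < sampling_rate / 2) {
    bf <- signal::butter(4, cutoff / (sampling_rate / 2))
    z <- signal::filtfilt(bf, z)
  }
  z * sd / stats::sd(z)
}

# Draw quick-phase events: Poisson onsets at qp_rate thinned to enforce a
# refractory gap >= 2*qp_duration after the previous pulse's offset; uniform
# amplitudes; peak velocity from the main-sequence line; width 2A/P.
draw_quick_phases <- function(duration, spec) {
  if (spec$qp_rate <= 0) {
    return(data.frame(onset = numeric(0), amplitude = numeric(0),
                      peak_velocity = numeric(0), width = numeric(0),
                      direction = numeric(0)))
  }
  n_cand <- stats::rpois(1, spec$qp_rate * duration)
  cand <- sort(stats::runif(n_cand, 0, duration))
  onset <- amp <- pk <- wid <- numeric(0)
  last_off <- -Inf
  for (tc in cand) {
    if (tc < last_off + 2 * spec$qp_duration) next
    a <- stats::runif(1, spec$qp_amp_range[1], spec$qp_amp_range[2])
    p <- spec$ms_slope * a + spec$ms_intercept
    w <- 2 * a / p
    if (tc + w > duration) next  # would overlap end of trace
    onset <- c(onset, tc); amp <- c(amp, a); pk <- c(pk, p); wid <- c(wid, w)
    last_off <- tc + w
  }
  data.frame(onset = onset, amplitude = amp, peak_velocity = pk,
             width = wid, direction = rep(1, length(onset)))
}

#' Generate a synthetic eye-velocity recording for a head stimulus
#'
#' The eye trace is \code{sense * gain * A * sin(2*pi*f*t + phase)} (with
#' \code{sense = -1} for compensatory reflexes, \code{+1} for stimulus-following
#' responses such as the OKR), plus band-limited Gaussian noise and injected
#' quick-phase velocity pulses. Each quick phase is a raised-cosine velocity
#' pulse whose time integral equals its amplitude and whose peak equals the
#' main-sequence prediction. A ground-truth log of the true gain/phase and all
#' injected pulses is attached.
#'
#' @param head a \code{head_stimulus} from \code{\link{gen_head_stimulus}}.
#' @param spec an \code{\link{eye_model_spec}}.
#' @param seed integer seed for this recording's RNG stream.
#' @param sense -1 (default, compensatory: ideal eye = -head) or +1
#'   (following: ideal eye = +stimulus).
#' @param metadata optional named list (animal, genotype, condition, ...).
#' @return a \code{\link{velocity_recording}} with a \code{ground_truth}
#'   element (true gain/phase, injected quick-phase table, noise SD).
#' @export
gen_eye_response <- function(head, spec, seed, sense = -1, metadata = list()) {
  stopifnot(inherits(head, "head_stimulus"), inherits(spec, "eye_model_spec"))
  stopifnot(sense %in% c(-1, 1))
  set.seed(seed)
  st <- head$spec
  t <- head$time
  n <- length(t)
  phi <- spec$phase * pi / 180
  slow <- sense * spec$gain * st$peak_velocity *
    sin(2 * pi * st$frequency * t + phi)
  eye <- slow + bandlimited_noise(n, spec$noise_sd, st$sampling_rate)

  qp <- draw_quick_phases(st$duration, spec)
  if (nrow(qp) > 0) {
    for (i in seq_len(nrow(qp))) {
      if (spec$alternate_direction && spec$gain > 0) {
        s <- slow[max(1L, 1L + round(qp$onset[i] * st$sampling_rate))]
        qp$direction[i] <- if (s < 0) 1 else -1
      } else {
        qp$direction[i] <- sample(c(-1, 1), 1)
      }
      i0 <- 1L + round(qp$onset[i] * st$sampling_rate)
      i1 <- min(n, 1L + round((qp$onset[i] + qp$width[i]) * st$sampling_rate))
      idx <- i0:i1
      tau <- (t[idx] - qp$onset[i]) / qp$width[i]
      pulse <- qp$peak_velocity[i] / 2 * (1 - cos(2 * pi * tau))
      eye[idx] <- eye[idx] + qp$direction[i] * pulse
    }
  }

  rec <- velocity_recording(time = t, head_vel = head$velocity, eye_vel = eye,
                            sampling_rate = st$sampling_rate,
                            stimulus_frequency = st$frequency,
                            metadata = metadata)
  rec$ground_truth <- list(gain = spec$gain, phase = spec$phase,
                           sense = sense, noise_sd = spec$noise_sd,
                           quick_phases = qp)
  rec
}

#' Renewal-process model for synthetic Purkinje-cell spike trains
#'
#' @param rate mean firing rate in spikes/s (> 0).
#' @param target_cv target coefficient of variation of the inter-spike
#'   intervals (> 0). For \code{gamma_renewal}, ISIs are i.i.d. gamma with
#'   shape \code{k = 1/target_cv^2} and scale \code{target_cv^2/rate}.
#' @param duration train duration in s (> 0).
#' @param process \code{"gamma_renewal"} (default) or \code{"burst_pause"}, a
#'   two-state alternation of high-rate bursts and long pauses that produces
#'   heavy-tailed ISI mixtures (supra-Poisson regularity, CV > 1).
#' @return an object of class \code{spike_model_spec}.
#' @export
spike_model_spec <- function(rate, target_cv, duration,
                             process = c("gamma_renewal", "burst_pause")) {
  check_that(is.numeric(rate) && rate > 0, "rate", "must be > 0")
  check_that(is.numeric(target_cv) && target_cv > 0, "target_cv", "must be > 0")
  check_that(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  process <- match.arg(process)
  structure(list(rate = rate, target_cv = target_cv, duration = duration,
                 process = process),
            class = "spike_model_spec")
}

# ISIs for the burst/pause generator: bursts are gamma(k=4) intervals at
# burst_factor * rate; every L-th interval on average is a pause drawn from a
# gamma(k=2) with mean chosen to keep the overall rate; burst_factor is solved
# so the ISI-mixture CV hits target_cv.
burst_pause_isis <- function(n, rate, target_cv, burst_len = 8) {
  q <- 1 / burst_len                       # fraction of ISIs that are pauses
  mix_cv <- function(f) {
    m_b <- 1 / (f * rate)
    m_p <- (1 / rate - (1 - q) * m_b) / q
    if (m_p <= 0) return(NA_real_)
    v <- (1 - q) * (m_b^2 / 4) + q * (m_p^2 / 2) +
      (1 - q) * (m_b - 1 / rate)^2 + q * (m_p - 1 / rate)^2
    sqrt(v) * rate
  }
  lo <- 1.05; hi <- 200
  f <- tryCatch(stats::uniroot(function(f) mix_cv(f) - target_cv,
                               c(lo, hi))$root,
                error = function(e) {
                  warning("burst_pause: target_cv ", target_cv,
                          " out of reachable range; using closest attainable")
                  if (!is.na(mix_cv(lo)) && target_cv < mix_cv(lo)) lo else hi
                })
  m_b <- 1 / (f * rate)
  m_p <- (1 / rate - (1 - q) * m_b) / q
  is_pause <- stats::runif(n) < q
  isi <- numeric(n)
  nb <- sum(!is_pause)
  isi[!is_pause] <- stats::rgamma(nb, shape = 4, scale = m_b / 4)
  isi[is_pause] <- stats::rgamma(n - nb, shape = 2, scale = m_p / 2)
  isi
}

#' Generate a synthetic spike train
#'
#' @param spec a \code{\link{spike_model_spec}}.
#' @param seed integer seed.
#' @param metadata optional named list (cell id, genotype, state).
#' @return a \code{\link{spike_train}} with strictly increasing spike times in
#'   \code{[0, duration]}.
#' @export
gen_spike_train <- function(spec, seed, metadata = list()) {
  stopifnot(inherits(spec, "spike_model_spec"))
  set.seed(seed)
  k <- 1 / spec$target_cv^2
  if (spec$process == "gamma_renewal" && k > 1e6) {
    warning("target_cv implies gamma shape > 1e6; generating a regular train")
    times <- seq(1 / spec$rate, spec$duration, by = 1 / spec$rate)
    return(spike_train(times, spec$duration, metadata))
  }
  draw <- function(m) {
    switch(spec$process,
           gamma_renewal = stats::rgamma(m, shape = k, scale = 1 / (k * spec$rate)),
           burst_pause = burst_pause_isis(m, spec$rate, spec$target_cv))
  }
  n0 <- ceiling(spec$rate * spec$duration +
                  10 * sqrt(spec$rate * spec$duration) + 10)
  isi <- draw(n0)
  times <- cumsum(isi)
  while (times[length(times)] < spec$duration) {
    isi <- draw(n0)
    times <- c(times, times[length(times)] + cumsum(isi))
  }
  spike_train(times[times <= spec$duration], spec$duration, metadata)
}
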