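# Shared fixture builders. Everything is generated in code at test time;
# cohort configs are scaled down from the study defaults so the suite stays
# fast, while the acceptance tests use the study-scale parameters directly.

# a small two-frequency cohort config for pipeline-level tests
small_cohort_config <- function(n_animals = 3, duration = 6,
                                frequencies = c(0.4, 2),
                                noise_sd = 1, qp_rate = 1,
                                spike_duration = 30, n_cells = 3) {
  pick <- match(frequencies, c(0.2, 0.4, 0.8, 1, 2))
  cfg <- cohort_config()
  cfg$stimulus$duration <- duration
  cfg$stimulus$frequencies <- frequencies
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$n_animals <- n_animals
    cfg$groups[[g]]$noise_sd <- noise_sd
    cfg$groups[[g]]$qp_rate <- qp_rate
    for (cc in names(cfg$groups[[g]]$conditions)) {
      cfg$groups[[g]]$conditions[[cc]]$gain <-
        cfg$groups[[g]]$conditions[[cc]]$gain[pick]
      cfg$groups[[g]]$conditions[[cc]]$phase <-
        cfg$groups[[g]]$conditions[[cc]]$phase[pick]
    }
  }
  for (g in names(cfg$learning)) {
    cfg$learning[[g]]$n_animals <- n_animals
    cfg$learning[[g]]$gain_pre <- cfg$learning[[g]]$gain_pre[pick]
    cfg$learning[[g]]$gain_post <- cfg$learning[[g]]$gain_post[pick]
  }
  cfg$spikes$duration <- spike_duration
  for (s in c("anesthetized", "awake"))
    for (g in names(cfg$spikes[[s]]))
      cfg$spikes[[s]][[g]]$n_cells <- n_cells
  cfg
}

# one synthetic recording with known truth
make_recording <- function(gain = 0.65, phase = 0, frequency = 2,
                           duration = 20, noise_sd = 2, qp_rate = 1.5,
                           seed = 1, sampling_rate = 1000, peak = 16,
                           sense = -1, metadata = list()) {
  sp <- stimulus_spec(frequency, peak, duration, sampling_rate)
  em <- eye_model_spec(gain = gain, phase = phase, noise_sd = noise_sd,
                       qp_rate = qp_rate)
  gen_eye_response(gen_head_stimulus(sp), em, seed = seed, sense = sense,
                   metadata = metadata)
}

# discrete Fourier projection of a uniformly sampled signal at frequency f:
# amplitude and phase of the best-fitting a*sin + b*cos over whole cycles
fourier_projection <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  a <- 2 * mean(x * sin(2 * pi * f * t))
  b <- 2 * mean(x * cos(2 * pi * f * t))
  list(amplitude = sqrt(a^2 + b^2), phase = atan2(b, a) * 180 / pi,
       a = a, b = b)
}

# exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1) group
# assignments of the pooled (tie-free) sample
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# did a detected event hit one of the injected pulses?
match_events <- function(detected, injected, opts = desaccade_options(),
                         slack = 0.01) {
  inj_on <- injected$onset - opts$margin_before - slack
  inj_off <- injected$onset + injected$width + opts$margin_after + slack
  hit_inj <- vapply(seq_len(nrow(injected)), function(i)
    any(detected$offset >= injected$onset[i] &
          detected$onset <= injected$onset[i] + injected$width[i]),
    logical(1))
  spurious <- vapply(seq_len(nrow(detected)), function(j)
    !any(detected$offset[j] >= inj_on & detected$onset[j] <= inj_off),
    logical(1))
  list(hit = hit_inj, spurious = spurious)
}
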