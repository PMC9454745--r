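test_that("sinusoid fit is exact on noiseless model signals", {
  t <- (0:1999) / 1000
  f1 <- fit_sinusoid(sin(2 * pi * 2 * t), 2, 1000)
  expect_equal(f1$amplitude, 1, tolerance = 1e-9)
  expect_equal(f1$phase, 0, tolerance = 1e-9)
  expect_equal(f1$offset, 0, tolerance = 1e-9)

  f0 <- fit_sinusoid(rep(0, 2000), 2, 1000)
  expect_equal(f0$amplitude, 0)
  expect_equal(f0$offset, 0)
})

test_that("sinusoid fit matches a brute-force grid-search oracle", {
  t <- (0:1999) / 1000
  s <- 12.8 * sin(2 * pi * t + 30 * pi / 180) + 5
  fit <- fit_sinusoid(s, 1, 1000)
  expect_equal(fit$amplitude, 12.8, tolerance = 1e-6)
  expect_equal(fit$phase, 30, tolerance = 1e-6)
  expect_equal(fit$offset, 5, tolerance = 1e-6)

  # independent oracle: zooming grid search over (a, b, c) minimising the SSE
  sse <- function(a, b, c0) {
    pred <- a * sin(2 * pi * t) + b * cos(2 * pi * t) + c0
    sum((s - pred)^2)
  }
  ctr <- c(0, 0, 0); span <- 20
  for (stage in 1:8) {
    gr <- expand.grid(a = ctr[1] + seq(-span, span, length.out = 11),
                      b = ctr[2] + seq(-span, span, length.out = 11),
                      c0 = ctr[3] + seq(-span, span, length.out = 11))
    vals <- mapply(sse, gr$a, gr$b, gr$c0)
    ctr <- unlist(gr[which.min(vals), ])
    span <- span / 5
  }
  expect_equal(unname(sqrt(ctr[1]^2 + ctr[2]^2)), fit$amplitude,
               tolerance = 1e-4)
  expect_equal(unname(atan2(ctr[2], ctr[1]) * 180 / pi), fit$phase,
               tolerance = 1e-3)
  expect_equal(unname(ctr[3]), fit$offset, tolerance = 1e-4)
})

test_that("masked samples have no influence on the fit", {
  t <- (0:999) / 500
  s <- 3 * sin(2 * pi * 2 * t) + 1
  mask <- rep(FALSE, 1000)
  mask[101:200] <- TRUE
  s_bad <- s
  s_bad[mask] <- 500  # garbage where masked
  f_ref <- fit_sinusoid(s, 2, 500, mask)
  f_bad <- fit_sinusoid(s_bad, 2, 500, mask)
  expect_equal(f_bad$amplitude, f_ref$amplitude)
  expect_equal(f_bad$phase, f_ref$phase)
})

test_that("sinusoid fit validates its inputs", {
  expect_error(fit_sinusoid(1:100, -2, 100), "frequency")
  expect_error(fit_sinusoid(1:10, 2, 100, mask = rep(TRUE, 10)), "3 unmasked")
})

test_that("fit equals the discrete Fourier projection on integer-cycle traces", {
  set.seed(7)
  for (f in c(0.5, 2)) {
    x <- 4 * sin(2 * pi * f * (0:3999) / 1000 + 1) + rnorm(4000)
    fit <- fit_sinusoid(x, f, 1000)
    pr <- fourier_projection(x, f, 1000)
    expect_equal(fit$amplitude, pr$amplitude, tolerance = 1e-8)
    expect_equal(fit$a, pr$a, tolerance = 1e-8)
    expect_equal(fit$b, pr$b, tolerance = 1e-8)
  }
})

test_that("a clean sinusoid yields no quick-phase detections", {
  h <- gen_head_stimulus(stimulus_spec(2, 16, 5, 1000))
  rec <- gen_eye_response(h, eye_model_spec(gain = 0.8), seed = 1)
  dq <- detect_quick_phases(rec)
  expect_equal(nrow(dq$events), 0)
  expect_false(any(dq$mask))
})

test_that("injected quick phases are found where they were injected", {
  rec <- make_recording(gain = 0.65, duration = 20, noise_sd = 2,
                        qp_rate = 1, seed = 31)
  inj <- rec$ground_truth$quick_phases
  dq <- detect_quick_phases(rec)
  m <- match_events(dq$events, inj)
  expect_gte(mean(m$hit), 0.95)
  expect_equal(sum(m$spurious), 0)
  # detected amplitudes within 10% of injected (median over matched events)
  det_amp <- vapply(seq_len(nrow(inj)), function(i) {
    j <- which(dq$events$offset >= inj$onset[i] &
                 dq$events$onset <= inj$onset[i] + inj$width[i])
    if (length(j)) abs(dq$events$amplitude[j[1]]) else NA_real_
  }, numeric(1))
  rel_err <- abs(det_amp - inj$amplitude) / inj$amplitude
  expect_lt(median(rel_err, na.rm = TRUE), 0.10)
})

test_that("saccade-dominated traces raise the degenerate-input error", {
  t <- (0:9999) / 1000
  # 85% duty square wave: nearly every sample sits far from the fitted
  # sinusoid while the robust SD collapses, so the mask swallows the trace
  big <- rep(c(rep(50, 17), rep(-50, 3)), length.out = length(t))
  rec <- velocity_recording(t, 16 * sin(2 * pi * 2 * t), big, 1000, 2)
  expect_error(detect_quick_phases(rec), "80%")
})

test_that("gain and phase follow the ideal-response conventions", {
  h <- gen_head_stimulus(stimulus_spec(2, 16, 5, 1000))
  rec <- gen_eye_response(h, eye_model_spec(gain = 1), seed = 1)
  fit <- estimate_gain_phase(rec, desaccade = FALSE)
  expect_equal(fit$gain, 1, tolerance = 1e-10)
  expect_equal(fit$phase, 0, tolerance = 1e-8)

  # absent response: gain ~ 0
  set.seed(2)
  rec0 <- velocity_recording(h$time, h$velocity, rnorm(length(h$time)),
                             1000, 2)
  expect_lt(estimate_gain_phase(rec0, desaccade = FALSE)$gain, 0.05)

  # OKR convention: eye following the surround has phase 0
  okr <- gen_eye_response(h, eye_model_spec(gain = 0.7), seed = 1, sense = 1,
                          metadata = list(condition = "OKR"))
  fit_okr <- estimate_gain_phase(okr, desaccade = FALSE)
  expect_equal(fit_okr$gain, 0.7, tolerance = 1e-10)
  expect_equal(fit_okr$phase, 0, tolerance = 1e-8)

  # no stimulus in the head channel
  rec_ns <- velocity_recording(h$time, h$velocity * 0, rec$eye_vel, 1000, 2)
  expect_error(estimate_gain_phase(rec_ns), "stimulus")
})

test_that("realistic traces recover gain and phase through desaccading", {
  rec <- make_recording(gain = 0.46, phase = 5, frequency = 2, duration = 60,
                        noise_sd = 2, qp_rate = 1.5, seed = 8)
  fit <- estimate_gain_phase(rec)
  expect_equal(fit$gain, 0.46, tolerance = 0.02 / 0.46)
  expect_equal(fit$phase, 5, tolerance = 2 / 5)
})

test_that("gain is offset-invariant and negation flips phase by 180 degrees", {
  rec <- make_recording(gain = 0.6, duration = 10, noise_sd = 1, qp_rate = 0,
                        seed = 3)
  fit <- estimate_gain_phase(rec, desaccade = FALSE)
  rec_off <- rec; rec_off$eye_vel <- rec$eye_vel + 7
  fit_off <- estimate_gain_phase(rec_off, desaccade = FALSE)
  expect_equal(fit_off$gain, fit$gain, tolerance = 1e-12)

  rec_neg <- rec; rec_neg$eye_vel <- -rec$eye_vel
  fit_neg <- estimate_gain_phase(rec_neg, desaccade = FALSE)
  expect_equal(wrap_degrees(fit_neg$phase - fit$phase), 180, tolerance = 1e-8)
})

test_that("gain variance grows with noise and shrinks with duration", {
  est <- function(noise_sd, duration, seed)
    estimate_gain_phase(make_recording(gain = 0.6, duration = duration,
                                       noise_sd = noise_sd, qp_rate = 0,
                                       seed = seed),
                        desaccade = FALSE)$gain
  seeds <- 1:12
  v_low <- var(vapply(seeds, function(s) est(0.5, 5, s), numeric(1)))
  v_high <- var(vapply(seeds, function(s) est(4, 5, s), numeric(1)))
  v_long <- var(vapply(seeds, function(s) est(4, 40, s), numeric(1)))
  expect_gt(v_high, v_low)
  expect_gt(v_high, v_long)
})

test_that("desaccading removes the quick-phase bias in the gain estimate", {
  errs <- vapply(1:6, function(s) {
    rec <- make_recording(gain = 0.5, duration = 30, noise_sd = 2,
                          qp_rate = 1.5, seed = 100 + s)
    c(raw = abs(estimate_gain_phase(rec, desaccade = FALSE)$gain - 0.5),
      des = abs(estimate_gain_phase(rec)$gain - 0.5))
  }, numeric(2))
  expect_gt(mean(errs["raw", ]), mean(errs["des", ]))
})

test_that("frequency response tables aggregate the cohort correctly", {
  dir <- withr::local_tempdir()
  cfg <- small_cohort_config(n_animals = 3, duration = 5, frequencies = 2,
                             noise_sd = 0, qp_rate = 0)
  cfg$learning <- NULL; cfg$spikes <- NULL
  out <- gen_cohort(cfg, seed = 4, out_dir = dir)
  fr <- frequency_response(out$manifest, dir)
  # 2 genotypes x 3 conditions x 3 animals x 1 frequency
  expect_equal(nrow(fr$table), 18)
  # identical noise-free recordings within a group -> SEM = 0
  expect_true(all(fr$summary$sem_gain < 1e-10))
  # group means equal the configured gains
  wt2 <- fr$summary[fr$summary$genotype == "WT" &
                      fr$summary$condition == "VORd", ]
  expect_equal(wt2$mean_gain, cfg$groups$WT$conditions$VORd$gain,
               tolerance = 1e-8)
})

test_that("group means recover the configured genotype gains under noise", {
  dir <- withr::local_tempdir()
  cfg <- small_cohort_config(n_animals = 4, duration = 20, frequencies = 2,
                             noise_sd = 2, qp_rate = 1.5)
  cfg$learning <- NULL; cfg$spikes <- NULL
  cfg$groups$WT$conditions <- cfg$groups$WT$conditions["VORd"]
  cfg$groups$SCA6$conditions <- cfg$groups$SCA6$conditions["VORd"]
  out <- gen_cohort(cfg, seed = 12, out_dir = dir)
  fr <- frequency_response(out$manifest, dir)
  s <- fr$summary
  expect_equal(s$mean_gain[s$genotype == "WT"], 0.80, tolerance = 0.02 / 0.80)
  expect_equal(s$mean_gain[s$genotype == "SCA6"], 0.576,
               tolerance = 0.02 / 0.576)
})
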