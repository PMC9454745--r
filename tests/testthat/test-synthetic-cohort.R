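test_that("head stimulus is an exact sinusoid at the requested grid", {
  h <- gen_head_stimulus(stimulus_spec(2, 16, 1, 1000))
  expect_length(h$velocity, 1000)
  expect_equal(max(h$velocity), 16)
  expect_equal(h$velocity[h$time == 0.125], 16)  # quarter period of 2 Hz
  expect_true(all(abs(h$velocity) <= 16 + 1e-12))

  h0 <- gen_head_stimulus(stimulus_spec(2, 0, 1, 1000))
  expect_true(all(h0$velocity == 0))

  h1 <- gen_head_stimulus(stimulus_spec(1, 10, 2, 1000))
  expect_equal(h1$velocity[h1$time == 0.25], 10)
})

test_that("stimulus validation names the offending field", {
  expect_error(stimulus_spec(-1), "frequency")
  expect_error(stimulus_spec(1, duration = 0.5), "duration")
  expect_error(stimulus_spec(1, sampling_rate = 50), "sampling_rate")
})

test_that("degenerate eye models produce the expected traces", {
  h <- gen_head_stimulus(stimulus_spec(1, 16, 4, 1000))
  null <- gen_eye_response(h, eye_model_spec(gain = 0), seed = 1)
  expect_true(all(null$eye_vel == 0))

  ideal <- gen_eye_response(h, eye_model_spec(gain = 1), seed = 1)
  expect_equal(ideal$eye_vel, -h$velocity)
})

test_that("eye response carries the requested gain at the stimulus frequency", {
  # Fourier amplitude of the generated eye trace vs the closed-form target
  h <- gen_head_stimulus(stimulus_spec(1, 16, 20, 1000))
  rec <- gen_eye_response(h, eye_model_spec(gain = 0.8, noise_sd = 0.5),
                          seed = 11)
  pr <- fourier_projection(rec$eye_vel, 1, 1000)
  expect_equal(pr$amplitude, 0.8 * 16, tolerance = 0.01)
})

test_that("noise-free generation and fitting are mutually exact (spectral fidelity)", {
  for (gain in c(0.3, 0.8)) {
    for (phase in c(-20, 0, 35)) {
      for (f in c(0.4, 2)) {
        h <- gen_head_stimulus(stimulus_spec(f, 16, 10, 500))
        rec <- gen_eye_response(h, eye_model_spec(gain = gain, phase = phase),
                                seed = 1)
        fit <- estimate_gain_phase(rec, desaccade = FALSE)
        expect_equal(fit$gain, gain, tolerance = 1e-10)
        expect_equal(fit$phase, phase, tolerance = 1e-8)
      }
    }
  }
})

test_that("injected quick phases honour the ground-truth contract", {
  h <- gen_head_stimulus(stimulus_spec(2, 16, 30, 1000))
  em <- eye_model_spec(gain = 0.8, noise_sd = 0, qp_rate = 1.5)
  rec <- gen_eye_response(h, em, seed = 5)
  qp <- rec$ground_truth$quick_phases
  expect_gt(nrow(qp), 10)
  expect_true(all(qp$onset >= 0 & qp$onset + qp$width <= 30))
  expect_true(all(qp$amplitude >= 2 & qp$amplitude <= 10))
  expect_equal(qp$peak_velocity, 35 * qp$amplitude + 10)
  # refractory: gaps between consecutive pulses at least 2 * qp_duration
  expect_true(all(diff(qp$onset) - qp$width[-nrow(qp)] >= 2 * 0.05 - 1e-9))
  # each pulse integrates to its amplitude (sampled raised cosine)
  slow <- -0.8 * 16 * sin(2 * pi * 2 * h$time)
  resid <- rec$eye_vel - slow
  for (i in seq_len(nrow(qp))) {
    idx <- which(h$time >= qp$onset[i] & h$time <= qp$onset[i] + qp$width[i])
    expect_equal(abs(sum(resid[idx]) / 1000), qp$amplitude[i],
                 tolerance = 0.02)
  }
  # main-sequence fidelity: injected pairs sit exactly on the configured line,
  # so their regression recovers the slope to numerical precision
  slope_hat <- cov(qp$amplitude, qp$peak_velocity) / var(qp$amplitude)
  expect_equal(slope_hat, 35, tolerance = 1e-10)
})

test_that("gamma renewal trains match their target moments", {
  # near-regular limit
  tr <- gen_spike_train(spike_model_spec(10, 0.01, 100), seed = 1)
  expect_lt(isi_cv(tr), 0.02)

  # k = 4 (CV 0.5) Monte Carlo vs gamma moments
  tr <- gen_spike_train(spike_model_spec(30, 0.5, 600), seed = 1)
  expect_equal(isi_cv(tr), 0.5, tolerance = 0.06)  # 0.5 +/- 0.03
  expect_equal(firing_rate(tr), 30, tolerance = 1 / 30)

  # CV 1 is indistinguishable from Poisson
  tr <- gen_spike_train(spike_model_spec(20, 1, 500), seed = 2)
  ks <- ks.test(isi(tr), "pexp", rate = 20)
  expect_gt(ks$p.value, 0.01)

  # contract: strictly increasing times within [0, duration]
  expect_true(all(diff(tr$times) > 0))
  expect_true(min(tr$times) >= 0 && max(tr$times) <= 500)
})

test_that("near-zero target CV is clamped to a regular train with a warning", {
  expect_warning(tr <- gen_spike_train(spike_model_spec(10, 1e-4, 10), seed = 1),
                 "regular")
  expect_equal(isi_cv(tr), 0)
})

test_that("empirical CV converges to target at root-n rate", {
  errs <- vapply(c(1e2, 1e3, 1e4), function(n) {
    tr <- gen_spike_train(spike_model_spec(20, 0.5, (n + 1) / 20), seed = 42)
    abs(isi_cv(tr) - 0.5)
  }, numeric(1))
  # O(n^-1/2): generous 5/sqrt(n) envelope, and the error must shrink
  expect_true(all(errs < 5 / sqrt(c(1e2, 1e3, 1e4))))
  expect_lt(errs[3], errs[1])
})

test_that("burst-pause trains reach supra-Poisson irregularity at the right rate", {
  tr <- gen_spike_train(spike_model_spec(25, 1.6, 400, process = "burst_pause"),
                        seed = 3)
  expect_gt(isi_cv(tr), 1.2)
  expect_equal(firing_rate(tr), 25, tolerance = 0.1)
})

test_that("cohort generation is deterministic, complete and truthfully logged", {
  cfg <- small_cohort_config(n_animals = 2, duration = 5, frequencies = 2,
                             spike_duration = 10, n_cells = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- gen_cohort(cfg, seed = 9, out_dir = d1)
  out2 <- gen_cohort(cfg, seed = 9, out_dir = d2)

  # counting: 2 genotypes x 1 freq x (3 conditions x 2 + pre/post x 2) animals
  n_traces <- 2 * 1 * (3 * 2 + 2 * 2)
  n_spikes <- 2 * 2 * 2
  expect_equal(nrow(out1$manifest), n_traces + n_spikes)
  expect_setequal(list.files(d1), c(out1$manifest$file, "manifest.json",
                                    "ground_truth.json"))

  # byte-identical outputs for identical (config, seed)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # ground-truth gains equal config gains exactly
  gt <- out1$ground_truth
  wt_vord <- grep("^WT_a.*VORd", names(gt), value = TRUE)
  expect_equal(unique(vapply(gt[wt_vord], `[[`, numeric(1), "gain")),
               cfg$groups$WT$conditions$VORd$gain)
})

test_that("incomplete cohort configs are rejected with the field named", {
  cfg <- small_cohort_config()
  cfg$groups$WT$conditions$VORd$gain <- 0.8  # one value for two frequencies
  expect_error(gen_cohort(cfg, 1, withr::local_tempdir()), "VORd")
  cfg2 <- small_cohort_config()
  cfg2$stimulus <- NULL
  expect_error(gen_cohort(cfg2, 1, withr::local_tempdir()), "stimulus")
})

test_that("YAML cohort configs drive the generator like native ones", {
  cfg <- read_cohort_config(system.file("extdata", "demo_cohort.yaml",
                                        package = "gazelab"))
  cfg$stimulus$duration <- 5
  cfg$stimulus$frequencies <- 2
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$n_animals <- 1
    for (cc in names(cfg$groups[[g]]$conditions)) {
      cfg$groups[[g]]$conditions[[cc]]$gain <-
        cfg$groups[[g]]$conditions[[cc]]$gain[2]
      cfg$groups[[g]]$conditions[[cc]]$phase <-
        cfg$groups[[g]]$conditions[[cc]]$phase[2]
    }
  }
  cfg$learning <- NULL
  cfg$spikes$duration <- 5
  for (s in c("anesthetized", "awake"))
    for (g in names(cfg$spikes[[s]]))
      cfg$spikes[[s]][[g]]$n_cells <- 1
  dir <- withr::local_tempdir()
  out <- gen_cohort(cfg, seed = 2, out_dir = dir)
  expect_equal(nrow(out$manifest), 2 * 3 + 4)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
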