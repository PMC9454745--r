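# Reduced demonstration cohort: two stimulus frequencies, short traces.
# The package defaults (cohort_config()) hold the full study conditions.
stimulus:
  frequencies: [0.4, 2.0]
  peak_velocity: 16
  duration: 10
  sampling_rate: 1000
groups:
  WT:
    n_animals: 3
    noise_sd: 2
    qp_rate: 1.5
    ms_slope: 35
    ms_intercept: 10
    conditions:
      VORd: {gain: [0.45, 0.80], phase: [5, 1]}
      OKR: {gain: [0.62, 0.20], phase: [-5, -25]}
      VORl: {gain: [0.92, 0.95], phase: [1, 0]}
  SCA6:
    n_animals: 3
    noise_sd: 2
    qp_rate: 1.5
    ms_slope: 33
    ms_intercept: 12
    conditions:
      VORd: {gain: [0.42, 0.576], phase: [5, 1]}
      OKR: {gain: [0.45, 0.19], phase: [-5, -25]}
      VORl: {gain: [0.72, 0.76], phase: [1, 0]}
learning:
  WT:
    n_animals: 3
    gain_pre: [0.45, 0.80]
    gain_post: [0.36, 0.4304]
  SCA6:
    n_animals: 3
    gain_pre: [0.42, 0.576]
    gain_post: [0.3864, 0.4516]
spikes:
  duration: 60
  process: gamma_renewal
  anesthetized:
    WT: {n_cells: 4, rate: 30.49, cv: 0.41}
    SCA6: {n_cells: 4, rate: 38.83, cv: 0.68}
  awake:
    WT: {n_cells: 4, rate: 38.49, cv: 0.43}
    SCA6: {n_cells: 4, rate: 24.22, cv: 1.06}
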