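#' Default synthetic cohort configuration
#'
#' Encodes the study conditions: sinusoidal stimulation at 0.2, 0.4, 0.8, 1
#' and 2 Hz with 16 deg/s peak velocity sampled at 1 kHz; VORd/OKR/VORl
#' cohorts of 7 WT and 8 SCA6 animals; gain-down learning cohorts of 6 WT and
#' 7 SCA6 animals (training at 2 Hz, where WT lose 46.2% and SCA6 21.6% of
#' their pre-training gain); anesthetized populations of 32 WT and 38 SCA6
#' cells and awake populations of 32 WT and 30 SCA6 cells with the group
#' firing rate and CV values used for calibration. The per-frequency gain and
#' phase profiles are plausible murine values anchored by the quantified 28%
#' WT-vs-SCA6 VORd deficit at 2 Hz (0.800 vs 0.576).
#'
#' @return nested list understood by \code{\link{gen_cohort}}; serialisable
#'   to/from YAML with \code{\link{read_cohort_config}}.
#' @export
cohort_config <- function() {
  freqs <- c(0.2, 0.4, 0.8, 1, 2)
  wt_vord <- c(0.35, 0.45, 0.60, 0.70, 0.80)
  sca_vord <- c(0.33, 0.42, 0.48, 0.55, 0.576)
  wt_pct <- c(10, 20, 30, 38, 46.2)
  sca_pct <- c(5, 8, 12, 15, 21.6)
  list(
    stimulus = list(frequencies = freqs, peak_velocity = 16, duration = 60,
                    sampling_rate = 1000),
    groups = list(
      WT = list(
        n_animals = 7, noise_sd = 2, qp_rate = 1.5,
        ms_slope = 35, ms_intercept = 10,
        conditions = list(
          VORd = list(gain = wt_vord, phase = c(8, 5, 3, 2, 1)),
          OKR = list(gain = c(0.75, 0.62, 0.45, 0.35, 0.20),
                     phase = c(-2, -5, -10, -15, -25)),
          VORl = list(gain = c(0.90, 0.92, 0.95, 0.95, 0.95),
                      phase = c(2, 1, 1, 0, 0)))),
      SCA6 = list(
        n_animals = 8, noise_sd = 2, qp_rate = 1.5,
        ms_slope = 33, ms_intercept = 12,
        conditions = list(
          VORd = list(gain = sca_vord, phase = c(8, 5, 3, 2, 1)),
          OKR = list(gain = c(0.55, 0.45, 0.40, 0.33, 0.19),
                     phase = c(-2, -5, -10, -15, -25)),
          VORl = list(gain = c(0.70, 0.72, 0.75, 0.75, 0.76),
                      phase = c(2, 1, 1, 0, 0))))),
    learning = list(
      WT = list(n_animals = 6, gain_pre = wt_vord,
                gain_post = wt_vord * (1 - wt_pct / 100)),
      SCA6 = list(n_animals = 7, gain_pre = sca_vord,
                  gain_post = sca_vord * (1 - sca_pct / 100))),
    spikes = list(
      duration = 120, process = "gamma_renewal",
      anesthetized = list(
        WT = list(n_cells = 32, rate = 30.49, cv = 0.41),
        SCA6 = list(n_cells = 38, rate = 38.83, cv = 0.68)),
      awake = list(
        WT = list(n_cells = 32, rate = 38.49, cv = 0.43),
        SCA6 = list(n_cells = 30, rate = 24.22, cv = 1.06))))
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file with the \code{\link{cohort_config}} structure.
#' @return the configuration list.
#' @export
read_cohort_config <- function(path) yaml::read_yaml(path)

validate_cohort_config <- function(config) {
  for (sec in c("stimulus", "groups"))
    check_that(!is.null(config[[sec]]), sec, "section missing from config")
  nf <- length(config$stimulus$frequencies)
  check_that(nf >= 1, "stimulus$frequencies", "must list at least one frequency")
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    check_that(!is.null(grp$n_animals), paste0("groups$", g, "$n_animals"),
               "missing")
    for (cond in names(grp$conditions)) {
      cc <- grp$conditions[[cond]]
      check_that(length(cc$gain) == nf,
                 paste0("groups$", g, "$conditions$", cond, "$gain"),
                 "must give one gain per stimulus frequency")
      check_that(length(cc$phase) == nf,
                 paste0("groups$", g, "$conditions$", cond, "$phase"),
                 "must give one phase per stimulus frequency")
    }
  }
  if (!is.null(config$learning)) {
    for (g in names(config$learning)) {
      lg <- config$learning[[g]]
      check_that(length(lg$gain_pre) == nf && length(lg$gain_post) == nf,
                 paste0("learning$", g),
                 "gain_pre/gain_post must give one value per frequency")
    }
  }
  invisible(TRUE)
}

# seconds-based config hash for report provenance
config_hash <- function(config) {
  sprintf("%08x", seed_stream(0, paste(deparse(config), collapse = "")))
}

#' Generate a synthetic cohort on disk
#'
#' Writes trace CSVs, spike-time files, a \code{manifest.json} and a
#' \code{ground_truth.json} under \code{out_dir}. Every file is drawn from
#' its own RNG stream derived from \code{(seed, file key)}, so re-running
#' with the same config and seed is byte-identical and any file can be
#' regenerated in isolation.
#'
#' @param config configuration list (\code{\link{cohort_config}} or
#'   \code{\link{read_cohort_config}}).
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with \code{dir}, \code{manifest} (data.frame)
#'   and \code{ground_truth} (list keyed by file name).
#' @export
gen_cohort <- function(config, seed, out_dir) {
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stimulus
  freqs <- st$frequencies
  manifest <- list()
  truth <- list()

  add_trace <- function(file, animal, genotype, condition, f, gain, phase,
                        grp) {
    spec <- stimulus_spec(f, st$peak_velocity, st$duration, st$sampling_rate)
    head <- gen_head_stimulus(spec)
    em <- eye_model_spec(gain = gain, phase = phase,
                         noise_sd = grp$noise_sd %||% 0,
                         qp_rate = grp$qp_rate %||% 0,
                         ms_slope = grp$ms_slope %||% 35,
                         ms_intercept = grp$ms_intercept %||% 10)
    sense <- if (condition == "OKR") 1 else -1
    rec <- gen_eye_response(head, em, seed_stream(seed, genotype, animal,
                                                  condition, f),
                            sense = sense)
    write_trace_csv(rec, file.path(out_dir, file))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, animal_id = animal, cell_id = NA_character_,
      genotype = genotype, state = NA_character_, condition = condition,
      frequency_hz = f)
    truth[[file]] <<- list(animal_id = animal, genotype = genotype,
                           condition = condition, frequency_hz = f,
                           gain = gain, phase = phase,
                           quick_phases = rec$ground_truth$quick_phases)
  }

  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    for (a in seq_len(grp$n_animals)) {
      animal <- sprintf("%s_a%02d", g, a)
      for (cond in names(grp$conditions)) {
        cc <- grp$conditions[[cond]]
        for (i in seq_along(freqs)) {
          file <- sprintf("%s_%s_%gHz.csv", animal, cond, freqs[i])
          add_trace(file, animal, g, cond, freqs[i], cc$gain[i], cc$phase[i],
                    grp)
        }
      }
    }
  }

  if (!is.null(config$learning)) {
    for (g in names(config$learning)) {
      lg <- config$learning[[g]]
      grp <- config$groups[[g]]
      for (a in seq_len(lg$n_animals)) {
        animal <- sprintf("%s_L%02d", g, a)
        for (i in seq_along(freqs)) {
          for (phase_cond in c("pre", "post")) {
            gain <- if (phase_cond == "pre") lg$gain_pre[i] else lg$gain_post[i]
            file <- sprintf("%s_%s_%gHz.csv", animal, phase_cond, freqs[i])
            add_trace(file, animal, g, phase_cond, freqs[i], gain, 0, grp)
          }
        }
      }
    }
  }

  if (!is.null(config$spikes)) {
    sp <- config$spikes
    for (state in intersect(c("anesthetized", "awake"), names(sp))) {
      for (g in names(sp[[state]])) {
        pg <- sp[[state]][[g]]
        for (cidx in seq_len(pg$n_cells)) {
          cell <- sprintf("%s_%s_c%02d", state, g, cidx)
          file <- sprintf("spikes_%s.txt", cell)
          spec <- spike_model_spec(pg$rate, pg$cv, sp$duration %||% 120,
                                   process = sp$process %||% "gamma_renewal")
          train <- gen_spike_train(spec, seed_stream(seed, state, g, cidx),
                                   metadata = list(cell_id = cell,
                                                   genotype = g, state = state))
          write_spike_file(train, file.path(out_dir, file))
          manifest[[length(manifest) + 1L]] <- data.frame(
            file = file, animal_id = NA_character_, cell_id = cell,
            genotype = g, state = state, condition = NA_character_,
            frequency_hz = NA_real_)
          truth[[file]] <- list(cell_id = cell, genotype = g, state = state,
                                rate = pg$rate, cv = pg$cv,
                                duration = sp$duration %||% 120)
        }
      }
    }
  }

  manifest <- do.call(rbind, manifest)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(dir = out_dir, manifest = manifest, ground_truth = truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
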