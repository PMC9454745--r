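#' Run the full analysis chain on a generated or recorded cohort
#'
#' Reads \code{manifest.json} in \code{data_dir} and produces, under
#' \code{out_dir}: \code{frequency_response.csv} and \code{group_summary.csv}
#' (slow-phase gains/phases), \code{quick_phases.csv} (pooled detected
#' events), \code{main_sequence.json} (per-genotype regression and slope
#' comparison), \code{learning.csv} and \code{learning_summary.csv}
#' (pre/post percent change), and \code{spike_metrics.csv}. Stages whose
#' inputs are absent from the manifest are skipped.
#'
#' @param data_dir directory with the manifest and data files.
#' @param out_dir output directory (created if needed).
#' @param desaccade,opts passed to \code{\link{estimate_gain_phase}}.
#' @return invisibly, a list of the stage outputs.
#' @export
analyze_cohort <- function(data_dir, out_dir,
                           desaccade = TRUE, opts = desaccade_options()) {
  manifest <- read_manifest(file.path(data_dir, "manifest.json"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)

  reflex <- manifest[!is.na(manifest$condition) &
                       manifest$condition %in% c("VORd", "OKR", "VORl"), ]
  if (nrow(reflex) > 0) {
    fr <- frequency_response(reflex, data_dir, desaccade = desaccade,
                             opts = opts, collect_quick_phases = TRUE)
    wcsv(fr$table, "frequency_response.csv")
    wcsv(fr$summary, "group_summary.csv")
    out$frequency_response <- fr
    qp <- fr$quick_phases
    if (!is.null(qp) && nrow(qp) > 0) {
      qp$amplitude <- abs(qp$amplitude)
      wcsv(qp[, c("animal", "genotype", "condition", "frequency_hz",
                  "onset", "amplitude", "peak_velocity", "direction")],
           "quick_phases.csv")
      out$quick_phases <- qp
      genos <- unique(qp$genotype)
      if (length(genos) == 2) {
        ms <- main_sequence_analysis(qp, groups = genos)
        ms_json <- list(
          groups = lapply(ms$fits, function(f)
            list(slope = f$slope, intercept = f$intercept, sse = f$sse,
                 n = f$n)),
          comparison = list(f_stat = ms$comparison$f_stat,
                            df_num = ms$comparison$df_num,
                            df_den = ms$comparison$df_den,
                            p_value = ms$comparison$p_value))
        jsonlite::write_json(ms_json, file.path(out_dir, "main_sequence.json"),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE)
        out$main_sequence <- ms
      }
    }
  }

  learn <- manifest[!is.na(manifest$condition) &
                      manifest$condition %in% c("pre", "post"), ]
  if (nrow(learn) > 0) {
    frl <- frequency_response(learn, data_dir, desaccade = desaccade,
                              opts = opts)
    lt <- learning_table(frl$table)
    wcsv(lt$table, "learning.csv")
    wcsv(lt$summary, "learning_summary.csv")
    out$learning <- lt
  }

  spikes <- manifest[!is.na(manifest$state), ]
  if (nrow(spikes) > 0) {
    trains <- lapply(seq_len(nrow(spikes)), function(i)
      read_spike_file(file.path(data_dir, spikes$file[i]),
                      metadata = list(cell_id = spikes$cell_id[i],
                                      genotype = spikes$genotype[i],
                                      state = spikes$state[i])))
    ps <- population_summary(trains)
    wcsv(ps$table, "spike_metrics.csv")
    wcsv(ps$summary, "spike_summary.csv")
    out$spikes <- ps
  }
  invisible(out)
}

read_stage <- function(dir, file, stage) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop(sprintf("missing stage output `%s` (stage: %s)", file, stage),
         call. = FALSE)
  if (grepl("[.]json$", file)) jsonlite::fromJSON(path) else
    utils::read.csv(path)
}

#' Assemble the statistics report from stage outputs
#'
#' Reproduces the study's result surface on the analysed dataset: per
#' condition, a two-way mixed ANOVA of gain and phase across frequencies with
#' Bonferroni-adjusted per-frequency genotype contrasts; the main-sequence
#' slope comparison; the learning ANOVA plus per-frequency Mann-Whitney tests
#' of percent change; and Mann-Whitney comparisons of firing rate, CV and CV2
#' per state. Writes \code{report.json} and a flat \code{stats_tables.csv}.
#'
#' @param results_dir directory holding the outputs of
#'   \code{\link{analyze_cohort}}.
#' @param out_file path of the JSON report (default
#'   \code{results_dir/report.json}).
#' @param seed seed recorded in the report for provenance (optional).
#' @param config configuration list whose hash is recorded (optional).
#' @return invisibly, the report list.
#' @export
build_report <- function(results_dir, out_file = file.path(results_dir,
                                                           "report.json"),
                         seed = NA, config = NULL) {
  report <- list(meta = list(
    package = "gazelab",
    version = as.character(utils::packageVersion("gazelab")),
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config) else NA))
  rows <- list()
  add_row <- function(analysis, metric, level, stat, value, p = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, metric = metric, level = as.character(level),
      statistic = stat, value = value, p = p)
  }

  fr <- read_stage(results_dir, "frequency_response.csv", "gaze_response")
  gaze <- list()
  for (cond in unique(fr$condition)) {
    d <- fr[fr$condition == cond, ]
    cond_out <- list()
    for (dv in c("gain", "phase_deg")) {
      an <- mixed_anova(d, dv)
      cond_out[[dv]] <- list(
        effects = an$effects,
        posthoc = an$posthoc)
      for (i in seq_len(nrow(an$effects)))
        add_row(paste0("gaze_", cond), dv, an$effects$effect[i], "F",
                an$effects$f[i], an$effects$p[i])
      for (i in seq_len(nrow(an$posthoc)))
        add_row(paste0("gaze_", cond), dv, paste0(an$posthoc$level[i], "Hz"),
                "bonferroni_t", an$posthoc$t[i], an$posthoc$p_adj[i])
    }
    gaze[[cond]] <- cond_out
  }
  report$gaze <- gaze

  ms <- tryCatch(read_stage(results_dir, "main_sequence.json", "quick_phase_kinematics"),
                 error = function(e) NULL)
  if (!is.null(ms)) {
    report$main_sequence <- ms
    add_row("main_sequence", "slope_comparison", "pooled", "F",
            ms$comparison$f_stat, ms$comparison$p_value)
  }

  lt <- tryCatch(read_stage(results_dir, "learning.csv", "vor_learning"),
                 error = function(e) NULL)
  if (!is.null(lt)) {
    an <- mixed_anova(lt, "pct_change")
    mw <- lapply(split(lt, lt$frequency_hz), function(d) {
      genos <- sort(unique(d$genotype), decreasing = TRUE)  # WT first
      mann_whitney(d$pct_change[d$genotype == genos[1]],
                   d$pct_change[d$genotype == genos[2]])
    })
    report$learning <- list(
      anova = list(effects = an$effects, posthoc = an$posthoc),
      mann_whitney = lapply(mw, function(m)
        list(u = m$u_stat, p = m$p_two_sided, method = m$method)))
    for (f in names(mw))
      add_row("learning", "pct_change", paste0(f, "Hz"), "U",
              mw[[f]]$u_stat, mw[[f]]$p_two_sided)
  }

  sm <- tryCatch(read_stage(results_dir, "spike_metrics.csv", "spike_metrics"),
                 error = function(e) NULL)
  if (!is.null(sm)) {
    spk <- list()
    for (state in unique(sm$state)) {
      d <- sm[sm$state == state, ]
      genos <- sort(unique(d$genotype), decreasing = TRUE)
      st_out <- list()
      for (v in c("rate_sps", "cv", "cv2")) {
        m <- mann_whitney(d[[v]][d$genotype == genos[1]],
                          d[[v]][d$genotype == genos[2]])
        st_out[[v]] <- list(u = m$u_stat, n1 = m$n1, n2 = m$n2,
                            p = m$p_two_sided, method = m$method,
                            means = stats::setNames(
                              lapply(genos, function(g)
                                mean(d[[v]][d$genotype == g])), genos))
        add_row(paste0("spikes_", state), v, paste(genos, collapse = "_vs_"),
                "U", m$u_stat, m$p_two_sided)
      }
      spk[[state]] <- st_out
    }
    report$spikes <- spk
  }

  jsonlite::write_json(report, out_file, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  utils::write.csv(do.call(rbind, rows),
                   file.path(dirname(out_file), "stats_tables.csv"),
                   row.names = FALSE)
  invisible(report)
}

#' Simulate, analyse and report in one call
#'
#' Chains \code{\link{gen_cohort}}, \code{\link{analyze_cohort}} and
#' \code{\link{build_report}}.
#'
#' @param config cohort configuration (default \code{\link{cohort_config}()}).
#' @param seed master seed.
#' @param out_dir root output directory; data goes to \code{out_dir/data},
#'   results to \code{out_dir/results}.
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config = cohort_config(), seed, out_dir) {
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  gen_cohort(config, seed, data_dir)
  analyze_cohort(data_dir, res_dir)
  build_report(res_dir, seed = seed, config = config)
}
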