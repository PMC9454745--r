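#' Main-sequence regression of quick-phase kinematics
#'
#' Rapid eye movements obey a stereotyped linear relation between amplitude
#' and peak velocity (the "main sequence"). \code{fit_main_sequence} fits the
#' ordinary least-squares line of peak velocity on amplitude; amplitudes and
#' peak velocities are rectified (absolute values), merging the two
#' directions.
#'
#' @param amplitude event amplitudes in degrees.
#' @param peak_velocity event peak velocities in deg/s.
#' @return an object of class \code{line_fit}: list with \code{slope}
#'   ((deg/s)/deg), \code{intercept} (deg/s), \code{sse}, \code{df}
#'   (\code{n - 2}) and \code{n}.
#' @export
fit_main_sequence <- function(amplitude, peak_velocity) {
  a <- abs(amplitude); p <- abs(peak_velocity)
  stopifnot(length(a) == length(p))
  if (length(a) < 3)
    stop("main-sequence fit needs at least 3 events (df = n - 2 >= 1)",
         call. = FALSE)
  if (stats::sd(a) == 0)
    stop("all amplitudes identical: main-sequence design is rank deficient",
         call. = FALSE)
  fit <- stats::lm(p ~ a)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 sse = sum(stats::residuals(fit)^2),
                 df = stats::df.residual(fit),
                 n = length(a)),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("<line_fit> peak = %.2f * amp + %.2f (n = %d, SSE = %.3g)\n",
              x$slope, x$intercept, x$n, x$sse))
  invisible(x)
}

#' Extra sum-of-squares F test comparing two main-sequence slopes
#'
#' Compares the full model (group-specific slopes and intercepts) against the
#' reduced model (common slope, group-specific intercepts):
#' \code{F = ((SSE_red - SSE_full) / (df_red - df_full)) / (SSE_full / df_full)}
#' with \code{df_num = 1}, so only the slope difference is tested and offset
#' differences between groups are not conflated with it.
#'
#' @param dataA,dataB data.frames with columns \code{amplitude} and
#'   \code{peak_velocity} (one event per row), one per group.
#' @return an object of class \code{slope_comparison}: list with
#'   \code{f_stat}, \code{df_num}, \code{df_den}, \code{p_value}, the two
#'   per-group \code{line_fit}s and the common-slope estimate.
#' @export
compare_slopes <- function(dataA, dataB) {
  need <- c("amplitude", "peak_velocity")
  stopifnot(all(need %in% names(dataA)), all(need %in% names(dataB)))
  fitA <- fit_main_sequence(dataA$amplitude, dataA$peak_velocity)
  fitB <- fit_main_sequence(dataB$amplitude, dataB$peak_velocity)
  d <- rbind(data.frame(a = abs(dataA$amplitude), p = abs(dataA$peak_velocity),
                        g = "A"),
             data.frame(a = abs(dataB$amplitude), p = abs(dataB$peak_velocity),
                        g = "B"))
  d$g <- factor(d$g)
  full <- stats::lm(p ~ a * g, data = d)
  red <- stats::lm(p ~ a + g, data = d)
  sse_full <- sum(stats::residuals(full)^2)
  sse_red <- sum(stats::residuals(red)^2)
  df_full <- stats::df.residual(full)
  df_red <- stats::df.residual(red)
  if (df_full < 1) stop("degenerate design: no residual df in full model",
                        call. = FALSE)
  f <- max(0, ((sse_red - sse_full) / (df_red - df_full)) / (sse_full / df_full))
  structure(list(f_stat = f, df_num = df_red - df_full, df_den = df_full,
                 p_value = stats::pf(f, df_red - df_full, df_full,
                                     lower.tail = FALSE),
                 fitA = fitA, fitB = fitB,
                 common_slope = unname(stats::coef(red)["a"])),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> slopes %.2f vs %.2f: F(%d, %d) = %.3f, p = %.4f\n",
              x$fitA$slope, x$fitB$slope, x$df_num, x$df_den, x$f_stat,
              x$p_value))
  invisible(x)
}

#' Main-sequence analysis of a pooled quick-phase table
#'
#' Pools events across animals within each genotype (events, not per-animal
#' summaries, are the unit of analysis) and compares the two genotype slopes.
#'
#' @param quick_phases data.frame with columns \code{genotype},
#'   \code{amplitude} (deg) and \code{peak_velocity} (deg/s).
#' @param groups the two genotype labels to compare (default WT vs SCA6).
#' @return list with per-group \code{line_fit}s and the
#'   \code{slope_comparison}.
#' @export
main_sequence_analysis <- function(quick_phases, groups = c("WT", "SCA6")) {
  dA <- quick_phases[quick_phases$genotype == groups[1], ]
  dB <- quick_phases[quick_phases$genotype == groups[2], ]
  cmp <- compare_slopes(dA, dB)
  list(groups = groups, fits = stats::setNames(list(cmp$fitA, cmp$fitB), groups),
       comparison = cmp)
}
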