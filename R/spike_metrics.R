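#' Inter-spike intervals of a spike train
#'
#' @param train a \code{\link{spike_train}} or a numeric vector of strictly
#'   increasing spike times in s.
#' @return numeric vector of ISIs in s (all > 0).
#' @export
isi <- function(train) {
  times <- spike_times(train)
  if (length(times) < 2)
    stop("at least 2 spikes are needed to form an ISI", call. = FALSE)
  diff(times)
}

spike_times <- function(train) {
  if (inherits(train, "spike_train")) return(train$times)
  if (is.numeric(train)) {
    d <- diff(train)
    if (length(d) && any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop(sprintf("spike times must be strictly increasing; violated at index %d",
                   i + 1L), call. = FALSE)
    }
    return(train)
  }
  stop("expected a spike_train or a numeric vector of spike times",
       call. = FALSE)
}

#' Firing rate of a spike train
#'
#' The default (\code{"span"}) definition is \code{(n_spikes - 1)} divided by
#' the time between first and last spike: the reciprocal of the mean ISI,
#' robust to silent padding at the record edges. \code{"duration"} divides the
#' spike count by the recording duration instead.
#'
#' @param train a \code{\link{spike_train}} or numeric spike times.
#' @param method \code{"span"} (default) or \code{"duration"}.
#' @param duration recording duration in s, required for
#'   \code{method = "duration"} when \code{train} is a bare vector.
#' @return firing rate in spikes/s.
#' @export
firing_rate <- function(train, method = c("span", "duration"),
                        duration = NULL) {
  method <- match.arg(method)
  times <- spike_times(train)
  if (length(times) < 2)
    stop("firing rate undefined for fewer than 2 spikes", call. = FALSE)
  if (method == "span")
    return((length(times) - 1) / (times[length(times)] - times[1]))
  if (is.null(duration))
    duration <- if (inherits(train, "spike_train")) train$duration else
      stop("`duration` required for method = \"duration\"", call. = FALSE)
  length(times) / duration
}

#' Coefficient of variation (CV) of the inter-spike intervals
#'
#' CV = sigma_ISI / mu_ISI with the population SD (denominator n, not n - 1).
#' CV = 0 for a perfectly regular train; CV = 1 for a Poisson process; CV > 1
#' indicates supra-Poisson irregularity (bursts and pauses).
#'
#' @param train a \code{\link{spike_train}} or numeric spike times.
#' @return CV (dimensionless, >= 0).
#' @export
isi_cv <- function(train) {
  x <- isi(train)
  if (length(x) < 2)
    stop("CV needs at least 3 spikes (2 ISIs)", call. = FALSE)
  sqrt(mean((x - mean(x))^2)) / mean(x)
}

#' Local coefficient of variation (CV2) of the inter-spike intervals
#'
#' CV2 is the mean over consecutive ISI pairs of
#' \code{2 * |ISI[n+1] - ISI[n]| / (ISI[n+1] + ISI[n])}, a short-timescale
#' regularity measure bounded in [0, 2] that, unlike CV, is insensitive to
#' slow drifts in firing rate. For a Poisson process E[CV2] = 1.
#'
#' @param train a \code{\link{spike_train}} or numeric spike times.
#' @return CV2 (dimensionless, in [0, 2]).
#' @export
isi_cv2 <- function(train) {
  x <- isi(train)
  if (length(x) < 2)
    stop("CV2 needs at least 3 spikes (2 ISIs)", call. = FALSE)
  x1 <- x[-length(x)]; x2 <- x[-1]
  mean(2 * abs(x2 - x1) / (x2 + x1))
}

#' Per-train spike metrics row
#'
#' @param train a \code{\link{spike_train}}.
#' @return one-row data.frame: cell_id, genotype, state, n_spikes, rate_sps,
#'   cv, cv2.
#' @export
spike_metrics <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  md <- train$metadata
  grab <- function(k) if (!is.null(md[[k]])) md[[k]] else NA_character_
  data.frame(cell_id = grab("cell_id"), genotype = grab("genotype"),
             state = grab("state"), n_spikes = length(train$times),
             rate_sps = firing_rate(train), cv = isi_cv(train),
             cv2 = isi_cv2(train))
}

#' Group summary of spike metrics (mean +/- SEM of rate, CV, CV2)
#'
#' @param metrics data.frame of per-cell rows (\code{\link{spike_metrics}}),
#'   or a list of \code{\link{spike_train}}s.
#' @param by grouping columns (default genotype and state).
#' @return list with \code{table} (per-cell rows) and \code{summary}
#'   (per-group n and mean/SEM of rate_sps, cv, cv2).
#' @export
population_summary <- function(metrics, by = c("genotype", "state")) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, lapply(metrics, spike_metrics))
  missing_by <- setdiff(by, names(metrics))
  if (length(missing_by))
    stop("unknown grouping column(s): ", paste(missing_by, collapse = ", "),
         call. = FALSE)
  grp <- split(metrics, metrics[by], drop = TRUE)
  summ <- do.call(rbind, lapply(grp, function(g) {
    out <- g[1, by, drop = FALSE]
    out$n <- nrow(g)
    for (v in c("rate_sps", "cv", "cv2")) {
      out[[paste0("mean_", v)]] <- mean(g[[v]])
      out[[paste0("sem_", v)]] <- sem(g[[v]])
    }
    out
  }))
  rownames(summ) <- NULL
  list(table = metrics, summary = summ)
}
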