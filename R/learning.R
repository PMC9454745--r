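#' Percent change in VOR gain after gain-down training
#'
#' Defined as \code{100 * (gain_pre - gain_post) / gain_pre}: positive values
#' mean the gain decreased after training, i.e. adaptation toward the trained
#' target gain of 0.
#'
#' @param gain_pre pre-training gain (> 0).
#' @param gain_post post-training gain.
#' @return percent change (vectorised).
#' @export
percent_change <- function(gain_pre, gain_post) {
  check_that(all(is.finite(gain_pre)) && all(gain_pre > 0), "gain_pre",
             "must be > 0")
  100 * (gain_pre - gain_post) / gain_pre
}

#' Per-animal, per-frequency learning table from pre/post gain estimates
#'
#' Pairs the \code{condition == "pre"} and \code{condition == "post"} rows of
#' a frequency-response table by (animal, frequency) and computes the percent
#' change in gain, plus a genotype x frequency group summary (mean +/- SEM).
#'
#' @param gains long-format data.frame with columns \code{animal},
#'   \code{genotype}, \code{condition} (\code{"pre"}/\code{"post"}),
#'   \code{frequency_hz} and \code{gain} — e.g. the \code{table} element of
#'   \code{\link{frequency_response}} run on a learning dataset.
#' @return list with \code{table} (animal, genotype, frequency_hz, gain_pre,
#'   gain_post, pct_change) and \code{summary} (genotype, frequency_hz, n,
#'   mean_pct_change, sem_pct_change).
#' @export
learning_table <- function(gains) {
  pre <- gains[gains$condition == "pre", ]
  post <- gains[gains$condition == "post", ]
  key <- function(d) paste(d$animal, d$frequency_hz, sep = "@")
  missing_post <- setdiff(key(pre), key(post))
  missing_pre <- setdiff(key(post), key(pre))
  if (length(missing_post) || length(missing_pre))
    stop("unmatched pre/post recordings for (animal@frequency): ",
         paste(c(missing_post, missing_pre), collapse = ", "), call. = FALSE)
  m <- merge(pre[, c("animal", "genotype", "frequency_hz", "gain")],
             post[, c("animal", "frequency_hz", "gain")],
             by = c("animal", "frequency_hz"), suffixes = c("_pre", "_post"))
  m$pct_change <- percent_change(m$gain_pre, m$gain_post)
  m <- m[order(m$genotype, m$frequency_hz, m$animal),
         c("animal", "genotype", "frequency_hz", "gain_pre", "gain_post",
           "pct_change")]
  rownames(m) <- NULL
  grp <- split(m, interaction(m$genotype, m$frequency_hz, drop = TRUE))
  summ <- do.call(rbind, lapply(grp, function(g) {
    data.frame(genotype = g$genotype[1], frequency_hz = g$frequency_hz[1],
               n = nrow(g), mean_pct_change = mean(g$pct_change),
               sem_pct_change = sem(g$pct_change))
  }))
  summ <- summ[order(summ$genotype, summ$frequency_hz), ]
  rownames(summ) <- NULL
  list(table = m, summary = summ)
}
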