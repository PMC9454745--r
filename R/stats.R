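#' Mann-Whitney U test (two-sided)
#'
#' U counts, over all (x_i, y_j) pairs, the x_i > y_j pairs plus half the
#' ties. The p-value is exact (full null distribution of U) when the pooled
#' sample is tie-free and n1 + n2 <= 40, otherwise the normal approximation
#' with continuity and tie correction is used.
#'
#' @param x,y numeric samples (each nonempty).
#' @return an object of class \code{mann_whitney_result}: list with
#'   \code{u_stat}, \code{n1}, \code{n2}, \code{p_two_sided} and
#'   \code{method} ("exact" or "normal_approx").
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_free <- !any(duplicated(c(x, y)))
  exact <- tie_free && (n1 + n2) <= 40
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  structure(list(u_stat = u, n1 = n1, n2 = n2, p_two_sided = p,
                 method = if (exact) "exact" else "normal_approx"),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("<mann_whitney> U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$u_stat, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Two-way mixed-design (repeated-measures) ANOVA with Bonferroni post hoc
#'
#' One between-subjects factor (genotype) and one within-subjects factor
#' (frequency), each subject measured at every within level exactly once.
#' The standard mixed decomposition is used: the between factor is tested
#' against the subject-within-group error, the within factor and the
#' interaction against the subject x within error. Post hoc, the two
#' genotypes are compared at each frequency with an independent two-sample
#' t test, Bonferroni-adjusted by the number of frequencies.
#'
#' @param data long-format data.frame.
#' @param dv name of the numeric response column.
#' @param between,within,subject names of the factor columns (defaults
#'   \code{"genotype"}, \code{"frequency_hz"}, \code{"animal"}).
#' @param posthoc run per-level between-group contrasts (default TRUE).
#' @return an object of class \code{anova_result}: list with \code{effects}
#'   (data.frame: effect, df_num, df_den, f, p) and \code{posthoc}
#'   (data.frame: level, mean_diff, t, df, p_raw, p_adj with
#'   \code{p_adj = min(1, p_raw * n_levels)}).
#' @export
mixed_anova <- function(data, dv, between = "genotype",
                        within = "frequency_hz", subject = "animal",
                        posthoc = TRUE) {
  d <- data.frame(y = data[[dv]],
                  B = factor(data[[between]]),
                  W = factor(data[[within]]),
                  S = factor(data[[subject]]))
  if (anyNA(d$y)) stop("missing values in the response", call. = FALSE)
  counts <- table(d$S, d$W)
  if (any(counts != 1))
    stop("unbalanced design: every subject must be measured at every ",
         "within-subject level exactly once (no silent imputation)",
         call. = FALSE)
  if (any(rowSums(table(d$S, d$B) > 0) != 1))
    stop("each subject must belong to exactly one between-subjects group",
         call. = FALSE)
  fit <- stats::aov(y ~ B * W + Error(S / W), data = d)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    data.frame(df_num = tab[i, "Df"],
               df_den = tab[nrow(tab), "Df"],
               f = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  effects <- rbind(
    cbind(effect = between, grab("Error: S", "B")),
    cbind(effect = within, grab("Error: S:W", "W")),
    cbind(effect = paste0(between, ":", within), grab("Error: S:W", "B:W")))
  rownames(effects) <- NULL
  out <- list(effects = effects, posthoc = NULL,
              n_levels = nlevels(d$W))
  if (posthoc) {
    lev <- levels(d$W)
    gl <- levels(d$B)
    ph <- do.call(rbind, lapply(lev, function(l) {
      di <- d[d$W == l, ]
      tt <- stats::t.test(di$y[di$B == gl[1]], di$y[di$B == gl[2]],
                          var.equal = TRUE)
      data.frame(level = l,
                 mean_diff = mean(di$y[di$B == gl[1]]) -
                   mean(di$y[di$B == gl[2]]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_adj = min(1, tt$p.value * length(lev)))
    }))
    out$posthoc <- ph
  }
  structure(out, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$effects, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat(sprintf("post hoc (Bonferroni x %d):\n", x$n_levels))
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param n_comparisons multiplier.
#' @return \code{min(1, p * n_comparisons)}, vectorised.
#' @export
bonferroni <- function(p, n_comparisons) pmin(1, p * n_comparisons)
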