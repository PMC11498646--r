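# Condition-level comparisons and correlation analyses over a table of
# fitted observer measures.

#' Paired t test between two conditions of a fit table
#'
#' Pairs are matched by `observer_id`; observers missing either condition are
#' dropped. A zero-variance difference with nonzero mean is reported with
#' `t = +/-Inf`, `p = 0` and `degenerate = TRUE` instead of erroring.
#'
#' @param fit_table Data frame with columns `observer_id`, `condition` and
#'   the measure columns (e.g. from [cohort_fit_table()]).
#' @param condition_a,condition_b Condition names to compare.
#' @param measure Measure column, e.g. `"bias_deg"` or `"sigma_deg"`.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_t <- function(fit_table, condition_a, condition_b, measure) {
  a <- fit_table[fit_table$condition == condition_a,
                 c("observer_id", measure)]
  b <- fit_table[fit_table$condition == condition_b,
                 c("observer_id", measure)]
  m <- merge(a, b, by = "observer_id", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  d <- m[[paste0(measure, "_a")]] - m[[paste0(measure, "_b")]]
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0, n = n,
                  degenerate = TRUE))
    }
    return(list(t = sign(md) * Inf, df = n - 1L, p = 0, mean_diff = md,
                n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(m[[paste0(measure, "_a")]],
                      m[[paste0(measure, "_b")]], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = md, n = n, degenerate = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` elementwise, for an explicit family size `m` (which may
#' exceed the number of p values supplied).
#'
#' @param pvals Numeric p values.
#' @param m Family size; defaults to `length(pvals)`.
#' @return Adjusted p values, capped at 1.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= length(pvals))
  pmin(1, m * pvals)
}

#' Pearson correlations between observer measures within conditions
#'
#' For every pair among the requested measures and every condition, the
#' Pearson correlation across observers with its two-sided p value, and
#' Bonferroni-adjusted p over the whole correlation family. Zero-variance
#' columns yield `r = NA` with `degenerate = TRUE`.
#'
#' @param fit_table Data frame with `observer_id`, `condition` and the
#'   measure columns.
#' @param measures Character vector of measure columns (at least two), e.g.
#'   `c("bias_deg", "sigma_deg", "boundary_low", "boundary_high")`.
#' @param family_size Bonferroni family size; defaults to the number of
#'   (condition, pair) tests performed.
#' @return Data frame with `condition`, `measure_x`, `measure_y`, `n`, `r`,
#'   `p`, `p_adj`, `degenerate`.
#' @export
correlate <- function(fit_table, measures, family_size = NULL) {
  stopifnot(length(measures) >= 2L)
  conds <- unique(fit_table$condition)
  pairs <- utils::combn(measures, 2L, simplify = FALSE)
  rows <- list()
  for (cond in conds) {
    d <- fit_table[fit_table$condition == cond, , drop = FALSE]
    for (pr in pairs) {
      x <- d[[pr[1]]]; y <- d[[pr[2]]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 3L) stop("need at least 3 observers per condition",
                       call. = FALSE)
      degen <- stats::sd(x) == 0 || stats::sd(y) == 0
      if (degen) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, measure_x = pr[1], measure_y = pr[2],
                   n = n, r = r, p = p, degenerate = degen)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(family_size)) family_size <- nrow(out)
  out$p_adj <- ifelse(is.na(out$p), NA_real_,
                      bonferroni(out$p, m = family_size))
  out[, c("condition", "measure_x", "measure_y", "n", "r", "p", "p_adj",
          "degenerate")]
}

#' Export a fit table in long format
#'
#' One row per observer, condition and measure — the layout linear
#' mixed-model software expects. The models themselves are out of scope here;
#' this is the hand-off hook.
#'
#' @param fit_table Data frame with `observer_id`, `condition` and measure
#'   columns.
#' @param measures Measure columns to stack.
#' @return Long data frame with `observer_id`, `condition`, `measure`,
#'   `value`.
#' @export
export_long <- function(fit_table,
                        measures = intersect(c("bias_deg", "bias_fraction",
                                               "sigma_deg"),
                                             names(fit_table))) {
  long <- stats::reshape(
    as.data.frame(fit_table)[, c("observer_id", "condition", measures)],
    direction = "long", varying = measures, v.names = "value",
    times = measures, timevar = "measure", idvar = c("observer_id",
                                                     "condition"))
  rownames(long) <- NULL
  long[order(long$observer_id, long$condition, long$measure), ]
}

#' Plot a measure by condition across observers
#'
#' Dots with connecting lines per observer and the group mean with +/- 1 SEM,
#' the conventional per-observer condition plot.
#'
#' @param fit_table Data frame with `observer_id`, `condition` and the
#'   measure.
#' @param measure Column to plot.
#' @param conditions Condition order on the x axis; defaults to order of
#'   appearance.
#' @param ... Passed to `plot`.
#' @export
plot_measure_by_condition <- function(fit_table, measure,
                                      conditions = unique(fit_table$condition),
                                      ...) {
  obs <- unique(fit_table$observer_id)
  xs <- seq_along(conditions)
  vals <- sapply(conditions, function(cc)
    fit_table[[measure]][match(paste(obs, cc),
                               paste(fit_table$observer_id,
                                     fit_table$condition))])
  vals <- matrix(vals, nrow = length(obs))
  graphics::plot(range(xs) + c(-0.2, 0.2), range(vals, na.rm = TRUE),
                 type = "n", xaxt = "n", xlab = "condition",
                 ylab = measure, ...)
  graphics::axis(1, at = xs, labels = conditions)
  for (i in seq_along(obs)) {
    graphics::lines(xs, vals[i, ], col = "grey60")
    graphics::points(xs, vals[i, ], col = "grey40", pch = 1)
  }
  mu <- colMeans(vals, na.rm = TRUE)
  sem <- apply(vals, 2, function(v) stats::sd(v, na.rm = TRUE) /
                 sqrt(sum(!is.na(v))))
  graphics::points(xs, mu, pch = 16, cex = 1.3)
  graphics::arrows(xs, mu - sem, xs, mu + sem, angle = 90, code = 3,
                   length = 0.05)
  invisible(fit_table)
}
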