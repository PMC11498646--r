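# Cumulative Gaussian psychometric functions: maximum-likelihood fitting,
# the validity rule, and the bias/threshold measures derived from a fit.

.PMF_MU_BOUNDS <- c(-90, 90)
.PMF_SIGMA_BOUNDS <- c(0.1, 500)

#' Tabulate 2IFC responses per comparison level
#'
#' Pools a response log into one row per (condition, comparison offset):
#' number of "higher hue angle" choices and number of trials. Dummy and
#' practice trials are excluded.
#'
#' @param log A `response_log` (see [simulate_2ifc()]).
#' @param by_block Also split by block (per-repetition fits).
#' @return Data frame with columns `condition`, `comparison_offset_deg`,
#'   `n_higher`, `n_total` (plus `block` if `by_block`), and the condition's
#'   target/distractor means carried along.
#' @export
tabulate_responses <- function(log, by_block = FALSE) {
  keep <- !log$is_dummy & !log$is_practice
  d <- as.data.frame(log)[keep, , drop = FALSE]
  grp <- list(condition = d$condition,
              comparison_offset_deg = d$comparison_offset_deg)
  if (by_block) grp$block <- d$block
  agg <- stats::aggregate(d$response, by = grp,
                          FUN = function(r) c(sum(r), length(r)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    n_higher = agg$x[, 1], n_total = agg$x[, 2])
  meta <- unique(d[, c("condition", "target_mean_deg",
                       "distractor_mean_deg")])
  merge(out, meta, by = "condition", sort = TRUE)
}

#' Maximum-likelihood cumulative Gaussian psychometric function
#'
#' Fits `P(choose higher) = pnorm((offset - mu) / sigma)` to per-level
#' binomial counts by minimising the Bernoulli negative log-likelihood,
#' with `mu` bounded in `[-90, 90]` degrees and `sigma` in `[0.1, 500]`
#' degrees. The fit is deterministic: a probit-regression start plus a fixed
#' grid of restarts. `mu` is the point of subjective equality (bias axis)
#' and `sigma` the discrimination threshold. Degenerate data drive the
#' parameters to their bounds and flag the fit invalid rather than erroring.
#'
#' An optional fixed lapse rate `lambda` rescales the curve to
#' `lambda/2 + (1 - lambda) * pnorm(...)`; the default 0 is the plain
#' two-parameter fit.
#'
#' @param data Data frame with columns `comparison_offset_deg` (or `offset`),
#'   `n_higher`, `n_total`; one row per level.
#' @param lapse Fixed lapse rate in `[0, 0.5)`; not estimated.
#' @return An object of class `pmf_fit` with elements `mu`, `sigma`, `nll`,
#'   `valid`, `data`, `lapse`.
#' @examples
#' d <- data.frame(comparison_offset_deg = seq(-20, 20, by = 4))
#' d$n_total <- 50
#' d$n_higher <- rbinom(nrow(d), 50, pnorm(d$comparison_offset_deg / 5))
#' fit_pmf(d)
#' @export
fit_pmf <- function(data, lapse = 0) {
  if (!is.null(data$offset) && is.null(data$comparison_offset_deg)) {
    data$comparison_offset_deg <- data$offset
  }
  stopifnot(all(c("comparison_offset_deg", "n_higher", "n_total") %in%
                  names(data)),
            lapse >= 0, lapse < 0.5)
  x <- data$comparison_offset_deg
  k <- data$n_higher
  n <- data$n_total
  if (length(unique(x)) < 2L) {
    stop("need responses at two or more distinct levels", call. = FALSE)
  }
  stopifnot(all(k >= 0), all(k <= n))
  nll_fun <- function(par) {
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((x - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  lower <- c(.PMF_MU_BOUNDS[1], .PMF_SIGMA_BOUNDS[1])
  upper <- c(.PMF_MU_BOUNDS[2], .PMF_SIGMA_BOUNDS[2])
  # probit-regression start where the data admit one
  starts <- list(c(0, diff(range(x)) / 4))
  gl <- try(suppressWarnings(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial("probit"))),
    silent = TRUE)
  if (!inherits(gl, "try-error") && stats::coef(gl)[2] > 0) {
    b <- stats::coef(gl)
    starts <- c(starts, list(c(
      min(max(-b[1] / b[2], lower[1]), upper[1]),
      min(max(1 / b[2], lower[2]), upper[2]))))
  }
  for (s0 in c(1, 5, 25)) starts <- c(starts, list(c(0, s0)))
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, nll_fun, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed from all starts",
                          call. = FALSE)
  out <- structure(list(mu = unname(best$par[1]),
                        sigma = unname(best$par[2]),
                        nll = best$value, lapse = lapse,
                        data = data.frame(comparison_offset_deg = x,
                                          n_higher = k, n_total = n)),
                   class = "pmf_fit")
  out$valid <- pmf_validity(out, x)
  out
}

#' Does a fitted PMF span the informative probability range?
#'
#' A fit is valid when the fitted curve reaches both 0.25 and 0.75 within the
#' range of comparison offsets actually tested; curves too shallow or too
#' displaced to do so are unreliable and flagged invalid.
#'
#' @param fit A `pmf_fit`.
#' @param comparison_offsets The offsets tested, degrees.
#' @return Logical.
#' @export
pmf_validity <- function(fit, comparison_offsets) {
  lo <- stats::pnorm((min(comparison_offsets) - fit$mu) / fit$sigma)
  hi <- stats::pnorm((max(comparison_offsets) - fit$mu) / fit$sigma)
  lo <= 0.25 && hi >= 0.75
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat("Cumulative Gaussian psychometric function (ML fit)\n")
  cat(sprintf("  PSE (mu)      : %8.3f deg\n", x$mu))
  cat(sprintf("  threshold (SD): %8.3f deg\n", x$sigma))
  cat(sprintf("  -log L: %.3f   valid: %s\n", x$nll, x$valid))
  invisible(x)
}

#' @export
summary.pmf_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d trials over %d comparison levels (%s)\n",
              sum(object$data$n_total), nrow(object$data),
              if (object$lapse > 0)
                sprintf("fixed lapse %.3f", object$lapse) else "no lapse"))
  invisible(object)
}

#' @export
coef.pmf_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
logLik.pmf_fit <- function(object, ...) {
  structure(-object$nll, df = 2L, class = "logLik")
}

#' @export
predict.pmf_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$comparison_offset_deg
  object$lapse / 2 + (1 - object$lapse) *
    stats::pnorm((newdata - object$mu) / object$sigma)
}

#' @export
residuals.pmf_fit <- function(object, ...) {
  p <- predict(object)
  object$data$n_higher / object$data$n_total - p
}

#' @export
simulate.pmf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    p <- predict(object)
    replicate(nsim, stats::rbinom(length(p), object$data$n_total, p),
              simplify = FALSE)
  })
}

#' Plot a fitted psychometric function
#'
#' Observed proportions per comparison level with the fitted curve and the
#' PSE marked.
#'
#' @param x A `pmf_fit`.
#' @param ... Passed to `plot`.
#' @export
plot.pmf_fit <- function(x, ...) {
  d <- x$data
  prop <- d$n_higher / d$n_total
  xs <- seq(min(d$comparison_offset_deg), max(d$comparison_offset_deg),
            length.out = 200)
  graphics::plot(d$comparison_offset_deg, prop, ylim = c(0, 1),
                 xlab = "comparison offset (deg)",
                 ylab = "P(chose higher hue angle)", ...)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(v = x$mu, h = 0.5, lty = 3, col = "grey40")
  invisible(x)
}

#' Signed bias toward the distractor from a PMF fit
#'
#' The fitted PSE `mu` is converted to a bias whose positive sign always
#' means a pull toward the distractor's side of the hue circle: a distractor
#' at lower hue angle drags the perceived test mean down and the PSE
#' negative, so the sign of the shortest arc from target to distractor
#' multiplies `mu`. For the baseline condition (no distractor) the raw PSE
#' relative to the zero-offset ground truth is reported and the bias fraction
#' is undefined; the 180-degree condition has a defined bias but no
#' full-integration prediction, so its fraction is also undefined.
#'
#' @param fit A `pmf_fit`.
#' @param target_mean,distractor_mean Nominal means in degrees;
#'   `distractor_mean = NA` for baseline.
#' @return List with `bias_deg` (signed, positive toward the distractor) and
#'   `bias_fraction` (`bias_deg` over the full-integration prediction, `NA`
#'   where undefined).
#' @examples
#' # pink group, distractor 60 deg below target, PSE -2 => bias +2 deg
#' f <- structure(list(mu = -2, sigma = 5), class = "pmf_fit")
#' bias_toward_distractor(f, 340, 280)
#' @export
bias_toward_distractor <- function(fit, target_mean, distractor_mean) {
  if (is.na(distractor_mean)) {
    return(list(bias_deg = fit$mu, bias_fraction = NA_real_))
  }
  d <- signed_diff(distractor_mean, target_mean)
  bias <- sign(d) * fit$mu
  sep <- abs(d)
  frac <- if (sep == 180) NA_real_ else bias / full_integration_bias(sep)
  list(bias_deg = bias, bias_fraction = frac)
}

#' Fit one PMF per condition of a response log
#'
#' Pools responses over block repetitions (or fits per repetition), fits
#' [fit_pmf()] per condition, and derives the bias measures.
#'
#' @param log A `response_log`.
#' @param by_block Fit each block repetition separately.
#' @param lapse Fixed lapse rate passed to [fit_pmf()].
#' @return Data frame (`pmf_fit_table`): one row per condition (x block),
#'   with `mu_deg`, `sigma_deg`, `valid`, `bias_deg`, `bias_fraction`. The
#'   individual `pmf_fit` objects are attached as the `fits` attribute.
#' @export
fit_pmf_by_condition <- function(log, by_block = FALSE, lapse = 0) {
  tab <- tabulate_responses(log, by_block = by_block)
  key <- if (by_block) interaction(tab$condition, tab$block, drop = TRUE)
         else factor(tab$condition)
  fits <- lapply(levels(key), function(lv) {
    d <- tab[key == lv, , drop = FALSE]
    fit <- fit_pmf(d, lapse = lapse)
    b <- bias_toward_distractor(fit, d$target_mean_deg[1],
                                d$distractor_mean_deg[1])
    list(fit = fit,
         row = data.frame(condition = d$condition[1],
                          block = if (by_block) d$block[1] else NA_integer_,
                          mu_deg = fit$mu, sigma_deg = fit$sigma,
                          valid = fit$valid, bias_deg = b$bias_deg,
                          bias_fraction = b$bias_fraction))
  })
  out <- do.call(rbind, lapply(fits, `[[`, "row"))
  attr(out, "fits") <- lapply(fits, `[[`, "fit")
  class(out) <- c("pmf_fit_table", "data.frame")
  out
}

#' @export
print.pmf_fit_table <- function(x, ...) {
  cat("Psychometric fits by condition\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
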