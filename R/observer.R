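# Synthetic observers: 2IFC ensemble-comparison responses, categorization
# responses, and staircase responses.

#' Generative parameters of a synthetic ensemble observer
#'
#' The observer forms a weighted circular mean over the elements of each
#' interval and compares the two noisy estimates.
#'
#' @param distractor_weight Per-element weight of distractor elements relative
#'   to target elements (which have weight 1). 0 = perfect segmentation,
#'   1 = full integration.
#' @param internal_noise_sd SD in degrees of the wrapped-normal noise added
#'   independently to each interval's ensemble estimate.
#' @param ctb_weight Central-tendency weight in `[0, 1]`: linear shrinkage of
#'   the test-interval estimate toward the across-trials grand mean (the
#'   nominal target mean). 0 recovers the pure sensory observer.
#' @param lapse_rate Probability in `[0, 0.5]` of responding uniformly at
#'   random, regardless of the stimulus.
#' @param subsample_size Optional number of elements (without replacement)
#'   actually integrated per ensemble; `NULL` integrates all elements.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(distractor_weight = 0, internal_noise_sd = 4,
                            ctb_weight = 0, lapse_rate = 0,
                            subsample_size = NULL) {
  stopifnot(distractor_weight >= 0, internal_noise_sd >= 0,
            ctb_weight >= 0, ctb_weight <= 1,
            lapse_rate >= 0, lapse_rate <= 0.5)
  if (!is.null(subsample_size)) {
    stopifnot(subsample_size >= 1)
    subsample_size <- as.integer(subsample_size)
  }
  structure(list(distractor_weight = distractor_weight,
                 internal_noise_sd = internal_noise_sd,
                 ctb_weight = ctb_weight, lapse_rate = lapse_rate,
                 subsample_size = subsample_size),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Synthetic ensemble observer:\n")
  cat(sprintf("  distractor weight : %.4g\n", x$distractor_weight))
  cat(sprintf("  internal noise SD : %.4g deg\n", x$internal_noise_sd))
  cat(sprintf("  CTB weight        : %.4g\n", x$ctb_weight))
  cat(sprintf("  lapse rate        : %.4g\n", x$lapse_rate))
  cat(sprintf("  subsample size    : %s\n",
              if (is.null(x$subsample_size)) "all elements"
              else x$subsample_size))
  invisible(x)
}

#' One-interval ensemble estimate of a synthetic observer
#'
#' Weighted circular mean of the (optionally subsampled) element hues, plus
#' wrapped-normal internal noise, optionally shrunk toward the grand mean by
#' the central-tendency weight. An undefined circular mean (antipodal
#' cancellation) is resolved by a fair coin between the two opposing arcs.
#' Uses the current RNG state.
#'
#' @param hues Element hues in degrees.
#' @param weights Per-element weights aligned with `hues`.
#' @param params An [observer_params()] object.
#' @param grand_mean Across-trials grand mean used by the central-tendency
#'   term; defaults to 0 and is irrelevant when `ctb_weight = 0`.
#' @return A single hue angle in `[0, 360)`.
#' @export
estimate_ensemble <- function(hues, weights = rep(1, length(hues)), params,
                              grand_mean = 0) {
  stopifnot(length(hues) == length(weights))
  idx <- seq_along(hues)
  if (!is.null(params$subsample_size) &&
      params$subsample_size < length(hues)) {
    idx <- sample(idx, params$subsample_size)
  }
  cm <- circular_mean(hues[idx], weights[idx])
  est <- if (cm$undefined) {
    # opposing hues: pick one of the two cancelling directions at random
    pos <- weights[idx] > 0
    half <- circular_mean(hues[idx][pos][1])$mean
    wrap_hue(half + 180 * stats::rbinom(1, 1, 0.5))
  } else cm$mean
  if (params$internal_noise_sd > 0) {
    est <- wrap_hue(est + stats::rnorm(1, 0, params$internal_noise_sd))
  }
  if (params$ctb_weight > 0) {
    est <- wrap_hue(est + params$ctb_weight * signed_diff(grand_mean, est))
  }
  est
}

# Row-wise weighted circular means for element matrices (trials x elements).
# Undefined rows (resultant below tol) get a fair-coin arc resolution based
# on the first column's hue.
.row_cmean <- function(H, W, tol = 1e-8) {
  th <- H * pi / 180
  C <- rowSums(W * cos(th))
  S <- rowSums(W * sin(th))
  R <- sqrt(C^2 + S^2) / rowSums(W)
  m <- wrap_hue(atan2(S, C) * 180 / pi)
  und <- R < tol
  if (any(und)) {
    flip <- stats::rbinom(sum(und), 1, 0.5)
    m[und] <- wrap_hue(H[und, 1] + 180 * flip)
  }
  m
}

#' Simulate 2IFC ensemble-comparison responses
#'
#' For each trial of the schedule, element hues for the test target ensemble,
#' the distractor ensemble (if the condition has one) and the comparison
#' ensemble are drawn from their uniform hue distributions around the
#' jittered means; comparison offsets are anchored to the jittered target
#' mean. The observer computes an internal estimate per interval
#' (distractor elements weighted by `distractor_weight` in the test
#' interval), and responds 1 when the comparison estimate lies toward higher
#' hue angle than the test estimate; lapses respond at random.
#'
#' @param schedule A `trial_schedule` data frame.
#' @param params An [observer_params()] object.
#' @param seed Integer seed; the same seed reproduces the responses exactly.
#' @param constants Design constants (for the element count and hue ranges).
#' @return The schedule with an added integer `response` column
#'   (1 = chose the comparison in the direction of higher hue angle), class
#'   `response_log`.
#' @export
simulate_2ifc <- function(schedule, params, seed = 1L,
                          constants = design_constants()) {
  stopifnot(inherits(params, "observer_params"))
  n <- nrow(schedule)
  ne <- constants$n_elements
  rng <- ifelse(schedule$experiment == "exp1",
                constants$exp1$range, constants$exp2$range)
  with_seed(seed, {
    jm <- schedule$target_mean_deg + schedule$jitter_deg
    # element draws: trials x elements
    Ht <- matrix(stats::runif(n * ne), n, ne) * rng - rng / 2 + jm
    has_d <- !is.na(schedule$distractor_mean_deg)
    Hd <- matrix(stats::runif(n * ne), n, ne) * rng - rng / 2 +
      (schedule$distractor_mean_deg + schedule$jitter_deg)
    Hd[!has_d, ] <- 0  # weight 0 below; avoids NA propagation
    Hc <- matrix(stats::runif(n * ne), n, ne) * rng - rng / 2 +
      (jm + schedule$comparison_offset_deg)

    wd <- ifelse(has_d, params$distractor_weight, 0)
    if (!is.null(params$subsample_size)) {
      test_est <- numeric(n)
      for (i in seq_len(n)) {
        hues <- if (has_d[i]) c(Ht[i, ], Hd[i, ]) else Ht[i, ]
        w <- if (has_d[i]) rep(c(1, params$distractor_weight), each = ne)
             else rep(1, ne)
        keep <- sample(seq_along(hues), min(params$subsample_size,
                                            length(hues)))
        test_est[i] <- .row_cmean(matrix(hues[keep], 1), matrix(w[keep], 1))
      }
    } else {
      test_est <- .row_cmean(cbind(Ht, Hd),
                             cbind(matrix(1, n, ne), matrix(wd, n, ne)))
    }
    comp_est <- .row_cmean(Hc, matrix(1, n, ne))
    if (params$internal_noise_sd > 0) {
      test_est <- wrap_hue(test_est +
                             stats::rnorm(n, 0, params$internal_noise_sd))
      comp_est <- wrap_hue(comp_est +
                             stats::rnorm(n, 0, params$internal_noise_sd))
    }
    if (params$ctb_weight > 0) {
      test_est <- wrap_hue(test_est + params$ctb_weight *
                             signed_diff(schedule$target_mean_deg, test_est))
    }
    resp <- as.integer(signed_diff(comp_est, test_est) > 0)
    if (params$lapse_rate > 0) {
      lapse <- stats::runif(n) < params$lapse_rate
      resp[lapse] <- stats::rbinom(sum(lapse), 1, 0.5)
    }
    out <- schedule
    out$response <- resp
    class(out) <- c("response_log", "data.frame")
    attr(out, "observer_params") <- params
    out
  })
}

#' Simulate categorization responses under a von Mises category model
#'
#' Each trial draws a noisy hue measurement from a von Mises distribution
#' centred on the stimulus with the model's concentration, and responds with
#' the category whose boundary arc contains the measurement.
#'
#' @param true_model A [category_model()] (or the fit returned by
#'   [fit_boundary_model()]).
#' @param stimulus_hues Stimulus hue angles in degrees.
#' @param reps Repetitions per stimulus.
#' @param seed Integer seed.
#' @return A `category_dataset`: list with `stimulus_hues`, `counts`
#'   (stimuli x categories integer matrix) and `category_names`.
#' @export
simulate_categorization <- function(true_model, stimulus_hues, reps = 4L,
                                    seed = 1L) {
  stopifnot(inherits(true_model, "category_model"))
  ns <- length(stimulus_hues)
  K <- length(true_model$boundaries)
  with_seed(seed, {
    counts <- matrix(0L, ns, K,
                     dimnames = list(NULL, true_model$category_names))
    for (i in seq_len(ns)) {
      meas <- rvonmises_deg(reps, stimulus_hues[i], true_model$kappa)
      cat_id <- assign_category(true_model, meas)
      counts[i, ] <- tabulate(cat_id, nbins = K)
    }
    category_dataset(stimulus_hues, counts, true_model$category_names)
  })
}

#' Two-choice responder for staircase boundary estimation
#'
#' Returns a closure mapping a stimulus hue to `"green"` or `"blue"`: the
#' responder draws a von Mises measurement around the stimulus and answers
#' green when the measurement falls on the green side (lower hue angle) of
#' its true boundary. The closure uses the current RNG state when called.
#'
#' @param true_boundary The responder's green-blue boundary in degrees.
#' @param kappa von Mises concentration of the measurement noise.
#' @return `function(stimulus_hue)` returning `"green"` or `"blue"`.
#' @export
staircase_responder <- function(true_boundary, kappa) {
  stopifnot(kappa >= 0)
  force(true_boundary)
  function(stimulus_hue) {
    meas <- rvonmises_deg(1L, stimulus_hue, kappa)
    if (signed_diff(meas, true_boundary) < 0) "green" else "blue"
  }
}

#' Write or read a 2IFC response log as CSV
#'
#' The observer parameters travel in a commented header block (`# key: value`
#' lines) so a log round-trips through the analysis functions.
#'
#' @param log A `response_log` from [simulate_2ifc()] (or external data with
#'   the same columns).
#' @param path File path.
#' @return `read_response_log` returns the `response_log` with its
#'   `observer_params` attribute when the header is present.
#' @export
write_response_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(log, "observer_params")
  if (!is.null(p)) {
    for (nm in names(p)) {
      writeLines(sprintf("# %s: %s", nm,
                         if (is.null(p[[nm]])) "NULL" else p[[nm]]), con)
    }
  }
  utils::write.csv(as.data.frame(log), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_log
#' @export
read_response_log <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  log <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                      collapse = "\n"),
                         stringsAsFactors = FALSE)
  class(log) <- c("response_log", "data.frame")
  if (length(hdr)) {
    kv <- sub("^# *", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: *", "", kv)
    p <- as.list(vals)
    names(p) <- keys
    num <- suppressWarnings(lapply(p, function(v)
      if (v == "NULL") NULL else as.numeric(v)))
    attr(log, "observer_params") <- do.call(observer_params, num)
  }
  log
}
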