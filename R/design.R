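# Parametric stimulus specifications and trial schedules for the two
# ensemble-comparison experiments.
#
# Geometry conventions (hue angle increases counterclockwise):
#   experiment 1: pink group target 340 deg, green group target 130 deg.
#     "Yellower" is toward higher hue angle for the pink target and toward
#     lower hue angle for the green target, so 60Y = +60 (340 -> 40) for
#     pink and -60 (130 -> 70) for green; 60B is the mirror image.
#   experiment 2: target at -22.5 deg (green group) or +22.5 deg (blue
#     group) from the observer's green-blue boundary; the across-boundary
#     distractor sits at +45 deg from the target mean for the green group
#     and -45 for the blue group, the within-category distractor at the
#     opposite offset.

#' Design constants for both experiments
#'
#' Every stimulus/schedule constant used by the generators, as a nested list:
#' ensemble size, uniform hue ranges, jitter bounds, comparison step sizes,
#' repetitions per level, block repetitions, nominal target means, distractor
#' offsets, and staircase settings. Override fields via `modifyList()` before
#' passing a config to [run_pipeline()].
#'
#' @return Nested list of design constants.
#' @export
design_constants <- function() {
  list(
    n_elements = 18L,
    n_levels = 11L,
    exp1 = list(
      range = 30, jitter = 7.5,
      target_mean = c(pink = 340, green = 130),
      step = c(baseline = 4, d180 = 5, d60Y = 6, d60B = 6),
      # signed distractor offsets from target mean, by group
      distractor_offset = list(
        pink  = c(d180 = 180, d60Y = 60,  d60B = -60),
        green = c(d180 = 180, d60Y = -60, d60B = 60)
      ),
      reps_per_level = 10L, block_reps = 2L
    ),
    exp2 = list(
      range = 25, jitter = 5,
      target_offset_from_boundary = c(green = -22.5, blue = 22.5),
      step = c(baseline = 4, across = 7, within = 7),
      distractor_offset = list(
        green = c(across = 45, within = -45),
        blue  = c(across = -45, within = 45)
      ),
      reps_per_level = 8L, block_reps = 3L,
      n_dummy = 11L
    ),
    practice = list(reps_per_level = 3L, n_outer_levels = 6L),
    staircase = list(n_staircases = 4L, n_trials = 25L, start_step = 4,
                     step_factor = 0.75, min_step = 0.25, start_offset = 20)
  )
}

.comparison_offsets <- function(step, n_levels = 11L) {
  half <- (n_levels - 1L) %/% 2L
  step * seq(-half, half)
}

.new_trials <- function(experiment, block, condition, jitter, offset,
                        interval_order, target_mean, distractor_mean,
                        is_dummy = FALSE, is_practice = FALSE) {
  data.frame(
    experiment = experiment, block = block, condition = condition,
    jitter_deg = jitter, comparison_offset_deg = offset,
    interval_order = interval_order,
    target_mean_deg = target_mean,
    distractor_mean_deg = distractor_mean,
    is_dummy = is_dummy, is_practice = is_practice,
    stringsAsFactors = FALSE
  )
}

.one_block <- function(experiment, block, condition, offsets, reps, jitter_max,
                       target_mean, distractor_mean, n_dummy = 0L,
                       dummy_offsets = NULL, is_practice = FALSE) {
  off <- sample(rep(offsets, each = reps))
  n <- length(off)
  main <- .new_trials(
    experiment, block, condition,
    jitter = stats::runif(n, -jitter_max, jitter_max),
    offset = off,
    interval_order = sample(c("test_first", "comparison_first"), n,
                            replace = TRUE),
    target_mean = target_mean, distractor_mean = distractor_mean,
    is_practice = is_practice
  )
  if (n_dummy > 0L) {
    doff <- sample(dummy_offsets, n_dummy)
    dummy <- .new_trials(
      experiment, block, condition,
      jitter = stats::runif(n_dummy, -jitter_max, jitter_max),
      offset = doff,
      interval_order = sample(c("test_first", "comparison_first"), n_dummy,
                              replace = TRUE),
      target_mean = target_mean, distractor_mean = distractor_mean,
      is_dummy = TRUE, is_practice = is_practice
    )
    main <- rbind(dummy, main)
  }
  main
}

.distractor_mean <- function(target_mean, offset) {
  if (is.na(offset)) NA_real_ else wrap_hue(target_mean + offset)
}

#' Build the full main-task schedule for experiment 1
#'
#' Eight blocks (four conditions, each repeated twice, order shuffled by
#' `seed`), 110 trials per block: each of the 11 comparison offsets appears
#' exactly 10 times per block in shuffled order. Per-trial hue jitter is drawn
#' uniformly within +/-7.5 deg and the presentation order of the two intervals
#' is a fair coin.
#'
#' @param group `"pink"` (target mean 340 deg) or `"green"` (130 deg).
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param constants Design constants, see [design_constants()].
#' @return A `trial_schedule` data frame, one row per trial, with columns
#'   `experiment`, `block`, `condition`, `jitter_deg`, `comparison_offset_deg`,
#'   `interval_order`, `target_mean_deg`, `distractor_mean_deg`, `is_dummy`,
#'   `is_practice`.
#' @export
build_exp1_schedule <- function(group = c("pink", "green"), seed = 1L,
                                constants = design_constants()) {
  group <- match.arg(group)
  k <- constants$exp1
  tmean <- k$target_mean[[group]]
  conditions <- rep(names(k$step), k$block_reps)
  with_seed(seed, {
    conditions <- sample(conditions)
    blocks <- lapply(seq_along(conditions), function(b) {
      cond <- conditions[b]
      doff <- if (cond == "baseline") NA_real_ else
        k$distractor_offset[[group]][[cond]]
      .one_block("exp1", b, cond,
                 offsets = .comparison_offsets(k$step[[cond]],
                                               constants$n_levels),
                 reps = k$reps_per_level, jitter_max = k$jitter,
                 target_mean = tmean,
                 distractor_mean = .distractor_mean(tmean, doff))
    })
    sched <- do.call(rbind, blocks)
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

#' Build the full main-task schedule for experiment 2
#'
#' Nine blocks (three conditions, each repeated three times, order shuffled by
#' `seed`), 88 analysed trials per block (11 comparison offsets times 8
#' repetitions) preceded by 11 dummy trials flagged `is_dummy = TRUE` and
#' excluded from analysis. Target mean is placed 22.5 deg from the supplied
#' green-blue boundary, on the green side for the green group and the blue
#' side for the blue group; distractors sit 45 deg from the target mean,
#' across or within the category by condition.
#'
#' @param group `"green"` or `"blue"`.
#' @param green_blue_boundary The observer's green-blue category boundary in
#'   degrees of hue angle.
#' @param seed Integer seed.
#' @inheritParams build_exp1_schedule
#' @return A `trial_schedule` data frame (see [build_exp1_schedule()]).
#' @export
build_exp2_schedule <- function(group = c("green", "blue"),
                                green_blue_boundary, seed = 1L,
                                constants = design_constants()) {
  group <- match.arg(group)
  stopifnot(is.finite(green_blue_boundary))
  k <- constants$exp2
  tmean <- wrap_hue(green_blue_boundary +
                      k$target_offset_from_boundary[[group]])
  conditions <- rep(names(k$step), k$block_reps)
  with_seed(seed, {
    conditions <- sample(conditions)
    blocks <- lapply(seq_along(conditions), function(b) {
      cond <- conditions[b]
      doff <- if (cond == "baseline") NA_real_ else
        k$distractor_offset[[group]][[cond]]
      offs <- .comparison_offsets(k$step[[cond]], constants$n_levels)
      .one_block("exp2", b, cond, offsets = offs,
                 reps = k$reps_per_level, jitter_max = k$jitter,
                 target_mean = tmean,
                 distractor_mean = .distractor_mean(tmean, doff),
                 n_dummy = k$n_dummy, dummy_offsets = offs)
    })
    sched <- do.call(rbind, blocks)
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

#' Build a practice schedule
#'
#' Practice uses only the three most distant comparison levels on each side
#' (six of the eleven levels; the zero offset never appears), three
#' repetitions each, 18 trials per block. The block order is fixed by design:
#' baseline first, then the 180-deg distractor block, then the remaining
#' distractor conditions in random order. Experiment 2 practice includes a
#' 180-deg distractor block in addition to its three main conditions.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param group Colour group, as in the schedule builders.
#' @param seed Integer seed.
#' @param green_blue_boundary Needed for `experiment = "exp2"`.
#' @inheritParams build_exp1_schedule
#' @return A `trial_schedule` data frame with `is_practice = TRUE`.
#' @export
build_practice_schedule <- function(experiment = c("exp1", "exp2"),
                                    group, seed = 1L,
                                    green_blue_boundary = NULL,
                                    constants = design_constants()) {
  experiment <- match.arg(experiment)
  pk <- constants$practice
  if (experiment == "exp1") {
    k <- constants$exp1
    group <- match.arg(group, c("pink", "green"))
    tmean <- k$target_mean[[group]]
    rest <- c("d60Y", "d60B")
    doff_tab <- k$distractor_offset[[group]]
  } else {
    k <- constants$exp2
    group <- match.arg(group, c("green", "blue"))
    stopifnot(!is.null(green_blue_boundary))
    tmean <- wrap_hue(green_blue_boundary +
                        k$target_offset_from_boundary[[group]])
    rest <- c("across", "within")
    doff_tab <- c(k$distractor_offset[[group]], d180 = 180)
  }
  with_seed(seed, {
    conditions <- c("baseline", "d180", sample(rest))
    blocks <- lapply(seq_along(conditions), function(b) {
      cond <- conditions[b]
      step <- if (cond == "d180" && experiment == "exp2") {
        constants$exp1$step[["d180"]]
      } else k$step[[cond]]
      offs <- .comparison_offsets(step, constants$n_levels)
      outer_idx <- order(abs(offs), decreasing = TRUE)[seq_len(pk$n_outer_levels)]
      doff <- if (cond == "baseline") NA_real_ else doff_tab[[cond]]
      .one_block(experiment, b, cond, offsets = offs[outer_idx],
                 reps = pk$reps_per_level, jitter_max = k$jitter,
                 target_mean = tmean,
                 distractor_mean = .distractor_mean(tmean, doff),
                 is_practice = TRUE)
    })
    sched <- do.call(rbind, blocks)
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

#' Schedule for a single condition at arbitrary repetition count
#'
#' Convenience generator for simulation studies: one condition of either
#' experiment with `reps_per_level` repetitions of each of the 11 comparison
#' offsets, in shuffled order with per-trial jitter, using that experiment's
#' stimulus parameters.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param group Colour group.
#' @param condition Condition name of the chosen experiment.
#' @param reps_per_level Repetitions of each comparison level.
#' @param seed Integer seed.
#' @param green_blue_boundary Needed for `experiment = "exp2"`.
#' @inheritParams build_exp1_schedule
#' @return A `trial_schedule` data frame.
#' @export
condition_schedule <- function(experiment = c("exp1", "exp2"), group,
                               condition, reps_per_level, seed = 1L,
                               green_blue_boundary = NULL,
                               constants = design_constants()) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    k <- constants$exp1
    group <- match.arg(group, c("pink", "green"))
    tmean <- k$target_mean[[group]]
  } else {
    k <- constants$exp2
    group <- match.arg(group, c("green", "blue"))
    stopifnot(!is.null(green_blue_boundary))
    tmean <- wrap_hue(green_blue_boundary +
                        k$target_offset_from_boundary[[group]])
  }
  condition <- match.arg(condition, names(k$step))
  doff <- if (condition == "baseline") NA_real_ else
    k$distractor_offset[[group]][[condition]]
  with_seed(seed, {
    sched <- .one_block(experiment, 1L, condition,
                        offsets = .comparison_offsets(k$step[[condition]],
                                                      constants$n_levels),
                        reps = as.integer(reps_per_level),
                        jitter_max = k$jitter, target_mean = tmean,
                        distractor_mean = .distractor_mean(tmean, doff))
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

#' Sample element hues for one ensemble
#'
#' Draws `n_elements` i.i.d. hues from the uniform distribution of full width
#' `range` centred on the jittered mean, wrapped onto the hue circle.
#'
#' @param mean_hue Nominal mean hue in degrees.
#' @param range Full width of the uniform hue distribution in degrees.
#' @param n_elements Number of ensemble elements.
#' @param trial_jitter Common jitter added to the mean for this trial.
#' @return Vector of `n_elements` hue angles in `[0, 360)`. Uses the current
#'   RNG state.
#' @export
sample_ensemble <- function(mean_hue, range, n_elements = 18L,
                            trial_jitter = 0) {
  m <- mean_hue + trial_jitter
  wrap_hue(stats::runif(n_elements, m - range / 2, m + range / 2))
}

#' Predicted absolute bias under full integration
#'
#' If the observer averaged all test elements (equal counts of target and
#' distractor elements with equal weight), the perceived test mean would sit
#' at the midpoint: half the target-distractor separation. The 180-deg
#' separation admits no meaningful average of opposing hues and returns `NA`.
#'
#' @param separation Absolute target-distractor separation in degrees
#'   (e.g. 60 or 45), or a condition's signed offset.
#' @return Predicted absolute bias in degrees, or `NA` for 180-deg
#'   separations.
#' @examples
#' full_integration_bias(60)   # 30
#' full_integration_bias(45)   # 22.5
#' @export
full_integration_bias <- function(separation) {
  s <- abs(signed_diff(separation, 0))
  if (any(s == 0)) stop("no distractor: full-integration bias undefined",
                        call. = FALSE)
  ifelse(s == 180, NA_real_, s / 2)
}

#' Expected bias of a mixing observer
#'
#' For equal counts of target and distractor elements, a per-element
#' distractor weight `w` (target weight 1) puts the expected weighted
#' circular mean at `atan2(w sin s, 1 + w cos s)` degrees from the target
#' mean toward the distractor, where `s` is the separation. `w = 0` is
#' perfect segmentation (bias 0); `w = 1` is full integration (the midpoint,
#' `s/2`).
#'
#' @param w Per-element distractor weight(s), nonnegative.
#' @param separation Target-distractor separation in degrees.
#' @return Expected bias toward the distractor, degrees.
#' @examples
#' mixing_bias(1, 60)    # 30: full integration
#' mixing_bias(0, 60)    # 0: perfect segmentation
#' @export
mixing_bias <- function(w, separation) {
  stopifnot(all(w >= 0))
  s <- separation * pi / 180
  atan2(w * sin(s), 1 + w * cos(s)) * 180 / pi
}

#' Distractor weight producing a given bias fraction
#'
#' Inverse of [mixing_bias()] expressed on the bias-fraction scale: returns
#' the per-element distractor weight `w` for which the expected bias equals
#' `fraction` times the full-integration prediction (`separation / 2`).
#'
#' @param fraction Target bias fraction in `[0, 1]`.
#' @param separation Target-distractor separation in degrees (not 180).
#' @return Per-element distractor weight in `[0, 1]`.
#' @examples
#' mixing_weight_for_fraction(1, 60)     # 1: full integration
#' mixing_weight_for_fraction(0.25, 60)  # ~0.165
#' @export
mixing_weight_for_fraction <- function(fraction, separation) {
  stopifnot(fraction >= 0, fraction <= 1)
  target <- fraction * full_integration_bias(separation)
  if (fraction == 0) return(0)
  if (fraction == 1) return(1)
  stats::uniroot(function(w) mixing_bias(w, separation) - target,
                 c(0, 1), tol = 1e-12)$root
}

#' Write or read a trial schedule as CSV
#'
#' One row per trial with the schedule columns; plain CSV, no metadata.
#'
#' @param schedule A `trial_schedule` data frame.
#' @param path File path.
#' @return `read_schedule` returns the `trial_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' @export
print.trial_schedule <- function(x, ...) {
  main <- !x$is_dummy & !x$is_practice
  cat(sprintf(
    "Trial schedule: %s, %d trials (%d analysed, %d dummy, %d practice)\n",
    x$experiment[1], nrow(x), sum(main), sum(x$is_dummy), sum(x$is_practice)))
  tab <- table(x$condition[main], x$comparison_offset_deg[main])
  if (any(main)) {
    cat("Analysed trials per condition:\n")
    print(rowSums(tab))
  }
  invisible(x)
}
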