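# End-to-end orchestration: a validated run configuration in, a bundle of
# schedules, simulated responses, fits and summary statistics out.

#' Build and validate a pipeline run configuration
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param group Colour group (`"pink"`/`"green"` for exp1,
#'   `"green"`/`"blue"` for exp2).
#' @param observers List of observer descriptions; each element is a list of
#'   [observer_params()] arguments, optionally with a `category_model`
#'   element (`list(kappa=, boundaries=, centroids=, category_names=)`) for
#'   experiment 2.
#' @param seed Base integer seed; per-observer seeds are derived from it and
#'   recorded in the manifest.
#' @param out_dir Output directory for [run_pipeline()].
#' @param category_model Shared true category model for experiment 2
#'   observers without their own.
#' @param analysis List of toggles: `by_block` (per-repetition PMF fits),
#'   `correlation_family` (Bonferroni family size for the correlation table,
#'   `NULL` = number of tests).
#' @return Validated `run_config` object.
#' @export
run_config <- function(experiment = c("exp1", "exp2"), group, observers,
                       seed = 1L, out_dir = tempfile("enshue_run_"),
                       category_model = NULL,
                       analysis = list(by_block = FALSE,
                                       correlation_family = NULL)) {
  experiment <- match.arg(experiment)
  group <- match.arg(group, if (experiment == "exp1") c("pink", "green")
                            else c("green", "blue"))
  stopifnot(is.list(observers), length(observers) >= 1L,
            is.numeric(seed), length(seed) == 1L, seed == round(seed))
  for (i in seq_along(observers)) {
    ob <- observers[[i]]
    if (!is.list(ob)) stop("observer ", i, " is not a list", call. = FALSE)
    do.call(observer_params, ob[setdiff(names(ob), "category_model")])
    if (experiment == "exp2" && is.null(ob$category_model) &&
        is.null(category_model)) {
      stop("experiment 2 needs a true category model per observer ",
           "(or a shared 'category_model')", call. = FALSE)
    }
  }
  structure(list(experiment = experiment, group = group,
                 observers = observers, seed = as.integer(seed),
                 out_dir = out_dir, category_model = category_model,
                 analysis = utils::modifyList(
                   list(by_block = FALSE, correlation_family = NULL),
                   analysis)),
            class = "run_config")
}

#' Read or write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

.as_category_model <- function(desc) {
  category_model(desc$kappa, unlist(desc$boundaries),
                 unlist(desc$centroids),
                 if (!is.null(desc$category_names))
                   unlist(desc$category_names) else NULL)
}

# Boundary of a fitted/true model closest to a reference hue (used to pick
# the green-blue boundary out of a multi-boundary model).
.nearest_boundary <- function(model, reference) {
  b <- model$boundaries
  b[which.min(abs(signed_diff(b, reference)))]
}

# The two fitted boundaries nearest to the target mean, reported low/high
# (clockwise/counterclockwise neighbour).
.flanking_boundaries <- function(model, target_mean) {
  d <- signed_diff(model$boundaries, target_mean)
  below <- d[d <= 0]
  above <- d[d > 0]
  c(boundary_low = if (length(below)) wrap_hue(target_mean + max(below))
                   else NA_real_,
    boundary_high = if (length(above)) wrap_hue(target_mean + min(above))
                    else NA_real_)
}

#' Run the full simulation-and-analysis pipeline
#'
#' For each observer in the configuration: build the experiment schedule,
#' simulate 2IFC responses, and fit per-condition psychometric functions.
#' For experiment 2, each observer first completes a simulated 72-hue
#' categorization task (von Mises category model), whose cleaned data are
#' fit for boundaries; the interleaved staircase then refines the green-blue
#' boundary, which anchors that observer's target mean. Condition-level
#' paired t tests (Bonferroni-corrected) and, when boundary measures exist,
#' within-condition Pearson correlations are computed over the cohort.
#' All artifacts are written as CSV plus a JSON manifest recording seeds and
#' the package version.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fit_table`, `ttests`, `correlations`,
#'   `category_fits`, `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  nobs <- length(config$observers)
  seeds <- config$seed + 1000L * seq_len(nobs)
  files <- character(0)
  rows <- list()
  cat_fits <- list()
  for (i in seq_len(nobs)) {
    ob <- config$observers[[i]]
    params <- do.call(observer_params,
                      ob[setdiff(names(ob), "category_model")])
    bnd <- c(boundary_low = NA_real_, boundary_high = NA_real_)
    if (config$experiment == "exp1") {
      sched <- build_exp1_schedule(config$group, seed = seeds[i])
    } else {
      true_cm <- .as_category_model(
        if (!is.null(ob$category_model)) ob$category_model
        else config$category_model)
      # first categorization task: 72 hues x 4 reps, cleaned and fitted
      cat_data <- simulate_categorization(true_cm, seq(0, 355, by = 5),
                                          reps = 4L, seed = seeds[i] + 1L)
      cleaned <- clean_category_data(cat_data)
      cm_fit <- fit_boundary_model(cleaned)
      true_gb <- .nearest_boundary(true_cm, 168)
      coarse_gb <- .nearest_boundary(cm_fit, true_gb)
      # staircase task refines the green-blue boundary
      sc <- with_seed(seeds[i] + 2L, {
        responder <- staircase_responder(true_gb, true_cm$kappa)
        run_staircase(responder, coarse_gb, seed = seeds[i] + 3L)
      })
      f <- file.path(config$out_dir,
                     sprintf("categorization_obs%02d.csv", i))
      write_categorization_log(cat_data, f)
      files <- c(files, f)
      f <- file.path(config$out_dir, sprintf("staircase_obs%02d.csv", i))
      write_staircase_trace(sc, f)
      files <- c(files, f)
      sched <- build_exp2_schedule(config$group, sc$estimate,
                                   seed = seeds[i])
      bnd <- .flanking_boundaries(cm_fit, sched$target_mean_deg[1])
      cat_fits[[i]] <- list(fit = cm_fit, staircase_estimate = sc$estimate,
                            coarse_estimate = coarse_gb)
    }
    resp <- simulate_2ifc(sched, params, seed = seeds[i] + 7L)
    f <- file.path(config$out_dir, sprintf("schedule_obs%02d.csv", i))
    write_schedule(sched, f); files <- c(files, f)
    f <- file.path(config$out_dir, sprintf("responses_obs%02d.csv", i))
    write_response_log(resp, f); files <- c(files, f)
    ft <- fit_pmf_by_condition(resp, by_block = config$analysis$by_block)
    ft <- data.frame(observer_id = i, group = config$group,
                     as.data.frame(ft),
                     boundary_low = bnd[["boundary_low"]],
                     boundary_high = bnd[["boundary_high"]])
    rows[[i]] <- ft
  }
  fit_table <- do.call(rbind, rows)
  fit_table <- fit_table[fit_table$valid, , drop = FALSE]
  f <- file.path(config$out_dir, "pmf_fit_table.csv")
  utils::write.csv(fit_table, f, row.names = FALSE); files <- c(files, f)
  if (length(cat_fits)) {
    cf <- do.call(rbind, lapply(seq_along(cat_fits), function(i) {
      data.frame(observer_id = i,
                 kappa = cat_fits[[i]]$fit$kappa,
                 t(stats::setNames(cat_fits[[i]]$fit$boundaries,
                                   paste0("boundary_",
                                          seq_along(cat_fits[[i]]$fit$boundaries)))),
                 staircase_gb = cat_fits[[i]]$staircase_estimate)
    }))
    f <- file.path(config$out_dir, "category_fits.csv")
    utils::write.csv(cf, f, row.names = FALSE); files <- c(files, f)
  }
  ttests <- correlations <- NULL
  conds <- unique(fit_table$condition)
  if (nobs >= 3L && length(conds) >= 2L) {
    prs <- utils::combn(conds, 2L, simplify = FALSE)
    tt <- list()
    for (ms in c("bias_deg", "sigma_deg")) {
      for (pr in prs) {
        res <- try(paired_t(fit_table, pr[1], pr[2], ms), silent = TRUE)
        if (inherits(res, "try-error")) next
        tt[[length(tt) + 1L]] <- data.frame(
          measure = ms, condition_a = pr[1], condition_b = pr[2],
          t = res$t, df = res$df, p = res$p)
      }
    }
    if (length(tt)) {
      ttests <- do.call(rbind, tt)
      ttests$p_adj <- stats::ave(ttests$p, ttests$measure,
                                 FUN = function(p) bonferroni(p))
      f <- file.path(config$out_dir, "stats_ttests.csv")
      utils::write.csv(ttests, f, row.names = FALSE); files <- c(files, f)
    }
    meas <- intersect(c("bias_deg", "sigma_deg", "boundary_low",
                        "boundary_high"), names(fit_table))
    meas <- meas[vapply(meas, function(m) !all(is.na(fit_table[[m]])),
                        logical(1))]
    if (length(meas) >= 2L) {
      correlations <- try(
        correlate(fit_table, meas,
                  family_size = config$analysis$correlation_family),
        silent = TRUE)
      if (inherits(correlations, "try-error")) correlations <- NULL
      else {
        f <- file.path(config$out_dir, "stats_correlations.csv")
        utils::write.csv(correlations, f, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }
  report <- c(
    sprintf("enshue pipeline run: %s, group %s, %d observer(s), seed %d",
            config$experiment, config$group, nobs, config$seed),
    "",
    utils::capture.output(print.data.frame(fit_table, row.names = FALSE,
                                           digits = 4)),
    if (!is.null(ttests)) c("", "Paired t tests (Bonferroni-adjusted):",
                            utils::capture.output(
                              print.data.frame(ttests, row.names = FALSE,
                                               digits = 4))))
  f <- file.path(config$out_dir, "report.txt")
  writeLines(report, f); files <- c(files, f)
  manifest <- list(package = "enshue",
                   version = as.character(utils::packageVersion("enshue")),
                   experiment = config$experiment, group = config$group,
                   base_seed = config$seed, observer_seeds = seeds,
                   n_observers = nobs, files = basename(files))
  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  invisible(list(fit_table = fit_table, ttests = ttests,
                 correlations = correlations, category_fits = cat_fits,
                 files = files))
}

#' Cohort fit table from independent response logs
#'
#' Convenience assembler for analyses outside [run_pipeline()]: fits PMFs per
#' condition for each observer's log and stacks them with observer ids.
#'
#' @param logs List of `response_log` objects, one per observer.
#' @param group Group label recycled across observers.
#' @return Data frame with `observer_id`, `group` and the per-condition fit
#'   columns of [fit_pmf_by_condition()].
#' @export
cohort_fit_table <- function(logs, group = "group1") {
  do.call(rbind, lapply(seq_along(logs), function(i) {
    data.frame(observer_id = i, group = group,
               as.data.frame(fit_pmf_by_condition(logs[[i]])))
  }))
}
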