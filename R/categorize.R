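# Categorization data handling, the von Mises category-boundary observer
# model, and the interleaved-staircase boundary estimator.

#' Construct a categorization dataset
#'
#' Counts of category responses per stimulus hue, typically 72 stimuli in
#' 5-degree steps around the hue circle with four repetitions each.
#'
#' @param stimulus_hues Stimulus hue angles in degrees (equally spaced grid).
#' @param counts Integer matrix, stimuli in rows and categories in columns.
#' @param category_names Category labels; defaults to column names.
#' @return An object of class `category_dataset`.
#' @export
category_dataset <- function(stimulus_hues, counts,
                             category_names = colnames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(stimulus_hues),
            all(counts >= 0), all(counts == round(counts)))
  if (is.null(category_names)) {
    category_names <- paste0("cat", seq_len(ncol(counts)))
  }
  colnames(counts) <- category_names
  structure(list(stimulus_hues = wrap_hue(stimulus_hues),
                 counts = counts,
                 category_names = category_names),
            class = "category_dataset")
}

#' @export
print.category_dataset <- function(x, ...) {
  cat(sprintf("Categorization dataset: %d stimuli, %d categories, %d responses\n",
              length(x$stimulus_hues), ncol(x$counts), sum(x$counts)))
  print(colSums(x$counts))
  invisible(x)
}

# Read a categorization log (stimulus_hue_deg, response_category rows) into
# a category_dataset on the grid of observed stimulus values.
#' Read or write categorization logs
#'
#' Long-format CSV with one row per trial: `stimulus_hue_deg`,
#' `response_category`.
#'
#' @param path File path.
#' @param dataset A `category_dataset`.
#' @return `read_categorization_log` returns a `category_dataset`.
#' @export
read_categorization_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stim <- sort(unique(wrap_hue(df$stimulus_hue_deg)))
  cats <- sort(unique(df$response_category))
  counts <- table(factor(wrap_hue(df$stimulus_hue_deg), levels = stim),
                  factor(df$response_category, levels = cats))
  category_dataset(stim, matrix(as.integer(counts), nrow = length(stim),
                                dimnames = list(NULL, cats)), cats)
}

#' @rdname read_categorization_log
#' @export
write_categorization_log <- function(dataset, path) {
  ns <- length(dataset$stimulus_hues)
  rows <- do.call(rbind, lapply(seq_len(ns), function(i) {
    reps <- rep(dataset$category_names, dataset$counts[i, ])
    if (!length(reps)) return(NULL)
    data.frame(stimulus_hue_deg = dataset$stimulus_hues[i],
               response_category = reps, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Circular gap (in grid steps) between successive occupied stimuli. Grid
# step inferred from the stimulus spacing.
.grid_step <- function(stimulus_hues) {
  d <- diff(sort(stimulus_hues))
  stats::median(d)
}

# Find the main response group for one category: maximal circular runs of
# occupied stimuli, where a gap of >= 3 consecutive empty grid steps
# terminates a run; the main group is the run spanning the most hue steps
# (ties broken by response count). Returns logical over stimuli: member of
# the main group.
.main_group <- function(occupied, counts_col, stimulus_hues, gap_steps = 3L) {
  n <- length(occupied)
  idx <- which(occupied)
  if (length(idx) <= 1L) {
    out <- logical(n); out[idx] <- TRUE; return(out)
  }
  # circular gaps between successive occupied stimuli, in grid steps
  gaps <- diff(c(idx, idx[1] + n)) - 1L
  breaks <- which(gaps >= gap_steps)
  if (!length(breaks)) {
    out <- logical(n); out[idx] <- TRUE; return(out)
  }
  # runs wrap circularly: start after each break
  runs <- list()
  nb <- length(breaks)
  for (k in seq_len(nb)) {
    from <- breaks[k] + 1L
    to <- if (k < nb) breaks[k + 1L] else breaks[1L] + length(idx)
    members <- idx[((seq(from, to) - 1L) %% length(idx)) + 1L]
    runs[[k]] <- members
  }
  span <- vapply(runs, function(m) {
    pos <- sort(m)
    # circular span in steps: total minus the largest internal gap
    g <- diff(c(pos, pos[1] + n))
    n - max(g)
  }, numeric(1))
  nresp <- vapply(runs, function(m) sum(counts_col[m]), numeric(1))
  best <- order(-span, -nresp)[1]
  out <- logical(n)
  out[runs[[best]]] <- TRUE
  out
}

#' Clean categorization data before boundary fitting
#'
#' Two exclusion passes remove likely response errors: (1) categories with
#' fewer than `min_responses` responses overall are dropped; (2) within each
#' remaining category, responses separated from the category's main group of
#' responses by `isolation_deg` degrees of hue or more are removed. A group
#' is a run of adjacent occupied stimulus values, terminated by three
#' consecutive grid steps without that category's response; the main group is
#' the largest in hue steps.
#'
#' @param raw A `category_dataset`.
#' @param min_responses Minimum total responses to retain a category.
#' @param isolation_deg Hue distance from the main group at which isolated
#'   responses are excluded.
#' @return The cleaned `category_dataset`, with an `exclusions` attribute
#'   listing dropped categories and removed response counts.
#' @export
clean_category_data <- function(raw, min_responses = 4L, isolation_deg = 20) {
  stopifnot(inherits(raw, "category_dataset"))
  keep_cat <- colSums(raw$counts) >= min_responses
  dropped <- raw$category_names[!keep_cat]
  counts <- raw$counts[, keep_cat, drop = FALSE]
  cats <- raw$category_names[keep_cat]
  if (!length(cats)) stop("all categories excluded", call. = FALSE)
  removed <- integer(length(cats))
  names(removed) <- cats
  for (k in seq_along(cats)) {
    col <- counts[, k]
    occ <- col > 0
    if (!any(occ)) next
    main <- .main_group(occ, col, raw$stimulus_hues)
    main_h <- raw$stimulus_hues[main]
    dist <- vapply(raw$stimulus_hues, function(h)
      min(abs(signed_diff(h, main_h))), numeric(1))
    far <- occ & !main & dist >= isolation_deg
    removed[k] <- sum(col[far])
    counts[far, k] <- 0L
  }
  out <- category_dataset(raw$stimulus_hues, counts, cats)
  attr(out, "exclusions") <- list(dropped_categories = dropped,
                                  removed_responses = removed)
  out
}

#' Category centroids as response-weighted circular means
#'
#' @param cleaned A `category_dataset` (after [clean_category_data()]).
#' @return Named vector of centroid hue angles, one per category.
#' @export
category_centroids <- function(cleaned) {
  stopifnot(inherits(cleaned, "category_dataset"))
  cents <- vapply(seq_len(ncol(cleaned$counts)), function(k) {
    w <- cleaned$counts[, k]
    if (sum(w) == 0) stop("empty category: no centroid", call. = FALSE)
    circular_mean(cleaned$stimulus_hues, w)$mean
  }, numeric(1))
  names(cents) <- cleaned$category_names
  cents
}

#' Construct a von Mises category-boundary model
#'
#' A categorical observer with von Mises measurement noise (shared
#' concentration `kappa`) and fixed boundaries on the hue circle. Category
#' `k` occupies the counterclockwise arc from `boundaries[k]` to
#' `boundaries[k + 1]` (wrapping at the end) and contains `centroids[k]`;
#' boundaries and centroids interleave strictly.
#'
#' @param kappa von Mises concentration (nonnegative).
#' @param boundaries Boundary hue angles; `boundaries[k]` is the lower
#'   (clockwise) edge of category `k`'s arc.
#' @param centroids Centroid hue angles, one per category, each inside its
#'   arc.
#' @param category_names Optional labels.
#' @return An object of class `category_model`.
#' @export
category_model <- function(kappa, boundaries, centroids,
                           category_names = names(centroids)) {
  stopifnot(kappa >= 0, length(boundaries) == length(centroids))
  boundaries <- wrap_hue(boundaries)
  centroids <- wrap_hue(centroids)
  K <- length(boundaries)
  for (k in seq_len(K)) {
    arc <- (boundaries[if (k == K) 1L else k + 1L] - boundaries[k]) %% 360
    pos <- (centroids[k] - boundaries[k]) %% 360
    if (K > 1L && !(pos > 0 && pos < arc)) {
      stop("centroid ", k, " not inside its boundary arc", call. = FALSE)
    }
  }
  if (is.null(category_names)) {
    category_names <- paste0("cat", seq_len(K))
  }
  structure(list(kappa = kappa, boundaries = boundaries,
                 centroids = centroids, category_names = category_names),
            class = "category_model")
}

#' Assign hues to categories under a boundary model
#'
#' @param model A `category_model`.
#' @param hues Hue angles in degrees.
#' @return Integer category indices (1-based, in model order).
#' @export
assign_category <- function(model, hues) {
  K <- length(model$boundaries)
  if (K == 1L) return(rep(1L, length(hues)))
  b <- model$boundaries
  upper <- b[c(2:K, 1L)]
  vapply(wrap_hue(hues), function(h) {
    pos <- (h - b) %% 360
    arc <- (upper - b) %% 360
    which(pos < arc)[1]
  }, integer(1))
}

# Matrix of category response probabilities for all stimuli under
# (kappa, boundaries): stimuli x categories, rows sum to 1.
.category_prob_matrix <- function(stimulus_hues, kappa, boundaries) {
  K <- length(boundaries)
  upper <- boundaries[c(2:K, 1L)]
  P <- vapply(seq_len(K), function(k) {
    .vm_arc_prob(stimulus_hues, kappa, boundaries[k], upper[k])
  }, numeric(length(stimulus_hues)))
  matrix(P, nrow = length(stimulus_hues))
}

#' Category response probabilities under a boundary model
#'
#' @param object A `category_model`.
#' @param newdata Stimulus hue angles in degrees; defaults to a 72-point
#'   5-degree grid.
#' @param ... Unused.
#' @return Matrix of probabilities, stimuli in rows, categories in columns;
#'   rows sum to 1.
#' @export
predict.category_model <- function(object, newdata = seq(0, 355, by = 5),
                                   ...) {
  P <- .category_prob_matrix(wrap_hue(newdata), object$kappa,
                             object$boundaries)
  colnames(P) <- object$category_names
  P
}

#' @export
coef.category_model <- function(object, ...) {
  c(kappa = object$kappa,
    stats::setNames(object$boundaries,
                    paste0("boundary_", seq_along(object$boundaries))))
}

#' @export
logLik.category_model <- function(object, ...) {
  if (is.null(object$nll)) stop("model was not fitted to data", call. = FALSE)
  structure(-object$nll, df = length(object$boundaries) + 1L,
            class = "logLik")
}

#' @export
print.category_model <- function(x, ...) {
  cat("von Mises category-boundary model\n")
  cat(sprintf("  kappa: %.4g (measurement noise SD ~ %.2f deg)\n",
              x$kappa, if (x$kappa > 0) 180 / pi / sqrt(x$kappa) else Inf))
  cat("  boundaries (deg):",
      paste(sprintf("%.1f", x$boundaries), collapse = ", "), "\n")
  cat("  centroids  (deg):",
      paste(sprintf("%.1f", x$centroids), collapse = ", "), "\n")
  if (!is.null(x$nll)) {
    cat(sprintf("  negative log-likelihood: %.3f (%s)\n", x$nll,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
summary.category_model <- function(object, ...) {
  print(object)
  if (!is.null(object$nll)) {
    cat(sprintf("  fitted to %d responses over %d stimuli\n",
                object$n_responses, object$n_stimuli))
  }
  invisible(object)
}

#' @export
simulate.category_model <- function(object, nsim = 1, seed = NULL, ...,
                                    stimulus_hues = seq(0, 355, by = 5),
                                    reps = 4L) {
  simulate_categorization(object, stimulus_hues, reps = reps,
                          seed = if (is.null(seed)) 1L else seed)
}

#' Plot a category model against data
#'
#' Model response probabilities per category as curves over the hue circle,
#' with observed response proportions as points when data are supplied.
#'
#' @param x A `category_model`.
#' @param data Optional `category_dataset`.
#' @param ... Passed to `matplot`.
#' @export
plot.category_model <- function(x, data = NULL, ...) {
  grid <- seq(0, 359.5, by = 0.5)
  P <- predict(x, grid)
  graphics::matplot(grid, P, type = "l", lty = 1,
                    xlab = "stimulus hue (deg)",
                    ylab = "category response probability", ...)
  graphics::abline(v = x$boundaries, lty = 3, col = "grey40")
  if (!is.null(data)) {
    prop <- data$counts / pmax(rowSums(data$counts), 1)
    graphics::matpoints(data$stimulus_hues, prop, pch = 1)
  }
  invisible(x)
}

#' Maximum-likelihood fit of the von Mises category-boundary model
#'
#' Fits a shared concentration `kappa` and one boundary per pair of adjacent
#' category centroids, each boundary box-constrained to lie between its two
#' centroids. The likelihood of a response is the von Mises probability mass
#' of the responded category's arc, centred on the stimulus; the negative
#' log-likelihood is minimised by `L-BFGS-B` from the centroid-interval
#' midpoints plus two deterministic jittered restarts.
#'
#' @param cleaned A `category_dataset` (ideally after
#'   [clean_category_data()]); at least two categories.
#' @param centroids Optional centroid vector; computed by
#'   [category_centroids()] when missing.
#' @param n_restarts Number of additional jittered starts.
#' @param control Passed to [stats::optim()]; the NLL convergence tolerance
#'   defaults to `factr = 1e7 * .Machine$double.eps` scale via `factr = 10`.
#' @return A fitted `category_model` with elements `nll`, `converged`,
#'   `n_responses`, `n_stimuli` and the centroid box constraints.
#' @export
fit_boundary_model <- function(cleaned, centroids = NULL, n_restarts = 2L,
                               control = list()) {
  stopifnot(inherits(cleaned, "category_dataset"))
  if (ncol(cleaned$counts) < 2L) {
    stop("need at least two categories to place a boundary", call. = FALSE)
  }
  if (is.null(centroids)) centroids <- category_centroids(cleaned)
  ord <- order(centroids)
  centroids <- centroids[ord]
  counts <- cleaned$counts[, ord, drop = FALSE]
  cats <- cleaned$category_names[ord]
  K <- length(centroids)
  stim <- cleaned$stimulus_hues
  # boundary k sits between centroid k-1 and centroid k (circularly);
  # boundary 1 between the last and first centroids. Parameterise each as a
  # fraction of its centroid gap.
  lower_cent <- centroids[c(K, seq_len(K - 1L))]
  gaps <- (centroids - lower_cent) %% 360
  nll_fun <- function(par) {
    kappa <- exp(par[1])
    b <- wrap_hue(lower_cent + par[-1] * gaps)
    P <- .category_prob_matrix(stim, kappa, b)
    -sum(counts * log(pmax(P, 1e-12)))
  }
  eps <- 1e-3
  starts <- list(c(log(5), rep(0.5, K)))
  jit <- c(0.25, 0.75)
  for (r in seq_len(n_restarts)) {
    starts[[r + 1L]] <- c(log(5) + (r - 1.5), rep(jit[(r - 1L) %% 2L + 1L], K))
  }
  ctrl <- utils::modifyList(list(factr = 10, maxit = 500), control)
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, nll_fun, method = "L-BFGS-B",
                            lower = c(log(1e-3), rep(eps, K)),
                            upper = c(log(1e8), rep(1 - eps, K)),
                            control = ctrl), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  kappa <- exp(best$par[1])
  boundaries <- wrap_hue(lower_cent + best$par[-1] * gaps)
  out <- category_model(kappa, boundaries, centroids, cats)
  out$nll <- best$value
  out$converged <- best$convergence == 0
  out$optim_message <- best$message
  out$n_responses <- sum(counts)
  out$n_stimuli <- length(stim)
  if (!out$converged) {
    warning("boundary-model optimizer did not report convergence: ",
            best$message, call. = FALSE)
  }
  out
}

#' Interleaved-staircase estimation of a category boundary
#'
#' Runs four interleaved 1-up/1-down staircases (two starting 20 deg below
#' and two 20 deg above the initial guess) in strict round-robin order. A
#' green response moves the stimulus toward higher hue angle, a blue response
#' toward lower. The step starts at 4 deg and shrinks by one fourth
#' (multiplied by 0.75) at every reversal, floored at 0.25 deg; each
#' staircase runs 25 trials. The boundary estimate is the circular mean of
#' the stimulus hues at the last two reversal points of every staircase;
#' staircases with fewer than two reversals are dropped with a warning.
#'
#' @param responder A function of a stimulus hue returning `"green"` or
#'   `"blue"`, e.g. from [staircase_responder()].
#' @param initial_boundary_guess Starting boundary guess in degrees.
#' @param seed Integer seed.
#' @param settings Staircase settings (`design_constants()$staircase`).
#' @return An object of class `staircase_fit`: `estimate` (degrees), `trace`
#'   (data frame of every trial), `reversal_hues` (those entering the
#'   estimate), `n_trials`.
#' @export
run_staircase <- function(responder, initial_boundary_guess, seed = 1L,
                          settings = design_constants()$staircase) {
  with_seed(seed, {
    ns <- settings$n_staircases
    starts <- initial_boundary_guess +
      rep(c(-1, 1), length.out = ns) * settings$start_offset
    level <- wrap_hue(starts)
    step <- rep(settings$start_step, ns)
    last_resp <- rep(NA_character_, ns)
    reversals <- vector("list", ns)
    trace <- vector("list", ns * settings$n_trials)
    ti <- 0L
    for (trial in seq_len(settings$n_trials)) {
      for (s in seq_len(ns)) {
        resp <- responder(level[s])
        is_rev <- !is.na(last_resp[s]) && resp != last_resp[s]
        ti <- ti + 1L
        trace[[ti]] <- data.frame(staircase = s, trial = trial,
                                  stimulus_hue_deg = level[s],
                                  response = resp, step_deg = step[s],
                                  is_reversal = is_rev)
        if (is_rev) {
          reversals[[s]] <- c(reversals[[s]], level[s])
          step[s] <- max(step[s] * settings$step_factor, settings$min_step)
        }
        last_resp[s] <- resp
        level[s] <- wrap_hue(level[s] +
                               if (resp == "green") step[s] else -step[s])
      }
    }
    used <- vapply(reversals, length, integer(1)) >= 2L
    if (!all(used)) {
      warning(sum(!used), " staircase(s) with fewer than two reversals ",
              "dropped from the estimate", call. = FALSE)
    }
    rev_hues <- unlist(lapply(reversals[used], function(r) utils::tail(r, 2)))
    est <- if (length(rev_hues)) circular_mean(rev_hues)$mean else NA_real_
    structure(list(estimate = est,
                   trace = do.call(rbind, trace[seq_len(ti)]),
                   reversal_hues = rev_hues,
                   n_trials = ti,
                   initial_guess = initial_boundary_guess),
              class = "staircase_fit")
  })
}

#' @export
print.staircase_fit <- function(x, ...) {
  cat(sprintf(
    "Interleaved staircases: %d trials, boundary estimate %.2f deg\n",
    x$n_trials, x$estimate))
  nrev <- table(x$trace$staircase[x$trace$is_reversal])
  cat("  reversals per staircase:", paste(nrev, collapse = ", "), "\n")
  invisible(x)
}

#' Plot staircase traces
#'
#' @param x A `staircase_fit`.
#' @param ... Passed to `plot`.
#' @export
plot.staircase_fit <- function(x, ...) {
  tr <- x$trace
  graphics::plot(range(tr$trial), range(tr$stimulus_hue_deg), type = "n",
                 xlab = "trial", ylab = "stimulus hue (deg)", ...)
  for (s in unique(tr$staircase)) {
    sub <- tr[tr$staircase == s, ]
    graphics::lines(sub$trial, sub$stimulus_hue_deg, col = s)
    graphics::points(sub$trial[sub$is_reversal],
                     sub$stimulus_hue_deg[sub$is_reversal], col = s, pch = 16)
  }
  graphics::abline(h = x$estimate, lty = 2)
  invisible(x)
}

#' Write a staircase trace as CSV
#'
#' Columns: `staircase_id`, `trial`, `stimulus_hue_deg`, `response`,
#' `step_deg`, `is_reversal`.
#'
#' @param fit A `staircase_fit`.
#' @param path File path.
#' @export
write_staircase_trace <- function(fit, path) {
  tr <- fit$trace
  names(tr)[names(tr) == "staircase"] <- "staircase_id"
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
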