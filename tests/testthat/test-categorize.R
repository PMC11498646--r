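test_that("sparse categories and isolated responses are excluded", {
  stim <- seq(0, 355, by = 5)
  counts <- matrix(0L, length(stim), 3,
                   dimnames = list(NULL, c("green", "other", "stray")))
  counts[stim >= 100 & stim <= 140, "green"] <- 2L
  counts[stim == 165, "green"] <- 1L          # 25 deg from the main group
  counts[stim < 95 | stim > 170, "other"] <- 4L
  counts[stim == 50, "stray"] <- 3L           # < 4 responses overall
  d <- category_dataset(stim, counts)
  cl <- clean_category_data(d)
  excl <- attr(cl, "exclusions")
  expect_equal(excl$dropped_categories, "stray")
  expect_false("stray" %in% cl$category_names)
  expect_equal(unname(cl$counts[stim == 165, "green"]), 0L)
  expect_equal(unname(excl$removed_responses["green"]), 1L)
  # a response 15 deg away from the group survives
  counts2 <- counts[, 1:2]
  counts2[stim == 165, "green"] <- 0L
  counts2[stim == 155, "green"] <- 1L
  cl2 <- clean_category_data(category_dataset(stim, counts2))
  expect_equal(unname(cl2$counts[stim == 155, "green"]), 1L)
})

test_that("cleaning is idempotent and preserves clean data", {
  d <- toy_category_data()
  cl <- clean_category_data(d)
  expect_equal(cl$counts, d$counts)
  expect_equal(clean_category_data(cl)$counts, cl$counts)
  # all categories too sparse
  stim <- seq(0, 355, by = 5)
  sparse <- matrix(0L, length(stim), 1, dimnames = list(NULL, "x"))
  sparse[1, 1] <- 2L
  expect_error(clean_category_data(category_dataset(stim, sparse)),
               "all categories excluded")
})

test_that("main response group detection wraps around the hue circle", {
  stim <- seq(0, 355, by = 5)
  counts <- matrix(0L, length(stim), 2,
                   dimnames = list(NULL, c("pinkish", "rest")))
  counts[stim >= 330 | stim <= 20, "pinkish"] <- 3L  # run across 0
  counts[stim == 90, "pinkish"] <- 1L                # isolated, 70 deg away
  counts[stim > 30 & stim < 320, "rest"] <- 2L
  cl <- clean_category_data(category_dataset(stim, counts))
  expect_equal(unname(cl$counts[stim == 90, "pinkish"]), 0L)
  expect_equal(sum(cl$counts[, "pinkish"]), sum(stim >= 330 | stim <= 20) * 3L)
})

test_that("category centroids are response-weighted circular means", {
  stim <- c(120, 130, 140)
  d <- category_dataset(stim, matrix(c(1L, 1L, 1L), 3, 1,
                                     dimnames = list(NULL, "g")))
  expect_equal(unname(category_centroids(d)), 130)
  d2 <- category_dataset(c(350, 10), matrix(c(2L, 2L), 2, 1,
                                            dimnames = list(NULL, "p")))
  expect_equal(unname(category_centroids(d2)), 0)
  set.seed(11)
  stim3 <- seq(0, 355, by = 5)
  cnt <- matrix(rpois(72, 1), 72, 1, dimnames = list(NULL, "x"))
  cnt[1] <- cnt[1] + 1L  # ensure nonempty
  d3 <- category_dataset(stim3, cnt)
  expect_equal(unname(category_centroids(d3)),
               vector_sum_mean(stim3, as.numeric(cnt)), tolerance = 1e-9)
  empty <- category_dataset(stim3, matrix(0L, 72, 1,
                                          dimnames = list(NULL, "e")))
  expect_error(category_centroids(empty), "empty category")
})

test_that("category models validate interleaving and normalise probabilities", {
  expect_error(category_model(5, c(78, 168), c(30, 200)), "not inside")
  m <- two_cat_model(8)
  P <- predict(m, seq(0, 355, by = 5))
  expect_equal(unname(rowSums(P)), rep(1, 72), tolerance = 1e-9)
  expect_equal(assign_category(m, c(100, 200, 78.2, 168.2)),
               c(1L, 2L, 1L, 2L))
  expect_equal(names(coef(m))[1], "kappa")
})

test_that("boundary fits beat the generating parameters in likelihood", {
  true <- two_cat_model(10)
  d <- simulate_categorization(true, seq(0, 355, by = 5), reps = 4, seed = 21)
  cl <- clean_category_data(d)
  fit <- fit_boundary_model(cl)
  nll_at <- function(kappa, boundaries) {
    P <- predict(category_model(kappa, boundaries, fit$centroids), cl$stimulus_hues)
    -sum(cl$counts * log(pmax(P, 1e-12)))
  }
  expect_lte(fit$nll, nll_at(10, c(78.1, 168.1)) + 1e-6)
  expect_true(fit$converged)
  expect_equal(stats::logLik(fit)[1], -fit$nll)
})

test_that("boundary fitting is rotation-equivariant", {
  true <- two_cat_model(12)
  d <- simulate_categorization(true, seq(0, 355, by = 5), reps = 4, seed = 31)
  cl <- clean_category_data(d)
  f0 <- fit_boundary_model(cl)
  rot <- 40
  d_r <- category_dataset(wrap_hue(cl$stimulus_hues + rot), cl$counts,
                          cl$category_names)
  f_r <- fit_boundary_model(d_r)
  expect_equal(sort(wrap_hue(f0$boundaries + rot)), sort(f_r$boundaries),
               tolerance = 0.1)
  expect_equal(f0$kappa, f_r$kappa, tolerance = 0.02 * f0$kappa)
})

test_that("noiseless categorization identifies boundaries within one grid step", {
  true <- two_cat_model(1e6)
  d <- simulate_categorization(true, seq(0, 355, by = 5), reps = 4, seed = 41)
  fit <- suppressWarnings(fit_boundary_model(clean_category_data(d)))
  b <- sort(fit$boundaries)
  expect_lt(abs(signed_diff(b[1], 78.1)), 5)
  expect_lt(abs(signed_diff(b[2], 168.1)), 5)
})

test_that("interleaved staircases converge on the boundary", {
  fit <- run_staircase(staircase_responder(168, 1e6), 170, seed = 9)
  expect_equal(fit$n_trials, 100)
  expect_lt(abs(signed_diff(fit$estimate, 168)), 1)
  tr <- fit$trace
  expect_setequal(unique(tr$staircase), 1:4)
  expect_equal(as.integer(table(tr$staircase)), rep(25L, 4))
  # two staircases start 20 below the guess, two 20 above
  first <- tr$stimulus_hue_deg[tr$trial == 1]
  expect_setequal(round(first, 6), c(150, 190))
  # after the first reversal the step drops from 4 to 3
  for (s in 1:4) {
    sub <- tr[tr$staircase == s, ]
    rev1 <- which(sub$is_reversal)[1]
    expect_equal(sub$step_deg[rev1], 4)
    if (rev1 < nrow(sub)) expect_equal(sub$step_deg[rev1 + 1L], 3)
  }
})

test_that("reversal-poor staircases are dropped with a warning", {
  always_green <- function(stimulus_hue) "green"
  expect_warning(fit <- run_staircase(always_green, 100, seed = 3),
                 "fewer than two reversals")
  expect_true(is.na(fit$estimate))
})

test_that("staircase traces round-trip to CSV", {
  fit <- run_staircase(staircase_responder(168, 50), 168, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_staircase_trace(fit, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 100)
  expect_true(all(c("staircase_id", "trial", "stimulus_hue_deg", "response",
                    "step_deg", "is_reversal") %in% names(back)))
  unlink(f)
})

test_that("categorization logs round-trip to CSV", {
  d <- simulate_categorization(two_cat_model(10), seq(0, 355, by = 5),
                               reps = 4, seed = 51)
  f <- tempfile(fileext = ".csv")
  write_categorization_log(d, f)
  back <- read_categorization_log(f)
  expect_equal(back$counts[, sort(colnames(back$counts))],
               d$counts[, sort(colnames(d$counts))])
  unlink(f)
})
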