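test_that("noiseless ensemble estimates are weighted circular means", {
  quiet <- observer_params(internal_noise_sd = 0)
  expect_equal(estimate_ensemble(c(338, 342), params = quiet), 340)
  hues <- c(rep(340, 18), rep(40, 18))
  w_full <- rep(1, 36)
  expect_equal(estimate_ensemble(hues, w_full, quiet), 10)
  w_third <- rep(c(1, 1/3), each = 18)
  expect_equal(estimate_ensemble(hues, w_third, quiet),
               vector_sum_mean(hues, w_third), tolerance = 1e-9)
  # the weighted vector sum: atan2 of 18 u(340) + 6 u(40)
  expect_equal(estimate_ensemble(hues, w_third, quiet),
               wrap_hue(340 + atan2(6 * sin(pi / 3),
                                    18 + 6 * cos(pi / 3)) * 180 / pi),
               tolerance = 1e-9)
})

test_that("antipodal cancellation resolves to one of the two arcs", {
  quiet <- observer_params(internal_noise_sd = 0)
  set.seed(1)
  est <- replicate(40, estimate_ensemble(c(rep(0, 5), rep(180, 5)),
                                         params = quiet))
  expect_true(all(est %in% c(0, 180)))
  expect_true(length(unique(est)) == 2)  # fair coin hits both arcs
})

test_that("central tendency shrinks the estimate toward the grand mean", {
  p <- observer_params(internal_noise_sd = 0, ctb_weight = 0.5)
  expect_equal(estimate_ensemble(c(338, 342), params = p, grand_mean = 320),
               330)
  p0 <- observer_params(internal_noise_sd = 0, ctb_weight = 0)
  expect_equal(estimate_ensemble(c(338, 342), params = p0, grand_mean = 320),
               340)
})

test_that("2IFC simulation is reproducible and sign-consistent when noiseless", {
  sch <- condition_schedule("exp1", "pink", "baseline", reps_per_level = 20,
                            seed = 31)
  seg <- observer_params(distractor_weight = 0, internal_noise_sd = 0)
  r1 <- simulate_2ifc(sch, seg, seed = 8)
  r2 <- simulate_2ifc(sch, seg, seed = 8)
  expect_identical(r1$response, r2$response)
  # outer comparison levels dwarf the 18-element sampling noise
  outer <- abs(r1$comparison_offset_deg) >= 12
  expect_equal(r1$response[outer],
               as.integer(r1$comparison_offset_deg[outer] > 0))
})

test_that("lapses push responses toward chance at extreme levels", {
  sch <- condition_schedule("exp1", "pink", "baseline", reps_per_level = 200,
                            seed = 13)
  lapser <- observer_params(internal_noise_sd = 0, lapse_rate = 0.5)
  r <- simulate_2ifc(sch, lapser, seed = 14)
  top <- r$comparison_offset_deg == 20
  expect_gt(mean(r$response[top]), 0.65)
  expect_lt(mean(r$response[top]), 0.85)  # 0.5 lapse: expect ~0.75
})

test_that("mixing observers produce the predicted bias fraction", {
  for (w in c(0, 1/3, 1)) {
    pred <- mixing_bias(w, 60) / full_integration_bias(60)
    got <- recovered_fraction(w, noise_sd = 4, reps = 910, seed = 100 + w * 9)
    expect_lt(abs(got - pred), 0.05)
  }
})

test_that("fitted thresholds are nondecreasing in internal noise", {
  sig <- vapply(c(2, 4, 8), function(nsd) {
    sch <- condition_schedule("exp1", "pink", "baseline",
                              reps_per_level = 910, seed = 55)
    r <- simulate_2ifc(sch, observer_params(internal_noise_sd = nsd),
                       seed = 56)
    fit_pmf_by_condition(r)$sigma_deg[1]
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("a segregating observer shows matched thresholds in baseline and 180", {
  sig <- sapply(1:6, function(s) {
    vapply(c("baseline", "d180"), function(cond) {
      sch <- condition_schedule("exp1", "pink", cond, reps_per_level = 40,
                                seed = 200 + s)
      r <- simulate_2ifc(sch, observer_params(distractor_weight = 0,
                                              internal_noise_sd = 4),
                         seed = 300 + s)
      fit_pmf_by_condition(r)$sigma_deg[1]
    }, numeric(1))
  })
  tt <- stats::t.test(sig["baseline", ], sig["d180", ], paired = TRUE)
  expect_gt(tt$p.value, 0.01)
})

test_that("categorization responses follow the boundary arcs", {
  m <- two_cat_model(1e6)
  stim <- seq(0, 355, by = 5)
  d <- simulate_categorization(m, stim, reps = 4, seed = 2)
  inside <- (stim - 78.1) %% 360 < (168.1 - 78.1) %% 360
  expect_equal(unname(d$counts[, "green"]), ifelse(inside, 4L, 0L))
  # kappa = 0: response frequencies proportional to arc widths
  d0 <- simulate_categorization(two_cat_model(0), 0, reps = 1e4, seed = 3)
  chi <- stats::chisq.test(as.vector(d0$counts), p = c(90, 270) / 360)
  expect_gt(chi$p.value, 0.01)
})

test_that("noisy categorization matches the von Mises arc-probability oracle", {
  m <- two_cat_model(10)
  stim <- seq(0, 355, by = 5)
  d <- simulate_categorization(m, stim, reps = 200, seed = 4)
  p_hat <- d$counts[, "green"] / 200
  p_true <- vm_interval_prob(stim, 10, 78.1, 168.1)
  expect_lt(max(abs(p_hat - p_true)), 4 * sqrt(0.25 / 200))
  # confusions live near the boundaries
  uncertain <- p_hat > 0.1 & p_hat < 0.9
  near_bound <- pmin(abs(signed_diff(stim, 78.1)),
                     abs(signed_diff(stim, 168.1))) < 45
  expect_true(all(near_bound[uncertain]))
})

test_that("the staircase responder behaves like the von Mises CDF", {
  r_sharp <- staircase_responder(168, 1e6)
  set.seed(6)
  expect_true(all(replicate(50, r_sharp(163)) == "green"))
  expect_true(all(replicate(50, r_sharp(173)) == "blue"))
  r20 <- staircase_responder(168, 20)
  set.seed(7)
  at_bound <- mean(replicate(2000, r20(168)) == "green")
  expect_lt(abs(at_bound - 0.5), 0.05)
  for (s in c(158, 165, 171, 178)) {
    p_hat <- mean(replicate(2000, r20(s)) == "green")
    # P(measurement below boundary) = mass of the half-circle arc ending
    # at the boundary
    p_true <- vm_interval_prob(s, 20, 168 - 180, 168)
    expect_lt(abs(p_hat - p_true), 4 * sqrt(0.25 / 2000))
  }
})

test_that("response logs round-trip with observer metadata", {
  sch <- condition_schedule("exp1", "green", "d60B", reps_per_level = 5,
                            seed = 77)
  p <- observer_params(distractor_weight = 0.2, internal_noise_sd = 3,
                       lapse_rate = 0.02)
  r <- simulate_2ifc(sch, p, seed = 78)
  f <- tempfile(fileext = ".csv")
  write_response_log(r, f)
  back <- read_response_log(f)
  expect_equal(back$response, r$response)
  expect_equal(attr(back, "observer_params")$distractor_weight, 0.2)
  expect_equal(attr(back, "observer_params")$lapse_rate, 0.02)
  unlink(f)
})
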