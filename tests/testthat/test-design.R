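test_that("experiment 1 schedules have the exact design arithmetic", {
  s <- build_exp1_schedule("pink", seed = 11)
  expect_equal(nrow(s), 880)
  expect_equal(as.integer(table(s$block)), rep(110L, 8))
  # permutation-complete: each condition x offset cell has 20 trials
  # (2 block repetitions x 10 reps per level)
  tab <- table(s$condition, s$comparison_offset_deg)
  expect_true(all(tab[tab > 0] == 20))
  expect_equal(sort(unique(s$comparison_offset_deg[s$condition == "baseline"])),
               4 * (-5:5))
  expect_equal(sort(unique(s$comparison_offset_deg[s$condition == "d180"])),
               5 * (-5:5))
  expect_equal(sort(unique(s$comparison_offset_deg[s$condition == "d60Y"])),
               6 * (-5:5))
  expect_true(all(abs(s$jitter_deg) <= 7.5))
  expect_false(any(s$is_dummy) || any(s$is_practice))
})

test_that("experiment 1 distractor geometry follows the hue-circle direction convention", {
  sp <- build_exp1_schedule("pink", seed = 2)
  expect_equal(unique(sp$target_mean_deg), 340)
  expect_equal(unique(sp$distractor_mean_deg[sp$condition == "d60Y"]), 40)
  expect_equal(unique(sp$distractor_mean_deg[sp$condition == "d60B"]), 280)
  expect_equal(unique(sp$distractor_mean_deg[sp$condition == "d180"]), 160)
  expect_true(all(is.na(sp$distractor_mean_deg[sp$condition == "baseline"])))
  sg <- build_exp1_schedule("green", seed = 2)
  expect_equal(unique(sg$target_mean_deg), 130)
  expect_equal(unique(sg$distractor_mean_deg[sg$condition == "d60Y"]), 70)
  expect_equal(unique(sg$distractor_mean_deg[sg$condition == "d60B"]), 190)
  expect_error(build_exp1_schedule("teal", seed = 1))
})

test_that("experiment 2 schedules count 792 analysed trials plus dummies", {
  s <- build_exp2_schedule("green", green_blue_boundary = 168.1, seed = 5)
  main <- !s$is_dummy
  expect_equal(sum(main), 792)
  expect_equal(sum(s$is_dummy), 99)
  expect_equal(as.integer(table(s$block[s$is_dummy])), rep(11L, 9))
  tab <- table(s$condition[main], s$comparison_offset_deg[main])
  expect_true(all(tab[tab > 0] == 24))  # 3 block reps x 8 per level
  expect_true(all(abs(s$jitter_deg) <= 5))
  # green group: target 22.5 below the boundary, across-distractor +45
  expect_equal(unique(s$target_mean_deg), 168.1 - 22.5)
  expect_equal(unique(s$distractor_mean_deg[s$condition == "across"]),
               168.1 - 22.5 + 45)
  expect_equal(unique(s$distractor_mean_deg[s$condition == "within"]),
               168.1 - 22.5 - 45)
  b <- build_exp2_schedule("blue", green_blue_boundary = 168.1, seed = 5)
  expect_equal(unique(b$target_mean_deg), 168.1 + 22.5)
  expect_equal(
    signed_diff(unique(b$distractor_mean_deg[b$condition == "across"]),
                unique(b$target_mean_deg)), -45)
  expect_error(build_exp2_schedule("pink", 168, seed = 1))
})

test_that("practice uses only the six outermost levels, 72 trials", {
  p <- build_practice_schedule("exp1", "pink", seed = 3)
  expect_equal(nrow(p), 72)
  expect_true(all(p$is_practice))
  expect_false(any(p$comparison_offset_deg == 0))
  for (cond in unique(p$condition)) {
    off <- p$comparison_offset_deg[p$condition == cond]
    expect_equal(length(off), 18)
    full <- sort(unique(abs(off)))
    expect_equal(length(full), 3)  # three most distant magnitudes per side
    step <- design_constants()$exp1$step[[cond]]
    expect_equal(sort(unique(off)), step * c(-5:-3, 3:5))
  }
  # baseline first, then the 180 block
  expect_equal(unique(p$condition[p$block == 1]), "baseline")
  expect_equal(unique(p$condition[p$block == 2]), "d180")
  p2 <- build_practice_schedule("exp2", "green", seed = 3,
                                green_blue_boundary = 168.1)
  expect_equal(nrow(p2), 72)  # four blocks: 180 practice block included
  expect_setequal(unique(p2$condition),
                  c("baseline", "d180", "across", "within"))
})

test_that("schedules regenerate bit-identically from the same seed", {
  expect_identical(build_exp1_schedule("green", seed = 9),
                   build_exp1_schedule("green", seed = 9))
  expect_identical(build_exp2_schedule("blue", 170, seed = 4),
                   build_exp2_schedule("blue", 170, seed = 4))
  expect_false(identical(build_exp1_schedule("green", seed = 9),
                         build_exp1_schedule("green", seed = 10)))
})

test_that("trial jitter is uniform within its bound", {
  s <- condition_schedule("exp1", "pink", "d60Y", reps_per_level = 910,
                          seed = 1)
  expect_true(all(abs(s$jitter_deg) <= 7.5))
  ks <- stats::ks.test((s$jitter_deg + 7.5) / 15, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("sample_ensemble draws inside the jittered uniform support", {
  set.seed(5)
  expect_equal(sample_ensemble(120, range = 0, n_elements = 18),
               rep(120, 18))
  h <- sample_ensemble(340, range = 30, n_elements = 18, trial_jitter = 5)
  expect_equal(length(h), 18)
  expect_true(all(abs(signed_diff(h, 345)) <= 15))
  big <- sample_ensemble(340, range = 30, n_elements = 1e5)
  expect_lt(abs(signed_diff(circular_mean(big)$mean, 340)), 0.2)
})

test_that("full-integration prediction is the equal-count midpoint", {
  expect_equal(full_integration_bias(60), 30)
  expect_equal(full_integration_bias(45), 22.5)
  expect_equal(full_integration_bias(-60), 30)
  expect_true(is.na(full_integration_bias(180)))
  expect_error(full_integration_bias(0), "undefined")
})

test_that("mixing weight and bias fraction are inverse maps", {
  expect_equal(mixing_bias(0, 60), 0)
  expect_equal(mixing_bias(1, 60), 30)
  expect_equal(mixing_bias(1, 45), 22.5)
  for (f in c(0.1, 0.25, 0.5, 0.9)) {
    w <- mixing_weight_for_fraction(f, 60)
    expect_equal(mixing_bias(w, 60) / full_integration_bias(60), f,
                 tolerance = 1e-9)
  }
  # the weighted vector-sum geometry, not linear averaging: w = 1/3
  expect_equal(mixing_bias(1/3, 60),
               atan2(6 * sin(pi / 3), 18 + 6 * cos(pi / 3)) * 180 / pi,
               tolerance = 1e-12)
})

test_that("schedules round-trip through CSV", {
  s <- build_exp2_schedule("green", 168.1, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_schedule(s, f)
  r <- read_schedule(f)
  expect_equal(as.data.frame(r), as.data.frame(s), tolerance = 1e-12)
  unlink(f)
})
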