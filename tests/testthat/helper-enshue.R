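# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own computational paths.

# Quadrature oracle for von Mises arc probability: adaptive integration of
# the density over the counterclockwise arc from lo to hi.
vm_quad_prob <- function(mu, kappa, lo, hi) {
  w <- (hi - lo) %% 360
  if (w == 0) w <- 360
  dens <- function(t) {
    th <- (lo + t - mu) * pi / 180
    exp(kappa * (cos(th) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) * pi / 180
  }
  stats::integrate(dens, 0, w, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Brute-force weighted circular mean: explicit vector sum in the plane.
vector_sum_mean <- function(angles, weights = rep(1, length(angles))) {
  v <- complex(modulus = weights, argument = angles * pi / 180)
  (Arg(sum(v)) * 180 / pi) %% 360
}

# Toy categorization dataset on a 5-degree grid with two well-separated
# categories; optionally plant isolated responses or a sparse category.
toy_category_data <- function() {
  stim <- seq(0, 355, by = 5)
  counts <- matrix(0L, length(stim), 2,
                   dimnames = list(NULL, c("green", "other")))
  counts[stim >= 80 & stim <= 165, "green"] <- 4L
  counts[stim < 80 | stim > 165, "other"] <- 4L
  category_dataset(stim, counts)
}

# A two-category von Mises observer with the group-average green-blue and
# yellow-green boundaries.
two_cat_model <- function(kappa) {
  category_model(kappa, boundaries = c(78.1, 168.1),
                 centroids = c(123, 303),
                 category_names = c("green", "other"))
}

# Fitted bias fraction of a simulated mixing observer in the exp1
# 60-degree geometry at ~10^4 trials.
recovered_fraction <- function(w, noise_sd = 4, reps = 910, seed = 7) {
  sch <- condition_schedule("exp1", "pink", "d60Y", reps_per_level = reps,
                            seed = seed)
  resp <- simulate_2ifc(sch, observer_params(distractor_weight = w,
                                             internal_noise_sd = noise_sd),
                        seed = seed + 1L)
  ft <- fit_pmf_by_condition(resp)
  ft$bias_fraction[1]
}
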