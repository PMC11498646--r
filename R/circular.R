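# Hue-circle arithmetic and von Mises probability machinery.
#
# All user-facing angles are degrees on the CIELUV LCh hue circle with
# lightness and chroma fixed; radians appear only transiently inside density
# and CDF evaluation.

#' Fixed CIELUV LCh coordinates of the stimulus hue circle
#'
#' All stimuli live on the hue circle at constant lightness and chroma; only
#' the hue angle varies. These constants are metadata: the package never
#' converts to XYZ/RGB.
#' @export
LCH_LIGHTNESS <- 70

#' @rdname LCH_LIGHTNESS
#' @export
LCH_CHROMA <- 70

#' Wrap an angle onto the hue circle
#'
#' Reduces any finite angle in degrees to its representative in `[0, 360)`;
#' 360 maps to 0.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @examples
#' wrap_hue(c(370, -20, 360))
#' @export
wrap_hue <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("'angle' must be finite numeric", call. = FALSE)
  }
  a <- angle %% 360
  a[a >= 360] <- 0  # tiny negatives round up to exactly 360 in doubles
  a
}

#' Signed shortest arc between two hues
#'
#' Returns the signed arc from `b` to `a` in degrees, in `(-180, 180]`.
#' Positive means `a` lies counterclockwise (toward higher hue angle) of `b`.
#' Antipodal pairs return +180 by convention.
#'
#' @param a,b Numeric vectors of hue angles in degrees (recycled).
#' @return Signed degrees in `(-180, 180]`.
#' @examples
#' signed_diff(40, 340)   # +60
#' signed_diff(340, 40)   # -60
#' @export
signed_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Weighted circular mean of hue angles
#'
#' Computes the direction and normalized length of the (weighted) resultant
#' vector. When the resultant length falls below `tol` the mean direction is
#' undefined (antipodal cancellation) and `mean` is `NA` with
#' `undefined = TRUE`: opposing hues admit no meaningful average.
#'
#' @param angles Numeric vector of hue angles in degrees; at least one.
#' @param weights Optional nonnegative weights, same length, not all zero.
#' @param tol Resultant-length tolerance below which the mean is flagged
#'   undefined. Default `1e-8`: only near-exact cancellation is meaningless.
#' @return A list with `mean` (degrees in `[0, 360)` or `NA`),
#'   `resultant_length` (in `[0, 1]`), and `undefined` (logical).
#' @examples
#' circular_mean(c(350, 10))          # mean 0
#' circular_mean(c(10, 20))$mean      # 15
#' @export
circular_mean <- function(angles, weights = NULL, tol = 1e-8) {
  if (length(angles) < 1L) stop("need at least one angle", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles)) {
    stop("'weights' must match 'angles' in length", call. = FALSE)
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("'weights' must be nonnegative and not all zero", call. = FALSE)
  }
  th <- angles * pi / 180
  C <- sum(weights * cos(th))
  S <- sum(weights * sin(th))
  R <- sqrt(C^2 + S^2) / sum(weights)
  if (R < tol) {
    return(list(mean = NA_real_, resultant_length = R, undefined = TRUE))
  }
  list(mean = wrap_hue(atan2(S, C) * 180 / pi),
       resultant_length = R, undefined = FALSE)
}

# Ratios I_j(kappa) / I_0(kappa) for j = 1..jmax via Miller's backward
# recurrence I_{j-1} = I_{j+1} + (2j/kappa) I_j, started well above jmax
# where the function is negligible and normalized at order zero. O(jmax),
# with periodic rescaling to avoid overflow on the way down.
.bessel_ratio <- function(kappa, jmax) {
  start <- jmax + max(20L, ceiling(0.1 * jmax))
  vals <- numeric(start + 1L)  # vals[j + 1] holds order j (unnormalized)
  hi <- 0
  cur <- 1e-30
  for (j in start:1) {
    nxt <- hi + (2 * j / kappa) * cur
    hi <- cur
    cur <- nxt
    if (j <= jmax + 1L) vals[j + 1L] <- hi
    if (cur > 1e250) {
      cur <- cur * 1e-250
      hi <- hi * 1e-250
      vals <- vals * 1e-250
    }
  }
  vals[1L] <- cur
  vals[2:(jmax + 1L)] / vals[1L]
}

# Number of Fourier terms needed for |error| < ~1e-12 in the von Mises CDF
# series; the term ratios decay like exp(-j^2 / (2 kappa)) for large kappa.
# Above .VM_SERIES_KAPPA_MAX the wrapped-normal limit takes over instead.
.VM_SERIES_KAPPA_MAX <- 2e4
.vm_nterms <- function(kappa) {
  max(30L, ceiling(8 * sqrt(max(kappa, 1))))
}

# Wrapped-normal limit of the von Mises arc probability for very large
# kappa (angular sd below ~0.2 deg): mass of N(0, sd) over the arc measured
# from the location, including the adjacent wrap. Error is O(1/kappa),
# negligible against the indicator-like shape at these concentrations.
.vm_arc_prob_largek <- function(mu, kappa, lo, w) {
  sd_deg <- (180 / pi) / sqrt(kappa)
  pos <- (mu - lo) %% 360  # location of mu past the arc start
  p <- stats::pnorm((w - pos) / sd_deg) - stats::pnorm(-pos / sd_deg) +
    stats::pnorm((w - pos + 360) / sd_deg) -
    stats::pnorm((360 - pos) / sd_deg)
  pmin(pmax(p, 0), 1)
}

# Probability mass of the counterclockwise arc from lo to hi under
# von Mises(mu, kappa), vectorized over mu (degrees). Uses the Fourier
# series of the CDF:
#   F(x) - F(lo) = (x - lo)/2pi + (1/pi) sum_j r_j/j [sin(j(x - mu)) -
#                                                     sin(j(lo - mu))]
# with r_j = I_j(kappa)/I_0(kappa); truncation error is far below 1e-9
# at the term counts used.
.vm_arc_prob <- function(mu, kappa, lo, hi) {
  w <- (hi - lo) %% 360
  full <- (w == 0)  # equal endpoints denote the full circle
  w_rad <- w * pi / 180
  if (kappa == 0) {
    p <- rep(w_rad / (2 * pi), length(mu))
    p[full] <- 1
    return(p)
  }
  if (kappa > .VM_SERIES_KAPPA_MAX) {
    p <- .vm_arc_prob_largek(mu, kappa, lo, w)
    p[full] <- 1
    return(p)
  }
  jmax <- .vm_nterms(kappa)
  r <- .bessel_ratio(kappa, jmax)
  j <- seq_len(jmax)
  lo_rad <- (lo - mu) * pi / 180     # arc start, centered on mu
  hi_rad <- lo_rad + w_rad
  # terms: jmax x length(mu)
  s <- (r / j) %*% (sin(outer(j, hi_rad)) - sin(outer(j, lo_rad)))
  p <- w_rad / (2 * pi) + as.vector(s) / pi
  p <- pmin(pmax(p, 0), 1)
  p[full] <- 1
  p
}

#' Probability of a von Mises variate falling on an arc
#'
#' Integrates the von Mises density with location `mu` and concentration
#' `kappa` over the counterclockwise arc from `lo` to `hi`. Equal endpoints
#' denote the full circle (probability 1). `kappa = 0` is the uniform
#' distribution, giving the arc fraction.
#'
#' @param mu Location (mean direction), degrees. May be a vector.
#' @param kappa Concentration, a single nonnegative number.
#' @param lo,hi Arc endpoints in degrees; the arc runs counterclockwise
#'   (toward higher hue angle) from `lo` to `hi`.
#' @return Probabilities in `[0, 1]`, one per element of `mu`.
#' @examples
#' vm_interval_prob(0, 0, 10, 100)     # 0.25: quarter circle, uniform
#' vm_interval_prob(100, 5, 80, 120)
#' @export
vm_interval_prob <- function(mu, kappa, lo, hi) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0) {
    stop("'kappa' must be a single nonnegative finite number", call. = FALSE)
  }
  .vm_arc_prob(mu, kappa, lo, hi)
}

#' Draw from a von Mises distribution on the hue circle
#'
#' Best-Fisher rejection sampling; `kappa = 0` falls back to the circular
#' uniform. Uses the current RNG state.
#'
#' @param n Number of draws.
#' @param mu Location in degrees.
#' @param kappa Concentration, nonnegative.
#' @return `n` hue angles in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 0) stop("'kappa' must be nonnegative", call. = FALSE)
  if (kappa < 1e-10) return(wrap_hue(stats::runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(stats::runif(m) - 0.5) * acos(f)
    keep <- which(ok)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), m))]
      out[(got + 1L):(got + length(take))] <- theta[take]
      got <- got + length(take)
    }
  }
  wrap_hue(mu + out * 180 / pi)
}

# Evaluate code with a private, restorable RNG stream seeded by `seed`.
# Leaves the caller's RNG state untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
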