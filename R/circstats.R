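# Circular statistics for the audiovisual weight index: four-quadrant weight
# angle, circular means and confidence intervals, circular correlation, and
# von Mises likelihood machinery for the LRTS.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Audiovisual weight index
#'
#' Four-quadrant angle of the visual and auditory regression weights,
#' `atan2(beta_V, beta_A) * 180 / pi`. Pure positive visual dominance
#' (`beta_A = 0, beta_V > 0`) gives 90 degrees; pure positive auditory
#' dominance gives 0; a repulsive auditory weight pushes the index above 90.
#'
#' @param beta_V,beta_A Visual and auditory regression weights. Vectorised.
#' @return Weight angle in degrees, in `(-180, 180]`.
#' @export
wav_index <- function(beta_V, beta_A) {
  if (any(beta_V == 0 & beta_A == 0)) {
    stop_("wav_index is undefined when both weights are zero")
  }
  rad2deg(atan2(beta_V, beta_A))
}

#' Circular mean direction
#'
#' @param angles Angles in degrees.
#' @return Mean direction in degrees, in `(-180, 180]`.
#' @export
circ_mean <- function(angles) {
  if (!length(angles)) stop_("empty angle vector")
  a <- deg2rad(angles)
  rad2deg(atan2(mean(sin(a)), mean(cos(a))))
}

# mean resultant length
circ_resultant <- function(angles) {
  a <- deg2rad(angles)
  sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' Circular mean with confidence interval
#'
#' Mean direction and the standard circular confidence-interval half-width
#' (Upton/Zar approximation, the construction used by the CircStat toolbox's
#' `circ_confmean`).
#'
#' @param angles Angles in degrees, nonempty.
#' @param confidence Confidence level as a fraction (default 0.68, the level
#'   plotted for the weight-index figures).
#' @return Named vector `c(mean, half_width)` in degrees.
#' @export
circ_mean_ci <- function(angles, confidence = 0.68) {
  n <- length(angles)
  if (!n) stop_("empty angle vector")
  rbar <- circ_resultant(angles)
  if (rbar < 1e-12) stop_("zero resultant length: CI undefined")
  r <- n * rbar
  c2 <- stats::qchisq(confidence, df = 1)
  t <- if (rbar <= 0.9) {
    if (rbar <= sqrt(c2 / (2 * n))) {
      stop_("resultant too small for a confidence interval at this level")
    }
    sqrt((2 * n * (2 * r^2 - n * c2)) / (4 * n - c2))
  } else {
    sqrt(n^2 - (n^2 - r^2) * exp(c2 / n))
  }
  half <- rad2deg(acos(pmin(pmax(t / r, -1), 1)))
  c(mean = circ_mean(angles), half_width = half)
}

#' Circular-circular correlation coefficient
#'
#' The sine-moment circular correlation for paired angles (Jammalamadaka &
#' SenGupta), as implemented by the CircStat toolbox's `circ_corrcc`:
#' `sum sin(a - abar) sin(b - bbar)` over the product of the sine standard
#' deviations.
#'
#' @param a,b Paired angle vectors in degrees, equal length of at least 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
circ_corr <- function(a, b) {
  if (length(a) != length(b)) stop_("angle vectors must have equal length")
  if (length(a) < 3L) stop_("need at least 3 paired angles")
  sa <- sin(deg2rad(a) - deg2rad(circ_mean(a)))
  sb <- sin(deg2rad(b) - deg2rad(circ_mean(b)))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) stop_("zero angular dispersion: correlation undefined")
  sum(sa * sb) / den
}

# Maximum-likelihood von Mises concentration from a mean resultant length
# (Fisher 1993 approximation).
a1inv <- function(rbar) {
  rbar <- min(rbar, 1 - 1e-10)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

# Maximised von Mises log likelihood with one mean direction per group and
# a common concentration. angles in degrees; groups a factor-like vector.
vm_loglik_groups <- function(angles, groups) {
  a <- deg2rad(angles)
  n <- length(a)
  groups <- as.character(groups)
  rsum <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    rsum <- rsum + sqrt(sum(sin(a[idx]))^2 + sum(cos(a[idx]))^2)
  }
  kappa <- a1inv(rsum / n)
  kappa * rsum - n * (log(2 * pi) + log_bessel_i0(kappa))
}

# Likelihood ratio test statistic for equality of mean directions:
# 2 * (logL with separate group means - logL with one pooled mean), both
# under a common ML concentration. Nonnegative by construction (clipped).
lrts_groups <- function(angles, groups) {
  stat <- 2 * (vm_loglik_groups(angles, groups) -
                 vm_loglik_groups(angles, rep("all", length(angles))))
  max(stat, 0)
}
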