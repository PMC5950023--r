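## Joint continuous-time aortic growth and rupture model.
##
## Growth: log-linear individual trajectories,
##     d(t) = d0 * exp(g * t),
## with the slope g drawn per individual from a population distribution and
## forced to zero below a cutoff diameter (small aortas do not grow).
##
## Rupture: log-linear diameter-dependent hazard,
##     h(d) = exp(intercept + slope * (d - reference)),
## so the cumulative hazard along a growing trajectory is
##     H(t) = int_0^t h(d(s)) ds
##          = exp(c)/g * (Ei(b*d0*e^(g*t)) - Ei(b*d0)),   c = intercept - b*dref,
## an exponential-integral closed form used for fast inverse-transform
## sampling of rupture times.

#' Construct an individual aortic trajectory
#'
#' @param baseline_diameter aortic diameter (cm) at entry; must be > 0.
#' @param log_growth_rate per-year slope on the log-diameter scale.
#' @param zero_growth_cutoff diameters below this (cm) do not grow; the
#'   slope is forced to zero.
#' @return object of class `aorta_trajectory`.
#' @export
aorta_trajectory <- function(baseline_diameter, log_growth_rate,
                             zero_growth_cutoff = 2.0) {
  stopifnot(length(baseline_diameter) == 1, baseline_diameter > 0,
            is.finite(log_growth_rate))
  zero <- baseline_diameter < zero_growth_cutoff
  structure(
    list(baseline_diameter = baseline_diameter,
         log_growth_rate = if (zero) 0 else log_growth_rate,
         zero_growth = zero),
    class = "aorta_trajectory"
  )
}

#' Evaluate a trajectory's true diameter
#'
#' @param traj an [aorta_trajectory()].
#' @param t time(s) in years since entry; must be >= 0.
#' @return diameter(s) in cm.
#' @export
diameter_at_time <- function(traj, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (traj$zero_growth) rep_len(traj$baseline_diameter, length(t))
  else traj$baseline_diameter * exp(traj$log_growth_rate * t)
}

#' First time a trajectory reaches a diameter threshold
#'
#' Closed-form inversion of the log-linear growth curve.  Returns 0 when the
#' baseline already meets the threshold and `Inf` ("never") when the
#' trajectory cannot reach it (zero or negative growth below threshold).
#'
#' @param traj an [aorta_trajectory()].
#' @param threshold diameter in cm, > 0.
#' @return years, or `Inf`.
#' @export
time_to_threshold <- function(traj, threshold) {
  stopifnot(threshold > 0)
  if (traj$baseline_diameter >= threshold) return(0)
  g <- traj$log_growth_rate
  if (traj$zero_growth || g <= 0) return(Inf)
  (log(threshold) - log(traj$baseline_diameter)) / g
}

#' Rupture hazard parameters
#'
#' @param intercept log-hazard (per year) at the reference diameter.
#' @param slope per-cm increase in log-hazard.
#' @param reference_diameter reference diameter in cm.
#' @return object of class `rupture_hazard_params`.
#' @export
rupture_hazard_params <- function(intercept, slope, reference_diameter = 5.5) {
  stopifnot(is.finite(intercept), is.finite(slope), reference_diameter > 0)
  structure(list(intercept = intercept, slope = slope,
                 reference_diameter = reference_diameter),
            class = "rupture_hazard_params")
}

#' Rupture hazard at a given diameter
#'
#' @param hz a [rupture_hazard_params()].
#' @param d diameter(s) in cm.
#' @return hazard(s), per year; always > 0.
#' @export
rupture_hazard <- function(hz, d) {
  exp(hz$intercept + hz$slope * (d - hz$reference_diameter))
}

## Exponential integral Ei(x) for x > 0.  Power series below 40, asymptotic
## expansion above; relative accuracy ~1e-15 over the range used here.
## (pracma::expint_Ei returns complex values off the positive axis and is an
## order of magnitude slower; this scalar path sits in the sampler's hot
## loop.  Cross-checked against pracma in the test suite.)
.ei <- function(x) {
  if (x <= 0) stop(".ei requires x > 0")
  if (x > 709) return(Inf)
  if (x < 40) {
    s <- 0
    term <- 1
    for (k in 1:120) {
      term <- term * x / k
      s <- s + term / k
      if (term / k < 1e-17 * abs(s) && k > x) break
    }
    0.5772156649015329 + log(x) + s
  } else {
    s <- 1
    term <- 1
    for (k in 1:40) {
      term <- term * k / x
      s <- s + term
    }
    exp(x) / x * s
  }
}

#' Cumulative rupture hazard along a trajectory
#'
#' \eqn{H(t) = \int_0^t h(d(s)) ds}.  Evaluated in closed form: constant
#' hazard for flat trajectories or zero slope, otherwise via the exponential
#' integral.  A numerical-quadrature fallback covers negative hazard slopes.
#'
#' @param traj an [aorta_trajectory()].
#' @param hz a [rupture_hazard_params()].
#' @param t time(s) in years, >= 0.
#' @return cumulative hazard(s).
#' @export
cumulative_rupture_hazard <- function(traj, hz, t) {
  if (any(t < 0)) stop("t must be >= 0")
  g <- traj$log_growth_rate
  b <- hz$slope
  d0 <- traj$baseline_diameter
  if (traj$zero_growth || g == 0 || b == 0) {
    ## flat trajectory or diameter-free hazard: constant rate
    return(rupture_hazard(hz, d0) * t)
  }
  if (b > 0) {
    cc <- exp(hz$intercept - b * hz$reference_diameter) / g
    x0 <- b * d0
    ei0 <- .ei(x0)
    vapply(t, function(ti) {
      if (ti == 0) return(0)
      xt <- x0 * exp(g * ti)
      if (xt > 709) return(Inf)
      cc * (.ei(xt) - ei0)
    }, numeric(1))
  } else {
    ## negative slope: hazard decreasing in diameter; rare, integrate numerically
    hfun <- function(s) rupture_hazard(hz, diameter_at_time(traj, s))
    vapply(t, function(ti) {
      if (ti == 0) return(0)
      stats::integrate(hfun, 0, ti, rel.tol = 1e-12, abs.tol = 1e-14)$value
    }, numeric(1))
  }
}

#' Sample a rupture time by inverse transform
#'
#' Solves \eqn{H(t) = -\log u} for t.  When even the capped horizon cannot
#' accumulate that much hazard the rupture is "so far in the future that
#' there is no chance" of it occurring and `Inf` is returned.
#'
#' @param traj an [aorta_trajectory()].
#' @param hz a [rupture_hazard_params()].
#' @param u a Uniform(0,1) draw, strictly inside (0, 1).
#' @param cap_years horizon cap in years (default 85, i.e. age 150 for entry
#'   at 65).
#' @return rupture time in years, or `Inf` ("never").
#' @export
sample_rupture_time <- function(traj, hz, u, cap_years = 85) {
  if (!is.finite(u) || u <= 0 || u >= 1) stop("u must lie strictly in (0, 1)")
  target <- -log(u)
  g <- traj$log_growth_rate
  b <- hz$slope
  if (traj$zero_growth || g == 0 || b == 0) {
    lam <- exp(hz$intercept + hz$slope * (traj$baseline_diameter - hz$reference_diameter))
    t <- target / lam
    return(if (t > cap_years) Inf else t)
  }
  Hcap <- cumulative_rupture_hazard(traj, hz, cap_years)
  if (Hcap < target) return(Inf)
  f <- function(ti) {
    h <- cumulative_rupture_hazard(traj, hz, ti)
    if (is.infinite(h)) h <- 1e300
    h - target
  }
  stats::uniroot(f, c(0, cap_years), tol = 1e-9)$root
}

#' Scan measurement-error model
#'
#' @param ultrasound_sd SD (cm) of ultrasound measurement error.
#' @param ct_sd SD (cm) of CT measurement error.
#' @param ct_offset mean additive difference (cm) of CT over ultrasound
#'   (outer-to-outer vs inner-to-inner diameters).
#' @return object of class `measurement_model`.
#' @export
measurement_model <- function(ultrasound_sd = 0.2, ct_sd = 0.2, ct_offset = 0.24) {
  stopifnot(ultrasound_sd >= 0, ct_sd >= 0)
  structure(list(ultrasound_sd = ultrasound_sd, ct_sd = ct_sd,
                 ct_offset = ct_offset),
            class = "measurement_model")
}

#' Generate a scan measurement of a true diameter
#'
#' A fresh, independent error is drawn per call (measurement error is an
#' event-specific parameter).  CT scans add the systematic offset.
#' Measurements are truncated below at zero.
#'
#' @param true_d true diameter(s), cm, >= 0.
#' @param modality `"ultrasound"` or `"ct"`.
#' @param mm a [measurement_model()].
#' @return measured diameter(s), cm.
#' @export
measure_diameter <- function(true_d, modality = c("ultrasound", "ct"), mm) {
  stopifnot(all(true_d >= 0))
  modality <- match.arg(modality)
  n <- length(true_d)
  m <- if (modality == "ct")
    true_d + mm$ct_offset + stats::rnorm(n, 0, mm$ct_sd)
  else
    true_d + stats::rnorm(n, 0, mm$ultrasound_sd)
  pmax(m, 0)
}
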