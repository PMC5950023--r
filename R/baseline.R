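## Baseline aortic-diameter population distributions.
##
## Two families:
##   lognormal    -- plain lognormal(meanlog, sdlog).
##   aaa_mixture  -- with probability `prevalence` the diameter is aneurysmal,
##                   `aaa_from + Gamma(excess_shape, excess_rate)` cm;
##                   otherwise it follows the lognormal body truncated below
##                   `aaa_from`.  A single lognormal cannot reproduce both a
##                   screening prevalence of a few percent and the observed
##                   spread of detected AAAs over the 3.0-4.4 / 4.5-5.4 /
##                   >= 5.5 cm categories; the mixture makes the prevalence an
##                   explicit, exact parameter.
##
## Both families expose a CDF and quantile function, which is what the
## engine needs: baselines are drawn by inverse transform so that stratified
## oversampling is an exact tail mapping of a single uniform.

.validate_baseline_spec <- function(spec) {
  if (!is.list(spec) || is.null(spec$family))
    stop("baseline_diameter must be a distribution spec")
  if (spec$family == "lognormal") {
    if (is.null(spec$meanlog) || is.null(spec$sdlog) || spec$sdlog < 0)
      stop("baseline_diameter lognormal needs meanlog and sdlog >= 0")
  } else if (spec$family == "aaa_mixture") {
    need <- c("prevalence", "meanlog", "sdlog", "aaa_from",
              "excess_shape", "excess_rate")
    missing <- setdiff(need, names(spec))
    if (length(missing))
      stop("baseline_diameter aaa_mixture: missing ",
           paste(missing, collapse = ", "))
    if (spec$prevalence <= 0 || spec$prevalence >= 1)
      stop("baseline_diameter prevalence must lie in (0, 1)")
    if (spec$sdlog < 0 || spec$aaa_from <= 0 ||
        spec$excess_shape <= 0 || spec$excess_rate <= 0)
      stop("baseline_diameter aaa_mixture parameters out of support")
  } else {
    stop("baseline_diameter family must be 'lognormal' or 'aaa_mixture'")
  }
  invisible(spec)
}

.baseline_cdf <- function(spec, x) {
  if (spec$family == "lognormal")
    return(stats::plnorm(x, spec$meanlog, spec$sdlog))
  p <- spec$prevalence
  body <- stats::plnorm(pmin(x, spec$aaa_from), spec$meanlog, spec$sdlog) /
    stats::plnorm(spec$aaa_from, spec$meanlog, spec$sdlog)
  tail <- ifelse(x < spec$aaa_from, 0,
                 stats::pgamma(x - spec$aaa_from, spec$excess_shape,
                               spec$excess_rate))
  (1 - p) * body + p * tail
}

.baseline_quantile <- function(spec, u) {
  if (spec$family == "lognormal")
    return(stats::qlnorm(u, spec$meanlog, spec$sdlog))
  p <- spec$prevalence
  Fknot <- stats::plnorm(spec$aaa_from, spec$meanlog, spec$sdlog)
  ifelse(u < 1 - p,
         stats::qlnorm(u / (1 - p) * Fknot, spec$meanlog, spec$sdlog),
         spec$aaa_from + stats::qgamma((u - (1 - p)) / p, spec$excess_shape,
                                       spec$excess_rate))
}
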