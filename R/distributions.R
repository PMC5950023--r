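## Distribution specifications for global uncertain parameters.
##
## A spec is a named list with a `family` element and the family's
## parameters.  Supported families:
##   beta(shape1, shape2)         -- probabilities
##   normal(mean, sd)
##   lognormal(meanlog, sdlog)
##   gamma(shape, rate)
##   fixed(value)                 -- point mass (no uncertainty)
##   dirichlet(alpha)             -- vector of proportions summing to 1

.dist_families <- c("beta", "normal", "lognormal", "gamma", "fixed", "dirichlet")

.dist_required <- list(
  beta      = c("shape1", "shape2"),
  normal    = c("mean", "sd"),
  lognormal = c("meanlog", "sdlog"),
  gamma     = c("shape", "rate"),
  fixed     = "value",
  dirichlet = "alpha"
)

#' Validate a distribution specification
#'
#' Checks that a specification names a known family, carries the family's
#' parameters, and that those parameters are admissible.  When
#' `probability = TRUE` the spec must additionally have support within
#' \[0, 1\] (beta, or a fixed value in \[0, 1\], or dirichlet).
#'
#' @param spec named list with a `family` element plus family parameters.
#' @param name parameter name, used in error messages.
#' @param probability logical; require support within \[0, 1\]?
#' @return the spec, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_dist_spec <- function(spec, name = "<spec>", probability = FALSE) {
  if (!is.list(spec) || is.null(spec$family))
    stop("parameter '", name, "': distribution spec must be a list with a 'family'")
  fam <- spec$family
  if (!fam %in% .dist_families)
    stop("parameter '", name, "': unknown family '", fam, "' (known: ",
         paste(.dist_families, collapse = ", "), ")")
  req <- .dist_required[[fam]]
  missing <- setdiff(req, names(spec))
  if (length(missing))
    stop("parameter '", name, "' (", fam, "): missing ", paste(missing, collapse = ", "))
  p <- spec[req]
  if (!all(vapply(p, is.numeric, logical(1))))
    stop("parameter '", name, "': non-numeric distribution parameters")
  ok <- switch(fam,
    beta      = spec$shape1 > 0 && spec$shape2 > 0,
    normal    = spec$sd >= 0,
    lognormal = spec$sdlog >= 0,
    gamma     = spec$shape > 0 && spec$rate > 0,
    fixed     = is.finite(spec$value),
    dirichlet = length(spec$alpha) >= 2 && all(spec$alpha > 0)
  )
  if (!ok)
    stop("parameter '", name, "': invalid ", fam, " parameters (out of support)")
  if (probability) {
    in01 <- switch(fam,
      beta      = TRUE,
      dirichlet = TRUE,
      fixed     = spec$value >= 0 && spec$value <= 1,
      FALSE
    )
    if (!in01)
      stop("parameter '", name, "' is probability-valued; its spec must have ",
           "support within [0, 1] (got family '", fam, "')")
  }
  invisible(spec)
}

## One realization from a spec, using the current RNG stream.
.dist_draw <- function(spec) {
  switch(spec$family,
    beta      = stats::rbeta(1, spec$shape1, spec$shape2),
    normal    = stats::rnorm(1, spec$mean, spec$sd),
    lognormal = stats::rlnorm(1, spec$meanlog, spec$sdlog),
    gamma     = stats::rgamma(1, shape = spec$shape, rate = spec$rate),
    fixed     = spec$value,
    dirichlet = { g <- stats::rgamma(length(spec$alpha), shape = spec$alpha); g / sum(g) }
  )
}

## Analytic mean of a spec.
.dist_mean <- function(spec) {
  switch(spec$family,
    beta      = spec$shape1 / (spec$shape1 + spec$shape2),
    normal    = spec$mean,
    lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
    gamma     = spec$shape / spec$rate,
    fixed     = spec$value,
    dirichlet = spec$alpha / sum(spec$alpha)
  )
}

## Analytic variance (scalar families; used in property tests).
.dist_var <- function(spec) {
  switch(spec$family,
    beta      = {
      a <- spec$shape1; b <- spec$shape2
      a * b / ((a + b)^2 * (a + b + 1))
    },
    normal    = spec$sd^2,
    lognormal = (exp(spec$sdlog^2) - 1) * exp(2 * spec$meanlog + spec$sdlog^2),
    gamma     = spec$shape / spec$rate^2,
    fixed     = 0,
    dirichlet = {
      a0 <- sum(spec$alpha)
      spec$alpha * (a0 - spec$alpha) / (a0^2 * (a0 + 1))
    }
  )
}
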