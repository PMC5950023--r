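## Parameter bundles: the hierarchical parameter model.
##
## A bundle has three blocks:
##   global_fixed     -- scalars, vectors and small tables known (or treated as)
##                       certain: waiting times, CT offset, discount rates,
##                       life table, costs, policy name, time horizon, ...
##   global_uncertain -- distribution specs for parameters carrying
##                       second-order uncertainty; realized once per PSA
##                       iteration by draw_global_uncertain().
##   metadata         -- bundle name and per-parameter provenance notes.
##
## Times are stored in the units the source literature uses (waiting times in
## days, everything else in years); the engine converts days to years at
## 365.25 d/y when it builds its simulation context.

DAYS_PER_YEAR <- 365.25

.fixed_keys <- c(
  "invitation_age", "time_horizon_years", "censoring",
  "discount_rate_cost", "discount_rate_effect",
  "wait_discovery_to_consultation_days", "wait_consultation_to_surgery_days",
  "ct_offset_cm", "ultrasound_sd_cm", "ct_sd_cm",
  "zero_growth_cutoff_cm", "baseline_diameter", "growth_rate",
  "rupture_hazard", "incidental_detection_rate",
  "oversampling_multiplier", "policy", "life_table", "utilities", "costs"
)

.uncertain_keys <- c(
  "attendance_prob", "dropout_prob", "contraindication_prob",
  "elective_mortality_open", "elective_mortality_evar",
  "emergency_mortality", "emergency_surgery_prob", "evar_proportion"
)

## All eight mandatory uncertain parameters are probabilities.
.probability_params <- .uncertain_keys

.cost_keys <- c("invitation", "scan", "consultation", "elective_open",
                "elective_evar", "emergency_open", "emergency_evar")

#' Construct and validate a parameter bundle
#'
#' @param global_fixed named list of fixed parameters (see the packaged
#'   fixture bundles for the full schema).
#' @param global_uncertain named list of distribution specs, one per
#'   uncertain parameter.  Unit costs may additionally be declared uncertain
#'   by adding a spec named `cost_<item>` (e.g. `cost_scan`), which then
#'   overrides the fixed cost at draw time.
#' @param metadata named list; at least `name`.
#' @return an object of class `aaa_bundle`.
#' @seealso [load_bundle()], [builtin_bundle()]
#' @export
aaa_bundle <- function(global_fixed, global_uncertain, metadata = list(name = "unnamed")) {
  b <- structure(
    list(global_fixed = global_fixed,
         global_uncertain = global_uncertain,
         metadata = metadata),
    class = "aaa_bundle"
  )
  validate_bundle(b)
  b
}

#' Validate a parameter bundle
#'
#' Checks mandatory parameter names, rejects unknown keys (naming them),
#' validates every distribution spec (probability-valued parameters must
#' have support within \[0, 1\]), and checks sign/ordering constraints:
#' discount rates and waiting times non-negative, time horizon positive,
#' costs non-negative, life-table rates non-negative, utilities in \[0, 1\].
#'
#' @param bundle an `aaa_bundle` (or bare list with the same structure).
#' @return the bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  gf <- bundle$global_fixed
  gu <- bundle$global_uncertain
  if (is.null(gf) || is.null(gu))
    stop("bundle must have 'global_fixed' and 'global_uncertain' blocks")

  missing <- setdiff(.fixed_keys, names(gf))
  if (length(missing))
    stop("missing global_fixed parameter(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(gf), .fixed_keys)
  if (length(unknown))
    stop("unknown global_fixed key(s): ", paste(unknown, collapse = ", "))

  missing <- setdiff(.uncertain_keys, names(gu))
  if (length(missing))
    stop("missing global_uncertain parameter(s): ", paste(missing, collapse = ", "))
  allowed_extra <- paste0("cost_", .cost_keys)
  unknown <- setdiff(names(gu), c(.uncertain_keys, allowed_extra))
  if (length(unknown))
    stop("unknown global_uncertain key(s): ", paste(unknown, collapse = ", "))

  for (nm in names(gu))
    validate_dist_spec(gu[[nm]], nm, probability = nm %in% .probability_params)

  stopifnot_named <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  stopifnot_named(gf$time_horizon_years > 0, "time_horizon_years must be > 0")
  stopifnot_named(gf$discount_rate_cost >= 0 && gf$discount_rate_effect >= 0,
                  "discount rates must be >= 0")
  stopifnot_named(gf$wait_discovery_to_consultation_days >= 0 &&
                  gf$wait_consultation_to_surgery_days >= 0,
                  "waiting times must be >= 0")
  stopifnot_named(gf$ultrasound_sd_cm >= 0 && gf$ct_sd_cm >= 0,
                  "measurement error SDs must be >= 0")

  .validate_baseline_spec(gf$baseline_diameter)
  gr <- gf$growth_rate
  if (!is.list(gr) || !all(c("band_from", "mean", "sd") %in% names(gr)))
    stop("growth_rate must have band_from, mean and sd")
  gb <- as.numeric(unlist(gr$band_from))
  if (length(gb) != length(unlist(gr$mean)) ||
      length(gb) != length(unlist(gr$sd)) ||
      is.unsorted(gb, strictly = TRUE) || any(unlist(gr$sd) < 0))
    stop("growth_rate bands must be strictly increasing with one mean and one sd >= 0 each")
  hz <- gf$rupture_hazard
  if (!is.list(hz) || !all(c("intercept", "slope", "reference_cm") %in% names(hz)))
    stop("rupture_hazard must have intercept, slope and reference_cm")

  cen <- gf$censoring
  if (!is.list(cen) || !cen$type %in% c("fixed", "uniform"))
    stop("censoring$type must be 'fixed' or 'uniform'")
  if (cen$type == "uniform" &&
      (is.null(cen$min) || is.null(cen$max) || cen$min > cen$max || cen$min < 0))
    stop("uniform censoring needs 0 <= min <= max")

  lt <- gf$life_table
  if (!is.list(lt) || is.null(lt$start_age) || is.null(lt$rates) ||
      any(unlist(lt$rates) < 0))
    stop("life_table must have start_age and non-negative rates")

  ut <- gf$utilities
  if (!is.list(ut) || length(ut$age_from) != length(ut$weight) ||
      is.unsorted(unlist(ut$age_from), strictly = TRUE) ||
      any(unlist(ut$weight) < 0) || any(unlist(ut$weight) > 1))
    stop("utilities must map strictly increasing age_from to weights in [0, 1]")

  co <- gf$costs
  missing <- setdiff(.cost_keys, names(co))
  if (length(missing))
    stop("missing cost(s): ", paste(missing, collapse = ", "))
  if (any(unlist(co) < 0)) stop("unit costs must be >= 0")

  if (gf$oversampling_multiplier < 1)
    stop("oversampling_multiplier must be >= 1")
  if (gf$incidental_detection_rate < 0)
    stop("incidental_detection_rate must be >= 0")

  invisible(bundle)
}

#' Read a parameter bundle from a YAML file
#'
#' @param path path to a bundle file.
#' @return a validated `aaa_bundle`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  raw <- yaml::read_yaml(path)
  aaa_bundle(raw$global_fixed, raw$global_uncertain,
             if (is.null(raw$metadata)) list(name = basename(path)) else raw$metadata)
}

#' Write a parameter bundle to a YAML file
#'
#' The file round-trips: `load_bundle(write_bundle(b, f))` reproduces `b`.
#'
#' @param bundle an `aaa_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  yaml::write_yaml(unclass(bundle), path, precision = 15)
  invisible(path)
}

#' Load one of the packaged fixture bundles
#'
#' Two documented configurations ship with the package:
#' \describe{
#'   \item{`mass-validation`}{trial-era configuration for 4-y validation runs:
#'     Uniform(3, 5.25) censoring, life-years discounted at 1.5%/y and costs
#'     at 6%/y, no EVAR.}
#'   \item{`naaasp-basecase`}{contemporary 30-y base case: 1.6% AAA
#'     prevalence, both discount rates 3.5%/y, EVAR available,
#'     population-norm utility weights.}
#' }
#' Parameter values not given in the primary literature are documented
#' approximations; each carries a provenance note in the bundle metadata.
#'
#' @param name `"mass-validation"` or `"naaasp-basecase"`.
#' @return an `aaa_bundle`.
#' @export
builtin_bundle <- function(name = c("mass-validation", "naaasp-basecase")) {
  name <- match.arg(name)
  load_bundle(system.file("extdata", paste0(name, ".yaml"),
                          package = "aaades", mustWork = TRUE))
}

#' Realize the global uncertain parameters
#'
#' Draws one value per uncertain spec.  Reproducible: the same seed and
#' bundle always give the same draw, and the caller's RNG state is left
#' untouched.  The returned draw is treated as read-only by all engine-level
#' code (the parameter hierarchy is strictly layered).
#'
#' @param bundle an `aaa_bundle`.
#' @param seed integer seed.
#' @param draw_index optional index recorded on the draw (PSA iteration).
#' @return named list of realized values, class `aaa_draw`, with attributes
#'   `seed` and `draw_index`.
#' @export
draw_global_uncertain <- function(bundle, seed, draw_index = 1L) {
  validate_bundle(bundle)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  specs <- bundle$global_uncertain[order(names(bundle$global_uncertain))]
  vals <- lapply(specs, .dist_draw)
  structure(vals, class = "aaa_draw", seed = seed, draw_index = draw_index)
}

#' Fix every uncertain parameter at its distribution mean
#'
#' Deterministic base-case runs use the means of the uncertain-parameter
#' distributions in place of random draws.
#'
#' @param bundle an `aaa_bundle`.
#' @return named list of means, class `aaa_draw`.
#' @export
fix_bundle_at_means <- function(bundle) {
  validate_bundle(bundle)
  specs <- bundle$global_uncertain[order(names(bundle$global_uncertain))]
  structure(lapply(specs, .dist_mean),
            class = "aaa_draw", seed = NA_integer_, draw_index = 0L)
}

## Fixed costs overridden by any cost_* entries realized in the draw.
.resolve_costs <- function(bundle, draw) {
  co <- bundle$global_fixed$costs
  for (k in .cost_keys) {
    nm <- paste0("cost_", k)
    if (!is.null(draw[[nm]])) co[[k]] <- draw[[nm]]
  }
  co
}

#' @export
print.aaa_bundle <- function(x, ...) {
  cat("<aaa_bundle>", x$metadata$name, "\n")
  cat("  policy:", x$global_fixed$policy,
      " horizon:", x$global_fixed$time_horizon_years, "y\n")
  cat("  discounting: costs", x$global_fixed$discount_rate_cost,
      "/y, effects", x$global_fixed$discount_rate_effect, "/y\n")
  cat("  uncertain parameters:", paste(names(x$global_uncertain), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.aaa_draw <- function(x, ...) {
  cat("<aaa_draw> seed:", attr(x, "seed"), "\n")
  print(unlist(x))
  invisible(x)
}
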