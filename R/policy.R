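## Surveillance policies as declarative partitions of the diameter axis.
##
## A policy is an ordered list of band lower edges with a rescan interval per
## band, plus a diagnosis threshold (smallest diameter entering surveillance,
## equal to the first band edge) and a referral threshold (measured diameter
## triggering a surgical consultation).  Bands are half-open [a, b): the
## published inclusive labels ("3.0 to 4.4 cm") sit on a continuous diameter
## scale, and half-open edges at the next cut-point make the bands
## exhaustive and disjoint.  Changing a programme is a matter of editing the
## two lists: e.g. inserting 2.5 into the thresholds and 5 (years) into the
## intervals extends surveillance to sub-aneurysmal aortas.

#' Construct a surveillance policy
#'
#' @param surveillance_thresholds strictly increasing band lower edges (cm);
#'   the first is the diagnosis threshold.
#' @param surveillance_intervals rescan interval (years) per band; same
#'   length as `surveillance_thresholds`, all > 0.
#' @param referral_threshold measured diameter (cm) triggering referral to a
#'   surgical consultation; must exceed the last band's lower edge.
#' @param invitation_age age (years) at the one-off screening invitation.
#' @param name label for reports.
#' @return object of class `policy_spec`.
#' @export
policy_spec <- function(surveillance_thresholds, surveillance_intervals,
                        referral_threshold = 5.5, invitation_age = 65,
                        name = "custom") {
  thr <- as.numeric(surveillance_thresholds)
  ivs <- as.numeric(surveillance_intervals)
  if (length(thr) < 1 || length(thr) != length(ivs))
    stop("need one interval per surveillance threshold")
  if (is.unsorted(thr, strictly = TRUE))
    stop("surveillance thresholds must be strictly increasing")
  if (any(ivs <= 0)) stop("surveillance intervals must be > 0")
  if (referral_threshold <= thr[length(thr)])
    stop("referral_threshold must exceed the last surveillance threshold")
  if (any(thr <= 0)) stop("thresholds must be > 0")
  structure(
    list(surveillance_thresholds = thr,
         surveillance_intervals = ivs,
         diagnosis_threshold = thr[1],
         referral_threshold = referral_threshold,
         invitation_age = invitation_age,
         name = name),
    class = "policy_spec"
  )
}

#' Built-in screening policies
#'
#' \describe{
#'   \item{`current`}{the NAAASP programme: 1-y rescans for 3.0–4.4 cm,
#'     3-mo rescans for 4.5–5.4 cm, referral at 5.5 cm.}
#'   \item{`scenario1`}{lengthened small-AAA interval: 2-y (3.0–3.9 cm),
#'     1-y (4.0–4.4 cm), 3-mo (4.5–5.4 cm).}
#'   \item{`scenario2`}{sub-aneurysmal extension: diagnosis lowered to
#'     2.5 cm with 5-y rescans for 2.5–2.9 cm; NAAASP intervals above 3.0 cm.}
#' }
#'
#' @param name one of `"current"`, `"scenario1"`, `"scenario2"`.
#' @return a [policy_spec()].
#' @export
builtin_policy <- function(name) {
  known <- c("current", "scenario1", "scenario2")
  if (length(name) != 1 || !name %in% known)
    stop("unknown policy '", name, "'; valid names: ",
         paste(known, collapse = ", "))
  switch(name,
    current   = policy_spec(c(3.0, 4.5), c(1, 0.25), 5.5, name = "current"),
    scenario1 = policy_spec(c(3.0, 4.0, 4.5), c(2, 1, 0.25), 5.5, name = "scenario1"),
    scenario2 = policy_spec(c(2.5, 3.0, 4.5), c(5, 1, 0.25), 5.5, name = "scenario2")
  )
}

#' Classify a measured diameter under a policy
#'
#' Total and deterministic: below the diagnosis threshold the individual is
#' discharged; at or above the referral threshold they are referred; in
#' between, the half-open surveillance band containing the measurement fixes
#' the rescan interval.
#'
#' @param policy a [policy_spec()].
#' @param measured_d measured diameter (cm), >= 0; scalar.
#' @return list with `action` (`"discharge"`, `"rescan"` or `"refer"`) and
#'   `interval` (years; `NA` unless rescanning).
#' @export
classify_measurement <- function(policy, measured_d) {
  stopifnot(length(measured_d) == 1, measured_d >= 0)
  if (measured_d < policy$diagnosis_threshold)
    return(list(action = "discharge", interval = NA_real_))
  if (measured_d >= policy$referral_threshold)
    return(list(action = "refer", interval = NA_real_))
  band <- findInterval(measured_d, policy$surveillance_thresholds)
  list(action = "rescan", interval = policy$surveillance_intervals[band])
}

#' @export
print.policy_spec <- function(x, ...) {
  cat("<policy_spec>", x$name, "\n")
  hi <- c(x$surveillance_thresholds[-1], x$referral_threshold)
  for (i in seq_along(x$surveillance_thresholds))
    cat(sprintf("  [%.2f, %.2f) cm : rescan every %g y\n",
                x$surveillance_thresholds[i], hi[i], x$surveillance_intervals[i]))
  cat(sprintf("  >= %.2f cm : refer;  < %.2f cm : discharge\n",
              x$referral_threshold, x$diagnosis_threshold))
  invisible(x)
}
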