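## Event-time accrual of costs, life-years and QALYs, and incremental
## cost-effectiveness summaries.
##
## Discounting uses the annually-compounded factor evaluated at continuous
## event times, (1 + r)^(-t): the simulation has no cycles, so costs are
## discounted at the instant they occur and person-time is discounted by
## exact integration -- no half-cycle corrections are needed or applied.

#' Discount factor at a continuous time
#'
#' @param t time(s) in years, >= 0.
#' @param rate annual discount rate, >= 0.
#' @return \eqn{(1+rate)^{-t}}.
#' @export
discount_factor <- function(t, rate) {
  stopifnot(all(t >= 0), rate >= 0)
  (1 + rate)^(-t)
}

#' Discounted person-time over an interval
#'
#' Closed form of \eqn{\int_{t_0}^{t_1}(1+r)^{-s}\,ds}; reduces to
#' \eqn{t_1-t_0} when the rate is zero.
#'
#' @param t0,t1 interval bounds in years, `0 <= t0 <= t1`; vectorized.
#' @param rate annual discount rate, >= 0.
#' @return discounted years.
#' @export
discounted_person_time <- function(t0, t1, rate) {
  stopifnot(all(t0 >= 0), all(t1 >= t0), rate >= 0)
  .dpt(t0, t1, rate)
}

#' Unit-cost schedule
#'
#' @param invitation,scan,consultation,elective_open,elective_evar,emergency_open,emergency_evar
#'   non-negative unit costs attached to event occurrences.
#' @return named list of class `cost_schedule`.
#' @export
cost_schedule <- function(invitation, scan, consultation, elective_open,
                          elective_evar, emergency_open, emergency_evar) {
  co <- list(invitation = invitation, scan = scan, consultation = consultation,
             elective_open = elective_open, elective_evar = elective_evar,
             emergency_open = emergency_open, emergency_evar = emergency_evar)
  if (any(unlist(co) < 0)) stop("unit costs must be >= 0")
  structure(co, class = "cost_schedule")
}

#' Accrue discounted cost, life-years and QALYs for one event history
#'
#' Cost is the sum of event unit costs discounted at their occurrence times;
#' life-years are the discounted person-time from entry to death or censor;
#' QALYs weight each integer-age segment of that person-time by the
#' age-specific population-norm utility.
#'
#' @param record an `aaa_record` from [simulate_individual()].
#' @param costs a [cost_schedule()] or equivalent named list.
#' @param utilities list with `age_from` (increasing ages) and `weight`
#'   (utilities in \[0, 1\]) defining a piecewise-constant age profile.
#' @param rates list with `cost` and `effect` annual discount rates.
#' @param entry_age age in years at simulation entry.
#' @return named numeric: `cost`, `life_years`, `qalys`.
#' @export
accrue <- function(record, costs, utilities, rates, entry_age = 65) {
  ev <- record$events
  kinds <- match(ev$kind, .ev_names)
  evar <- isTRUE(record$gets_evar)
  cv <- numeric(12)
  cv[.EV_CON] <- costs$consultation
  cv[c(.EV_SUR, .EV_SCR)] <- costs$scan
  cv[.EV_INV] <- costs$invitation
  cv[.EV_ELE] <- if (evar) costs$elective_evar else costs$elective_open
  cv[.EV_EME] <- if (evar) costs$emergency_evar else costs$emergency_open
  cost <- sum(cv[kinds] * discount_factor(ev$time, rates$cost))

  tend <- record$death_time
  ly <- .dpt(0, tend, rates$effect)

  age_from <- as.numeric(unlist(utilities$age_from))
  w <- as.numeric(unlist(utilities$weight))
  if (tend <= 0) {
    qaly <- 0
  } else {
    k <- ceiling(tend)
    t0 <- seq_len(k) - 1
    t1 <- pmin(seq_len(k), tend)
    wy <- w[pmax(findInterval(entry_age + t0, age_from), 1L)]
    qaly <- sum(wy * .dpt(t0, t1, rates$effect))
  }
  c(cost = cost, life_years = ly, qalys = qaly)
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies the incremental pair on the cost-effectiveness plane:
#' positive cost and effect give the ratio; non-positive cost with
#' non-negative effect (not both zero) is *dominant*; negative effect with
#' non-negative cost is *dominated* (reported as an infinite ICER in PSA
#' summaries); both negative is the south-west quadrant, where the ratio is
#' returned but flagged since a smaller ratio is then preferable.
#'
#' @param delta_cost incremental cost.
#' @param delta_effect incremental effect (QALYs or life-years).
#' @return list of class `icer` with `value` and `classification`
#'   (`"ratio"`, `"dominant"`, `"dominated"`, `"south_west"`, `"undefined"`).
#' @export
icer <- function(delta_cost, delta_effect) {
  cls <- if (delta_cost == 0 && delta_effect == 0) "undefined"
  else if (delta_effect >= 0 && delta_cost <= 0) "dominant"
  else if (delta_effect < 0 && delta_cost >= 0) "dominated"
  else if (delta_effect < 0 && delta_cost < 0) "south_west"
  else "ratio"
  value <- switch(cls,
    undefined = NaN,
    dominant = if (delta_effect > 0) delta_cost / delta_effect else -Inf,
    dominated = Inf,
    south_west = delta_cost / delta_effect,
    ratio = delta_cost / delta_effect
  )
  structure(list(value = value, classification = cls), class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (x$classification == "ratio")
    cat(sprintf("ICER: %.2f per unit effect\n", x$value))
  else
    cat("ICER:", x$classification,
        if (is.finite(x$value)) sprintf("(ratio %.2f)", x$value) else "", "\n")
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' @param delta_cost incremental cost.
#' @param delta_effect incremental effect.
#' @param lambda willingness-to-pay threshold (currency per unit effect).
#' @return \eqn{\lambda \Delta E - \Delta C}.
#' @export
inmb <- function(delta_cost, delta_effect, lambda) {
  stopifnot(lambda >= 0)
  lambda * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold, the fraction of PSA increments with positive INMB.
#'
#' @param psa_increments data frame (or list) with columns/elements
#'   `delta_cost` and `delta_effect`, one row per PSA iteration.
#' @param lambda_grid thresholds at which to evaluate the curve.
#' @return data frame with `lambda` and `probability` in \[0, 1\].
#' @export
ceac <- function(psa_increments, lambda_grid = seq(0, 50000, by = 1000)) {
  dc <- psa_increments$delta_cost
  de <- psa_increments$delta_effect
  if (is.null(dc) || length(dc) == 0) stop("psa_increments must be non-empty")
  stopifnot(length(dc) == length(de))
  prob <- vapply(lambda_grid,
                 function(l) mean(l * de - dc > 0),
                 numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Incremental cost-effectiveness summary for two arms
#'
#' Computes invited-minus-non-invited incremental cost and effects from
#' per-arm means, with the ICER (and its dominance classification) and the
#' INMB at a willingness-to-pay threshold.
#'
#' @param per_arm data frame with columns `arm` (containing `"invited"` and
#'   `"non_invited"`), `cost`, `life_years`, and optionally `qalys`.
#' @param lambda willingness-to-pay threshold.
#' @return object of class `ce_result` with per-arm means, `delta_cost`,
#'   `delta_qalys`, `delta_life_years`, `icer`, `inmb`.
#' @export
ce_result <- function(per_arm, lambda = 20000) {
  i <- match("invited", per_arm$arm)
  n <- match("non_invited", per_arm$arm)
  if (is.na(i) || is.na(n)) stop("per_arm must contain both arms")
  dcost <- per_arm$cost[i] - per_arm$cost[n]
  dly <- per_arm$life_years[i] - per_arm$life_years[n]
  dq <- if (!is.null(per_arm$qalys)) per_arm$qalys[i] - per_arm$qalys[n] else NA_real_
  eff <- if (is.na(dq)) dly else dq
  structure(
    list(per_arm = per_arm,
         delta_cost = dcost,
         delta_qalys = dq,
         delta_life_years = dly,
         lambda = lambda,
         icer = icer(dcost, eff),
         inmb = inmb(dcost, eff, lambda)),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("  delta cost %.4f | delta QALYs %.6f | delta LY %.6f\n",
              x$delta_cost, x$delta_qalys, x$delta_life_years))
  cat("  ")
  print(x$icer)
  cat(sprintf("  INMB at lambda=%g: %.4f\n", x$lambda, x$inmb))
  invisible(x)
}
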