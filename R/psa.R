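## Probabilistic sensitivity analysis, oversampling with reweighting, and
## policy comparison under common random numbers.

#' Oversampling plan for aneurysmal baselines
#'
#' Model output is driven by the small fraction of individuals whose
#' baseline diameter reaches the diagnosis threshold, so those baselines are
#' sampled at `multiplier` times their population rate and downweighted in
#' every mean (Horvitz-Thompson weights `pop stratum probability / sampling
#' stratum probability`), leaving all estimates unbiased while cutting the
#' Monte Carlo error of incremental quantities.  The sampling fraction is
#' capped at one-half: beyond an even split additional aneurysmal pairs add
#' little information.
#'
#' @param multiplier sampling multiplier k >= 1 for the AAA stratum.
#' @param threshold stratum boundary (cm); baselines at or above it form the
#'   AAA stratum.  Defaults to the policy diagnosis threshold at run time.
#' @return object of class `oversampling_plan`.
#' @export
oversampling_plan <- function(multiplier = 1, threshold = NULL) {
  stopifnot(multiplier >= 1)
  structure(list(multiplier = multiplier, threshold = threshold),
            class = "oversampling_plan")
}

## Probability that a simulated pair falls in the AAA stratum.
.plan_sampling_prob <- function(plan, prevalence) {
  min(plan$multiplier * prevalence, max(0.5, prevalence))
}

#' Stratum weights restoring population proportions
#'
#' @param plan an [oversampling_plan()].
#' @param prevalence population probability of the AAA stratum.
#' @return named numeric `c(aaa = , other = )` giving the per-pair weight in
#'   each stratum.
#' @export
stratum_weights <- function(plan, prevalence) {
  q <- .plan_sampling_prob(plan, prevalence)
  c(aaa = prevalence / q, other = (1 - prevalence) / (1 - q))
}

#' Weighted (Horvitz-Thompson ratio) mean
#'
#' The estimator used for every per-arm mean under oversampling:
#' \eqn{\sum w_i x_i / \sum w_i}.
#'
#' @param x values.
#' @param w weights.
#' @return weighted mean.
#' @export
ht_mean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  sum(w * x) / sum(w)
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_iterations` realizations of the global uncertain parameters,
#' runs the main analysis for each, and summarizes the distribution of the
#' incrementals.  ICERs in the dominated quadrant (negative incremental
#' effect, positive cost) are set to infinite before percentile computation;
#' infinite ICERs sort above all finite values.
#'
#' @param n_iterations number of PSA iterations (>= 1).
#' @param n_pairs twin pairs per iteration.
#' @param bundle an `aaa_bundle`.
#' @param policy optional [policy_spec()].
#' @param seed master seed; iteration draws and simulation streams derive
#'   from it.
#' @param workers forked workers passed to [run_main_analysis()].
#' @param lambda willingness-to-pay for INMB.
#' @param lambda_grid thresholds for the CEAC.
#' @return object of class `psa_result`: per-iteration data frame, summary
#'   (means and 2.5th/97.5th percentiles), and the CEAC.
#' @export
run_psa <- function(n_iterations, n_pairs, bundle, policy = NULL, seed = 1L,
                    workers = 1L, lambda = 20000,
                    lambda_grid = seq(0, 50000, by = 1000)) {
  stopifnot(n_iterations >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister")
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    draw <- draw_global_uncertain(bundle, draw_seeds[it], draw_index = it)
    run <- run_main_analysis(n_pairs, draw, bundle, policy,
                             seed = run_seeds[it], workers = workers,
                             lambda = lambda)
    ce <- run$ce
    ic <- ce$icer
    icer_val <- if (ic$classification == "dominated") Inf else ic$value
    rows[[it]] <- data.frame(
      iteration = it,
      delta_cost = ce$delta_cost,
      delta_effect = ce$delta_qalys,
      delta_life_years = ce$delta_life_years,
      icer = icer_val,
      inmb = ce$inmb
    )
  }
  iters <- do.call(rbind, rows)

  qi <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  summ <- data.frame(
    quantity = c("delta_cost", "delta_effect", "delta_life_years", "icer", "inmb"),
    mean = c(mean(iters$delta_cost), mean(iters$delta_effect),
             mean(iters$delta_life_years), mean(iters$icer), mean(iters$inmb)),
    lower = c(qi(iters$delta_cost)[1], qi(iters$delta_effect)[1],
              qi(iters$delta_life_years)[1], qi(iters$icer)[1], qi(iters$inmb)[1]),
    upper = c(qi(iters$delta_cost)[2], qi(iters$delta_effect)[2],
              qi(iters$delta_life_years)[2], qi(iters$icer)[2], qi(iters$inmb)[2])
  )

  structure(
    list(iterations = iters,
         summary = summ,
         ceac = ceac(iters, lambda_grid),
         n_pairs = n_pairs, seed = seed, lambda = lambda),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", nrow(x$iterations), "iterations x", x$n_pairs, "pairs\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare two surveillance policies under common random numbers
#'
#' Both policies are simulated on identical twin-pair streams (same master
#' seed, same oversampling plan covering the smaller diagnosis threshold),
#' so the non-invited arms coincide exactly and the incremental of the
#' alternative relative to the baseline is estimated with minimal Monte
#' Carlo error.
#'
#' @param baseline_policy,alternative_policy [policy_spec()] objects.
#' @param n_pairs twin pairs per run.
#' @param draw realized uncertain parameters.
#' @param bundle an `aaa_bundle`.
#' @param seed shared master seed.
#' @param workers forked workers.
#' @param lambda willingness-to-pay.
#' @return object of class `policy_comparison`: incrementals of
#'   alternative vs baseline, their ICER/INMB, and both underlying runs.
#' @export
compare_policies <- function(baseline_policy, alternative_policy, n_pairs,
                             draw, bundle, seed = 1L, workers = 1L,
                             lambda = 20000) {
  thr <- min(baseline_policy$diagnosis_threshold,
             alternative_policy$diagnosis_threshold)
  plan <- oversampling_plan(bundle$global_fixed$oversampling_multiplier, thr)
  run_a <- run_main_analysis(n_pairs, draw, bundle, baseline_policy,
                             seed = seed, workers = workers, plan = plan,
                             lambda = lambda)
  run_b <- run_main_analysis(n_pairs, draw, bundle, alternative_policy,
                             seed = seed, workers = workers, plan = plan,
                             lambda = lambda)
  dcost <- run_b$ce$delta_cost - run_a$ce$delta_cost
  dq <- run_b$ce$delta_qalys - run_a$ce$delta_qalys
  dly <- run_b$ce$delta_life_years - run_a$ce$delta_life_years
  structure(
    list(baseline = baseline_policy$name,
         alternative = alternative_policy$name,
         delta_cost = dcost,
         delta_qalys = dq,
         delta_life_years = dly,
         icer = icer(dcost, dq),
         inmb = inmb(dcost, dq, lambda),
         lambda = lambda,
         runs = list(baseline = run_a, alternative = run_b)),
    class = "policy_comparison"
  )
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat("<policy_comparison>", x$alternative, "vs", x$baseline, "\n")
  cat(sprintf("  delta cost %.4f | delta QALYs %.6f\n", x$delta_cost, x$delta_qalys))
  print(x$icer)
  cat(sprintf("  INMB at lambda=%g: %.4f\n", x$lambda, x$inmb))
  invisible(x)
}
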