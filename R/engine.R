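## Event-scheduling simulation engine.
##
## Each individual owns a future event list (FEL): at most one pending event
## per kind, popped in time order with a fixed kind-priority order breaking
## ties (deaths are processed first, censoring last).  Individuals are
## simulated in matched pairs ("identical twins"): one invited to screening,
## one not, sharing their latent aortic trajectory, non-AAA death time,
## rupture time and the binary indicators for attendance, contraindication,
## surgery survival and repair modality.  Incremental costs and effects then
## estimate the causal effect of invitation with greatly reduced Monte Carlo
## error (common random numbers).
##
## Reproducibility: one master seed; each pair is given three dedicated
## L'Ecuyer-CMRG substreams (shared latents, invited arm, non-invited arm),
## assigned by pair index.  Results are therefore bit-identical whatever the
## number of parallel workers, and the non-invited arm is identical across
## policies compared under the same seed.

## Event kind codes.  1..9 are FEL-schedulable, in tie-break priority order;
## 10..12 occur only in histories (instantaneous consequences of others).
.EV_NAD <- 1L   # non_aaa_death
.EV_RUP <- 2L   # rupture
.EV_ELE <- 3L   # elective_surgery
.EV_CON <- 4L   # consultation
.EV_INC <- 5L   # incidental_detection
.EV_SUR <- 6L   # surveillance_scan
.EV_SCR <- 7L   # screen_scan
.EV_INV <- 8L   # invitation
.EV_CEN <- 9L   # censor
.EV_EME <- 10L  # emergency_surgery
.EV_AAD <- 11L  # aaa_death
.EV_DRO <- 12L  # dropout

.ev_names <- c("non_aaa_death", "rupture", "elective_surgery", "consultation",
               "incidental_detection", "surveillance_scan", "screen_scan",
               "invitation", "censor", "emergency_surgery", "aaa_death",
               "dropout")

.state_names <- c("undetected", "under_surveillance", "referred",
                  "post_repair", "contraindicated_exit", "discharged")

#' Event kinds understood by the simulator
#' @return character vector of kind names.
#' @export
event_kinds <- function() .ev_names

## ---- Future event list -----------------------------------------------------

#' Create an empty future event list
#'
#' The FEL holds at most one pending event per schedulable kind.  It is a
#' named numeric vector of event times stored in tie-break priority order
#' (deaths first, censoring last); `Inf` marks "no pending event".
#'
#' @return object of class `fel`.
#' @export
fel_new <- function() {
  structure(stats::setNames(rep(Inf, 9L), .ev_names[1:9]), class = "fel")
}

#' Schedule (or reschedule) an event
#'
#' @param fel a [fel_new()] list.
#' @param kind schedulable kind name.
#' @param time event time in years, finite and >= 0.
#' @return the updated FEL.
#' @export
fel_schedule <- function(fel, kind, time) {
  if (!kind %in% .ev_names[1:9])
    stop("'", kind, "' is not a schedulable event kind")
  if (!is.finite(time) || time < 0) stop("event time must be finite and >= 0")
  fel[kind] <- time
  fel
}

#' Cancel a pending event
#'
#' @inheritParams fel_schedule
#' @return the updated FEL.
#' @export
fel_cancel <- function(fel, kind) {
  if (!kind %in% .ev_names[1:9])
    stop("'", kind, "' is not a schedulable event kind")
  fel[kind] <- Inf
  fel
}

#' Pop the next event
#'
#' Returns the pending event with the minimum time; ties are broken by the
#' fixed kind-priority order (non-AAA death, rupture, surgical pathway,
#' detection, scans, invitation, censor).
#'
#' @param fel a [fel_new()] list.
#' @return list with `kind`, `time`, and the updated `fel`; `kind` is `NA`
#'   if nothing is pending.
#' @export
fel_pop <- function(fel) {
  j <- which.min(fel)           # first minimum == priority order
  if (!is.finite(fel[[j]])) return(list(kind = NA_character_, time = Inf, fel = fel))
  out <- list(kind = names(fel)[j], time = fel[[j]], fel = fel_cancel(fel, names(fel)[j]))
  out
}

## ---- Simulation context ----------------------------------------------------

## Everything the hot loop needs, flattened out of bundle + draw + policy.
.build_context <- function(bundle, draw, policy = NULL, plan = NULL,
                           oversample = TRUE) {
  gf <- bundle$global_fixed
  if (is.null(policy)) policy <- builtin_policy(gf$policy)
  co <- .resolve_costs(bundle, draw)

  entry <- gf$invitation_age
  if (entry != round(entry)) stop("invitation_age must be an integer age")
  cap <- 150 - entry

  lt <- gf$life_table
  rates <- as.numeric(unlist(lt$rates))
  if (lt$start_age > entry) stop("life table must start at or before invitation_age")
  rates <- rates[(entry - lt$start_age + 1):length(rates)]
  if (!length(rates)) stop("life table does not cover the invitation age")
  cumH <- cumsum(rates)

  ut <- gf$utilities
  util_age_from <- as.numeric(unlist(ut$age_from))
  util_w <- as.numeric(unlist(ut$weight))
  yrs <- 0:(ceiling(cap) - 1)
  util_by_year <- util_w[pmax(findInterval(entry + yrs, util_age_from), 1L)]

  bd <- gf$baseline_diameter
  hz <- rupture_hazard_params(gf$rupture_hazard$intercept,
                              gf$rupture_hazard$slope,
                              gf$rupture_hazard$reference_cm)

  if (is.null(plan))
    plan <- oversampling_plan(multiplier = if (oversample) gf$oversampling_multiplier else 1,
                              threshold = policy$diagnosis_threshold)
  p_aaa <- 1 - .baseline_cdf(bd, plan$threshold)
  q_aaa <- .plan_sampling_prob(plan, p_aaa)

  cen <- gf$censoring

  ## per-kind unit costs, indexed by event code, for each repair modality
  cost_vec <- function(elective, emergency) {
    v <- numeric(12)
    v[.EV_CON] <- co$consultation
    v[c(.EV_SUR, .EV_SCR)] <- co$scan
    v[.EV_INV] <- co$invitation
    v[.EV_ELE] <- elective
    v[.EV_EME] <- emergency
    v
  }

  list(
    entry_age = entry, cap = cap,
    diag = policy$diagnosis_threshold, refer = policy$referral_threshold,
    thr = policy$surveillance_thresholds, ivs = policy$surveillance_intervals,
    w1 = gf$wait_discovery_to_consultation_days / DAYS_PER_YEAR,
    w2 = gf$wait_consultation_to_surgery_days / DAYS_PER_YEAR,
    us_sd = gf$ultrasound_sd_cm, ct_sd = gf$ct_sd_cm, ct_off = gf$ct_offset_cm,
    zero_cut = gf$zero_growth_cutoff_cm,
    baseline = bd,
    g_band_from = as.numeric(unlist(gf$growth_rate$band_from)),
    g_mean = as.numeric(unlist(gf$growth_rate$mean)),
    g_sd = as.numeric(unlist(gf$growth_rate$sd)),
    hz = hz,
    inc_rate = gf$incidental_detection_rate,
    cen_type = cen$type,
    horizon = gf$time_horizon_years,
    cen_min = if (cen$type == "uniform") cen$min else NA_real_,
    cen_max = if (cen$type == "uniform") cen$max else NA_real_,
    lt_rates = rates, lt_cumH = cumH,
    p_attend = draw$attendance_prob, p_drop = draw$dropout_prob,
    p_contra = draw$contraindication_prob,
    m_open = draw$elective_mortality_open, m_evar = draw$elective_mortality_evar,
    m_emerg = draw$emergency_mortality, p_emerg = draw$emergency_surgery_prob,
    p_evar = draw$evar_proportion,
    plan = plan, p_aaa = p_aaa, q_aaa = q_aaa,
    w_aaa = p_aaa / q_aaa,
    w_oth = (1 - p_aaa) / (1 - q_aaa),
    cost_open = cost_vec(co$elective_open, co$emergency_open),
    cost_evar = cost_vec(co$elective_evar, co$emergency_evar),
    r_cost = gf$discount_rate_cost, r_eff = gf$discount_rate_effect,
    util_by_year = util_by_year,
    policy = policy,
    bundle_name = bundle$metadata$name
  )
}

## Inverse-transform non-AAA death time from the piecewise-constant
## life-table hazard; the last tabulated rate extends beyond the table.
.lt_invert <- function(ctx, E) {
  cumH <- ctx$lt_cumH
  m <- length(cumH)
  if (E >= cumH[m]) {
    t <- m + (E - cumH[m]) / ctx$lt_rates[m]
  } else {
    k <- findInterval(E, cumH)          # completed whole years
    H0 <- if (k == 0L) 0 else cumH[k]
    t <- k + (E - H0) / ctx$lt_rates[k + 1L]
  }
  min(t, ctx$cap)
}

## ---- Twin-pair creation ----------------------------------------------------

## Draws a pair's shared latent attributes from the current RNG stream.
## Baseline diameters use a single uniform with a tail mapping so that a
## multiplier of 1 reproduces plain (unstratified) sampling draw-for-draw.
.make_pair <- function(ctx) {
  v <- stats::runif(1)
  q <- ctx$q_aaa; p <- ctx$p_aaa
  if (v >= 1 - q) {                     # AAA stratum (upper tail)
    u <- 1 - p + (v - (1 - q)) / q * p
    w <- ctx$w_aaa
  } else {
    u <- v / (1 - q) * (1 - p)
    w <- ctx$w_oth
  }
  u <- min(max(u, 1e-12), 1 - 1e-12)
  d0 <- .baseline_quantile(ctx$baseline, u)

  ## latent slope conditional on the baseline band (sub-aneurysmal aortas
  ## grow more slowly than established AAAs); zero below the cutoff
  gb <- max(findInterval(d0, ctx$g_band_from), 1L)
  traj <- aorta_trajectory(d0, stats::rnorm(1, ctx$g_mean[gb], ctx$g_sd[gb]),
                           ctx$zero_cut)

  t_nd <- .lt_invert(ctx, stats::rexp(1))
  u_r <- min(max(stats::runif(1), 1e-15), 1 - 1e-15)
  t_r <- sample_rupture_time(traj, ctx$hz, u_r, ctx$cap)

  contraindicated <- stats::runif(1) < ctx$p_contra
  gets_evar <- stats::runif(1) < ctx$p_evar
  survives_elective <- stats::runif(1) >=
    (if (gets_evar) ctx$m_evar else ctx$m_open)
  survives_emergency <- stats::runif(1) >= ctx$m_emerg
  gets_emergency_surgery <- stats::runif(1) < ctx$p_emerg
  would_attend <- stats::runif(1) < ctx$p_attend

  t_censor <- if (ctx$cen_type == "uniform")
    stats::runif(1, ctx$cen_min, ctx$cen_max) else ctx$horizon
  inc_wait <- if (ctx$inc_rate > 0) stats::rexp(1, ctx$inc_rate) else Inf

  list(trajectory = traj,
       baseline_diameter = d0,
       t_cross = time_to_threshold(traj, ctx$diag),
       non_aaa_death_time = t_nd,
       rupture_time = t_r,
       contraindicated = contraindicated,
       gets_evar = gets_evar,
       survives_elective_surgery = survives_elective,
       survives_emergency_surgery = survives_emergency,
       gets_emergency_surgery = gets_emergency_surgery,
       would_attend = would_attend,
       censor_time = t_censor,
       incidental_wait = inc_wait,
       weight = w)
}

#' Create a twin pair
#'
#' Draws the latent attributes shared by an invited/non-invited twin pair:
#' the aortic trajectory (baseline from the population distribution, slope
#' conditional on the zero-growth cutoff), the non-AAA death time from the
#' life table, the rupture time by inverse transform, the shared binary
#' indicators, and the pair's censoring time.  Both arms reference the same
#' shared fields, which are never mutated.
#'
#' @param draw realized uncertain parameters ([draw_global_uncertain()]).
#' @param bundle an `aaa_bundle`.
#' @param policy optional [policy_spec()]; defaults to the bundle's policy.
#' @param seed optional integer; when given, the pair is drawn from a fresh
#'   RNG state (otherwise the current stream is used).
#' @param oversample draw the baseline under the bundle's oversampling plan?
#' @return object of class `twin_pair` with a `shared` element and empty
#'   `invited`/`non_invited` slots (filled by [simulate_pair()]).
#' @export
create_twin_pair <- function(draw, bundle, policy = NULL, seed = NULL,
                             oversample = FALSE) {
  ctx <- .build_context(bundle, draw, policy, oversample = oversample)
  if (!is.null(seed)) set.seed(seed)
  structure(list(shared = .make_pair(ctx), invited = NULL, non_invited = NULL),
            class = "twin_pair")
}

## ---- Individual event loop -------------------------------------------------

## Simulates one arm of a pair.  Returns a light record: integer event
## kinds, event times, end time, survival flag, detection state and route.
##
## Event-specific randomness (scan errors, dropout, incidental re-detection
## waits) is pre-generated in indexed blocks from the arm's substream, so
## that the k-th scan of this individual consumes the k-th error whatever
## the surveillance policy: comparisons between policies under a shared
## seed then differ only where the policies genuinely disagree.
.sim_arm <- function(ctx, sh, invited) {
  us_err <- stats::rnorm(160, 0, ctx$us_sd); i_us <- 0L
  ct_err <- stats::rnorm(32, 0, ctx$ct_sd); i_ct <- 0L
  drop_u <- stats::runif(160); i_dr <- 0L
  inc_e <- if (ctx$inc_rate > 0) stats::rexp(16, ctx$inc_rate) else rep(Inf, 16)
  i_in <- 0L
  fel <- rep(Inf, 9L)
  fel[.EV_NAD] <- sh$non_aaa_death_time
  fel[.EV_RUP] <- sh$rupture_time
  fel[.EV_CEN] <- sh$censor_time
  if (invited) fel[.EV_INV] <- 0
  if (is.finite(sh$t_cross) && is.finite(sh$incidental_wait))
    fel[.EV_INC] <- sh$t_cross + sh$incidental_wait

  state <- 0L           # index into .state_names - 1
  route <- 0L           # 0 none, 1 screen, 2 incidental
  contra_route <- 0L
  times <- numeric(16L); kinds <- integer(16L); n <- 0L
  end_time <- NA_real_; alive <- FALSE

  traj <- sh$trajectory
  push <- function(k, tt) {
    n <<- n + 1L
    if (n > length(times)) {
      times <<- c(times, numeric(length(times)))
      kinds <<- c(kinds, integer(length(kinds)))
    }
    times[n] <<- tt; kinds[n] <<- k
  }
  resched_incidental <- function(tnow) {
    if (is.finite(sh$t_cross) && ctx$inc_rate > 0) {
      i_in <<- i_in %% 16L + 1L
      max(tnow, sh$t_cross) + inc_e[i_in]
    } else Inf
  }

  repeat {
    j <- which.min(fel)
    tnow <- fel[j]
    fel[j] <- Inf

    if (j == .EV_NAD) {
      push(.EV_NAD, tnow); end_time <- tnow; break

    } else if (j == .EV_RUP) {
      push(.EV_RUP, tnow)
      if (sh$gets_emergency_surgery) {
        push(.EV_EME, tnow)
        if (sh$survives_emergency_surgery) {
          state <- 3L
          fel[c(.EV_ELE, .EV_CON, .EV_INC, .EV_SUR, .EV_SCR, .EV_INV)] <- Inf
        } else {
          push(.EV_AAD, tnow); end_time <- tnow; break
        }
      } else {
        push(.EV_AAD, tnow); end_time <- tnow; break
      }

    } else if (j == .EV_ELE) {
      push(.EV_ELE, tnow)
      if (sh$survives_elective_surgery) {
        state <- 3L
        fel[c(.EV_RUP, .EV_CON, .EV_INC, .EV_SUR)] <- Inf
      } else {
        push(.EV_AAD, tnow); end_time <- tnow; break
      }

    } else if (j == .EV_CON) {
      push(.EV_CON, tnow)
      i_ct <- i_ct %% 32L + 1L
      m <- diameter_at_time(traj, tnow) + ctx$ct_off + ct_err[i_ct]
      if (m < 0) m <- 0
      if (m >= ctx$refer) {
        if (sh$contraindicated) {
          state <- 4L; contra_route <- route
        } else {
          fel[.EV_ELE] <- tnow + ctx$w2
        }
      } else if (m >= ctx$diag) {
        band <- findInterval(m, ctx$thr)
        fel[.EV_SUR] <- tnow + ctx$ivs[band]
        state <- 1L
      } else {
        state <- 5L
        fel[.EV_INC] <- resched_incidental(tnow)
      }

    } else if (j == .EV_INC) {
      push(.EV_INC, tnow)
      route <- 2L; state <- 2L
      fel[.EV_CON] <- tnow + ctx$w1

    } else if (j == .EV_SUR) {
      i_dr <- i_dr %% 160L + 1L
      if (drop_u[i_dr] < ctx$p_drop) {
        push(.EV_DRO, tnow)
        state <- 0L; route <- 0L
        fel[.EV_INC] <- resched_incidental(tnow)
      } else {
        push(.EV_SUR, tnow)
        i_us <- i_us %% 160L + 1L
        m <- diameter_at_time(traj, tnow) + us_err[i_us]
        if (m < 0) m <- 0
        if (m >= ctx$refer) {
          state <- 2L
          fel[.EV_CON] <- tnow + ctx$w1
        } else if (m >= ctx$diag) {
          band <- findInterval(m, ctx$thr)
          fel[.EV_SUR] <- tnow + ctx$ivs[band]
          state <- 1L
        } else {
          state <- 5L
          fel[.EV_INC] <- resched_incidental(tnow)
        }
      }

    } else if (j == .EV_SCR) {
      push(.EV_SCR, tnow)
      i_us <- i_us %% 160L + 1L
      m <- diameter_at_time(traj, tnow) + us_err[i_us]
      if (m < 0) m <- 0
      if (m >= ctx$refer) {
        route <- 1L; state <- 2L
        fel[.EV_CON] <- tnow + ctx$w1
        fel[.EV_INC] <- Inf
      } else if (m >= ctx$diag) {
        route <- 1L; state <- 1L
        band <- findInterval(m, ctx$thr)
        fel[.EV_SUR] <- tnow + ctx$ivs[band]
        fel[.EV_INC] <- Inf
      } else {
        state <- 5L                      # one-off discharge; incidental stays
      }

    } else if (j == .EV_INV) {
      push(.EV_INV, tnow)                # invitation cost accrues regardless
      if (sh$would_attend) fel[.EV_SCR] <- tnow

    } else {                             # censor
      push(.EV_CEN, tnow); end_time <- tnow; alive <- TRUE; break
    }
  }

  list(times = times[seq_len(n)], kinds = kinds[seq_len(n)],
       end_time = end_time, alive = alive,
       state = state, route = route, contra_route = contra_route)
}

## ---- Accrual and counting (fast internal forms) ----------------------------

.dpt <- function(t0, t1, rate) {
  if (rate == 0) return(t1 - t0)
  lr <- log1p(rate)
  (exp(-t0 * lr) - exp(-t1 * lr)) / lr
}

.accrue_fast <- function(ctx, arm_res, gets_evar) {
  cv <- if (gets_evar) ctx$cost_evar else ctx$cost_open
  unit <- cv[arm_res$kinds]
  cost <- sum(unit * (1 + ctx$r_cost)^(-arm_res$times))
  tend <- arm_res$end_time
  ly <- .dpt(0, tend, ctx$r_eff)
  if (tend <= 0) {
    qaly <- 0
  } else {
    k <- ceiling(tend)
    t0 <- seq_len(k) - 1
    t1 <- pmin(seq_len(k), tend)
    qaly <- sum(ctx$util_by_year[seq_len(k)] * .dpt(t0, t1, ctx$r_eff))
  }
  c(cost = cost, life_years = ly, qalys = qaly)
}

.count_categories <- c("invitation", "screen_scan", "surveillance_scan",
                       "incidental_detection", "consultation",
                       "elective_screen", "elective_incidental",
                       "emergency_operation", "rupture",
                       "contraindicated_screen", "contraindicated_incidental",
                       "aaa_death", "non_aaa_death", "loss_to_recall",
                       "censored_alive")

.count_arm <- function(arm_res) {
  k <- arm_res$kinds
  cnt <- numeric(length(.count_categories))
  cnt[1] <- sum(k == .EV_INV)
  cnt[2] <- sum(k == .EV_SCR)
  cnt[3] <- sum(k == .EV_SUR)
  cnt[4] <- sum(k == .EV_INC)
  cnt[5] <- sum(k == .EV_CON)
  has_ele <- any(k == .EV_ELE)
  if (has_ele) {
    if (arm_res$route == 2L) cnt[7] <- 1 else cnt[6] <- 1
  }
  cnt[8] <- sum(k == .EV_EME)
  cnt[9] <- sum(k == .EV_RUP)
  if (arm_res$state == 4L) {
    if (arm_res$contra_route == 2L) cnt[11] <- 1 else cnt[10] <- 1
  }
  cnt[12] <- sum(k == .EV_AAD)
  cnt[13] <- sum(k == .EV_NAD)
  cnt[14] <- sum(k == .EV_DRO)
  cnt[15] <- as.numeric(arm_res$alive)
  cnt
}

## ---- Public single-pair simulation -----------------------------------------

.record_public <- function(arm_res, sh, arm) {
  routes <- c(NA_character_, "screen", "incidental")
  structure(
    list(arm = arm,
         events = data.frame(time = arm_res$times,
                             kind = .ev_names[arm_res$kinds],
                             stringsAsFactors = FALSE),
         death_time = arm_res$end_time,
         alive_at_censor = arm_res$alive,
         state = .state_names[arm_res$state + 1L],
         detection_route = routes[arm_res$route + 1L],
         contraindicated_route = routes[arm_res$contra_route + 1L],
         gets_evar = sh$gets_evar),
    class = "aaa_record"
  )
}

#' Simulate both arms of a twin pair
#'
#' Runs the event loop for the invited and non-invited twins.  The shared
#' latent fields of `pair` are read-only; per-arm randomness (measurement
#' errors, dropout, emergency-surgery access) comes from the current RNG
#' stream, invited arm first.
#'
#' @param pair a [create_twin_pair()] object.
#' @param policy a [policy_spec()]; defaults to the bundle's policy.
#' @param draw realized uncertain parameters.
#' @param bundle an `aaa_bundle`.
#' @return the `twin_pair` with `invited` and `non_invited` filled with
#'   `aaa_record` objects.
#' @export
simulate_pair <- function(pair, policy = NULL, draw, bundle) {
  ctx <- .build_context(bundle, draw, policy)
  inv <- .sim_arm(ctx, pair$shared, TRUE)
  non <- .sim_arm(ctx, pair$shared, FALSE)
  pair$invited <- .record_public(inv, pair$shared, "invited")
  pair$non_invited <- .record_public(non, pair$shared, "non_invited")
  pair
}

#' Simulate a single arm of a twin pair
#'
#' @inheritParams simulate_pair
#' @param arm `"invited"` or `"non_invited"`.
#' @return an `aaa_record`: the time-ordered event history, death/censor
#'   time, and final detection state.
#' @export
simulate_individual <- function(pair, arm = c("invited", "non_invited"),
                                policy = NULL, draw, bundle) {
  arm <- match.arg(arm)
  ctx <- .build_context(bundle, draw, policy)
  res <- .sim_arm(ctx, pair$shared, arm == "invited")
  .record_public(res, pair$shared, arm)
}

## ---- Main analysis ---------------------------------------------------------

#' Run the main individual-patient simulation
#'
#' Simulates `n_pairs` twin pairs under one realized parameter set and one
#' policy, and returns weighted per-arm mean discounted costs, life-years
#' and QALYs plus event counts by category.  Aneurysmal baselines are
#' oversampled per the bundle's plan and reweighted (Horvitz-Thompson ratio
#' estimator), leaving all means unbiased.  Deterministic given `seed` and
#' invariant to `workers`.
#'
#' @param n_pairs number of twin pairs (>= 1).
#' @param draw realized uncertain parameters ([draw_global_uncertain()] or
#'   [fix_bundle_at_means()]).
#' @param bundle an `aaa_bundle`.
#' @param policy optional [policy_spec()]; defaults to the bundle's policy.
#' @param seed master seed; every pair derives three dedicated RNG
#'   substreams from it.
#' @param workers parallel forked workers (results identical for any value).
#' @param oversample use the bundle's oversampling multiplier? `FALSE`
#'   reproduces plain population sampling.
#' @param plan optional [oversampling_plan()] overriding the bundle's.
#' @param lambda willingness-to-pay threshold for the attached [ce_result()].
#' @return object of class `aaa_run`: `per_arm` data frame, raw and
#'   weighted event-count matrices, and the incremental `ce` summary.
#' @export
run_main_analysis <- function(n_pairs, draw, bundle, policy = NULL, seed = 1L,
                              workers = 1L, oversample = TRUE, plan = NULL,
                              lambda = 20000) {
  stopifnot(n_pairs >= 1)
  ctx <- .build_context(bundle, draw, policy, plan, oversample)

  ## master seed -> per-pair substreams, assigned by pair index
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  base_stream <- get(".Random.seed", globalenv())

  chunk_size <- 1000L
  starts <- seq.int(1L, n_pairs, by = chunk_size)
  chunk_streams <- vector("list", length(starts))
  s <- base_stream
  for (ci in seq_along(starts)) {
    chunk_streams[[ci]] <- s
    n_in <- min(chunk_size, n_pairs - starts[ci] + 1L)
    for (i in seq_len(3L * n_in)) s <- parallel::nextRNGStream(s)
  }

  ncat <- length(.count_categories)
  chunk_fun <- function(ci) {
    s <- chunk_streams[[ci]]
    n_in <- min(chunk_size, n_pairs - starts[ci] + 1L)
    acc <- matrix(0, nrow = 3, ncol = 2)       # cost/ly/qaly x arm (weighted)
    wsum <- 0
    cnt_raw <- matrix(0, nrow = ncat, ncol = 2)
    cnt_w <- matrix(0, nrow = ncat, ncol = 2)
    for (i in seq_len(n_in)) {
      assign(".Random.seed", s, globalenv())
      sh <- .make_pair(ctx)
      s <- parallel::nextRNGStream(s)
      assign(".Random.seed", s, globalenv())
      inv <- .sim_arm(ctx, sh, TRUE)
      s <- parallel::nextRNGStream(s)
      assign(".Random.seed", s, globalenv())
      non <- .sim_arm(ctx, sh, FALSE)
      s <- parallel::nextRNGStream(s)

      w <- sh$weight
      acc[, 1] <- acc[, 1] + w * .accrue_fast(ctx, inv, sh$gets_evar)
      acc[, 2] <- acc[, 2] + w * .accrue_fast(ctx, non, sh$gets_evar)
      ci_inv <- .count_arm(inv); ci_non <- .count_arm(non)
      cnt_raw[, 1] <- cnt_raw[, 1] + ci_inv
      cnt_raw[, 2] <- cnt_raw[, 2] + ci_non
      cnt_w[, 1] <- cnt_w[, 1] + w * ci_inv
      cnt_w[, 2] <- cnt_w[, 2] + w * ci_non
      wsum <- wsum + w
    }
    list(acc = acc, wsum = wsum, cnt_raw = cnt_raw, cnt_w = cnt_w)
  }

  res <- if (workers > 1L)
    parallel::mclapply(seq_along(starts), chunk_fun, mc.cores = workers,
                       mc.preschedule = TRUE)
  else
    lapply(seq_along(starts), chunk_fun)

  acc <- Reduce(`+`, lapply(res, `[[`, "acc"))
  wsum <- Reduce(`+`, lapply(res, `[[`, "wsum"))
  cnt_raw <- Reduce(`+`, lapply(res, `[[`, "cnt_raw"))
  cnt_w <- Reduce(`+`, lapply(res, `[[`, "cnt_w"))
  dimnames(cnt_raw) <- dimnames(cnt_w) <-
    list(.count_categories, c("invited", "non_invited"))

  per_arm <- data.frame(
    arm = c("invited", "non_invited"),
    cost = acc[1, ] / wsum,
    life_years = acc[2, ] / wsum,
    qalys = acc[3, ] / wsum,
    stringsAsFactors = FALSE
  )

  structure(
    list(per_arm = per_arm,
         counts = cnt_raw,
         counts_weighted = cnt_w,
         n_pairs = n_pairs,
         sum_weights = wsum,
         seed = seed,
         policy_name = ctx$policy$name,
         bundle_name = ctx$bundle_name,
         ce = ce_result(per_arm, lambda = lambda)),
    class = "aaa_run"
  )
}

#' @export
print.aaa_run <- function(x, ...) {
  cat("<aaa_run>", x$n_pairs, "pairs | bundle:", x$bundle_name,
      "| policy:", x$policy_name, "| seed:", x$seed, "\n")
  print(x$per_arm, row.names = FALSE)
  print(x$ce)
  invisible(x)
}
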