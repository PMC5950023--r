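# Event-scheduling engine: FEL semantics, twin pairs, event-loop pathways,
# and the main analysis contract.

test_that("the future event list pops by time with deaths-first tie-break", {
  f <- fel_new()
  expect_true(all(is.infinite(unclass(f))))
  f <- fel_schedule(f, "censor", 4)
  f <- fel_schedule(f, "surveillance_scan", 2)
  f <- fel_schedule(f, "rupture", 2)
  f <- fel_schedule(f, "non_aaa_death", 2)
  p <- fel_pop(f)
  expect_equal(p$kind, "non_aaa_death")     # ties: deaths first
  p <- fel_pop(p$fel)
  expect_equal(p$kind, "rupture")
  p <- fel_pop(p$fel)
  expect_equal(p$kind, "surveillance_scan")
  p <- fel_pop(p$fel)
  expect_equal(list(p$kind, p$time), list("censor", 4))
  expect_true(is.na(fel_pop(p$fel)$kind))

  # reschedule keeps at most one pending event per kind
  f <- fel_schedule(fel_new(), "consultation", 5)
  f <- fel_schedule(f, "consultation", 1)
  expect_equal(fel_pop(f)$time, 1)
  expect_true(is.na(fel_pop(fel_cancel(f, "consultation"))$kind))

  expect_error(fel_schedule(fel_new(), "aaa_death", 1), "schedulable")
  expect_error(fel_schedule(fel_new(), "censor", Inf), "finite")
})

test_that("twin pairs share their latent attributes by construction", {
  b <- quick_bundle()
  d <- fix_bundle_at_means(b)
  set.seed(77)
  shared_names <- c("non_aaa_death_time", "rupture_time", "contraindicated",
                    "survives_elective_surgery", "survives_emergency_surgery",
                    "gets_emergency_surgery", "would_attend", "gets_evar",
                    "censor_time")
  for (i in 1:200) {
    p <- create_twin_pair(d, b)
    expect_true(all(shared_names %in% names(p$shared)))
    pp <- simulate_pair(p, draw = d, bundle = b)
    # both simulated arms end no later than the shared censor and share it
    # exactly when censored alive
    if (pp$invited$alive_at_censor && pp$non_invited$alive_at_censor)
      expect_identical(pp$invited$death_time, pp$non_invited$death_time)
  }
})

test_that("a null rupture hazard yields no ruptures and no AAA deaths", {
  b <- quick_bundle()
  b$global_fixed$rupture_hazard$intercept <- -60     # hazard ~ 0
  b$global_fixed$rupture_hazard$slope <- 0           # at every diameter
  d <- fix_bundle_at_means(b)
  r <- run_main_analysis(500, d, b, seed = 3)
  expect_equal(sum(r$counts["rupture", ]), 0)
  expect_equal(sum(r$counts["emergency_operation", ]), 0)
  # zero surgery mortality on top: no AAA deaths at all
  b$global_uncertain$elective_mortality_open <- list(family = "fixed", value = 0)
  b$global_uncertain$elective_mortality_evar <- list(family = "fixed", value = 0)
  d <- fix_bundle_at_means(b)
  r <- run_main_analysis(500, d, b, seed = 3)
  expect_equal(sum(r$counts["aaa_death", ]), 0)
})

test_that("baseline prevalence matches the configured population rate", {
  b <- quick_bundle()
  d <- fix_bundle_at_means(b)
  set.seed(15)
  n <- 2e4
  aaa <- logical(n)
  for (i in seq_len(n))
    aaa[i] <- create_twin_pair(d, b)$shared$baseline_diameter >= 3.0
  p <- 0.016
  expect_lt(abs(mean(aaa) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a small zero-growth aorta is screened once and discharged", {
  b <- quick_bundle()
  pair <- manual_pair(baseline = 1.8, slope = 0.07, t_nd = 100, t_censor = 30)
  rec <- simulate_individual(pair, "invited", draw = forced_draw(), bundle = b)
  expect_equal(rec$events$kind, c("invitation", "screen_scan", "censor"))
  expect_equal(rec$state, "discharged")
  expect_true(rec$alive_at_censor)

  non <- simulate_individual(pair, "non_invited", draw = forced_draw(), bundle = b)
  expect_equal(non$events$kind, "censor")
})

test_that("a large AAA walks the screen-consult-surgery pathway on time", {
  b <- quick_bundle()
  b$global_fixed$ultrasound_sd_cm <- 0
  b$global_fixed$ct_sd_cm <- 0
  pair <- manual_pair(baseline = 6.0, slope = 0.03, t_nd = 100,
                      t_rupture = 12, t_censor = 30)
  rec <- simulate_individual(pair, "invited", draw = forced_draw(), bundle = b)
  kinds <- rec$events$kind
  expect_equal(kinds[1:4], c("invitation", "screen_scan", "consultation",
                             "elective_surgery"))
  tt <- rec$events$time
  expect_equal(tt[3], 71 / DAYS, tolerance = 1e-12)
  expect_equal(tt[4], (71 + 59) / DAYS, tolerance = 1e-12)
  expect_equal(rec$state, "post_repair")
  # repair cancelled the rupture scheduled at year 12
  expect_false("rupture" %in% kinds)
  expect_true(rec$alive_at_censor)

  # the non-invited twin with no emergency access dies at the shared
  # rupture time
  pair2 <- manual_pair(baseline = 6.0, slope = 0.03, t_nd = 100,
                       t_rupture = 12, t_censor = 30,
                       gets_emergency_surgery = FALSE)
  non <- simulate_individual(pair2, "non_invited", draw = forced_draw(), bundle = b)
  expect_equal(non$events$kind, c("rupture", "aaa_death"))
  expect_equal(non$death_time, 12)
  inv2 <- simulate_individual(pair2, "invited", draw = forced_draw(), bundle = b)
  expect_true(inv2$alive_at_censor)
})

test_that("contraindicated referrals exit but keep their rupture risk", {
  b <- quick_bundle()
  b$global_fixed$ultrasound_sd_cm <- 0
  b$global_fixed$ct_sd_cm <- 0
  pair <- manual_pair(baseline = 6.0, slope = 0.03, t_nd = 100,
                      t_rupture = 10, t_censor = 30, contraindicated = TRUE,
                      gets_emergency_surgery = FALSE)
  rec <- simulate_individual(pair, "invited", draw = forced_draw(), bundle = b)
  expect_equal(rec$state, "contraindicated_exit")
  expect_equal(rec$contraindicated_route, "screen")
  expect_false("elective_surgery" %in% rec$events$kind)
  expect_true("rupture" %in% rec$events$kind)     # risk persists
  expect_equal(rec$death_time, 10)
})

test_that("surveillance rescans are spaced by the policy interval", {
  b <- quick_bundle()
  b$global_fixed$ultrasound_sd_cm <- 0
  b$global_fixed$ct_sd_cm <- 0
  b$global_fixed$incidental_detection_rate <- 0
  # 3.2 cm growing slowly: stays in the 3.0-4.4 band (1-y rescans) for years
  pair <- manual_pair(baseline = 3.2, slope = 0.01, t_nd = 100, t_censor = 8.5)
  rec <- simulate_individual(pair, "invited",
                             draw = forced_draw(attendance = 1, dropout = 0),
                             bundle = b)
  scans <- rec$events$time[rec$events$kind == "surveillance_scan"]
  expect_equal(scans, 1:8)
})

test_that("every simulated history satisfies the record invariants", {
  b <- quick_bundle()
  d <- draw_global_uncertain(b, seed = 4)
  set.seed(21)
  terminal <- c("non_aaa_death", "aaa_death", "censor")
  for (i in 1:300) {
    p <- create_twin_pair(d, b, oversample = TRUE)
    pp <- simulate_pair(p, draw = d, bundle = b)
    for (arm in c("invited", "non_invited")) {
      r <- pp[[arm]]
      ev <- r$events
      expect_true(all(diff(ev$time) >= 0))                  # time-ordered
      expect_equal(sum(ev$kind %in% terminal), 1)           # one terminal
      expect_equal(ev$kind[nrow(ev)] %in% terminal, TRUE)   # nothing after it
      if (arm == "non_invited")
        expect_false(any(ev$kind %in% c("invitation", "screen_scan")))
      # incidental detection only past the diagnosis threshold
      inc <- ev$time[ev$kind == "incidental_detection"]
      if (length(inc))
        expect_true(all(diameter_at_time(p$shared$trajectory, inc) >= 3.0 - 1e-9))
      # no rupture after repair
      if ("elective_surgery" %in% ev$kind && r$state == "post_repair")
        expect_false(any(ev$kind == "rupture" &
                         ev$time > ev$time[ev$kind == "elective_surgery"][1]))
      expect_lte(max(ev$time), p$shared$censor_time + 1e-9)
    }
  }
})

test_that("main analysis results are deterministic and worker-invariant", {
  b <- quick_bundle()
  d <- fix_bundle_at_means(b)
  r1 <- run_main_analysis(1500, d, b, seed = 10, workers = 1)
  r2 <- run_main_analysis(1500, d, b, seed = 10, workers = 1)
  expect_identical(r1$per_arm, r2$per_arm)
  expect_identical(r1$counts, r2$counts)
  r4 <- run_main_analysis(1500, d, b, seed = 10, workers = 4)
  expect_identical(r1$per_arm, r4$per_arm)
  expect_identical(r1$counts, r4$counts)
  r5 <- run_main_analysis(1500, d, b, seed = 11)
  expect_false(identical(r1$per_arm, r5$per_arm))
})

test_that("inviting a population can only add cost when unit costs are positive", {
  b <- quick_bundle()
  d <- fix_bundle_at_means(b)
  r <- run_main_analysis(2000, d, b, seed = 6)
  expect_gt(r$per_arm$cost[r$per_arm$arm == "invited"],
            r$per_arm$cost[r$per_arm$arm == "non_invited"])
})

test_that("the smallest run returns two linked records", {
  b <- quick_bundle()
  d <- fix_bundle_at_means(b)
  r <- run_main_analysis(1, d, b, seed = 1)
  expect_equal(r$n_pairs, 1)
  expect_equal(nrow(r$per_arm), 2)
  expect_true(all(is.finite(r$per_arm$cost)))
})
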