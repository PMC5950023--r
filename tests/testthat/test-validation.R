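# Validation surfaces: censoring, event tables, ratios, cumulative curves.

test_that("trial censoring times are Uniform(3, 5.25) and shared in pairs", {
  set.seed(31)
  x <- mass_censoring_times(1e5)
  expect_true(all(x >= 3 & x <= 5.25))
  expect_lt(abs(mean(x) - (3 + 5.25) / 2), 3 * (5.25 - 3) / sqrt(12 * 1e5))

  b <- builtin_bundle("mass-validation")
  d <- fix_bundle_at_means(b)
  set.seed(32)
  for (i in 1:50) {
    p <- create_twin_pair(d, b)
    pp <- simulate_pair(p, draw = d, bundle = b)
    expect_true(p$shared$censor_time >= 3 && p$shared$censor_time <= 5.25)
    for (arm in c("invited", "non_invited"))
      if (pp[[arm]]$alive_at_censor)
        expect_equal(pp[[arm]]$death_time, p$shared$censor_time)
  }
})

test_that("event tables tally realized events by category and arm", {
  expect_equal(sum(event_count_table(list())), 0)

  rec <- structure(list(
    arm = "non_invited",
    events = data.frame(time = c(2, 2), kind = c("rupture", "aaa_death")),
    death_time = 2, alive_at_censor = FALSE, state = "undetected",
    detection_route = NA, contraindicated_route = NA, gets_evar = FALSE),
    class = "aaa_record")
  tab <- event_count_table(list(rec))
  expect_equal(tab["rupture", "non_invited"], 1)
  expect_equal(tab["aaa_death", "non_invited"], 1)
  expect_equal(sum(tab[, "invited"]), 0)

  expect_error(event_count_table(list(rec), categories = "appendectomy"),
               "appendectomy")
})

test_that("a hand-built record set matches its manual tally", {
  mk <- function(arm, kinds, times, state = "undetected", route = NA,
                 croute = NA, alive = FALSE) {
    structure(list(arm = arm,
                   events = data.frame(time = times, kind = kinds),
                   death_time = max(times), alive_at_censor = alive,
                   state = state, detection_route = route,
                   contraindicated_route = croute, gets_evar = FALSE),
              class = "aaa_record")
  }
  recs <- list(
    mk("invited", c("invitation", "screen_scan", "consultation",
                    "elective_surgery", "censor"),
       c(0, 0, 0.2, 0.36, 4), state = "post_repair", route = "screen",
       alive = TRUE),
    mk("invited", c("invitation", "censor"), c(0, 4), alive = TRUE),
    mk("invited", c("invitation", "screen_scan", "surveillance_scan",
                    "dropout", "non_aaa_death"),
       c(0, 0, 1, 2, 3), state = "undetected", route = "screen"),
    mk("non_invited", c("incidental_detection", "consultation",
                        "elective_surgery", "censor"),
       c(1, 1.2, 1.36, 4), state = "post_repair", route = "incidental",
       alive = TRUE),
    mk("non_invited", c("rupture", "emergency_surgery", "aaa_death"),
       c(2.5, 2.5, 2.5)),
    mk("non_invited", c("censor"), 4, alive = TRUE)
  )
  tab <- event_count_table(recs)
  expect_equal(tab["elective_screen", "invited"], 1)
  expect_equal(tab["elective_incidental", "non_invited"], 1)
  expect_equal(tab["loss_to_recall", "invited"], 1)
  expect_equal(tab["emergency_operation", "non_invited"], 1)
  expect_equal(tab["rupture", "non_invited"], 1)
  expect_equal(tab["aaa_death", "non_invited"], 1)
  expect_equal(tab["non_aaa_death", "invited"], 1)
  expect_equal(tab["censored_alive", "invited"], 2)
  expect_equal(tab["censored_alive", "non_invited"], 2)
})

test_that("percent-of-observed rounds halves away from zero", {
  expect_equal(percent_of_observed(154, 138), 112)
  expect_equal(percent_of_observed(68, 62), 110)
  expect_equal(percent_of_observed(0, 5), 0)
  expect_equal(percent_of_observed(3, 2), 150)
  expect_equal(percent_of_observed(1, 8), 13)      # 12.5 -> 13
  expect_true(is.na(percent_of_observed(3, 0)))
})

test_that("cumulative event curves step with events and match the table", {
  expect_equal(nrow(cumulative_event_curve(list(), "rupture")), 0)

  mk <- function(times) structure(list(
    arm = "invited",
    events = data.frame(time = c(times, 4), kind = c(rep("rupture", length(times)), "censor")),
    death_time = 4, alive_at_censor = TRUE, state = "undetected",
    detection_route = NA, contraindicated_route = NA, gets_evar = FALSE),
    class = "aaa_record")
  recs <- list(mk(1), mk(c(1, 2)))
  cv <- cumulative_event_curve(recs, "rupture", "invited")
  expect_equal(cv$time, c(1, 2))
  expect_equal(cv$cumulative, c(2, 3))
  expect_true(all(diff(cv$cumulative) > 0))

  # final curve value equals the count-table entry on simulated histories
  b <- builtin_bundle("mass-validation")
  d <- fix_bundle_at_means(b)
  set.seed(33)
  recs <- list()
  for (i in 1:150) {
    pp <- simulate_pair(create_twin_pair(d, b, oversample = TRUE),
                        draw = d, bundle = b)
    recs <- c(recs, list(pp$invited, pp$non_invited))
  }
  tab <- event_count_table(recs)
  for (kind in c("rupture", "non_aaa_death", "surveillance_scan")) {
    for (arm in c("invited", "non_invited")) {
      cv <- cumulative_event_curve(recs, kind, arm)
      final <- if (nrow(cv)) cv$cumulative[nrow(cv)] else 0L
      expect_equal(final, tab[kind, arm])
    }
  }
})
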