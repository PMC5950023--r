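# Discounting, accrual, ICER/INMB/CEAC.

test_that("discount factors follow annually-compounded continuous time", {
  expect_equal(discount_factor(c(0, 3, 50), 0), rep(1, 3))
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(10, 0.035), exp(-10 * log(1.035)),
               tolerance = 1e-12)
  expect_equal(discount_factor(10, 0.035), 0.70892, tolerance = 1e-4)
})

test_that("discounted person-time matches quadrature", {
  expect_equal(discounted_person_time(0, 4, 0), 4)
  expect_equal(discounted_person_time(2, 2, 0.05), 0)
  expect_equal(discounted_person_time(0, 4, 0.015), 3.88322, tolerance = 1e-5)
  set.seed(8)
  for (i in 1:100) {
    t0 <- runif(1, 0, 20); t1 <- t0 + runif(1, 0, 30)
    r <- runif(1, 0, 0.12)
    num <- stats::integrate(function(s) (1 + r)^(-s), t0, t1,
                            rel.tol = 1e-12)$value
    expect_equal(discounted_person_time(t0, t1, r), num, tolerance = 1e-9)
  }
})

test_that("accrual prices events at their occurrence times", {
  costs <- cost_schedule(invitation = 10, scan = 50, consultation = 200,
                         elective_open = 5000, elective_evar = 6000,
                         emergency_open = 8000, emergency_evar = 9000)
  u1 <- list(age_from = 65, weight = 1)
  r0 <- list(cost = 0, effect = 0)

  censor_only <- structure(list(
    arm = "non_invited",
    events = data.frame(time = 4, kind = "censor"),
    death_time = 4, alive_at_censor = TRUE, state = "undetected",
    detection_route = NA, contraindicated_route = NA, gets_evar = FALSE),
    class = "aaa_record")
  expect_equal(accrue(censor_only, costs, u1, r0),
               c(cost = 0, life_years = 4, qalys = 4))

  inv <- censor_only
  inv$events <- data.frame(time = c(0, 4), kind = c("invitation", "censor"))
  expect_equal(accrue(inv, costs, u1, r0)[["cost"]], 10)

  # flat utility below 1, death at 10, no discounting
  u9 <- list(age_from = 65, weight = 0.9)
  death <- censor_only
  death$events <- data.frame(time = 10, kind = "non_aaa_death")
  death$death_time <- 10; death$alive_at_censor <- FALSE
  expect_equal(accrue(death, costs, u9, r0),
               c(cost = 0, life_years = 10, qalys = 9))

  # modality-specific surgery pricing and discounting
  surg <- censor_only
  surg$events <- data.frame(time = c(0, 0, 2), kind = c("invitation", "screen_scan", "elective_surgery"))
  surg$gets_evar <- TRUE
  r <- list(cost = 0.035, effect = 0.035)
  got <- accrue(surg, costs, u1, r)
  expect_equal(got[["cost"]], 10 + 50 + 6000 * 1.035^-2, tolerance = 1e-12)
})

test_that("ICER classification covers the cost-effectiveness plane", {
  expect_equal(icer(49.61, 0.00781)$value, 49.61 / 0.00781)
  expect_equal(round(icer(49.61, 0.00781)$value), 6352)

  expect_equal(icer(-1.07, 0.0)$classification, "dominant")
  expect_equal(icer(-5, 0.001)$classification, "dominant")
  expect_equal(icer(0, 1)$value, 0)
  expect_equal(icer(5, -0.001)$classification, "dominated")
  expect_equal(icer(5, -0.001)$value, Inf)
  expect_equal(icer(-5, -0.001)$classification, "south_west")
  expect_equal(icer(0, 0)$classification, "undefined")

  # exhaustive and mutually exclusive over a signed grid
  for (dc in c(-2, 0, 3)) for (de in c(-0.1, 0, 0.2)) {
    cls <- icer(dc, de)$classification
    expect_length(cls, 1)
    expect_true(cls %in% c("ratio", "dominant", "dominated", "south_west",
                           "undefined"))
  }
})

test_that("INMB is linear in the threshold", {
  expect_equal(inmb(5.56, 0.00080, 20000), 10.44)
  expect_equal(inmb(7, 0.001, 0), -7)
  expect_equal(inmb(0, 0, 30000), 0)
  l <- c(0, 10000, 20000, 40000)
  v <- vapply(l, function(x) inmb(3, 0.0005, x), numeric(1))
  expect_equal(diff(v) / diff(l), rep(0.0005, 3))
})

test_that("the CEAC is the fraction of positive-INMB iterations", {
  inc <- data.frame(delta_cost = c(10, 10), delta_effect = c(0.001, -0.001))
  expect_equal(ceac(inc, 20000)$probability, 0.5)

  all_dom <- data.frame(delta_cost = c(-1, -2), delta_effect = c(0.1, 0.2))
  expect_equal(ceac(all_dom, c(0, 1e4, 5e4))$probability, rep(1, 3))

  # at lambda = 0 the curve equals the fraction of cost-saving samples
  set.seed(14)
  inc <- data.frame(delta_cost = rnorm(500), delta_effect = rnorm(500, 0.001, 0.002))
  expect_equal(ceac(inc, 0)$probability, mean(inc$delta_cost < 0))

  # non-decreasing in lambda when all effects are non-negative
  inc$delta_effect <- abs(inc$delta_effect)
  curve <- ceac(inc, seq(0, 5e4, by = 5000))
  expect_true(all(diff(curve$probability) >= 0))

  expect_error(ceac(data.frame(delta_cost = numeric(0),
                               delta_effect = numeric(0))), "non-empty")
})

test_that("CE summaries compute incrementals from per-arm means", {
  per_arm <- data.frame(arm = c("invited", "non_invited"),
                        cost = c(98.42, 35.03),
                        life_years = c(3.819, 3.816))
  ce <- ce_result(per_arm)
  expect_equal(ce$delta_cost, 63.39, tolerance = 1e-12)
  expect_equal(ce$delta_life_years, 0.003, tolerance = 1e-9)

  same <- data.frame(arm = c("invited", "non_invited"),
                     cost = c(12, 12), life_years = c(3, 3), qalys = c(2, 2))
  ce0 <- ce_result(same)
  expect_identical(ce0$delta_cost, 0)
  expect_identical(ce0$delta_qalys, 0)
  expect_equal(ce0$icer$classification, "undefined")
})
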