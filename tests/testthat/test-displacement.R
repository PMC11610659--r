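# Step-pair construction, the displacement-decay model and the
# disturbance-distance derivation.

test_that("step pairs follow the retention geometry", {
  # fixes at (0,0),(0,100),(0,400); event 30 min after the second fix,
  # centroid 1 km away
  fx <- hand_fixes(cbind(0, c(0, 100, 400)))
  ev <- data.frame(event_id = "E1",
                   timestamp = fx$timestamp[2] + 1800,
                   field_id = "P1", centroid_x = 1000, centroid_y = 100,
                   n_shots = 1L, n_killed = 0L)
  pr <- suppressMessages(build_step_pairs(fx, ev))
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$sl_t, 300)
  expect_equal(pr$sl_t_minus_1, 100)
  expect_equal(pr$delta_sl, 200)
  expect_equal(pr$dist_to_event, sqrt(1000^2 + 0))

  # prior fix at 5 km -> excluded by the 4 km rule
  ev_far <- ev; ev_far$centroid_x <- 5000
  expect_equal(nrow(suppressMessages(build_step_pairs(fx, ev_far))), 0L)

  # prior fix 90 min before the event -> excluded by the 1 h rule
  ev_late <- ev; ev_late$timestamp <- fx$timestamp[2] + 90 * 60
  # (the fix after the prior one becomes the prior fix; push it out too)
  fx2 <- fx[c(1, 2), ]
  expect_equal(nrow(suppressMessages(build_step_pairs(fx2, ev_late))), 0L)
})

test_that("simultaneous events keep only the nearest; pairs need 3 fixes", {
  fx <- hand_fixes(cbind(0, c(0, 100, 400)))
  ev <- data.frame(event_id = c("E1", "E2"),
                   timestamp = rep(fx$timestamp[2] + 1800, 2),
                   field_id = c("P1", "P2"),
                   centroid_x = c(2000, 500), centroid_y = 100,
                   n_shots = 1L, n_killed = 0L)
  pr <- suppressMessages(build_step_pairs(fx, ev))
  expect_equal(nrow(pr), 1L)
  expect_identical(pr$event_id, "E2")      # nearest event wins

  # only two fixes: SL_t exists but no control step -> no pair
  expect_equal(nrow(suppressMessages(build_step_pairs(fx[1:2, ], ev))), 0L)
})

test_that("noiseless pairs recover the line exactly (least-squares oracle)", {
  set.seed(1)
  n <- 120
  d <- exp(runif(n, log(50), log(3000)))
  pairs <- data.frame(individual_id = rep(sprintf("B%d", 1:6), each = n / 6),
                      event_id = sprintf("E%d", seq_len(n)),
                      species = "GBG", winter = "2019-2020",
                      sl_t = 0, sl_t_minus_1 = 0,
                      delta_sl = 1000 - 200 * log(d),
                      dist_to_event = d, event_time_h = runif(n, 8, 16))
  f <- suppressWarnings(suppressMessages(fit_displacement_model(pairs, "GBG")))
  expect_equal(unname(f$coefficients["(Intercept)"]), 1000, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["ln_dist"]), -200, tolerance = 1e-6)

  # oracle: plain least squares on the same design
  ols <- lm(delta_sl ~ log(dist_to_event), pairs)
  expect_equal(unname(f$coefficients["ln_dist"]),
               unname(coef(ols)[2]), tolerance = 1e-6)
})

test_that("threshold derivation matches the analytic root to 1 m", {
  f <- analytic_fit(1711.0, -224.3)
  th <- derive_disturbance_threshold(f)
  expect_identical(th$status, "crossed")
  expect_lt(abs(th$threshold_m - exp(1711.0 / 224.3)), 1)

  # non-negative slope -> sentinel
  expect_identical(derive_disturbance_threshold(analytic_fit(100, 0.5))$status,
                   "never_positive")

  # inflating the covariance pulls the crossing closer
  f2 <- analytic_fit(1711.0, -224.3)
  f2$vcov["(Intercept)", "(Intercept)"] <- 100^2
  th2 <- derive_disturbance_threshold(f2)
  f3 <- f2; f3$vcov["(Intercept)", "(Intercept)"] <- 300^2
  th3 <- derive_disturbance_threshold(f3)
  expect_lt(th2$threshold_m, th$threshold_m)
  expect_lt(th3$threshold_m, th2$threshold_m)
})

test_that("threshold is invariant to shifting all timestamps", {
  st <- simulate_displacement_study("GBG", n_birds = 10, n_events = 60,
                                    seed = 3)
  pr <- suppressMessages(build_step_pairs(st$fixes, st$events))
  f1 <- suppressMessages(fit_displacement_model(pr, "GBG"))
  st$fixes$timestamp <- st$fixes$timestamp + 86400 * 7
  st$events$timestamp <- st$events$timestamp + 86400 * 7
  pr2 <- suppressMessages(build_step_pairs(st$fixes, st$events))
  f2 <- suppressMessages(fit_displacement_model(pr2, "GBG"))
  expect_equal(derive_disturbance_threshold(f1)$threshold_m,
               derive_disturbance_threshold(f2)$threshold_m, tolerance = 1e-6)
})

test_that("self-control design: unperturbed pairs give a null slope", {
  # pairs built from random events at matched distances with no injected
  # perturbation: the ln-distance CI must cover 0
  set.seed(21)
  covered <- 0L
  for (r in 1:20) {
    n <- 150
    d <- exp(runif(n, log(50), log(2000)))
    base <- rgamma(n, 2, 2 / 250)
    prev <- rgamma(n, 2, 2 / 250)
    pairs <- data.frame(individual_id = rep(sprintf("B%d", 1:10), n / 10),
                        event_id = sprintf("E%d", seq_len(n)),
                        species = "GBG", winter = "2019-2020",
                        sl_t = base, sl_t_minus_1 = prev,
                        delta_sl = base - prev, dist_to_event = d,
                        event_time_h = runif(n, 8, 16))
    f <- suppressWarnings(suppressMessages(
      fit_displacement_model(pairs, "GBG")))
    ci <- displacement_coef_table(f)
    b <- ci[ci$term == "ln_dist", ]
    covered <- covered + (b$lwr <= 0 && b$upr >= 0)
  }
  expect_gte(covered / 20, 0.9)
})

test_that("model guards: too few pairs or individuals", {
  pr <- data.frame(individual_id = "B1", species = "GBG", winter = "w",
                   delta_sl = 1, dist_to_event = 100, event_time_h = 10)
  expect_error(fit_displacement_model(pr, "GBG"), "30")
  pr2 <- pr[rep(1, 40), ]
  expect_error(fit_displacement_model(pr2, "GBG"), "individuals")
})
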