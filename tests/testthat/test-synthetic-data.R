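# The synthetic-data generators: landscape structure, track movement,
# displacement injection and accelerometer signal.

test_that("landscape meets its structural invariants and is deterministic", {
  cfg <- sim_config(seed = 1, n_farms = 25L)
  L1 <- generate_landscape(cfg)
  L2 <- generate_landscape(cfg)
  expect_identical(L1, L2)                       # same seed, same landscape

  expect_equal(nrow(L1$farms), 25L)
  expect_setequal(sort(unique(as.vector(L1$habitat$codes))), 1:7)
  expect_gt(sum(vapply(L1$roads, function(r)
    sum(sqrt(diff(r[, 1])^2 + diff(r[, 2])^2)), numeric(1))), 0)

  # farms pairwise disjoint (interiors): no midpoint of one farm inside
  # another
  for (i in seq_len(nrow(L1$farms))) {
    cx <- (L1$farms$xmin[i] + L1$farms$xmax[i]) / 2
    cy <- (L1$farms$ymin[i] + L1$farms$ymax[i]) / 2
    expect_equal(sum(cx >= L1$farms$xmin & cx <= L1$farms$xmax &
                       cy >= L1$farms$ymin & cy <= L1$farms$ymax), 1L)
  }
  # every shooting field lies inside exactly one farm
  sf <- L1$fields[L1$fields$shooting, ]
  owner <- farm_at(L1, (sf$xmin + sf$xmax) / 2, (sf$ymin + sf$ymax) / 2)
  expect_identical(owner, sf$farm_id)
})

test_that("habitat raster hits configured class proportions within 2%", {
  cfg <- sim_config(seed = 3)
  L <- generate_landscape(cfg)
  p <- habitat_proportions(L)
  expect_true(all(abs(p - cfg$habitat_props[names(p)]) <= 0.02))
  expect_gte(p["improved_grassland"], 0.38)
  expect_lte(p["improved_grassland"], 0.42)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(extent_km = 0), "extent")
  expect_error(sim_config(n_farms = 3L), "farms")
  expect_error(sim_config(displacement_slope = c(GBG = 1, GWfG = -1)),
               "negative")
  expect_error(sim_config(shooting_rate = -1), "shooting_rate")
})

test_that("tracks: fix cadence, extent containment and daily-distance target", {
  cfg <- sim_config(seed = 2, n_individuals = c(GBG = 5L, GWfG = 0L),
                    n_winters = 1L, days_per_winter = 20L,
                    fix_interval_min = 60L)
  L <- generate_landscape(cfg)
  tr <- generate_tracks(L, cfg)
  one_day <- tr[tr$individual_id == tr$individual_id[1] &
                  as.Date(tr$timestamp, tz = "UTC") ==
                  as.Date("2019-11-05"), ]
  expect_equal(nrow(one_day), 24L)               # 60-min interval, 1 day
  expect_true(all(diff(as.numeric(one_day$timestamp)) > 0))
  W <- cfg$extent_km * 1000
  expect_true(all(tr$x >= 0 & tr$x <= W & tr$y >= 0 & tr$y <= W))

  # undisturbed mean daytime cumulative distance within 15% of target
  fx <- annotate_fixes(tr, L)
  sm <- daily_distance(fx)
  expect_gt(nrow(sm), 90)                        # ~100 bird-days
  expect_lt(abs(mean(sm$total_distance_km) - 3.14) / 3.14, 0.15)
})

test_that("zero individuals yields an empty track table with a warning", {
  cfg <- sim_config(seed = 1, n_individuals = c(GBG = 0L, GWfG = 0L))
  L <- generate_landscape(cfg)
  expect_warning(tr <- generate_tracks(L, cfg), "zero individuals")
  expect_equal(nrow(tr), 0L)
})

test_that("shooting_rate = 0 produces an empty log and untouched tracks", {
  w <- small_world()
  cfg0 <- small_config(); cfg0$shooting_rate <- 0
  tr <- generate_tracks(w$landscape, cfg0)
  sh <- generate_shooting_log(w$landscape, tr, cfg0)
  expect_equal(nrow(sh$events), 0L)
  expect_identical(sh$tracks, tr)
})

test_that("displacement injection follows the configured decay law", {
  cfg <- sim_config(seed = 9)
  # analytic root of the GBG decay law: expected perturbation 0 there
  root <- exp(-cfg$displacement_intercept[["GBG"]] /
                cfg$displacement_slope[["GBG"]])
  mu_at_root <- cfg$displacement_intercept[["GBG"]] +
    cfg$displacement_slope[["GBG"]] * log(root)
  expect_equal(mu_at_root, 0, tolerance = 1e-10)

  # Monte-Carlo: 500 perturbed steps at 100 m match the closed form
  set.seed(31)
  P <- gooseshot:::displacement_magnitude(rep(100, 500), "GBG", cfg)
  mu <- cfg$displacement_intercept[["GBG"]] +
    cfg$displacement_slope[["GBG"]] * log(100)
  se <- sd(P) / sqrt(length(P))
  expect_lt(abs(mean(P) - mu), 2 * se)
})

test_that("no perturbation beyond the exposure radius; ground truth recorded", {
  w <- small_world()
  expect_true(all(c("event_id", "individual_id", "dist_m",
                    "perturbation_m") %in% names(w$exposures)))
  radius <- w$config$exposure_radius_m[c("GBG", "GWfG")]
  sp <- substr(w$exposures$individual_id, 1, 3)
  sp[sp != "GBG"] <- "GWfG"
  expect_true(all(w$exposures$dist_m <= radius[sp] + 1e-9))
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 77)
  L <- generate_landscape(cfg)
  t1 <- generate_tracks(L, cfg); s1 <- generate_shooting_log(L, t1, cfg)
  t2 <- generate_tracks(L, cfg); s2 <- generate_shooting_log(L, t2, cfg)
  expect_identical(t1, t2)
  expect_identical(s1, s2)
  b1 <- generate_acc_bursts(NULL, c(walking = 20, grazing = 30, alert = 10,
                                    resting = 10, flying = 20), cfg)
  b2 <- generate_acc_bursts(NULL, c(walking = 20, grazing = 30, alert = 10,
                                    resting = 10, flying = 20), cfg)
  expect_identical(b1, b2)
})

test_that("labelled bursts honour configured counts and signal structure", {
  cfg <- small_config(seed = 4)
  counts <- c(walking = 50, grazing = 80, alert = 30, resting = 40,
              flying = 60)
  g <- generate_acc_bursts(NULL, counts, cfg)
  expect_equal(as.vector(table(g$info$label)[names(counts)]),
               as.vector(counts))

  ft <- burst_features(g$bursts)
  med <- tapply(ft$odba, ft$label, median)
  expect_true(med["resting"] < med["grazing"] &
                med["grazing"] < med["walking"] &
                med["walking"] < med["flying"])

  # a class with zero dynamic SD gives ODBA exactly 0
  cfg0 <- cfg
  cfg0$signal_params$dyn_sd[cfg0$signal_params$behavior == "resting"] <- 0
  cfg0$signal_params$dyn_log_sd[cfg0$signal_params$behavior == "resting"] <- 0
  g0 <- generate_acc_bursts(NULL, c(resting = 10), cfg0)
  f0 <- burst_features(g0$bursts)
  expect_true(all(f0$odba < 1e-12))

  expect_error(generate_acc_bursts(NULL, c(swimming = 5), cfg),
               "signal parameters")
})
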