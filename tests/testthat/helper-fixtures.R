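# Shared small fixtures, built once per test run.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_individuals = c(GBG = 3L, GWfG = 3L),
             n_winters = 1L, days_per_winter = 12L,
             shooting_rate = 2, ...)
}

.fix_env <- new.env()

small_world <- function() {
  if (is.null(.fix_env$world)) {
    cfg <- small_config()
    L <- generate_landscape(cfg)
    tr <- generate_tracks(L, cfg)
    sh <- generate_shooting_log(L, tr, cfg)
    fx <- suppressWarnings(annotate_fixes(resample_hourly(sh$tracks), L))
    .fix_env$world <- list(config = cfg, landscape = L, tracks = sh$tracks,
                           events = sh$events, exposures = sh$exposures,
                           fixes = fx)
  }
  .fix_env$world
}

# hand-built hourly fixes along given coordinates for one bird
hand_fixes <- function(xy, start = "2019-12-01 09:00:00", species = "GBG",
                       id = "B1", by_s = 3600) {
  n <- nrow(xy)
  data.frame(individual_id = id, species = species, sex = "F",
             timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_s,
             x = xy[, 1], y = xy[, 2])
}

# zero-covariance displacement fit for analytic threshold checks
analytic_fit <- function(a, b) {
  nm <- c("(Intercept)", "ln_dist", "time_c", "I(time_c^2)")
  structure(list(coefficients = stats::setNames(c(a, b, 0, 0), nm),
                 vcov = matrix(0, 4, 4, dimnames = list(nm, nm)),
                 species = "GBG", n_pairs = 0L, winter_effect = "none",
                 time_center = 12),
            class = "displacement_fit")
}
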