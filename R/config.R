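#' The seven-class habitat scheme
#'
#' Integer codes 1..7 with the class labels used throughout the package.
#' @export
habitat_classes <- function() {
  c("improved_grassland", "other_grassland", "arable",
    "saltmarsh_coastal", "bog", "freshwater", "other")
}

#' Default per-behaviour accelerometer signal parameters
#'
#' Each row gives the burst-level signal model for one behaviour: the
#' static (postural) mean acceleration per axis in g, the within-burst
#' dynamic standard deviation in g, the between-burst standard deviation
#' of the postural means, and the log-scale spread of the per-burst
#' dynamic-SD multiplier. Flight has by far the largest dynamic
#' component (wing-beat), grazing a rhythmic head-down signal, alert a
#' head-up posture close to resting — the hard pair for any classifier.
#'
#' @return data.frame keyed by `behavior`.
#' @export
default_signal_params <- function() {
  data.frame(
    behavior     = c("walking", "grazing", "alert", "resting", "flying"),
    mean_x       = c(-0.10, -0.35, 0.20, 0.00, 0.05),
    mean_y       = c( 0.00,  0.05, 0.00, 0.00, 0.00),
    mean_z       = c( 0.95,  0.90, 0.98, 1.00, 1.00),
    dyn_sd       = c( 0.25,  0.12, 0.05, 0.02, 0.80),
    posture_sd   = c( 0.06,  0.06, 0.06, 0.06, 0.10),
    dyn_log_sd   = c( 0.20,  0.20, 0.25, 0.25, 0.20),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' set to the study conditions of the analyses the package implements:
#' two goose species wintering on a farmed island, hourly-capable GPS
#' fixes, shooting restricted to designated fields in daylight, and a
#' displacement response that decays with the natural log of distance to
#' the shooting field centroid.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   output byte-identical.
#' @param n_individuals named count of tagged birds per species
#'   (defaults: 33 GBG, 94 GWfG).
#' @param n_winters number of winters to simulate.
#' @param start_year calendar year in which the first winter begins.
#' @param days_per_winter days simulated from 1 November each winter.
#' @param fix_interval_min GPS fix interval in minutes (sub-hourly so
#'   that resampling to the 1-h analysis scale is exercised).
#' @param extent_km side of the square landscape in km.
#' @param n_farms number of farm polygons tiling the farmland block.
#' @param habitat_res_m habitat raster resolution in metres.
#' @param habitat_props named numeric, proportions of the seven habitat
#'   classes (must sum to 1).
#' @param shooting_field_frac fraction of fields designated for shooting.
#' @param n_roosts number of communal roost sites.
#' @param displacement_intercept named per-species intercept of the
#'   displacement-decay law, metres.
#' @param displacement_slope named per-species slope on ln(distance m),
#'   metres per log-metre; must be negative.
#' @param displacement_noise_sd SD of the noise added to the displacement
#'   magnitude before flooring at zero, metres.
#' @param exposure_radius_m named per-species radius within which a bird
#'   responds to a shooting event; `NULL` means the analytic zero of the
#'   decay law, `exp(-intercept/slope)`.
#' @param shooting_rate mean shooting events per day across the
#'   landscape (Poisson).
#' @param step_shape gamma shape of undisturbed hourly step lengths.
#' @param daily_distance_km named per-species target mean undisturbed
#'   daytime cumulative distance, km.
#' @param roost_jitter_m SD of night-time scatter around the roost.
#' @param signal_params per-behaviour accelerometer signal parameters,
#'   see [default_signal_params()].
#' @param burst_n_samples accelerometer samples per burst and axis.
#' @param bursts_per_hour mean accelerometer bursts recorded per hour.
#' @param behavior_effects logit-scale shifts applied on shooting-disturbed
#'   days: `grazing_day` on daytime grazing, `flying_night` on night
#'   flight after a disturbed day.
#' @param site_lat,site_lon coordinates used for solar day/night.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = c(GBG = 33L, GWfG = 94L),
                       n_winters = 2L,
                       start_year = 2019L,
                       days_per_winter = 120L,
                       fix_interval_min = 30L,
                       extent_km = 10,
                       n_farms = 25L,
                       habitat_res_m = 50,
                       habitat_props = c(improved_grassland = 0.40,
                                         other_grassland = 0.15,
                                         arable = 0.12,
                                         saltmarsh_coastal = 0.10,
                                         bog = 0.12,
                                         freshwater = 0.06,
                                         other = 0.05),
                       shooting_field_frac = 0.3,
                       n_roosts = 3L,
                       displacement_intercept = c(GBG = 1711.0, GWfG = 630.6),
                       displacement_slope = c(GBG = -224.3, GWfG = -90.0),
                       displacement_noise_sd = 50,
                       exposure_radius_m = NULL,
                       shooting_rate = 1.5,
                       step_shape = 2,
                       daily_distance_km = c(GBG = 3.14, GWfG = 2.38),
                       roost_jitter_m = 30,
                       signal_params = default_signal_params(),
                       burst_n_samples = 40L,
                       bursts_per_hour = 1.5,
                       behavior_effects = c(grazing_day = -0.073,
                                            flying_night = 0.089),
                       site_lat = 55.75,
                       site_lon = -6.25) {
  if (extent_km <= 0) stop("degenerate extent: extent_km must be > 0")
  if (n_farms < 4L) stop("need at least 4 farms")
  if (abs(sum(habitat_props) - 1) > 1e-8)
    stop("habitat_props must sum to 1")
  if (!all(names(habitat_props) %in% habitat_classes()))
    stop("habitat_props names must be drawn from habitat_classes()")
  if (any(displacement_slope >= 0))
    stop("displacement_slope must be negative for every species")
  if (shooting_rate < 0) stop("shooting_rate must be >= 0")
  req <- c("walking", "grazing", "alert", "resting", "flying")
  if (!all(req %in% signal_params$behavior))
    stop("signal_params must define all five behaviour classes: ",
         paste(setdiff(req, signal_params$behavior), collapse = ", "))
  if (is.null(exposure_radius_m))
    exposure_radius_m <- exp(-displacement_intercept / displacement_slope)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|",
      sum(x$n_individuals), "birds,", x$n_winters, "winter(s),",
      x$days_per_winter, "days each |",
      x$extent_km, "km extent,", x$n_farms, "farms\n")
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Scalar fields in the file override the [sim_config()] defaults; named
#' vectors (e.g. `displacement_intercept`) are given as mappings.
#'
#' @param path file ending in .yml/.yaml/.json.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  do.call(sim_config, raw)
}
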