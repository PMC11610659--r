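# Synthetic goose biologging data. The generators reproduce the
# statistical structure the downstream analyses assume -- roost-forage
# daily movement on a farmed landscape, shooting events on designated
# fields with a displacement response that decays with log distance,
# and behaviour-dependent tri-axial accelerometer signal -- so the whole
# pipeline is testable without access to restricted tracking data.

winter_start_date <- function(year) as.Date(sprintf("%d-11-01", year))

#' Simulate GPS tracks for all individuals
#'
#' Movement follows a roost-forage template: each bird holds a communal
#' roost and a home farm per winter; positions are generated at hourly
#' "nodes" (night nodes scatter around the roost, day nodes perform a
#' gamma-step random walk inside the home farm) and sub-hourly fixes are
#' interpolated along the node segments at the configured fix interval.
#' Hourly step lengths are gamma distributed with the mean calibrated so
#' that mean undisturbed daytime cumulative distance matches the
#' configured per-species target.
#'
#' @param landscape a [generate_landscape()] result.
#' @param config the [sim_config()] used to build the landscape.
#' @return data.frame of fixes: `individual_id`, `species`, `sex`,
#'   `timestamp` (POSIXct UTC), `x`, `y` (m), sorted by individual and
#'   time, with strictly increasing timestamps per individual.
#' @export
generate_tracks <- function(landscape, config = sim_config()) {
  stopifnot(inherits(landscape, "landscape"))
  set.seed(config$seed + 1L)
  n_ind <- config$n_individuals
  if (sum(n_ind) == 0) {
    warning("zero individuals configured: returning empty track table")
    return(empty_fixes())
  }
  birds <- data.frame(
    individual_id = sprintf("%s%03d",
                            rep(names(n_ind), n_ind),
                            unlist(lapply(n_ind, seq_len))),
    species = rep(names(n_ind), n_ind),
    sex = NA_character_, stringsAsFactors = FALSE)
  birds$sex <- sample(c("M", "F"), nrow(birds), replace = TRUE)

  winters <- config$start_year + seq_len(config$n_winters) - 1L
  per_hour <- 60L %/% config$fix_interval_min
  out <- vector("list", nrow(birds) * length(winters))
  k <- 0L
  for (w in winters) {
    dates <- winter_start_date(w) + seq_len(config$days_per_winter) - 1L
    node_times <- as.POSIXct(as.character(rep(dates, each = 24)),
                             tz = "UTC") + rep(3600 * (0:23), length(dates))
    day_node <- is_daylight(node_times, config$site_lat, config$site_lon)
    n_day_steps <- mean(tapply(day_node, rep(seq_along(dates), each = 24),
                               function(z) max(0, sum(z) - 1)))
    for (b in seq_len(nrow(birds))) {
      k <- k + 1L
      target <- config$daily_distance_km[[birds$species[b]]] * 1000
      step_mean <- target / max(1, n_day_steps)
      roost <- landscape$roosts[sample(nrow(landscape$roosts), 1), ]
      farm <- landscape$farms[sample(nrow(landscape$farms), 1), ]
      nodes <- simulate_node_path(node_times, day_node, roost, farm,
                                  step_mean, config)
      fx <- interpolate_fixes(nodes, per_hour)
      fx$individual_id <- birds$individual_id[b]
      fx$species <- birds$species[b]
      fx$sex <- birds$sex[b]
      out[[k]] <- fx
    }
  }
  fixes <- do.call(rbind, out)
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp),
                 c("individual_id", "species", "sex", "timestamp", "x", "y")]
  rownames(fixes) <- NULL
  fixes
}

empty_fixes <- function() {
  data.frame(individual_id = character(), species = character(),
             sex = character(),
             timestamp = as.POSIXct(character(), tz = "UTC"),
             x = numeric(), y = numeric())
}

simulate_node_path <- function(node_times, day_node, roost, farm,
                               step_mean, config) {
  n <- length(node_times)
  x <- numeric(n); y <- numeric(n)
  cx <- (farm$xmin + farm$xmax) / 2
  cy <- (farm$ymin + farm$ymax) / 2
  px <- cx; py <- cy
  for (i in seq_len(n)) {
    if (!day_node[i]) {
      x[i] <- roost$x + stats::rnorm(1, 0, config$roost_jitter_m)
      y[i] <- roost$y + stats::rnorm(1, 0, config$roost_jitter_m)
    } else {
      if (i == 1 || !day_node[i - 1]) {
        # morning arrival on the home farm
        px <- stats::runif(1, farm$xmin, farm$xmax)
        py <- stats::runif(1, farm$ymin, farm$ymax)
      } else {
        len <- stats::rgamma(1, shape = config$step_shape,
                             rate = config$step_shape / step_mean)
        # re-draw the heading until the step stays on the farm, so the
        # realised fix-to-fix distance equals the drawn step length
        for (try in 1:20) {
          ang <- stats::runif(1, 0, 2 * pi)
          nx <- px + len * cos(ang); ny <- py + len * sin(ang)
          if (nx >= farm$xmin && nx <= farm$xmax &&
              ny >= farm$ymin && ny <= farm$ymax) break
        }
        px <- reflect_into(nx, farm$xmin, farm$xmax)
        py <- reflect_into(ny, farm$ymin, farm$ymax)
      }
      x[i] <- px; y[i] <- py
    }
  }
  data.frame(timestamp = node_times, x = x, y = y)
}

interpolate_fixes <- function(nodes, per_hour) {
  if (per_hour <= 1L) return(nodes)
  n <- nrow(nodes)
  fr <- seq(0, 1 - 1 / per_hour, by = 1 / per_hour)
  i <- rep(seq_len(n - 1), each = per_hour)
  f <- rep(fr, n - 1)
  data.frame(
    timestamp = nodes$timestamp[i] + f * 3600,
    x = nodes$x[i] + f * (nodes$x[i + 1] - nodes$x[i]),
    y = nodes$y[i] + f * (nodes$y[i + 1] - nodes$y[i]))
}

# Displacement magnitude injected on the exposed step: the decay law
# plus noise, floored at zero (a flight response cannot be negative).
displacement_magnitude <- function(dist_m, species, config) {
  a <- config$displacement_intercept[[species]]
  b <- config$displacement_slope[[species]]
  mu <- a + b * log(pmax(dist_m, 1))
  pmax(0, mu + stats::rnorm(length(dist_m), 0, config$displacement_noise_sd))
}

#' Simulate a shooting log and inject displacement responses
#'
#' Draws Poisson-distributed shooting events on the designated shooting
#' fields during daylight and perturbs every bird that holds a fix
#' within the species exposure radius of the event field centroid in the
#' hour before the event: on its next hourly node the bird travels its
#' planned step plus a displacement `max(0, a + b*ln(dist) + noise)`
#' along the bearing away from the event, so the expected step-length
#' difference of exposed steps follows the configured decay law.
#'
#' @param landscape a [generate_landscape()] result.
#' @param tracks fix table from [generate_tracks()].
#' @param config the [sim_config()].
#' @return list with `events` (the shooting log: `event_id`, `timestamp`,
#'   `field_id`, `centroid_x/y`, `n_shots`, `n_killed`), `tracks` (fix
#'   table with perturbations applied) and `exposures` (ground-truth
#'   table of perturbed bird-events with the distance and injected
#'   displacement).
#' @export
generate_shooting_log <- function(landscape, tracks, config = sim_config()) {
  set.seed(config$seed + 2L)
  empty_events <- data.frame(
    event_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    field_id = character(), centroid_x = numeric(), centroid_y = numeric(),
    n_shots = integer(), n_killed = integer())
  empty_exp <- data.frame(event_id = character(), individual_id = character(),
                          dist_m = numeric(), perturbation_m = numeric())
  if (config$shooting_rate == 0 || nrow(tracks) == 0) {
    return(list(events = empty_events, tracks = tracks, exposures = empty_exp))
  }
  shoot_fields <- landscape$fields[landscape$fields$shooting, ]
  dates <- sort(unique(as.Date(tracks$timestamp, tz = "UTC")))
  ev <- list()
  for (d in as.character(dates)) {
    n_ev <- stats::rpois(1, config$shooting_rate)
    if (n_ev == 0) next
    # candidate daylight hours (events happen during the working day)
    hrs <- 0:23
    tt <- as.POSIXct(d, tz = "UTC") + hrs * 3600
    day_hrs <- hrs[is_daylight(tt, config$site_lat, config$site_lon)]
    if (!length(day_hrs)) next
    for (j in seq_len(n_ev)) {
      f <- shoot_fields[sample(nrow(shoot_fields), 1), ]
      tm <- as.POSIXct(d, tz = "UTC") +
        sample(day_hrs, 1) * 3600 + round(stats::runif(1, 5, 55)) * 60
      n_shots <- 1L + stats::rpois(1, 3)
      ev[[length(ev) + 1L]] <- data.frame(
        timestamp = tm, field_id = f$id,
        centroid_x = (f$xmin + f$xmax) / 2, centroid_y = (f$ymin + f$ymax) / 2,
        n_shots = n_shots, n_killed = stats::rbinom(1, n_shots, 0.15))
    }
  }
  if (!length(ev)) {
    return(list(events = empty_events, tracks = tracks, exposures = empty_exp))
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$timestamp), ]
  events <- cbind(event_id = sprintf("E%04d", seq_len(nrow(events))), events)
  rownames(events) <- NULL

  pert <- apply_displacements(tracks, events, config)
  list(events = events, tracks = pert$tracks, exposures = pert$exposures)
}

# Perturb the node following each event for every exposed bird, and
# re-interpolate the sub-hourly fixes of the two affected segments.
apply_displacements <- function(tracks, events, config) {
  tracks <- tracks[order(tracks$individual_id, tracks$timestamp), ]
  rownames(tracks) <- NULL
  is_node <- as.POSIXlt(tracks$timestamp, tz = "UTC")$min == 0 &
    as.POSIXlt(tracks$timestamp, tz = "UTC")$sec == 0
  expo <- list()
  for (e in seq_len(nrow(events))) {
    t_ev <- events$timestamp[e]
    cx <- events$centroid_x[e]; cy <- events$centroid_y[e]
    # last node strictly before the event, within the preceding hour
    cand <- which(is_node & tracks$timestamp < t_ev &
                    tracks$timestamp >= t_ev - 3600)
    if (!length(cand)) next
    prior <- cand[!duplicated(tracks$individual_id[cand], fromLast = TRUE)]
    d <- euclid(tracks$x[prior], tracks$y[prior], cx, cy)
    radius <- config$exposure_radius_m[as.character(tracks$species[prior])]
    hit <- which(d <= radius)
    for (h in hit) {
      i <- prior[h]
      bird_rows <- which(tracks$individual_id == tracks$individual_id[i])
      nxt <- bird_rows[is_node[bird_rows] &
                         tracks$timestamp[bird_rows] > tracks$timestamp[i]]
      if (!length(nxt)) next
      j <- nxt[1]
      sp <- as.character(tracks$species[i])
      P <- displacement_magnitude(d[h], sp, config)
      base <- euclid(tracks$x[i], tracks$y[i], tracks$x[j], tracks$y[j])
      if (d[h] > 0) {
        ux <- (tracks$x[i] - cx) / d[h]; uy <- (tracks$y[i] - cy) / d[h]
      } else {
        ang <- stats::runif(1, 0, 2 * pi); ux <- cos(ang); uy <- sin(ang)
      }
      W <- config$extent_km * 1000
      tracks$x[j] <- reflect_into(tracks$x[i] + (base + P) * ux, 0, W)
      tracks$y[j] <- reflect_into(tracks$y[i] + (base + P) * uy, 0, W)
      # re-interpolate sub-hourly fixes around the displaced node
      for (seg in list(c(i, j), c(j, j + 1L))) {
        a <- seg[1]; b <- seg[2]
        if (!(b %in% bird_rows)) next
        mid <- bird_rows[tracks$timestamp[bird_rows] > tracks$timestamp[a] &
                           tracks$timestamp[bird_rows] < tracks$timestamp[b]]
        if (length(mid)) {
          f <- as.numeric(tracks$timestamp[mid] - tracks$timestamp[a],
                          units = "secs") /
            as.numeric(tracks$timestamp[b] - tracks$timestamp[a],
                       units = "secs")
          tracks$x[mid] <- tracks$x[a] + f * (tracks$x[b] - tracks$x[a])
          tracks$y[mid] <- tracks$y[a] + f * (tracks$y[b] - tracks$y[a])
        }
      }
      expo[[length(expo) + 1L]] <- data.frame(
        event_id = events$event_id[e],
        individual_id = tracks$individual_id[i],
        dist_m = d[h], perturbation_m = P)
    }
  }
  exposures <- if (length(expo)) do.call(rbind, expo) else
    data.frame(event_id = character(), individual_id = character(),
               dist_m = numeric(), perturbation_m = numeric())
  list(tracks = tracks, exposures = exposures)
}

#' Simulate a focused displacement study
#'
#' Generates the minimal tracking dataset for displacement-recovery
#' experiments: `n_events` shooting events, each exposing a random
#' subset of `n_birds` birds whose distances to the event centroid are
#' log-uniform between `min_dist_m` and the species exposure radius.
#' Each exposed bird contributes three consecutive hourly fixes (so both
#' the control and the exposed step exist) and the exposed step carries
#' the displacement perturbation of [generate_shooting_log()].
#'
#' @param species `"GBG"` or `"GWfG"` (selects decay-law truth and the
#'   winter structure: two winters for GBG, four for GWfG).
#' @param n_birds,n_events study size.
#' @param expose_prob probability a given bird is exposed to an event.
#' @param min_dist_m closest simulated bird-event distance.
#' @param base_step_mean,ind_sd mean undisturbed hourly step (m) and SD
#'   of per-individual displacement intercepts (m).
#' @param config a [sim_config()] holding the decay-law truth.
#' @param seed RNG seed.
#' @return list with `fixes`, `events` ready for [build_step_pairs()],
#'   and `truth` (the generator's intercept/slope).
#' @export
simulate_displacement_study <- function(species = "GBG", n_birds = 30,
                                        n_events = 200, expose_prob = 0.5,
                                        min_dist_m = 30,
                                        base_step_mean = 250, ind_sd = 50,
                                        config = sim_config(), seed = 1L) {
  set.seed(seed)
  radius <- config$exposure_radius_m[[species]]
  n_w <- if (species == "GBG") 2L else 4L
  winters <- config$start_year + seq_len(n_w) - 1L
  bird_ids <- sprintf("%s%03d", species, seq_len(n_birds))
  bird_re <- stats::rnorm(n_birds, 0, ind_sd)
  fixes <- list(); events <- list()
  for (e in seq_len(n_events)) {
    w <- winters[1 + (e - 1) %% n_w]
    day <- winter_start_date(w) + ((e - 1) %/% n_w) %% 150
    hr <- sample(8:15, 1)
    t_ev <- as.POSIXct(paste(day, sprintf("%02d:30:00", hr)), tz = "UTC")
    cx <- stats::runif(1, 2e4, 3e4); cy <- stats::runif(1, 2e4, 3e4)
    events[[e]] <- data.frame(
      event_id = sprintf("E%04d", e), timestamp = t_ev,
      field_id = sprintf("P%03d", 1 + e %% 50),
      centroid_x = cx, centroid_y = cy, n_shots = 2L, n_killed = 0L)
    exposed <- which(stats::runif(n_birds) < expose_prob)
    if (!length(exposed)) next
    d <- exp(stats::runif(length(exposed), log(min_dist_m), log(radius)))
    th <- stats::runif(length(exposed), 0, 2 * pi)
    x1 <- cx + d * cos(th); y1 <- cy + d * sin(th)       # fix at exposure
    s_prev <- stats::rgamma(length(exposed), config$step_shape,
                            config$step_shape / base_step_mean)
    a_prev <- stats::runif(length(exposed), 0, 2 * pi)
    x0 <- x1 - s_prev * cos(a_prev); y0 <- y1 - s_prev * sin(a_prev)
    P <- displacement_magnitude(d, species, config) + bird_re[exposed]
    s_next <- stats::rgamma(length(exposed), config$step_shape,
                            config$step_shape / base_step_mean)
    x2 <- x1 + (s_next + P) * cos(th); y2 <- y1 + (s_next + P) * sin(th)
    t1 <- t_ev - 1800                                     # 30 min pre-event
    fixes[[e]] <- data.frame(
      individual_id = rep(bird_ids[exposed], 3),
      species = species,
      sex = "F",
      timestamp = rep(c(t1 - 3600, t1, t1 + 3600), each = length(exposed)),
      x = c(x0, x1, x2), y = c(y0, y1, y2))
  }
  fixes <- do.call(rbind, fixes)
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), ]
  rownames(fixes) <- NULL
  list(fixes = fixes, events = do.call(rbind, events),
       truth = c(intercept = config$displacement_intercept[[species]],
                 slope = config$displacement_slope[[species]]))
}

#' Simulate labelled accelerometer bursts
#'
#' With `tracks = NULL`, generates a standalone labelled training set
#' with exactly the class counts in `behavior_schedule` (defaults: the
#' video-validated library sizes of the analyses this package
#' reimplements). With a fix table, generates bursts along each bird's
#' track with behaviour drawn from day/night context; if
#' `behavior_schedule` is a data.frame of disturbed goose-days
#' (`individual_id`, `date`, `disturbed`), the configured logit-scale
#' behavioural effects of disturbance are injected.
#'
#' @param tracks `NULL` or a fix table.
#' @param behavior_schedule named class counts (standalone mode) or a
#'   disturbed-day table (track mode).
#' @param config a [sim_config()].
#' @return list with `bursts` (long-format samples: `burst_id`,
#'   `individual_id`, `timestamp`, `label`, `sample_id`, `ax`, `ay`,
#'   `az`) and `info` (one row per burst).
#' @export
generate_acc_bursts <- function(tracks = NULL,
                                behavior_schedule = c(walking = 376,
                                                      grazing = 1689,
                                                      alert = 472,
                                                      resting = 287,
                                                      flying = 1753),
                                config = sim_config()) {
  set.seed(config$seed + 3L)
  sp <- config$signal_params
  if (is.null(tracks)) {
    counts <- behavior_schedule
    missing <- setdiff(names(counts), sp$behavior)
    if (length(missing))
      stop("no signal parameters for class(es): ",
           paste(missing, collapse = ", "))
    labels <- rep(names(counts), counts)
    info <- data.frame(
      burst_id = sprintf("B%05d", seq_along(labels)),
      individual_id = sprintf("GWfG%03d", 1 + (seq_along(labels) %% 8)),
      timestamp = as.POSIXct("2019-12-01 10:00:00", tz = "UTC") +
        3600 * seq_along(labels),
      label = labels, stringsAsFactors = FALSE)
  } else {
    info <- schedule_track_bursts(tracks, behavior_schedule, config)
  }
  samples <- synthesize_burst_signal(info, sp, config$burst_n_samples)
  list(bursts = samples, info = info)
}

schedule_track_bursts <- function(tracks, disturbed_days, config) {
  tr <- tracks[order(tracks$individual_id, tracks$timestamp), ]
  lt <- as.POSIXlt(tr$timestamp, tz = "UTC")
  node <- lt$min == 0 & lt$sec == 0
  tr <- tr[node, ]
  # one candidate burst per hourly node, thinned to the configured rate
  keep <- stats::runif(nrow(tr)) < min(1, config$bursts_per_hour)
  tr <- tr[keep, ]
  day <- is_daylight(tr$timestamp, config$site_lat, config$site_lon)
  date <- as.Date(tr$timestamp, tz = "UTC")
  # a night belongs to the preceding day (sunset -> sunrise)
  night_date <- date - as.integer(!day & as.POSIXlt(tr$timestamp)$hour < 12)
  eff_date <- ifelse(day, as.character(date), as.character(night_date))
  disturbed <- rep(FALSE, nrow(tr))
  if (is.data.frame(disturbed_days) && nrow(disturbed_days)) {
    key <- paste(disturbed_days$individual_id, disturbed_days$date)
    disturbed <- paste(tr$individual_id, eff_date) %in%
      key[disturbed_days$disturbed]
  }
  probs_day <- c(walking = 0.12, grazing = 0.50, alert = 0.15,
                 resting = 0.13, flying = 0.10)
  probs_night <- c(walking = 0.055, grazing = 0.02, alert = 0.09,
                   resting = 0.783, flying = 0.052)
  lab <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    p <- if (day[i]) probs_day else probs_night
    if (disturbed[i] && day[i]) {
      p["grazing"] <- stats::plogis(stats::qlogis(p["grazing"]) +
                                      config$behavior_effects[["grazing_day"]])
    }
    if (disturbed[i] && !day[i]) {
      p["flying"] <- stats::plogis(stats::qlogis(p["flying"]) +
                                     config$behavior_effects[["flying_night"]])
    }
    lab[i] <- sample(names(p), 1, prob = p / sum(p))
  }
  data.frame(burst_id = sprintf("B%05d", seq_len(nrow(tr))),
             individual_id = tr$individual_id, timestamp = tr$timestamp,
             label = lab, stringsAsFactors = FALSE)
}

synthesize_burst_signal <- function(info, sp, n_samples) {
  rows <- match(info$label, sp$behavior)
  nb <- nrow(info)
  mx <- sp$mean_x[rows] + stats::rnorm(nb, 0, sp$posture_sd[rows])
  my <- sp$mean_y[rows] + stats::rnorm(nb, 0, sp$posture_sd[rows])
  mz <- sp$mean_z[rows] + stats::rnorm(nb, 0, sp$posture_sd[rows])
  sd_b <- sp$dyn_sd[rows] * exp(stats::rnorm(nb, 0, sp$dyn_log_sd[rows]))
  idx <- rep(seq_len(nb), each = n_samples)
  data.frame(
    burst_id = info$burst_id[idx],
    individual_id = info$individual_id[idx],
    timestamp = info$timestamp[idx],
    label = info$label[idx],
    sample_id = rep(seq_len(n_samples), nb),
    ax = stats::rnorm(nb * n_samples, mx[idx], sd_b[idx]),
    ay = stats::rnorm(nb * n_samples, my[idx], sd_b[idx]),
    az = stats::rnorm(nb * n_samples, mz[idx], sd_b[idx]),
    stringsAsFactors = FALSE)
}

#' Simulate goose-day travel distances for model recovery
#'
#' Gamma-distributed total daily distances on a log-scale linear
#' predictor with individual random intercepts and an AR1 day-to-day
#' latent process, shooting-disturbed days drawn at a daily rate --
#' the structure assumed by [fit_distance_model()].
#'
#' @param n_ind individuals; `days_per_ind` consecutive days each.
#' @param mean_undisturbed,mean_disturbed true marginal mean daily
#'   distances (km) at reference random-effect level.
#' @param p_disturbed daily probability of shooting disturbance.
#' @param shape gamma shape (residual day-to-day noise).
#' @param rho AR1 correlation of the latent daily process.
#' @param ar_sd SD of the latent AR1 process on the log scale.
#' @param ind_sd SD of individual random intercepts (log scale).
#' @param exp_slope optional log-scale slope on scaled cumulative
#'   experience for undisturbed days (0 = none).
#' @param seed RNG seed.
#' @return data.frame shaped like [daily_distance()] output plus the
#'   true disturbance flags.
#' @export
simulate_goose_days <- function(n_ind = 127, days_per_ind = 40,
                                mean_undisturbed = 3.14,
                                mean_disturbed = 4.32,
                                p_disturbed = 0.09,
                                shape = 8, rho = 0.3, ar_sd = 0.10,
                                ind_sd = 0.15, exp_slope = 0, seed = 1L) {
  set.seed(seed)
  n <- n_ind * days_per_ind
  id <- rep(seq_len(n_ind), each = days_per_ind)
  day <- rep(seq_len(days_per_ind), n_ind)
  u <- stats::rnorm(n_ind, 0, ind_sd)
  lat <- unlist(lapply(seq_len(n_ind), function(i) {
    x <- numeric(days_per_ind)
    x[1] <- stats::rnorm(1)
    for (t in seq_len(days_per_ind)[-1])
      x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, sqrt(1 - rho^2))
    x
  }))
  disturbed <- stats::rbinom(n, 1, p_disturbed) == 1
  expc <- stats::ave(as.integer(disturbed), id, FUN = cumsum)
  exp_scaled <- as.numeric(scale(expc))
  logmu <- log(mean_undisturbed) +
    log(mean_disturbed / mean_undisturbed) * disturbed +
    exp_slope * exp_scaled * (!disturbed) +
    u[id] + ar_sd * lat
  td <- stats::rgamma(n, shape, shape / exp(logmu))
  data.frame(
    individual_id = sprintf("S%03d", id),
    species = "GBG", sex = rep(c("F", "M"), length.out = n_ind)[id],
    winter = "2019-2020",
    date = winter_start_date(2019L) + day - 1L,
    date_index = day, n_fixes = 10L,
    total_distance_km = td,
    modal_farm_id = sprintf("F%02d", 1 + id %% 20),
    disturbed = disturbed,
    disturbance_class = ifelse(disturbed, "nearby", "undisturbed"),
    exp_scaled = exp_scaled)
}

#' Simulate day/night activity-budget counts
#'
#' Beta-binomial behaviour counts on a logit-scale linear predictor
#' with disturbance, night, and their interaction -- the structure
#' assumed by [fit_budget_model()].
#'
#' @param n_ind,days_per_ind panel size.
#' @param base_p baseline behaviour proportion (day, undisturbed).
#' @param beta_shot,beta_night,beta_interaction logit-scale effects.
#' @param theta beta-binomial dispersion (larger = closer to binomial).
#' @param n_bursts bursts per goose-day/night.
#' @param p_disturbed probability a day is shooting-disturbed.
#' @param ind_sd individual random-intercept SD (logit scale).
#' @param seed RNG seed.
#' @return data.frame of budgets usable by [fit_budget_model()].
#' @export
simulate_budget_counts <- function(n_ind = 30, days_per_ind = 40,
                                   base_p = 0.446, beta_shot = -0.073,
                                   beta_night = -0.5, beta_interaction = 0,
                                   theta = 30, n_bursts = 15,
                                   p_disturbed = 0.15, ind_sd = 0.2,
                                   seed = 1L) {
  set.seed(seed)
  n <- n_ind * days_per_ind * 2L
  id <- rep(seq_len(n_ind), each = days_per_ind * 2L)
  day <- rep(rep(seq_len(days_per_ind), each = 2L), n_ind)
  night <- rep(c(FALSE, TRUE), n_ind * days_per_ind)
  u <- stats::rnorm(n_ind, 0, ind_sd)
  disturbed <- rep(stats::rbinom(n_ind * days_per_ind, 1, p_disturbed) == 1,
                   each = 2L)
  eta <- stats::qlogis(base_p) + beta_shot * disturbed +
    beta_night * night + beta_interaction * disturbed * night + u[id]
  pi <- stats::plogis(eta)
  p <- stats::rbeta(n, theta * pi, theta * (1 - pi))
  k <- stats::rbinom(n, n_bursts, p)
  data.frame(
    individual_id = sprintf("S%03d", id), winter = "2019-2020",
    date = winter_start_date(2019L) + day - 1L, date_index = day,
    is_night = night, n_bursts = n_bursts, k = k,
    disturbed = disturbed)
}

#' Simulate daily total ODBA for model recovery
#'
#' Gamma-distributed daily ODBA totals with effects of burst count,
#' a quadratic seasonal trend, and optional disturbance effects -- the
#' structure assumed by [fit_odba_model()].
#'
#' @param n_ind,days_per_ind panel size.
#' @param base_odba expected total ODBA (g) at reference levels.
#' @param beta_shot,beta_n,beta_date,beta_date2 log-scale coefficients
#'   (`beta_date`/`beta_date2` act on date index scaled to [0, 1]).
#' @param shape gamma shape.
#' @param ind_sd individual random-intercept SD (log scale).
#' @param p_disturbed probability of a disturbed day.
#' @param seed RNG seed.
#' @return data.frame usable by [fit_odba_model()].
#' @export
simulate_odba_daily <- function(n_ind = 40, days_per_ind = 50,
                                base_odba = 60, beta_shot = 0,
                                beta_n = 0.02, beta_date = 0,
                                beta_date2 = 0, shape = 10,
                                ind_sd = 0.15, p_disturbed = 0.12,
                                seed = 1L) {
  set.seed(seed)
  n <- n_ind * days_per_ind
  id <- rep(seq_len(n_ind), each = days_per_ind)
  day <- rep(seq_len(days_per_ind), n_ind)
  ds <- (day - 1) / (days_per_ind - 1)
  nb <- stats::rpois(n, 20) + 6L
  u <- stats::rnorm(n_ind, 0, ind_sd)
  disturbed <- stats::rbinom(n, 1, p_disturbed) == 1
  logmu <- log(base_odba) + beta_shot * disturbed + beta_n * (nb - 20) +
    beta_date * ds + beta_date2 * ds^2 + u[id]
  sex_i <- sample(c("F", "M"), n_ind, replace = TRUE)
  data.frame(
    individual_id = sprintf("S%03d", id),
    species = rep(c("GBG", "GWfG"), length.out = n_ind)[id],
    sex = sex_i[id],
    winter = "2019-2020",
    date = winter_start_date(2019L) + day - 1L, date_index = day,
    total_odba = stats::rgamma(n, shape, shape / exp(logmu)),
    n_bursts = nb, disturbed = disturbed)
}
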