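# Displacement response to shooting: paired step lengths around each
# event, a per-species linear mixed model of the step-length difference
# on log distance, and the distance at which the response stops being
# statistically detectable.

#' Build paired step lengths around shooting events
#'
#' For every (bird, event) combination, finds the fix immediately prior
#' to the event and retains the pair if that fix lies within 1 h and
#' 4 km of the event field centroid and three consecutive fixes exist
#' (so both the exposed step `SL_t` and the control step `SL_{t-1}` are
#' computable). If a step is eligible for several simultaneous events
#' only the nearest event is kept, so no response row is duplicated.
#'
#' @param fixes hourly-resampled, annotated fix table.
#' @param events shooting-event table.
#' @param max_dist_m,max_lag_s retention rule (defaults 4 km, 1 h).
#' @return data.frame of step pairs: `individual_id`, `event_id`,
#'   `species`, `winter`, `sl_t`, `sl_t_minus_1`, `delta_sl` (m),
#'   `dist_to_event` (m), `event_time_h` (hours since midnight UTC).
#'   The number of ineligible combinations is reported as a message.
#' @export
build_step_pairs <- function(fixes, events, max_dist_m = 4000,
                             max_lag_s = 3600) {
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), ]
  if (!"winter" %in% names(fixes))
    fixes$winter <- winter_label(as.Date(fixes$timestamp, tz = "UTC"))
  rows <- list()
  n_checked <- 0L
  split_idx <- split(seq_len(nrow(fixes)), fixes$individual_id)
  for (e in seq_len(nrow(events))) {
    t_ev <- events$timestamp[e]
    for (ids in split_idx) {
      n_checked <- n_checked + 1L
      tt <- fixes$timestamp[ids]
      k <- findInterval(as.numeric(t_ev) - 1e-9, as.numeric(tt))
      if (k < 2 || k >= length(ids)) next          # need prev and next fix
      if (as.numeric(t_ev) - as.numeric(tt[k]) > max_lag_s) next
      i_prev <- ids[k - 1]; i_t <- ids[k]; i_next <- ids[k + 1]
      d <- euclid(fixes$x[i_t], fixes$y[i_t],
                  events$centroid_x[e], events$centroid_y[e])
      if (d > max_dist_m) next
      lt <- as.POSIXlt(t_ev, tz = "UTC")
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = fixes$individual_id[i_t],
        event_id = events$event_id[e],
        species = fixes$species[i_t],
        winter = fixes$winter[i_t],
        sl_t = euclid(fixes$x[i_t], fixes$y[i_t],
                      fixes$x[i_next], fixes$y[i_next]),
        sl_t_minus_1 = euclid(fixes$x[i_prev], fixes$y[i_prev],
                              fixes$x[i_t], fixes$y[i_t]),
        dist_to_event = d,
        event_time_h = lt$hour + lt$min / 60 + lt$sec / 3600,
        step_time = fixes$timestamp[i_t])
    }
  }
  if (!length(rows)) {
    message("build_step_pairs: 0 eligible pairs (", n_checked, " checked)")
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  out$delta_sl <- out$sl_t - out$sl_t_minus_1
  # one response row per step: keep the nearest simultaneous event
  key <- paste(out$individual_id, out$step_time)
  out <- out[order(key, out$dist_to_event), ]
  out <- out[!duplicated(paste(out$individual_id, out$step_time)), ]
  out$step_time <- NULL
  rownames(out) <- NULL
  message(sprintf("build_step_pairs: %d pairs retained, %d combinations excluded",
                  nrow(out), n_checked - nrow(out)))
  out
}

#' Fit the displacement-decay mixed model
#'
#' Linear mixed model of the step-length difference on the natural log
#' of distance to the shooting event, a quadratic in event time of day
#' (centred at its sample mean), and winter, with a random intercept
#' per individual. Winter enters as a fixed effect for GBG and as a
#' random intercept for GWfG (too few levels vs. too many); with a
#' single winter level it is dropped.
#'
#' @param pairs output of [build_step_pairs()] (one species).
#' @param species `"GBG"` or `"GWfG"`; controls the winter term.
#' @param winter_effect override: `"fixed"`, `"random"` or `"none"`.
#' @return object of class `displacement_fit`: list with `coefficients`,
#'   `vcov` (fixed effects), `fit` (the lmer object), `n_pairs`,
#'   `species`, `time_center`.
#' @export
fit_displacement_model <- function(pairs, species = pairs$species[1],
                                   winter_effect = NULL) {
  if (nrow(pairs) < 30) stop("need at least 30 step pairs")
  if (length(unique(pairs$individual_id)) < 2)
    stop("need at least 2 individuals")
  if (is.null(winter_effect))
    winter_effect <- if (identical(species, "GWfG")) "random" else "fixed"
  if (length(unique(pairs$winter)) < 2) winter_effect <- "none"
  d <- pairs
  d$ln_dist <- log(pmax(d$dist_to_event, 1))   # floor 0-distances at 1 m
  tc <- mean(d$event_time_h)
  d$time_c <- d$event_time_h - tc
  d$winter <- factor(d$winter)
  d$individual_id <- factor(d$individual_id)
  form <- switch(winter_effect,
    fixed  = delta_sl ~ ln_dist + time_c + I(time_c^2) + winter +
      (1 | individual_id),
    random = delta_sl ~ ln_dist + time_c + I(time_c^2) +
      (1 | individual_id) + (1 | winter),
    none   = delta_sl ~ ln_dist + time_c + I(time_c^2) + (1 | individual_id))
  fit <- tryCatch(
    lme4::lmer(form, data = d, REML = TRUE),
    error = function(e) stop("displacement model failed to fit: ",
                             conditionMessage(e)))
  beta <- lme4::fixef(fit)
  dropped <- setdiff(colnames(stats::model.matrix(
    lme4::nobars(form), d)), names(beta))
  if (length(dropped)) {
    stop("displacement model is singular; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(coefficients = beta,
                 vcov = as.matrix(stats::vcov(fit)),
                 fit = fit, n_pairs = nrow(d), species = species,
                 winter_effect = winter_effect, time_center = tc),
            class = "displacement_fit")
}

#' @export
print.displacement_fit <- function(x, ...) {
  cat("<displacement_fit>", x$species, "|", x$n_pairs, "pairs | winter:",
      x$winter_effect, "\n")
  print(round(x$coefficients, 2))
  invisible(x)
}

#' Coefficient table of a displacement fit
#' @param fit a `displacement_fit`.
#' @return data.frame with estimates, SEs and Wald 95% CIs.
#' @export
displacement_coef_table <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  data.frame(term = names(fit$coefficients),
             estimate = as.numeric(fit$coefficients), se = se,
             lwr = as.numeric(fit$coefficients) - 1.96 * se,
             upr = as.numeric(fit$coefficients) + 1.96 * se,
             row.names = NULL)
}

# Design row for a prediction at distance d (reference winter, mean
# event time), matching the fitted parameterisation.
displacement_design_row <- function(fit, d) {
  nm <- names(fit$coefficients)
  x <- stats::setNames(numeric(length(nm)), nm)
  x["(Intercept)"] <- 1
  x["ln_dist"] <- log(pmax(d, 1))
  x   # time_c = 0 (mean event time), winter dummies 0 (reference level)
}

predict_displacement <- function(fit, d) {
  X <- t(vapply(d, function(di) displacement_design_row(fit, di),
                numeric(length(fit$coefficients))))
  mu <- as.numeric(X %*% fit$coefficients)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  list(mu = mu, se = se, lwr = mu - 1.96 * se)
}

#' Distance at which displacement stops being detectable
#'
#' Evaluates the fitted mean displacement curve and its lower 95%
#' confidence bound (fixed-effect uncertainty, at the mean event time
#' and reference winter) over a distance grid and returns the smallest
#' distance at which the lower bound first crosses `y = 0`, refined by
#' bisection to within 1 m.
#'
#' @param fit a [fit_displacement_model()] result.
#' @param grid_max_m,grid_step_m evaluation grid (m).
#' @return list with `threshold_m` (numeric; `Inf` if the lower bound is
#'   never positive) and `status` (`"crossed"`, `"never_positive"` or
#'   `"no_crossing_below_grid_max"`).
#' @export
derive_disturbance_threshold <- function(fit, grid_max_m = 4000,
                                         grid_step_m = 10) {
  b <- fit$coefficients["ln_dist"]
  if (is.na(b) || b >= 0) {
    return(list(threshold_m = Inf, status = "never_positive"))
  }
  grid <- seq(1, grid_max_m, by = grid_step_m)
  lwr <- predict_displacement(fit, grid)$lwr
  if (lwr[1] <= 0) {
    return(list(threshold_m = Inf, status = "never_positive"))
  }
  below <- which(lwr <= 0)
  if (!length(below)) {
    return(list(threshold_m = Inf, status = "no_crossing_below_grid_max"))
  }
  hi <- grid[below[1]]
  lo <- grid[below[1] - 1L]
  while (hi - lo > 1) {
    mid <- (hi + lo) / 2
    if (predict_displacement(fit, mid)$lwr <= 0) hi <- mid else lo <- mid
  }
  list(threshold_m = hi, status = "crossed")
}
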