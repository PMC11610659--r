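# End-to-end orchestration: simulate (or load) -> ingest -> displacement
# -> exposure -> movement / accelerometry / habitat-selection models ->
# report bundle. Every stage logs row counts in/out for its filter
# rules via message().

#' Run the full analysis pipeline
#'
#' Simulates a dataset under `config` (or ingests the tables given in
#' `paths`), then runs every analysis stage and returns (and optionally
#' writes) a report bundle of coefficient tables, thresholds, rates,
#' AIC tables and evaluations. Deterministic under the config seed.
#'
#' @param config a [sim_config()]; ignored for input tables if `paths`
#'   is given.
#' @param paths optional named list (`tracks`, `events`, `bursts`) of
#'   CSV paths to analyse instead of simulating; a `config` is still
#'   used for landscape/solar context.
#' @param outdir optional directory: CSV/JSON outputs are written there.
#' @param threshold_m species buffers for exposure; `NULL` derives them
#'   from the displacement fits where possible, falling back to the
#'   package defaults.
#' @param fit_movement_set also rank the movement a-priori model set
#'   (slow; default FALSE fits the global model only).
#' @return a list report with one element per stage.
#' @export
run_pipeline <- function(config = sim_config(), paths = NULL, outdir = NULL,
                         threshold_m = NULL, fit_movement_set = FALSE) {
  report <- list(config = list(seed = config$seed))
  landscape <- generate_landscape(config)
  if (is.null(paths)) {
    tracks <- generate_tracks(landscape, config)
    shoot <- generate_shooting_log(landscape, tracks, config)
    tracks <- shoot$tracks; events <- shoot$events
    acc <- generate_acc_bursts(tracks, behavior_schedule = NULL,
                               config = config)
    bursts <- acc$bursts
    report$simulation <- list(n_fixes = nrow(tracks),
                              n_events = nrow(events),
                              n_true_exposures = nrow(shoot$exposures))
  } else {
    tracks <- read_tracks(paths$tracks)
    events <- read_shooting_log(paths$events)
    bursts <- if (!is.null(paths$bursts)) read_bursts(paths$bursts) else NULL
  }

  ## ingest: resample + annotate -------------------------------------
  n0 <- nrow(tracks)
  fixes <- resample_hourly(tracks)
  message("resample_hourly: ", n0, " -> ", nrow(fixes), " fixes")
  fixes <- annotate_fixes(fixes, landscape)
  report$ingest <- list(n_fixes_raw = n0, n_fixes_hourly = nrow(fixes),
                        n_events = nrow(events))

  ## displacement ------------------------------------------------------
  pairs <- build_step_pairs(fixes, events)
  report$displacement <- list(n_pairs = if (nrow(pairs)) nrow(pairs) else 0L)
  thresholds <- c(GBG = 1184, GWfG = 644)   # package defaults
  for (sp in unique(fixes$species)) {
    psp <- pairs[pairs$species == sp, , drop = FALSE]
    if (!is.data.frame(psp) || nrow(psp) < 30 ||
        length(unique(psp$individual_id)) < 2) {
      message("displacement[", sp, "]: too few pairs, using default threshold")
      next
    }
    fit <- fit_displacement_model(psp, species = sp)
    thr <- derive_disturbance_threshold(fit)
    report$displacement[[sp]] <- list(
      coefficients = displacement_coef_table(fit),
      threshold_m = thr$threshold_m, threshold_status = thr$status,
      n_pairs = fit$n_pairs)
    if (is.null(threshold_m) && is.finite(thr$threshold_m))
      thresholds[sp] <- thr$threshold_m
  }
  if (!is.null(threshold_m)) thresholds[names(threshold_m)] <- threshold_m
  report$thresholds_m <- thresholds

  ## exposure ----------------------------------------------------------
  records <- classify_exposure(fixes, events, thresholds, landscape)
  records <- cumulative_experience(records)
  rates <- disturbance_rate(records)
  message("exposure: ", sum(records$disturbed), " disturbed of ",
          nrow(records), " goose-days")
  report$exposure <- list(n_goose_days = nrow(records),
                          n_disturbed = sum(records$disturbed),
                          rates = rates$species)

  ## daily movement ----------------------------------------------------
  summaries <- daily_distance(fixes)
  message("daily_distance: ", nrow(summaries), " goose-days retained (>=8 fixes)")
  summaries <- join_exposure(summaries, records)
  ok <- summaries$total_distance_km > 0
  if (any(!ok)) message("daily_distance: dropping ", sum(!ok),
                        " zero-distance days before the gamma fit")
  move <- tryCatch(fit_distance_model(summaries[ok, ]),
                   error = function(e) {message("movement model: ",
                                                conditionMessage(e)); NULL})
  if (!is.null(move)) {
    report$movement <- list(coefficients = move$coefficients,
                            aic = move$aic,
                            marginal_means = distance_marginal_means(move))
    if (fit_movement_set) {
      cmp <- run_model_set(summaries[ok, ])
      report$movement$model_set <- as.data.frame(cmp)
    }
  }

  ## accelerometry -----------------------------------------------------
  if (!is.null(bursts) && nrow(bursts)) {
    train <- generate_acc_bursts(NULL, config = config)
    train_feat <- burst_features(train$bursts)
    clf <- train_behavior_classifier(train_feat, seed = config$seed)
    report$classifier <- list(accuracy = clf$accuracy,
                              accuracy_ci = clf$accuracy_ci,
                              confusion = clf$confusion)
    feat <- burst_features(bursts)
    feat$behavior <- classify_bursts(clf, feat)
    sp_of <- tracks$species[match(feat$individual_id, tracks$individual_id)]
    budgets <- build_budgets(feat, records, config$site_lat, config$site_lon)
    message("budgets: ", nrow(budgets), " goose-day/nights retained")
    report$budgets <- list(n = nrow(budgets))
    bud <- tryCatch(fit_budget_model(budgets, "grazing"),
                    error = function(e) {message("budget model: ",
                                                 conditionMessage(e)); NULL})
    if (!is.null(bud))
      report$budgets$grazing <- list(coefficients = bud$coefficients,
                                     aic_table = bud$aic_table)
    od <- daily_odba(feat, records, config$site_lat, config$site_lon)
    od$species <- sp_of[match(od$individual_id, feat$individual_id)]
    od <- od[od$total_odba > 0, ]
    message("daily_odba: ", nrow(od), " goose-days retained (>=10 days/winter)")
    ofit <- tryCatch(fit_odba_model(od),
                     error = function(e) {message("ODBA model: ",
                                                  conditionMessage(e)); NULL})
    if (!is.null(ofit))
      report$odba <- list(coefficients = ofit$coefficients,
                          aic_table = ofit$aic_table)
  }

  ## habitat selection --------------------------------------------------
  rsf_out <- list()
  for (sp in unique(fixes$species)) {
    f <- fixes[fixes$species == sp & fixes$is_day, ]
    if (nrow(f) < 30) next
    f$date <- as.Date(f$timestamp, tz = "UTC")
    i <- match(paste(f$individual_id, f$date),
               paste(records$individual_id, records$date))
    f$shooting_day <- !is.na(i) & records$disturbed[i]
    mcp <- species_mcp(f)
    pseudo <- sample_pseudoabsences(mcp, nrow(f), seed = config$seed)
    pts <- annotate_rsf_points(f, pseudo, landscape, "between_days")
    fit <- fit_rsf(pts, "between_days")
    rsf_out[[sp]] <- list(auc = fit$evaluation$auc,
                          evaluation = fit$evaluation[
                            c("sensitivity", "specificity", "accuracy")],
                          use_nonshooting = rsf_habitat_use(fit, FALSE),
                          n_used = nrow(f), n_pseudo = nrow(pseudo))
  }
  report$rsf <- rsf_out

  if (!is.null(outdir)) write_report(report, records, summaries, outdir)
  report
}

write_report <- function(report, records, summaries, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(outdir, "exposure_records.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(outdir, "goose_day_summaries.csv"),
                   row.names = FALSE)
  to_json <- rapply(report, function(x) {
    if (inherits(x, "table")) as.data.frame(x) else x
  }, how = "replace")
  jsonlite::write_json(to_json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(outdir)
}

#' Build a small bundled test dataset
#'
#' Generates a compact dataset (2 species x 5 birds x ~30 days) that
#' exercises every filter rule at least once: a day with fewer than 8
#' fixes, a night with fewer than 6 bursts, an in-field exposure, and a
#' rare habitat that the within-day grouping rule collapses. Written as
#' CSV/GeoJSON/ASCII-grid under `dir`.
#'
#' @param seed RNG seed.
#' @param dir output directory (default: a temp directory).
#' @return invisibly, a list with the fixture `config`, `landscape`
#'   and file paths.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("goosefix")) {
  config <- sim_config(seed = seed,
                       n_individuals = c(GBG = 5L, GWfG = 5L),
                       n_winters = 1L, days_per_winter = 30L,
                       shooting_rate = 3)
  landscape <- generate_landscape(config)
  tracks <- generate_tracks(landscape, config)
  shoot <- generate_shooting_log(landscape, tracks, config)
  tracks <- shoot$tracks; events <- shoot$events

  ## force an in-field exposure: one event dropped onto the field a
  ## bird occupies mid-morning on day 10
  b1 <- tracks$individual_id[1]
  t_ev <- as.POSIXct(paste(winter_start_date(config$start_year) + 9,
                           "11:30:00"), tz = "UTC")
  pre <- tracks[tracks$individual_id == b1 & tracks$timestamp < t_ev, ]
  pos <- pre[nrow(pre), ]
  fid <- field_at(landscape, pos$x, pos$y)
  if (is.na(fid)) fid <- landscape$fields$id[1]
  fr <- landscape$fields[landscape$fields$id == fid, ]
  events <- rbind(events, data.frame(
    event_id = "E9999", timestamp = t_ev, field_id = fid,
    centroid_x = (fr$xmin + fr$xmax) / 2, centroid_y = (fr$ymin + fr$ymax) / 2,
    n_shots = 4L, n_killed = 1L))
  events <- events[order(events$timestamp), ]

  ## force a sparse day (< 8 fixes) for the second bird on day 5
  b2 <- unique(tracks$individual_id)[2]
  d5 <- as.Date(winter_start_date(config$start_year)) + 4
  on_d5 <- tracks$individual_id == b2 &
    as.Date(tracks$timestamp, tz = "UTC") == d5
  drop <- which(on_d5)
  keep5 <- utils::head(drop, 5)
  tracks <- tracks[-setdiff(drop, keep5), ]

  acc <- generate_acc_bursts(tracks, behavior_schedule = NULL,
                             config = config)
  bursts <- acc$bursts
  ## force a sparse night (< 6 bursts): thin the largest goose-night of
  ## bird 1 to 3 bursts, using the same night grouping as build_budgets
  is_d <- is_daylight(bursts$timestamp, config$site_lat, config$site_lon)
  hrs <- as.POSIXlt(bursts$timestamp, tz = "UTC")$hour
  eff <- as.Date(bursts$timestamp, tz = "UTC") - (!is_d & hrs < 12)
  nk <- paste(bursts$individual_id, eff)
  night_sizes <- tapply(bursts$burst_id[!is_d & bursts$individual_id == b1],
                        nk[!is_d & bursts$individual_id == b1],
                        function(z) length(unique(z)))
  target <- names(which.max(night_sizes))
  in_target <- !is_d & nk == target
  keep_b <- utils::head(unique(bursts$burst_id[in_target]), 3)
  bursts <- bursts[!in_target | bursts$burst_id %in% keep_b, ]

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(tracks = file.path(dir, "tracks.csv"),
                events = file.path(dir, "shooting_log.csv"),
                bursts = file.path(dir, "bursts.csv"))
  write_tracks(tracks, paths$tracks)
  write_shooting_log(events, paths$events)
  write_bursts(bursts, paths$bursts)
  write_landscape(landscape, dir)
  invisible(list(config = config, landscape = landscape, paths = paths,
                 truth = shoot$exposures))
}
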