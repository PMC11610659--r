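# Accelerometer processing: ODBA, burst features, the random-forest
# behaviour classifier, day/night activity budgets (beta-binomial) and
# daily energy expenditure (gamma ODBA model).

#' Overall dynamic body acceleration of one burst
#'
#' `ODBA = sum_i (|x_i - xbar| + |y_i - ybar| + |z_i - zbar|) / n`:
#' the mean absolute deviation around the static (mean) acceleration,
#' summed across the three axes. A proxy for energy expenditure.
#'
#' @param x,y,z equal-length numeric vectors of tri-axial samples
#'   (n >= 2).
#' @return single non-negative ODBA value (g).
#' @export
compute_odba <- function(x, y, z) {
  n <- length(x)
  if (n < 2 || length(y) != n || length(z) != n)
    stop("invalid burst: need three equal-length axes with n >= 2")
  (sum(abs(x - mean(x))) + sum(abs(y - mean(y))) +
     sum(abs(z - mean(z)))) / n
}

#' Per-burst summary features for behaviour classification
#'
#' Per-axis mean, SD, min, max and mean absolute deviation, the burst
#' ODBA, and the dominant-axis ratio (largest axis MAD over the summed
#' MADs).
#'
#' @param bursts long-format burst samples (see [read_bursts()]).
#' @return data.frame, one row per burst (`burst_id`, `individual_id`,
#'   `timestamp`, `label` if present, then the feature columns).
#' @export
burst_features <- function(bursts) {
  f1 <- function(v) c(mean = mean(v), sd = stats::sd(v), min = min(v),
                      max = max(v), mad = mean(abs(v - mean(v))))
  out <- lapply(split(bursts, bursts$burst_id), function(g) {
    fx <- f1(g$ax); fy <- f1(g$ay); fz <- f1(g$az)
    odba <- fx["mad"] + fy["mad"] + fz["mad"]
    dom <- max(fx["mad"], fy["mad"], fz["mad"]) / max(odba, 1e-12)
    row <- data.frame(burst_id = g$burst_id[1],
                      individual_id = g$individual_id[1],
                      timestamp = g$timestamp[1],
                      t(c(stats::setNames(fx, paste0("x_", names(fx))),
                          stats::setNames(fy, paste0("y_", names(fy))),
                          stats::setNames(fz, paste0("z_", names(fz))))),
                      odba = unname(odba), dom_ratio = unname(dom))
    if ("label" %in% names(g)) row$label <- g$label[1]
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

feature_cols <- function() {
  c(paste0(rep(c("x_", "y_", "z_"), each = 5),
           c("mean", "sd", "min", "max", "mad")), "odba", "dom_ratio")
}

#' Train the behaviour random forest on labelled bursts
#'
#' Stratified 70/30 train/test split, a random forest over
#' [burst_features()], held-out overall accuracy with an exact binomial
#' CI and the per-class confusion matrix. After prediction the five
#' training behaviours collapse to the four analysis behaviours
#' (alert + resting = stationary).
#'
#' @param features labelled feature table from [burst_features()].
#' @param split_fraction fraction used for training (default 0.7).
#' @param seed RNG seed for the split and the forest.
#' @param ntree trees in the forest.
#' @return object of class `behavior_classifier`: list with `forest`,
#'   `accuracy`, `accuracy_ci`, `confusion`, `test_n`, `classes`.
#' @export
train_behavior_classifier <- function(features, split_fraction = 0.7,
                                      seed = 1L, ntree = 500) {
  stopifnot("label" %in% names(features))
  set.seed(seed)
  y <- factor(features$label)
  if (nlevels(y) < 2) stop("need at least 2 behaviour classes")
  tr <- logical(nrow(features))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- round(split_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("stratification error: class '", cl,
           "' too small for a ", split_fraction, " split")
    tr[sample(idx, n_tr)] <- TRUE
  }
  X <- features[, feature_cols()]
  forest <- randomForest::randomForest(x = X[tr, ], y = y[tr], ntree = ntree)
  pred <- stats::predict(forest, X[!tr, ])
  acc <- mean(pred == y[!tr])
  ci <- stats::binom.test(sum(pred == y[!tr]), sum(!tr))$conf.int
  structure(list(forest = forest, accuracy = acc,
                 accuracy_ci = as.numeric(ci),
                 confusion = table(truth = y[!tr], predicted = pred),
                 test_n = sum(!tr), classes = levels(y)),
            class = "behavior_classifier")
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat(sprintf(
    "<behavior_classifier> %d classes | held-out accuracy %.3f [%.3f, %.3f] (n = %d)\n",
    length(x$classes), x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2],
    x$test_n))
  invisible(x)
}

#' Predict analysis behaviours for unlabelled bursts
#'
#' @param classifier a [train_behavior_classifier()] result.
#' @param features [burst_features()] table.
#' @param collapse collapse alert/resting to `stationary` (default).
#' @return character vector of behaviours per burst.
#' @export
classify_bursts <- function(classifier, features, collapse = TRUE) {
  p <- as.character(stats::predict(classifier$forest,
                                   features[, feature_cols()]))
  if (collapse) p[p %in% c("alert", "resting")] <- "stationary"
  p
}

#' Build day/night activity budgets
#'
#' Counts classified bursts per goose-day and goose-night. A night runs
#' sunset-to-sunrise and belongs to the preceding day; night records
#' inherit that day's disturbance flag (shooting happens in daylight).
#' Days/nights with fewer than `min_bursts` bursts are removed, then
#' individuals with fewer than `min_days` distinct days in a winter.
#'
#' @param features [burst_features()] table with a `behavior` column
#'   (from [classify_bursts()]).
#' @param records exposure table from [classify_exposure()] (may be
#'   empty: all budgets undisturbed).
#' @param site_lat,site_lon solar position site.
#' @param min_bursts,min_days inclusion rules (defaults 6 and 10).
#' @return data.frame of budgets: `individual_id`, `winter`, `date`,
#'   `date_index`, `is_night`, `n_bursts`, `bursts_grazing`,
#'   `bursts_stationary`, `bursts_flying`, `bursts_walking`,
#'   `disturbed`.
#' @export
build_budgets <- function(features, records = NULL,
                          site_lat = 55.75, site_lon = -6.25,
                          min_bursts = 6L, min_days = 10L) {
  stopifnot("behavior" %in% names(features))
  day <- is_daylight(features$timestamp, site_lat, site_lon)
  date <- as.Date(features$timestamp, tz = "UTC")
  hr <- as.POSIXlt(features$timestamp, tz = "UTC")$hour
  eff_date <- date - as.integer(!day & hr < 12)   # pre-dawn -> previous night
  f <- data.frame(individual_id = features$individual_id, date = eff_date,
                  is_night = !day, behavior = features$behavior)
  agg <- lapply(split(f, list(f$individual_id, f$date, f$is_night),
                      drop = TRUE), function(g) {
    data.frame(individual_id = g$individual_id[1], date = g$date[1],
               is_night = g$is_night[1], n_bursts = nrow(g),
               bursts_grazing = sum(g$behavior == "grazing"),
               bursts_stationary = sum(g$behavior == "stationary"),
               bursts_flying = sum(g$behavior == "flying"),
               bursts_walking = sum(g$behavior == "walking"))
  })
  b <- do.call(rbind, agg)
  b$winter <- winter_label(b$date)
  b$date_index <- date_index_from(b$date)
  b <- b[b$n_bursts >= min_bursts, ]
  # drop individual-winters observed on < min_days distinct days
  key <- paste(b$individual_id, b$winter)
  ndays <- tapply(b$date, key, function(d) length(unique(d)))
  b <- b[ndays[key] >= min_days, ]
  b$disturbed <- FALSE
  if (!is.null(records) && nrow(records)) {
    i <- match(paste(b$individual_id, b$date),
               paste(records$individual_id, records$date))
    b$disturbed <- !is.na(i) & records$disturbed[i]
  }
  b <- b[order(b$individual_id, b$date, b$is_night), ]
  rownames(b) <- NULL
  b
}

#' Shift a baseline proportion on the logit scale
#'
#' Applies a logit-scale coefficient to a baseline proportion:
#' `plogis(qlogis(p) + shift)`. This is how the disturbance effects of
#' the budget models translate into changes in time-activity
#' proportions.
#'
#' @param p baseline proportion in (0, 1).
#' @param shift logit-scale shift.
#' @return shifted proportion.
#' @export
logit_shift <- function(p, shift) stats::plogis(stats::qlogis(p) + shift)

prep_budget_frame <- function(budgets, behavior) {
  col <- paste0("bursts_", behavior)
  stopifnot(col %in% names(budgets) || "k" %in% names(budgets))
  d <- budgets
  d$k <- if (col %in% names(d)) d[[col]] else d$k
  if (all(d$k == 0) || all(d$k == d$n_bursts))
    stop("degenerate dispersion: behaviour proportions are all 0 or all 1")
  d$shot <- factor(ifelse(d$disturbed, "disturbed", "undisturbed"),
                   levels = c("undisturbed", "disturbed"))
  d$night <- factor(ifelse(d$is_night, "night", "day"),
                    levels = c("day", "night"))
  d$individual_id <- factor(d$individual_id)
  d$winter_f <- factor(d$winter)
  d$date_s <- as.numeric(scale(d$date_index))
  d$series <- interaction(d$individual_id, d$winter_f, drop = TRUE)
  idx <- d$date_index
  d$day_f <- factor(idx, levels = seq(min(idx), max(idx)))
  d
}

budget_formula <- function(d, drop_interaction = FALSE, drop_shot = FALSE,
                           ar1 = TRUE) {
  fe <- c(if (!drop_shot) "shot", "night",
          if (!drop_shot && !drop_interaction) "shot:night",
          "date_s", "I(date_s^2)")
  re <- c("(1 | individual_id)",
          if (nlevels(d$winter_f) > 1) "(1 | winter_f)",
          if (ar1) "ar1(day_f + 0 | series)")
  stats::as.formula(paste("cbind(k, n_bursts - k) ~",
                          paste(c(fe, re), collapse = " + ")))
}

#' Fit the activity-budget beta-binomial model
#'
#' Beta-binomial (logit link) mixed model of the per-day/night count of
#' one behaviour out of all bursts, with disturbance, day/night, their
#' interaction, a quadratic seasonal (date) term, random intercepts for
#' individual and winter, and AR1 across the daily series. Ranks the
#' three a-priori models (global / no interaction / no disturbance) by
#' AIC.
#'
#' @param budgets [build_budgets()] output (or
#'   [simulate_budget_counts()], which supplies `k` directly).
#' @param behavior which behaviour to model (`"grazing"`, `"flying"`,
#'   `"stationary"`, `"walking"`); ignored if `budgets` has a `k`
#'   column.
#' @param ar1 fit the AR1 structure.
#' @return object of class `budget_fit`: list with `fit` (global
#'   model), `coefficients`, `vcov`, `aic_table`, `behavior`.
#' @export
fit_budget_model <- function(budgets, behavior = "grazing", ar1 = TRUE) {
  d <- prep_budget_frame(budgets, behavior)
  specs <- list(global = c(FALSE, FALSE), no_interaction = c(TRUE, FALSE),
                no_shot = c(TRUE, TRUE))
  fits <- lapply(specs, function(s) {
    tryCatch(glmmTMB::glmmTMB(budget_formula(d, s[1], s[2], ar1), data = d,
                              family = glmmTMB::betabinomial(link = "logit")),
             error = function(e) NULL)
  })
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else stats::AIC(f),
                numeric(1))
  tab <- data.frame(model = names(specs), AIC = aic,
                    dAIC = aic - min(aic, na.rm = TRUE))
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  g <- fits$global
  if (is.null(g)) stop("global budget model failed to fit")
  structure(list(fit = g, coefficients = glmmTMB::fixef(g)$cond,
                 vcov = as.matrix(stats::vcov(g)$cond),
                 aic_table = tab, behavior = behavior, data = d),
            class = "budget_fit")
}

#' @export
print.budget_fit <- function(x, ...) {
  cat("<budget_fit> beta-binomial(logit),", x$behavior, "\n")
  print(round(x$coefficients, 3))
  print(x$aic_table)
  invisible(x)
}

#' Summarise daily total ODBA per goose-day
#'
#' Sums burst ODBA over the daytime bursts of each goose-day and
#' applies the inclusion rule: individuals with fewer than `min_days`
#' days in a winter are removed.
#'
#' @param features [burst_features()] table (needs `odba`).
#' @param records exposure table (as in [build_budgets()]).
#' @param site_lat,site_lon solar position site.
#' @param min_days inclusion rule (default 10).
#' @return data.frame: `individual_id`, `species` (if present),
#'   `winter`, `date`, `date_index`, `total_odba`, `n_bursts`,
#'   `disturbed`.
#' @export
daily_odba <- function(features, records = NULL,
                       site_lat = 55.75, site_lon = -6.25, min_days = 10L) {
  day <- is_daylight(features$timestamp, site_lat, site_lon)
  f <- features[day, ]
  f$date <- as.Date(f$timestamp, tz = "UTC")
  agg <- lapply(split(f, list(f$individual_id, f$date), drop = TRUE),
                function(g) {
    data.frame(individual_id = g$individual_id[1], date = g$date[1],
               total_odba = sum(g$odba), n_bursts = nrow(g))
  })
  b <- do.call(rbind, agg)
  b$winter <- winter_label(b$date)
  b$date_index <- date_index_from(b$date)
  key <- paste(b$individual_id, b$winter)
  ndays <- tapply(b$date, key, function(d) length(unique(d)))
  b <- b[ndays[key] >= min_days, ]
  b$disturbed <- FALSE
  if (!is.null(records) && nrow(records)) {
    i <- match(paste(b$individual_id, b$date),
               paste(records$individual_id, records$date))
    b$disturbed <- !is.na(i) & records$disturbed[i]
  }
  b <- b[order(b$individual_id, b$date), ]
  rownames(b) <- NULL
  b
}

odba_formula <- function(d, drop = character(), ar1 = TRUE) {
  fe <- c(if (!"shot" %in% drop) "shot",
          if (!"sp" %in% drop && nlevels(d$sp) > 1) "sp",
          if (!any(c("shot", "sp", "interaction") %in% drop) &&
                nlevels(d$sp) > 1) "shot:sp",
          if (nlevels(d$sex) > 1) "sex",
          "date_s", "I(date_s^2)", "n_c")
  re <- c("(1 | individual_id)",
          if (nlevels(d$winter_f) > 1) "(1 | winter_f)",
          if (ar1) "ar1(day_f + 0 | series)")
  stats::as.formula(paste("total_odba ~", paste(c(fe, re), collapse = " + ")))
}

#' Fit the daily-ODBA gamma model with its a-priori model set
#'
#' Gamma (log link) mixed model of total daily ODBA with disturbance,
#' species, their interaction, sex, a quadratic date term and the
#' number of bursts, random intercepts for individual and winter, and
#' AR1 over days. Five models are ranked by AIC: global, no
#' interaction, no disturbance, no species, neither.
#'
#' @param daily [daily_odba()] or [simulate_odba_daily()] output.
#' @param ar1 fit the AR1 structure.
#' @return object of class `odba_fit`: list with `fit` (global),
#'   `coefficients`, `vcov`, `aic_table`.
#' @export
fit_odba_model <- function(daily, ar1 = TRUE) {
  if (any(daily$total_odba <= 0))
    stop("gamma model requires strictly positive daily ODBA totals")
  d <- daily
  d$shot <- factor(ifelse(d$disturbed, "disturbed", "undisturbed"),
                   levels = c("undisturbed", "disturbed"))
  d$sp <- factor(if ("species" %in% names(d)) d$species else "one")
  d$sex <- factor(if ("sex" %in% names(d)) d$sex else "one")
  d$individual_id <- factor(d$individual_id)
  d$winter_f <- factor(d$winter)
  d$date_s <- as.numeric(scale(d$date_index))
  d$n_c <- d$n_bursts - mean(d$n_bursts)
  d$series <- interaction(d$individual_id, d$winter_f, drop = TRUE)
  d$day_f <- factor(d$date_index,
                    levels = seq(min(d$date_index), max(d$date_index)))
  specs <- list(global = character(), no_interaction = "interaction",
                no_shot = "shot", no_sp = "sp", base = c("shot", "sp"))
  fits <- lapply(specs, function(s) {
    tryCatch(glmmTMB::glmmTMB(odba_formula(d, s, ar1), data = d,
                              family = Gamma(link = "log")),
             error = function(e) NULL)
  })
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else stats::AIC(f),
                numeric(1))
  tab <- data.frame(model = names(specs), AIC = aic,
                    dAIC = aic - min(aic, na.rm = TRUE))
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  g <- fits$global
  if (is.null(g)) stop("global ODBA model failed to fit")
  structure(list(fit = g, coefficients = glmmTMB::fixef(g)$cond,
                 vcov = as.matrix(stats::vcov(g)$cond),
                 aic_table = tab, data = d),
            class = "odba_fit")
}

#' @export
print.odba_fit <- function(x, ...) {
  cat("<odba_fit> gamma(log) daily ODBA\n")
  print(round(x$coefficients, 3))
  print(x$aic_table)
  invisible(x)
}
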