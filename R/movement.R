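# Daily foraging distance: goose-day summaries and the gamma(log)
# mixed model with a first-order autoregressive day-to-day structure.

#' Summarise daily foraging distance per goose-day
#'
#' Total distance is the cumulative point-to-point Euclidean distance
#' over consecutive daytime fixes within the calendar day, in km.
#' Days with fewer than `min_fixes` fixes are dropped. The modal farm
#' is the farm containing most fixes that day (ties broken toward the
#' lexicographically smallest farm id; `NA` if every fix is outside all
#' farms).
#'
#' @param fixes hourly, annotated fix table (needs `is_day`, `farm_id`,
#'   `winter`, `date_index`).
#' @param min_fixes minimum fixes per day for inclusion (default 8).
#' @return data.frame of goose-day summaries: `individual_id`,
#'   `species`, `sex`, `winter`, `date`, `date_index`, `n_fixes`,
#'   `total_distance_km`, `modal_farm_id`.
#' @export
daily_distance <- function(fixes, min_fixes = 8L) {
  stopifnot(all(c("is_day", "farm_id", "winter") %in% names(fixes)))
  fixes$date <- as.Date(fixes$timestamp, tz = "UTC")
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), ]
  out <- lapply(split(fixes, list(fixes$individual_id, fixes$date),
                      drop = TRUE), function(g) {
    if (nrow(g) < min_fixes) return(NULL)
    day <- g[g$is_day, ]
    td <- if (nrow(day) >= 2) {
      sum(euclid(day$x[-nrow(day)], day$y[-nrow(day)],
                 day$x[-1], day$y[-1])) / 1000
    } else 0
    farms <- day$farm_id[!is.na(day$farm_id)]
    modal <- if (length(farms)) {
      tab <- table(farms)
      sort(names(tab)[tab == max(tab)])[1]
    } else NA_character_
    data.frame(individual_id = g$individual_id[1], species = g$species[1],
               sex = g$sex[1], winter = g$winter[1], date = g$date[1],
               date_index = g$date_index[1], n_fixes = nrow(g),
               total_distance_km = td, modal_farm_id = modal)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame())
  out <- out[order(out$individual_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Merge exposure classes onto goose-day summaries
#'
#' @param summaries [daily_distance()] output.
#' @param records [cumulative_experience()] output.
#' @return summaries with `disturbed`, `disturbance_class`,
#'   `exp_scaled` appended (days without an exposure record are treated
#'   as undisturbed, experience carried at 0 raw).
#' @export
join_exposure <- function(summaries, records) {
  key_s <- paste(summaries$individual_id, summaries$date)
  key_r <- paste(records$individual_id, records$date)
  i <- match(key_s, key_r)
  summaries$disturbed <- ifelse(is.na(i), FALSE, records$disturbed[i])
  summaries$disturbance_class <-
    ifelse(is.na(i), "undisturbed", records$disturbance_class[i])
  summaries$exp_scaled <-
    ifelse(is.na(i), 0, if ("exp_scaled" %in% names(records))
      records$exp_scaled[i] else 0)
  summaries
}

prep_movement_frame <- function(summaries, shot_levels = 2L) {
  d <- summaries
  if (any(d$total_distance_km <= 0))
    stop("gamma model requires strictly positive daily distances (",
         sum(d$total_distance_km <= 0), " non-positive rows)")
  d$shot <- if (shot_levels == 3L) {
    factor(d$disturbance_class, levels = c("undisturbed", "in_field", "nearby"))
  } else {
    factor(ifelse(d$disturbed, "disturbed", "undisturbed"),
           levels = c("undisturbed", "disturbed"))
  }
  d$shot <- droplevels(d$shot)
  d$individual_id <- factor(d$individual_id)
  d$winter_f <- factor(d$winter)
  d$farm_f <- factor(ifelse(is.na(d$modal_farm_id), "none", d$modal_farm_id))
  d$sex <- factor(d$sex)
  d$sp <- factor(d$species)
  d$series <- interaction(d$individual_id, d$winter_f, drop = TRUE)
  idx <- if ("date_index" %in% names(d)) d$date_index else
    as.integer(d$date - min(d$date)) + 1L
  d$day_f <- factor(idx, levels = seq(min(idx), max(idx)))
  d
}

# Assemble a glmmTMB formula from the term switches of one model row.
movement_formula <- function(terms, d, ar1 = TRUE) {
  fe <- c("sp", "sex",
    if (terms[["shot"]]) "shot",
    if (terms[["exp"]]) "exp_scaled",
    if (terms[["shot_sp"]]) "shot:sp",
    if (terms[["shot_exp"]]) "shot:exp_scaled",
    if (terms[["sp_exp"]]) "sp:exp_scaled",
    if (terms[["shot_sp_exp"]]) "shot:sp:exp_scaled")
  re <- c("(1 | individual_id)",
          if (nlevels(d$winter_f) > 1) "(1 | winter_f)",
          if (nlevels(d$farm_f) > 1) "(1 | farm_f)",
          if (ar1) "ar1(day_f + 0 | series)")
  stats::as.formula(paste("total_distance_km ~",
                          paste(c(fe, re), collapse = " + ")))
}

#' Fit the daily-distance gamma mixed model
#'
#' Gamma (log link) mixed model of total daily distance with random
#' intercepts for individual, winter and modal farm and an AR1
#' covariance over consecutive days within each individual-winter
#' series (gaps enter as missing AR1 levels, i.e. correlation
#' `rho^ndays`). Single-level grouping factors are dropped
#' automatically.
#'
#' @param summaries goose-day summaries with exposure columns (see
#'   [join_exposure()]; or [simulate_goose_days()] output).
#' @param shot_levels 2 (disturbed/undisturbed) or 3 (undisturbed /
#'   in_field / nearby; undisturbed is the reference level).
#' @param terms named logical switches for the fixed-effect structure
#'   (default: the global model).
#' @param ar1 fit the AR1 structure (default TRUE).
#' @return object of class `movement_fit`: list with `fit`,
#'   `coefficients`, `vcov`, `aic`, `shot_levels`, `data`.
#' @export
fit_distance_model <- function(summaries, shot_levels = 2L,
                               terms = c(shot = TRUE, exp = TRUE,
                                         shot_sp = TRUE, shot_exp = TRUE,
                                         sp_exp = TRUE, shot_sp_exp = TRUE),
                               ar1 = TRUE) {
  d <- prep_movement_frame(summaries, shot_levels)
  terms <- terms_with_defaults(terms)
  if (terms[["shot"]] || any(terms[c("shot_sp", "shot_exp", "shot_sp_exp")]))
    if (nlevels(d$shot) < 2)
      stop("shot factor has a single level in these data")
  drop1 <- nlevels(d$sp) < 2
  if (drop1) {            # single-species table: drop species terms
    terms[c("shot_sp", "sp_exp", "shot_sp_exp")] <- FALSE
  }
  form <- movement_formula(terms, d, ar1)
  if (drop1) form <- stats::update(form, . ~ . - sp)
  if (nlevels(d$sex) < 2) form <- stats::update(form, . ~ . - sex)
  fit <- glmmTMB::glmmTMB(form, data = d, family = Gamma(link = "log"))
  structure(list(fit = fit,
                 coefficients = glmmTMB::fixef(fit)$cond,
                 vcov = as.matrix(stats::vcov(fit)$cond),
                 aic = stats::AIC(fit), shot_levels = shot_levels,
                 terms = terms, data = d),
            class = "movement_fit")
}

terms_with_defaults <- function(terms) {
  full <- c(shot = FALSE, exp = FALSE, shot_sp = FALSE, shot_exp = FALSE,
            sp_exp = FALSE, shot_sp_exp = FALSE)
  full[names(terms)] <- terms
  full
}

#' @export
print.movement_fit <- function(x, ...) {
  cat("<movement_fit> gamma(log),", x$shot_levels, "-level shot | AIC",
      round(x$aic, 1), "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Back-transformed marginal mean daily distances
#'
#' Marginal means by shot level at the reference sex and species, the
#' mean of scaled experience (0) and random effects at zero, with Wald
#' CIs on the link scale back-transformed to km.
#'
#' @param fit a [fit_distance_model()] result.
#' @return data.frame with `shot`, `mean_km`, `lwr_km`, `upr_km`.
#' @export
distance_marginal_means <- function(fit) {
  beta <- fit$coefficients[!is.na(fit$coefficients)]  # rank-deficiency drops
  fit$coefficients <- beta
  fit$vcov <- fit$vcov[names(beta), names(beta), drop = FALSE]
  nm <- names(fit$coefficients)
  levs <- levels(fit$data$shot)
  out <- lapply(levs, function(l) {
    x <- stats::setNames(numeric(length(nm)), nm)
    x["(Intercept)"] <- 1
    dummy <- paste0("shot", l)
    if (dummy %in% nm) x[dummy] <- 1
    eta <- sum(x * fit$coefficients)
    se <- sqrt(drop(t(x) %*% fit$vcov %*% x))
    data.frame(shot = l, mean_km = exp(eta),
               lwr_km = exp(eta - 1.96 * se), upr_km = exp(eta + 1.96 * se))
  })
  do.call(rbind, out)
}

#' Default a-priori model set for daily distance
#'
#' The 23-model set crossing the 2- and 3-level disturbance factor with
#' progressively reduced interaction structure, down to a base model
#' with neither disturbance nor experience. Species and sex stay in
#' every model.
#'
#' @return data.frame, one row per candidate model.
#' @export
movement_model_set <- function() {
  g <- expand.grid(shot_levels = c(2L, 3L),
                   shot = TRUE, exp = c(TRUE, FALSE),
                   shot_sp = c(TRUE, FALSE), shot_exp = c(TRUE, FALSE),
                   sp_exp = c(TRUE, FALSE), shot_sp_exp = c(TRUE, FALSE))
  # interactions only alongside their margins
  ok <- (!g$shot_exp | g$exp) & (!g$sp_exp | g$exp) &
    (!g$shot_sp_exp | (g$shot_sp & g$shot_exp & g$sp_exp))
  g <- g[ok, ]
  base <- data.frame(shot_levels = 2L, shot = FALSE, exp = FALSE,
                     shot_sp = FALSE, shot_exp = FALSE, sp_exp = FALSE,
                     shot_sp_exp = FALSE)
  out <- rbind(g, base)
  out$model_id <- sprintf("M%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c(ncol(out), seq_len(ncol(out) - 1))]
}

#' Fit and rank an a-priori model set by AIC
#'
#' All models are fitted on identical rows; non-converging models are
#' recorded as failed and excluded from the ranking.
#'
#' @param summaries goose-day summaries with exposure columns.
#' @param model_set data.frame like [movement_model_set()].
#' @param ar1 fit the AR1 structure in every model.
#' @return object of class `model_comparison`: data.frame with
#'   `model_id`, term flags, `k`, `AIC`, `dAIC`, `failed`, sorted by
#'   AIC; the best row has `dAIC = 0`. Fitted objects in
#'   `attr(, "fits")`.
#' @export
run_model_set <- function(summaries, model_set = movement_model_set(),
                          ar1 = TRUE) {
  fits <- vector("list", nrow(model_set))
  rows <- lapply(seq_len(nrow(model_set)), function(i) {
    m <- model_set[i, ]
    tm <- c(shot = m$shot, exp = m$exp, shot_sp = m$shot_sp,
            shot_exp = m$shot_exp, sp_exp = m$sp_exp,
            shot_sp_exp = m$shot_sp_exp)
    f <- tryCatch(suppressWarnings(
      fit_distance_model(summaries, m$shot_levels, tm, ar1)),
      error = function(e) e)
    if (inherits(f, "movement_fit") && is.finite(f$aic)) {
      fits[[i]] <<- f
      data.frame(m, k = attr(stats::logLik(f$fit), "df"),
                 AIC = f$aic, failed = FALSE)
    } else {
      msg <- if (inherits(f, "condition")) conditionMessage(f) else
        "non-finite AIC"
      message("model ", m$model_id, " failed: ", msg)
      data.frame(m, k = NA_integer_, AIC = NA_real_, failed = TRUE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  tab <- tab[order(tab$failed, tab$AIC), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", class(tab))
  tab
}
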