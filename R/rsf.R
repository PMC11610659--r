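# Resource selection: availability domain (100% MCP), pseudoabsence
# sampling, habitat/road annotation, weighted logistic RSFs and
# ROC-based evaluation.

#' 100% minimum convex polygon of a species' fixes
#'
#' @param fixes fix table of one species (daytime fixes are the usual
#'   input); needs >= 3 non-collinear points.
#' @return data.frame of hull vertices (`x`, `y`, counter-clockwise).
#' @export
species_mcp <- function(fixes) {
  if (nrow(fixes) < 3) stop("need at least 3 fixes for an MCP")
  hull <- convex_hull(fixes$x, fixes$y)
  if (nrow(hull) < 3 || abs(polygon_area(hull)) < 1e-9)
    stop("degenerate hull: fixes are collinear")
  hull
}

#' Sample pseudoabsences uniformly inside the MCP
#'
#' Draws exactly `ratio * n_used` points uniformly inside the polygon
#' by rejection from its bounding box; reproducible under `seed`.
#'
#' @param mcp polygon from [species_mcp()].
#' @param n_used number of used fixes.
#' @param ratio pseudoabsences per used fix (default 10).
#' @param seed RNG seed.
#' @return data.frame with `x`, `y`.
#' @export
sample_pseudoabsences <- function(mcp, n_used, ratio = 10, seed = 1L) {
  set.seed(seed)
  n <- ratio * n_used
  xr <- range(mcp$x); yr <- range(mcp$y)
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(1000L, 2L * (n - length(out_x)))
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_convex(px, py, mcp)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
  }
  data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Assemble and annotate an RSF point table
#'
#' Builds the used/pseudoabsence table for one species: used daytime
#' fixes get weight 10, pseudoabsences (shared across disturbance
#' classes, replicated per class) weight 1; every point is annotated
#' with habitat class (raster lookup; off-raster points are dropped
#' with a warning) and z-scored distance to the nearest road (scaling
#' over the assembled table).
#'
#' @param used used fixes, with a `shooting_day` logical column and,
#'   for within-day designs, a `period` column (`"pre"`/`"post"`).
#' @param pseudo pseudoabsence coordinates from
#'   [sample_pseudoabsences()].
#' @param landscape a [generate_landscape()] result (habitat + roads).
#' @param design `"between_days"` or `"within_days"`; within-day tables
#'   collapse habitats with fewer than `min_fixes` used fixes in both
#'   periods to `"other"`.
#' @param min_fixes grouping rule threshold (default 50).
#' @return data.frame of `RsfPoint`s: `x`, `y`, `used`, `weight`,
#'   `habitat`, `dist_road_scaled`, plus `shooting_day` or `period`.
#' @export
annotate_rsf_points <- function(used, pseudo, landscape,
                                design = c("between_days", "within_days"),
                                min_fixes = 50L) {
  design <- match.arg(design)
  class_col <- if (design == "between_days") "shooting_day" else "period"
  if (design == "within_days") stopifnot("period" %in% names(used))
  u <- data.frame(x = used$x, y = used$y, used = 1L, weight = 10,
                  cls = used[[class_col]],
                  individual_id = used$individual_id)
  # the shared availability sample is partitioned across classes in
  # proportion to the used-fix counts, preserving the 10:1 ratio (and
  # hence the use-proportional-to-availability = 0.5 convention) within
  # every class
  u_counts <- table(u$cls)
  n_per <- round(nrow(pseudo) * as.numeric(u_counts) / nrow(u))
  n_per[length(n_per)] <- nrow(pseudo) - sum(n_per[-length(n_per)])
  p_cls <- rep(names(u_counts), n_per)
  if (is.logical(u$cls)) p_cls <- as.logical(p_cls)
  p <- data.frame(x = pseudo$x, y = pseudo$y, used = 0L, weight = 1,
                  cls = p_cls, individual_id = NA_character_)
  pts <- rbind(u, p)
  names(pts)[names(pts) == "cls"] <- class_col
  pts$habitat <- habitat_at(landscape, pts$x, pts$y)
  off <- is.na(pts$habitat)
  if (any(off)) {
    warning(sum(off), " point(s) fall off the habitat raster; dropped")
    pts <- pts[!off, ]
  }
  if (design == "within_days") {
    u_tab <- table(pts$habitat[pts$used == 1], pts$period[pts$used == 1])
    rare <- rownames(u_tab)[apply(u_tab < min_fixes, 1, all)]
    pts$habitat[pts$habitat %in% rare] <- "other"
  }
  pts$habitat <- factor(pts$habitat)
  d_road <- dist_to_roads(pts$x, pts$y, landscape$roads)
  pts$dist_road_m <- d_road
  pts$dist_road_scaled <- as.numeric(scale(d_road))
  rownames(pts) <- NULL
  pts
}

#' Fit a weighted resource-selection function
#'
#' Weighted logistic regression (no random intercepts: the 10/1
#' weighting encodes the constant used:availability ratio).
#' Between-days: `used ~ habitat * shooting_day`. Within-days:
#' `used ~ habitat * period * dist_road_scaled`. Evaluation: ROC/AUC on
#' the fitted probabilities plus a confusion matrix at probability 0.5.
#'
#' @param points [annotate_rsf_points()] output.
#' @param design `"between_days"` or `"within_days"`.
#' @return object of class `rsf_fit`: list with `fit` (the glm),
#'   `coefficients`, `evaluation` (AUC, sensitivity, specificity,
#'   accuracy, predictive power, confusion counts), `design`.
#' @export
fit_rsf <- function(points, design = c("between_days", "within_days")) {
  design <- match.arg(design)
  if (!all(c(0, 1) %in% points$used))
    stop("need both used and pseudoabsence rows")
  no_pseudo <- setdiff(unique(points$habitat[points$used == 1]),
                       unique(points$habitat[points$used == 0]))
  if (length(no_pseudo))
    warning("habitat level(s) without pseudoabsences (separation risk): ",
            paste(no_pseudo, collapse = ", "))
  d <- points
  d$habitat <- droplevels(factor(d$habitat))
  form <- if (design == "between_days") {
    d$shooting_day <- factor(ifelse(d$shooting_day, "shooting",
                                    "nonshooting"),
                             levels = c("nonshooting", "shooting"))
    if (length(unique(d$shooting_day[d$used == 1])) < 2) {
      message("fit_rsf: only one disturbance class present; ",
              "fitting habitat-only model")
      d$shooting_day <- droplevels(d$shooting_day)
      used ~ habitat
    } else used ~ habitat * shooting_day
  } else {
    d$period <- factor(d$period, levels = c("pre", "post"))
    if (length(unique(d$period[d$used == 1])) < 2) {
      message("fit_rsf: only one shooting period present; ",
              "fitting habitat * road model")
      d$period <- droplevels(d$period)
      used ~ habitat * dist_road_scaled
    } else used ~ habitat * period * dist_road_scaled
  }
  p <- ncol(stats::model.matrix(form, d))
  # start at zero: IRLS from the default mustart can diverge for large
  # prior weights even though the likelihood is weight-scale invariant
  fit <- suppressWarnings(
    stats::glm(form, data = d, family = stats::binomial("logit"),
               weights = d$weight, start = rep(0, p)))
  p <- stats::fitted(fit)
  roc <- pROC::roc(response = d$used, predictor = p, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  pred_pos <- p >= 0.5
  tp <- sum(pred_pos & d$used == 1); fp <- sum(pred_pos & d$used == 0)
  fn <- sum(!pred_pos & d$used == 1); tn <- sum(!pred_pos & d$used == 0)
  ev <- list(auc = as.numeric(pROC::auc(roc)),
             sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
             accuracy = (tp + tn) / length(p),
             predictive_power = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 evaluation = ev, design = design, data = d),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("<rsf_fit>", x$design, "| AUC", round(x$evaluation$auc, 3), "\n")
  invisible(x)
}

#' Relative probability of use per habitat
#'
#' Predicted use probability by habitat at reference levels of the
#' other covariates; with the 10:1 weighting and 1:10 used:pseudo
#' ratio, 0.5 means use in proportion to availability.
#'
#' @param rsf a [fit_rsf()] result (between-days design).
#' @param shooting predict for shooting (`TRUE`) or nonshooting days.
#' @return data.frame with `habitat` and `prob_use`.
#' @export
rsf_habitat_use <- function(rsf, shooting = FALSE) {
  stopifnot(rsf$design == "between_days")
  nd <- data.frame(habitat = factor(levels(rsf$data$habitat),
                                    levels = levels(rsf$data$habitat)),
                   shooting_day = factor(
                     if (shooting) "shooting" else "nonshooting",
                     levels = c("nonshooting", "shooting")))
  data.frame(habitat = as.character(nd$habitat),
             prob_use = as.numeric(stats::predict(rsf$fit, nd,
                                                  type = "response")))
}
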