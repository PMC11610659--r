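#' Generate a synthetic farmed-island landscape
#'
#' Builds the spatial scaffold the downstream analyses assume: a square
#' extent in projected metres; a block of farmland tiled by disjoint
#' rectangular farms, each subdivided into fields of which a subset is
#' designated for shooting; a seven-class habitat raster generated from
#' a smoothed Gaussian random field and classified at the exact
#' configured class proportions; a small road network; and communal
#' roost sites placed on wetland/coastal habitat.
#'
#' @param config a [sim_config()].
#' @return object of class `landscape`: a list with elements `extent`
#'   (xmin, xmax, ymin, ymax in m), `farms` and `fields` (data.frames of
#'   axis-aligned rectangles; fields carry a logical `shooting` flag),
#'   `habitat` (list: `res`, origin, integer code matrix; codes index
#'   [habitat_classes()]), `roads` (list of polyline matrices) and
#'   `roosts` (data.frame of points).
#' @export
generate_landscape <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  W <- config$extent_km * 1000
  extent <- list(xmin = 0, xmax = W, ymin = 0, ymax = W)

  ## -- farms: jittered grid tiling the central farmland block ----------
  n <- config$n_farms
  margin <- 0.1 * W
  block <- c(margin, W - margin)
  ncol_f <- max(2L, floor(sqrt(n)))
  rows_per_col <- rep(n %/% ncol_f, ncol_f)
  extra <- n - sum(rows_per_col)
  if (extra > 0) rows_per_col[seq_len(extra)] <- rows_per_col[seq_len(extra)] + 1L
  xcuts <- jitter_cuts(block[1], block[2], ncol_f)
  farms <- do.call(rbind, lapply(seq_len(ncol_f), function(j) {
    ycuts <- jitter_cuts(block[1], block[2], rows_per_col[j])
    data.frame(xmin = xcuts[j], xmax = xcuts[j + 1],
               ymin = ycuts[-length(ycuts)], ymax = ycuts[-1])
  }))
  farms <- cbind(id = sprintf("F%02d", seq_len(nrow(farms))), farms)

  ## -- fields: vertical strips within each farm ------------------------
  fields <- do.call(rbind, lapply(seq_len(nrow(farms)), function(i) {
    k <- sample(1:3, 1)
    cuts <- jitter_cuts(farms$xmin[i], farms$xmax[i], k)
    data.frame(farm_id = farms$id[i],
               xmin = cuts[-length(cuts)], xmax = cuts[-1],
               ymin = farms$ymin[i], ymax = farms$ymax[i])
  }))
  fields <- cbind(id = sprintf("P%03d", seq_len(nrow(fields))), fields)
  n_shoot <- max(1L, round(config$shooting_field_frac * nrow(fields)))
  fields$shooting <- FALSE
  fields$shooting[sample(nrow(fields), n_shoot)] <- TRUE

  ## -- habitat raster: smoothed field cut at exact proportions ---------
  res <- config$habitat_res_m
  ncell <- ceiling(W / res)
  coarse_n <- 12L
  coarse <- matrix(stats::rnorm(coarse_n^2), coarse_n, coarse_n)
  field <- bilinear_upscale(coarse, ncell) +
    matrix(stats::rnorm(ncell^2, sd = 0.15), ncell, ncell)
  props <- config$habitat_props[habitat_classes()]
  props[is.na(props)] <- 0
  codes <- cut_by_proportions(field, as.numeric(props))
  habitat <- list(res = res, xmin = 0, ymin = 0, n = ncell, codes = codes,
                  classes = habitat_classes())

  ## -- roads: jittered transects across the extent ---------------------
  roads <- c(
    lapply(c(0.3, 0.7), function(f) road_line(W, at = f * W, horizontal = TRUE)),
    lapply(c(0.25, 0.75), function(f) road_line(W, at = f * W, horizontal = FALSE))
  )

  ## -- roosts on freshwater / coastal cells ----------------------------
  wet_codes <- match(c("freshwater", "saltmarsh_coastal"), habitat_classes())
  wet <- which(matrix(codes %in% wet_codes, nrow(codes)), arr.ind = TRUE)
  if (nrow(wet) < config$n_roosts) {
    wet <- which(codes > 0, arr.ind = TRUE)
  }
  pick <- wet[sample(nrow(wet), config$n_roosts), , drop = FALSE]
  roosts <- data.frame(id = sprintf("R%d", seq_len(config$n_roosts)),
                       x = (pick[, "col"] - 0.5) * res,
                       y = (pick[, "row"] - 0.5) * res)

  structure(list(extent = extent, farms = farms, fields = fields,
                 habitat = habitat, roads = roads, roosts = roosts,
                 site_lat = config$site_lat, site_lon = config$site_lon),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape>", (x$extent$xmax - x$extent$xmin) / 1000, "km square,",
      nrow(x$farms), "farms /", nrow(x$fields), "fields (",
      sum(x$fields$shooting), "shooting ),",
      length(x$roads), "roads,", nrow(x$roosts), "roosts\n")
  invisible(x)
}

# n interior cuts jittered around an even partition of [lo, hi]
jitter_cuts <- function(lo, hi, k) {
  cuts <- seq(lo, hi, length.out = k + 1)
  if (k > 1) {
    w <- (hi - lo) / k
    inner <- cuts[2:k] + stats::runif(k - 1, -0.2 * w, 0.2 * w)
    cuts <- c(lo, sort(inner), hi)
  }
  cuts
}

bilinear_upscale <- function(m, n_out) {
  n_in <- nrow(m)
  pos <- seq(0.5 / n_out, 1 - 0.5 / n_out, length.out = n_out) * (n_in - 1) + 1
  i0 <- pmin(floor(pos), n_in - 1)
  f <- pos - i0
  row_interp <- m[i0, , drop = FALSE] * (1 - f) + m[i0 + 1, , drop = FALSE] * f
  row_interp[, i0, drop = FALSE] * rep(1 - f, each = n_out) +
    row_interp[, i0 + 1, drop = FALSE] * rep(f, each = n_out)
}

# Classify matrix values into integer codes at exact count proportions.
cut_by_proportions <- function(field, props) {
  n <- length(field)
  counts <- floor(props * n)
  while (sum(counts) < n) {
    i <- which.max(props * n - counts)
    counts[i] <- counts[i] + 1L
  }
  codes <- integer(n)
  codes[order(field)] <- rep.int(seq_along(props), counts)
  matrix(codes, nrow(field), ncol(field))
}

road_line <- function(W, at, horizontal) {
  s <- seq(0, W, length.out = 9)
  jit <- c(0, stats::runif(7, -0.03 * W, 0.03 * W), 0)
  if (horizontal) cbind(x = s, y = at + jit) else cbind(x = at + jit, y = s)
}

#' Habitat class at point locations
#'
#' @param landscape a [generate_landscape()] result.
#' @param x,y point coordinates in metres.
#' @return character vector of habitat class labels (`NA` off-raster).
#' @export
habitat_at <- function(landscape, x, y) {
  h <- landscape$habitat
  col <- floor((x - h$xmin) / h$res) + 1L
  row <- floor((y - h$ymin) / h$res) + 1L
  ok <- col >= 1 & col <= h$n & row >= 1 & row <= h$n
  out <- rep(NA_character_, length(x))
  out[ok] <- h$classes[h$codes[cbind(row[ok], col[ok])]]
  out
}

#' Empirical habitat class proportions of a landscape raster
#' @param landscape a [generate_landscape()] result.
#' @return named numeric vector over [habitat_classes()].
#' @export
habitat_proportions <- function(landscape) {
  tab <- tabulate(landscape$habitat$codes, nbins = 7)
  stats::setNames(tab / sum(tab), habitat_classes())
}

#' Farm containing each point
#' @param landscape a [generate_landscape()] result.
#' @param x,y coordinates in metres.
#' @return farm id or `NA` for points outside every farm. Boundary
#'   points count as inside (closed rectangles).
#' @export
farm_at <- function(landscape, x, y) {
  rect_id_at(x, y, landscape$farms)
}

#' Field containing each point
#' @inheritParams farm_at
#' @return field id or `NA`.
#' @export
field_at <- function(landscape, x, y) {
  rect_id_at(x, y, landscape$fields)
}
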