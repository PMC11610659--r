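# Readers, writers and fix annotation. All delimited files are plain
# CSV with documented headers; timestamps are ISO-8601 UTC.

TRACK_COLS <- c("individual_id", "species", "sex", "timestamp", "x", "y")
EVENT_COLS <- c("event_id", "timestamp", "field_id", "centroid_x",
                "centroid_y", "n_shots", "n_killed")
BURST_COLS <- c("burst_id", "individual_id", "timestamp", "label",
                "sample_id", "ax", "ay", "az")

parse_utc <- function(x, what, lines) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"), tz = "UTC")
  }
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop(sprintf("%s: unparseable timestamp on line(s) %s", what,
                 paste(utils::head(lines[bad], 5), collapse = ", ")))
  out
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(miss, collapse = ", ")))
}

#' Read a GPS track table
#'
#' Expects columns `individual_id, species, sex, timestamp, x, y`
#' (any annotation columns already present are kept). Validates
#' timestamps, coordinate numerics, and that timestamps are strictly
#' increasing within each individual.
#'
#' @param path CSV file path.
#' @return validated fix data.frame sorted by individual and time.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, TRACK_COLS, "tracks")
  lines <- seq_len(nrow(df)) + 1L
  df$timestamp <- parse_utc(df$timestamp, "tracks", lines)
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("tracks: non-numeric %s on line(s) %s", cc,
                   paste(utils::head(lines[bad], 5), collapse = ", ")))
    df[[cc]] <- v
  }
  df <- df[order(df$individual_id, df$timestamp), ]
  dup <- stats::ave(as.numeric(df$timestamp), df$individual_id,
                    FUN = function(t) c(FALSE, diff(t) <= 0)) > 0
  if (any(dup)) {
    ex <- df[dup, c("individual_id", "timestamp")][1, ]
    stop(sprintf(
      "tracks: duplicated/non-increasing timestamps per individual (%d rows, e.g. %s at %s)",
      sum(dup), ex$individual_id, format(ex$timestamp, tz = "UTC")))
  }
  rownames(df) <- NULL
  df
}

#' Write a GPS track table
#' @param fixes fix data.frame.
#' @param path output CSV path.
#' @export
write_tracks <- function(fixes, path) {
  fixes$timestamp <- format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(fixes, path, row.names = FALSE)
  invisible(path)
}

#' Read a shooting log
#'
#' Expects the field-log schema `event_id, timestamp, field_id,
#' centroid_x, centroid_y, n_shots, n_killed`.
#'
#' @param path CSV file path.
#' @return validated shooting-event data.frame sorted by time.
#' @export
read_shooting_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, EVENT_COLS, "shooting log")
  df$timestamp <- parse_utc(df$timestamp, "shooting log",
                            seq_len(nrow(df)) + 1L)
  if (any(df$n_killed > df$n_shots, na.rm = TRUE))
    stop("shooting log: n_killed exceeds n_shots on some rows")
  df <- df[order(df$timestamp), ]
  rownames(df) <- NULL
  df
}

#' Write a shooting log
#' @param events shooting-event data.frame.
#' @param path output CSV path.
#' @export
write_shooting_log <- function(events, path) {
  events$timestamp <- format(events$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read accelerometer bursts (long format)
#'
#' Expects `burst_id, individual_id, timestamp, label, sample_id, ax,
#' ay, az`; each burst must have at least two samples and equal-length
#' axes (guaranteed by the long format).
#'
#' @param path CSV file path.
#' @return validated long-format burst data.frame.
#' @export
read_bursts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, BURST_COLS, "bursts")
  df$timestamp <- parse_utc(df$timestamp, "bursts", seq_len(nrow(df)) + 1L)
  n <- table(df$burst_id)
  if (any(n < 2))
    stop("bursts: burst(s) with fewer than 2 samples: ",
         paste(utils::head(names(n)[n < 2], 5), collapse = ", "))
  df
}

#' Write accelerometer bursts
#' @param bursts long-format burst data.frame.
#' @param path output CSV path.
#' @export
write_bursts <- function(bursts, path) {
  bursts$timestamp <- format(bursts$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(bursts, path, row.names = FALSE)
  invisible(path)
}

#' Resample fixes to one per clock hour
#'
#' For each individual and clock hour keeps the single fix nearest the
#' hour mark, provided it lies within `tolerance_min` minutes of it;
#' ties go to the earlier fix. Hours with no fix inside the tolerance
#' window are left as gaps -- no interpolation. The operation is
#' idempotent.
#'
#' @param fixes fix data.frame.
#' @param tolerance_min half-width of the snapping window in minutes.
#' @return the retained subset of `fixes`.
#' @export
resample_hourly <- function(fixes, tolerance_min = 30) {
  if (!nrow(fixes)) return(fixes)
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), ]
  tt <- as.numeric(fixes$timestamp)
  hour_mark <- round(tt / 3600) * 3600
  offset <- abs(tt - hour_mark)
  ok <- offset <= tolerance_min * 60
  key <- paste(fixes$individual_id, hour_mark)
  # stable order => ties resolved toward the earlier fix
  best <- !duplicated(key[ok][order(offset[ok], method = "radix")])
  keep_idx <- which(ok)[order(offset[ok], method = "radix")][best]
  out <- fixes[sort(keep_idx), ]
  rownames(out) <- NULL
  out
}

#' Winter label for a vector of dates
#'
#' Winters run August--July and are labelled `"YYYY-YYYY+1"` after the
#' year in which they start (October--April is the tracked season).
#' @param dates `Date` vector.
#' @return character vector of winter labels.
#' @export
winter_label <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  start <- ifelse(m >= 8, y, y - 1L)
  sprintf("%d-%d", start, start + 1L)
}

#' Integer day index since 1 November of the winter
#'
#' 1 November = 1 (so 2 January = 63); October dates of the same winter
#' get non-positive indices.
#' @param dates `Date` vector.
#' @return integer vector.
#' @export
date_index_from <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  start <- ifelse(m >= 8, y, y - 1L)
  as.integer(dates - as.Date(sprintf("%d-11-01", start))) + 1L
}

#' Annotate fixes with winter, date index, day/night and farm
#'
#' Adds the modelling covariates used throughout the package: the
#' winter label (`"YYYY-YYYY+1"`, running October--April), the integer
#' day index since 1 November of that winter (1 November = 1), a solar
#' day/night flag, and the id of the farm polygon containing the fix
#' (`NA` outside all farms). Coordinates and timestamps are never
#' modified.
#'
#' @param fixes fix data.frame.
#' @param landscape a [generate_landscape()] result (or any object with
#'   `farms` rectangles and an `extent`).
#' @return `fixes` with columns `winter`, `date_index`, `is_day`,
#'   `farm_id` appended.
#' @export
annotate_fixes <- function(fixes, landscape) {
  if (!nrow(fixes)) {
    fixes$winter <- character(); fixes$date_index <- integer()
    fixes$is_day <- logical(); fixes$farm_id <- character()
    return(fixes)
  }
  dates <- as.Date(fixes$timestamp, tz = "UTC")
  fixes$winter <- winter_label(dates)
  fixes$date_index <- date_index_from(dates)
  fixes$is_day <- is_daylight(fixes$timestamp, landscape$site_lat,
                              landscape$site_lon)
  fixes$farm_id <- farm_at(landscape, fixes$x, fixes$y)
  ext <- landscape$extent
  off <- fixes$x < ext$xmin | fixes$x > ext$xmax |
    fixes$y < ext$ymin | fixes$y > ext$ymax
  if (any(off))
    warning(sum(off), " fix(es) outside the landscape extent; farm_id set NA")
  fixes
}

#' Write landscape vectors as GeoJSON and the habitat raster as an
#' ESRI ASCII grid
#'
#' @param landscape a [generate_landscape()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rect_feature <- function(r, props) {
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  fc <- function(features) list(type = "FeatureCollection", features = features)
  paths <- c(farms = file.path(dir, "farms.geojson"),
             fields = file.path(dir, "fields.geojson"),
             roads = file.path(dir, "roads.geojson"),
             roosts = file.path(dir, "roosts.geojson"),
             habitat = file.path(dir, "habitat.asc"))
  jsonlite::write_json(
    fc(lapply(seq_len(nrow(landscape$farms)), function(i)
      rect_feature(landscape$farms[i, ], list(id = landscape$farms$id[i])))),
    paths["farms"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    fc(lapply(seq_len(nrow(landscape$fields)), function(i)
      rect_feature(landscape$fields[i, ],
                   list(id = landscape$fields$id[i],
                        farm_id = landscape$fields$farm_id[i],
                        shooting = landscape$fields$shooting[i])))),
    paths["fields"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    fc(lapply(landscape$roads, function(r)
      list(type = "Feature", properties = list(),
           geometry = list(type = "LineString",
                           coordinates = lapply(seq_len(nrow(r)),
                                                function(k) r[k, ]))))),
    paths["roads"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    fc(lapply(seq_len(nrow(landscape$roosts)), function(i)
      list(type = "Feature",
           properties = list(id = landscape$roosts$id[i]),
           geometry = list(type = "Point",
                           coordinates = c(landscape$roosts$x[i],
                                           landscape$roosts$y[i]))))),
    paths["roosts"], auto_unbox = TRUE, digits = NA)
  h <- landscape$habitat
  con <- file(paths["habitat"], "w")
  writeLines(c(sprintf("ncols %d", h$n), sprintf("nrows %d", h$n),
               sprintf("xllcorner %f", h$xmin), sprintf("yllcorner %f", h$ymin),
               sprintf("cellsize %f", h$res), "NODATA_value -9999"), con)
  # ASCII grids run top row first
  for (r in h$n:1) writeLines(paste(h$codes[r, ], collapse = " "), con)
  close(con)
  invisible(paths)
}
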