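#' Analysis window
#'
#' The bounded observation period an animal's relocations are analysed
#' within. The study design behind this package uses 50-day seasonal
#' windows of hourly fixes, so `days = 50` is the default when only a
#' start is given.
#'
#' @param start,end POSIXct window bounds (end exclusive); `end` may be
#'   omitted in favour of `days`.
#' @param days window length in days, used when `end` is NULL.
#' @param season free-text season label (e.g. "summer").
#' @return an object of class `analysis_window`.
#' @export
analysis_window <- function(start, end = NULL, days = 50, season = "season") {
  start <- as.POSIXct(start)
  if (is.null(end)) end <- start + days * 86400 else end <- as.POSIXct(end)
  if (!is.finite(start) || !is.finite(end)) stop("window bounds must be finite")
  if (as.numeric(end) <= as.numeric(start)) stop("window end must be after start")
  structure(list(start = start, end = end, season = as.character(season)),
            class = "analysis_window")
}

window_days <- function(window) {
  as.numeric(difftime(window$end, window$start, units = "days"))
}

#' Hourly GPS trajectory
#'
#' One animal's time-ordered hourly relocation series within an analysis
#' window. Coordinates are planar metres in a projected CRS — every
#' statistic downstream is a metric distance, so geographic coordinates
#' must be projected before ingest. Gaps in the nominal 1-h cadence are
#' permitted and recorded, never interpolated here.
#'
#' @param animal_id animal label.
#' @param time POSIXct fix times (tz-aware), strictly increasing.
#' @param x,y planar coordinates in metres.
#' @param window an [analysis_window]; defaults to the span of `time`
#'   (end padded by one hour so the last fix is inside).
#' @param cadence_h nominal fix cadence in hours.
#' @param tol_min cadence tolerance in minutes (GPS scheduling jitter).
#' @return an object of class `trajectory`: list with `animal_id`, `fixes`
#'   (data.frame time/x/y), `window`, `gaps` (data.frame after_time/gap_h)
#'   and `cadence_h`, `tol_min`.
#' @export
trajectory <- function(animal_id, time, x, y, window = NULL,
                       cadence_h = 1, tol_min = 5) {
  time <- as.POSIXct(time)
  if (anyNA(time)) stop("fix times must be parseable timestamps")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("fix coordinates must be finite")
  if (length(time) != length(x) || length(x) != length(y))
    stop("time, x, y must have equal length")
  o <- order(time)
  time <- time[o]; x <- x[o]; y <- y[o]
  if (any(duplicated(time)))
    stop("duplicate timestamps for animal ", animal_id,
         " (duplicates are errors, not averaged)")
  if (is.null(window)) {
    window <- analysis_window(time[1], time[length(time)] + 3600)
  }
  inside <- time >= window$start & time < window$end
  n_dropped <- sum(!inside)
  time <- time[inside]; x <- x[inside]; y <- y[inside]
  dt_h <- diff(as.numeric(time)) / 3600
  gap <- which(dt_h > cadence_h + tol_min / 60)
  gaps <- data.frame(after_time = time[gap], gap_h = dt_h[gap])
  structure(list(
    animal_id = as.character(animal_id),
    fixes = data.frame(time = time, x = x, y = y),
    window = window, gaps = gaps, n_dropped = n_dropped,
    cadence_h = cadence_h, tol_min = tol_min),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> animal %s: %d fixes, %s [%s .. %s], %d gap(s)\n",
              x$animal_id, nrow(x$fixes), x$window$season,
              format(x$window$start), format(x$window$end), nrow(x$gaps)))
  invisible(x)
}

#' Number of fixes in a trajectory
#' @param traj a [trajectory].
#' @export
n_fixes <- function(traj) nrow(traj$fixes)

#' Parse a delimited fix table into trajectories
#'
#' Expects columns `id`, `timestamp`, `x`, `y` (ISO-8601 timestamps,
#' planar metre coordinates). One trajectory per animal; fixes are sorted,
#' fixes outside the window are dropped (count recorded on each
#' trajectory), and cadence gaps are recorded.
#'
#' @param rows a data.frame with the four columns, or a path to a CSV file.
#' @param window an [analysis_window] applied to every animal.
#' @param tz timezone used to interpret the timestamps.
#' @param reject_geographic error when every coordinate fits in lon/lat
#'   ranges — planar metres are required, and an entire table inside
#'   [-180, 180] x [-90, 90] is almost certainly unprojected.
#' @param ... passed on to [trajectory()] (cadence, tolerance).
#' @return named list of [trajectory] objects (one per animal id).
#' @export
parse_fix_table <- function(rows, window, tz = "UTC",
                            reject_geographic = TRUE, ...) {
  if (is.character(rows) && length(rows) == 1L)
    rows <- utils::read.csv(rows, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "x", "y")
  if (!all(need %in% names(rows)))
    stop("fix table must have columns: ", paste(need, collapse = ", "))
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  ts <- as.POSIXct(rep(NA_real_, nrow(rows)), tz = tz,
                   origin = "1970-01-01")
  for (fmt in fmts) {
    na <- is.na(ts)
    if (!any(na)) break
    ts[na] <- as.POSIXct(strptime(as.character(rows$timestamp[na]), fmt,
                                  tz = tz))
  }
  if (anyNA(ts))
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(which(is.na(ts)), 10L), collapse = ", "))
  x <- suppressWarnings(as.numeric(rows$x))
  y <- suppressWarnings(as.numeric(rows$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("non-numeric coordinate at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (reject_geographic && all(abs(x) <= 180) && all(abs(y) <= 90))
    stop("coordinates look geographic (lon/lat); project to planar metres ",
         "before ingest")
  if (anyDuplicated(paste(rows$id, format(ts, "%Y-%m-%d %H:%M:%S"))))
    stop("duplicate (id, timestamp) pairs in fix table")
  ids <- unique(as.character(rows$id))
  out <- lapply(ids, function(i) {
    sel <- as.character(rows$id) == i
    trajectory(i, ts[sel], x[sel], y[sel], window = window, ...)
  })
  names(out) <- ids
  out
}

#' Steps between successive fixes
#'
#' Euclidean distances between successive locations, with the elapsed time
#' of each step. Steps whose duration differs from the nominal cadence by
#' more than the tolerance are flagged; downstream hourly statistics
#' exclude flagged steps.
#'
#' @param traj a [trajectory].
#' @return data.frame with `start_time`, `hour` (clock hour of the start
#'   fix), `duration_h`, `distance_m`, `flagged`; zero rows when the
#'   trajectory has fewer than two fixes.
#' @export
step_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2L)
    return(data.frame(start_time = f$time[0], hour = integer(0),
                      duration_h = numeric(0), distance_m = numeric(0),
                      flagged = logical(0)))
  dur <- diff(as.numeric(f$time)) / 3600
  dist <- sqrt(diff(f$x)^2 + diff(f$y)^2)
  start <- f$time[-n]
  data.frame(
    start_time = start,
    hour = hour_of_day(start, tol_min = traj$tol_min),
    duration_h = dur,
    distance_m = dist,
    flagged = abs(dur - traj$cadence_h) > traj$tol_min / 60)
}

#' Local clock hour of a timestamp, with cadence snapping
#'
#' Returns the hour of day (0-23) in the timestamp's own timezone.
#' Timestamps within `tol_min` of a whole hour snap to that hour, so a fix
#' logged at 13:58 under a 5-minute tolerance counts as hour 14.
#'
#' @param time POSIXct vector carrying a timezone.
#' @param tol_min snapping tolerance in minutes.
#' @return integer vector of hours in 0-23.
#' @export
hour_of_day <- function(time, tol_min = 5) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  tzone <- attr(time, "tzone")
  if (is.null(tzone) || !nzchar(tzone[1]))
    stop("naive timestamp: `time` must carry an explicit timezone")
  lt <- as.POSIXlt(time)
  secs_into_hour <- lt$min * 60 + lt$sec
  snap_up <- secs_into_hour >= 3600 - tol_min * 60
  h <- lt$hour + as.integer(snap_up)
  as.integer(h %% 24)
}

#' Export fixes as a GeoJSON point collection
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixes_geojson <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  feats <- lapply(seq_len(nrow(f)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(f$x[i], f$y[i])),
         properties = list(animal_id = traj$animal_id,
                           timestamp = format(f$time[i], "%Y-%m-%dT%H:%M:%S%z")))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write trajectories back to the canonical CSV fix table
#'
#' @param trajs a [trajectory] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fix_table <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  tab <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(id = tr$animal_id,
               timestamp = format(tr$fixes$time, "%Y-%m-%dT%H:%M:%S"),
               x = tr$fixes$x, y = tr$fixes$y)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
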