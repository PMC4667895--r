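#' Water point
#'
#' A labelled point source with the 50-m "passing" threshold used to
#' collect near-water movement series, and (once derived or supplied) the
#' visit-detection radius.
#'
#' @param label point label.
#' @param x,y planar coordinates in metres.
#' @param pass_threshold_m passing-series threshold (default 50 m).
#' @param visit_radius_m visit-detection radius in metres; usually left
#'   NULL and derived via [visit_radius()] from the local mean hourly
#'   travel distance.
#' @return object of class `water_point`.
#' @export
water_point <- function(label, x, y, pass_threshold_m = 50,
                        visit_radius_m = NULL) {
  if (pass_threshold_m <= 0) stop("`pass_threshold_m` must be > 0")
  if (!is.null(visit_radius_m) && visit_radius_m <= 0)
    stop("`visit_radius_m` must be > 0")
  structure(list(label = as.character(label), x = x, y = y,
                 pass_threshold_m = pass_threshold_m,
                 visit_radius_m = visit_radius_m),
            class = "water_point")
}

#' Passing series near a water point
#'
#' Extracts every series of at least three consecutive locations passing
#' within the threshold of the point — all locations of a series but the
#' first and the last lie within `pass_threshold_m` — and the mean step
#' length (with SE) pooled over all steps of all series. That mean hourly
#' distance near the point is the empirical basis for the visit radius.
#'
#' @param traj a [trajectory].
#' @param wp a [water_point].
#' @return list with `series` (list of integer fix-index vectors),
#'   `mean_hourly_distance_m`, `se_m`, `n_steps`.
#' @export
passing_series <- function(traj, wp) {
  stopifnot(inherits(traj, "trajectory"), inherits(wp, "water_point"))
  f <- traj$fixes
  n <- nrow(f)
  d <- sqrt((f$x - wp$x)^2 + (f$y - wp$y)^2)
  inside <- d < wp$pass_threshold_m
  series <- list()
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    lo <- max(1L, starts[j] - 1L)   # flank with one fix each side when present
    hi <- min(n, ends[j] + 1L)
    if (hi - lo + 1L >= 3L) series[[length(series) + 1L]] <- lo:hi
  }
  if (length(series) == 0L) {
    warning("no passing series near water point ", wp$label)
    return(list(series = list(), mean_hourly_distance_m = NA_real_,
                se_m = NA_real_, n_steps = 0L))
  }
  steps <- unlist(lapply(series, function(ix) {
    sqrt(diff(f$x[ix])^2 + diff(f$y[ix])^2)
  }))
  list(series = series,
       mean_hourly_distance_m = mean(steps),
       se_m = if (length(steps) >= 2L)
         stats::sd(steps) / sqrt(length(steps)) else NA_real_,
       n_steps = length(steps))
}

#' Visit radius from the mean hourly distance near a water point
#'
#' Half the mean distance travelled per hour near the point, rounded up
#' to the nearest 10 m — the only rounding rule consistent with the three
#' published radius/mean pairs (879 m -> 440 m, 408 m -> 210 m,
#' 1633 m -> 820 m). Overridable per point by supplying
#' `visit_radius_m` directly to [water_point()].
#'
#' @param mean_hourly_distance_m positive mean hourly travel distance (m).
#' @return visit radius in metres.
#' @export
visit_radius <- function(mean_hourly_distance_m) {
  if (any(!is.finite(mean_hourly_distance_m)) ||
      any(mean_hourly_distance_m <= 0))
    stop("`mean_hourly_distance_m` must be positive")
  ceiling(mean_hourly_distance_m / 2 / 10) * 10
}

#' Detect visits to a water point
#'
#' Any location or maximal run of consecutive locations within the visit
#' radius (closed: distance equal to the radius counts as inside) is one
#' visit; the visit time is the time of the run's closest location to the
#' point (earliest such location on ties). By default a cadence gap
#' inside a run does not split the visit when the fixes on both sides are
#' in-radius (the animal plausibly stayed); `strict_gaps = TRUE` splits
#' runs at every cadence gap.
#'
#' @param traj a [trajectory].
#' @param wp a [water_point] with `visit_radius_m` set.
#' @param strict_gaps split in-radius runs at cadence gaps.
#' @return data.frame with one row per visit: `animal_id`, `water`,
#'   `time`, `hour`, `n_fixes`, `min_dist_m`.
#' @export
detect_visits <- function(traj, wp, strict_gaps = FALSE) {
  stopifnot(inherits(traj, "trajectory"), inherits(wp, "water_point"))
  if (is.null(wp$visit_radius_m))
    stop("water point ", wp$label, " has no visit radius set")
  f <- traj$fixes
  empty <- data.frame(animal_id = character(0), water = character(0),
                      time = f$time[0], hour = integer(0),
                      n_fixes = integer(0), min_dist_m = numeric(0))
  if (nrow(f) == 0L) return(empty)
  d <- sqrt((f$x - wp$x)^2 + (f$y - wp$y)^2)
  inside <- d <= wp$visit_radius_m
  runs <- .membership_runs(inside, as.numeric(f$time) / 3600,
                           cadence_h = traj$cadence_h,
                           tol_h = traj$tol_min / 60,
                           strict_gaps = strict_gaps)
  if (length(runs) == 0L) return(empty)
  out <- lapply(runs, function(ix) {
    best <- ix[which.min(d[ix])]  # which.min returns the earliest tie
    data.frame(animal_id = traj$animal_id, water = wp$label,
               time = f$time[best],
               hour = hour_of_day(f$time[best], tol_min = traj$tol_min),
               n_fixes = length(ix), min_dist_m = min(d[ix]))
  })
  do.call(rbind, out)
}

# maximal runs of TRUE in `inside`; with strict_gaps, a time gap larger
# than the cadence tolerance splits a run even if both sides are inside
.membership_runs <- function(inside, t_h, cadence_h = 1, tol_h = 5 / 60,
                             strict_gaps = FALSE) {
  n <- length(inside)
  if (n == 0L) return(list())
  brk <- logical(n)  # brk[i]: run may not continue from i-1 to i
  if (n > 1L && strict_gaps)
    brk[2:n] <- diff(t_h) > cadence_h + tol_h
  runs <- list()
  cur <- integer(0)
  for (i in seq_len(n)) {
    if (inside[i]) {
      if (length(cur) && brk[i]) { runs[[length(runs) + 1L]] <- cur; cur <- integer(0) }
      cur <- c(cur, i)
    } else if (length(cur)) {
      runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

#' Visit rate and diel histogram
#'
#' @param visits a [detect_visits()] table (possibly pooled over points).
#' @param window the [analysis_window] the visits fall in.
#' @return list with `rate_per_day` and `hour_histogram` (named 24-vector
#'   of visit counts by clock hour).
#' @export
visit_stats <- function(visits, window) {
  days <- window_days(window)
  if (days <= 0) stop("zero-length analysis window")
  hist <- integer(24)
  names(hist) <- as.character(0:23)
  if (nrow(visits)) {
    tb <- table(factor(visits$hour, levels = 0:23))
    hist[] <- as.integer(tb)
  }
  list(rate_per_day = nrow(visits) / days, hour_histogram = hist)
}
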