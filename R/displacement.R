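#' Hourly displacement profile
#'
#' Mean (and SE) of the distances between successive hourly locations,
#' per hour of day. Each valid 1-h step is assigned to the clock hour of
#' its start fix; steps flagged as spanning a cadence gap are excluded.
#'
#' @param traj a [trajectory].
#' @param bin_by bin steps by the hour of their "start" fix (default) or
#'   "end" fix.
#' @return data.frame of class `hourly_profile` with one row per hour
#'   0-23: `animal_id`, `season`, `hour`, `n`, `mean_m`, `se_m` (SE is NA
#'   where n < 2).
#' @export
hourly_mean_distance <- function(traj, bin_by = c("start", "end")) {
  bin_by <- match.arg(bin_by)
  steps <- step_series(traj)
  steps <- steps[!steps$flagged, , drop = FALSE]
  if (bin_by == "end")
    steps$hour <- hour_of_day(steps$start_time + steps$duration_h * 3600,
                              tol_min = traj$tol_min)
  if (nrow(steps) == 0L)
    warning("no valid hourly steps for animal ", traj$animal_id)
  out <- data.frame(animal_id = traj$animal_id,
                    season = traj$window$season,
                    hour = 0:23, n = 0L, mean_m = NA_real_, se_m = NA_real_)
  for (h in 0:23) {
    d <- steps$distance_m[steps$hour == h]
    out$n[h + 1L] <- length(d)
    if (length(d) >= 1L) out$mean_m[h + 1L] <- mean(d)
    if (length(d) >= 2L) out$se_m[h + 1L] <- stats::sd(d) / sqrt(length(d))
  }
  class(out) <- c("hourly_profile", "data.frame")
  out
}

#' Cross-animal mean displacement over a set of hours
#'
#' Two-stage summary matching the "mean +/- SE of the individual means"
#' convention: first the per-animal mean over the listed hour bins
#' (weighted by each bin's step count), then the mean and SE of those
#' per-animal means.
#'
#' @param profiles list of [hourly_mean_distance()] profiles (one per
#'   animal).
#' @param hours integer clock hours to pool (subset of 0-23).
#' @return list with `mean_m`, `se_m` (NA for a single animal),
#'   `n_animals` and `animal_means`.
#' @export
period_mean_distance <- function(profiles, hours) {
  if (length(hours) == 0L) stop("`hours` must be a non-empty set")
  if (!all(hours %in% 0:23)) stop("`hours` must be clock hours in 0-23")
  if (inherits(profiles, "hourly_profile")) profiles <- list(profiles)
  am <- vapply(profiles, function(p) {
    sel <- p$hour %in% hours & p$n > 0L
    if (!any(sel)) return(NA_real_)
    stats::weighted.mean(p$mean_m[sel], p$n[sel])
  }, numeric(1))
  am <- am[!is.na(am)]
  list(mean_m = mean(am),
       se_m = if (length(am) >= 2L) stats::sd(am) / sqrt(length(am)) else NA_real_,
       n_animals = length(am), animal_means = am)
}

#' Spearman correlation between activity and displacement
#'
#' Rank correlation (average ranks on ties) between the per-hour
#' proportion of active behavioural scans and the per-hour mean distance
#' travelled, over a common set of hours.
#'
#' @param activity_props data.frame with columns `hour` and `prop_active`.
#' @param profile an [hourly_mean_distance()] profile, or any data.frame
#'   with columns `hour` and `mean_m`.
#' @param hours hours to correlate over; default is the hours present in
#'   both series.
#' @return list with `rho` and `n`.
#' @export
activity_distance_correlation <- function(activity_props, profile,
                                          hours = NULL) {
  if (is.null(hours))
    hours <- intersect(activity_props$hour,
                       profile$hour[!is.na(profile$mean_m)])
  a <- activity_props$prop_active[match(hours, activity_props$hour)]
  d <- profile$mean_m[match(hours, profile$hour)]
  ok <- !is.na(a) & !is.na(d)
  if (sum(ok) < 3L) stop("need at least 3 common hours for a correlation")
  list(rho = stats::cor(a[ok], d[ok], method = "spearman"), n = sum(ok))
}
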