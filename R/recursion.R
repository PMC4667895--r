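#' Recursion analysis configuration
#'
#' The focal-circle radius (chosen in the field study in relation to the
#' median and mean hourly travel distances), the upper duration bound for
#' periodicity fitting, and the scanned phase range.
#'
#' @param radius_m focal circle radius in metres (default 200).
#' @param fit_t_max_h largest duration (h) binned for the periodic
#'   Poisson fits (default 168 = 7 days).
#' @param k_range integer phases scanned (default 0:23).
#' @param strict_gaps split in-circle runs at cadence gaps; by default an
#'   unobserved hour flanked by in-circle fixes does not break a run.
#' @return object of class `recursion_config`.
#' @export
recursion_config <- function(radius_m = 200, fit_t_max_h = 168,
                             k_range = 0:23, strict_gaps = FALSE) {
  if (radius_m <= 0) stop("`radius_m` must be > 0")
  if (fit_t_max_h < 24) stop("`fit_t_max_h` must be at least 24")
  stopifnot(all(k_range %in% 0:23))
  structure(list(radius_m = radius_m, fit_t_max_h = fit_t_max_h,
                 k_range = as.integer(k_range), strict_gaps = strict_gaps),
            class = "recursion_config")
}

# per-focal decomposition over a precomputed membership vector.
# t_h: fix times in hours; brk: TRUE where a run may not continue across
# i-1 -> i (strict gap splitting); end_h: window end in hours.
.decompose_membership <- function(inside, t_h, focal, brk, end_h) {
  n <- length(inside)
  prev_in <- c(FALSE, inside[-n])
  starts <- inside & (!prev_in | brk)
  run_id <- cumsum(starts)
  run_id[!inside] <- NA_integer_
  fr <- run_id[focal]
  members <- which(!is.na(run_id) & run_id == fr)
  res_h <- t_h[members[length(members)]] - t_h[members[1]] + 1
  t_exit <- t_h[members[length(members)]]
  later <- which(inside & seq_len(n) > members[length(members)])
  if (length(later)) {
    rec_h <- t_h[later[1]] - t_exit - 1
    censored <- FALSE
  } else {
    rec_h <- end_h - t_exit
    censored <- TRUE
  }
  list(residence_h = as.integer(round(res_h)),
       recursion_h = as.integer(round(rec_h)),
       censored = censored,
       n_visits = as.integer(sum(starts)))
}

#' Residence/recursion/visit metrics for one focal fix
#'
#' Centres a circle of `radius_m` on the focal fix and evaluates in/out
#' membership at every fix of the window: the residence time is the span
#' (in hours) of the maximal in-circle run containing the focal fix; the
#' recursion time is the number of hours spent beyond the radius between
#' that run's end and the next in-circle fix (right-censored at the
#' window end when the animal never returns, carrying the time from the
#' final exit to the window end); the number of visits is the count of
#' maximal in-circle runs over the whole window.
#'
#' @param traj a [trajectory].
#' @param focal_index fix index (1-based) of the focal location.
#' @param cfg a [recursion_config].
#' @return list with `animal_id`, `focal_index`, `residence_h`,
#'   `recursion_h`, `censored`, `n_visits`.
#' @export
focal_visit_decomposition <- function(traj, focal_index,
                                      cfg = recursion_config()) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  n <- nrow(f)
  if (focal_index < 1L || focal_index > n) stop("invalid `focal_index`")
  t_h <- as.numeric(f$time) / 3600
  d <- sqrt((f$x - f$x[focal_index])^2 + (f$y - f$y[focal_index])^2)
  brk <- .gap_breaks(t_h, traj, cfg$strict_gaps)
  res <- .decompose_membership(d <= cfg$radius_m, t_h, focal_index, brk,
                               as.numeric(traj$window$end) / 3600)
  c(list(animal_id = traj$animal_id, focal_index = focal_index), res)
}

.gap_breaks <- function(t_h, traj, strict_gaps) {
  n <- length(t_h)
  brk <- logical(n)
  if (strict_gaps && n > 1L)
    brk[2:n] <- diff(t_h) > traj$cadence_h + traj$tol_min / 60
  brk
}

#' Recursion metrics for every location of a trajectory
#'
#' One [focal_visit_decomposition()] record per fix, plus the summary
#' mean number of visits per location for the animal-season.
#'
#' @param traj a [trajectory].
#' @param cfg a [recursion_config].
#' @return data.frame of class `recursion_table` with one row per fix
#'   (`animal_id`, `season`, `focal_index`, `time`, `x`, `y`, `hour`,
#'   `residence_h`, `recursion_h`, `censored`, `n_visits`); the mean
#'   number of visits per location is attached as attribute
#'   `mean_visits`.
#' @export
recursion_table <- function(traj, cfg = recursion_config()) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  n <- nrow(f)
  if (n == 0L) stop("empty trajectory")
  t_h <- as.numeric(f$time) / 3600
  brk <- .gap_breaks(t_h, traj, cfg$strict_gaps)
  end_h <- as.numeric(traj$window$end) / 3600
  res_h <- integer(n); rec_h <- integer(n); cen <- logical(n); nv <- integer(n)
  r2 <- cfg$radius_m^2
  for (i in seq_len(n)) {
    inside <- (f$x - f$x[i])^2 + (f$y - f$y[i])^2 <= r2
    z <- .decompose_membership(inside, t_h, i, brk, end_h)
    res_h[i] <- z$residence_h; rec_h[i] <- z$recursion_h
    cen[i] <- z$censored; nv[i] <- z$n_visits
  }
  out <- data.frame(animal_id = traj$animal_id,
                    season = traj$window$season,
                    focal_index = seq_len(n), time = f$time,
                    x = f$x, y = f$y,
                    hour = hour_of_day(f$time, tol_min = traj$tol_min),
                    residence_h = res_h, recursion_h = rec_h,
                    censored = cen, n_visits = nv)
  attr(out, "mean_visits") <- mean(nv)
  attr(out, "radius_m") <- cfg$radius_m
  class(out) <- c("recursion_table", "data.frame")
  out
}

#' Kaplan-Meier curve of recursion times
#'
#' Product-limit estimate of the survival curve of (right-censored)
#' recursion times, with the median taken as the smallest time at which
#' survival drops to 0.5 or below (undefined when survival never reaches
#' 0.5).
#'
#' @param durations_h duration values in hours.
#' @param censored logical vector; TRUE marks a right-censored duration.
#' @return object of class `km_curve`: list with `time`, `surv`,
#'   `n_risk`, `n_event` and `median_h` (NA when undefined).
#' @export
km_curve <- function(durations_h, censored = rep(FALSE, length(durations_h))) {
  if (length(durations_h) == 0L) stop("need at least one duration")
  if (length(censored) != length(durations_h))
    stop("`censored` must match `durations_h` in length")
  if (all(durations_h <= 0))
    stop("all durations censored at time zero: nothing to estimate")
  fit <- survival::survfit(
    survival::Surv(durations_h, !censored) ~ 1,
    conf.type = "none")
  med <- suppressWarnings(min(fit$time[fit$surv <= 0.5]))
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median_h = if (is.finite(med)) med else NA_real_),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d event times; median %s h\n", length(x$time),
              if (is.na(x$median_h)) "undefined" else format(x$median_h)))
  invisible(x)
}

#' Pooled recursion durations for model fitting
#'
#' The per-focal first-recursion durations of all fixes of all supplied
#' animal-season tables, uncensored only — the sample the periodic
#' Poisson models are fitted to. `all_gaps = TRUE` instead pools every
#' inter-visit gap of every focal circle (the alternative pooled
#' histogram; see the methods vignette).
#'
#' @param tables one [recursion_table] or a list of them.
#' @param all_gaps pool all inter-visit gaps rather than first
#'   recursions. This requires the originating trajectories and is
#'   computed directly from the stored fix coordinates.
#' @return integer vector of uncensored durations in hours.
#' @export
recursion_durations <- function(tables, all_gaps = FALSE) {
  if (inherits(tables, "recursion_table")) tables <- list(tables)
  if (!all_gaps) {
    return(unlist(lapply(tables, function(tb)
      tb$recursion_h[!tb$censored])))
  }
  unlist(lapply(tables, function(tb) {
    r2 <- attr(tb, "radius_m")
    if (is.null(r2)) r2 <- 200
    out <- integer(0)
    t_h <- as.numeric(tb$time) / 3600
    for (i in seq_len(nrow(tb))) {
      inside <- (tb$x - tb$x[i])^2 + (tb$y - tb$y[i])^2 <= r2^2
      ends <- which(inside & c(inside[-1] == FALSE, TRUE))
      starts <- which(inside & c(TRUE, inside[-length(inside)] == FALSE))
      if (length(starts) > 1L)
        out <- c(out, as.integer(round(
          t_h[starts[-1]] - t_h[ends[-length(ends)]] - 1)))
    }
    out
  }))
}
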