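# Shared fixture builders and independent oracles.
# Oracles deliberately use naive scans/loops, never the package's own
# vectorized code paths.

t0_utc <- as.POSIXct("2013-08-12 00:00:00", tz = "UTC")

# hourly trajectory from coordinate vectors
make_traj <- function(x, y, id = "T1", start = t0_utc, window = NULL,
                      season = "summer") {
  n <- length(x)
  if (is.null(window))
    window <- analysis_window(start, start + n * 3600, season = season)
  trajectory(id, start + 3600 * (seq_len(n) - 1), x, y, window = window)
}

# trajectory whose fixes sit at given distances from a reference point
# (placed along +x), handy for circle-membership cases
traj_at_distances <- function(d, ...) make_traj(x = d, y = rep(0, length(d)), ...)

# random-walk trajectory (plain, no landscape) for oracle comparisons
random_walk_traj <- function(n, step_sd = 150, seed = 1, ...) {
  set.seed(seed)
  make_traj(cumsum(stats::rnorm(n, sd = step_sd)),
            cumsum(stats::rnorm(n, sd = step_sd)), ...)
}

# tiny constant-value landscape stack on an nr x nc grid
flat_landscape <- function(nr = 10, nc = 10, cellsize = 30, elev = 500,
                           ndvi = 0.1, thalweg = 0) {
  mk <- function(v) land_raster(matrix(v, nr, nc), c(0, 0), cellsize)
  structure(list(elevation = mk(elev), slope = mk(0), aspect = mk(0),
                 ndvi = mk(ndvi), thalweg = mk(thalweg),
                 stream_network = list(),
                 water_points = data.frame(label = character(0),
                                           x = numeric(0), y = numeric(0))),
            class = "landscape_stack")
}

## ---- oracles -------------------------------------------------------------

# brute-force focal decomposition: explicit scan, no cumsum/rle tricks
oracle_focal <- function(traj, focal, radius) {
  f <- traj$fixes
  n <- nrow(f)
  t_h <- as.numeric(f$time) / 3600
  inside <- logical(n)
  for (j in seq_len(n))
    inside[j] <- sqrt((f$x[j] - f$x[focal])^2 +
                      (f$y[j] - f$y[focal])^2) <= radius
  # walk left and right from the focal fix to find its run
  lo <- focal
  while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- focal
  while (hi < n && inside[hi + 1]) hi <- hi + 1
  residence <- round(t_h[hi] - t_h[lo] + 1)
  nxt <- NA_integer_
  j <- hi + 1
  while (j <= n) {
    if (inside[j]) { nxt <- j; break }
    j <- j + 1
  }
  if (is.na(nxt)) {
    recursion <- round(as.numeric(traj$window$end) / 3600 - t_h[hi])
    censored <- TRUE
  } else {
    recursion <- round(t_h[nxt] - t_h[hi] - 1)
    censored <- FALSE
  }
  nv <- 0L
  j <- 1L
  while (j <= n) {
    if (inside[j] && (j == 1L || !inside[j - 1L])) nv <- nv + 1L
    j <- j + 1L
  }
  list(residence_h = residence, recursion_h = recursion,
       censored = censored, n_visits = nv)
}

# hand product-limit estimator
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv,
       median = if (any(surv <= 0.5)) ts[which(surv <= 0.5)[1]] else NA_real_)
}

# transitive-closure clustering: repeatedly merge any two groups holding
# points within the link distance
oracle_components <- function(x, y, link) {
  n <- length(x)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      if (grp[i] != grp[j] &&
          sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= link) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# Spearman rho from explicitly averaged ranks
oracle_spearman <- function(a, b) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    # mean position of equal values in the sorted order
    r
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
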