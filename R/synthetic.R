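#' Simulation configuration
#'
#' Parameters of the synthetic landscape and movement generator. Defaults
#' describe the arid-highlands study system the package's analyses were
#' designed around: a ~4.5 x 4.5 km rocky-hills landscape on a 30-m grid,
#' five collared animals tracked hourly over a 50-day seasonal window,
#' diel habitat switching (high ground by day, vegetated streambeds by
#' night) and, in the summer configuration, approximately daily visits to
#' a permanent water point performed around dusk.
#'
#' @param season "summer" or "winter"; sets the water-visit probability
#'   and NDVI contrast defaults.
#' @param nrow,ncol grid dimensions in cells.
#' @param cellsize cell size in metres (one shared grid for all layers).
#' @param seed base seed; all stage randomness flows from it via named
#'   substreams (landscape, per-animal walk, water days).
#' @param n_individuals number of simulated animals.
#' @param days window length in days.
#' @param start window start time (POSIXct, tz-aware).
#' @param step_scale_m mean hourly step length (gamma-distributed lengths).
#' @param turn_sd_rad SD of the wrapped-normal heading turn.
#' @param n_candidates candidate headings scored per step (softmax choice).
#' @param hour_weights 24 x 4 matrix of per-hour attraction weights on the
#'   standardized elevation, ndvi, thalweg layers and on proximity to the
#'   territory centre; NULL builds the default diel schedule (elevation by
#'   day, vegetation/thalweg by night).
#' @param p_water_day daily probability of a steered trip to the nearest
#'   water point (summer default 1, winter 0.1).
#' @param water_hours clock hours during which water steering may run
#'   (default 19:00-23:00, the dusk visit peak).
#' @param water_speed_m steering speed towards water, metres per hour.
#' @param territory_radius_m scale of the quadratic pull towards the
#'   territory centre that keeps ranges bounded.
#' @param elev_range_m landscape elevation range (metres a.s.l.).
#' @param ndvi_base,ndvi_contrast baseline NDVI and its elevation inside
#'   thalwegs (sparse dryland vegetation concentrated along streambeds).
#' @param n_water number of water points placed on the stream network.
#' @param n_streams number of traced drainage lines.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(season = c("summer", "winter"),
                       nrow = 150, ncol = 150, cellsize = 30,
                       seed = 1L,
                       n_individuals = 5, days = 50,
                       start = as.POSIXct(
                         if (match.arg(season) == "summer")
                           "2013-08-12 00:00:00" else "2013-12-12 00:00:00",
                         tz = "UTC"),
                       step_scale_m = 400, turn_sd_rad = 0.8,
                       n_candidates = 24,
                       hour_weights = NULL,
                       p_water_day = if (match.arg(season) == "summer") 1 else 0.1,
                       water_hours = 19:23, water_speed_m = 1500,
                       territory_radius_m = 1500,
                       elev_range_m = c(470, 1037),
                       ndvi_base = 0.10,
                       ndvi_contrast = if (match.arg(season) == "summer") 0.08 else 0.04,
                       n_water = 2, n_streams = 4) {
  season <- match.arg(season)
  if (nrow < 50 || ncol < 50) stop("grid must be at least 50 x 50 cells")
  if (p_water_day < 0 || p_water_day > 1) stop("p_water_day must be in [0, 1]")
  if (is.null(hour_weights)) hour_weights <- default_hour_weights()
  stopifnot(is.matrix(hour_weights), nrow(hour_weights) == 24,
            ncol(hour_weights) == 4, all(is.finite(hour_weights)))
  structure(list(
    season = season, nrow = nrow, ncol = ncol, cellsize = cellsize,
    seed = as.integer(seed), n_individuals = n_individuals, days = days,
    start = start, step_scale_m = step_scale_m, turn_sd_rad = turn_sd_rad,
    n_candidates = n_candidates, hour_weights = hour_weights,
    p_water_day = p_water_day, water_hours = water_hours,
    water_speed_m = water_speed_m, territory_radius_m = territory_radius_m,
    elev_range_m = elev_range_m, ndvi_base = ndvi_base,
    ndvi_contrast = ndvi_contrast, n_water = n_water, n_streams = n_streams),
    class = "sim_config")
}

#' Default diel attraction schedule
#'
#' Columns: elevation, ndvi, thalweg, territory pull. Day hours (8-16)
#' attract to high standardized elevation; night hours (20-04) to high
#' NDVI and thalwegs; the territory pull is constant.
#'
#' @return a 24 x 4 numeric matrix (rows = hours 0-23).
#' @export
default_hour_weights <- function() {
  w <- matrix(0, 24, 4, dimnames = list(NULL, c("elevation", "ndvi",
                                                "thalweg", "territory")))
  day <- 8:16 + 1L
  night <- c(20:23, 0:4) + 1L
  w[day, "elevation"] <- 2.0
  w[night, "ndvi"] <- 1.5
  w[night, "thalweg"] <- 1.5
  w[, "territory"] <- 1
  w
}

# deterministic substream seed derived from a base seed and a label
substream_seed <- function(seed, label, index = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(paste0(label, ":", index)))
    h <- (h * 131 + ch) %% 2147483647  # doubles stay exact below 2^53
  as.integer(h)
}

# mean-preserving Gaussian smoothing with edge replication
smooth_matrix <- function(m, sigma_cells) {
  L <- max(1L, ceiling(3 * sigma_cells))
  w <- stats::dnorm(-L:L, sd = sigma_cells)
  w <- w / sum(w)
  nr <- nrow(m); nc <- ncol(m)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, nr, nc)
  for (d in -L:L) {       # rows
    out <- out + w[d + L + 1L] * m[clamp(seq_len(nr) + d, nr), , drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (d in -L:L) {       # columns
    out2 <- out2 + w[d + L + 1L] * out[, clamp(seq_len(nc) + d, nc), drop = FALSE]
  }
  out2
}

#' Generate a synthetic landscape stack
#'
#' Builds co-registered habitat layers on one grid: a smooth random
#' elevation field, a drainage (stream) network traced by steepest
#' descent, a thalweg mask as the 25-m buffer of that network, NDVI
#' elevated inside thalwegs by the configured contrast, slope and aspect
#' derived from the elevation, and 1-3 water points placed on the
#' network. Fully reproducible per seed.
#'
#' @param cfg a [sim_config].
#' @param seed optional override of `cfg$seed`.
#' @return an object of class `landscape_stack`: list of [land_raster]
#'   layers (`elevation`, `slope`, `aspect`, `ndvi`, `thalweg`), plus
#'   `stream_network` (list of 2-column vertex matrices) and
#'   `water_points` (data.frame label/x/y).
#' @export
generate_landscape <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(seed, "landscape"))
  nr <- cfg$nrow; nc <- cfg$ncol; cs <- cfg$cellsize
  z <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sigma_cells = 8)
  z <- (z - min(z)) / (max(z) - min(z))
  z <- cfg$elev_range_m[1] + z * diff(cfg$elev_range_m)
  elevation <- land_raster(z, origin = c(0, 0), cellsize = cs)

  network <- trace_streams(elevation, n_streams = cfg$n_streams)
  thalweg <- buffer_network(network, elevation, buffer_m = 25)

  ndvi_v <- cfg$ndvi_base +
    smooth_matrix(matrix(stats::rnorm(nr * nc, sd = 0.05), nr, nc), 4) +
    cfg$ndvi_contrast * thalweg$values
  ndvi_v <- pmin(pmax(ndvi_v, 0), 0.35)
  ndvi <- land_raster(ndvi_v, c(0, 0), cs)

  terr <- derive_terrain(elevation)

  verts <- do.call(rbind, network)
  n_water <- max(1L, min(cfg$n_water, nrow(verts)))
  wi <- sample.int(nrow(verts), n_water)
  water_points <- data.frame(label = paste0("W", seq_len(n_water)),
                             x = verts[wi, 1], y = verts[wi, 2])

  structure(list(
    elevation = elevation, slope = terr$slope, aspect = terr$aspect,
    ndvi = ndvi, thalweg = thalweg,
    stream_network = network, water_points = water_points),
    class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d cells @ %g m; %d stream line(s), %d water point(s)\n",
              nrow(x$elevation$values), ncol(x$elevation$values),
              x$elevation$cellsize, length(x$stream_network),
              nrow(x$water_points)))
  invisible(x)
}

# trace drainage lines by steepest descent from high ground
trace_streams <- function(elevation, n_streams = 4, max_len = 400L) {
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  cs <- elevation$cellsize
  # start from cells in the top elevation quartile, away from the border
  cand <- which(z > stats::quantile(z, 0.75), arr.ind = TRUE)
  cand <- cand[cand[, 1] > 2 & cand[, 1] < nr - 1 &
               cand[, 2] > 2 & cand[, 2] < nc - 1, , drop = FALSE]
  starts <- cand[sample.int(nrow(cand), min(n_streams, nrow(cand))), ,
                 drop = FALSE]
  lines <- list()
  for (s in seq_len(nrow(starts))) {
    r <- starts[s, 1]; c <- starts[s, 2]
    path <- matrix(NA_real_, 0, 2)
    for (step in seq_len(max_len)) {
      path <- rbind(path, c(elevation$origin[1] + (c - 0.5) * cs,
                            elevation$origin[2] + (r - 0.5) * cs))
      nb_r <- pmin(pmax(r + c(-1, -1, -1, 0, 0, 1, 1, 1), 1L), nr)
      nb_c <- pmin(pmax(c + c(-1, 0, 1, -1, 1, -1, 0, 1), 1L), nc)
      vals <- z[cbind(nb_r, nb_c)]
      k <- which.min(vals)
      if (vals[k] >= z[r, c]) break  # local minimum reached
      r <- nb_r[k]; c <- nb_c[k]
      if (r == 1L || r == nr || c == 1L || c == nc) break
    }
    if (nrow(path) >= 2L) lines[[length(lines) + 1L]] <- path
  }
  lines
}

# standardize a raster layer over its whole extent (z-score)
.std_layer <- function(r) {
  v <- r$values
  s <- stats::sd(v)
  if (s == 0) return(land_raster(v * 0, r$origin, r$cellsize))
  land_raster((v - mean(v)) / s, r$origin, r$cellsize)
}

#' Simulate one animal's trajectory
#'
#' A biased correlated random walk at hourly cadence: each hour a set of
#' candidate headings (previous heading plus wrapped-normal turns, each
#' with its own gamma step length) is scored by the hour-specific habitat
#' weights at the candidate position, and one candidate is chosen by
#' softmax. On "water days" (Bernoulli per day) the walk is steered to
#' the nearest water point during the designated evening hours until it
#' comes within 50 m. Positions are clamped to the landscape bounds.
#' Reproducible per (seed, animal_id).
#'
#' @param cfg a [sim_config].
#' @param land a [landscape_stack].
#' @param animal_id label for the simulated animal.
#' @param seed optional override of `cfg$seed`.
#' @param centre optional territory centre (x, y in metres); default is
#'   drawn per animal near the landscape centre.
#' @return a [trajectory].
#' @export
simulate_trajectory <- function(cfg, land, animal_id, seed = cfg$seed,
                                centre = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(land, "landscape_stack"))
  n_hours <- as.integer(round(cfg$days * 24))
  if (n_hours < 1L) stop("empty schedule: window must cover at least 1 hour")
  grid <- land$elevation
  xmax <- grid$origin[1] + ncol(grid$values) * grid$cellsize
  ymax <- grid$origin[2] + nrow(grid$values) * grid$cellsize
  layers <- list(elevation = .std_layer(land$elevation),
                 ndvi = .std_layer(land$ndvi),
                 thalweg = land$thalweg)  # binary layer kept on its own scale

  set.seed(substream_seed(seed, "waterdays", .label_index(animal_id)))
  water_day <- stats::runif(cfg$days + 1L) < cfg$p_water_day

  set.seed(substream_seed(seed, "walk", .label_index(animal_id)))
  if (is.null(centre))
    centre <- c(stats::runif(1, 0.35, 0.65) * xmax,
                stats::runif(1, 0.35, 0.65) * ymax)
  pos <- centre
  heading <- stats::runif(1, 0, 2 * pi)
  times <- cfg$start + 3600 * (seq_len(n_hours) - 1)
  hours <- hour_of_day(times)
  days_idx <- floor(as.numeric(difftime(times, cfg$start, units = "days"))) + 1L
  xs <- numeric(n_hours); ys <- numeric(n_hours)
  xs[1] <- pos[1]; ys[1] <- pos[2]
  watered_today <- FALSE
  shape <- 2  # gamma shape for step lengths; scale set to match the mean

  for (i in 2:n_hours) {
    if (i > 2L && days_idx[i] != days_idx[i - 1L]) watered_today <- FALSE
    h <- hours[i - 1L]
    steer <- water_day[days_idx[i]] && !watered_today &&
      (h %in% cfg$water_hours) && nrow(land$water_points) > 0L
    if (steer) {
      dw <- sqrt((land$water_points$x - pos[1])^2 +
                 (land$water_points$y - pos[2])^2)
      j <- which.min(dw)
      if (dw[j] <= 50) {
        # already at the water: hold position for this hour (drinking)
        watered_today <- TRUE
      } else {
        len <- min(dw[j], cfg$water_speed_m)
        ang <- atan2(land$water_points$y[j] - pos[2],
                     land$water_points$x[j] - pos[1])
        pos <- pos + len * c(cos(ang), sin(ang))
        heading <- ang
        if (sqrt((land$water_points$x[j] - pos[1])^2 +
                 (land$water_points$y[j] - pos[2])^2) <= 50)
          watered_today <- TRUE
      }
    }
    if (!steer) {
      nc_ <- cfg$n_candidates
      turns <- stats::rnorm(nc_, 0, cfg$turn_sd_rad) %% (2 * pi)
      lens <- stats::rgamma(nc_, shape = shape,
                            scale = cfg$step_scale_m / shape)
      angs <- heading + turns
      cx <- pmin(pmax(pos[1] + lens * cos(angs), grid$origin[1]), xmax)
      cy <- pmin(pmax(pos[2] + lens * sin(angs), grid$origin[2]), ymax)
      w <- cfg$hour_weights[h + 1L, ]
      score <- w[1] * extract_values(layers$elevation, cx, cy, strict = FALSE) +
        w[2] * extract_values(layers$ndvi, cx, cy, strict = FALSE) +
        w[3] * extract_values(layers$thalweg, cx, cy, strict = FALSE) -
        w[4] * ((cx - centre[1])^2 + (cy - centre[2])^2) /
          cfg$territory_radius_m^2
      score[is.na(score)] <- -Inf
      p <- exp(score - max(score))
      k <- sample.int(nc_, 1L, prob = p / sum(p))
      pos <- c(cx[k], cy[k])
      if (lens[k] > 0) heading <- angs[k]
    }
    xs[i] <- pos[1]; ys[i] <- pos[2]
  }
  window <- analysis_window(cfg$start, cfg$start + cfg$days * 86400,
                            season = cfg$season)
  trajectory(animal_id, times, xs, ys, window = window)
}

.label_index <- function(label) {
  sum(utf8ToInt(as.character(label))) %% 1000L
}

#' Simulate a full cohort
#'
#' One trajectory per individual under a shared landscape.
#'
#' @param cfg a [sim_config].
#' @param land optional pre-generated [landscape_stack].
#' @return list with `landscape` and `trajectories` (named list).
#' @export
simulate_cohort <- function(cfg, land = NULL) {
  if (is.null(land)) land <- generate_landscape(cfg)
  ids <- sprintf("A%02d", seq_len(cfg$n_individuals))
  trajs <- lapply(ids, function(id) simulate_trajectory(cfg, land, id))
  names(trajs) <- ids
  list(landscape = land, trajectories = trajs)
}

#' Sample recursion durations from a periodic Poisson model
#'
#' Draws, for each integer duration t in `t_range`, a Poisson count with
#' the model's intensity lambda(t), and expands the counts into a duration
#' multiset. The three usable intensity families are the non-oscillating
#' log-linear/log-log model and its two 24-h periodic extensions:
#' \deqn{\log \lambda = a_0 + a_1 t + a_2 \log t \; [+\; a_3 \cos(2\pi(t+k)/24)
#'   \;\mathrm{or}\; a_3 \log(\cos(2\pi(t+k)/24)+2)]}
#'
#' @param coef named numeric vector `c(a0, a1, a2, a3)`; `a3` ignored for
#'   the non-periodic model.
#' @param model "M3" (no oscillation), "M4" (cosine) or "M5" (log-cosine).
#' @param k integer phase in 0-23 (periodic models only).
#' @param t_range integer durations (hours) to sample over, from 1 up.
#' @param n optional target total count; when given, `a0` is shifted so
#'   that the expected total over `t_range` equals `n`.
#' @param seed RNG seed.
#' @return integer vector of durations (hours), one entry per sampled
#'   recursion event.
#' @export
sample_recursion_durations <- function(coef, model = c("M3", "M4", "M5"),
                                       k = 0L, t_range = 1:168, n = NULL,
                                       seed = 1L) {
  model <- match.arg(model)
  if (!all(is.finite(coef))) stop("coefficients must be finite")
  if (any(t_range < 1)) stop("t_range must start at 1 or later")
  lam <- periodic_lambda(coef, model, k, t_range)
  if (any(!is.finite(lam)))
    stop("lambda overflow at t = ",
         paste(utils::head(t_range[!is.finite(lam)], 5L), collapse = ", "))
  if (!is.null(n)) lam <- lam * n / sum(lam)
  set.seed(substream_seed(seed, "durations"))
  counts <- stats::rpois(length(t_range), lam)
  rep(as.integer(t_range), counts)
}

# intensity lambda(t) for the M3/M4-k/M5-k families
periodic_lambda <- function(coef, model, k, t) {
  a <- rep(0, 4)
  a[seq_along(coef)] <- coef
  eta <- a[1] + a[2] * t + a[3] * log(t)
  if (model == "M4") eta <- eta + a[4] * cos(2 * pi * (t + k) / 24)
  if (model == "M5") eta <- eta + a[4] * log(cos(2 * pi * (t + k) / 24) + 2)
  exp(eta)
}
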