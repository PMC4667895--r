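#' Northern exposure of a slope
#'
#' \eqn{E_N = \sin\theta \cos\alpha}: the orthogonal projection, on the
#' south-north axis, of the unit vector normal to the terrain surface.
#' Ranges from -1 for a south-facing vertical slope to +1 for a
#' north-facing vertical slope; 0 on flat ground.
#'
#' @param slope_deg slope angle theta in degrees, in `[0, 90]`.
#' @param aspect_deg slope azimuth alpha in degrees clockwise from north,
#'   in `[0, 360)`.
#' @return numeric vector of E_N values in `[-1, 1]`.
#' @export
northern_exposure <- function(slope_deg, aspect_deg) {
  if (any(!is.finite(slope_deg)) || any(!is.finite(aspect_deg)))
    stop("angles must be finite")
  if (any(slope_deg < 0 | slope_deg > 90))
    stop("`slope_deg` must lie in [0, 90]")
  if (any(aspect_deg < 0 | aspect_deg >= 360))
    stop("`aspect_deg` must lie in [0, 360)")
  sin(slope_deg * pi / 180) * cos(aspect_deg * pi / 180)
}

#' The five habitat variables
#' @return character vector of variable names used throughout.
#' @export
habitat_variables <- function() {
  c("thalweg", "ndvi", "elevation", "slope", "northern_exposure")
}

#' Sample a habitat variable at point locations
#'
#' Nearest-cell lookup of one of the five habitat variables on a
#' [landscape_stack]; northern exposure is computed on the fly from the
#' slope and aspect cells.
#'
#' @param x,y point coordinates in metres.
#' @param land a [landscape_stack].
#' @param variable one of [habitat_variables()].
#' @param strict error when a point falls off the raster (default);
#'   otherwise NA.
#' @return numeric vector of sampled values.
#' @export
sample_habitat <- function(x, y, land, variable, strict = TRUE) {
  variable <- match.arg(variable, habitat_variables())
  if (variable == "northern_exposure") {
    th <- extract_values(land$slope, x, y, strict = strict)
    al <- extract_values(land$aspect, x, y, strict = strict)
    out <- rep(NA_real_, length(x))
    ok <- !is.na(th) & !is.na(al)
    out[ok] <- northern_exposure(th[ok], al[ok])
    return(out)
  }
  extract_values(land[[variable]], x, y, strict = strict)
}

#' Use-versus-availability selection coefficient
#'
#' \deqn{SC = (\mathrm{mean}_{use} - \mathrm{mean}_{avail}) /
#'   \mathrm{SD}_{avail}}
#' The availability SD uses the sample (n-1) denominator. A zero
#' availability SD makes the coefficient undefined: `NA` is returned
#' (never 0), and undefined values propagate as missing downstream.
#'
#' @param use habitat values at used locations (non-empty).
#' @param avail habitat values at availability nodes.
#' @return a single numeric SC, or NA when undefined.
#' @export
selection_coefficient <- function(use, avail) {
  use <- use[!is.na(use)]; avail <- avail[!is.na(avail)]
  if (length(use) == 0L) stop("`use` must be non-empty")
  if (length(avail) < 2L) return(NA_real_)
  s <- stats::sd(avail)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (mean(use) - mean(avail)) / s
}

#' Diel selection-coefficient profile
#'
#' For each habitat variable and each hour of day, the selection
#' coefficient contrasting the animal's in-range locations recorded at
#' that hour (use) against the nodes of a square availability lattice
#' covering the same home range.
#'
#' @param traj a [trajectory].
#' @param land a [landscape_stack].
#' @param hr the animal-season's 95% [home_range].
#' @param node_spacing_m availability-lattice spacing (default 30 m).
#' @return data.frame with columns `animal_id`, `season`, `variable`,
#'   `hour`, `n` (in-mask locations at that hour) and `sc` (NA when
#'   undefined: no locations, or zero availability SD).
#' @export
sc_profile <- function(traj, land, hr, node_spacing_m = 30) {
  stopifnot(inherits(traj, "trajectory"), inherits(hr, "home_range"))
  f <- traj$fixes
  maskr <- land_raster(hr$mask * 1, hr$grid$origin, hr$grid$cellsize)
  inmask <- extract_values(maskr, f$x, f$y, strict = FALSE)
  inmask <- !is.na(inmask) & inmask == 1
  hrs <- hour_of_day(f$time, tol_min = traj$tol_min)
  nodes <- grid_nodes(hr, node_spacing_m)
  out <- vector("list", length(habitat_variables()))
  for (vi in seq_along(habitat_variables())) {
    v <- habitat_variables()[vi]
    avail <- sample_habitat(nodes$x, nodes$y, land, v, strict = FALSE)
    use_all <- sample_habitat(f$x, f$y, land, v, strict = FALSE)
    sc <- rep(NA_real_, 24)
    nh <- integer(24)
    for (h in 0:23) {
      sel <- inmask & hrs == h & !is.na(use_all)
      nh[h + 1L] <- sum(sel)
      if (nh[h + 1L] > 0L)
        sc[h + 1L] <- selection_coefficient(use_all[sel], avail)
    }
    out[[vi]] <- data.frame(animal_id = traj$animal_id,
                            season = traj$window$season,
                            variable = v, hour = 0:23, n = nh, sc = sc)
  }
  do.call(rbind, out)
}

#' Habitat summary of a home range
#'
#' Mean of each habitat variable over the availability nodes of a home
#' range — the per-range baseline used when flagging recursion-site
#' characteristics.
#'
#' @param hr a [home_range].
#' @param land a [landscape_stack].
#' @param node_spacing_m lattice spacing in metres.
#' @return named numeric vector of means (thalweg as a proportion).
#' @export
home_range_habitat_means <- function(hr, land, node_spacing_m = 30) {
  nodes <- grid_nodes(hr, node_spacing_m)
  vapply(habitat_variables(), function(v) {
    mean(sample_habitat(nodes$x, nodes$y, land, v, strict = FALSE),
         na.rm = TRUE)
  }, numeric(1))
}
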