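#' Parameters of the movement-based utilization distribution
#'
#' @param T_max maximum step duration (h) across which interpolation is
#'   performed; longer steps (gaps) contribute endpoint kernels only.
#' @param tau interpolation time step (h) along each retained step.
#' @param L_min minimum step length (m) for interpolation; shorter steps
#'   contribute their endpoints only.
#' @param h_min kernel bandwidth (m; isotropic Gaussian SD).
#' @param b kept for provenance with the time-dependent-bandwidth
#'   estimator this simplifies; unused (variance growth not modelled).
#' @return object of class `ud_params`.
#' @export
ud_params <- function(T_max = 2.5, tau = 0.1, L_min = 50, h_min = 100, b = 0) {
  if (any(c(T_max, tau, L_min, h_min) <= 0)) stop("UD parameters must be > 0")
  if (tau >= T_max) stop("`tau` must be smaller than `T_max`")
  structure(list(T_max = T_max, tau = tau, L_min = L_min, h_min = h_min,
                 b = b), class = "ud_params")
}

#' Movement-based kernel utilization distribution
#'
#' A simplified movement-based kernel density estimate: every step with
#' duration <= T_max and length >= L_min is densified by linear
#' interpolation every `tau` hours, an isotropic Gaussian kernel of
#' bandwidth `h_min` is centred at every observed and interpolated point,
#' and the summed surface is normalized to integrate to one over the
#' grid. Smoothing along steps (rather than at fixes alone) carries the
#' serial correlation of hourly relocations into the surface; the
#' time-dependent bandwidth of the full estimator is deliberately not
#' reproduced.
#'
#' @param traj a [trajectory] with at least 2 fixes.
#' @param params a [ud_params].
#' @param grid a [land_raster] defining the target grid.
#' @return a [land_raster] of class `c("ud_raster", "land_raster")` whose
#'   values are probability densities (1/m^2).
#' @export
movement_kernel_ud <- function(traj, params = ud_params(), grid) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "ud_params"),
            inherits(grid, "land_raster"))
  f <- traj$fixes
  if (nrow(f) < 2L) stop("need at least 2 fixes for a UD")
  px <- f$x; py <- f$y
  dur <- diff(as.numeric(f$time)) / 3600
  len <- sqrt(diff(f$x)^2 + diff(f$y)^2)
  for (i in which(dur <= params$T_max & len >= params$L_min)) {
    nseg <- floor(dur[i] / params$tau)
    if (nseg < 2L) next
    frac <- seq_len(nseg - 1L) / nseg
    px <- c(px, f$x[i] + frac * (f$x[i + 1L] - f$x[i]))
    py <- c(py, f$y[i] + frac * (f$y[i + 1L] - f$y[i]))
  }
  dens <- .kernel_surface(px, py, grid, params$h_min)
  cell_area <- grid$cellsize^2
  total <- sum(dens) * cell_area
  if (total <= 0) stop("all kernel mass fell outside the grid")
  out <- land_raster(dens / total, grid$origin, grid$cellsize)
  class(out) <- c("ud_raster", "land_raster")
  out
}

# sum of truncated Gaussian kernels evaluated at cell centres
.kernel_surface <- function(px, py, grid, h, trunc_sd = 4) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cellsize
  dens <- matrix(0, nr, nc)
  rad <- ceiling(trunc_sd * h / cs)
  cx0 <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  cy0 <- grid$origin[2] + (seq_len(nr) - 0.5) * cs
  for (i in seq_along(px)) {
    c0 <- floor((px[i] - grid$origin[1]) / cs) + 1
    r0 <- floor((py[i] - grid$origin[2]) / cs) + 1
    cl <- max(1L, c0 - rad); cu <- min(nc, c0 + rad)
    rl <- max(1L, r0 - rad); ru <- min(nr, r0 + rad)
    if (cl > nc || cu < 1L || rl > nr || ru < 1L) next
    gx <- stats::dnorm(cx0[cl:cu], px[i], h)
    gy <- stats::dnorm(cy0[rl:ru], py[i], h)
    dens[rl:ru, cl:cu] <- dens[rl:ru, cl:cu] + outer(gy, gx)
  }
  dens
}

#' Isopleth home range from a utilization distribution
#'
#' Smallest-area cell set containing at least `level` of the probability
#' mass, built by greedy inclusion in descending density order (density
#' ties broken in row-major cell order).
#'
#' @param ud a `ud_raster` from [movement_kernel_ud()].
#' @param level isopleth level in (0, 1), e.g. 0.95.
#' @return object of class `home_range`: list with `level`, logical
#'   `mask` matrix, `grid` (origin/cellsize) and `area_km2`.
#' @export
isopleth_mask <- function(ud, level) {
  stopifnot(inherits(ud, "land_raster"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be a single number in (0, 1)")
  v <- as.vector(ud$values)
  nr <- nrow(ud$values)
  row <- (seq_along(v) - 1L) %% nr + 1L
  col <- (seq_along(v) - 1L) %/% nr + 1L
  ord <- order(-v, row, col)
  cell_area <- ud$cellsize^2
  cum <- cumsum(v[ord]) * cell_area
  n_in <- which(cum >= level)[1]
  if (is.na(n_in)) n_in <- length(v)  # mass short of level: take everything
  mask <- matrix(FALSE, nr, ncol(ud$values))
  mask[ord[seq_len(n_in)]] <- TRUE
  structure(list(level = level, mask = mask,
                 grid = list(origin = ud$origin, cellsize = ud$cellsize),
                 area_km2 = n_in * cell_area / 1e6),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("<home_range> %d%% isopleth: %.2f km2 (%d cells @ %g m)\n",
              round(100 * x$level), x$area_km2, sum(x$mask),
              x$grid$cellsize))
  invisible(x)
}

#' Availability nodes on a square lattice over a home range
#'
#' A square lattice with the given spacing, anchored at the minimum
#' corner of the mask's bounding box; nodes whose containing cell belongs
#' to the mask are returned. The number of lattice candidates examined is
#' attached as attribute `n_candidates`.
#'
#' @param hr a [home_range].
#' @param spacing_m lattice spacing in metres (default 30).
#' @return data.frame with node `x`, `y`.
#' @export
grid_nodes <- function(hr, spacing_m = 30) {
  stopifnot(inherits(hr, "home_range"))
  if (spacing_m <= 0) stop("`spacing_m` must be positive")
  if (!any(hr$mask)) stop("empty home-range mask")
  cs <- hr$grid$cellsize
  idx <- which(hr$mask, arr.ind = TRUE)
  x0 <- hr$grid$origin[1] + (min(idx[, 2]) - 1) * cs
  y0 <- hr$grid$origin[2] + (min(idx[, 1]) - 1) * cs
  x1 <- hr$grid$origin[1] + max(idx[, 2]) * cs
  y1 <- hr$grid$origin[2] + max(idx[, 1]) * cs
  gx <- seq(x0, x1, by = spacing_m)
  gy <- seq(y0, y1, by = spacing_m)
  nodes <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  r <- land_raster(hr$mask * 1, hr$grid$origin, cs)
  inmask <- extract_values(r, nodes$x, nodes$y, strict = FALSE)
  keep <- !is.na(inmask) & inmask == 1
  out <- nodes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- nrow(nodes)
  out
}
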