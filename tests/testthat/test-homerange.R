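small_grid <- function(n = 40, cs = 30) land_raster(matrix(0, n, n), c(0, 0), cs)

test_that("utilization distribution normalizes and peaks at a point cluster", {
  grid <- small_grid()
  centre <- c(600, 600)
  tr <- make_traj(rep(centre[1], 6), rep(centre[2], 6))
  ud <- movement_kernel_ud(tr, ud_params(), grid)
  expect_equal(sum(ud$values) * ud$cellsize^2, 1, tolerance = 1e-6)
  peak <- which(ud$values == max(ud$values), arr.ind = TRUE)
  cc <- cell_centres(grid)
  pk <- cc[cc$row == peak[1, 1] & cc$col == peak[1, 2], ]
  expect_lt(sqrt((pk$x - centre[1])^2 + (pk$y - centre[2])^2), 45)
  # radial symmetry: equal-offset cells carry equal density
  expect_equal(extract_values(ud, centre[1] + 105, centre[2]),
               extract_values(ud, centre[1] - 105, centre[2]),
               tolerance = 1e-9)
  expect_equal(extract_values(ud, centre[1] + 105, centre[2]),
               extract_values(ud, centre[1], centre[2] + 105),
               tolerance = 1e-9)
})

test_that("a step is smoothed along its path, matching the closed form", {
  grid <- small_grid()
  p <- ud_params(T_max = 2.5, tau = 0.1, L_min = 50, h_min = 100)
  a <- c(100, 600); b <- c(1100, 600)  # 1 km apart, 1-h step
  tr <- make_traj(c(a[1], b[1]), c(a[2], b[2]))
  ud <- movement_kernel_ud(tr, p, grid)

  # independent closed form: Gaussian kernels at the fixes plus the
  # tau-interpolated points, evaluated directly
  frac <- seq_len(9) / 10
  px <- c(a[1], b[1], a[1] + frac * (b[1] - a[1]))
  py <- rep(600, 11)
  closed_form <- function(x, y)
    sum(stats::dnorm(x, px, 100) * stats::dnorm(y, py, 100))
  # evaluate at exact cell centres (the grid the surface lives on),
  # inside the kernel truncation range
  mid <- c(615, 615); off <- c(615, 915)
  expect_equal(extract_values(ud, mid[1], mid[2]) /
                 extract_values(ud, off[1], off[2]),
               closed_form(mid[1], mid[2]) / closed_form(off[1], off[2]),
               tolerance = 1e-6)
  expect_gt(extract_values(ud, mid[1], mid[2]),
            extract_values(ud, off[1], off[2]))
})

test_that("short and long steps contribute endpoint kernels only", {
  grid <- small_grid()
  p <- ud_params(T_max = 2.5, tau = 0.1, L_min = 50, h_min = 100)
  # 40-m step, below L_min: no interpolation -> two kernels
  tr_short <- make_traj(c(600, 640), c(600, 600))
  ud_s <- movement_kernel_ud(tr_short, p, grid)
  cf <- function(x, y, px, py)
    sum(stats::dnorm(x, px, 100) * stats::dnorm(y, py, 100))
  r_impl <- extract_values(ud_s, 615, 615) / extract_values(ud_s, 615, 915)
  r_cf <- cf(615, 615, c(600, 640), c(600, 600)) /
          cf(615, 915, c(600, 640), c(600, 600))
  expect_equal(r_impl, r_cf, tolerance = 1e-6)

  # 3-h step, above T_max: same as the short-step rule
  tr_gap <- trajectory("a", t0_utc + 3600 * c(0, 3), c(100, 1100),
                       c(600, 600))
  ud_g <- movement_kernel_ud(tr_gap, p, grid)
  r_impl_g <- extract_values(ud_g, 105, 615) / extract_values(ud_g, 405, 615)
  r_cf_g <- cf(105, 615, c(100, 1100), c(600, 600)) /
            cf(405, 615, c(100, 1100), c(600, 600))
  expect_equal(r_impl_g, r_cf_g, tolerance = 1e-6)
})

test_that("isopleths take the smallest cell set reaching the level", {
  # uniform density over a 10 x 10 block
  v <- matrix(0, 20, 20)
  v[6:15, 6:15] <- 1
  ud <- land_raster(v / (sum(v) * 30^2), c(0, 0), 30)
  class(ud) <- c("ud_raster", "land_raster")
  hr <- isopleth_mask(ud, 0.95)
  expect_equal(sum(hr$mask), 95)
  expect_equal(hr$area_km2, 95 * 900 / 1e6)

  hr50 <- isopleth_mask(ud, 0.50)
  expect_true(all(hr$mask[hr50$mask]))  # nesting
  expect_error(isopleth_mask(ud, 1.2), "level")
})

test_that("greedy isopleth equals the exhaustive threshold sweep", {
  set.seed(12)
  grid <- small_grid(25)
  tr <- make_traj(c(rnorm(30, 250, 60), rnorm(10, 550, 60)),
                  c(rnorm(30, 250, 60), rnorm(10, 500, 60)))
  ud <- movement_kernel_ud(tr, ud_params(), grid)
  hr <- isopleth_mask(ud, 0.95)
  # oracle: lower the density threshold until the included mass reaches
  # the level; the greedy mask must equal that threshold set
  v <- sort(as.vector(ud$values), decreasing = TRUE)
  mass <- cumsum(v) * ud$cellsize^2
  ncut <- which(mass >= 0.95)[1]
  expect_equal(sum(hr$mask), ncut)
  expect_true(all(ud$values[hr$mask] >= v[ncut]))
  # areas weakly increase with level
  areas <- vapply(c(0.2, 0.5, 0.8, 0.95),
                  function(l) isopleth_mask(ud, l)$area_km2, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("availability lattice covers the mask at the stated spacing", {
  # full 10 x 10 mask of 30-m cells: 11 x 11 lattice candidates
  v <- matrix(1, 10, 10)
  ud <- land_raster(v / (sum(v) * 30^2), c(0, 0), 30)
  hr <- isopleth_mask(ud, 0.995)
  expect_equal(sum(hr$mask), 100)
  nodes <- grid_nodes(hr, 30)
  expect_equal(attr(nodes, "n_candidates"), 121L)
  expect_equal(nrow(nodes), 121L)

  # single-cell mask still yields a node
  ud1 <- land_raster(matrix(c(1 / 900, rep(0, 99)), 10, 10), c(0, 0), 30)
  expect_equal(sum(isopleth_mask(ud, 0.99)$mask), 99)  # exact-mass cutoff
  hr1 <- isopleth_mask(ud1, 0.5)
  expect_equal(sum(hr1$mask), 1)
  expect_gte(nrow(grid_nodes(hr1, 30)), 1L)

  # spacing beyond the mask extent leaves at most a handful of corner nodes
  wide <- grid_nodes(hr, 10 * 30 * 2)
  expect_lte(nrow(wide), 1L)
  expect_error(grid_nodes(hr, -5), "positive")
})
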