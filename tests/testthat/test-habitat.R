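test_that("northern exposure follows its analytic limits", {
  expect_equal(northern_exposure(90, 180), -1)
  expect_equal(northern_exposure(90, 0), 1)
  expect_equal(northern_exposure(0, 123), 0)
  expect_equal(northern_exposure(30, 0), 0.5)
  expect_error(northern_exposure(95, 0), "slope")
  expect_error(northern_exposure(45, 360), "aspect")
  expect_error(northern_exposure(NA, 0), "finite")
})

test_that("habitat sampling reads the right cells for all five variables", {
  land <- flat_landscape(8, 8)
  land$elevation$values[3, 5] <- 900
  land$ndvi$values[3, 5] <- 0.25
  land$thalweg$values[3, 5] <- 1
  land$slope$values[3, 5] <- 30
  land$aspect$values[3, 5] <- 0
  x <- 4.5 * 30; y <- 2.5 * 30  # centre of cell [3, 5]
  expect_equal(sample_habitat(x, y, land, "elevation"), 900)
  expect_equal(sample_habitat(x, y, land, "ndvi"), 0.25)
  expect_equal(sample_habitat(x, y, land, "thalweg"), 1)
  expect_equal(sample_habitat(x, y, land, "slope"), 30)
  expect_equal(sample_habitat(x, y, land, "northern_exposure"), 0.5)
  expect_equal(sample_habitat(10, 10, land, "northern_exposure"), 0)
  expect_error(sample_habitat(-50, 10, land, "ndvi"), "off the raster")

  set.seed(4)
  land$elevation$values[] <- rnorm(64, 800, 50)
  px <- runif(20, 0, 240); py <- runif(20, 0, 240)
  manual <- land$elevation$values[cbind(floor(py / 30) + 1,
                                        floor(px / 30) + 1)]
  expect_equal(sample_habitat(px, py, land, "elevation"), manual)
})

test_that("selection coefficient is the standardized use-availability contrast", {
  expect_equal(selection_coefficient(c(2, 4), c(1, 3, 5)), 0)
  got <- selection_coefficient(c(1, 1), c(0, 0, 1, 1))
  expect_equal(got, 0.5 / stats::sd(c(0, 0, 1, 1)))
  expect_equal(got, 0.866, tolerance = 1e-3)
  # affine invariance
  u <- c(3, 5, 8); a <- c(1, 4, 9, 2)
  expect_equal(selection_coefficient(3 * u + 7, 3 * a + 7),
               selection_coefficient(u, a))
  # sign flip when use and availability are swapped after centring
  expect_equal(sign(selection_coefficient(a, u)),
               -sign(selection_coefficient(u, a)))
  expect_true(is.na(selection_coefficient(c(1, 2), c(5, 5, 5))))
  expect_error(selection_coefficient(numeric(0), c(1, 2)), "non-empty")
})

test_that("diel SC profile equals a direct use/availability recomputation", {
  set.seed(19)
  land <- flat_landscape(12, 12)
  land$elevation$values[] <- rnorm(144, 800, 60)
  land$ndvi$values[] <- runif(144, 0.05, 0.2)
  tr <- make_traj(runif(96, 30, 330), runif(96, 30, 330))
  ud <- movement_kernel_ud(tr, ud_params(), land$elevation)
  hr <- isopleth_mask(ud, 0.95)
  prof <- sc_profile(tr, land, hr)
  expect_equal(nrow(prof), 5 * 24)

  nodes <- grid_nodes(hr, 30)
  maskr <- land_raster(hr$mask * 1, hr$grid$origin, hr$grid$cellsize)
  for (v in c("elevation", "ndvi")) {
    avail <- sample_habitat(nodes$x, nodes$y, land, v)
    for (h in c(3, 14)) {
      f <- tr$fixes
      sel <- as.POSIXlt(f$time)$hour == h &
        extract_values(maskr, f$x, f$y, strict = FALSE) == 1
      expected <- (mean(sample_habitat(f$x[sel], f$y[sel], land, v)) -
                     mean(avail)) / stats::sd(avail)
      expect_equal(prof$sc[prof$variable == v & prof$hour == h], expected)
      expect_equal(prof$n[prof$variable == v & prof$hour == h], sum(sel))
    }
  }
})

test_that("uniform habitat yields undefined (not zero) SC", {
  land <- flat_landscape(12, 12)
  tr <- make_traj(runif(48, 30, 330), runif(48, 30, 330))
  ud <- movement_kernel_ud(tr, ud_params(), land$elevation)
  hr <- isopleth_mask(ud, 0.95)
  prof <- sc_profile(tr, land, hr)
  elev <- prof[prof$variable == "elevation", ]
  expect_true(all(is.na(elev$sc)))
  expect_true(any(elev$n > 0))
})

test_that("locations placed one availability-SD above the mean give SC = 1", {
  land <- flat_landscape(10, 10)
  set.seed(2)
  land$elevation$values[] <- rnorm(100, 800, 40)
  v <- matrix(1, 10, 10)
  ud <- land_raster(v / (sum(v) * 30^2), c(0, 0), 30)
  hr <- isopleth_mask(ud, 0.99)
  nodes <- grid_nodes(hr, 30)
  avail <- sample_habitat(nodes$x, nodes$y, land, "elevation")
  target <- mean(avail) + stats::sd(avail)
  # engineer one cell to hold exactly the target value and park the
  # animal there around the clock
  land$elevation$values[4, 6] <- target
  avail2 <- sample_habitat(nodes$x, nodes$y, land, "elevation")
  x <- 5.5 * 30; y <- 3.5 * 30
  tr <- make_traj(rep(x, 48), rep(y, 48))
  prof <- sc_profile(tr, land, hr)
  elev <- prof[prof$variable == "elevation", ]
  expected <- (target - mean(avail2)) / stats::sd(avail2)
  expect_equal(elev$sc, rep(expected, 24))
})
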