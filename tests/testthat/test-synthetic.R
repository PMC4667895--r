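cfg_small <- function(season = "summer", seed = 5, days = 10, ...) {
  sim_config(season, nrow = 60, ncol = 60, seed = seed, n_individuals = 1,
             days = days, ...)
}

test_that("landscape generation is deterministic per seed", {
  l1 <- generate_landscape(cfg_small())
  l2 <- generate_landscape(cfg_small())
  expect_identical(l1$elevation$values, l2$elevation$values)
  expect_identical(l1$ndvi$values, l2$ndvi$values)
  expect_identical(l1$water_points, l2$water_points)
  l3 <- generate_landscape(cfg_small(seed = 6))
  expect_false(identical(l1$elevation$values, l3$elevation$values))
})

test_that("landscape layers respect their invariants", {
  l <- generate_landscape(cfg_small())
  expect_true(all(l$slope$values >= 0 & l$slope$values <= 90))
  expect_true(all(l$aspect$values >= 0 & l$aspect$values < 360))
  expect_true(all(l$thalweg$values %in% c(0, 1)))
  expect_true(all(l$ndvi$values >= 0))
  expect_gte(nrow(l$water_points), 1)
  expect_error(generate_landscape(sim_config(nrow = 10, ncol = 10)),
               "50 x 50")
})

test_that("NDVI is elevated inside thalwegs by the configured contrast", {
  l <- generate_landscape(cfg_small(ndvi_contrast = 0.1))
  inside <- l$thalweg$values == 1
  expect_gt(mean(l$ndvi$values[inside]), mean(l$ndvi$values[!inside]))

  l0 <- generate_landscape(cfg_small(ndvi_contrast = 0))
  inside0 <- l0$thalweg$values == 1
  diff0 <- mean(l0$ndvi$values[inside0]) - mean(l0$ndvi$values[!inside0])
  se <- sqrt(stats::var(l0$ndvi$values[inside0]) / sum(inside0) +
             stats::var(l0$ndvi$values[!inside0]) / sum(!inside0))
  expect_lt(abs(diff0), 2 * se + 0.01)
})

test_that("trajectory simulation is deterministic and stays in bounds", {
  cfg <- cfg_small()
  land <- generate_landscape(cfg)
  t1 <- simulate_trajectory(cfg, land, "A1")
  t2 <- simulate_trajectory(cfg, land, "A1")
  expect_identical(t1$fixes, t2$fixes)
  t3 <- simulate_trajectory(cfg, land, "A2")
  expect_false(identical(t1$fixes$x, t3$fixes$x))
  xmax <- ncol(land$elevation$values) * land$elevation$cellsize
  expect_true(all(t1$fixes$x >= 0 & t1$fixes$x <= xmax))
  expect_true(all(t1$fixes$y >= 0 & t1$fixes$y <= xmax))
  expect_equal(n_fixes(t1), 10 * 24)
})

test_that("zero step scale and zero weights give a stationary animal", {
  cfg <- cfg_small(step_scale_m = 0, p_water_day = 0,
                   hour_weights = matrix(0, 24, 4))
  land <- generate_landscape(cfg)
  tr <- simulate_trajectory(cfg, land, "A1")
  expect_equal(stats::sd(tr$fixes$x), 0)
  expect_equal(stats::sd(tr$fixes$y), 0)
})

test_that("daily water steering reaches a water point every day at p = 1", {
  cfg <- cfg_small(p_water_day = 1, days = 15)
  land <- generate_landscape(cfg)
  tr <- simulate_trajectory(cfg, land, "A1")
  d <- do.call(pmin, lapply(seq_len(nrow(land$water_points)), function(i)
    sqrt((tr$fixes$x - land$water_points$x[i])^2 +
         (tr$fixes$y - land$water_points$y[i])^2)))
  days_near <- unique(as.Date(tr$fixes$time[d <= 50]))
  expect_equal(length(days_near), 15L)
})

test_that("duration sampler reproduces its Poisson intensities", {
  # flat model: log lambda = log 5 -> expected total 500 over t = 1..100
  d <- sample_recursion_durations(c(log(5), 0, 0), "M3", t_range = 1:100,
                                  seed = 9)
  expect_lt(abs(length(d) - 500), 3 * sqrt(500))

  # a3 = 0 reduces the periodic model to the non-periodic one exactly
  co <- c(2, -0.01, 0.3, 0)
  d3 <- sample_recursion_durations(co[1:3], "M3", t_range = 1:168, seed = 4)
  d4 <- sample_recursion_durations(co, "M4", k = 3, t_range = 1:168, seed = 4)
  expect_identical(d3, d4)

  # strong cosine with k = 3: peaks at t = 21 mod 24
  dp <- sample_recursion_durations(c(2, 0, 0, 2), "M4", k = 3,
                                   t_range = 1:168, seed = 2)
  by_residue <- tapply(tabulate(dp, 168), (1:168) %% 24, sum)
  expect_equal(as.integer(names(which.max(by_residue))), 21L)

  # n rescaling hits the requested expected total
  dn <- sample_recursion_durations(c(0, 0, 0.5), "M3", t_range = 1:168,
                                   n = 5000, seed = 1)
  expect_lt(abs(length(dn) - 5000), 4 * sqrt(5000))
  expect_error(sample_recursion_durations(c(1000, 1, 0), "M3",
                                          t_range = 1:10),
               "overflow")
})
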