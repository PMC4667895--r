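fake_records <- function(x, y, n_visits, id = "A1", hour = NULL) {
  n <- length(x)
  data.frame(animal_id = id, season = "summer",
             focal_index = seq_len(n),
             time = t0_utc + 3600 * (seq_len(n) - 1),
             x = x, y = y,
             hour = if (is.null(hour)) (seq_len(n) - 1) %% 24 else hour,
             residence_h = 1L, recursion_h = 1L, censored = FALSE,
             n_visits = n_visits)
}

test_that("top-visited selection keeps ties at the cutoff", {
  r <- fake_records(1:10 * 100, rep(0, 10), n_visits = 1:10)
  top <- top_visited(r, site_config(top_fraction = 0.2))
  expect_equal(sort(top$n_visits), c(9, 10))

  r2 <- fake_records(1:10 * 100, rep(0, 10),
                     n_visits = c(9, 5, 5, 5, rep(1, 6)))
  top2 <- top_visited(r2, site_config(top_fraction = 0.2))
  expect_equal(nrow(top2), 4L)
  expect_equal(sort(top2$n_visits), c(5, 5, 5, 9))

  top3 <- top_visited(r, site_config(top_fraction = 0.999))
  expect_equal(nrow(top3), 10L)
})

test_that("raising the fraction never drops selected locations", {
  set.seed(71)
  r <- fake_records(runif(50, 0, 3000), runif(50, 0, 3000),
                    n_visits = sample(1:20, 50, TRUE))
  ns <- vapply(c(0.1, 0.2, 0.4, 0.8), function(fr)
    nrow(top_visited(r, site_config(top_fraction = fr))), numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("overlapping-circle clustering follows the link rule", {
  sel <- fake_records(c(0, 350, 900), c(0, 0, 0), n_visits = c(5, 5, 5))
  sites <- cluster_overlapping(sel, site_config(radius_m = 200,
                                                min_cluster_size = 2))
  expect_length(sites, 1)
  expect_equal(sort(sites[[1]]$members$x), c(0, 350))
  expect_equal(sites[[1]]$n_locations, 2L)

  # tangent circles (distance exactly 2R) still link
  tang <- fake_records(c(0, 400), c(0, 0), n_visits = c(1, 1))
  st <- cluster_overlapping(tang, site_config(min_cluster_size = 2))
  expect_length(st, 1)

  co <- fake_records(rep(10, 20), rep(10, 20), n_visits = rep(2, 20))
  expect_length(cluster_overlapping(co, site_config(min_cluster_size = 15)),
                1)
})

test_that("components equal the transitive-closure oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    sel <- fake_records(runif(n, 0, 2500), runif(n, 0, 2500),
                        n_visits = rep(1, n))
    cfg <- site_config(radius_m = 200, min_cluster_size = 1)
    sites <- cluster_overlapping(sel, cfg)
    grp <- oracle_components(sel$x, sel$y, 400)
    # same partition: every site is exactly one oracle group
    expect_equal(length(sites), length(unique(grp)))
    for (s in sites) {
      g <- grp[match(s$members$focal_index, sel$focal_index)]
      expect_equal(length(unique(g)), 1L)
      expect_equal(s$n_locations, sum(grp == g[1]))
    }
  }
})

test_that("clustering is invariant to input order and flags common sites", {
  set.seed(72)
  n <- 30
  sel <- fake_records(runif(n, 0, 2000), runif(n, 0, 2000),
                      n_visits = sample(1:9, n, TRUE),
                      id = rep(c("A1", "A2"), length.out = n))
  cfg <- site_config(radius_m = 200, min_cluster_size = 2)
  s1 <- cluster_overlapping(sel, cfg)
  s2 <- cluster_overlapping(sel[sample(n), ], cfg)
  key <- function(ss) lapply(ss, function(s)
    sort(paste(s$members$x, s$members$y)))
  expect_equal(key(s1), key(s2))
  multi <- vapply(s1, function(s) length(s$animal_ids) > 1, logical(1))
  expect_equal(vapply(s1, `[[`, logical(1), "common"), multi)
})

test_that("raising the minimum cluster size never adds sites", {
  set.seed(73)
  sel <- fake_records(runif(60, 0, 2500), runif(60, 0, 2500),
                      n_visits = rep(1, 60))
  ns <- vapply(c(1, 3, 5, 10, 15), function(m)
    length(cluster_overlapping(sel, site_config(min_cluster_size = m))),
    numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("site characterization summarizes habitat and diel use", {
  land <- flat_landscape(20, 20)
  sel <- fake_records(runif(16, 100, 500), runif(16, 100, 500),
                      n_visits = rep(3, 16), hour = rep(c(22, 23, 0, 1), 4))
  site <- cluster_overlapping(sel, site_config(min_cluster_size = 10))[[1]]
  ch <- characterize_site(site, land)
  expect_equal(ch$habitat$sd, rep(0, 5))  # uniform layers
  expect_equal(sum(ch$hour_histogram[as.character(8:16)]), 0L)
  expect_equal(sum(ch$hour_histogram), 16L)

  # non-uniform layer: means/SDs equal a direct recomputation
  set.seed(74)
  land$elevation$values[] <- rnorm(400, 800, 50)
  ch2 <- characterize_site(site, land)
  vals <- sample_habitat(site$members$x, site$members$y, land, "elevation")
  erow <- ch2$habitat[ch2$habitat$variable == "elevation", ]
  expect_equal(erow$mean, mean(vals))
  expect_equal(erow$sd, stats::sd(vals))
  # exceeds-home-range flag
  hm <- c(thalweg = 0, ndvi = 0.1, elevation = mean(vals) - 10,
          slope = 0, northern_exposure = 0)
  ch3 <- characterize_site(site, land, hm)
  expect_true(ch3$habitat$exceeds_hr[ch3$habitat$variable == "elevation"])
})
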