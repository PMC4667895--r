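#' Pipeline run configuration
#'
#' One flat configuration for the end-to-end analysis. In synthetic mode
#' the landscape and trajectories are generated per season from
#' [sim_config()]s; in files mode they are read from a fix-table CSV,
#' ASCII-grid habitat rasters and GeoJSON vector layers.
#'
#' @param mode "synthetic" or "files".
#' @param out_dir output directory (created if needed).
#' @param seed base seed; in synthetic mode it overrides the seeds of the
#'   season configs so one number reproduces the full bundle.
#' @param sim_configs named list of [sim_config()]s, one per season
#'   (synthetic mode).
#' @param paths named list (files mode) with entries `fix_table`,
#'   `elevation`, `ndvi`, `thalweg` (ASCII grids), `stream_network`,
#'   `water_points` (GeoJSON); `window` (an [analysis_window]) selects
#'   the fixes.
#' @param ud a [ud_params].
#' @param recursion a [recursion_config].
#' @param sites a [site_config].
#' @param hr_levels isopleth levels; the first is used for habitat
#'   selection and site flags (default c(0.95, 0.50)).
#' @param write_rasters also write UD and mask rasters as `.asc`.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       out_dir = tempfile("onager_run_"),
                       seed = 1L,
                       sim_configs = list(
                         summer = sim_config("summer", seed = seed),
                         winter = sim_config("winter", seed = seed)),
                       paths = NULL,
                       ud = ud_params(),
                       recursion = recursion_config(),
                       sites = site_config(),
                       hr_levels = c(0.95, 0.50),
                       write_rasters = TRUE) {
  mode <- match.arg(mode)
  if (mode == "files") {
    need <- c("fix_table", "elevation", "ndvi", "thalweg",
              "stream_network", "water_points")
    missing_layers <- setdiff(need, names(paths))
    if (length(missing_layers))
      stop("files mode: missing layer(s): ",
           paste(missing_layers, collapse = ", "))
    for (p in paths[need])
      if (!file.exists(p)) stop("files mode: path does not exist: ", p)
    if (is.null(paths$window) || !inherits(paths$window, "analysis_window"))
      stop("files mode: `paths$window` must be an analysis_window")
  } else {
    for (s in names(sim_configs)) sim_configs[[s]]$seed <- as.integer(seed)
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 sim_configs = sim_configs, paths = paths, ud = ud,
                 recursion = recursion, sites = sites,
                 hr_levels = hr_levels, write_rasters = write_rasters),
            class = "run_config")
}

#' Run the full space-use analysis pipeline
#'
#' Executes the stages in order — ingest/simulate, displacement, home
#' ranges, selection-coefficient profiles, water visits, recursion
#' tables, Kaplan-Meier and periodicity fits, visits-versus-home-range
#' models, recursion sites — writing every stage's CSV (and optionally
#' raster/GeoJSON) artifacts plus a JSON run manifest into `out_dir`.
#' Idempotent for a fixed seed: rerunning a synthetic configuration
#' reproduces the CSV outputs byte for byte.
#'
#' @param cfg a [run_config].
#' @return (invisibly) a list bundle: `config`, per-season `landscape`
#'   and `trajectories`, the stage result objects, and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = cfg$seed, mode = cfg$mode, counters = list(),
              warnings = character(0))
  note <- function(msg) {
    log$warnings <<- c(log$warnings, msg)
    message(msg)
  }

  ## stage 1: ingest or simulate -------------------------------------------
  seasons <- list()
  if (cfg$mode == "synthetic") {
    for (s in names(cfg$sim_configs)) {
      sc <- cfg$sim_configs[[s]]
      land <- generate_landscape(sc)
      trajs <- simulate_cohort(sc, land)$trajectories
      seasons[[s]] <- list(landscape = land, trajectories = trajs,
                           water_points = land$water_points)
    }
  } else {
    land <- list(elevation = read_asc(cfg$paths$elevation),
                 ndvi = read_asc(cfg$paths$ndvi),
                 thalweg = read_asc(cfg$paths$thalweg),
                 stream_network = read_lines_geojson(cfg$paths$stream_network),
                 water_points = read_points_geojson(cfg$paths$water_points))
    terr <- derive_terrain(land$elevation)
    land$slope <- terr$slope; land$aspect <- terr$aspect
    class(land) <- "landscape_stack"
    trajs <- parse_fix_table(cfg$paths$fix_table, cfg$paths$window)
    seasons[[cfg$paths$window$season]] <-
      list(landscape = land, trajectories = trajs,
           water_points = land$water_points)
  }
  log$counters$fixes <- sum(vapply(seasons, function(se)
    sum(vapply(se$trajectories, n_fixes, 0L)), 0))
  log$counters$gaps <- sum(vapply(seasons, function(se)
    sum(vapply(se$trajectories, function(tr) nrow(tr$gaps), 0L)), 0))

  ## stage 2: displacement -------------------------------------------------
  profiles <- list()
  for (s in names(seasons))
    for (tr in seasons[[s]]$trajectories)
      profiles[[paste(s, tr$animal_id)]] <- hourly_mean_distance(tr)
  prof_tab <- do.call(rbind, profiles)
  rownames(prof_tab) <- NULL
  utils::write.csv(prof_tab, file.path(cfg$out_dir, "displacement.csv"),
                   row.names = FALSE)

  ## stage 3: home ranges ---------------------------------------------------
  hr <- list(); hr_rows <- list()
  for (s in names(seasons)) {
    grid <- seasons[[s]]$landscape$elevation
    for (tr in seasons[[s]]$trajectories) {
      ud <- movement_kernel_ud(tr, cfg$ud, grid)
      masks <- lapply(cfg$hr_levels, function(l) isopleth_mask(ud, l))
      names(masks) <- sprintf("hr%02d", round(100 * cfg$hr_levels))
      hr[[paste(s, tr$animal_id)]] <- list(ud = ud, masks = masks)
      for (l in seq_along(masks))
        hr_rows[[length(hr_rows) + 1L]] <- data.frame(
          animal_id = tr$animal_id, season = s,
          level = cfg$hr_levels[l], area_km2 = masks[[l]]$area_km2)
      if (cfg$write_rasters) {
        tag <- paste0(s, "_", tr$animal_id)
        write_asc(ud, file.path(cfg$out_dir, paste0("ud_", tag, ".asc")))
        for (l in seq_along(masks))
          write_asc(land_raster(masks[[l]]$mask * 1, grid$origin,
                                grid$cellsize),
                    file.path(cfg$out_dir, paste0(
                      "mask_", names(masks)[l], "_", tag, ".asc")))
      }
    }
  }
  hr_tab <- do.call(rbind, hr_rows)
  utils::write.csv(hr_tab, file.path(cfg$out_dir, "home_ranges.csv"),
                   row.names = FALSE)

  ## stage 4: habitat selection profiles ------------------------------------
  sc_rows <- list()
  hr_means <- list()
  main_level <- sprintf("hr%02d", round(100 * cfg$hr_levels[1]))
  for (s in names(seasons)) {
    land <- seasons[[s]]$landscape
    hr_means[[s]] <- list()
    for (tr in seasons[[s]]$trajectories) {
      mask <- hr[[paste(s, tr$animal_id)]]$masks[[main_level]]
      sc_rows[[paste(s, tr$animal_id)]] <- sc_profile(tr, land, mask)
      hr_means[[s]][[tr$animal_id]] <- home_range_habitat_means(mask, land)
    }
  }
  sc_tab <- do.call(rbind, sc_rows)
  rownames(sc_tab) <- NULL
  log$counters$undefined_sc <- sum(is.na(sc_tab$sc))
  utils::write.csv(sc_tab, file.path(cfg$out_dir, "selection_coefficients.csv"),
                   row.names = FALSE)

  ## stage 5: water visits ---------------------------------------------------
  visit_rows <- list(); rate_rows <- list()
  for (s in names(seasons)) {
    wps <- seasons[[s]]$water_points
    trajs <- seasons[[s]]$trajectories
    window <- trajs[[1]]$window
    for (w in seq_len(nrow(wps))) {
      wp <- water_point(wps$label[w], wps$x[w], wps$y[w])
      pooled <- unlist(lapply(trajs, function(tr) {
        ps <- suppressWarnings(passing_series(tr, wp))
        if (ps$n_steps > 0)
          unlist(lapply(ps$series, function(ix)
            sqrt(diff(tr$fixes$x[ix])^2 + diff(tr$fixes$y[ix])^2)))
      }))
      if (length(pooled) > 0) {
        wp$visit_radius_m <- visit_radius(mean(pooled))
      } else {
        overall <- mean(unlist(lapply(trajs, function(tr) {
          st <- step_series(tr); st$distance_m[!st$flagged]
        })))
        wp$visit_radius_m <- visit_radius(overall)
        note(sprintf(
          "no passing series near %s in %s; visit radius from overall mean",
          wp$label, s))
      }
      for (tr in trajs) {
        v <- detect_visits(tr, wp)
        v$season <- rep(s, nrow(v))
        visit_rows[[paste(s, wp$label, tr$animal_id)]] <- v
      }
    }
    for (tr in trajs) {
      va <- do.call(rbind, visit_rows[paste(s, wps$label, tr$animal_id)])
      st <- visit_stats(if (is.null(va)) empty_visits() else va, window)
      rate_rows[[paste(s, tr$animal_id)]] <- data.frame(
        animal_id = tr$animal_id, season = s,
        visits_per_day = st$rate_per_day)
    }
  }
  visit_tab <- do.call(rbind, visit_rows)
  rownames(visit_tab) <- NULL
  utils::write.csv(visit_tab, file.path(cfg$out_dir, "water_visits.csv"),
                   row.names = FALSE)
  rate_tab <- do.call(rbind, rate_rows)
  rownames(rate_tab) <- NULL
  utils::write.csv(rate_tab, file.path(cfg$out_dir, "water_visit_rates.csv"),
                   row.names = FALSE)

  ## stage 6: recursion tables ----------------------------------------------
  rec <- list()
  for (s in names(seasons))
    for (tr in seasons[[s]]$trajectories)
      rec[[paste(s, tr$animal_id)]] <- recursion_table(tr, cfg$recursion)
  rec_tab <- do.call(rbind, lapply(rec, as.data.frame))
  rownames(rec_tab) <- NULL
  log$counters$censored_recursions <- sum(rec_tab$censored)
  utils::write.csv(rec_tab, file.path(cfg$out_dir, "recursion_records.csv"),
                   row.names = FALSE)

  ## stage 7: KM + periodicity ----------------------------------------------
  km_rows <- list(); fit_rows <- list(); lam_rows <- list()
  periodicity <- list()
  for (s in names(seasons)) {
    for (tr in seasons[[s]]$trajectories) {
      tb <- rec[[paste(s, tr$animal_id)]]
      km <- km_curve(tb$recursion_h, tb$censored)
      km_rows[[paste(s, tr$animal_id)]] <- data.frame(
        animal_id = tr$animal_id, season = s,
        median_recursion_h = km$median_h)
    }
    dur <- recursion_durations(rec[paste(s, vapply(
      seasons[[s]]$trajectories, `[[`, "", "animal_id"))])
    fit <- tryCatch(fit_poisson_periodicity(dur, cfg$recursion),
                    error = function(e) {
                      note(paste0("periodicity fit skipped for ", s, ": ",
                                  conditionMessage(e)))
                      NULL
                    })
    periodicity[[s]] <- fit
    if (!is.null(fit)) {
      f <- fit$fits; f$season <- s
      fit_rows[[s]] <- f
      lam <- fitted_lambda(fit); lam$season <- s
      lam_rows[[s]] <- lam
    }
  }
  km_tab <- do.call(rbind, km_rows)
  rownames(km_tab) <- NULL
  utils::write.csv(km_tab, file.path(cfg$out_dir, "km_medians.csv"),
                   row.names = FALSE)
  if (length(fit_rows)) {
    utils::write.csv(do.call(rbind, fit_rows),
                     file.path(cfg$out_dir, "periodicity_models.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, lam_rows),
                     file.path(cfg$out_dir, "periodicity_lambda.csv"),
                     row.names = FALSE)
  }

  ## stage 8: visits vs home range size --------------------------------------
  vhr <- list()
  for (lvl in seq_along(cfg$hr_levels)) {
    tag <- sprintf("hr%02d", round(100 * cfg$hr_levels[lvl]))
    rows <- do.call(rbind, lapply(names(rec), function(key) {
      tb <- rec[[key]]
      s <- tb$season[1]; id <- tb$animal_id[1]
      data.frame(animal_id = id, season = s,
                 mean_visits = attr(tb, "mean_visits"),
                 area_km2 = hr[[key]]$masks[[tag]]$area_km2)
    }))
    fit <- tryCatch(fit_visits_vs_hr(rows), error = function(e) {
      note(paste0("visits-vs-HR fit skipped for ", tag, ": ",
                  conditionMessage(e)))
      NULL
    })
    vhr[[tag]] <- list(rows = rows, fit = fit)
  }
  vhr_tab <- do.call(rbind, lapply(names(vhr), function(tag) {
    f <- vhr[[tag]]$fit
    if (is.null(f)) return(NULL)
    ff <- f$fits; ff$hr_level <- tag; ff
  }))
  if (!is.null(vhr_tab))
    utils::write.csv(vhr_tab, file.path(cfg$out_dir, "visits_vs_hr_models.csv"),
                     row.names = FALSE)

  ## stage 9: recursion sites -------------------------------------------------
  all_sites <- list()
  site_rows <- list()
  for (s in names(seasons)) {
    keys <- paste(s, vapply(seasons[[s]]$trajectories, `[[`, "", "animal_id"))
    sites <- tryCatch(
      main_recursion_sites(rec[keys], seasons[[s]]$landscape, cfg$sites,
                           hr_means[[s]]),
      error = function(e) {
        note(paste0("site clustering skipped for ", s, ": ",
                    conditionMessage(e)))
        list()
      })
    all_sites[[s]] <- sites
    if (length(sites)) {
      st <- sites_table(sites); st$season <- s
      site_rows[[s]] <- st
      write_sites_geojson(sites, file.path(cfg$out_dir,
                                           paste0("sites_", s, ".geojson")))
    }
  }
  if (length(site_rows))
    utils::write.csv(do.call(rbind, site_rows),
                     file.path(cfg$out_dir, "recursion_sites.csv"),
                     row.names = FALSE)

  ## manifest -----------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("onager")),
    seed = cfg$seed, mode = cfg$mode,
    seasons = names(seasons),
    counters = log$counters,
    warnings = log$warnings,
    artifacts = sort(c(list.files(cfg$out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = cfg, seasons = seasons, profiles = profiles,
                 home_ranges = hr, sc = sc_tab, visits = visit_tab,
                 visit_rates = rate_tab, recursion = rec, km = km_tab,
                 periodicity = periodicity, visits_vs_hr = vhr,
                 sites = all_sites, manifest = manifest))
}

empty_visits <- function() {
  data.frame(animal_id = character(0), water = character(0),
             time = as.POSIXct(character(0), tz = "UTC"),
             hour = integer(0), n_fixes = integer(0),
             min_dist_m = numeric(0))
}

#' Summarize a pipeline run
#'
#' One row per animal-season: home-range areas, mean visits per location,
#' median recursion time, best periodicity model and phase, number of
#' main sites, and water-visit rate. Works from the in-memory bundle
#' returned by [run_pipeline()].
#'
#' @param bundle a [run_pipeline()] result.
#' @return data.frame of class `run_summary`.
#' @export
summarize_run <- function(bundle) {
  rows <- list()
  for (key in names(bundle$recursion)) {
    tb <- bundle$recursion[[key]]
    s <- tb$season[1]; id <- tb$animal_id[1]
    masks <- bundle$home_ranges[[key]]$masks
    km <- bundle$km
    rate <- bundle$visit_rates
    fit <- bundle$periodicity[[s]]
    rows[[key]] <- data.frame(
      animal_id = id, season = s,
      hr95_km2 = if ("hr95" %in% names(masks)) masks$hr95$area_km2 else NA,
      hr50_km2 = if ("hr50" %in% names(masks)) masks$hr50$area_km2 else NA,
      mean_visits = attr(tb, "mean_visits"),
      median_recursion_h =
        km$median_recursion_h[km$animal_id == id & km$season == s],
      best_model = if (is.null(fit)) NA_character_ else fit$best$model,
      best_k = if (is.null(fit)) NA_integer_ else fit$best$k,
      n_sites = length(bundle$sites[[s]]),
      water_visits_per_day = {
        r <- rate$visits_per_day[rate$animal_id == id & rate$season == s]
        if (length(r)) r else 0
      })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("run_summary", "data.frame")
  out
}
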