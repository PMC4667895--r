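#' Recursion-site configuration
#'
#' @param top_fraction fraction of locations (ranked by number of visits)
#'   mapped as high-recursion candidates (default 0.20).
#' @param radius_m radius of the circle drawn around each candidate
#'   location; circles whose centres are within `2 * radius_m` overlap
#'   (default 200).
#' @param min_cluster_size minimum locations per main site (default 15).
#' @return object of class `site_config`.
#' @export
site_config <- function(top_fraction = 0.20, radius_m = 200,
                        min_cluster_size = 15) {
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("`top_fraction` must be in (0, 1)")
  if (min_cluster_size < 1) stop("`min_cluster_size` must be >= 1")
  structure(list(top_fraction = top_fraction, radius_m = radius_m,
                 min_cluster_size = min_cluster_size),
            class = "site_config")
}

#' Most-visited locations of an animal-season
#'
#' Ranks locations by their number of visits (descending) and selects
#' the top `ceiling(top_fraction * n)`; every location tied with the
#' cutoff visit count is included, so slightly more than the nominal
#' fraction can be returned.
#'
#' @param records a [recursion_table] (or data.frame with `n_visits`).
#' @param cfg a [site_config].
#' @return the selected rows of `records`.
#' @export
top_visited <- function(records, cfg = site_config()) {
  if (nrow(records) == 0L) stop("`records` is empty")
  n_sel <- ceiling(cfg$top_fraction * nrow(records))
  cut <- sort(records$n_visits, decreasing = TRUE)[n_sel]
  out <- records[records$n_visits >= cut, , drop = FALSE]
  out[order(-out$n_visits, out$focal_index %||% seq_len(nrow(out))), ,
      drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster selected locations into recursion sites
#'
#' Builds the undirected graph linking every pair of locations whose
#' circles of `radius_m` overlap (centre distance <= 2 * radius_m,
#' closed: tangent circles count) and returns its connected components
#' of at least `min_cluster_size` locations, ordered by size (largest
#' first) then by centroid coordinates. Components spanning more than
#' one animal are flagged common.
#'
#' @param selected selected locations ([top_visited()] output, or any
#'   data.frame with `x`, `y` and optionally `animal_id`).
#' @param cfg a [site_config].
#' @return list of `recursion_site` objects: each a list with `site_id`,
#'   `animal_ids`, `common`, `members` (the member rows), `n_locations`,
#'   `n_visits` (summed when available).
#' @export
cluster_overlapping <- function(selected, cfg = site_config()) {
  n <- nrow(selected)
  if (n == 0L) stop("`selected` is empty")
  d2 <- (outer(selected$x, selected$x, "-"))^2 +
        (outer(selected$y, selected$y, "-"))^2
  adj <- d2 <= (2 * cfg$radius_m)^2
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sites <- list()
  for (cid in unique(comp)) {
    ix <- which(comp == cid)
    if (length(ix) < cfg$min_cluster_size) next
    mem <- selected[ix, , drop = FALSE]
    ids <- if ("animal_id" %in% names(mem))
      sort(unique(as.character(mem$animal_id))) else character(0)
    sites[[length(sites) + 1L]] <- structure(list(
      site_id = NA_character_,
      animal_ids = ids,
      common = length(ids) > 1L,
      members = mem,
      n_locations = nrow(mem),
      n_visits = if ("n_visits" %in% names(mem)) sum(mem$n_visits)
                 else NA_integer_,
      centroid = c(x = mean(mem$x), y = mean(mem$y))),
      class = "recursion_site")
  }
  if (length(sites) == 0L) return(sites)
  ord <- order(-vapply(sites, `[[`, 0L, "n_locations"),
               vapply(sites, function(s) s$centroid["x"], 0),
               vapply(sites, function(s) s$centroid["y"], 0))
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$site_id <- sprintf("S%02d", i)
  sites
}

#' @export
print.recursion_site <- function(x, ...) {
  cat(sprintf("<recursion_site> %s%s: %d locations, %s visits (animals: %s)\n",
              x$site_id, if (x$common) " [common]" else "",
              x$n_locations,
              if (is.na(x$n_visits)) "?" else x$n_visits,
              paste(x$animal_ids, collapse = ", ")))
  invisible(x)
}

#' Habitat and diel characterization of a recursion site
#'
#' Mean and SD of each habitat variable over the member locations
#' (thalweg reported as a proportion), the 24-bin histogram of member
#' location hours, and flags marking the variables whose site mean (or
#' proportion) exceeds the animal's 95% home-range mean.
#'
#' @param site a `recursion_site` from [cluster_overlapping()].
#' @param land a [landscape_stack] covering the site.
#' @param hr_means optional named vector of 95%-home-range habitat means
#'   ([home_range_habitat_means()]); enables the exceeds-range flags.
#' @return the site with `habitat` (data.frame variable/mean/sd/
#'   exceeds_hr) and `hour_histogram` filled in.
#' @export
characterize_site <- function(site, land, hr_means = NULL) {
  stopifnot(inherits(site, "recursion_site"))
  mem <- site$members
  hab <- lapply(habitat_variables(), function(v) {
    vals <- sample_habitat(mem$x, mem$y, land, v, strict = TRUE)
    data.frame(variable = v, mean = mean(vals),
               sd = stats::sd(vals),
               exceeds_hr = if (is.null(hr_means)) NA
                            else mean(vals) > hr_means[[v]])
  })
  site$habitat <- do.call(rbind, hab)
  hrs <- if ("hour" %in% names(mem)) mem$hour
         else hour_of_day(mem$time)
  site$hour_histogram <- stats::setNames(
    as.integer(table(factor(hrs, levels = 0:23))), as.character(0:23))
  site
}

#' Identify and characterize main recursion sites
#'
#' Per animal-season selection of the most-visited locations, clustering
#' into sites, then a second pass clustering the union of all animals'
#' selected locations with the same rule so that sites shared by several
#' animals are recovered as common sites. Single-animal components of
#' the union pass reproduce the per-animal sites.
#'
#' @param tables list of [recursion_table] objects (one animal-season
#'   each, same season).
#' @param land a [landscape_stack].
#' @param cfg a [site_config].
#' @param hr_means_by_animal optional named list (by animal id) of
#'   [home_range_habitat_means()] vectors for the exceeds-range flags.
#' @return list of characterized `recursion_site` objects.
#' @export
main_recursion_sites <- function(tables, land, cfg = site_config(),
                                 hr_means_by_animal = NULL) {
  if (inherits(tables, "recursion_table")) tables <- list(tables)
  selected <- do.call(rbind, lapply(tables, function(tb)
    as.data.frame(top_visited(tb, cfg))))
  sites <- cluster_overlapping(selected, cfg)
  lapply(sites, function(s) {
    hm <- NULL
    if (!is.null(hr_means_by_animal) && length(s$animal_ids) == 1L)
      hm <- hr_means_by_animal[[s$animal_ids]]
    characterize_site(s, land, hm)
  })
}

#' Export sites as a Table-3-style CSV table
#'
#' One row per site: id, common flag, location/visit counts, and the
#' per-variable mean (SD) columns with the exceeds-home-range flags.
#'
#' @param sites list of characterized sites.
#' @return data.frame (written by the pipeline as CSV).
#' @export
sites_table <- function(sites) {
  if (length(sites) == 0L)
    return(data.frame(site = character(0)))
  do.call(rbind, lapply(sites, function(s) {
    h <- s$habitat
    row <- data.frame(site = s$site_id,
                      animals = paste(s$animal_ids, collapse = "+"),
                      common = s$common,
                      n_locations = s$n_locations,
                      n_visits = s$n_visits)
    for (i in seq_len(nrow(h))) {
      row[[paste0(h$variable[i], "_mean")]] <- h$mean[i]
      row[[paste0(h$variable[i], "_sd")]] <- h$sd[i]
      row[[paste0(h$variable[i], "_exceeds_hr")]] <- h$exceeds_hr[i]
    }
    row
  }))
}
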