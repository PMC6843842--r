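#' Mean grid-cell distance to the nearest destination
#'
#' Walkability-style accessibility metric: the urbanized land of an area is
#' divided into 100 m x 100 m grid cells, and the metric is the mean over
#' cell centres of the planar Euclidean distance to the nearest destination
#' of one class (public physical-activity facility, park, or transit stop).
#' Destinations may lie outside the area: the nearest one anywhere counts.
#'
#' @param cell_centers numeric matrix (n x 2) of cell-centre coordinates in
#'   meters.
#' @param destinations numeric matrix (m x 2) of destination coordinates in
#'   meters; m >= 1.
#' @return Mean nearest distance in meters.
#' @examples
#' mean_grid_distance(rbind(c(50, 50)), rbind(c(50, 50))) # 0
#' # two-cell strip, destination on the first centre: (0 + 100)/2
#' mean_grid_distance(rbind(c(50, 50), c(150, 50)), rbind(c(50, 50)))
#' @export
mean_grid_distance <- function(cell_centers, destinations) {
  cell_centers <- as.matrix(cell_centers)
  destinations <- as.matrix(destinations)
  if (nrow(cell_centers) < 1L) stop("area has no urbanized cells", call. = FALSE)
  if (nrow(destinations) < 1L) stop("no destinations exist", call. = FALSE)
  # squared-distance matrix via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(cell_centers^2), rowSums(destinations^2), `+`) -
    2 * tcrossprod(cell_centers, destinations)
  mean(sqrt(pmax(apply(d2, 1L, min), 0)))
}

#' Count density per square kilometre
#'
#' Population density (persons per km^2 of urbanized land) and intersection
#' density (intersections with three or more legs per km^2) both reduce to
#' a count divided by the urbanized land area.
#'
#' @param count non-negative count.
#' @param urban_area_km2 urbanized land area in km^2, > 0.
#' @return Density per km^2.
#' @export
density_per_km2 <- function(count, urban_area_km2) {
  if (any(urban_area_km2 <= 0)) stop("urbanized area must be positive",
                                     call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count / urban_area_km2
}

#' Land-use-mix entropy index
#'
#' The 3-category entropy index over the proportions p_k of domestic,
#' commercial and business building floor area:
#' `-sum(p_k * log(p_k)) / log(3)`, with zero proportions contributing 0.
#' Ranges from 0 (single land use, lowest heterogeneity) to 1 (equal thirds,
#' highest heterogeneity).
#'
#' @param floor_areas numeric vector of three non-negative floor areas
#'   (m^2), in any order; at least one positive.
#' @return LUM in `[0, 1]`.
#' @examples
#' land_use_mix(c(1, 1, 1))  # 1
#' land_use_mix(c(5, 0, 0))  # 0
#' land_use_mix(c(1, 1, 0))  # log(2)/log(3)
#' @export
land_use_mix <- function(floor_areas) {
  if (length(floor_areas) != 3L) stop("exactly three land-use classes expected",
                                      call. = FALSE)
  if (any(floor_areas < 0)) stop("floor areas must be non-negative", call. = FALSE)
  tot <- sum(floor_areas)
  if (tot == 0) stop("all floor areas are zero; LUM undefined", call. = FALSE)
  p <- floor_areas / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(3)
}

#' Tertile categorization of an area-level metric
#'
#' Cuts a continuous per-area metric at its 33.3rd and 66.7th percentiles
#' into ordered labels T1 (lowest) < T2 < T3 (highest). Percentiles use the
#' inclusive linear-interpolation convention (type 7); values exactly at a
#' cut point receive the lower tertile. By default every area counts once;
#' with `weights` (e.g. area populations) the cut points are
#' weighted percentiles so tertiles balance individuals instead of areas.
#'
#' @param values numeric per-area vector with >= 3 distinct values.
#' @param weights optional non-negative per-area weights for the cut-point
#'   computation.
#' @return Factor with levels T1, T2, T3, plus attribute `"cuts"`.
#' @export
tertile_categorize <- function(values, weights = NULL) {
  if (length(unique(values)) < 3L)
    stop("need at least 3 distinct values to form tertiles", call. = FALSE)
  if (is.null(weights)) {
    cuts <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  } else {
    stopifnot(length(weights) == length(values), all(weights >= 0))
    o <- order(values)
    cw <- cumsum(weights[o]) / sum(weights)
    cuts <- vapply(c(1, 2) / 3, function(pr) values[o][which(cw >= pr)[1L]], 0)
  }
  lab <- ifelse(values <= cuts[1L], "T1",
                ifelse(values <= cuts[2L], "T2", "T3"))
  structure(factor(lab, levels = c("T1", "T2", "T3")), cuts = cuts)
}

#' Compute the built-environment metric table of a landscape
#'
#' For each area of a (synthetic) landscape, computes the six
#' walkability-related metrics: mean grid distance to the nearest public
#' physical-activity facility, park and transit stop (m); population and
#' intersection densities (per km^2 of urbanized land); and the land-use-mix
#' entropy. Optionally appends tertile labels for each metric.
#'
#' @param landscape a `landscape` object from [simulate_landscape()] (or
#'   any list with the same per-area fields).
#' @param tertiles append `<metric>_tertile` columns via
#'   [tertile_categorize()].
#' @return data.frame with one row per area: `area_id`, `dist_pa_m`,
#'   `dist_park_m`, `dist_transit_m`, `pop_density`,
#'   `intersection_density`, `lum`, and tertile columns if requested.
#' @export
landscape_metrics <- function(landscape, tertiles = TRUE) {
  stopifnot(inherits(landscape, "landscape"))
  dest <- landscape$destinations
  for (cl in c("pa_facility", "park", "transit"))
    if (is.null(dest[[cl]]) || nrow(dest[[cl]]) == 0L)
      stop("no destinations of class '", cl, "' anywhere in the landscape",
           call. = FALSE)
  rows <- lapply(landscape$areas, function(a) {
    data.frame(
      area_id = a$area_id,
      dist_pa_m = mean_grid_distance(a$cell_centers, dest$pa_facility),
      dist_park_m = mean_grid_distance(a$cell_centers, dest$park),
      dist_transit_m = mean_grid_distance(a$cell_centers, dest$transit),
      pop_density = density_per_km2(a$population, a$urban_area_km2),
      intersection_density = density_per_km2(a$n_intersections,
                                             a$urban_area_km2),
      lum = land_use_mix(a$floor_areas),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (tertiles) {
    for (m in c("dist_pa_m", "dist_park_m", "dist_transit_m",
                "pop_density", "intersection_density", "lum"))
      out[[paste0(m, "_tertile")]] <- as.character(tertile_categorize(out[[m]]))
  }
  out
}
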