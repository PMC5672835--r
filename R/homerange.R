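## shoelace signed area of a closed ring (first vertex repeated last)
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

## TRUE for points inside or on the boundary of a convex CCW ring
in_convex <- function(ring, xy, eps = 1e-9) {
  xy <- as.matrix(xy)
  inside <- rep(TRUE, nrow(xy))
  n <- nrow(ring)
  for (i in seq_len(n - 1L)) {
    ex <- ring[i + 1L, 1] - ring[i, 1]
    ey <- ring[i + 1L, 2] - ring[i, 2]
    cross <- ex * (xy[, 2] - ring[i, 2]) - ey * (xy[, 1] - ring[i, 1])
    scale <- sqrt(ex^2 + ey^2)
    inside <- inside & cross >= -eps * max(scale, 1)
  }
  inside
}

#' Minimum convex polygon home range
#'
#' Convex hull of an animal's relocations. At `percent = 100` (the default,
#' and the only setting used in the downstream selection analyses) all points
#' are enclosed; for `percent < 100` the `(100 - percent)%` of points farthest
#' from the centroid are discarded before taking the hull.
#'
#' @param points two-column matrix or data.frame of planar coordinates (m).
#' @param percent percentage of points to retain, in (0, 100].
#' @param animal_id optional label used in error messages and kept on the
#'   result.
#' @param period optional period label kept on the result.
#'
#' @return An object of class `home_range`: list with `vertices` (closed
#'   counter-clockwise ring), `area` (m^2, shoelace formula), `n_points`,
#'   `animal_id`, `period`.
#' @export
mcp <- function(points, percent = 100, animal_id = NA, period = NA) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  if (!is.numeric(percent) || percent <= 0 || percent > 100)
    stop("`percent` must lie in (0, 100]")
  if (nrow(xy) < 3L)
    stop(sprintf("animal %s: need at least 3 points for an MCP", animal_id))
  if (percent < 100) {
    ctr <- colMeans(xy)
    d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    xy <- xy[d <= stats::quantile(d, percent / 100), , drop = FALSE]
  }
  h <- grDevices::chull(xy)
  if (length(h) < 3L)
    stop(sprintf("animal %s: points are collinear, MCP undefined", animal_id))
  ring <- xy[c(h, h[1]), , drop = FALSE]
  a <- ring_area(ring)
  if (a < 0) {                       # force counter-clockwise orientation
    ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    a <- -a
  }
  if (a == 0)
    stop(sprintf("animal %s: degenerate (zero-area) MCP", animal_id))
  structure(list(vertices = unname(ring), area = a, n_points = nrow(xy),
                 animal_id = animal_id, period = period),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range (100%% MCP style): animal %s, period %s\n",
              x$animal_id, x$period))
  cat(sprintf("  %d vertices, area %.4g km^2, from %d points\n",
              nrow(x$vertices) - 1L, x$area / 1e6, x$n_points))
  invisible(x)
}

#' Per-animal availability from RUs inside the home range
#'
#' Resource units are assigned to the home range by a centre-in-polygon test;
#' the available proportion of each habitat category is the share of those
#' RUs whose dominant cover class is that category.
#'
#' Near the hull boundary an RU can contain one of the animal's points while
#' its centre lies just outside the polygon; such RUs are demonstrably
#' available to the animal, so `used_ru_ids` (when given) are always included
#' in the availability set. This keeps used resources a subset of available
#' ones at the RU grain.
#'
#' @param rut RU table from [aggregate_to_ru()].
#' @param polygon a [mcp()] home range.
#' @param used_ru_ids optional RU ids known to be used by this animal.
#' @return list with `ru_ids` (RUs inside the polygon), `pi` (named available
#'   proportions over the full class universe, summing to 1), `animal_id`,
#'   `period`.
#' @export
hr_availability <- function(rut, polygon, used_ru_ids = NULL) {
  inside <- in_convex(polygon$vertices, cbind(rut$x, rut$y))
  if (!is.null(used_ru_ids))
    inside <- inside | rut$ru_id %in% used_ru_ids
  if (!any(inside))
    stop(sprintf("animal %s: no RU centre falls inside the home range polygon",
                 polygon$animal_id))
  classes <- attr(rut, "classes")
  dom <- rut$dominant[inside]
  counts <- vapply(classes, function(k) sum(dom == k), 0)
  list(ru_ids = rut$ru_id[inside],
       pi = stats::setNames(counts / sum(counts), paste0("class_", classes)),
       animal_id = polygon$animal_id, period = polygon$period)
}

#' Resource units used by a set of relocations
#'
#' Maps each point to its RU by the half-open cell rule (boundary points
#' belong to the cell to the east/south) and tallies used counts per dominant
#' cover class.
#'
#' @param points two-column matrix of coordinates.
#' @param rut RU table.
#' @param grid the coarse [raster_grid] the RU table was built on (any layer
#'   of the aggregation stack).
#' @return list with `ru_ids` (one per point, a multiset), `u` (named used
#'   counts per class over the full class universe).
#' @export
used_units <- function(points, rut, grid) {
  loc <- locate_cells(grid, as.matrix(points)[, 1:2, drop = FALSE])
  idx <- match(loc$cell, rut$ru_id)
  if (anyNA(idx))
    stop("point(s) fall in RUs dropped as nodata: records ",
         paste(utils::head(which(is.na(idx)), 10L), collapse = ", "))
  classes <- attr(rut, "classes")
  dom <- rut$dominant[idx]
  u <- vapply(classes, function(k) sum(dom == k), 0)
  list(ru_ids = rut$ru_id[idx],
       u = stats::setNames(u, paste0("class_", classes)))
}

#' Write home-range polygons as GeoJSON
#'
#' @param polygons list of [mcp()] objects.
#' @param path output file.
#' @export
write_geojson <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    ## GeoJSON rings are closed and exterior rings counter-clockwise,
    ## matching the home_range convention
    coords <- lapply(seq_len(nrow(p$vertices)),
                     function(i) as.numeric(p$vertices[i, ]))
    list(type = "Feature",
         properties = list(animal_id = p$animal_id, period = p$period,
                           area_m2 = p$area, n_points = p$n_points),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
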