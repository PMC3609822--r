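# Geographic indices between populations: centroids, great-circle distances,
# tributary-crossing counts and headwater-detoured distances over a river
# map of polylines.
#
# Rivers are open polylines: a detour path may not cross a large river
# anywhere, but may pass around its upstream terminus (the headwater). The
# downstream terminus (mouth) is treated as joining a larger waterway and is
# closed off by a long ray extension. All planar work happens in a local
# equirectangular projection about the midpoint of the pair of sites, whose
# error is negligible at river-basin scale.

EARTH_RADIUS_KM <- 6371

#' Construct a river map
#'
#' @param rivers list of rivers; each a list with `name`, `width_class`
#'   (`"large"` or `"small"`), `coords` (two-column matrix of longitude,
#'   latitude with >= 2 vertices) and optional `headwater` (`"first"` or
#'   `"last"` vertex, default `"last"`).
#' @return an object of class `"river_map"`.
#' @export
river_map <- function(rivers = list()) {
  for (rv in rivers) {
    if (is.null(rv$name) || is.null(rv$width_class) || is.null(rv$coords)) {
      abort("each river needs name, width_class and coords", "input_error")
    }
    if (!rv$width_class %in% c("large", "small")) {
      abort("width_class must be 'large' or 'small'", "input_error")
    }
    if (nrow(rv$coords) < 2L) abort("river polyline needs >= 2 vertices", "input_error")
  }
  structure(rivers, class = "river_map")
}

#' @export
print.river_map <- function(x, ...) {
  cat(sprintf("River map: %d rivers (%d large)\n", length(x),
              sum(vapply(x, function(r) r$width_class == "large", logical(1L)))))
  invisible(x)
}

#' Read a river map from GeoJSON
#'
#' Expects a FeatureCollection of LineString features with properties
#' `name`, `width_class` and optionally `headwater`.
#'
#' @param path path to the GeoJSON file.
#' @return a [river_map()].
#' @export
read_rivers <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "input_error")
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("expected a GeoJSON FeatureCollection", "input_error")
  }
  rivers <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      abort("only LineString river features are supported", "input_error")
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) c(p[[1L]], p[[2L]])))
    list(name = f$properties$name %||% "river",
         width_class = f$properties$width_class %||% "large",
         coords = coords,
         headwater = f$properties$headwater %||% "last")
  })
  river_map(rivers)
}

#' Write a river map to GeoJSON
#' @param map a [river_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rivers <- function(map, path) {
  features <- lapply(map, function(rv) {
    list(type = "Feature",
         properties = list(name = rv$name, width_class = rv$width_class,
                           headwater = rv$headwater %||% "last"),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(rv$coords)),
                                              function(i) as.numeric(rv$coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Population centroids from sample coordinates
#'
#' The centre of a population is the arithmetic mean of its samples'
#' latitudes and longitudes (a small-extent approximation of the centre of
#' gravity of the sampling places).
#'
#' @param meta metadata `data.frame` with `population`, `latitude`,
#'   `longitude`.
#' @return a data.frame: population, latitude, longitude, n_samples.
#' @export
population_centroids <- function(meta) {
  keep <- !is.na(meta$latitude) & !is.na(meta$longitude)
  pops <- sort(unique(meta$population))
  rows <- lapply(pops, function(p) {
    sel <- keep & meta$population == p
    if (!any(sel)) abort(sprintf("population '%s' has no coordinates", p),
                         "input_error")
    data.frame(population = p,
               latitude = mean(meta$latitude[sel]),
               longitude = mean(meta$longitude[sel]),
               n_samples = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Great-circle (straight) distance in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b numeric `c(latitude, longitude)` in decimal degrees.
#' @return distance in km.
#' @export
straight_distance <- function(a, b) {
  geosphere::distHaversine(c(a[2L], a[1L]), c(b[2L], b[1L]),
                           r = EARTH_RADIUS_KM)
}

# local equirectangular projection (km) about a reference point
project_xy <- function(lat, lon, lat0, lon0) {
  cbind(x = EARTH_RADIUS_KM * (lon - lon0) * pi / 180 * cos(lat0 * pi / 180),
        y = EARTH_RADIUS_KM * (lat - lat0) * pi / 180)
}

large_rivers <- function(map, width_threshold = "large") {
  if (width_threshold == "small") return(unclass(map))
  Filter(function(rv) rv$width_class == "large", unclass(map))
}

# crossing parameters t (position along p1->p2 in [0,1]) of one segment
# against a set of segments S (matrix columns x1,y1,x2,y2); touches included
segment_cross_params <- function(p1, p2, S, eps = 1e-12) {
  r <- p2 - p1
  qx <- S[, 1L]; qy <- S[, 2L]
  sx <- S[, 3L] - qx; sy <- S[, 4L] - qy
  denom <- r[1L] * sy - r[2L] * sx
  dqx <- qx - p1[1L]; dqy <- qy - p1[2L]
  t <- (dqx * sy - dqy * sx) / denom
  u <- (dqx * r[2L] - dqy * r[1L]) / denom
  ok <- abs(denom) > eps & t >= -eps & t <= 1 + eps & u >= -eps & u <= 1 + eps
  t[ok]
}

# TRUE if segment p1-p2 properly crosses or touches any segment in S
segment_blocked <- function(p1, p2, S, eps = 1e-12) {
  if (length(segment_cross_params(p1, p2, S, eps)) > 0L) return(TRUE)
  # collinear overlap: all four orientation products ~0 with bbox overlap
  r <- p2 - p1
  d1 <- r[1L] * (S[, 2L] - p1[2L]) - r[2L] * (S[, 1L] - p1[1L])
  d2 <- r[1L] * (S[, 4L] - p1[2L]) - r[2L] * (S[, 3L] - p1[1L])
  col <- abs(d1) < eps & abs(d2) < eps
  if (!any(col)) return(FALSE)
  bb <- pmin(S[col, 1L], S[col, 3L]) <= max(p1[1L], p2[1L]) + eps &
    pmax(S[col, 1L], S[col, 3L]) >= min(p1[1L], p2[1L]) - eps &
    pmin(S[col, 2L], S[col, 4L]) <= max(p1[2L], p2[2L]) + eps &
    pmax(S[col, 2L], S[col, 4L]) >= min(p1[2L], p2[2L]) - eps
  any(bb)
}

# distance from point to each segment in S
point_segment_dist <- function(p, S) {
  vx <- S[, 3L] - S[, 1L]; vy <- S[, 4L] - S[, 2L]
  wx <- p[1L] - S[, 1L]; wy <- p[2L] - S[, 2L]
  len2 <- pmax(vx^2 + vy^2, 1e-300)
  t <- pmin(pmax((wx * vx + wy * vy) / len2, 0), 1)
  sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
}

river_segments_xy <- function(rv, lat0, lon0) {
  xy <- project_xy(rv$coords[, 2L], rv$coords[, 1L], lat0, lon0)
  if (nrow(xy) < 2L) return(NULL)
  cbind(xy[-nrow(xy), 1L], xy[-nrow(xy), 2L], xy[-1L, 1L], xy[-1L, 2L])
}

#' Number of large-river crossings along the straight line between two sites
#'
#' Counts transversal intersections of the straight segment between `a` and
#' `b` with every river polyline at or above the width threshold; tangential
#' touches at a shared polyline vertex are counted once. Both endpoints must
#' lie off large rivers.
#'
#' @param a,b `c(latitude, longitude)`.
#' @param map a [river_map()].
#' @param width_threshold `"large"` (default: only large rivers count) or
#'   `"small"` (all rivers count).
#' @return integer crossing count.
#' @export
tributary_crossings <- function(a, b, map, width_threshold = "large") {
  rivers <- large_rivers(map, width_threshold)
  if (length(rivers) == 0L) return(0L)
  lat0 <- (a[1L] + b[1L]) / 2; lon0 <- (a[2L] + b[2L]) / 2
  pa <- as.numeric(project_xy(a[1L], a[2L], lat0, lon0))
  pb <- as.numeric(project_xy(b[1L], b[2L], lat0, lon0))
  total <- 0L
  for (rv in rivers) {
    S <- river_segments_xy(rv, lat0, lon0)
    if (min(point_segment_dist(pa, S)) < 1e-6 ||
        min(point_segment_dist(pb, S)) < 1e-6) {
      abort("an endpoint lies exactly on a large river (ill-posed)",
            "geometry_error")
    }
    t <- segment_cross_params(pa, pb, S)
    if (length(t)) {
      t <- sort(t)
      total <- total + sum(c(TRUE, diff(t) > 1e-9))
    }
  }
  total
}

# obstacle polylines (projected) for detour routing: large rivers with the
# mouth end closed off by a long ray extension
detour_obstacles <- function(rivers, lat0, lon0, ray_km) {
  lapply(rivers, function(rv) {
    xy <- project_xy(rv$coords[, 2L], rv$coords[, 1L], lat0, lon0)
    headwater <- rv$headwater %||% "last"
    if (headwater == "first") xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    # now headwater is the LAST row; mouth is the first -> extend before row 1
    dir <- xy[1L, ] - xy[2L, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-12) dir <- c(1, 0) else dir <- dir / nrm
    rbind(xy[1L, ] + dir * ray_km, xy)
  })
}

polyline_segments <- function(xy) {
  cbind(xy[-nrow(xy), 1L], xy[-nrow(xy), 2L], xy[-1L, 1L], xy[-1L, 2L])
}

#' Headwater-detoured distance between two sites
#'
#' Length (km) of the shortest polygonal path from `a` to `b` whose segments
#' cross no large river; the only way past a river is around its headwater
#' terminus. Computed on a visibility graph whose candidate nodes are the two
#' sites plus points offset by `epsilon_km` around every large-river vertex
#' (including the headwater terminus); the mouth terminus is closed by a long
#' ray so paths cannot round the downstream end. Returns the straight
#' great-circle distance when the direct segment is unobstructed.
#'
#' @param a,b `c(latitude, longitude)`; must not lie on a large river.
#' @param map a [river_map()].
#' @param epsilon_km offset past river vertices (default 0.1 km).
#' @return distance in km; `Inf` with attribute `infeasible = TRUE` when no
#'   feasible path exists.
#' @export
detoured_distance <- function(a, b, map, epsilon_km = 0.1) {
  straight <- straight_distance(a, b)
  if (tributary_crossings(a, b, map) == 0L) return(straight)
  rivers <- large_rivers(map)
  lat0 <- (a[1L] + b[1L]) / 2; lon0 <- (a[2L] + b[2L]) / 2
  pa <- as.numeric(project_xy(a[1L], a[2L], lat0, lon0))
  pb <- as.numeric(project_xy(b[1L], b[2L], lat0, lon0))
  all_xy <- do.call(rbind, lapply(rivers, function(rv)
    project_xy(rv$coords[, 2L], rv$coords[, 1L], lat0, lon0)))
  span <- rbind(all_xy, pa, pb)
  ray_km <- 10 * sqrt(diff(range(span[, 1L]))^2 + diff(range(span[, 2L]))^2) + 10
  obstacles <- detour_obstacles(rivers, lat0, lon0, ray_km)
  S <- do.call(rbind, lapply(obstacles, polyline_segments))
  # candidate nodes: endpoints + 8 compass offsets around each river vertex
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  offs <- cbind(cos(ang), sin(ang)) * epsilon_km
  verts <- do.call(rbind, obstacles)
  nodes <- rbind(pa, pb,
                 verts[rep(seq_len(nrow(verts)), each = 8L), ] +
                   offs[rep(seq_len(8L), nrow(verts)), ])
  n <- nrow(nodes)
  pairs <- utils::combn(n, 2L)
  open <- !vapply(seq_len(ncol(pairs)), function(k) {
    segment_blocked(nodes[pairs[1L, k], ], nodes[pairs[2L, k], ], S)
  }, logical(1L))
  if (!any(open)) return(structure(Inf, infeasible = TRUE))
  edges <- pairs[, open, drop = FALSE]
  weights <- sqrt(rowSums((nodes[edges[1L, ], , drop = FALSE] -
                             nodes[edges[2L, ], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(edges))
  dist <- igraph::distances(g, v = 1L, to = 2L, weights = weights)[1L, 1L]
  if (!is.finite(dist)) return(structure(Inf, infeasible = TRUE))
  max(dist, straight)
}

#' Geographic index table for all site pairs
#'
#' Computes, for every unordered pair of sites, the straight great-circle
#' distance, the headwater-detoured distance and the number of large-river
#' crossings.
#'
#' @param sites data.frame from [population_centroids()] (columns
#'   `population`, `latitude`, `longitude`).
#' @param map a [river_map()].
#' @param epsilon_km detour offset, see [detoured_distance()].
#' @return data.frame: pop_a, pop_b, straight_km, detoured_km, crossings.
#' @export
geo_index_table <- function(sites, map, epsilon_km = 0.1) {
  if (nrow(sites) < 2L) abort("need at least two sites", "input_error")
  pairs <- utils::combn(nrow(sites), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    a <- c(sites$latitude[i], sites$longitude[i])
    b <- c(sites$latitude[j], sites$longitude[j])
    data.frame(pop_a = sites$population[i], pop_b = sites$population[j],
               straight_km = straight_distance(a, b),
               detoured_km = as.numeric(detoured_distance(a, b, map, epsilon_km)),
               crossings = tributary_crossings(a, b, map),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
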