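# Adaptive local convex hull (a-LoCoH) home ranges.  For each fix, a local
# hull is built from the neighbors whose cumulative distances stay within
# the adaptive parameter a; hulls are unioned smallest-first up to the
# requested isopleth.  The union defines the availability domain.

#' Maximum pairwise distance (the adaptive 'a' parameter)
#'
#' The a-LoCoH convention of the motivating analysis sets a to the maximum
#' distance between any two fixes.  Computed exactly via the convex hull
#' (the diameter of a point set is attained on its hull).
#'
#' @param points two-column matrix of planar coordinates (m).
#' @return The maximum pairwise Euclidean distance.
#' @export
compute_a <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- unique(points)
  if (nrow(points) < 2L) stop("need at least 2 distinct points")
  h <- if (nrow(points) > 3L) {
    idx <- grDevices::chull(points)
    points[idx, , drop = FALSE]
  } else points
  max(stats::dist(h))
}

#' Adaptive local convex hull home range
#'
#' For every point, neighbors are collected in increasing distance order
#' (ties broken by point index; a tied group is admitted whenever its first
#' member fits) while the cumulative sum of neighbor distances stays within
#' \code{a}.  The convex hulls of these local sets are sorted by area and
#' unioned cumulatively until the union contains at least \code{isopleth}
#' percent of the input points.
#'
#' @param points two-column matrix of fixes (planar meters).
#' @param a adaptive parameter in meters (default: the maximum pairwise
#'   distance, \code{\link{compute_a}}).
#' @param isopleth percent of points the union must enclose (default 100).
#' @param animal_id,year identifiers carried on the result.
#' @return An object of class \code{"alocoh_hr"}: the retained local hulls,
#'   the stitched union rings (outer counter-clockwise, holes clockwise),
#'   \code{area_km2}, and bookkeeping fields.
#' @export
alocoh <- function(points, a = NULL, isopleth = 100,
                   animal_id = NA_character_, year = NA_integer_) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  pts <- unique(points)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 distinct points")
  if (abs(ring_area(convex_hull_ccw(pts))) <= 0)
    stop("all points are collinear; jitter the coordinates to proceed")
  if (is.null(a)) a <- compute_a(pts)
  if (a <= 0) stop("a must be positive")

  D <- as.matrix(stats::dist(pts))
  hulls <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    dd <- d[ord]
    sel <- i
    cum <- 0
    k <- 1L
    while (k <= length(ord)) {
      grp <- which(dd == dd[k])
      grp <- grp[grp >= k]
      if (cum + dd[k] > a) break
      sel <- c(sel, ord[grp])
      cum <- cum + sum(dd[grp])
      k <- max(grp) + 1L
    }
    hulls[[i]] <- convex_hull_ccw(pts[sel, , drop = FALSE])
  }
  areas <- vapply(hulls, function(h) abs(ring_area(h)), numeric(1))
  if (all(areas <= 0))
    stop("a is smaller than the nearest-neighbor distances; ",
         "all local hulls are degenerate")
  ord <- order(areas, seq_along(areas))
  covered <- rep(FALSE, n)
  if (isopleth >= 100) {
    # the 100% isopleth is the union of every local hull
    included <- ord
    covered[] <- TRUE
  } else {
    included <- integer(0)
    need <- isopleth / 100 * n
    for (j in ord) {
      included <- c(included, j)
      todo <- which(!covered)
      if (length(todo))
        covered[todo] <- points_in_convex(pts[todo, , drop = FALSE], hulls[[j]])
      if (sum(covered) >= need - 1e-9) break
    }
  }
  hl <- hulls[included]
  u <- poly_union(hl)
  if (u$area <= 0)
    stop("degenerate home range (zero area); check a and the input points")
  structure(list(animal_id = animal_id, year = year, years = year,
                 a_param = a, isopleth = isopleth,
                 hulls = hl, rings = u$rings,
                 area_km2 = u$area / 1e6,
                 n_points = n, coverage = sum(covered) / n,
                 bbox = c(range(unlist(lapply(hl, function(h) h[, 1]))),
                          range(unlist(lapply(hl, function(h) h[, 2])))),
                 points = pts),
            class = "alocoh_hr")
}

#' @export
print.alocoh_hr <- function(x, ...) {
  cat(sprintf("a-LoCoH home range%s%s\n",
              if (!is.na(x$animal_id)) paste0(": animal ", x$animal_id) else "",
              if (!all(is.na(x$years))) paste0(", year ", paste(x$years, collapse = "+")) else ""))
  cat(sprintf("  a = %.0f m, isopleth %g%% (%.1f%% of %d points enclosed)\n",
              x$a_param, x$isopleth, 100 * x$coverage, x$n_points))
  cat(sprintf("  area = %.2f km2 from %d local hulls\n", x$area_km2,
              length(x$hulls)))
  invisible(x)
}

#' Home-range area in square kilometers
#'
#' Shoelace area over the union rings (holes subtracted); falls back to the
#' fragment-sum area computed at union time when ring stitching failed.
#'
#' @param hr an \code{"alocoh_hr"}.
#' @return Area in km^2.
#' @export
hr_area <- function(hr) {
  stopifnot(inherits(hr, "alocoh_hr"))
  if (!is.null(hr$rings) && length(hr$rings))
    sum(vapply(hr$rings, ring_area, numeric(1))) / 1e6
  else hr$area_km2
}

#' Point membership in a home range
#' @param hr an \code{"alocoh_hr"}.
#' @param points two-column matrix.
#' @return Logical vector: inside (or on the boundary of) the union.
#' @export
hr_contains <- function(hr, points) {
  points_in_hulls(points, hr$hulls)
}

#' Estimate annual home ranges for a telemetry set
#'
#' Fixes are grouped per animal and calendar year; a year with fewer than
#' \code{min_days} distinct days of data is merged with the adjacent
#' calendar year (continuous data across two consecutive years), mirroring
#' standard practice when monitoring starts or ends mid-year.
#'
#' @param fixes telemetry \code{data.frame}.
#' @param isopleth passed to \code{\link{alocoh}}.
#' @param min_days minimum days of data for a stand-alone annual range.
#' @return List of \code{"alocoh_hr"} objects; each carries \code{year}
#'   (the year with the most data) and \code{years} (all years merged in).
#' @export
estimate_home_ranges <- function(fixes, isopleth = 100, min_days = 40) {
  out <- list()
  for (aid in unique(fixes$animal_id)) {
    sub <- fixes[fixes$animal_id == aid, , drop = FALSE]
    yr <- as.integer(format(sub$timestamp, "%Y", tz = "UTC"))
    days <- tapply(format(sub$timestamp, "%Y-%m-%d", tz = "UTC"), yr,
                   function(d) length(unique(d)))
    yrs <- sort(as.integer(names(days)))
    # merge short years into an adjacent year (prefer the better-sampled)
    group <- stats::setNames(seq_along(yrs), yrs)
    for (i in seq_along(yrs)) {
      if (days[[as.character(yrs[i])]] >= min_days) next
      nb <- c(if (i > 1L) i - 1L, if (i < length(yrs)) i + 1L)
      nb <- nb[abs(yrs[nb] - yrs[i]) == 1L]
      if (!length(nb)) next
      best <- nb[which.max(vapply(nb, function(j)
        days[[as.character(yrs[j])]], numeric(1)))]
      group[i] <- group[best]
    }
    for (g in unique(group)) {
      sel <- yr %in% yrs[group == g]
      if (sum(sel) < 3L) next
      yg <- yrs[group == g]
      major <- yg[which.max(vapply(yg, function(y)
        days[[as.character(y)]], numeric(1)))]
      hr <- alocoh(cbind(sub$x[sel], sub$y[sel]), isopleth = isopleth,
                   animal_id = aid, year = major)
      hr$years <- yg
      out[[length(out) + 1L]] <- hr
    }
  }
  out
}

#' Write home-range polygons as GeoJSON
#'
#' @param ranges an \code{"alocoh_hr"} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_homerange_geojson <- function(ranges, path) {
  if (inherits(ranges, "alocoh_hr")) ranges <- list(ranges)
  feats <- lapply(ranges, function(hr) {
    rings <- hr$rings
    if (is.null(rings) || !length(rings))
      rings <- hr$hulls
    signs <- vapply(rings, ring_area, numeric(1))
    outers <- which(signs >= 0); holes <- which(signs < 0)
    polys <- lapply(outers, function(o) {
      ring_list <- list(rings[[o]])
      for (h in holes) {
        if (points_in_ring(rings[[h]][1, , drop = FALSE], rings[[o]]))
          ring_list <- c(ring_list, list(rings[[h]]))
      }
      lapply(ring_list, function(r) rbind(r, r[1, , drop = FALSE]))
    })
    list(type = "Feature",
         properties = list(animal_id = hr$animal_id, year = hr$year,
                           a_param = hr$a_param, isopleth = hr$isopleth,
                           area_km2 = hr$area_km2),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
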