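# Planar geometry primitives used by the home-range estimator and the
# availability sampler: convex hulls, point-in-polygon tests, shoelace
# areas, and an exact union of convex polygons via edge-fragment clipping.
# All coordinates are projected planar meters.

# numeric tolerance scaled to the extent of the geometry at hand
.geom_tol <- function(xy) {
  d <- max(diff(range(xy[, 1])), diff(range(xy[, 2])), 1)
  d * 1e-9
}

#' Convex hull in counter-clockwise order
#'
#' @param pts two-column matrix of planar coordinates (meters).
#' @return Matrix of hull vertices in counter-clockwise order (no repeated
#'   closing vertex).  Collinear inputs return the two extreme points
#'   (a degenerate, zero-area hull).
#' @keywords internal
convex_hull_ccw <- function(pts) {
  pts <- unique(round(pts, 10))
  if (nrow(pts) == 1L) return(pts)
  if (nrow(pts) == 2L) return(pts)
  idx <- grDevices::chull(pts)
  h <- pts[idx, , drop = FALSE]
  if (nrow(h) < 3L) return(h[!duplicated(h), , drop = FALSE])
  if (ring_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  h
}

#' Signed area of a polygon ring (shoelace formula)
#'
#' Positive for counter-clockwise rings, negative for clockwise.
#'
#' @param ring two-column matrix of ring vertices (open ring; the closing
#'   edge back to the first vertex is implied).
#' @return Signed area in squared coordinate units.
#' @export
ring_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2]) / 2
}

#' Polygon area with holes (shoelace over rings)
#'
#' Rings wound opposite to the outer boundary (holes) subtract from the
#' total; the absolute value of the signed sum is returned so that the
#' overall winding convention does not matter.
#'
#' @param rings a single two-column matrix or a list of them.
#' @return Area in squared coordinate units (non-negative).
#' @export
poly_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  abs(sum(vapply(rings, ring_area, numeric(1))))
}

# Vectorized point-in-convex-polygon, boundary inclusive.
# hull must be CCW; degenerate hulls (1-2 vertices) are treated as a point
# or segment with tolerance `tol`.
points_in_convex <- function(pts, hull, tol = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  if (is.null(tol)) tol <- .geom_tol(rbind(pts, hull))
  n <- nrow(hull)
  if (n == 1L) {
    return(abs(pts[, 1] - hull[1, 1]) <= tol & abs(pts[, 2] - hull[1, 2]) <= tol)
  }
  if (n == 2L) {
    return(.dist_point_segment(pts, hull[1, ], hull[2, ]) <= tol)
  }
  inside <- rep(TRUE, nrow(pts))
  j <- c(2:n, 1L)
  for (k in seq_len(n)) {
    ex <- hull[j[k], 1] - hull[k, 1]
    ey <- hull[j[k], 2] - hull[k, 2]
    cr <- ex * (pts[, 2] - hull[k, 2]) - ey * (pts[, 1] - hull[k, 1])
    inside <- inside & (cr >= -tol * sqrt(ex^2 + ey^2 + 1))
    if (!any(inside)) break
  }
  inside
}

.dist_point_segment <- function(pts, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  L2 <- abx^2 + aby^2
  if (L2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * abx + (pts[, 2] - a[2]) * aby) / L2))
  sqrt((pts[, 1] - (a[1] + t * abx))^2 + (pts[, 2] - (a[2] + t * aby))^2)
}

# TRUE for points contained in at least one hull of a list
points_in_hulls <- function(pts, hulls, tol = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  hit <- rep(FALSE, nrow(pts))
  for (h in hulls) {
    todo <- which(!hit)
    if (!length(todo)) break
    bb <- c(range(h[, 1]), range(h[, 2]))
    t0 <- if (is.null(tol)) .geom_tol(h) * 10 else tol
    cand <- todo[pts[todo, 1] >= bb[1] - t0 & pts[todo, 1] <= bb[2] + t0 &
                 pts[todo, 2] >= bb[3] - t0 & pts[todo, 2] <= bb[4] + t0]
    if (!length(cand)) next
    hit[cand] <- points_in_convex(pts[cand, , drop = FALSE], h, tol = tol)
  }
  hit
}

#' Point-in-polygon test for an arbitrary simple ring
#'
#' Even-odd ray casting, boundary inclusive (within numerical tolerance).
#'
#' @param pts two-column matrix of query points.
#' @param ring two-column matrix of polygon vertices (open ring).
#' @return Logical vector.
#' @export
points_in_ring <- function(pts, ring) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  tol <- .geom_tol(ring)
  n <- nrow(ring)
  j <- c(2:n, 1L)
  inside <- rep(FALSE, nrow(pts))
  onb <- rep(FALSE, nrow(pts))
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[j[k], ]
    onb <- onb | (.dist_point_segment(pts, a, b) <= tol * 10)
    cross_y <- (a[2] > pts[, 2]) != (b[2] > pts[, 2])
    if (any(cross_y)) {
      xint <- a[1] + (pts[, 2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      flip <- cross_y & (pts[, 1] < xint)
      inside <- xor(inside, flip & cross_y)
    }
  }
  inside | onb
}

# ---- exact union of convex polygons --------------------------------------

# parametric positions (on segment a->b) of intersections with all edges of
# convex hull G (rows C -> D), including collinear overlap endpoints
.seg_cut_params_poly <- function(a, b, G, tol) {
  n <- nrow(G)
  j <- c(2:n, 1L)
  C <- G; D <- G[j, , drop = FALSE]
  rx <- b[1] - a[1]; ry <- b[2] - a[2]
  sx <- D[, 1] - C[, 1]; sy <- D[, 2] - C[, 2]
  qx <- C[, 1] - a[1]; qy <- C[, 2] - a[2]
  denom <- rx * sy - ry * sx
  cross_q <- qx * ry - qy * rx
  out <- numeric(0)
  gen <- abs(denom) > tol
  if (any(gen)) {
    t <- (qx * sy - qy * sx)[gen] / denom[gen]
    u <- cross_q[gen] / denom[gen]
    ok <- t >= -1e-12 & t <= 1 + 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
    out <- t[ok]
  }
  L2 <- rx^2 + ry^2
  col <- !gen & abs(cross_q) <= tol * sqrt(L2 + 1)
  if (any(col) && L2 > 0) {
    tc <- (qx[col] * rx + qy[col] * ry) / L2
    td <- ((D[col, 1] - a[1]) * rx + (D[col, 2] - a[2]) * ry) / L2
    cand <- c(tc, td)
    out <- c(out, cand[cand >= -1e-12 & cand <= 1 + 1e-12])
  }
  out
}

# bulk classification of points against one convex hull: returns a list with
# strict (strictly interior), onb (on boundary), and for boundary points the
# index of the nearest edge
.classify_points_hull <- function(M, hull, tol) {
  n <- nrow(hull)
  j <- c(2:n, 1L)
  m <- nrow(M)
  min_margin <- rep(Inf, m)
  best_edge <- rep(1L, m)
  best_dist <- rep(Inf, m)
  for (k in seq_len(n)) {
    ex <- hull[j[k], 1] - hull[k, 1]; ey <- hull[j[k], 2] - hull[k, 2]
    el <- sqrt(ex^2 + ey^2)
    if (el == 0) next
    cr <- (ex * (M[, 2] - hull[k, 2]) - ey * (M[, 1] - hull[k, 1])) / el
    min_margin <- pmin(min_margin, cr)
    dseg <- .dist_point_segment(M, hull[k, ], hull[j[k], ])
    upd <- dseg < best_dist
    best_dist[upd] <- dseg[upd]
    best_edge[upd] <- k
  }
  onb <- best_dist <= tol * 10
  list(strict = min_margin > tol * 10 & !onb, onb = onb, edge = best_edge)
}

#' Exact union of convex polygons
#'
#' Computes the boundary and area of the union of a set of convex polygons
#' by clipping every polygon edge against all overlapping polygons, keeping
#' only the fragments on the union boundary, and stitching the surviving
#' fragments into rings.  Outer rings come out counter-clockwise and holes
#' clockwise, so \code{\link{poly_area}} applies directly.
#'
#' @param hulls list of two-column CCW vertex matrices (degenerate hulls with
#'   fewer than 3 vertices are ignored for the boundary; they carry no area).
#' @return List with \code{rings} (list of matrices; \code{NULL} if ring
#'   stitching failed numerically) and \code{area} (exact union area from the
#'   surviving fragments, available even when stitching fails).
#' @keywords internal
poly_union <- function(hulls) {
  hulls <- Filter(function(h) nrow(h) >= 3L && abs(ring_area(h)) > 0, hulls)
  if (!length(hulls)) return(list(rings = list(), area = 0))
  allxy <- do.call(rbind, hulls)
  tol <- .geom_tol(allxy)
  # prune hulls fully contained in another (cheap dominance filter)
  keep <- rep(TRUE, length(hulls))
  areas <- vapply(hulls, function(h) abs(ring_area(h)), numeric(1))
  ord <- order(areas, decreasing = TRUE)
  bb <- t(vapply(hulls, function(h) c(range(h[, 1]), range(h[, 2])), numeric(4)))
  for (i in ord) {
    if (!keep[i]) next
    for (j in seq_along(hulls)) {
      if (i == j || !keep[j] || areas[j] > areas[i]) next
      if (bb[j, 1] < bb[i, 1] - tol || bb[j, 2] > bb[i, 2] + tol ||
          bb[j, 3] < bb[i, 3] - tol || bb[j, 4] > bb[i, 4] + tol) next
      if (areas[j] == areas[i] && j < i) next
      if (all(points_in_convex(hulls[[j]], hulls[[i]], tol = tol))) keep[j] <- FALSE
    }
  }
  hulls <- hulls[keep]
  bb <- bb[keep, , drop = FALSE]
  nh <- length(hulls)

  # phase 1: cut every edge at its intersections with overlapping hulls
  overlaps <- lapply(seq_len(nh), function(i)
    which(seq_len(nh) != i &
          bb[, 1] <= bb[i, 2] + tol & bb[, 2] >= bb[i, 1] - tol &
          bb[, 3] <= bb[i, 4] + tol & bb[, 4] >= bb[i, 3] - tol))
  fr_p <- list(); fr_q <- list(); fr_own <- integer(0); nf <- 0L
  for (i in seq_len(nh)) {
    H <- hulls[[i]]
    n <- nrow(H); jn <- c(2:n, 1L)
    for (k in seq_len(n)) {
      a <- H[k, ]; b <- H[jn[k], ]
      elen <- sqrt(sum((b - a)^2))
      if (elen == 0) next
      ts <- c(0, 1)
      for (j in overlaps[[i]])
        ts <- c(ts, .seg_cut_params_poly(a, b, hulls[[j]], tol))
      ts <- sort(unique(pmin(1, pmax(0, ts))))
      keep_seg <- diff(ts) * elen > tol * 10
      if (!any(keep_seg)) next
      t0 <- ts[-length(ts)][keep_seg]; t1 <- ts[-1][keep_seg]
      nf <- nf + 1L
      fr_p[[nf]] <- cbind(a[1] + t0 * (b[1] - a[1]), a[2] + t0 * (b[2] - a[2]))
      fr_q[[nf]] <- cbind(a[1] + t1 * (b[1] - a[1]), a[2] + t1 * (b[2] - a[2]))
      fr_own <- c(fr_own, rep(i, sum(keep_seg)))
    }
  }
  if (nf == 0L) return(list(rings = list(), area = 0))
  P <- do.call(rbind, fr_p); Q <- do.call(rbind, fr_q)

  # phase 2: bulk-classify fragment midpoints against every hull
  M <- (P + Q) / 2
  V <- Q - P
  drop <- rep(FALSE, nrow(M))
  for (j in seq_len(nh)) {
    cand <- which(!drop & fr_own != j &
                  M[, 1] >= bb[j, 1] - tol * 10 & M[, 1] <= bb[j, 2] + tol * 10 &
                  M[, 2] >= bb[j, 3] - tol * 10 & M[, 2] <= bb[j, 4] + tol * 10)
    if (!length(cand)) next
    cl <- .classify_points_hull(M[cand, , drop = FALSE], hulls[[j]], tol)
    drop[cand[cl$strict]] <- TRUE
    onb <- which(cl$onb)
    if (length(onb)) {
      G <- hulls[[j]]; jn <- c(2:nrow(G), 1L)
      for (ii in onb) {
        gi <- cand[ii]
        if (drop[gi]) next
        k <- cl$edge[ii]
        e <- c(G[jn[k], 1] - G[k, 1], G[jn[k], 2] - G[k, 2])
        same_dir <- sum(e * V[gi, ]) > 0
        if (!same_dir || j < fr_own[gi]) drop[gi] <- TRUE
      }
    }
  }
  P <- P[!drop, , drop = FALSE]; Q <- Q[!drop, , drop = FALSE]
  if (!nrow(P)) return(list(rings = list(), area = 0))
  area <- sum(P[, 1] * Q[, 2] - Q[, 1] * P[, 2]) / 2
  rings <- .stitch_fragments(P, Q, tol)
  list(rings = rings, area = abs(area))
}

# chain directed fragments P->Q into closed rings; returns NULL on failure
.stitch_fragments <- function(P, Q, tol) {
  snap <- function(xy) paste(round(xy[, 1] / (tol * 100)), round(xy[, 2] / (tol * 100)))
  kp <- snap(P); kq <- snap(Q)
  used <- rep(FALSE, nrow(P))
  from_idx <- split(seq_len(nrow(P)), kp)
  rings <- list()
  for (start in seq_len(nrow(P))) {
    if (used[start]) next
    ring <- list(P[start, ])
    used[start] <- TRUE
    cur <- start
    ok <- FALSE
    for (step in seq_len(nrow(P) + 1L)) {
      nxt_key <- kq[cur]
      cand <- from_idx[[nxt_key]]
      cand <- cand[!used[cand]]
      if (nxt_key == kp[start]) { ok <- TRUE; break }
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # prefer the sharpest left turn (keeps interior on the left)
        vin <- Q[cur, ] - P[cur, ]
        ang <- vapply(cand, function(ci) {
          vo <- Q[ci, ] - P[ci, ]
          atan2(vin[1] * vo[2] - vin[2] * vo[1], sum(vin * vo))
        }, numeric(1))
        cur2 <- cand[which.max(ang)]
      } else cur2 <- cand
      ring[[length(ring) + 1L]] <- P[cur2, ]
      used[cur2] <- TRUE
      cur <- cur2
    }
    if (!ok) return(NULL)
    m <- do.call(rbind, ring)
    if (nrow(m) >= 3L && abs(ring_area(m)) > tol) rings[[length(rings) + 1L]] <- m
  }
  rings
}
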