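# Covariate engineering: exact Euclidean distance transforms of the class
# rasters, Horn-method slope, systematic availability sampling within home
# ranges, use-availability table assembly, and collinearity screening.

#' Exact Euclidean distance transform of a class raster
#'
#' Per-pixel Euclidean distance (meters) from each pixel centroid to the
#' nearest centroid of a pixel carrying \code{target_class}.  Computed with
#' the two-pass lower-envelope (parabola) algorithm, which is exact for
#' centroid-to-centroid distances; target pixels get distance 0.
#'
#' @param ls a \code{"landscape"}.
#' @param target_class a class label from \code{\link{landscape_classes}},
#'   or \code{"trail"} for the trail mask.
#' @return Numeric matrix of distances in meters.
#' @export
distance_transform <- function(ls, target_class) {
  if (target_class == "trail") {
    mask <- ls$trail_mask
  } else {
    if (!target_class %in% ls$classes)
      stop("unknown class: ", target_class)
    mask <- ls$class_grid == match(target_class, ls$classes)
  }
  if (!any(mask))
    stop("class '", target_class,
         "' is absent from the landscape; distances would be infinite")
  .edt(mask) * ls$resolution
}

# exact squared EDT in pixel units, then sqrt (Felzenszwalb & Huttenlocher)
.edt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  INF <- (nr + nc)^2 + 1
  # pass 1: per-column 1D distance (in rows) to nearest target in the column
  d1 <- matrix(INF, nr, nc)
  cur <- rep(INF, nc)
  for (r in seq_len(nr)) {
    cur <- cur + 1
    cur[mask[r, ]] <- 0
    d1[r, ] <- cur
  }
  cur <- rep(INF, nc)
  for (r in rev(seq_len(nr))) {
    cur <- cur + 1
    cur[mask[r, ]] <- 0
    d1[r, ] <- pmin(d1[r, ], cur)
  }
  d1sq <- pmin(d1, nr + nc)^2
  d1sq[d1 >= INF] <- INF
  # pass 2: per-row lower envelope of parabolas f(c') + (c - c')^2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    f <- d1sq[r, ]
    v <- integer(nc); z <- numeric(nc + 1L)
    k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
    for (q in 2:nc) {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      while (k > 1L && s <= z[k]) {
        k <- k - 1L
        s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
    k2 <- 1L
    row <- numeric(nc)
    for (q in seq_len(nc)) {
      while (z[k2 + 1L] < q) k2 <- k2 + 1L
      row[q] <- (q - v[k2])^2 + f[v[k2]]
    }
    out[r, ] <- row
  }
  sqrt(out)
}

#' Percent slope from a DEM (Horn's method)
#'
#' Interior pixels use 3x3 weighted central differences; edge pixels use
#' one-sided differences.  Slope is reported as percent rise,
#' 100 * sqrt((dz/dx)^2 + (dz/dy)^2).
#'
#' @param elevation numeric matrix of elevations (m), rows north-to-south.
#' @param resolution pixel edge length (m).
#' @return Numeric matrix of percent slope, same shape as \code{elevation}.
#' @export
slope_from_dem <- function(elevation, resolution) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  if (is.null(nr) || nr < 3L || nc < 3L)
    stop("elevation raster must be at least 3 x 3")
  # replicate edges so one-sided differences fall out of the same stencil
  zp <- rbind(elevation[1, ], elevation, elevation[nr, ])
  zp <- cbind(zp[, 1], zp, zp[, nc])
  # neighbors: z[r+dr, c+dc] on the padded grid
  nb <- function(dr, dc) zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  dzdx <- ((nb(-1, 1) + 2 * nb(0, 1) + nb(1, 1)) -
           (nb(-1, -1) + 2 * nb(0, -1) + nb(1, -1))) / (8 * resolution)
  dzdy <- ((nb(1, -1) + 2 * nb(1, 0) + nb(1, 1)) -
           (nb(-1, -1) + 2 * nb(-1, 0) + nb(-1, 1))) / (8 * resolution)
  # edge replication halves the effective step there; rescale the borders
  # back to true one-sided differences
  dzdx[, c(1L, nc)] <- dzdx[, c(1L, nc)] * 2
  dzdy[c(1L, nr), ] <- dzdy[c(1L, nr), ] * 2
  100 * sqrt(dzdx^2 + dzdy^2)
}

#' Systematic availability sample within a home range
#'
#' Draws a square lattice with the given spacing, anchored to the landscape
#' grid origin (points sit on pixel centroids when the spacing is a multiple
#' of the resolution), and keeps the lattice points inside the home-range
#' polygon (boundary inclusive).  At 150 m spacing the asymptotic density is
#' 10^6 / 150^2 = 44.4 points per square kilometer.
#'
#' @param hr an \code{"alocoh_hr"} home range (see \code{\link{alocoh}}) or a
#'   two-column matrix interpreted as a simple polygon ring.
#' @param spacing_m lattice spacing in meters (default 150).
#' @param ls optional \code{"landscape"} supplying the anchoring origin;
#'   default anchors to (0, 0).
#' @param offset optional numeric length-2 lattice offset in meters.
#' @return Two-column matrix of sample coordinates; zero rows (with a
#'   warning) when the polygon is smaller than one lattice cell.
#' @export
systematic_sample <- function(hr, spacing_m = 150, ls = NULL, offset = c(0, 0)) {
  if (spacing_m <= 0) stop("spacing must be positive")
  ox <- if (is.null(ls)) 0 else ls$origin_x
  oy <- if (is.null(ls)) 0 else ls$origin_y
  if (inherits(hr, "alocoh_hr")) {
    bb <- hr$bbox
    test <- function(p) points_in_hulls(p, hr$hulls)
  } else {
    ring <- hr
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    test <- function(p) points_in_ring(p, ring)
  }
  kx <- seq(floor((bb[1] - ox - offset[1]) / spacing_m),
            ceiling((bb[2] - ox - offset[1]) / spacing_m))
  ky <- seq(floor((bb[3] - oy - offset[2]) / spacing_m),
            ceiling((bb[4] - oy - offset[2]) / spacing_m))
  gx <- ox + offset[1] + kx * spacing_m
  gy <- oy + offset[2] + ky * spacing_m
  gx <- gx[gx >= bb[1] - 1e-9 & gx <= bb[2] + 1e-9]
  gy <- gy[gy >= bb[3] - 1e-9 & gy <= bb[4] + 1e-9]
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  if (!nrow(pts)) {
    warning("polygon smaller than one lattice cell; no sample points")
    return(pts)
  }
  keep <- test(pts)
  out <- pts[keep, , drop = FALSE]
  if (!nrow(out)) warning("polygon smaller than one lattice cell; no sample points")
  out
}

# distance rasters for the standard covariate set; returns a named list of
# matrices (classes absent from the landscape raise an error when requested)
.covariate_names <- function() {
  c(d_chaparral = "chaparral", d_coastal_sage = "coastal_sage_scrub",
    d_prairie = "prairie_meadow", d_upland = "upland_woodland",
    d_riparian = "riparian_woodland", d_water = "water",
    d_developed = "developed", d_altered_open = "altered_open",
    d_trail = "trail")
}

#' Distance rasters for the standard covariate set
#'
#' @param ls a \code{"landscape"}.
#' @param which character vector of distance covariate names (defaults to
#'   all of \code{d_chaparral, d_coastal_sage, d_prairie, d_upland,
#'   d_riparian, d_water, d_developed, d_altered_open, d_trail}).
#' @return Named list of distance matrices (meters).
#' @export
distance_stack <- function(ls, which = names(.covariate_names())) {
  cn <- .covariate_names()
  bad <- setdiff(which, names(cn))
  if (length(bad)) stop("unknown distance covariate: ", paste(bad, collapse = ", "))
  out <- lapply(which, function(nm) distance_transform(ls, cn[[nm]]))
  names(out) <- which
  out
}

#' Extract covariates at point locations
#'
#' Each point is snapped to its containing 30 m pixel and covariates are
#' read from that pixel, so two points in the same pixel get identical
#' covariates (the convention of a pixel-based use-availability design).
#'
#' @param points two-column matrix of planar coordinates (m).
#' @param ls a \code{"landscape"}.
#' @param dstack named list of distance rasters from
#'   \code{\link{distance_stack}}.
#' @return \code{data.frame} with one row per point: \code{x}, \code{y}
#'   (pixel centroid coordinates), the distance covariates, \code{elevation}
#'   and \code{slope}.
#' @export
extract_covariates <- function(points, ls, dstack = distance_stack(ls)) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  rc <- xy_to_rc(ls, points[, 1], points[, 2])
  idx <- cbind(rc[, "row"], rc[, "col"])
  out <- data.frame(
    x = ls$origin_x + (rc[, "col"] - 0.5) * ls$resolution,
    y = ls$origin_y - (rc[, "row"] - 0.5) * ls$resolution)
  for (nm in names(dstack)) out[[nm]] <- dstack[[nm]][idx]
  out$elevation <- ls$elevation[idx]
  out$slope <- ls$slope[idx]
  out
}

#' Assemble a use-availability table
#'
#' Used rows (response 1) are the feeding sites; available rows (response 0)
#' are systematic lattice samples of the matching animal-year home range.
#' Availability is only sampled for animal-years that contributed at least
#' one feeding site, the convention of a third-order use-availability
#' design.
#'
#' @param sites \code{data.frame} of feeding sites with columns
#'   \code{animal_id}, \code{year}, \code{x}, \code{y} (see
#'   \code{\link{clusters_to_feeding_sites}}).
#' @param ranges list of \code{"alocoh_hr"} home ranges carrying
#'   \code{animal_id} and \code{year}.
#' @param ls a \code{"landscape"}.
#' @param metadata \code{data.frame} with columns \code{animal_id} and
#'   \code{sex_male} (0 female, 1 male).
#' @param spacing_m availability lattice spacing (m), default 150.
#' @param dstack precomputed \code{\link{distance_stack}} (computed on the
#'   fly when omitted).
#' @return A \code{data.frame} of class \code{"rsf_data"}: columns
#'   \code{response}, \code{animal_id}, \code{year}, \code{sex_male},
#'   \code{x}, \code{y}, the distance covariates, \code{elevation},
#'   \code{slope}.
#' @export
build_table <- function(sites, ranges, ls, metadata, spacing_m = 150,
                        dstack = NULL) {
  if (!nrow(sites)) stop("no feeding sites supplied")
  if (is.null(dstack)) dstack <- distance_stack(ls)
  key <- function(a, y) paste(a, y, sep = "\r")
  rkey <- vapply(ranges, function(r) key(r$animal_id, r$year), character(1))
  sex <- stats::setNames(metadata$sex_male, metadata$animal_id)
  rows <- list()
  for (ky in unique(key(sites$animal_id, sites$year))) {
    sel <- sites[key(sites$animal_id, sites$year) == ky, , drop = FALSE]
    aid <- sel$animal_id[1]; yr <- sel$year[1]
    hi <- match(ky, rkey)
    if (is.na(hi))
      stop("no home range for animal ", aid, ", year ", yr)
    if (!aid %in% names(sex)) stop("no sex recorded for animal ", aid)
    used <- extract_covariates(cbind(sel$x, sel$y), ls, dstack)
    used <- cbind(response = 1L, animal_id = aid, year = yr,
                  sex_male = sex[[aid]], used)
    av_xy <- systematic_sample(ranges[[hi]], spacing_m, ls = ls)
    # clip availability to the landscape extent
    inx <- av_xy[, 1] >= ls$origin_x & av_xy[, 1] <= ls$origin_x + ls$n_cols * ls$resolution &
           av_xy[, 2] <= ls$origin_y & av_xy[, 2] >= ls$origin_y - ls$n_rows * ls$resolution
    av_xy <- av_xy[inx, , drop = FALSE]
    avail <- extract_covariates(av_xy, ls, dstack)
    avail <- cbind(response = 0L, animal_id = aid, year = yr,
                   sex_male = sex[[aid]], avail)
    rows[[length(rows) + 1L]] <- used
    rows[[length(rows) + 1L]] <- avail
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rsf_data", "data.frame")
  out
}

#' Screen covariates for collinearity
#'
#' Pearson correlations are computed over all rows; for every pair at or
#' above the threshold the lower-priority covariate is dropped, and each
#' exclusion is logged with its correlation.
#'
#' @param table an \code{"rsf_data"} table (or any data.frame).
#' @param covariates character vector of covariate columns to screen.
#' @param threshold absolute-correlation threshold (default 0.5).
#' @param priority character vector, earlier entries are kept in preference
#'   to later ones; covariates not listed rank after all listed ones.
#' @return List with \code{retained} (character), \code{correlation}
#'   (matrix) and \code{excluded} (\code{data.frame} with the dropped
#'   covariate, its partner and r).
#' @export
correlation_screen <- function(table, covariates, threshold = 0.5,
                               priority = covariates) {
  if (length(covariates) < 2L) stop("need at least two covariates to screen")
  X <- as.matrix(table[, covariates, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate: ",
         paste(covariates[sds == 0], collapse = ", "))
  cm <- stats::cor(X)
  rank <- match(covariates, priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  retained <- covariates
  excl <- data.frame(dropped = character(), kept = character(), r = numeric())
  repeat {
    sub <- cm[retained, retained, drop = FALSE]
    diag(sub) <- 0
    worst <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)[1, ]
    if (max(abs(sub)) < threshold) break
    a <- retained[worst[1]]; b <- retained[worst[2]]
    drop <- if (rank[match(a, covariates)] <= rank[match(b, covariates)]) b else a
    keep <- setdiff(c(a, b), drop)
    excl <- rbind(excl, data.frame(dropped = drop, kept = keep,
                                   r = sub[worst[1], worst[2]]))
    retained <- setdiff(retained, drop)
    if (length(retained) < 2L) break
  }
  list(retained = retained, correlation = cm, excluded = excl)
}
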