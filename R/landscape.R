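# Synthetic raster landscapes: a categorical habitat/land-use grid, a trail
# mask, and a smoothed-noise DEM with derived percent slope.  The class
# vocabulary mirrors a southern-California urban-wildland mosaic: six
# natural classes, two anthropogenic classes, and a catch-all.

#' Habitat / land-use class vocabulary
#' @export
landscape_classes <- function() {
  c("chaparral", "coastal_sage_scrub", "prairie_meadow", "upland_woodland",
    "riparian_woodland", "water", "developed", "altered_open", "other")
}

# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Landscape generator configuration
#'
#' Default class weights put developed cover at 3\% and altered-open cover at
#' 9\% of the extent, matching the availability of those land uses across
#' the mountain-lion home ranges that motivated the pipeline; the remaining
#' weight is spread over the natural classes with chaparral dominant.
#'
#' @param n_rows,n_cols grid dimensions in pixels.
#' @param resolution pixel edge length in meters (30 m pixels by default).
#' @param origin_x,origin_y planar coordinates (m) of the top-left corner of
#'   the grid; pixel (r, c) has its centroid at
#'   (origin_x + (c - 0.5) * resolution, origin_y - (r - 0.5) * resolution).
#' @param class_weights named non-negative weights over
#'   \code{\link{landscape_classes}}; realized cover fractions approximate
#'   the normalized weights.
#' @param n_patches approximate total number of habitat patches grown.
#' @param n_trails number of trail polylines rasterized into the trail mask.
#' @param elev_range numeric length-2, min and max elevation in meters.
#' @param smooth_passes smoothing iterations applied to the DEM noise field.
#' @return A list of class \code{"landscape_config"}.
#' @export
landscape_config <- function(n_rows = 120, n_cols = 120, resolution = 30,
                             origin_x = 0, origin_y = n_rows * resolution,
                             class_weights = c(chaparral = 0.37,
                                               coastal_sage_scrub = 0.20,
                                               prairie_meadow = 0.08,
                                               upland_woodland = 0.12,
                                               riparian_woodland = 0.05,
                                               water = 0.02,
                                               developed = 0.03,
                                               altered_open = 0.09,
                                               other = 0.04),
                             n_patches = 250, n_trails = 6,
                             elev_range = c(0, 2432), smooth_passes = 25) {
  if (n_rows < 1 || n_cols < 1) stop("landscape extent must be positive")
  if (any(class_weights < 0)) stop("class weights must be non-negative")
  if (sum(class_weights) <= 0) stop("at least one class weight must be positive")
  unknown <- setdiff(names(class_weights), landscape_classes())
  if (length(unknown)) stop("unknown class in weights: ", paste(unknown, collapse = ", "))
  structure(list(n_rows = n_rows, n_cols = n_cols, resolution = resolution,
                 origin_x = origin_x, origin_y = origin_y,
                 class_weights = class_weights, n_patches = n_patches,
                 n_trails = n_trails, elev_range = elev_range,
                 smooth_passes = smooth_passes),
            class = "landscape_config")
}

#' Generate a synthetic landscape stack
#'
#' Habitat patches are grown as a noise-warped nearest-seed tessellation:
#' each class receives a number of seed points proportional to its weight,
#' every pixel is assigned the class of its nearest seed under a per-seed
#' random radius factor, which yields spatially contiguous, irregular
#' patches whose realized cover fractions approximate the weights.  The DEM
#' is iteratively smoothed white noise rescaled to \code{elev_range}; slope
#' (percent) is derived from the DEM by Horn's method
#' (\code{\link{slope_from_dem}}).  Trails are random polylines rasterized
#' one pixel wide.
#'
#' @param config a \code{\link{landscape_config}}.
#' @param seed integer; the generator is a pure function of (config, seed).
#' @return An object of class \code{"landscape"}: a list with grid geometry
#'   (\code{origin_x}, \code{origin_y}, \code{resolution}, \code{n_rows},
#'   \code{n_cols}), \code{classes}, integer \code{class_grid}, logical
#'   \code{trail_mask}, and numeric \code{elevation} and \code{slope}
#'   matrices (rows index north-to-south).
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  stopifnot(inherits(config, "landscape_config"))
  .with_seed(seed, {
    nr <- config$n_rows; nc <- config$n_cols
    w <- config$class_weights[config$class_weights > 0]
    w <- w / sum(w)
    classes <- landscape_classes()
    # seeds per class, at least 1 for every positive-weight class
    ns <- pmax(round(w * config$n_patches), 1L)
    names(ns) <- names(w)
    seed_class <- rep(match(names(ns), classes), ns)
    n_seed <- length(seed_class)
    sr <- runif(n_seed, 0.5, nr + 0.5)
    sc <- runif(n_seed, 0.5, nc + 0.5)
    # per-seed radius factor scaled so each class's expected cover tracks its
    # weight: nearest-seed assignment alone gives cover ~ n_seeds/class
    rad <- runif(n_seed, 0.7, 1.3)
    rr <- matrix(rep(seq_len(nr), nc), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    # mild coordinate warp for organic boundaries
    wr <- rr + .smooth_noise(nr, nc, passes = 6) * 6
    wc <- cc + .smooth_noise(nr, nc, passes = 6) * 6
    D2 <- (outer(as.vector(wr), sr, "-"))^2 + (outer(as.vector(wc), sc, "-"))^2
    target <- as.vector(w[match(seed_class, match(names(w), classes))])
    target_frac <- stats::setNames(as.vector(w), match(names(w), classes))
    # a few calibration sweeps pull realized class cover toward the weights
    cls_rad <- rep(1, length(w))
    names(cls_rad) <- names(target_frac)
    for (it in 1:12) {
      eff <- rad * cls_rad[as.character(seed_class)]
      assign_idx <- max.col(-sweep(D2, 2, eff^2, "/"), ties.method = "first")
      got <- tabulate(seed_class[assign_idx], nbins = length(classes))
      realized <- got[as.integer(names(target_frac))] / (nr * nc)
      adj <- (target_frac / pmax(realized, 1e-6))^0.4
      cls_rad <- cls_rad * pmin(pmax(adj, 0.7), 1.4)
    }
    class_grid <- matrix(seed_class[assign_idx], nr, nc)

    elev <- .smooth_noise(nr, nc, passes = config$smooth_passes)
    er <- range(elev)
    if (diff(er) == 0) {
      elev <- matrix(mean(config$elev_range), nr, nc)
    } else {
      elev <- (elev - er[1]) / diff(er) *
        diff(config$elev_range) + config$elev_range[1]
    }

    trail_mask <- matrix(FALSE, nr, nc)
    if (config$n_trails > 0) {
      for (t in seq_len(config$n_trails)) {
        # polyline wandering across the grid
        edge <- sample(4, 1)
        pos <- switch(edge,
                      c(1, sample(nc, 1)), c(nr, sample(nc, 1)),
                      c(sample(nr, 1), 1), c(sample(nr, 1), nc))
        heading <- switch(edge, pi / 2, -pi / 2, 0, pi) + runif(1, -0.5, 0.5)
        r <- pos[1]; c2 <- pos[2]
        for (step in seq_len(nr + nc)) {
          ri <- round(r); ci <- round(c2)
          if (ri < 1 || ri > nr || ci < 1 || ci > nc) break
          trail_mask[ri, ci] <- TRUE
          heading <- heading + rnorm(1, 0, 0.25)
          r <- r + sin(heading); c2 <- c2 + cos(heading)
        }
      }
    }

    ls <- structure(list(origin_x = config$origin_x, origin_y = config$origin_y,
                         resolution = config$resolution, n_rows = nr, n_cols = nc,
                         classes = classes, class_grid = class_grid,
                         trail_mask = trail_mask, elevation = elev,
                         slope = NULL),
                    class = "landscape")
    ls$slope <- slope_from_dem(elev, config$resolution)
    ls
  })
}

# iteratively box-smoothed standard-normal noise, centered and unit-scaled
.smooth_noise <- function(nr, nc, passes = 20) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    zp <- rbind(z[1, ], z, z[nr, ])
    z <- (zp[1:nr, ] + zp[2:(nr + 1), ] + zp[3:(nr + 2), ]) / 3
    zp <- cbind(z[, 1], z, z[, nc])
    z <- (zp[, 1:nc] + zp[, 2:(nc + 1)] + zp[, 3:(nc + 2)]) / 3
  }
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' @export
print.landscape <- function(x, ...) {
  cat("Synthetic landscape stack\n")
  cat(sprintf("  grid: %d x %d pixels at %g m (%.1f x %.1f km)\n",
              x$n_rows, x$n_cols, x$resolution,
              x$n_cols * x$resolution / 1000, x$n_rows * x$resolution / 1000))
  fr <- class_fractions(x)
  fr <- fr[fr > 0]
  cat("  cover:", paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", "), "\n")
  cat(sprintf("  elevation: %.0f-%.0f m; slope: %.0f-%.0f%%; trail pixels: %d\n",
              min(x$elevation), max(x$elevation), min(x$slope), max(x$slope),
              sum(x$trail_mask)))
  invisible(x)
}

#' Realized cover fraction of each class
#' @param ls a \code{"landscape"}.
#' @return Named numeric vector over \code{\link{landscape_classes}}.
#' @export
class_fractions <- function(ls) {
  tab <- tabulate(ls$class_grid, nbins = length(ls$classes))
  stats::setNames(tab / length(ls$class_grid), ls$classes)
}

#' Pixel centroid coordinates
#' @param ls a \code{"landscape"}.
#' @return A list with matrices \code{x} and \code{y} of per-pixel centroid
#'   coordinates (meters).
#' @export
pixel_centroids <- function(ls) {
  x <- ls$origin_x + (seq_len(ls$n_cols) - 0.5) * ls$resolution
  y <- ls$origin_y - (seq_len(ls$n_rows) - 0.5) * ls$resolution
  list(x = matrix(rep(x, each = ls$n_rows), ls$n_rows, ls$n_cols),
       y = matrix(rep(y, ls$n_cols), ls$n_rows, ls$n_cols))
}

# map x/y coordinates to 1-based row/col indices (clamped = FALSE errors
# for out-of-extent points)
xy_to_rc <- function(ls, x, y, clamp = FALSE) {
  c0 <- floor((x - ls$origin_x) / ls$resolution) + 1L
  r0 <- floor((ls$origin_y - y) / ls$resolution) + 1L
  if (clamp) {
    c0 <- pmin(pmax(c0, 1L), ls$n_cols)
    r0 <- pmin(pmax(r0, 1L), ls$n_rows)
  } else if (any(c0 < 1 | c0 > ls$n_cols | r0 < 1 | r0 > ls$n_rows)) {
    stop("point outside landscape extent")
  }
  cbind(row = r0, col = c0)
}

# ---- plain-text raster I/O (ESRI ASCII grid + JSON sidecar) ---------------

.write_asc <- function(m, path, ls, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.6f", ls$origin_x),
               sprintf("yllcorner %.6f", ls$origin_y - ls$n_rows * ls$resolution),
               sprintf("cellsize %.6f", ls$resolution),
               "NODATA_value -9999"), con)
  utils::write.table(round(m, digits), con, row.names = FALSE,
                     col.names = FALSE)
}

.read_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6,
                           col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  vals <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(vals) <- NULL
  h <- stats::setNames(hdr$value, tolower(hdr$key))
  list(header = h, values = vals)
}

#' Write a landscape stack to a directory of ASCII grids
#'
#' Layers are written as ESRI ASCII grids (\code{class.asc},
#' \code{elevation.asc}, \code{slope.asc}, \code{trails.asc}) with a JSON
#' sidecar (\code{landscape.json}) mapping integer codes to class labels.
#'
#' @param ls a \code{"landscape"}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_asc(ls$class_grid, file.path(dir, "class.asc"), ls, digits = 0)
  .write_asc(ls$elevation, file.path(dir, "elevation.asc"), ls)
  .write_asc(ls$slope, file.path(dir, "slope.asc"), ls)
  .write_asc(ls$trail_mask + 0L, file.path(dir, "trails.asc"), ls, digits = 0)
  jsonlite::write_json(list(classes = ls$classes,
                            origin_x = ls$origin_x, origin_y = ls$origin_y,
                            resolution = ls$resolution,
                            n_rows = ls$n_rows, n_cols = ls$n_cols),
                       file.path(dir, "landscape.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a landscape stack written by \code{\link{write_landscape}}
#' @param dir directory containing the ASCII grids and sidecar.
#' @return A \code{"landscape"}.
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "landscape.json"),
                              simplifyVector = TRUE)
  cls <- .read_asc(file.path(dir, "class.asc"))
  structure(list(origin_x = meta$origin_x, origin_y = meta$origin_y,
                 resolution = meta$resolution, n_rows = meta$n_rows,
                 n_cols = meta$n_cols, classes = meta$classes,
                 class_grid = matrix(as.integer(cls$values),
                                     meta$n_rows, meta$n_cols),
                 trail_mask = .read_asc(file.path(dir, "trails.asc"))$values > 0,
                 elevation = .read_asc(file.path(dir, "elevation.asc"))$values,
                 slope = .read_asc(file.path(dir, "slope.asc"))$values),
            class = "landscape")
}
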