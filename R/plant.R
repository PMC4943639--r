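# Plant feeding-site clusters into a simulated track under a known
# exponential selection model, returning the ground truth needed for
# parameter-recovery testing.

#' Plant feeding clusters under known selection coefficients
#'
#' Candidate kill pixels are the landscape pixels inside the convex hull of
#' the track.  Covariates at candidate pixels are standardized with the
#' availability-domain mean and 2 SD (the model-fitting convention), and
#' \code{n_kills} pixels are drawn without replacement with probability
#' proportional to \code{exp(beta_true . x)}, subject to a minimum
#' separation so planted clusters cannot chain into each other.  Each kill
#' generates a cluster of fixes at the carcass position - the kill site
#' displaced by a uniform 0-80 m drag - with at least 2 night fixes within
#' the chaining radius and a dwell span of at least 24 h, spliced into the
#' track in time order.
#'
#' @param track telemetry \code{data.frame} from \code{\link{generate_track}}.
#' @param ls a \code{"landscape"}.
#' @param beta_true named numeric vector of selection coefficients on the
#'   standardized covariates (names from \code{\link{distance_stack}} plus
#'   \code{elevation}, \code{slope}); covariates not named get weight 0.
#' @param n_kills number of feeding sites to plant.
#' @param dwell_hours_range length-2 range of cluster temporal spans (h).
#' @param drag_range length-2 range (m) of the carcass drag displacement.
#' @param min_sep_m minimum separation between planted kill pixels (m).
#' @param n_cluster_fixes range of fixes per planted cluster.
#' @param seed integer seed.
#' @param dstack optional precomputed \code{\link{distance_stack}}.
#' @param scaling optional \code{data.frame} (covariate, mean, sd) fixing
#'   the standardization; the default standardizes over the availability
#'   domain (the candidate pixels).  Supplying a shared scaling makes one
#'   \code{beta_true} comparable across animals in multi-animal
#'   simulations.
#' @return List with \code{track} (augmented, time-ordered fixes) and
#'   \code{truth}: \code{beta_true}, \code{kill_sites} (matrix of kill
#'   pixel centroids), \code{carcass_sites} (dragged cluster centers),
#'   \code{scaling} (availability means/SDs used), and \code{seed}.
#' @export
plant_feeding_clusters <- function(track, ls, beta_true, n_kills,
                                   dwell_hours_range = c(26, 48),
                                   drag_range = c(0, 80), min_sep_m = 250,
                                   n_cluster_fixes = c(5, 8), seed = 1L,
                                   dstack = NULL, scaling = NULL) {
  covnames <- names(beta_true)
  known <- c(names(.covariate_names()), "elevation", "slope")
  bad <- setdiff(covnames, known)
  if (length(bad))
    stop("no covariate raster derivable for: ", paste(bad, collapse = ", "))
  .with_seed(seed, {
    hull <- convex_hull_ccw(cbind(track$x, track$y))
    cent <- pixel_centroids(ls)
    pts <- cbind(as.vector(cent$x), as.vector(cent$y))
    inside <- which(points_in_convex(pts, hull))
    if (n_kills > length(inside))
      stop("n_kills exceeds the ", length(inside),
           " candidate pixels inside the track's range")
    if (is.null(dstack))
      dstack <- distance_stack(ls, intersect(covnames, names(.covariate_names())))
    X <- matrix(0, length(inside), length(covnames),
                dimnames = list(NULL, covnames))
    for (nm in covnames) {
      lay <- if (nm == "elevation") ls$elevation
             else if (nm == "slope") ls$slope
             else dstack[[nm]]
      X[, nm] <- lay[inside]
    }
    if (is.null(scaling)) {
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd)
      sdv[sdv == 0] <- 1
    } else {
      mu <- stats::setNames(scaling$mean, scaling$covariate)[covnames]
      sdv <- stats::setNames(scaling$sd, scaling$covariate)[covnames]
    }
    Xs <- sweep(sweep(X, 2, mu), 2, 2 * sdv, "/")
    lp <- as.vector(Xs %*% beta_true)
    wgt <- exp(lp - max(lp))
    chosen <- integer(0)
    avail <- rep(TRUE, length(inside))
    for (k in seq_len(n_kills)) {
      if (!any(avail & wgt > 0))
        stop("minimum separation exhausted the candidate pixels")
      pick <- sample(length(inside), 1, prob = wgt * avail)
      chosen <- c(chosen, pick)
      d2 <- (pts[inside, 1] - pts[inside[pick], 1])^2 +
            (pts[inside, 2] - pts[inside[pick], 2])^2
      avail[d2 <= min_sep_m^2] <- FALSE
    }
    kill_xy <- pts[inside[chosen], , drop = FALSE]

    t_range <- range(as.numeric(track$timestamp))
    new_rows <- list()
    carcass <- matrix(NA_real_, n_kills, 2)
    for (k in seq_len(n_kills)) {
      drag <- stats::runif(1, drag_range[1], drag_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      cxy <- kill_xy[k, ] + drag * c(cos(ang), sin(ang))
      carcass[k, ] <- cxy
      dwell <- stats::runif(1, dwell_hours_range[1], dwell_hours_range[2])
      nfix <- sample(seq(n_cluster_fixes[1], n_cluster_fixes[2]), 1)
      # anchor the first fix at 21:00 on a random monitoring day so the
      # first and last fixes are night fixes and the span equals the dwell
      day0 <- as.POSIXct(trunc(as.POSIXct(
        stats::runif(1, t_range[1], max(t_range[1], t_range[2] - dwell * 3600)),
        origin = "1970-01-01", tz = "UTC"), "days"), tz = "UTC")
      start <- as.numeric(day0) + 21 * 3600
      # first two fixes at 21:00 and 01:00 are always night fixes
      offs <- c(0, 4, sort(stats::runif(nfix - 3L, 4.5, dwell - 0.5)), dwell)
      tms <- as.POSIXct(start + offs * 3600, origin = "1970-01-01", tz = "UTC")
      r <- stats::runif(nfix, 0, 15)
      th <- stats::runif(nfix, 0, 2 * pi)
      new_rows[[k]] <- data.frame(animal_id = track$animal_id[1],
                                  timestamp = tms,
                                  x = cxy[1] + r * cos(th),
                                  y = cxy[2] + r * sin(th))
    }
    aug <- rbind(track[, c("animal_id", "timestamp", "x", "y")],
                 do.call(rbind, new_rows))
    aug <- aug[order(aug$timestamp), , drop = FALSE]
    rownames(aug) <- NULL
    aug <- classify_night(aug)
    list(track = aug,
         truth = list(beta_true = beta_true, kill_sites = kill_xy,
                      carcass_sites = carcass,
                      scaling = data.frame(covariate = covnames, mean = mu,
                                           sd = sdv, row.names = NULL),
                      seed = seed))
  })
}
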