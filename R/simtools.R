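# Parameter-recovery simulation tools.  A setup object fixes the expensive
# ingredients (landscape, tracks, home ranges, availability samples); each
# replicate then plants feeding sites under known coefficients and returns
# a ready-to-fit use-availability table together with the ground truth on
# the fitted (2 SD standardized) scale.

#' Prepare a reusable parameter-recovery simulation setup
#'
#' Simulates one track per animal, estimates a-LoCoH home ranges, draws the
#' systematic availability sample, and precomputes covariates for both the
#' availability rows and the candidate kill pixels (all landscape pixels
#' inside each track's convex hull).
#'
#' @param ls a \code{"landscape"}.
#' @param n_animals number of animals.
#' @param days monitoring days per animal.
#' @param frac_male fraction of males.
#' @param covariates covariate columns to carry.
#' @param spacing_m availability lattice spacing (m).
#' @param seed integer seed.
#' @param dstack optional precomputed \code{\link{distance_stack}}.
#' @return A list of class \code{"rsf_sim_setup"}.
#' @export
rsf_sim_setup <- function(ls, n_animals = 20, days = 40, frac_male = 0.5,
                          covariates = c("d_developed", "d_riparian",
                                         "d_water", "elevation", "slope"),
                          spacing_m = 150, seed = 1L, dstack = NULL) {
  dn <- intersect(covariates, names(.covariate_names()))
  if (is.null(dstack)) dstack <- distance_stack(ls, dn)
  # landscape-wide scaling shared by all animals (the generative scale)
  X <- vapply(covariates, function(nm) {
    lay <- if (nm == "elevation") ls$elevation
           else if (nm == "slope") ls$slope else dstack[[nm]]
    as.vector(lay)
  }, numeric(ls$n_rows * ls$n_cols))
  scaling <- data.frame(covariate = covariates, mean = colMeans(X),
                        sd = apply(X, 2, stats::sd), row.names = NULL)
  n_male <- round(frac_male * n_animals)
  sex <- rep(c(1L, 0L), c(n_male, n_animals - n_male))
  cent <- pixel_centroids(ls)
  pix <- cbind(as.vector(cent$x), as.vector(cent$y))
  animals <- list()
  for (i in seq_len(n_animals)) {
    aid <- sprintf("S%02d", i)
    trk <- generate_track(ls, animal_config(animal_id = aid), days = days,
                          seed = seed * 1000L + i)
    hr <- alocoh(cbind(trk$x, trk$y), animal_id = aid, year = 2013L)
    # candidate kill pixels share the availability domain (the home range),
    # so the planted density ratio is exactly the fitted one
    cand <- which(hr_contains(hr, pix))
    av_xy <- systematic_sample(hr, spacing_m, ls = ls)
    avail <- extract_covariates(av_xy, ls, dstack)
    avail <- cbind(response = 0L, animal_id = aid, year = 2013L,
                   sex_male = sex[i], avail)
    Xc <- X[cand, , drop = FALSE]
    Xs <- sweep(sweep(Xc, 2, scaling$mean), 2, 2 * scaling$sd, "/")
    animals[[aid]] <- list(animal_id = aid, sex_male = sex[i], hr = hr,
                           cand = cand, cand_xy = pix[cand, , drop = FALSE],
                           cand_std = Xs, avail = avail)
  }
  structure(list(ls = ls, dstack = dstack, scaling = scaling,
                 covariates = covariates, animals = animals,
                 metadata = data.frame(
                   animal_id = names(animals),
                   sex_male = vapply(animals, function(a) a$sex_male,
                                     integer(1)), row.names = NULL)),
            class = "rsf_sim_setup")
}

#' Simulate a use-availability table at known coefficients
#'
#' For each animal, \code{n_kills} pixels are drawn (without replacement)
#' from the candidate pixels with probability proportional to
#' \code{exp(beta . x)} on the setup's shared standardized scale (plus sex
#' interaction effects for males), and combined with the precomputed
#' availability rows.  The returned truth maps the generative coefficients
#' onto the scale of a table standardized by \code{\link{standardize_gelman}}
#' (coefficients scale by the ratio of the pooled-table SD to the
#' generative SD).
#'
#' @param setup an \code{\link{rsf_sim_setup}}.
#' @param beta_true named generative coefficients (female / both sexes).
#' @param sex_effects named coefficients added for males.
#' @param n_kills feeding sites per animal (recycled over animals).  Under
#'   a no-selection null the homogeneous-intensity convention is
#'   \code{n_kills = "area"}: kills proportional to each range's pixel
#'   count (mean 30), so the pooled used distribution matches pooled
#'   availability exactly.
#' @param seed integer seed.
#' @return List: \code{table} (an \code{"rsf_data"} data.frame, raw scale)
#'   and \code{truth} with \code{beta_true}, \code{sex_effects} and
#'   \code{beta_fit} / \code{sex_fit} (the same coefficients on the
#'   pooled-table standardized scale).
#' @export
rsf_sim_table <- function(setup, beta_true, sex_effects = NULL, n_kills = 30,
                          seed = 1L) {
  stopifnot(inherits(setup, "rsf_sim_setup"))
  covs <- setup$covariates
  b_f <- stats::setNames(rep(0, length(covs)), covs)
  b_f[names(beta_true)] <- beta_true
  b_m <- b_f
  if (length(sex_effects)) b_m[names(sex_effects)] <-
    b_m[names(sex_effects)] + sex_effects
  sizes <- vapply(setup$animals, function(a) nrow(a$cand_std), numeric(1))
  if (identical(n_kills, "area")) {
    n_kills <- pmax(5L, round(30 * length(sizes) * sizes / sum(sizes)))
  } else n_kills <- rep_len(n_kills, length(sizes))
  rows <- .with_seed(seed, {
    out <- list()
    for (ai in seq_along(setup$animals)) {
      a <- setup$animals[[ai]]
      b <- if (a$sex_male == 1L) b_m else b_f
      lp <- as.vector(a$cand_std %*% b)
      w <- exp(lp - max(lp))
      pick <- sample(nrow(a$cand_std), n_kills[ai], prob = w)
      used <- extract_covariates(a$cand_xy[pick, , drop = FALSE],
                                 setup$ls, setup$dstack)
      out[[a$animal_id]] <- cbind(response = 1L, animal_id = a$animal_id,
                                  year = 2013L, sex_male = a$sex_male, used)
    }
    out
  })
  avail <- lapply(setup$animals, function(a) a$avail)
  tab <- do.call(rbind, c(rows, avail))
  rownames(tab) <- NULL
  class(tab) <- c("rsf_data", "data.frame")
  # map generative coefficients to the pooled-table standardized scale
  sd_fit <- vapply(covs, function(v) stats::sd(tab[[v]]), numeric(1))
  sd_gen <- stats::setNames(setup$scaling$sd, setup$scaling$covariate)[covs]
  ratio <- sd_fit / sd_gen
  list(table = tab,
       truth = list(beta_true = b_f, sex_effects = sex_effects,
                    beta_fit = b_f * ratio,
                    sex_fit = if (length(sex_effects))
                      sex_effects * ratio[names(sex_effects)],
                    sd_ratio = ratio))
}
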