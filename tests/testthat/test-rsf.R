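# RSF fitting machinery: standardization, GLMM against oracles, AIC
# comparison, interaction reduction, selection inference, prediction maps.

test_that("Gelman standardization divides centered values by 2 sd", {
  tab <- data.frame(response = rep(0:1, 50),
                    animal_id = "A", year = 2013, sex_male = rep(0:1, 50),
                    elevation = rnorm(100, 5, 2))
  tab$elevation <- c(9, tab$elevation[-1])
  std <- standardize_gelman(tab, "elevation")
  m <- mean(tab$elevation); s <- sd(tab$elevation)
  expect_equal(std$elevation[1], (9 - m) / (2 * s))
  expect_equal(mean(std$elevation), 0, tolerance = 1e-12)
  expect_equal(sd(std$elevation), 0.5, tolerance = 1e-12)
  expect_equal(std$sex_male, tab$sex_male)   # binary dummy untouched
  sc <- attr(std, "scaling")
  expect_equal(sc$mean, m)
  expect_equal(sc$sd, s)
  tab$flat <- 1
  expect_error(standardize_gelman(tab, "flat"), "zero-variance")
})

# logistic data with no random-effect variance: two grouping levels exist
# but contribute nothing
sim_logit_table <- function(n_per = 200, beta = c(-1, 0.8), seed = 1,
                            n_animals = 4, re_sd = 0) {
  withr::with_seed(seed, {
    n <- n_per * n_animals
    x1 <- rnorm(n); x2 <- rnorm(n)
    aid <- rep(sprintf("A%d", seq_len(n_animals)), each = n_per)
    b0 <- rep(rnorm(n_animals, 0, re_sd), each = n_per)
    eta <- -1 + beta[1] * x1 + beta[2] * x2 + b0
    y <- rbinom(n, 1, plogis(eta))
    tab <- data.frame(response = y, animal_id = aid, year = 2013L,
                      sex_male = 0L, d_developed = x1, elevation = x2)
    attr(tab, "scaling") <- data.frame(covariate = c("d_developed", "elevation"),
                                       mean = c(0, 0), sd = c(0.5, 0.5))
    tab
  })
}

test_that("with zero random-effect variance the GLMM matches plain logistic regression", {
  tab <- sim_logit_table()
  fit <- rsf_fit(tab, c("d_developed", "elevation"))
  oracle <- glm(response ~ d_developed + elevation, binomial(), tab)
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-2)
  expect_gte(fit$var_individual, 0)
  expect_lt(fit$var_individual, 0.05)
})

test_that("marginal likelihood matches 101-node Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  tab <- sim_logit_table(n_per = 10, seed = 3, n_animals = 3, re_sd = 0.8)
  fit <- rsf_fit(tab, c("d_developed", "elevation"), random = "individual",
                 nAGQ = 25L)
  # independent oracle: non-adaptive quadrature of the same likelihood at
  # the fitted parameters
  gh <- pracma::gaussHermite(101)
  beta <- fit$beta
  sig <- sqrt(fit$var_individual)
  ll <- 0
  for (aid in unique(tab$animal_id)) {
    sub <- tab[tab$animal_id == aid, ]
    eta0 <- beta[1] + beta[2] * sub$d_developed + beta[3] * sub$elevation
    contrib <- vapply(seq_along(gh$x), function(i) {
      u <- sqrt(2) * sig * gh$x[i]
      p <- plogis(eta0 + u)
      gh$w[i] / sqrt(pi) * prod(ifelse(sub$response == 1, p, 1 - p))
    }, numeric(1))
    ll <- ll + log(sum(contrib))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-4)
})

test_that("AIC accounting and confidence-interval nesting hold", {
  tab <- sim_logit_table(n_per = 60, seed = 5)
  fit <- rsf_fit(tab, c("d_developed", "elevation"))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  # npar = fixed effects + 2 variance parameters
  expect_equal(fit$npar, length(fit$beta) + 2)
  w95 <- fit$ci[["95"]][, 2] - fit$ci[["95"]][, 1]
  w90 <- fit$ci[["90"]][, 2] - fit$ci[["90"]][, 1]
  w85 <- fit$ci[["85"]][, 2] - fit$ci[["85"]][, 1]
  expect_true(all(w95 > w90 & w90 > w85))
  expect_true(all(fit$ci[["85"]][, 1] >= fit$ci[["90"]][, 1]))
  expect_true(all(fit$ci[["90"]][, 1] >= fit$ci[["95"]][, 1]))
  expect_equal(AIC(fit), fit$aic)
})

test_that("AIC comparison ranks, differences and flags support", {
  f1 <- structure(list(aic = 100, npar = 3, nobs = 500), class = "rsf_fit")
  f2 <- structure(list(aic = 94, npar = 5, nobs = 500), class = "rsf_fit")
  cmp <- compare_aic(list(simple = f1, complex = f2))
  expect_equal(cmp$model, c("complex", "simple"))
  expect_equal(cmp$delta_aic, c(0, 6))
  expect_true(attr(cmp, "strong_support"))

  cmp2 <- compare_aic(list(a = f1, b = structure(list(aic = 100, npar = 3,
                                                      nobs = 500),
                                                 class = "rsf_fit")))
  expect_equal(cmp2$delta_aic, c(0, 0))
  expect_false(attr(cmp2, "strong_support"))
  f3 <- structure(list(aic = 90, npar = 3, nobs = 400), class = "rsf_fit")
  expect_error(compare_aic(list(f1, f3)), "differing row counts")
})

test_that("interactions are retained exactly when the 85% CI excludes zero", {
  beta <- c("(Intercept)" = -3, d_developed = -1, d_riparian = 0.5,
            "d_developed:sex_male" = 0.66, "d_riparian:sex_male" = 0.1)
  se <- c(0.2, 0.2, 0.2, 0.36, 0.35)   # 0.66 +/- 1.44*0.36 excludes 0
  names(se) <- names(beta)
  fit <- fake_rsf_fit(beta, se, c("d_developed", "d_riparian"),
                      interactions = c("d_developed", "d_riparian"))
  red <- reduce_interactions(fit)
  expect_equal(red$interactions, "d_developed")
  expect_equal(red$covariates, c("d_developed", "d_riparian"))
  # pushing the tight interaction wider drops everything
  se2 <- se; se2["d_developed:sex_male"] <- 1.0
  fit2 <- fake_rsf_fit(beta, se2, c("d_developed", "d_riparian"),
                       interactions = c("d_developed", "d_riparian"))
  expect_length(reduce_interactions(fit2)$interactions, 0)
})

test_that("null-simulated interactions are retained at roughly the 15% type-I rate", {
  withr::with_seed(99, {
    R <- 2000
    z <- rnorm(R)   # Wald z of a null interaction
    retained <- abs(z) > qnorm(1 - 0.15 / 2)
    expect_equal(mean(retained), 0.15, tolerance = 0.025)
  })
})

test_that("selection labels follow the sign conventions of each covariate kind", {
  # mirrors the shape of the published population-level coefficient table
  beta <- c(d_developed = -1.05, slope = 0.23, d_water = -0.04,
            d_riparian = 0.74, elevation = -0.93, d_trail = -0.43)
  se <- c(0.29, 0.105, 0.21, 0.33, 0.18, 0.24)
  names(se) <- names(beta)
  fit <- fake_rsf_fit(beta, se, names(beta))
  lab <- infer_selection(fit)
  get <- function(term) lab$label[lab$term == term]
  expect_equal(get("d_developed"), "selected")   # closer than available
  expect_equal(get("slope"), "selected")         # classification convention
  expect_equal(get("d_water"), "none")
  expect_equal(get("d_riparian"), "avoided")
  expect_equal(get("elevation"), "avoided")
  expect_equal(get("d_trail"), "marginal")       # 90% CI only
  bad <- fake_rsf_fit(c(foo = 1), c(foo = 1), "foo")
  expect_error(infer_selection(bad), "unknown covariate kind")
})

test_that("prediction maps are monotone transforms of the linear predictor", {
  ls <- fix_landscape()
  ds <- fix_dstack()
  scaling <- data.frame(covariate = "d_developed",
                        mean = mean(ds$d_developed),
                        sd = sd(ds$d_developed))
  flat <- fake_rsf_fit(c(d_developed = 0), c(d_developed = 1), "d_developed",
                       scaling = scaling)
  m0 <- predict_map(flat, ls, ds)
  expect_true(all(m0 == 0))

  neg <- fake_rsf_fit(c(d_developed = -1), c(d_developed = 1), "d_developed",
                      scaling = scaling)
  m1 <- predict_map(neg, ls, ds)
  expect_equal(dim(m1), c(ls$n_rows, ls$n_cols))
  expect_equal(range(m1), c(0, 1))
  # strictly decreasing in the distance raster
  ord <- order(ds$d_developed)
  expect_true(all(diff(m1[ord]) <= 1e-12))
  # pixel-level ratio equals exp(beta * delta-x) on the standardized scale
  i <- ord[1]; j <- ord[1000]
  dx <- (ds$d_developed[j] - ds$d_developed[i]) / (2 * scaling$sd)
  w <- exp(predict(neg, data.frame(d_developed = ds$d_developed[c(i, j)]),
                   type = "link"))
  expect_equal(w[2] / w[1], exp(-1 * dx), tolerance = 1e-9)
})

test_that("standardized and raw-scale predictions agree to machine precision", {
  tab <- sim_logit_table(n_per = 50, seed = 8)
  # give the raw table a nontrivial scale
  raw <- tab
  raw$d_developed <- raw$d_developed * 400 + 900
  raw$elevation <- raw$elevation * 150 + 700
  attr(raw, "scaling") <- NULL
  fit <- rsf_fit(raw, c("d_developed", "elevation"))
  sc <- fit$scaling
  std_rows <- raw[1:20, ]
  for (i in seq_len(nrow(sc))) {
    v <- sc$covariate[i]
    std_rows[[v]] <- (std_rows[[v]] - sc$mean[i]) / (2 * sc$sd[i])
  }
  expect_equal(predict(fit, raw[1:20, ], type = "relative"),
               predict(fit, std_rows, type = "relative",
                       standardize = FALSE),
               tolerance = 1e-10)
})

test_that("cross-validation separates a perfectly informative score", {
  # construct a table where one covariate separates used from available
  withr::with_seed(12, {
    n <- 400
    tab <- data.frame(response = rep(c(1L, 0L), c(80, 320)),
                      animal_id = rep(sprintf("A%d", 1:4), 100),
                      year = 2013L, sex_male = 0L)
    tab$d_developed <- ifelse(tab$response == 1, runif(n, 0, 120),
                              runif(n, 1500, 4000))
    tab$elevation <- rnorm(n, 800, 150)
  })
  cv <- kfold_cv(tab, c("d_developed", "elevation"), k = 4, seed = 2)
  expect_equal(sum(cv$bin_frequencies), 80)
  expect_equal(cv$bin_frequencies[10], 80)   # all in the top bin
  expect_error(kfold_cv(tab, "d_developed", k = 1), "at least 2")
})
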