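# Selection proportions and the beta-regression functional response.

test_that("selection proportion arithmetic, symmetry and scale invariance", {
  expect_equal(selection_proportion(1000, 1000)$proportion, 0.5)
  expect_equal(selection_proportion(500, 1500)$proportion, 0.25)
  withr::with_seed(3, {
    u <- rexp(40, 1 / 800); a <- rexp(60, 1 / 1200)
  })
  p <- selection_proportion(u, a)$proportion
  expect_equal(selection_proportion(a, u)$proportion, 1 - p)
  expect_equal(selection_proportion(3.7 * u, 3.7 * a)$proportion, p)
  expect_error(selection_proportion(numeric(0), a), "nonempty")
  expect_error(selection_proportion(-1, a), "non-negative")
  expect_error(selection_proportion(0, 0), "undefined")
})

test_that("animals are aggregated across years and filtered by site count", {
  mkrows <- function(aid, yr, used_d, avail_d) {
    rbind(data.frame(response = 1L, animal_id = aid, year = yr,
                     d_developed = used_d),
          data.frame(response = 0L, animal_id = aid, year = yr,
                     d_developed = avail_d))
  }
  tab <- rbind(
    mkrows("A1", 2013, rep(400, 3), rep(600, 10)),   # P = 0.4
    mkrows("A1", 2014, rep(200, 3), rep(300, 10)),   # P = 0.4 again
    mkrows("A2", 2013, rep(100, 4), rep(900, 10)))   # only 4 sites
  res <- aggregate_animals(tab, "d_developed", min_sites = 5)
  expect_equal(res$animal_id, "A1")
  expect_equal(res$proportion, 0.4)
  expect_equal(res$n_sites, 6)
  expect_equal(res$n_years, 2)
  expect_equal(res$mean_avail_m, mean(c(600, 300)))
  excl <- attr(res, "excluded")
  expect_equal(excl$animal_id, "A2")

  # a cohort sized to leave 19 animals above the threshold
  withr::with_seed(11, {
    counts <- c(rep(4, 7), sample(5:40, 19, replace = TRUE))
    cohort <- do.call(rbind, lapply(seq_along(counts), function(i)
      mkrows(sprintf("C%02d", i), 2013,
             rexp(counts[i], 1 / 800), rexp(25, 1 / 1000))))
  })
  res19 <- aggregate_animals(cohort, "d_developed")
  expect_equal(nrow(res19), 19)
})

test_that("planted attraction produces proportions below one half", {
  setup <- fix_recovery_setup()
  st <- rsf_sim_table(setup, c(d_developed = -2), n_kills = 30, seed = 77)
  props <- aggregate_animals(st$table, "d_developed")
  expect_equal(nrow(props), 20)
  expect_gt(mean(props$proportion < 0.5), 0.9)
})

test_that("the fixed-phi profile likelihood of the linear fit matches a direct optimizer", {
  withr::with_seed(21, {
    x <- runif(19, 500, 4000)
    mu <- pnorm(0.2 - 0.3 * (x - 2250) / 1750)
    y <- rbeta(19, mu * 40, (1 - mu) * 40)
  })
  f <- fit_beta_fr(data.frame(proportion = y, mean_avail_m = x),
                   smooth = FALSE)
  phi <- f$precision_phi
  z <- (x - mean(x)) / sd(x)   # reparametrization leaves the maximum unchanged
  nll <- function(par) {
    m <- pnorm(par[1] + par[2] * z)
    -sum(dbeta(y, m * phi, (1 - m) * phi, log = TRUE))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(-opt$value, as.numeric(logLik(f$gam)), tolerance = 1e-3)
  expect_equal(f$edf, 1)
  expect_lt(f$slope, 0)
  expect_true(f$p_value >= 0 && f$p_value <= 1)
  expect_true(f$deviance_explained >= 0 && f$deviance_explained <= 100)
})

test_that("a clear linear trend collapses the smooth and recovers the sign", {
  withr::with_seed(31, {
    lin <- 0; neg <- 0; R <- 40
    for (r in seq_len(R)) {
      x <- runif(19, 500, 4000)
      mu <- pnorm(0.3 - 0.45 * (x - 2250) / 1750)
      y <- rbeta(19, mu * 120, (1 - mu) * 120)
      f <- fit_beta_fr(data.frame(proportion = y, mean_avail_m = x))
      if (f$linear) lin <- lin + 1
      fl <- fit_beta_fr(data.frame(proportion = y, mean_avail_m = x),
                        smooth = FALSE)
      if (fl$slope < 0) neg <- neg + 1
    }
    expect_gte(lin / R, 0.8)
    expect_gte(neg / R, 0.95)
  })
})

test_that("a sine-shaped trend is recognized as nonlinear", {
  withr::with_seed(32, {
    det <- 0; R <- 30
    for (r in seq_len(R)) {
      x <- runif(19, 500, 4000)
      mu <- 0.2 + 0.5 * (sin((x - 500) / 3500 * 2 * pi) + 1) / 2
      y <- rbeta(19, mu * 150, (1 - mu) * 150)
      f <- fit_beta_fr(data.frame(proportion = y, mean_avail_m = x))
      if (f$edf > 1.5) det <- det + 1
    }
    expect_gte(det / R, 0.9)
  })
})

test_that("boundary proportions are compressed, interior left alone", {
  p <- c(0, 0.5, 1)
  cp <- feedrsf:::.compress_proportions(p, 19)
  expect_true(all(cp > 0 & cp < 1))
  expect_equal(cp[2], 0.5)
  expect_equal(feedrsf:::.compress_proportions(c(0.3, 0.7), 19), c(0.3, 0.7))
  expect_error(fit_beta_fr(data.frame(proportion = rep(0.5, 3),
                                      mean_avail_m = 1:3)), "at least 6")
})

test_that("the functional-response plot draws the fitted curve", {
  withr::with_seed(41, {
    x <- runif(19, 500, 4000)
    mu <- pnorm(0.4 - 0.5 * (x - 2250) / 1750)
    y <- rbeta(19, mu * 120, (1 - mu) * 120)
  })
  f <- fit_beta_fr(data.frame(proportion = y, mean_avail_m = x))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, width = 500, height = 400)
  curve <- plot(f)
  grDevices::dev.off()
  expect_true(file.exists(path) && file.size(path) > 0)
  # negative-trend fixture: fitted curve decreases monotonically
  expect_true(all(diff(curve$fitted) < 1e-9))
})
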