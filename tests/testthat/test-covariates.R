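# Covariate engine: distance transforms, slope, systematic sampling, table
# assembly, correlation screening.

test_that("distance transform honors centroid geometry", {
  ls <- generate_landscape(landscape_config(
    n_rows = 9, n_cols = 9, class_weights = c(chaparral = 1), n_trails = 0), 1)
  ls$class_grid[5, 5] <- match("water", ls$classes)
  d <- distance_transform(ls, "water")
  expect_equal(d[5, 5], 0)
  expect_equal(d[5, 6], 30)
  expect_equal(d[4, 5], 30)
  expect_equal(d[4, 4], 30 * sqrt(2))
  expect_equal(d[5, 9], 120)
  expect_error(distance_transform(ls, "developed"), "absent")
  expect_error(distance_transform(ls, "lava"), "unknown")
})

test_that("distance transform equals brute-force nearest-centroid search", {
  for (seed in 1:3) {
    mask <- withr::with_seed(seed, matrix(runif(50 * 50) < 0.04, 50, 50))
    if (!any(mask)) next
    d <- feedrsf:::.edt(mask)
    tg <- which(mask, arr.ind = TRUE)
    bf <- matrix(Inf, 50, 50)
    for (k in seq_len(nrow(tg)))
      bf <- pmin(bf, sqrt(outer((seq_len(50) - tg[k, 1])^2,
                                (seq_len(50) - tg[k, 2])^2, "+")))
    expect_equal(d, bf, tolerance = 1e-12)
  }
})

test_that("neighboring pixels never differ by more than a diagonal step", {
  d <- distance_transform(fix_landscape(), "water")
  res <- fix_landscape()$resolution
  expect_lte(max(abs(diff(d))), res * sqrt(2) + 1e-9)          # row direction
  expect_lte(max(abs(diff(t(d)))), res * sqrt(2) + 1e-9)       # col direction
})

test_that("Horn slope matches closed forms and the analytic gradient", {
  flat <- matrix(500, 10, 10)
  expect_equal(slope_from_dem(flat, 30), matrix(0, 10, 10))

  ramp <- outer(rep(1, 10), 1:10) * 30   # rises 30 m per 30 m eastward
  expect_equal(slope_from_dem(ramp, 30)[3:8, 3:8], matrix(100, 6, 6))

  res <- 30
  quad <- outer(1:30, 1:30, function(r, c) 0.01 * (c * res)^2 +
                                           0.005 * (r * res)^2)
  sl <- slope_from_dem(quad, res)
  an <- outer(1:30, 1:30, function(r, c)
    100 * sqrt((0.02 * c * res)^2 + (0.01 * r * res)^2))
  expect_lt(max(abs(sl - an)[3:28, 3:28] / an[3:28, 3:28]), 0.01)
  expect_error(slope_from_dem(matrix(1, 2, 2), 30), "3 x 3")
})

test_that("systematic sampling is origin-anchored with the documented density", {
  km <- 1000
  sq <- rbind(c(0, 0), c(km, 0), c(km, km), c(0, km))
  pts <- systematic_sample(sq, 150)
  expect_equal(nrow(pts), 49)          # 7 x 7 inclusive lattice
  expect_true(all(pts %% 150 == 0))

  big <- rbind(c(0, 0), c(90e3, 0), c(90e3, 90e3), c(0, 90e3))
  dens <- nrow(systematic_sample(big, 150)) / (90^2)
  expect_lt(abs(dens - 1e6 / 150^2) / (1e6 / 150^2), 0.005)

  expect_equal(nrow(systematic_sample(sq, 1000)), 4)
  expect_error(systematic_sample(sq, -5), "positive")
  expect_warning(
    out <- systematic_sample(rbind(c(10, 10), c(40, 10), c(25, 40)), 150),
    "lattice")
  expect_equal(nrow(out), 0)
})

test_that("lattice-in-polygon agrees with barycentric enumeration on triangles", {
  withr::with_seed(4, {
    for (rep in 1:4) {
      v <- matrix(runif(6, 0, 2000), 3, 2)
      pts <- systematic_sample(v, 150)
      # independent oracle: barycentric point-in-triangle over the lattice
      gx <- seq(0, 2100, by = 150)
      grid <- as.matrix(expand.grid(gx, gx))
      d <- (v[2, 2] - v[3, 2]) * (v[1, 1] - v[3, 1]) +
           (v[3, 1] - v[2, 1]) * (v[1, 2] - v[3, 2])
      l1 <- ((v[2, 2] - v[3, 2]) * (grid[, 1] - v[3, 1]) +
             (v[3, 1] - v[2, 1]) * (grid[, 2] - v[3, 2])) / d
      l2 <- ((v[3, 2] - v[1, 2]) * (grid[, 1] - v[3, 1]) +
             (v[1, 1] - v[3, 1]) * (grid[, 2] - v[3, 2])) / d
      l3 <- 1 - l1 - l2
      eps <- 1e-9
      inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
      expect_equal(nrow(pts), sum(inside), info = paste("rep", rep))
    }
  })
})

test_that("covariates are read from the containing pixel", {
  ls <- fix_landscape()
  ds <- fix_dstack()
  wpix <- which(ls$class_grid == match("water", ls$classes), arr.ind = TRUE)[1, ]
  cx <- ls$origin_x + (wpix["col"] - 0.5) * ls$resolution
  cy <- ls$origin_y - (wpix["row"] - 0.5) * ls$resolution
  row <- extract_covariates(cbind(cx, cy), ls, ds)
  expect_equal(row$d_water, 0)
  # two points in one pixel share covariates
  two <- extract_covariates(rbind(c(cx - 10, cy + 10), c(cx + 10, cy - 10)),
                            ls, ds)
  expect_equal(two[1, ], two[2, ], ignore_attr = TRUE)
  # brute-force lookup oracle for random points
  withr::with_seed(5, {
    n <- 100
    px <- runif(n, ls$origin_x, ls$origin_x + ls$n_cols * ls$resolution - 1)
    py <- runif(n, ls$origin_y - ls$n_rows * ls$resolution + 1, ls$origin_y)
  })
  got <- extract_covariates(cbind(px, py), ls, ds)
  r <- floor((ls$origin_y - py) / ls$resolution) + 1
  c2 <- floor((px - ls$origin_x) / ls$resolution) + 1
  expect_equal(got$elevation, ls$elevation[cbind(r, c2)])
  expect_equal(got$d_developed, ds$d_developed[cbind(r, c2)])
  expect_error(extract_covariates(cbind(-1e6, 0), ls, ds), "extent")
})

test_that("build_table assembles used and available rows per animal-year", {
  ls <- fix_landscape()
  ds <- fix_dstack()
  withr::with_seed(6, {
    mk_range <- function(aid) {
      ctr <- runif(2, 500, 1200)
      alocoh(cbind(runif(40, ctr[1] - 400, ctr[1] + 400),
                   runif(40, ctr[2] - 400, ctr[2] + 400)),
             animal_id = aid, year = 2013L)
    }
    ranges <- list(mk_range("A1"), mk_range("A2"), mk_range("A3"))
    sites <- do.call(rbind, lapply(1:3, function(i) {
      hr <- ranges[[i]]
      pts <- hr$points[sample(nrow(hr$points), 4), ]
      data.frame(site_id = paste0("s", i, 1:4),
                 animal_id = paste0("A", i), year = 2013L,
                 x = pts[, 1], y = pts[, 2])
    }))
  })
  meta <- data.frame(animal_id = c("A1", "A2", "A3"), sex_male = c(1, 0, 1))
  tab <- build_table(sites, ranges, ls, meta, spacing_m = 150, dstack = ds)
  expect_equal(sum(tab$response == 1), nrow(sites))
  n_lattice <- sum(vapply(ranges, function(r)
    nrow(systematic_sample(r, 150, ls = ls)), numeric(1)))
  expect_equal(nrow(tab), nrow(sites) + n_lattice)
  expect_false(anyNA(tab))
  # every animal-year with used rows has available rows
  for (aid in unique(tab$animal_id))
    expect_gt(sum(tab$response == 0 & tab$animal_id == aid), 0)
  # sex joined from metadata, constant within animal
  expect_equal(unique(tab$sex_male[tab$animal_id == "A2"]), 0)
  # distance zero iff on the class pixel
  onch <- tab$d_chaparral == 0
  rc <- feedrsf:::xy_to_rc(ls, tab$x, tab$y)
  expect_equal(onch,
               ls$class_grid[cbind(rc[, 1], rc[, 2])] ==
                 match("chaparral", ls$classes))
  expect_error(build_table(sites, ranges[1:2], ls, meta, dstack = ds),
               "no home range")
  expect_error(build_table(sites, ranges, ls, meta[1:2, ], dstack = ds),
               "no sex")
})

test_that("correlation screening drops the lower-priority member of a pair", {
  withr::with_seed(8, {
    n <- 10000
    elev <- rnorm(n)
    css <- 0.63 * elev + sqrt(1 - 0.63^2) * rnorm(n)
    tab <- data.frame(elevation = elev, d_coastal_sage = css,
                      d_water = rnorm(n), d_trail = rnorm(n))
  })
  scr <- correlation_screen(tab, names(tab), threshold = 0.5,
                            priority = c("elevation", "d_water", "d_trail",
                                         "d_coastal_sage"))
  expect_false("d_coastal_sage" %in% scr$retained)
  expect_true(all(c("elevation", "d_water", "d_trail") %in% scr$retained))
  expect_equal(scr$excluded$dropped, "d_coastal_sage")
  expect_equal(scr$excluded$kept, "elevation")
  expect_equal(scr$excluded$r, 0.63, tolerance = 0.05)

  # duplicated covariate: r = 1, one of the pair dropped
  tab$dup <- tab$d_water
  scr2 <- correlation_screen(tab, c("d_water", "dup"),
                             priority = c("d_water", "dup"))
  expect_equal(scr2$retained, "d_water")
  expect_equal(scr2$excluded$r, 1)

  # independent covariates: nothing dropped at 0.5
  scr3 <- correlation_screen(tab, c("elevation", "d_water", "d_trail"))
  expect_equal(nrow(scr3$excluded), 0)

  tab$flat <- 1
  expect_error(correlation_screen(tab, c("d_water", "flat")), "zero-variance")
})
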