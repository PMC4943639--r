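# Cluster detection: the spatio-temporal rule, oracle equivalence,
# monotonicity and permutation invariance.

mkfix <- function(hours, x, y, night = TRUE, id = "A") {
  data.frame(animal_id = id,
             timestamp = as.POSIXct("2013-06-01", tz = "UTC") + hours * 3600,
             x = x, y = y, is_night = rep_len(night, length(hours)))
}

test_that("the distance, night and span rules gate cluster formation", {
  # 3 night fixes at one spot spanning 30 h -> one cluster
  f <- mkfix(c(0, 10, 30), 100, 100)
  cl <- detect_clusters(f)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_night, 3)
  expect_equal(cl$span_hours, 30)
  expect_equal(cl$centroid_x, 100)

  # 2 night fixes 60 m apart -> no cluster
  expect_equal(nrow(detect_clusters(mkfix(c(0, 30), c(0, 60), 0))), 0)
  # fixes within 10 m but spanning only 12 h -> no cluster
  expect_equal(nrow(detect_clusters(
    mkfix(seq(0, 12, length.out = 5), seq(0, 10, length.out = 5), 0))), 0)
  # at exactly 50 m the fixes chain
  expect_equal(nrow(detect_clusters(mkfix(c(0, 26), c(0, 50), 0))), 1)
})

test_that("empty input gives an empty result, bad radius errors", {
  empty <- detect_clusters(data.frame(
    animal_id = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    x = numeric(0), y = numeric(0), is_night = logical(0)))
  expect_equal(nrow(empty), 0)
  expect_error(detect_clusters(mkfix(0, 0, 0), radius_m = -1), "radius")
})

test_that("detector matches the brute-force connected-components oracle", {
  for (seed in 1:6) {
    n <- sample(c(50, 120, 200), 1)
    f <- random_fixes(n, seed, extent = if (seed %% 2) 400 else 1500)
    got <- detect_clusters(f)
    want <- brute_clusters(f)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got)) {
      ord <- order(got$centroid_x, got$centroid_y)
      expect_equal(got$centroid_x[ord], want[, 1], tolerance = 1e-9)
      expect_equal(got$centroid_y[ord], want[, 2], tolerance = 1e-9)
      expect_equal(got$n_fixes[ord], as.integer(want[, 3]))
    }
  }
})

test_that("radius and threshold monotonicity", {
  f <- random_fixes(150, 42, extent = 600)
  in_cluster <- function(cl) sum(cl$n_fixes)
  r_small <- detect_clusters(f, radius_m = 30)
  r_big <- detect_clusters(f, radius_m = 80)
  expect_gte(in_cluster(r_big), in_cluster(r_small))
  expect_lte(nrow(detect_clusters(f, min_night = 4)),
             nrow(detect_clusters(f, min_night = 2)))
  expect_lte(nrow(detect_clusters(f, min_span_h = 48)),
             nrow(detect_clusters(f, min_span_h = 24)))
})

test_that("cluster membership is invariant to input order", {
  f <- random_fixes(120, 5, extent = 500)
  base <- detect_clusters(f)
  perm <- withr::with_seed(1, f[sample(nrow(f)), ])
  shuf <- detect_clusters(perm)
  expect_equal(nrow(base), nrow(shuf))
  o1 <- order(base$centroid_x, base$centroid_y)
  o2 <- order(shuf$centroid_x, shuf$centroid_y)
  expect_equal(base$centroid_x[o1], shuf$centroid_x[o2], tolerance = 1e-9)
  expect_equal(base$n_fixes[o1], shuf$n_fixes[o2])
})

test_that("max-gap option splits temporally separated visits", {
  f <- mkfix(c(0, 30, 24 * 20, 24 * 20 + 30), 0, 0)
  expect_equal(nrow(detect_clusters(f)), 1)               # default: no split
  expect_equal(nrow(detect_clusters(f, max_gap_h = 72)), 2)
})

test_that("feeding-site conversion applies the detection probability", {
  f <- mkfix(c(0, 10, 30), 100, 100)
  cl <- detect_clusters(f)
  expect_equal(nrow(clusters_to_feeding_sites(cl, p = 1)), 1)
  expect_equal(nrow(clusters_to_feeding_sites(cl, p = 0)), 0)
  expect_error(clusters_to_feeding_sites(cl, p = 1.2), "probability")
  s <- clusters_to_feeding_sites(cl)
  expect_equal(s$year, 2013L)
  expect_equal(s$x, 100)
})
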