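# Shared fixtures, memoized so each expensive object is built at most once
# per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fix)) assign(key, builder(), envir = .fix)
  get(key, envir = .fix)
}

# a small landscape for unit tests
fix_landscape <- function() memo("ls60", function()
  generate_landscape(landscape_config(n_rows = 60, n_cols = 60), seed = 2))

fix_dstack <- function() memo("ds60", function()
  distance_stack(fix_landscape()))

# the parameter-recovery setup used by the simulation-heavy tests
fix_recovery_setup <- function() memo("setup", function() {
  ls <- generate_landscape(landscape_config(n_rows = 150, n_cols = 150),
                           seed = 11)
  rsf_sim_setup(ls, n_animals = 20, days = 40, seed = 11)
})

# brute-force single-linkage connected components from the full pairwise
# distance matrix (the O(n^2) oracle for the cluster detector)
brute_components <- function(x, y, radius) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  adj <- D <= radius + 1e-9
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & comp == 0L)
      comp[nb] <- cur
      frontier <- c(frontier[-1], nb)
    }
  }
  comp
}

# oracle cluster table: apply the filtering rule to brute-force components
brute_clusters <- function(fixes, radius = 50, min_night = 2, min_span_h = 24) {
  out <- list()
  for (aid in unique(fixes$animal_id)) {
    sub <- fixes[fixes$animal_id == aid, , drop = FALSE]
    comp <- brute_components(sub$x, sub$y, radius)
    for (g in split(seq_len(nrow(sub)), comp)) {
      nn <- sum(sub$is_night[g])
      span <- diff(range(as.numeric(sub$timestamp[g]))) / 3600
      if (nn >= min_night && span >= min_span_h)
        out[[length(out) + 1L]] <- c(mean(sub$x[g]), mean(sub$y[g]),
                                     length(g))
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# random telemetry with is_night flags, for property tests
random_fixes <- function(n, seed, extent = 2000, animal_id = "T1") {
  withr::with_seed(seed, {
    ts <- as.POSIXct("2013-04-01", tz = "UTC") +
      sort(sample(0:(n * 7200), n))
    data.frame(animal_id = animal_id, timestamp = ts,
               x = runif(n, 0, extent), y = runif(n, 0, extent),
               is_night = runif(n) < 0.6)
  })
}

# minimal rsf_fit-shaped object for methods that only need coefficients
# and confidence intervals
fake_rsf_fit <- function(beta, se, covariates, interactions = character(0),
                         scaling = NULL) {
  ci <- lapply(c(0.95, 0.90, 0.85), function(lv) {
    z <- stats::qnorm(1 - (1 - lv) / 2)
    cbind(lower = beta - z * se, upper = beta + z * se)
  })
  names(ci) <- c("95", "90", "85")
  structure(list(beta = beta, se = se, ci = ci, covariates = covariates,
                 interactions = interactions, scaling = scaling),
            class = "rsf_fit")
}
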