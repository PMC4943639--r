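# GPS telemetry: simulation of collared-animal tracks with day/night fix
# schedules, night classification, and CSV I/O.  A fix record is a row of
# animal_id, timestamp (POSIXct, treated as local clock time), x, y and the
# assigned is_night flag.

#' Track simulation configuration
#'
#' @param animal_id identifier for the simulated animal.
#' @param n_day,n_night fixes emitted per 24 h in the day and night windows
#'   (GPS collars in the motivating study took 1-2 day and 5-7 night fixes).
#' @param step_mean mean step length in meters of the correlated random
#'   walk (per fix interval).
#' @param turn_sd standard deviation (radians) of the heading increment.
#' @param start_xy optional length-2 start coordinate; random within the
#'   landscape when \code{NULL}.
#' @param start_date first day of monitoring (anything
#'   \code{\link[base]{as.POSIXct}} accepts; clock times are local).
#' @param night_window length-2 clock hours (start, end) of the night
#'   window; the default 18-6 wraps midnight.
#' @return A list of class \code{"animal_config"}.
#' @export
animal_config <- function(animal_id = "A1", n_day = 2, n_night = 5,
                          step_mean = 400, turn_sd = 0.8, start_xy = NULL,
                          start_date = "2013-06-01",
                          night_window = c(18, 6)) {
  if (step_mean <= 0) stop("step-length parameter must be positive")
  structure(list(animal_id = animal_id, n_day = n_day, n_night = n_night,
                 step_mean = step_mean, turn_sd = turn_sd,
                 start_xy = start_xy, start_date = start_date,
                 night_window = night_window),
            class = "animal_config")
}

#' Simulate a GPS track over a landscape
#'
#' A correlated random walk reflected at the landscape boundary, sampled on
#' a day/night fix schedule: each 24 h period emits \code{n_day} fixes at
#' random clock times inside the day window and \code{n_night} fixes inside
#' the night window.
#'
#' @param ls a \code{"landscape"}.
#' @param animal an \code{\link{animal_config}}.
#' @param days number of 24 h periods (>= 1).
#' @param seed integer seed; the track is a pure function of
#'   (landscape, animal, days, seed).
#' @return \code{data.frame} with columns \code{animal_id},
#'   \code{timestamp} (POSIXct, UTC-encoded local clock), \code{x},
#'   \code{y}, \code{is_night}; rows strictly time-ordered.
#' @export
generate_track <- function(ls, animal = animal_config(), days = 30, seed = 1L) {
  stopifnot(inherits(animal, "animal_config"))
  if (days < 1) stop("days must be >= 1")
  .with_seed(seed, {
    xmin <- ls$origin_x; xmax <- ls$origin_x + ls$n_cols * ls$resolution
    ymin <- ls$origin_y - ls$n_rows * ls$resolution; ymax <- ls$origin_y
    w <- animal$night_window
    t0 <- as.POSIXct(animal$start_date, tz = "UTC")
    times <- c()
    for (d in seq_len(days) - 1L) {
      day_h <- sort(stats::runif(animal$n_day, w[2], w[1]))
      # night window wraps midnight: hours in [w1, 24 + w2)
      night_h <- sort(stats::runif(animal$n_night, w[1], 24 + w[2]))
      times <- c(times, (d * 24 + c(day_h, night_h)) * 3600)
    }
    times <- sort(times)
    n <- length(times)
    start <- animal$start_xy
    if (is.null(start)) {
      start <- c(stats::runif(1, xmin + (xmax - xmin) / 4, xmax - (xmax - xmin) / 4),
                 stats::runif(1, ymin + (ymax - ymin) / 4, ymax - (ymax - ymin) / 4))
    }
    xy <- matrix(NA_real_, n, 2)
    xy[1, ] <- start
    heading <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(n - 1L)) {
      heading <- heading + stats::rnorm(1, 0, animal$turn_sd)
      step <- stats::rexp(1, 1 / animal$step_mean)
      p <- xy[i, ] + step * c(cos(heading), sin(heading))
      # reflect at the landscape boundary
      if (p[1] < xmin) { p[1] <- 2 * xmin - p[1]; heading <- pi - heading }
      if (p[1] > xmax) { p[1] <- 2 * xmax - p[1]; heading <- pi - heading }
      if (p[2] < ymin) { p[2] <- 2 * ymin - p[2]; heading <- -heading }
      if (p[2] > ymax) { p[2] <- 2 * ymax - p[2]; heading <- -heading }
      p[1] <- min(max(p[1], xmin), xmax)
      p[2] <- min(max(p[2], ymin), ymax)
      xy[i + 1L, ] <- p
    }
    fixes <- data.frame(animal_id = animal$animal_id,
                        timestamp = t0 + times,
                        x = xy[, 1], y = xy[, 2])
    classify_night(fixes, night_window = w)
  })
}

#' Assign the night flag from clock time
#'
#' A fix is a night fix when its local clock hour falls inside the night
#' window, closed at the window start and open at the end; the default
#' window 18:00-06:00 wraps midnight.  Idempotent: re-running only
#' recomputes the flag.
#'
#' @param fixes telemetry \code{data.frame} with a POSIXct
#'   \code{timestamp} column.
#' @param night_window length-2 clock hours (start, end).
#' @return The input with \code{is_night} set.
#' @export
classify_night <- function(fixes, night_window = c(18, 6)) {
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("timestamp column must be POSIXct")
  lt <- as.POSIXlt(fixes$timestamp, tz = "UTC")
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  a <- night_window[1]; b <- night_window[2]
  fixes$is_night <- if (a <= b) h >= a & h < b else h >= a | h < b
  fixes
}

#' Read / write telemetry CSV
#'
#' Columns: \code{animal_id}, \code{timestamp} (ISO 8601), \code{x},
#' \code{y}.  Fixes are time-ordered within animal on read, and the night
#' flag is (re)assigned.
#'
#' @param path CSV file path.
#' @param night_window passed to \code{\link{classify_night}}.
#' @return \code{read_telemetry}: a telemetry \code{data.frame}.
#' @export
read_telemetry <- function(path, night_window = c(18, 6)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("telemetry file missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp in row ", bad, ": ", df$timestamp[bad])
  }
  df$timestamp <- ts
  df <- df[order(df$animal_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  classify_night(df, night_window)
}

#' @rdname read_telemetry
#' @param fixes telemetry \code{data.frame} to write.
#' @export
write_telemetry <- function(fixes, path) {
  out <- data.frame(animal_id = fixes$animal_id,
                    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"),
                    x = fixes$x, y = fixes$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
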