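#' Read / write cell-track tables
#'
#' Track tables are CSV files with columns `track_id`, `frame`, `t`
#' (hours), `x`, `y` (micrometers), one row per sample, uniformly sampled
#' in time within each track.
#'
#' @param path CSV file path.
#' @return A data frame of tracks.
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("track_id", "frame", "t", "x", "y")
  if (!all(need %in% names(tr)))
    stop("track table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tr
}

#' @rdname read_tracks
#' @param tracks A track data frame.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

.track_xy <- function(track) {
  ord <- order(track$t)
  t <- track$t[ord]
  if (length(t) < 2) stop("a track needs at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("track times must be strictly increasing",
                              call. = FALSE)
  list(t = t, x = track$x[ord], y = track$y[ord])
}

#' Root-mean-square speed of a track
#'
#' The square root of the mean of squared frame-to-frame speeds, where each
#' frame speed is the displacement between consecutive samples divided by
#' the (uniform) sampling interval.
#'
#' @param track Data frame with columns `t` (h), `x`, `y` (um) for one
#'   track.
#' @return RMS speed in um/h.
#' @export
#' @examples
#' tr <- data.frame(t = 0:2, x = c(0, 30, 70), y = 0)
#' rms_speed(tr)  # sqrt((900 + 1600) / 2)
rms_speed <- function(track) {
  s <- .track_xy(track)
  dt <- diff(s$t)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("track sampling must be uniform", call. = FALSE)
  v2 <- (diff(s$x)^2 + diff(s$y)^2) / dt^2
  sqrt(mean(v2))
}

#' Persistence ratio of a track
#'
#' Net displacement (first to last sample) divided by total path length
#' (sum of segment lengths): 1 for perfectly straight motion, near 0 for
#' frequent direction reversal.
#'
#' @param track Data frame with columns `t`, `x`, `y` for one track.
#' @return Ratio in \[0, 1\].
#' @export
#' @examples
#' tr <- data.frame(t = 0:2, x = c(0, 30, 30), y = c(0, 0, 40))
#' persistence_ratio(tr)  # 50 / 70
persistence_ratio <- function(track) {
  s <- .track_xy(track)
  path <- sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
  if (path <= 0) stop("persistence ratio is undefined for zero path length",
                      call. = FALSE)
  n <- length(s$x)
  net <- sqrt((s$x[n] - s$x[1])^2 + (s$y[n] - s$y[1])^2)
  net / path
}

#' Assign tracks to the four speed-persistence groups
#'
#' Each track's RMS speed and persistence ratio are scaled by the
#' respective population means (so the scaled population means equal 1)
#' and the track is assigned to the quadrant it falls in: group 1 = low
#' speed / low persistence, 2 = low/high, 3 = high/low, 4 = high/high.
#' Values exactly at the mean count as "high" (boundary `>= 1`).
#'
#' @param tracks Track data frame (see [read_tracks()]) with >= 2 tracks.
#' @return List with `tracks` (one row per track: `track_id`, `rms_speed`,
#'   `persistence_ratio`, `scaled_speed`, `scaled_persistence`, `group`)
#'   and `abundances` (4-vector of group frequencies summing to 1).
#' @export
assign_groups <- function(tracks) {
  ids <- unique(tracks$track_id)
  if (length(ids) < 2) stop("need at least 2 tracks", call. = FALSE)
  per <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    data.frame(track_id = id, rms_speed = rms_speed(tr),
               persistence_ratio = persistence_ratio(tr))
  })
  per <- do.call(rbind, per)
  ms <- mean(per$rms_speed)
  mp <- mean(per$persistence_ratio)
  if (ms <= 0 || mp <= 0)
    stop("population mean speed/persistence must be positive", call. = FALSE)
  per$scaled_speed <- per$rms_speed / ms
  per$scaled_persistence <- per$persistence_ratio / mp
  hi_s <- per$scaled_speed >= 1 - 1e-9
  hi_p <- per$scaled_persistence >= 1 - 1e-9
  per$group <- ifelse(hi_s, ifelse(hi_p, 4L, 3L), ifelse(hi_p, 2L, 1L))
  ab <- tabulate(per$group, nbins = 4)
  list(tracks = per, abundances = ab / sum(ab))
}

#' Generate synthetic unobstructed cell tracks
#'
#' Simulates single cells with the motility module's discretized
#' persistent-random-walk rule — 8 headings, forward/backward selection by
#' the persistence ratio — in an empty unbounded field, and emits a track
#' table in the format of [read_tracks()]. Deterministic under `seed`.
#'
#' @param speed Speed profile (um/h): constant or empirical sample.
#' @param persistence Target persistence ratio in \[0, 1\].
#' @param n_tracks,n_steps Number of tracks and steps per track.
#' @param dt Sampling interval, hours.
#' @param seed Integer seed.
#' @return Track data frame (`track_id`, `frame`, `t`, `x`, `y`).
#' @export
#' @examples
#' tr <- generate_tracks(30, 0.8, n_tracks = 2, n_steps = 10, seed = 1)
#' rms_speed(tr[tr$track_id == 1, ])
generate_tracks <- function(speed, persistence, n_tracks = 100, n_steps = 60,
                            dt = 1, seed = 1) {
  if (persistence < 0 || persistence > 1)
    stop("'persistence' must be in [0, 1]", call. = FALSE)
  streams <- rng_streams(seed)
  generate_tracks_cpp(as.numeric(speed), persistence, as.integer(n_tracks),
                      as.integer(n_steps), dt, streams$ptr)
}
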