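#' Initialize the simulation state
#'
#' Places `n_init` cells in a compact cluster at the domain center — one
#' per lattice square, filled ring by ring, skipping lumen squares — and
#' assigns each cell a phenotype by an independent draw from `fractions`
#' (phenotype stream); grouped phenotypes then draw a migratory group from
#' their abundances.
#'
#' @param params A [model_params()] object.
#' @param phenotypes A [phenotype_table()].
#' @param fractions Named numeric vector of phenotype fractions summing
#'   to 1 (names matching the table), or `NULL` for 100% of the first
#'   phenotype.
#' @param map A [build_vessel_map()] object.
#' @param streams An [rng_streams()] object.
#' @return A `sim_state` list (`x`, `y`, `heading`, `cohort`, `T`) plus
#'   the cohort table.
#' @export
initialize_state <- function(params, phenotypes, fractions = NULL, map,
                             streams) {
  stopifnot(inherits(params, "model_params"),
            inherits(phenotypes, "phenotype_table"),
            inherits(map, "vessel_map"), inherits(streams, "rng_streams"))
  if (is.null(fractions))
    fractions <- setNames(c(1, rep(0, length(phenotypes) - 1)),
                          names(phenotypes))
  if (is.null(names(fractions)) ||
      !all(names(fractions) %in% names(phenotypes)))
    stop("'fractions' must be named after the phenotype table", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must sum to 1", call. = FALSE)
  frac_full <- setNames(numeric(length(phenotypes)), names(phenotypes))
  frac_full[names(fractions)] <- fractions

  n <- params$n_init
  d <- params$d_cell
  nx <- map$nx
  c0 <- nx %/% 2L
  # ring-by-ring square enumeration around the center, fixed order
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  r <- 0L
  while (placed < n) {
    ring <- if (r == 0L) {
      cbind(0L, 0L)
    } else {
      offs <- expand.grid(dx = -r:r, dy = -r:r)
      offs <- offs[pmax(abs(offs$dx), abs(offs$dy)) == r, ]
      as.matrix(offs[order(atan2(offs$dy, offs$dx)), ])
    }
    for (k in seq_len(nrow(ring))) {
      ix <- (c0 + ring[k, 1]) %% nx
      iy <- (c0 + ring[k, 2]) %% nx
      if (map$type[ix + nx * iy + 1L] == 2L) next  # never start in a lumen
      placed <- placed + 1L
      pos[placed, ] <- c((ix + 0.5) * d, (iy + 0.5) * d)
      if (placed == n) break
    }
    r <- r + 1L
    if (r > nx) stop("n_init exceeds lattice capacity", call. = FALSE)
  }

  cohorts <- build_cohorts(phenotypes)
  cum <- cumsum(frac_full)
  u_ph <- draw_uniform(streams, n, "phenotype")
  phen <- vapply(u_ph, function(u) which(u <= cum + 1e-12)[1], integer(1))
  coh <- integer(n)
  for (i in seq_len(n)) {
    ids <- cohorts$phen_cohorts[[phen[i]]]
    if (length(ids) == 1) {
      coh[i] <- ids
    } else {
      ab <- cumsum(cohorts$phen_abund[[phen[i]]])
      u <- draw_uniform(streams, 1, "phenotype")
      coh[i] <- ids[which(u <= ab + 1e-12)[1]]
    }
  }
  cohorts$phen_frac <- as.numeric(frac_full)
  structure(list(x = pos[, 1], y = pos[, 2],
                 heading = rep(-1L, n), cohort = coh,
                 T = rep(0, n), cohorts = cohorts),
            class = "sim_state")
}

#' Run the tumor-progression simulation
#'
#' The discrete-time main loop. At every step, each living cell — in a
#' freshly randomized order — (1) advances its division and G1 clocks and
#' is removed if necrotic, (2) performs one persistent-random-walk move
#' (with vessel contacts routed through the intravasation draw), and
#' (3) may divide according to its proliferation score, placing the second
#' daughter in a free Moore spot. Counts, the uniformity index, and the
#' conservation identity quantities are recorded every `record_every`
#' hours.
#'
#' @param params A [model_params()] object.
#' @param phenotypes A [phenotype_table()]; default one intact-Golgi-like
#'   constant phenotype (4.8 um/h, persistence 0.5).
#' @param fractions Named phenotype fractions summing to 1.
#' @param seed Master seed; defaults to `params$seed`.
#' @param record_every Recording interval in hours (multiple of `dt`).
#' @param stop_alive Optional early-stop threshold: stop once the living
#'   population reaches this size (0 = never). The run is always capped at
#'   `params$duration`.
#' @param k_quadrats Number of quadrats for the uniformity index (perfect
#'   square).
#' @param map Optional pre-built [build_vessel_map()]; built from `params`
#'   when omitted.
#' @return A `simulation_result` with the recorded time series
#'   (`alive_count`, `cumulative_intravasated`, `cumulative_necrotic`,
#'   `quiescent_count`, `ui_series`), final cell table, counters, and the
#'   mean time cells spent in nourished zones.
#' @export
#' @examples
#' p <- model_params(L = 400, duration = 48, vessel_count = 1L, tau = 24,
#'                   t_G1 = 8)
#' r <- run_simulation(p, seed = 1)
#' summarize(r)
run_simulation <- function(params,
                           phenotypes = phenotype_table(
                             phenotype("intact_golgi", speed = 4.8,
                                       persistence = 0.5)),
                           fractions = NULL, seed = NULL,
                           record_every = 24, stop_alive = 0,
                           k_quadrats = 25, map = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(seed)) seed <- params$seed
  streams <- rng_streams(seed)
  if (is.null(map)) map <- build_vessel_map(params, streams)
  state <- initialize_state(params, phenotypes, fractions, map, streams)
  rec <- record_every
  if (rec > 0 && abs(rec / params$dt - round(rec / params$dt)) > 1e-9)
    stop("'record_every' must be a multiple of 'dt'", call. = FALSE)
  ks <- sqrt(k_quadrats)
  if (abs(ks - round(ks)) > 1e-9 || k_quadrats < 4)
    stop("'k_quadrats' must be a perfect square >= 4", call. = FALSE)

  raw <- run_sim_cpp(unclass(params), map[c("nx", "type", "lumen_adj")],
                     state$cohorts,
                     list(x = state$x, y = state$y, T = state$T,
                          heading = state$heading, cohort = state$cohort),
                     params$duration, rec, as.integer(stop_alive),
                     as.integer(k_quadrats), streams$ptr)

  cohorts <- state$cohorts
  cells <- as.data.frame(raw$cells)
  cells$id <- seq_len(nrow(cells))
  cells$phenotype <- cohorts$labels[cohorts$phenotype[cells$cohort + 1L]]
  cells$fate <- NA_character_
  cells$fate[cells$alive] <- classify_fate(cells$T[cells$alive], params)

  structure(list(
    timepoints = raw$time,
    alive_count = raw$alive,
    cumulative_intravasated = raw$intravasated,
    cumulative_necrotic = raw$necrotic,
    quiescent_count = raw$quiescent,
    ui_series = raw$ui,
    cumulative_births = raw$births_series,
    cells = cells,
    final_positions = cells[cells$alive,
                            c("id", "x", "y", "phenotype", "birth_time")],
    births = raw$births,
    n_init = params$n_init,
    intravasated_total = raw$intravasated_total,
    necrotic_total = raw$necrotic_total,
    mean_nourished_time = raw$mean_nourished_h,
    final_clock = raw$final_clock,
    k_quadrats = k_quadrats,
    seed = seed,
    params = params,
    map = map), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- length(x$timepoints)
  cat("<simulation_result>", sprintf(
    "%g h simulated, %d recording points\n", x$final_clock, n))
  cat(sprintf(
    "  alive %d | intravasated %d | necrotic %d | quiescent %d | UI %.3f\n",
    x$alive_count[n], x$cumulative_intravasated[n], x$cumulative_necrotic[n],
    x$quiescent_count[n], x$ui_series[n]))
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(time = x$timepoints, alive = x$alive_count,
             births = x$cumulative_births,
             intravasated = x$cumulative_intravasated,
             necrotic = x$cumulative_necrotic,
             quiescent = x$quiescent_count, ui = x$ui_series)
}

#' Plot the recorded time series of a simulation
#'
#' @param x A `simulation_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.simulation_result <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::matplot(df$time, cbind(df$alive, df$intravasated, df$necrotic),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b7837", "#d73027", "#878787"),
                    xlab = "time (h)", ylab = "cells", ...)
  graphics::legend("topleft", c("alive", "intravasated (cum.)",
                                "necrotic (cum.)"),
                   col = c("#1b7837", "#d73027", "#878787"), lwd = 2,
                   bty = "n")
  invisible(x)
}
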