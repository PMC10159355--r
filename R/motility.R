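#' The eight discrete headings and their forward/backward split
#'
#' Cells move along one of 8 unit vectors at 45 degree spacing (Moore
#' directions). Relative to the previous heading, the *forward* set is the
#' 5 headings within bilateral 90 degrees inclusive; the *backward* set is
#' the complementary 3 headings.
#'
#' @param prev Previous heading index in 0..7 (0 = East, counter-clockwise),
#'   or `NULL` for the full set.
#' @return A list with `headings` (8 x 2 matrix of unit vectors), and —
#'   when `prev` is given — integer vectors `forward` and `backward`.
#' @export
#' @examples
#' heading_set(0)$forward  # East +/- 90 degrees
heading_set <- function(prev = NULL) {
  ang <- (0:7) * pi / 4
  out <- list(headings = cbind(ux = cos(ang), uy = sin(ang)))
  if (!is.null(prev)) {
    stopifnot(prev %in% 0:7)
    out$forward <- sort((prev + (-2:2)) %% 8)
    out$backward <- sort((prev + 3:5) %% 8)
  }
  out
}

#' Wrap a position into the periodic domain
#'
#' Both coordinates are mapped into the half-open interval \[0, L) by
#' modular arithmetic.
#'
#' @param position Numeric `c(x, y)` (or a matrix with two columns).
#' @param L Domain side length, um.
#' @return The wrapped position(s).
#' @export
#' @examples
#' wrap_position(c(2010, -5), 2000)
wrap_position <- function(position, L) {
  stopifnot(L > 0)
  w <- position %% L
  w[w >= L | abs(w - L) < 1e-12] <- 0
  w
}

#' Sample a step speed from a phenotype's speed profile
#'
#' Constant profiles return their nominal value without consuming a draw;
#' empirical profiles return one draw (with replacement) from the stored
#' sample.
#'
#' @param phenotype A [phenotype()] object, or a bare numeric speed profile.
#' @param streams An [rng_streams()] object (movement stream).
#' @param group For grouped phenotypes, which group's profile to sample.
#' @return A speed in um/h (>= 0).
#' @export
sample_speed <- function(phenotype, streams, group = 1) {
  prof <- if (inherits(phenotype, "phenotype")) {
    phenotype$profiles[[group]]
  } else {
    as.numeric(phenotype)
  }
  if (length(prof) == 0 || anyNA(prof))
    stop("empty or invalid speed profile", call. = FALSE)
  if (length(prof) == 1) return(prof)
  u <- draw_uniform(streams, 1, "movement")
  prof[min(length(prof), ceiling(u * length(prof)))]
}

#' Propose one persistent-random-walk move for a cell
#'
#' Implements the discretized persistent random walk of the simulator: the
#' step length is a sampled speed times `dt`; with probability equal to the
#' persistence ratio the candidate headings are the forward set of the
#' previous heading, otherwise the backward set (all 8 before the first
#' move). Candidates are discarded when the destination would overlap
#' another cell (center distance < `d_cell`, periodic metric, destination
#' checked only — cells may cross through occupied ground), land in a lumen
#' square, or leave a nourished zone the cell currently occupies (the
#' latter survive only when a single zone-exit draw accepts, with
#' probability `p_exit_nourished`). One surviving candidate is chosen
#' uniformly; with none, the cell stays and keeps its heading. A move
#' ending in contact with a lumen square routes through the intravasation
#' draw.
#'
#' This wrapper runs the same compiled routine as the simulation engine.
#'
#' @param cell List with `position` (`c(x, y)` um), `heading` (0..7 or `NA`),
#'   `persistence`, `speed` (profile), and optional `intravasation_fold`.
#' @param map A [build_vessel_map()] object.
#' @param occupancy Matrix (n x 2) of other cells' center positions, um.
#' @param params A [model_params()] object.
#' @param streams An [rng_streams()] object.
#' @return List with `outcome` (`"moved"`, `"stayed"`, `"intravasated"`),
#'   the new `position`, and the new `heading`.
#' @export
propose_move <- function(cell, map, occupancy, params, streams) {
  stopifnot(inherits(map, "vessel_map"), inherits(params, "model_params"),
            inherits(streams, "rng_streams"))
  if (is.null(occupancy)) occupancy <- matrix(numeric(0), ncol = 2)
  occupancy <- as.matrix(occupancy)
  hd <- cell$heading
  if (is.null(hd) || is.na(hd)) hd <- -1L
  fold <- if (is.null(cell$intravasation_fold)) 1 else cell$intravasation_fold
  res <- propose_move_cpp(cell$position[1], cell$position[2], as.integer(hd),
                          cell$persistence, as.numeric(cell$speed), fold,
                          occupancy, unclass(params),
                          map[c("nx", "type", "lumen_adj")], streams$ptr)
  list(outcome = res$outcome, position = c(res$x, res$y),
       heading = if (res$heading < 0) NA_integer_ else res$heading)
}

#' Place the second daughter cell after a division
#'
#' The daughter occupies a free Moore spot of the mother (axial offsets at
#' distance `d_cell`, diagonal at `sqrt(2) * d_cell`), chosen by the same
#' forward/backward persistence rule applied to the mother's heading and
#' restricted to free spots; when the selected half has no free spot the
#' choice falls back to all free spots. With no free Moore spot at all the
#' division fails and the mother's division clock is left untouched.
#'
#' @inheritParams propose_move
#' @param cell List with `position`, `heading`, `persistence`.
#' @return List with `success`, daughter `position` (or `NULL`), and
#'   `mother_T` (0 on success, unchanged on failure).
#' @export
place_daughter <- function(cell, map, occupancy, params, streams) {
  stopifnot(inherits(map, "vessel_map"), inherits(params, "model_params"))
  if (is.null(occupancy)) occupancy <- matrix(numeric(0), ncol = 2)
  occupancy <- as.matrix(occupancy)
  hd <- cell$heading
  if (is.null(hd) || is.na(hd)) hd <- -1L
  res <- place_daughter_cpp(cell$position[1], cell$position[2],
                            as.integer(hd), cell$persistence, occupancy,
                            unclass(params), map[c("nx", "type", "lumen_adj")],
                            streams$ptr)
  list(success = res$success,
       position = if (res$success) c(res$x, res$y) else NULL,
       mother_T = res$mother_T)
}
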