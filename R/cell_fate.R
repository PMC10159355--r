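#' Moore-neighborhood local density
#'
#' The local density `n` of a cell is the number of the 8 lattice squares
#' around the square containing its center (periodic wrap) that hold at
#' least one other cell center.
#'
#' @param position Numeric `c(x, y)` of the focal cell, um.
#' @param occupancy Matrix (m x 2) of the other cells' centers, um.
#' @param map A [build_vessel_map()] object (provides the lattice).
#' @return Integer in 0..8.
#' @export
local_density <- function(position, occupancy, map) {
  stopifnot(inherits(map, "vessel_map"))
  if (is.null(occupancy) || nrow(as.matrix(occupancy)) == 0) return(0L)
  occupancy <- as.matrix(occupancy)
  nx <- map$nx
  me <- square_of(position[1], position[2], map)
  mx <- me %% nx; my <- me %/% nx
  dxs <- c(1, 1, 0, -1, -1, -1, 0, 1)
  dys <- c(0, 1, 1, 1, 0, -1, -1, -1)
  nbr <- ((mx + dxs) %% nx) + nx * ((my + dys) %% nx)
  occ_sq <- square_of(occupancy[, 1], occupancy[, 2], map)
  sum(nbr %in% occ_sq)
}

#' Proliferation score
#'
#' `PS = T + D + V`: the hours since the last division `T`, a crowding
#' bonus `D = delta_D * (8 - n) / 8` that shrinks as the Moore
#' neighborhood fills, and a vessel bonus
#' `V = tau * (1 - 1 / (1 + nourished_advantage))` for cells inside a
#' nourished zone (so the effective cycle length there is
#' `tau / (1 + nourished_advantage)`). All three terms are in hours, so PS
#' compares directly with the cell-cycle length `tau`.
#'
#' @param T Hours since division (>= 0).
#' @param n Moore occupancy in 0..8.
#' @param nourished Logical: is the cell in a nourished zone?
#' @param params A [model_params()] object.
#' @return PS in hours.
#' @export
#' @examples
#' p <- model_params()
#' proliferation_score(20, 0, FALSE, p)  # 20 + 4 = 24
proliferation_score <- function(T, n, nourished, params) {
  if (any(n < 0 | n > 8)) stop("'n' must be in 0..8", call. = FALSE)
  stopifnot(all(T >= 0))
  D <- params$delta_D * (8 - n) / 8
  V <- ifelse(nourished,
              params$tau * (1 - 1 / (1 + params$nourished_advantage)), 0)
  T + D + V
}

#' Per-step division probability
#'
#' Proliferation is completely inhibited (probability 0) when the Moore
#' neighborhood is fully occupied (`n = 8`). Otherwise the probability is
#' `p_div_high` when `PS >= tau` or when the cell completed its G1 phase in
#' nourished zones (the G1 fast track), and `p_div_low` otherwise.
#'
#' @param PS Proliferation score, hours.
#' @param n Moore occupancy in 0..8.
#' @param g1_fast Logical: G1 fast track engaged?
#' @param params A [model_params()] object.
#' @return Probability per time step.
#' @export
division_probability <- function(PS, n, g1_fast, params) {
  if (any(n < 0 | n > 8)) stop("'n' must be in 0..8", call. = FALSE)
  ifelse(n == 8, 0,
         ifelse(PS >= params$tau | g1_fast, params$p_div_high,
                params$p_div_low))
}

#' G1 fast track
#'
#' A cell that has spent the G1-phase length `t_G1` in nourished zones
#' since its last division divides at the high probability regardless of
#' its proliferation score. The nourished clock accrues whenever the cell
#' is inside a zone (brief exits do not reset it) and resets on division.
#'
#' @param g1_nourished_clock Hours accrued in nourished zones since the
#'   last division.
#' @param params A [model_params()] object.
#' @return Logical (boundary inclusive).
#' @export
g1_fast_track <- function(g1_nourished_clock, params) {
  g1_nourished_clock >= params$t_G1 - 1e-9
}

#' Classify cell fate from the time since division
#'
#' A cell that has not divided for `n_n` cell cycles is necrotic and is
#' removed from the field; between `n_s` and `n_n` cycles it is quiescent
#' (it remains in the field and can re-enter the cycle); below `n_s` it is
#' proliferating.
#'
#' @param T Hours since division (vectorized).
#' @param params A [model_params()] object.
#' @return Character vector in `{"proliferating", "quiescent", "necrotic"}`.
#' @export
#' @examples
#' classify_fate(c(0, 60, 72), model_params())
classify_fate <- function(T, params) {
  stopifnot(all(T >= 0))
  ifelse(T >= params$n_n * params$tau - 1e-9, "necrotic",
         ifelse(T >= params$n_s * params$tau - 1e-9, "quiescent",
                "proliferating"))
}
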