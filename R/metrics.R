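#' Quadrat counts over the simulation field
#'
#' @param positions Matrix or data frame with x, y in um (columns 1-2).
#' @param L Domain side, um.
#' @param k Number of equal square quadrats (perfect square >= 4) tiling
#'   the full fixed domain.
#' @return Integer vector of length `k` summing to the number of cells.
#' @export
quadrat_counts <- function(positions, L, k = 25) {
  positions <- as.matrix(positions)
  qs <- sqrt(k)
  if (abs(qs - round(qs)) > 1e-9 || k < 4)
    stop("'k' must be a perfect square >= 4", call. = FALSE)
  qs <- as.integer(round(qs))
  side <- L / qs
  ix <- pmin(qs - 1L, as.integer(floor((positions[, 1] %% L) / side)))
  iy <- pmin(qs - 1L, as.integer(floor((positions[, 2] %% L) / side)))
  tabulate(ix + qs * iy + 1L, nbins = qs * qs)
}

#' Uniformity index of a cell distribution
#'
#' `UI = 1 - sum(|c_i - N/k|) / (2 N (1 - 1/k))` over `k` equal quadrat
#' counts `c_i`: the normalized total-variation distance between the
#' observed quadrat distribution and the uniform one, subtracted from 1.
#' UI equals 1 for perfectly even counts and 0 when all cells share a
#' single quadrat; low values indicate cluster formation. Values are
#' comparable only at a fixed `k` (default 25).
#'
#' @param positions Matrix/data frame of cell centers (um), `N >= 1` rows.
#' @param L Domain side, um.
#' @param k Number of quadrats (perfect square >= 4).
#' @return UI in \[0, 1\].
#' @export
#' @examples
#' pts <- expand.grid(x = seq(50, 950, 100), y = seq(50, 950, 100))
#' uniformity_index(pts, 1000, 25)  # 1: one cell per quadrat
uniformity_index <- function(positions, L, k = 25) {
  positions <- as.matrix(positions)
  N <- nrow(positions)
  if (N < 1) stop("uniformity index is undefined for zero cells",
                  call. = FALSE)
  cc <- quadrat_counts(positions, L, k)
  ui <- 1 - sum(abs(cc - N / k)) / (2 * N * (1 - 1 / k))
  min(1, max(0, ui))
}

#' Summarize a simulation result
#'
#' @param result A [run_simulation()] result.
#' @return One-row data frame: final alive count, cumulative intravasated
#'   and necrotic counts, final quiescent count, final uniformity index,
#'   and mean time spent in nourished zones (hours, averaged over every
#'   cell that ever existed).
#' @export
summarize <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  n <- length(result$timepoints)
  data.frame(seed = result$seed,
             alive = result$alive_count[n],
             intravasated = result$cumulative_intravasated[n],
             necrotic = result$cumulative_necrotic[n],
             quiescent = result$quiescent_count[n],
             ui = result$ui_series[n],
             mean_nourished_h = result$mean_nourished_time)
}

#' Pearson correlation between two sweep outcome columns
#'
#' @param rows Data frame of per-run summaries (>= 3 rows).
#' @param x,y Column names.
#' @return Pearson product-moment correlation coefficient.
#' @export
correlate_outcomes <- function(rows, x, y) {
  stopifnot(is.data.frame(rows), x %in% names(rows), y %in% names(rows))
  if (nrow(rows) < 3) stop("need at least 3 rows", call. = FALSE)
  vx <- rows[[x]]
  vy <- rows[[y]]
  if (stats::var(vx) == 0 || stats::var(vy) == 0)
    stop("zero variance in '", if (stats::var(vx) == 0) x else y, "'",
         call. = FALSE)
  stats::cor(vx, vy)
}
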