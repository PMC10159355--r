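#' Build the vessel lattice and nourished zones
#'
#' Blood vessels are assumed perpendicular to the simulated tissue section,
#' so each appears as a single impenetrable *lumen* square of side `d_cell`
#' on the lattice overlay. Lumen squares are placed one per block of a
#' jittered regular grid (deterministic under the `vessel` RNG stream), or
#' at explicit coordinates when supplied. Every lattice square whose center
#' lies within `nourished_radius` of a lumen-square center under the
#' periodic metric — excluding the lumen squares themselves — forms the
#' *nourished* zone in which cells cycle faster and are retained.
#'
#' @param params A [model_params()] object (uses `L`, `d_cell`,
#'   `vessel_count`, `nourished_radius`).
#' @param streams An [rng_streams()] object (vessel stream used for jitter).
#' @param vessel_coords Optional n x 2 matrix of lumen positions in um,
#'   overriding the jittered grid (`vessel_count` is then ignored).
#' @return A `vessel_map` with the lattice size, the square `type` field
#'   (0 free, 1 nourished, 2 lumen), and the lumen-adjacency indicator.
#' @export
#' @examples
#' p <- model_params(L = 400, vessel_count = 2L, nourished_radius = 60)
#' vm <- build_vessel_map(p, rng_streams(1))
#' sum(vm$type == 2L)
build_vessel_map <- function(params, streams, vessel_coords = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(streams, "rng_streams"))
  nx <- as.integer(round(params$L / params$d_cell))
  if (is.null(vessel_coords)) vessel_coords <- attr(params, "vessel_coords")
  if (is.null(vessel_coords)) {
    vc <- params$vessel_count
    if (vc > nx * nx)
      stop("vessel_count exceeds lattice capacity (", nx * nx, " squares)",
           call. = FALSE)
    lumen <- integer(0)
    if (vc > 0) {
      g <- ceiling(sqrt(vc))
      block <- nx / g
      # choose vc of the g*g blocks without replacement, then jitter within
      u <- draw_uniform(streams, g * g, "vessel")
      blocks <- order(u)[seq_len(vc)]
      jit <- matrix(draw_uniform(streams, 2 * vc, "vessel"), ncol = 2)
      bx <- (blocks - 1L) %% g
      by <- (blocks - 1L) %/% g
      ix <- pmin(nx - 1L, as.integer(floor((bx + jit[, 1] * 0.9999) * block)))
      iy <- pmin(nx - 1L, as.integer(floor((by + jit[, 2] * 0.9999) * block)))
      lumen <- unique(ix + nx * iy)
      # jitter collisions are only possible when blocks overlap squares;
      # resolve by walking to the next free square (deterministic)
      while (length(lumen) < vc) {
        cand <- setdiff(seq_len(nx * nx) - 1L, lumen)
        lumen <- c(lumen, cand[[1]])
      }
    }
  } else {
    vessel_coords <- as.matrix(vessel_coords)
    stopifnot(ncol(vessel_coords) == 2)
    ix <- as.integer(floor((vessel_coords[, 1] %% params$L) / params$d_cell))
    iy <- as.integer(floor((vessel_coords[, 2] %% params$L) / params$d_cell))
    lumen <- unique(ix + nx * iy)
  }

  type <- integer(nx * nx)  # 0 free
  if (length(lumen)) {
    idx <- seq_len(nx * nx) - 1L
    cx <- (idx %% nx + 0.5) * params$d_cell
    cy <- (idx %/% nx + 0.5) * params$d_cell
    near <- rep(FALSE, nx * nx)
    adj <- rep(FALSE, nx * nx)
    for (sq in lumen) {
      lx <- (sq %% nx + 0.5) * params$d_cell
      ly <- (sq %/% nx + 0.5) * params$d_cell
      dx <- abs(cx - lx); dx <- pmin(dx, params$L - dx)
      dy <- abs(cy - ly); dy <- pmin(dy, params$L - dy)
      near <- near | (dx * dx + dy * dy <= params$nourished_radius^2 + 1e-9)
      adj <- adj | (dx <= params$d_cell + 1e-9 & dy <= params$d_cell + 1e-9)
    }
    type[near] <- 1L
    type[lumen + 1L] <- 2L
    adj[lumen + 1L] <- FALSE  # cells can never stand in a lumen square
    lumen_adj <- as.integer(adj)
  } else {
    lumen_adj <- integer(nx * nx)
  }
  structure(list(nx = nx, lattice_size = params$d_cell, L = params$L,
                 type = type, lumen_adj = lumen_adj,
                 lumen = sort(lumen)),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat("<vessel_map>", x$nx, "x", x$nx, "squares of", x$lattice_size, "um:",
      sum(x$type == 2L), "lumen,", sum(x$type == 1L), "nourished\n")
  invisible(x)
}

#' @export
as.data.frame.vessel_map <- function(x, ...) {
  keep <- which(x$type != 0L) - 1L
  data.frame(square_x = keep %% x$nx, square_y = keep %/% x$nx,
             type = c("nourished", "lumen")[x$type[keep + 1L]])
}

#' Is a position inside a nourished zone?
#'
#' @param position Numeric `c(x, y)` in um, inside the domain.
#' @param map A [build_vessel_map()] object.
#' @return `TRUE` iff the lattice square containing the position is
#'   nourished.
#' @export
in_nourished_zone <- function(position, map) {
  stopifnot(inherits(map, "vessel_map"))
  ix <- min(map$nx - 1L, floor((position[1] %% map$L) / map$lattice_size))
  iy <- min(map$nx - 1L, floor((position[2] %% map$L) / map$lattice_size))
  map$type[ix + map$nx * iy + 1L] == 1L
}

# Square index (0-based) of a position; shared lattice convention.
square_of <- function(x, y, map) {
  ix <- pmin(map$nx - 1L, floor((x %% map$L) / map$lattice_size))
  iy <- pmin(map$nx - 1L, floor((y %% map$L) / map$lattice_size))
  as.integer(ix + map$nx * iy)
}

#' Attempt intravasation for a cell in contact with a vessel
#'
#' Called when a cell occupies (or its proposed move reaches) a square
#' Moore-adjacent to a lumen square. With probability
#' `p_intr * intravasation_fold` the cell enters the lumen and is removed
#' from the field; otherwise it stays outside (lumen squares are never
#' occupied).
#'
#' @param intravasation_fold Phenotype multiplier >= 0 on `p_intr`.
#' @param params A [model_params()] object.
#' @param streams An [rng_streams()] object (intravasation stream).
#' @return `"intravasated"` or `"stays"`.
#' @export
attempt_intravasation <- function(intravasation_fold, params, streams) {
  if (!is.numeric(intravasation_fold) || intravasation_fold < 0)
    stop("'intravasation_fold' must be >= 0", call. = FALSE)
  p <- min(1, params$p_intr * intravasation_fold)
  if (trigger(p, streams, "intravasation")) "intravasated" else "stays"
}
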