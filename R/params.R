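.param_defaults <- list(
  L = 2000,                  # domain side, um
  dt = 1,                    # time step, h
  duration = 2160,           # total simulated time, h (90 days)
  d_cell = 20,               # cell diameter, um (= lattice square side)
  tau = 336,                 # cell-cycle length, h (14 d, in vivo scale)
  t_G1 = 144,                # G1-phase length, h (~43% of the cycle)
  n_s = 2L,                  # quiescence threshold, cell cycles
  n_n = 3L,                  # necrosis threshold, cell cycles
  delta_D = 4,               # maximum density bonus, h
  nourished_advantage = 0.30,# fractional proliferation-rate gain near vessels
  p_div_high = 0.25,         # division probability per step when PS >= tau
  p_div_low = 1e-4,          # division probability per step when PS < tau
  p_intr = 1e-4,             # baseline intravasation probability per contact
  p_exit_nourished = 0.5,    # acceptance probability for leaving a nourished zone
  vessel_count = 240L,       # lumen cross-sections (60 vessels per mm^2)
  nourished_radius = 100,    # nourished-zone radius around a lumen square, um
  n_init = 1L,               # initial cell count
  contact_mode = "resident", # "resident": every step in a lumen-adjacent square
                             # is a contact; "move": only a move landing there
  seed = 1L                  # default master seed
)

#' Construct and validate the model parameter set
#'
#' `model_params()` builds a validated parameter object from named
#' overrides of the documented defaults; `validate_params()` does the same
#' from a raw key-value list (e.g. parsed from a config file). Unknown keys
#' are rejected, missing keys are filled with the defaults, and every
#' invariant of the model is checked (probabilities in \[0, 1\], `n_s < n_n`,
#' `tau > t_G1 > 0`, positive step and domain, domain side divisible by the
#' cell diameter).
#'
#' Lengths are in micrometers, times in hours. The necrosis threshold
#' `n_n = 3` cell cycles, the baseline intravasation probability
#' `p_intr = 1e-4` per contact, and the 30% nourished proliferation
#' advantage are the model's anchored values; the remaining defaults are
#' implementation choices documented in the methods vignette.
#'
#' @param ... Named parameter overrides (see [`.param_defaults`] source for
#'   the full key list).
#' @param raw A named list of raw parameter values.
#' @return A `model_params` object (validated named list).
#' @export
#' @examples
#' p <- model_params(L = 600, vessel_count = 4L)
#' p$n_n
model_params <- function(...) {
  validate_params(list(...))
}

#' @rdname model_params
#' @export
validate_params <- function(raw = list()) {
  stopifnot(is.list(raw))
  if (length(raw) && (is.null(names(raw)) || any(names(raw) == "")))
    stop("all parameters must be named", call. = FALSE)
  unknown <- setdiff(names(raw), names(.param_defaults))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- .param_defaults
  p[names(raw)] <- raw

  num1 <- function(key, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", key, "' must be a single finite number", call. = FALSE)
    if (v < lo || (strict_lo && v <= lo) || v > hi)
      stop("parameter '", key, "' out of range: ", v, call. = FALSE)
    as.numeric(v)
  }
  for (key in c("p_div_high", "p_div_low", "p_intr", "p_exit_nourished"))
    p[[key]] <- num1(key, 0, 1)
  p$L <- num1("L", 0, strict_lo = TRUE)
  p$dt <- num1("dt", 0, strict_lo = TRUE)
  p$duration <- num1("duration", 0)
  p$d_cell <- num1("d_cell", 0, strict_lo = TRUE)
  p$tau <- num1("tau", 0, strict_lo = TRUE)
  p$t_G1 <- num1("t_G1", 0, strict_lo = TRUE)
  p$delta_D <- num1("delta_D", 0)
  p$nourished_advantage <- num1("nourished_advantage", 0)
  p$nourished_radius <- num1("nourished_radius", 0)
  p$n_s <- as.integer(num1("n_s", 1))
  p$n_n <- as.integer(num1("n_n", 1))
  p$vessel_count <- as.integer(num1("vessel_count", 0))
  p$n_init <- as.integer(num1("n_init", 1))
  p$seed <- as.integer(num1("seed"))
  if (p$n_s >= p$n_n)
    stop("parameter 'n_s' must be < 'n_n' (got n_s = ", p$n_s,
         ", n_n = ", p$n_n, ")", call. = FALSE)
  if (p$tau <= p$t_G1)
    stop("parameter 't_G1' must be < 'tau'", call. = FALSE)
  nx <- p$L / p$d_cell
  if (abs(nx - round(nx)) > 1e-9)
    stop("parameter 'L' must be an integer multiple of 'd_cell'", call. = FALSE)
  if (!p$contact_mode %in% c("resident", "move"))
    stop("parameter 'contact_mode' must be \"resident\" or \"move\"",
         call. = FALSE)
  nsteps <- p$duration / p$dt
  if (abs(nsteps - round(nsteps)) > 1e-9)
    stop("parameter 'duration' must be an integer multiple of 'dt'",
         call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  domain %g um (%d x %d squares of %g um), dt %g h, duration %g h\n",
              x$L, x$L / x$d_cell, x$L / x$d_cell, x$d_cell, x$dt, x$duration))
  cat(sprintf("  cycle tau %g h, t_G1 %g h, quiescent >= %d tau, necrotic >= %d tau\n",
              x$tau, x$t_G1, x$n_s, x$n_n))
  cat(sprintf("  p_div %g/%g, p_intr %g, p_exit_nourished %g, contact '%s'\n",
              x$p_div_high, x$p_div_low, x$p_intr, x$p_exit_nourished,
              x$contact_mode))
  cat(sprintf("  %d vessels, nourished radius %g um (+%d%% proliferation)\n",
              x$vessel_count, x$nourished_radius,
              round(100 * x$nourished_advantage)))
  invisible(x)
}

#' Read model parameters from a configuration file
#'
#' Reads a flat YAML or JSON file whose keys match [model_params()] field
#' names and validates the result. An optional `vessel_coords` key (list of
#' `[x, y]` pairs in micrometers) is split off and returned in the
#' `vessel_coords` attribute for use by [build_vessel_map()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `model_params` object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json", call. = FALSE)
  }
  coords <- raw$vessel_coords
  raw$vessel_coords <- NULL
  p <- validate_params(raw)
  if (!is.null(coords)) {
    coords <- if (is.list(coords)) {
      do.call(rbind, lapply(coords, as.numeric))
    } else {
      as.matrix(coords)
    }
    attr(p, "vessel_coords") <- coords
  }
  p
}
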