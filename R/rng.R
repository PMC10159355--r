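.stream_ids <- c(movement = 0L, division = 1L, intravasation = 2L,
                 zone_exit = 3L, phenotype = 4L, vessel = 5L, scheduler = 6L)

#' Create the named random-number streams for one simulation
#'
#' Every stochastic process category (movement, division, intravasation,
#' zone exit, phenotype assignment, vessel placement, update-order
#' scheduling) draws from its own xoshiro256++ stream, all derived from a
#' single master seed. Adding draws to one process therefore never perturbs
#' the sequence seen by another, and a fixed seed reproduces a simulation
#' bit for bit.
#'
#' @param seed Integer master seed.
#' @return An object of class `rng_streams`.
#' @export
#' @examples
#' s <- rng_streams(1)
#' draw_uniform(s, 3, "movement")
rng_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  structure(list(ptr = make_streams_cpp(as.integer(seed)), seed = as.integer(seed)),
            class = "rng_streams")
}

#' @export
print.rng_streams <- function(x, ...) {
  cat("<rng_streams> master seed", x$seed, "-", length(.stream_ids),
      "process streams\n")
  invisible(x)
}

#' Draw uniforms from a named process stream
#'
#' Draws are uniform on the half-open interval (0, 1], so that an event with
#' probability 0 can never trigger and probability 1 always triggers.
#'
#' @param streams An [rng_streams()] object.
#' @param n Number of draws.
#' @param stream Stream name, one of `"movement"`, `"division"`,
#'   `"intravasation"`, `"zone_exit"`, `"phenotype"`, `"vessel"`,
#'   `"scheduler"`.
#' @return Numeric vector of `n` uniforms in (0, 1].
#' @export
draw_uniform <- function(streams, n = 1, stream = "movement") {
  stopifnot(inherits(streams, "rng_streams"))
  id <- .stream_ids[[match.arg(stream, names(.stream_ids))]]
  stream_uniform_cpp(streams$ptr, id, as.integer(n))
}

#' Trigger a stochastic event
#'
#' The universal event contract of the model: one uniform `u` in (0, 1] is
#' drawn from the requested stream and the event fires iff `u <= p`.
#'
#' @param p Event probability in \[0, 1\].
#' @param streams An [rng_streams()] object.
#' @param stream Stream name (see [draw_uniform()]).
#' @return Logical: did the event fire? Exactly one draw is consumed.
#' @export
#' @examples
#' s <- rng_streams(7)
#' trigger(0.5, s, "division")
trigger <- function(p, streams, stream = "division") {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single probability in [0, 1]", call. = FALSE)
  draw_uniform(streams, 1, stream) <= p
}

# Deterministic 31-bit child seed for replicate r of a batch run.
derive_seed <- function(master, index) {
  s <- (as.numeric(master) * 48271 + as.numeric(index) * 16807 + 12345) %%
    2147483647
  as.integer(s)
}
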