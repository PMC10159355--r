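#' Speed-persistence parameter sweep
#'
#' Runs the full simulation for every combination of constant speed and
#' persistence ratio, with `replicates` independent runs per condition
#' (child seeds derived deterministically from the master seed), and
#' returns one summary row per run. The resulting long-format table feeds
#' [correlate_outcomes()] — e.g. the correlation between the final
#' necrotic count and the uniformity index across conditions.
#'
#' The default grid is the package's reduced sweep: tissue-scale speeds
#' 0.5-8 um/h crossed with persistence 0.2-0.8, five replicates, on a
#' 1.2 mm domain with 81 vessels over a 30-day horizon, started from a
#' compact 9-cell seed (see [sweep_params()]).
#'
#' @param speeds Numeric vector of nominal speeds, um/h.
#' @param persistences Numeric vector of persistence ratios in \[0, 1\].
#' @param replicates Runs per condition (>= 1).
#' @param params A [model_params()] object (shared across conditions).
#' @param seed Master seed.
#' @param record_every Recording interval, h.
#' @return Data frame with one row per (speed, persistence, replicate):
#'   `speed`, `persistence`, `rep`, `seed`, `alive`, `intravasated`,
#'   `necrotic`, `quiescent`, `ui`, `mean_nourished_h`.
#' @export
run_sweep <- function(speeds = c(0.5, 1, 2, 4, 8),
                      persistences = c(0.2, 0.4, 0.6, 0.8), replicates = 5,
                      params = sweep_params(), seed = 1,
                      record_every = 720) {
  stopifnot(replicates >= 1, all(persistences >= 0 & persistences <= 1))
  grid <- expand.grid(speed = speeds, persistence = persistences,
                      rep = seq_len(replicates))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ph <- phenotype_table(phenotype("custom", speed = grid$speed[i],
                                    persistence = grid$persistence[i]))
    child <- derive_seed(seed, i)
    res <- run_simulation(params, ph, seed = child,
                          record_every = record_every)
    s <- summarize(res)
    rows[[i]] <- cbind(grid[i, , drop = FALSE], s, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameters of the reduced speed-persistence sweep
#'
#' A scaled-down variant of the default tumor-progression conditions used
#' by [run_sweep()]: a 1.2 mm domain with 81 vessels (56 vessels per mm^2,
#' comparable to the full field), a 30-day horizon, a 7-day cell cycle
#' with G1 at 40% of the cycle, and a compact 9-cell starting cluster so
#' that crowding-driven quiescence and necrosis can develop within the
#' horizon.
#'
#' @param ... Overrides forwarded to [model_params()].
#' @return A `model_params` object.
#' @export
sweep_params <- function(...) {
  over <- list(...)
  base <- list(L = 1200, vessel_count = 81L, tau = 168, t_G1 = 67.2,
               duration = 720, n_init = 9L)
  base[names(over)] <- over
  do.call(model_params, base)
}

.mixture_fractions <- function(frac_fragmented) {
  c(intact_golgi = 1 - frac_fragmented, fragmented_golgi = frac_fragmented)
}

#' Phenotype-mixture experiment (low-Giantin fractions and folds)
#'
#' Simulates tumors in which a fraction of cells carries the fragmented
#' Golgi (low-Giantin) phenotype — slower migration, drawn
#' preferentially from the low-speed groups — with an elevated
#' intravasation rate (`folds`, applied only to fragmented cells). One
#' summary row per (fraction, fold, replicate).
#'
#' @param fracs Fractions of fragmented-Golgi cells in \[0, 1\], e.g.
#'   `c(0.14, 0.65)` or `seq(0, 1, 0.25)`.
#' @param folds Intravasation-fold multipliers for the fragmented
#'   phenotype, e.g. `c(1, 2, 4)`.
#' @param replicates Runs per condition.
#' @param params A [model_params()] object.
#' @param seed Master seed.
#' @param record_every Recording interval, h.
#' @param stop_alive Optional early stop at a living-cell count (0 = none).
#' @return Data frame with `frac_fragmented`, `fold`, `rep`, and the
#'   [summarize()] columns.
#' @export
run_mixture <- function(fracs, folds = 1, replicates = 5,
                        params = model_params(), seed = 1,
                        record_every = 120, stop_alive = 0) {
  stopifnot(all(fracs >= 0 & fracs <= 1), all(folds >= 0))
  grid <- expand.grid(frac_fragmented = fracs, fold = folds,
                      rep = seq_len(replicates))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ph <- default_phenotypes(fold_fragmented = grid$fold[i])
    child <- derive_seed(seed, i)
    res <- run_simulation(params, ph,
                          fractions = .mixture_fractions(
                            grid$frac_fragmented[i]),
                          seed = child, record_every = record_every,
                          stop_alive = stop_alive)
    rows[[i]] <- cbind(grid[i, , drop = FALSE], summarize(res),
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intravasation per thousand cancer cells
#'
#' For each fragmented-Golgi fraction, runs replicate simulations that stop
#' as soon as the living population reaches `target` cells (capped at
#' `params$duration`) and reports the cumulative number of intravasated
#' cells at that point — the number of intravasating cells in a population
#' of a thousand cancer cells when `target = 1000`.
#'
#' @param fracs Fragmented-cell fractions, e.g. `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param fold Intravasation fold of the fragmented phenotype.
#' @param replicates Replicate runs per fraction.
#' @param params A [model_params()] object.
#' @param seed Master seed.
#' @param target Living-cell count at which each run stops.
#' @return List with `runs` (per-run rows: `frac_fragmented`, `rep`,
#'   `intravasated`, `alive`, `hours`) and `summary` (per fraction: mean,
#'   sd, n).
#' @export
run_thousand_cell_assay <- function(fracs = c(0, 0.25, 0.5, 0.75, 1),
                                    fold = 4, replicates = 25,
                                    params = model_params(), seed = 1,
                                    target = 1000) {
  rows <- vector("list", length(fracs) * replicates)
  i <- 0L
  for (f in fracs) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      ph <- default_phenotypes(fold_fragmented = fold)
      child <- derive_seed(seed, i)
      res <- run_simulation(params, ph,
                            fractions = .mixture_fractions(f),
                            seed = child, record_every = 0,
                            stop_alive = target)
      n <- length(res$timepoints)
      rows[[i]] <- data.frame(frac_fragmented = f, rep = r,
                              intravasated = res$cumulative_intravasated[n],
                              alive = res$alive_count[n],
                              hours = res$final_clock)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$frac_fragmented), function(g)
    data.frame(frac_fragmented = g$frac_fragmented[1],
               mean_intravasated = mean(g$intravasated),
               sd_intravasated = sd(g$intravasated),
               mean_alive = mean(g$alive), n = nrow(g))))
  rownames(agg) <- NULL
  list(runs = runs, summary = agg)
}
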