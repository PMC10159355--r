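# Small, fast parameter set used across tests: 400 um field, one vessel,
# culture-like 24 h cycle so fate transitions happen within short horizons.
tiny_params <- function(...) {
  over <- list(...)
  base <- list(L = 400, vessel_count = 1L, nourished_radius = 60,
               tau = 24, t_G1 = 8, duration = 120)
  base[names(over)] <- over
  do.call(model_params, base)
}

const_phenotypes <- function(speed = 10, persistence = 0.5, fold = 1) {
  phenotype_table(phenotype("custom", speed = speed,
                            persistence = persistence,
                            intravasation_fold = fold))
}

# Minimum-image periodic distance matrix of a set of points.
periodic_dist <- function(xy, L) {
  dx <- abs(outer(xy[, 1], xy[, 1], "-")); dx <- pmin(dx, L - dx)
  dy <- abs(outer(xy[, 2], xy[, 2], "-")); dy <- pmin(dy, L - dy)
  sqrt(dx^2 + dy^2)
}
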