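#' Define a cell phenotype
#'
#' A phenotype is either *simple* — one speed profile and one persistence
#' ratio — or *grouped*, carrying four migratory groups (speed, persistence,
#' abundance) from which each newly created cell draws its group. Grouped
#' phenotypes mirror the four speed-persistence classes obtained from
#' trajectory analysis ([assign_groups()]): group 1 low speed / low
#' persistence, 2 low/high, 3 high/low, 4 high/high.
#'
#' @param label Phenotype name, e.g. `"intact_golgi"` or `"fragmented_golgi"`.
#' @param speed Speed profile in um/h: a single number (constant) or a
#'   numeric vector treated as an empirical sample drawn from with
#'   replacement at every step. Ignored when `groups` is given.
#' @param persistence Persistence ratio in \[0, 1\]. Ignored when `groups`
#'   is given.
#' @param intravasation_fold Multiplier >= 0 applied to the baseline
#'   per-contact intravasation probability `p_intr`.
#' @param groups Optional data frame with columns `speed`, `persistence`,
#'   `abundance` (abundances summing to 1), one row per migratory group.
#' @return A `phenotype` object.
#' @export
#' @examples
#' phenotype("intact_golgi", speed = 30, persistence = 0.45)
phenotype <- function(label, speed = NULL, persistence = NULL,
                      intravasation_fold = 1, groups = NULL) {
  stopifnot(is.character(label), length(label) == 1)
  if (!is.numeric(intravasation_fold) || length(intravasation_fold) != 1 ||
      intravasation_fold < 0)
    stop("'intravasation_fold' must be a single number >= 0", call. = FALSE)
  if (is.null(groups)) {
    if (is.null(speed) || is.null(persistence))
      stop("a simple phenotype needs 'speed' and 'persistence'", call. = FALSE)
    if (!is.numeric(speed) || length(speed) < 1 || any(speed < 0))
      stop("'speed' must be non-negative (constant or empirical sample)",
           call. = FALSE)
    if (!is.numeric(persistence) || length(persistence) != 1 ||
        persistence < 0 || persistence > 1)
      stop("'persistence' must be a single ratio in [0, 1]", call. = FALSE)
    groups <- data.frame(speed = NA_real_, persistence = persistence,
                         abundance = 1)
    profiles <- list(as.numeric(speed))
  } else {
    stopifnot(is.data.frame(groups),
              all(c("speed", "persistence", "abundance") %in% names(groups)))
    if (any(groups$persistence < 0 | groups$persistence > 1))
      stop("group persistence values must lie in [0, 1]", call. = FALSE)
    if (any(groups$speed < 0))
      stop("group speeds must be >= 0", call. = FALSE)
    if (abs(sum(groups$abundance) - 1) > 1e-9)
      stop("group abundances must sum to 1", call. = FALSE)
    profiles <- lapply(groups$speed, as.numeric)
  }
  structure(list(label = label, groups = groups, profiles = profiles,
                 intravasation_fold = as.numeric(intravasation_fold)),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat("<phenotype>", x$label, "- fold", x$intravasation_fold, "\n")
  g <- x$groups
  g$speed <- vapply(x$profiles, function(p)
    if (length(p) == 1) p else mean(p), numeric(1))
  print(g, row.names = FALSE)
  invisible(x)
}

#' Bundle phenotypes into a lookup table
#'
#' @param ... `phenotype` objects with distinct labels.
#' @return A `phenotype_table` (named list of phenotypes).
#' @export
phenotype_table <- function(...) {
  ph <- list(...)
  if (length(ph) == 1 && is.list(ph[[1]]) && !inherits(ph[[1]], "phenotype"))
    ph <- ph[[1]]
  stopifnot(length(ph) >= 1,
            all(vapply(ph, inherits, logical(1), "phenotype")))
  labels <- vapply(ph, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("phenotype labels must be distinct",
                                  call. = FALSE)
  names(ph) <- labels
  structure(ph, class = "phenotype_table")
}

#' Default intact/fragmented Golgi phenotype pair
#'
#' A synthetic parameterization of the four migratory groups at tissue
#' scale: two low-speed groups (2.4 um/h) and two high-speed groups
#' (7.2 um/h), each at low (0.3) or high (0.7) persistence. Cells with an intact Golgi draw their group
#' uniformly; cells with a fragmented (low-Giantin) Golgi are shifted
#' toward the low-speed groups, reflecting the slower migration of
#' Giantin-depleted cells, and carry the intravasation fold. The numeric
#' abundances are synthetic fixtures, not measured values.
#'
#' @param fold_fragmented Intravasation fold of the fragmented phenotype.
#' @return A `phenotype_table` with elements `intact_golgi` and
#'   `fragmented_golgi`.
#' @export
default_phenotypes <- function(fold_fragmented = 1) {
  speeds <- c(2.4, 2.4, 7.2, 7.2)
  pers <- c(0.3, 0.7, 0.3, 0.7)
  phenotype_table(
    phenotype("intact_golgi",
              groups = data.frame(speed = speeds, persistence = pers,
                                  abundance = c(0.25, 0.25, 0.25, 0.25))),
    phenotype("fragmented_golgi", intravasation_fold = fold_fragmented,
              groups = data.frame(speed = speeds, persistence = pers,
                                  abundance = c(0.40, 0.35, 0.15, 0.10))))
}

# Flatten a phenotype table into the cohort structure consumed by the C++
# engine: one cohort per (phenotype, group).
build_cohorts <- function(phenotypes) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  speed <- list(); pers <- c(); fold <- c(); phen <- c()
  phen_cohorts <- list(); phen_abund <- list()
  for (pi in seq_along(phenotypes)) {
    ph <- phenotypes[[pi]]
    ids <- integer(0)
    for (gi in seq_along(ph$profiles)) {
      speed[[length(speed) + 1]] <- ph$profiles[[gi]]
      pers <- c(pers, ph$groups$persistence[gi])
      fold <- c(fold, ph$intravasation_fold)
      phen <- c(phen, pi)
      ids <- c(ids, length(speed) - 1L)  # 0-based for C++
    }
    phen_cohorts[[pi]] <- as.integer(ids)
    phen_abund[[pi]] <- as.numeric(ph$groups$abundance)
  }
  list(speed = speed, persistence = as.numeric(pers),
       fold = as.numeric(fold), phenotype = as.integer(phen),
       phen_cohorts = phen_cohorts, phen_abund = phen_abund,
       labels = names(phenotypes))
}
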