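#' Simulation configuration for one condition
#'
#' Bundles every parameter of one simulated transplantation condition:
#' the capacity growth profile, the division-interval schedule, the
#' niche-healing profile, the aneuploidy generation rate per cell
#' division, the aneuploid fitness cost, duration, replicate count and
#' base seed.
#'
#' @param growth A [growth_profile()].
#' @param schedule A [division_schedule()].
#' @param healing A [niche_healing()].
#' @param aneu_rate Probability that a euploid cell division generates
#'   one aneuploid daughter, in `[0, 1]` (default 0.01).
#' @param fitness_cost Relative fitness cost of aneuploidy, in
#'   `[0, 1)`: aneuploid cells have fitness `1 - fitness_cost`,
#'   euploid cells fitness 1 (default 0.01).
#' @param duration Simulated days (default 600).
#' @param n_replicates Number of independent replicate runs
#'   (default 100).
#' @param base_seed Integer; replicate `i` is seeded with
#'   `base_seed + i`.
#' @param label Condition label used in outputs.
#' @param efflux_before_cull Apply the niche-efflux trial before the
#'   capacity cull instead of after it (sensitivity switch,
#'   default `FALSE`).
#' @param mutation_per_daughter Subject each daughter of a euploid
#'   division to an independent aneuploidy trial instead of one trial
#'   per division (sensitivity switch, default `FALSE`; doubles the
#'   effective generation rate).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_replicates = 5, duration = 60)
#' cfg
#' @export
sim_config <- function(growth = growth_profile(),
                       schedule = division_schedule(),
                       healing = niche_healing(),
                       aneu_rate = 0.01,
                       fitness_cost = 0.01,
                       duration = 600,
                       n_replicates = 100,
                       base_seed = 1,
                       label = "condition",
                       efflux_before_cull = FALSE,
                       mutation_per_daughter = FALSE) {
  stopifnot(inherits(growth, "growth_profile"),
            inherits(schedule, "division_schedule"),
            inherits(healing, "niche_healing"),
            is.character(label), length(label) == 1L,
            is.logical(efflux_before_cull),
            is.logical(mutation_per_daughter))
  if (!is.numeric(aneu_rate) || aneu_rate < 0 || aneu_rate > 1)
    stop("`aneu_rate` must be in [0, 1]")
  if (!is.numeric(fitness_cost) || fitness_cost < 0 || fitness_cost >= 1)
    stop("`fitness_cost` must be in [0, 1)")
  if (!is.numeric(duration) || duration < 1)
    stop("`duration` must be >= 1")
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop("`n_replicates` must be >= 1")
  if (!is.numeric(base_seed) || abs(base_seed) >= 2^31)
    stop("`base_seed` must be a 32-bit integer")
  structure(list(growth = growth, schedule = schedule, healing = healing,
                 aneu_rate = as.numeric(aneu_rate),
                 fitness_cost = as.numeric(fitness_cost),
                 duration = as.integer(duration),
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.numeric(base_seed),
                 label = label,
                 efflux_before_cull = isTRUE(efflux_before_cull),
                 mutation_per_daughter = isTRUE(mutation_per_daughter)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  g <- x$growth; s <- x$schedule; h <- x$healing
  cat("<sim_config> ", x$label, "\n", sep = "")
  cat(sprintf("  growth: %g -> %g cells, coeff %g/day\n",
              g$n_initial, g$k_max, g$growth_coeff))
  if (is.null(s$fixed_interval)) {
    cat(sprintf("  division interval: %g -> %g days (size-coupled)\n",
                s$interval_fast, s$interval_slow))
  } else {
    cat(sprintf("  division interval: fixed at %g days\n",
                s$fixed_interval))
  }
  cat(sprintf("  niche health: H0 = %g, healing %g/day\n",
              h$initial_health, h$healing_coeff))
  cat(sprintf("  aneuploidy rate %g per division, fitness cost %g\n",
              x$aneu_rate, x$fitness_cost))
  cat(sprintf("  %d days, %d replicates, base seed %d\n",
              x$duration, x$n_replicates, x$base_seed))
  invisible(x)
}
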