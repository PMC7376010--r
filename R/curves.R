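#' Niche-capacity growth profile
#'
#' Describes how the number of available single-cell bone-marrow niches
#' (the carrying capacity of the stem-cell pool) recovers after
#' myeloablative conditioning.  Capacity follows a logistic curve from
#' `n_initial` engrafted cells toward the homeostatic `k_max` niches at
#' per-day rate `growth_coeff`; `growth_coeff = 0` encodes a
#' constant-capacity (stable-size) condition, in which case
#' `n_initial` must equal `k_max`.
#'
#' @param n_initial Initial cell count at transplantation (default 100).
#' @param k_max Maximum niche capacity in cells (default 10000).
#' @param growth_coeff Logistic growth rate, per day.  The default
#'   0.165/day brings capacity to 99% of `k_max` at day 56, i.e. full
#'   reconstitution in eight weeks.
#' @return An object of class `growth_profile`.
#' @seealso [capacity_at()]
#' @examples
#' g <- growth_profile()
#' capacity_at(c(0, 56, 600), g)
#' @export
growth_profile <- function(n_initial = 100, k_max = 10000,
                           growth_coeff = 0.165) {
  stopifnot(is.numeric(n_initial), length(n_initial) == 1L,
            is.numeric(k_max), length(k_max) == 1L,
            is.numeric(growth_coeff), length(growth_coeff) == 1L)
  if (n_initial < 1 || n_initial > k_max)
    stop("`n_initial` must satisfy 1 <= n_initial <= k_max")
  if (growth_coeff < 0)
    stop("`growth_coeff` must be >= 0")
  if (growth_coeff == 0 && n_initial != k_max)
    stop("growth_coeff = 0 encodes a stable population: ",
         "`n_initial` must equal `k_max`")
  structure(list(n_initial = as.numeric(n_initial),
                 k_max = as.numeric(k_max),
                 growth_coeff = as.numeric(growth_coeff)),
            class = "growth_profile")
}

#' Niche capacity at a given day
#'
#' Logistic capacity curve
#' `K(t) = round(k_max / (1 + ((k_max - n0)/n0) exp(-g t)))`.
#' Nondecreasing in `t`, equal to `n_initial` at `t = 0` and saturating
#' at `k_max`.  For `growth_coeff = 0` the capacity is `k_max`
#' throughout.
#'
#' @param t Day index (vectorised), must be >= 0.
#' @param profile A [growth_profile()].
#' @return Integer-valued capacity (cells), same length as `t`.
#' @export
capacity_at <- function(t, profile) {
  stopifnot(inherits(profile, "growth_profile"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be >= 0")
  n0 <- profile$n_initial
  km <- profile$k_max
  g <- profile$growth_coeff
  if (g == 0) return(rep(round(km), length(t)))
  round(km / (1 + ((km - n0) / n0) * exp(-g * t)))
}

#' Division-interval schedule
#'
#' Average cell-division interval as the pool reconstitutes.  Divisions
#' start fast (`interval_fast`, once per ~3 days immediately after
#' transplantation) and slow to `interval_slow` (once per ~40 days) as
#' the population approaches its final size.  Setting `fixed_interval`
#' decouples division rate from population size for the
#' stable-division-rate experiments.
#'
#' @param interval_fast Division interval at the start of
#'   reconstitution, days (default 3).
#' @param interval_slow Division interval at full capacity, days
#'   (default 40).
#' @param fixed_interval Optional constant interval in days overriding
#'   the coupling.
#' @return An object of class `division_schedule`.
#' @export
division_schedule <- function(interval_fast = 3, interval_slow = 40,
                              fixed_interval = NULL) {
  stopifnot(is.numeric(interval_fast), is.numeric(interval_slow))
  if (interval_fast <= 0 || interval_fast > interval_slow)
    stop("need 0 < interval_fast <= interval_slow")
  if (!is.null(fixed_interval)) {
    stopifnot(is.numeric(fixed_interval), length(fixed_interval) == 1L)
    if (fixed_interval <= 0) stop("`fixed_interval` must be > 0")
    fixed_interval <- as.numeric(fixed_interval)
  }
  structure(list(interval_fast = as.numeric(interval_fast),
                 interval_slow = as.numeric(interval_slow),
                 fixed_interval = fixed_interval),
            class = "division_schedule")
}

#' Scheduled division interval at a given day
#'
#' The deterministic division-interval schedule obtained by assuming
#' the pool tracks the capacity curve: the interval interpolates
#' linearly in the reconstituted fraction
#' `phi(t) = (K(t) - n0) / (k_max - n0)`, so it equals `interval_fast`
#' at `t = 0` and `interval_slow` once capacity has saturated.  When
#' `fixed_interval` is set it is returned unchanged.  The stochastic
#' engine couples the interval to the realised population size via
#' [interval_for_size()]; the two agree whenever the pool fills the
#' niche space, which is the case in all undamaged-niche conditions.
#'
#' @param t Day index (vectorised), >= 0.
#' @param profile A [growth_profile()].
#' @param schedule A [division_schedule()].
#' @return Division interval in days, same length as `t`.
#' @export
division_interval_at <- function(t, profile, schedule) {
  stopifnot(inherits(schedule, "division_schedule"))
  if (any(t < 0)) stop("`t` must be >= 0")
  if (!is.null(schedule$fixed_interval))
    return(rep(schedule$fixed_interval, length(t)))
  stopifnot(inherits(profile, "growth_profile"))
  n0 <- profile$n_initial
  km <- profile$k_max
  phi <- if (km == n0) rep(1, length(t)) else
    (capacity_at(t, profile) - n0) / (km - n0)
  phi <- pmin(pmax(phi, 0), 1)
  schedule$interval_fast +
    (schedule$interval_slow - schedule$interval_fast) * phi
}

#' Division interval for a realised population size
#'
#' The interval used by the engine when drawing fresh division timers:
#' cells divide fast while the pool is far from its final size and slow
#' down as it fills the niche space ("the closer to the final size the
#' slower the cells became").  Linear interpolation in
#' `psi = clamp((n - n0) / (k_max - n0), 0, 1)`; pools at or below the
#' initial size divide at `interval_fast`.
#'
#' @param n Current population size, cells (vectorised).
#' @param profile A [growth_profile()].
#' @param schedule A [division_schedule()].
#' @return Division interval in days.
#' @export
interval_for_size <- function(n, profile, schedule) {
  stopifnot(inherits(schedule, "division_schedule"))
  if (!is.null(schedule$fixed_interval))
    return(rep(schedule$fixed_interval, length(n)))
  stopifnot(inherits(profile, "growth_profile"))
  n0 <- profile$n_initial
  km <- profile$k_max
  psi <- if (km == n0) rep(1, length(n)) else (n - n0) / (km - n0)
  psi <- pmin(pmax(psi, 0), 1)
  schedule$interval_fast +
    (schedule$interval_slow - schedule$interval_fast) * psi
}

#' Niche-healing profile
#'
#' Health of the bone-marrow niche after irradiation, on a 0-1 scale.
#' `initial_health` is the probability that a cell maintains stemness
#' per daily trial at day 0 (e.g. 0.85 for a 15% degraded niche); the
#' complement `1 - H(t)` is the per-day, fitness-independent
#' probability of leaving the pool.  Health relaxes exponentially
#' toward 1 at rate `healing_coeff` per day.  `initial_health = 1`
#' encodes an undamaged niche (efflux disabled).
#'
#' @param initial_health Niche health at day 0, in (0, 1].
#' @param healing_coeff Healing rate, per day (default 0.005, the
#'   standard healing profile).
#' @return An object of class `niche_healing`.
#' @export
niche_healing <- function(initial_health = 1, healing_coeff = 0.005) {
  stopifnot(is.numeric(initial_health), length(initial_health) == 1L,
            is.numeric(healing_coeff), length(healing_coeff) == 1L)
  if (initial_health <= 0 || initial_health > 1)
    stop("`initial_health` must be in (0, 1]")
  if (healing_coeff < 0) stop("`healing_coeff` must be >= 0")
  structure(list(initial_health = as.numeric(initial_health),
                 healing_coeff = as.numeric(healing_coeff)),
            class = "niche_healing")
}

#' Niche health at a given day
#'
#' `H(t) = 1 - (1 - H0) exp(-c t)`: monotone nondecreasing exponential
#' relaxation from `initial_health` toward a perfect niche.
#'
#' @param t Day index (vectorised), >= 0.
#' @param profile A [niche_healing()].
#' @return Niche health in `[H0, 1]`, same length as `t`.
#' @export
niche_health_at <- function(t, profile) {
  stopifnot(inherits(profile, "niche_healing"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be >= 0")
  1 - (1 - profile$initial_health) * exp(-profile$healing_coeff * t)
}
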