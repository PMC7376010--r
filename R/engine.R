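#' @keywords internal
new_pool <- function(timer = numeric(0), aneu = logical(0)) {
  structure(list(timer = timer, aneu = aneu), class = "cell_pool")
}

#' @export
print.cell_pool <- function(x, ...) {
  cat(sprintf("<cell_pool> %d cells (%d aneuploid)\n",
              length(x$timer), sum(x$aneu)))
  invisible(x)
}

pool_size <- function(pool) length(pool$timer)

# Fresh division timers: Normal(d, d/8) truncated below at half a day,
# so a pathological draw can never schedule a division in the past.
draw_timers <- function(n, d) {
  pmax(stats::rnorm(n, mean = d, sd = d / 8), 0.5)
}

#' Fitness-weighted retention probabilities
#'
#' The per-cell probability of staying in the pool during the capacity
#' cull: `p_i = min(1, K w_i / sum(w))`.  Absent clipping the expected
#' number of survivors is exactly the capacity `K`; when the pool is
#' at or below capacity and all fitness values are equal every
#' probability clips at 1 and no cell is removed.
#'
#' @param fitness Per-cell relative fitness values (> 0).
#' @param capacity Current niche capacity, cells.
#' @return Vector of retention probabilities in `[0, 1]`.
#' @export
retention_probabilities <- function(fitness, capacity) {
  stopifnot(is.numeric(fitness), is.numeric(capacity),
            length(capacity) == 1L, capacity >= 0)
  if (length(fitness) == 0L) return(numeric(0))
  if (any(fitness <= 0)) stop("`fitness` must be positive")
  pmin(1, capacity * fitness / sum(fitness))
}

#' Initialise the transplanted cell pool
#'
#' Creates the engrafted population: `n_initial` euploid cells, each
#' with a division timer drawn from Normal(d0, d0/8) truncated at 0.5
#' day, where d0 is the division interval at the initial population
#' size.
#'
#' @param config A [sim_config()].
#' @return A `cell_pool`.
#' @export
initialize_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- config$growth$n_initial
  d0 <- interval_for_size(n0, config$growth, config$schedule)
  new_pool(timer = draw_timers(n0, d0), aneu = rep(FALSE, n0))
}

#' Advance division timers by one day and divide ripe cells
#'
#' Every timer is decremented by one day; each cell whose timer has
#' reached zero is replaced by two daughters with fresh timers drawn
#' at the interval for the current population size.  Daughters of an
#' aneuploid mother are aneuploid (the state is heritable and
#' absorbing).  A euploid division generates, with probability
#' `aneu_rate`, exactly one aneuploid daughter (uniformly chosen);
#' with `mutation_per_daughter = TRUE` each daughter is instead tested
#' independently.
#'
#' @param pool A `cell_pool`.
#' @param t Day index in `1..duration`.
#' @param config A [sim_config()].
#' @return The updated `cell_pool`.
#' @export
perform_divisions <- function(pool, t, config) {
  n <- pool_size(pool)
  if (n == 0L) return(pool)
  timer <- pool$timer - 1
  ripe <- timer <= 0
  n_div <- sum(ripe)
  if (n_div == 0L) return(new_pool(timer, pool$aneu))
  d_now <- interval_for_size(n, config$growth, config$schedule)
  mother_aneu <- pool$aneu[ripe]
  daughter_aneu <- rep(mother_aneu, each = 2L)
  u <- config$aneu_rate
  if (u > 0) {
    eu <- which(!mother_aneu)
    if (length(eu)) {
      if (config$mutation_per_daughter) {
        base <- 2L * (eu - 1L)
        hit1 <- stats::runif(length(eu)) < u
        hit2 <- stats::runif(length(eu)) < u
        daughter_aneu[base + 1L] <- hit1
        daughter_aneu[base + 2L] <- hit2
      } else {
        hit <- eu[stats::runif(length(eu)) < u]
        if (length(hit)) {
          which_one <- ifelse(stats::runif(length(hit)) < 0.5, 1L, 2L)
          daughter_aneu[2L * (hit - 1L) + which_one] <- TRUE
        }
      }
    }
  }
  new_pool(timer = c(timer[!ripe], draw_timers(2L * n_div, d_now)),
           aneu = c(pool$aneu[!ripe], daughter_aneu))
}

#' Fitness-weighted cull to the current niche capacity
#'
#' Each cell is independently retained with probability
#' `min(1, K(t) w_i / sum(w))` (see [retention_probabilities()]),
#' simulating death or differentiation under fitness-based competition
#' for the limited niche space.  When every probability clips at 1
#' (pool at or under capacity, uniform fitness) the pool is returned
#' unchanged without consuming random numbers.
#'
#' @inheritParams perform_divisions
#' @return The culled `cell_pool`.
#' @export
capacity_cull <- function(pool, t, config) {
  n <- pool_size(pool)
  if (n == 0L) return(pool)
  k <- capacity_at(t, config$growth)
  w <- 1 - config$fitness_cost * pool$aneu
  sw <- sum(w)
  # every p_i clips at 1: nothing to remove, consume no random numbers
  if (k * min(w) >= sw) return(pool)
  # drawing runif < K w/sum(w) realises min(1, .) without materialising it
  keep <- stats::runif(n) < k * w / sw
  new_pool(pool$timer[keep], pool$aneu[keep])
}

#' Fitness-independent niche efflux
#'
#' Each cell is removed with probability `1 - H(t)` where `H(t)` is the
#' niche health, modelling loss of stemness support in the
#' radiation-damaged microenvironment.  A no-op for an undamaged niche
#' (`initial_health = 1`).
#'
#' @inheritParams perform_divisions
#' @return The `cell_pool` after efflux.
#' @export
niche_efflux <- function(pool, t, config) {
  n <- pool_size(pool)
  if (n == 0L) return(pool)
  h <- niche_health_at(t, config$healing)
  if (h >= 1) return(pool)
  keep <- stats::runif(n) < h
  new_pool(pool$timer[keep], pool$aneu[keep])
}

#' One daily update of the simulation
#'
#' Applies, in order, [perform_divisions()], [capacity_cull()] and
#' [niche_efflux()] (the efflux trial is "additional" to the main
#' fitness trial; set `efflux_before_cull` in the configuration to
#' swap the last two), then records the population state.  An empty
#' pool short-circuits: extinction is absorbing and recorded with a
#' missing aneuploid fraction.
#'
#' @inheritParams perform_divisions
#' @return A list with elements `pool` (the updated `cell_pool`) and
#'   `record`, a numeric vector `(n_total, n_aneuploid,
#'   aneu_fraction)` where the fraction is `NA` for an empty pool.
#' @export
daily_update <- function(pool, t, config) {
  stopifnot(inherits(config, "sim_config"), t >= 1,
            t <= config$duration)
  if (pool_size(pool) > 0L) {
    pool <- perform_divisions(pool, t, config)
    if (config$efflux_before_cull) {
      pool <- niche_efflux(pool, t, config)
      pool <- capacity_cull(pool, t, config)
    } else {
      pool <- capacity_cull(pool, t, config)
      pool <- niche_efflux(pool, t, config)
    }
  }
  n <- pool_size(pool)
  a <- sum(pool$aneu)
  list(pool = pool,
       record = c(n_total = n, n_aneuploid = a,
                  aneu_fraction = if (n > 0L) a / n else NA_real_))
}

#' Run one replicate trajectory
#'
#' Simulates a single replicate of `config$duration` daily updates from
#' a freshly seeded random stream.  The trajectory includes the day-0
#' state, so it has `duration + 1` rows and is fully determined by
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this replicate.
#' @return A data frame with columns `day`, `n_total`, `n_aneuploid`,
#'   `aneu_fraction`.
#' @export
run_replicate <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  t_max <- config$duration
  n_total <- integer(t_max + 1L)
  n_aneu <- integer(t_max + 1L)
  frac <- rep(NA_real_, t_max + 1L)
  pool <- initialize_pool(config)
  n_total[1L] <- pool_size(pool)
  n_aneu[1L] <- sum(pool$aneu)
  frac[1L] <- if (n_total[1L] > 0L) n_aneu[1L] / n_total[1L] else NA_real_
  for (t in seq_len(t_max)) {
    step <- daily_update(pool, t, config)
    pool <- step$pool
    n_total[t + 1L] <- as.integer(step$record[[1L]])
    n_aneu[t + 1L] <- as.integer(step$record[[2L]])
    frac[t + 1L] <- step$record[[3L]]
  }
  data.frame(day = 0:t_max, n_total = n_total, n_aneuploid = n_aneu,
             aneu_fraction = frac)
}

#' Run all replicates of one condition
#'
#' Runs `n_replicates` independent trajectories with replicate `i`
#' seeded by `base_seed + i`, and aggregates the per-day replicate-mean
#' aneuploid fraction (arithmetic mean over replicates, ignoring
#' extinct replicates; `NA` if all replicates are extinct on a day).
#'
#' @param config A [sim_config()].
#' @return An object of class `replicate_set`: list with the condition
#'   `label`, `config`, `days` (0..duration) and matrices `n_total`,
#'   `n_aneuploid`, `aneu_fraction` of dimension `(duration + 1) x
#'   n_replicates`, plus the `mean_fraction` curve.
#' @export
run_condition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reps <- config$n_replicates
  t_max <- config$duration
  frac <- matrix(NA_real_, t_max + 1L, reps)
  tot <- matrix(0L, t_max + 1L, reps)
  ane <- matrix(0L, t_max + 1L, reps)
  for (i in seq_len(reps)) {
    tr <- run_replicate(config, config$base_seed + i)
    tot[, i] <- tr$n_total
    ane[, i] <- tr$n_aneuploid
    frac[, i] <- tr$aneu_fraction
  }
  mean_frac <- rowMeans(frac, na.rm = TRUE)
  mean_frac[is.nan(mean_frac)] <- NA_real_
  structure(list(label = config$label, config = config, days = 0:t_max,
                 n_total = tot, n_aneuploid = ane, aneu_fraction = frac,
                 mean_fraction = mean_frac),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %s: %d replicates x %d days\n",
              x$label, ncol(x$aneu_fraction), length(x$days) - 1L))
  pk <- peak_of(x)
  cat(sprintf("  peak mean aneuploid fraction %.4f at day %d; day-%d mean %.4f\n",
              pk["value"], as.integer(pk["day"]),
              max(x$days), x$mean_fraction[length(x$days)]))
  invisible(x)
}

# Peak (value, day) of the replicate-mean aneuploid-fraction curve.
peak_of <- function(rs) {
  m <- rs$mean_fraction
  i <- which.max(m)
  c(value = m[i], day = rs$days[i])
}

#' Long-format trajectory table of a replicate set
#'
#' @param rs A `replicate_set`.
#' @return A data frame with columns `condition`, `replicate`, `day`,
#'   `n_total`, `n_aneuploid`, `aneu_fraction`.
#' @export
trajectory_table <- function(rs) {
  stopifnot(inherits(rs, "replicate_set"))
  reps <- ncol(rs$aneu_fraction)
  days <- rs$days
  data.frame(condition = rs$label,
             replicate = rep(seq_len(reps), each = length(days)),
             day = rep(days, reps),
             n_total = as.vector(rs$n_total),
             n_aneuploid = as.vector(rs$n_aneuploid),
             aneu_fraction = as.vector(rs$aneu_fraction))
}
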