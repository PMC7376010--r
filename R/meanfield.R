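# Probability that a fresh timer ~ Normal(d, d/8), truncated below at
# 0.5 day, schedules the division r daily updates ahead (r = ceiling of
# the drawn timer).  Mass beyond the last bin is folded into it.
division_day_probs <- function(d, n_bins) {
  s <- d / 8
  p <- stats::pnorm(seq_len(n_bins), mean = d, sd = s) -
    stats::pnorm(seq_len(n_bins) - 1, mean = d, sd = s)
  p[1] <- stats::pnorm(1, mean = d, sd = s)
  p[n_bins] <- p[n_bins] + max(0, 1 - sum(p))
  p
}

mf_bins <- function(schedule) {
  dmax <- if (is.null(schedule$fixed_interval)) schedule$interval_slow
          else schedule$fixed_interval
  as.integer(ceiling(dmax * (1 + 5 / 8)) + 2)
}

#' Deterministic mean-field trajectory
#'
#' Expected-value counterpart of the stochastic engine, used as an
#' oracle for replicate means.  The state is the expected number of
#' euploid and aneuploid cells stratified by days remaining until
#' division, so the division flow reproduces the engine's
#' timer-renewal process (including the early synchronised division
#' waves and the lag with which interval changes take effect) rather
#' than assuming an instantaneous per-day rate.  Each day the ripe
#' stratum divides (a euploid division feeds `aneu_rate` expected
#' aneuploid daughters, matching the one-daughter mutation rule),
#' daughters are redistributed over timer strata for the
#' current-population-size interval, and both classes are scaled by
#' the expected capacity-cull retention `min(1, K w_i / W)` and by the
#' niche health `H(t)`.
#'
#' Being deterministic, the mean field carries no drift: it is an
#' oracle for means only, never for peak sharpness or
#' replicate-to-replicate spread in small pools.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `day`, `n_total`, `n_aneuploid`
#'   (real-valued expectations) and `aneu_fraction`.
#' @export
meanfield_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t_max <- config$duration
  u <- config$aneu_rate
  s <- config$fitness_cost
  n_bins <- mf_bins(config$schedule)
  n0 <- config$growth$n_initial
  d0 <- interval_for_size(n0, config$growth, config$schedule)
  m_e <- n0 * division_day_probs(d0, n_bins)
  m_a <- numeric(n_bins)
  n_total <- numeric(t_max + 1L)
  n_aneu <- numeric(t_max + 1L)
  n_total[1L] <- sum(m_e) + sum(m_a)
  n_aneu[1L] <- sum(m_a)
  for (t in seq_len(t_max)) {
    n_pre <- sum(m_e) + sum(m_a)
    if (n_pre > 1e-9) {
      d_now <- interval_for_size(n_pre, config$growth, config$schedule)
      div_e <- m_e[1L]
      div_a <- m_a[1L]
      m_e <- c(m_e[-1L], 0)
      m_a <- c(m_a[-1L], 0)
      converted <- if (config$mutation_per_daughter) 2 * u * div_e
                   else u * div_e
      born_a <- 2 * div_a + converted
      born_e <- 2 * div_e - converted
      p <- division_day_probs(d_now, n_bins)
      m_e <- m_e + born_e * p
      m_a <- m_a + born_a * p
      scale_classes <- function(fe, fa) {
        m_e <<- m_e * fe
        m_a <<- m_a * fa
      }
      cull <- function() {
        k <- capacity_at(t, config$growth)
        w_a <- 1 - s
        big_w <- sum(m_e) + w_a * sum(m_a)
        if (big_w > 0)
          scale_classes(min(1, k / big_w), min(1, k * w_a / big_w))
      }
      efflux <- function() {
        h <- niche_health_at(t, config$healing)
        if (h < 1) scale_classes(h, h)
      }
      if (config$efflux_before_cull) {
        efflux(); cull()
      } else {
        cull(); efflux()
      }
    }
    n_total[t + 1L] <- sum(m_e) + sum(m_a)
    n_aneu[t + 1L] <- sum(m_a)
  }
  frac <- ifelse(n_total > 1e-9, n_aneu / n_total, NA_real_)
  data.frame(day = 0:t_max, n_total = n_total, n_aneuploid = n_aneu,
             aneu_fraction = frac)
}

#' Mutation-selection balance of the daily-update model
#'
#' Equilibrium aneuploid fraction of a pool held at constant capacity
#' with a constant division interval `d`: the fixed point of the
#' two-type expected-value recursion (timer-renewal divisions feeding
#' `u` expected aneuploid daughters per euploid division, followed by
#' the daily fitness-weighted cull), iterated numerically to
#' convergence.
#'
#' Because selection is exerted by the cull at every daily update
#' while aneuploid cells are generated only at divisions, the balance
#' scales inversely with the division interval: to a good
#' approximation it is `u / (2 s d)` for `u` much smaller than `s d`.
#' It is therefore far below the classical per-generation balance
#' `(u/2)/s` that would apply if fitness were tested once per
#' division cycle.
#'
#' @param aneu_rate Aneuploidy generation probability per division
#'   (`u`).
#' @param fitness_cost Aneuploid fitness cost per daily cull (`s`),
#'   in (0, 1).
#' @param interval Division interval `d`, days.
#' @param tol Convergence tolerance on the daily change of the
#'   fraction.
#' @return Equilibrium aneuploid fraction.
#' @examples
#' equilibrium_frequency(0.001, 0.1, 20)
#' @export
equilibrium_frequency <- function(aneu_rate, fitness_cost, interval = 20,
                                  tol = 1e-12) {
  stopifnot(is.numeric(aneu_rate), is.numeric(fitness_cost),
            is.numeric(interval), length(interval) == 1L, interval > 0)
  if (fitness_cost <= 0 || fitness_cost >= 1)
    stop("`fitness_cost` must be in (0, 1): no finite equilibrium otherwise")
  if (aneu_rate < 0 || aneu_rate > 1)
    stop("`aneu_rate` must be in [0, 1]")
  if (aneu_rate == 0) return(0)
  n_bins <- as.integer(ceiling(interval * (1 + 5 / 8)) + 2)
  p <- division_day_probs(interval, n_bins)
  m_e <- p  # unit population at capacity 1
  m_a <- numeric(n_bins)
  w_a <- 1 - fitness_cost
  f <- 0
  f_checkpoint <- -1
  for (iter in seq_len(200000L)) {
    born_a <- 2 * m_a[1L] + aneu_rate * m_e[1L]
    born_e <- (2 - aneu_rate) * m_e[1L]
    m_e <- c(m_e[-1L], 0) + born_e * p
    m_a <- c(m_a[-1L], 0) + born_a * p
    big_w <- sum(m_e) + w_a * sum(m_a)
    m_e <- m_e * min(1, 1 / big_w)
    m_a <- m_a * min(1, w_a / big_w)
    f <- sum(m_a) / (sum(m_e) + sum(m_a))
    # compare across whole interval windows so the early synchronised
    # division waves (and the pre-first-division burn-in) cannot
    # masquerade as convergence
    if (iter %% (10L * n_bins) == 0L) {
      if (f > 0 && abs(f - f_checkpoint) < tol * 10 * n_bins) return(f)
      f_checkpoint <- f
    }
  }
  f
}
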