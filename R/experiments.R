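# Shared sweep values.  The capacity growth coefficients span the
# published 0.008-0.3 range; intermediate values are a package choice.
.growth_coeffs <- c(0.008, 0.016, 0.05, 0.165, 0.3)
.fitness_costs <- c(0.10, 0.05, 0.01, 0.005, 0.001)
.stable_sizes <- c(1000, 5000, 10000, 25000, 50000)
.stable_intervals <- c(3, 10, 20, 40, 60)

#' Known experiment identifiers
#'
#' @return Character vector of the figure-panel sweep ids understood
#'   by [condition_grid()].
#' @export
experiment_ids <- function() {
  c("fig1b", "fig1c", "fig1e", "fig1f", "fig1g", "fig1h", "fig1i",
    "fig2c", "fig2d", "fig2e", "fig3a", "fig3b")
}

#' Parameter grid of a figure-panel experiment
#'
#' Reconstructs each simulated sweep as a named list of fully
#' specified conditions:
#' \describe{
#'   \item{fig1b}{aneuploidy generation rate u in \{0.001, 0.01,
#'     0.05\} under the standard reconstitution.}
#'   \item{fig1c}{aneuploid fitness cost s in \{0.10, 0.05, 0.01,
#'     0.005, 0.001\}.}
#'   \item{fig1e}{capacity growth coefficient in \{0.008, 0.016, 0.05,
#'     0.165, 0.3\}.}
#'   \item{fig1f}{expansion from 1,000 cells to \{1,000; 5,000;
#'     10,000; 25,000; 50,000\} at a fixed 20-day division interval.}
#'   \item{fig1g}{stable population sizes \{1,000 ... 50,000\} at a
#'     fixed 20-day interval.}
#'   \item{fig1h}{stable 10,000-cell population, fixed division
#'     intervals \{3, 10, 20, 40, 60\} days.}
#'   \item{fig1i}{expansion 1,000 to 10,000 cells across the same
#'     fixed intervals.}
#'   \item{fig2c}{niche-healing coefficients \{0.0005, 0.005, 0.05\}
#'     from 85% initial niche health.}
#'   \item{fig2d, fig2e}{fitness-cost sweep under slow (0.0005/day)
#'     and fast (0.05/day) niche healing.}
#'   \item{fig3a, fig3b}{growth-coefficient sweep at 90% and 70%
#'     initial niche health, healing 0.005/day.}
#' }
#' Unswept parameters take the standard values: u = 1% per division,
#' s = 1% (10% for the damaged-niche experiments, where the stronger
#' default cost is appropriate), undamaged niche for the fig1 panels,
#' healing coefficient 0.005/day where fixed, reconstitution from 100
#' toward 10,000 cells at growth 0.165/day with the 3-to-40-day
#' division-interval coupling.
#'
#' @param experiment_id One of [experiment_ids()].
#' @param base_seed Base seed; condition `i` of the grid uses
#'   `base_seed + (i - 1) * 10000` so replicate streams never overlap.
#' @param n_replicates Replicates per condition (default 100).
#' @param duration Simulated days (default 600).
#' @return An object of class `experiment_grid`: list with
#'   `experiment_id` and `conditions` (named list of [sim_config()]).
#' @export
condition_grid <- function(experiment_id, base_seed = 1,
                           n_replicates = 100, duration = 600) {
  if (!is.character(experiment_id) ||
      !experiment_id %in% experiment_ids())
    stop("unknown experiment id; see experiment_ids()")
  std_growth <- function(g = 0.165, k = 10000, n0 = 100)
    growth_profile(n_initial = n0, k_max = k, growth_coeff = g)
  stable <- function(k) growth_profile(n_initial = k, k_max = k,
                                       growth_coeff = 0)
  coupled <- division_schedule()
  fixed <- function(d) division_schedule(fixed_interval = d)
  conds <- switch(
    experiment_id,
    fig1b = lapply(c(0.001, 0.01, 0.05), function(u)
      list(label = sprintf("u=%g", u), aneu_rate = u)),
    fig1c = lapply(.fitness_costs, function(s)
      list(label = sprintf("s=%g", s), fitness_cost = s)),
    fig1e = lapply(.growth_coeffs, function(g)
      list(label = sprintf("g=%g", g), growth = std_growth(g))),
    fig1f = lapply(.stable_sizes, function(k)
      list(label = sprintf("1000to%d", k),
           growth = if (k == 1000) stable(1000)
                    else std_growth(k = k, n0 = 1000),
           schedule = fixed(20))),
    fig1g = lapply(.stable_sizes, function(k)
      list(label = sprintf("K=%d", k), growth = stable(k),
           schedule = fixed(20))),
    fig1h = lapply(.stable_intervals, function(d)
      list(label = sprintf("d=%g", d), growth = stable(10000),
           schedule = fixed(d))),
    fig1i = lapply(.stable_intervals, function(d)
      list(label = sprintf("d=%g", d), growth = std_growth(n0 = 1000),
           schedule = fixed(d))),
    fig2c = lapply(c(0.0005, 0.005, 0.05), function(cc)
      list(label = sprintf("heal=%g", cc), fitness_cost = 0.1,
           healing = niche_healing(0.85, cc))),
    fig2d = lapply(.fitness_costs, function(s)
      list(label = sprintf("s=%g", s), fitness_cost = s,
           healing = niche_healing(0.85, 0.0005))),
    fig2e = lapply(.fitness_costs, function(s)
      list(label = sprintf("s=%g", s), fitness_cost = s,
           healing = niche_healing(0.85, 0.05))),
    fig3a = lapply(.growth_coeffs, function(g)
      list(label = sprintf("g=%g", g), fitness_cost = 0.1,
           growth = std_growth(g), healing = niche_healing(0.9, 0.005))),
    fig3b = lapply(.growth_coeffs, function(g)
      list(label = sprintf("g=%g", g), fitness_cost = 0.1,
           growth = std_growth(g), healing = niche_healing(0.7, 0.005)))
  )
  configs <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    spec <- conds[[i]]
    args <- list(growth = spec$growth %||% std_growth(),
                 schedule = spec$schedule %||% coupled,
                 healing = spec$healing %||% niche_healing(),
                 aneu_rate = spec$aneu_rate %||% 0.01,
                 fitness_cost = spec$fitness_cost %||% 0.01,
                 duration = duration, n_replicates = n_replicates,
                 base_seed = base_seed + (i - 1) * 10000,
                 label = spec$label)
    configs[[i]] <- do.call(sim_config, args)
  }
  names(configs) <- vapply(conds, `[[`, character(1), "label")
  if (anyDuplicated(names(configs)))
    stop("condition labels must be unique")
  structure(list(experiment_id = experiment_id, conditions = configs),
            class = "experiment_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("<experiment_grid> %s: %d conditions (%s)\n",
              x$experiment_id, length(x$conditions),
              paste(names(x$conditions), collapse = ", ")))
  invisible(x)
}

#' Run a figure-panel experiment end to end
#'
#' Runs every condition of the grid, compares the conditions with the
#' per-day Kruskal-Wallis procedure (when the grid has two or more
#' conditions) and summarises each condition.  When `out_dir` is
#' given, writes `trajectories.csv`, `means.csv`, `pvalues.csv`,
#' `summary.csv` and a `manifest.json` under
#' `out_dir/<experiment_id>/`.
#'
#' @param grid An `experiment_grid` from [condition_grid()], or an
#'   experiment id string.
#' @param out_dir Optional output directory.
#' @param verbose Print per-condition progress.
#' @return A list with `replicate_sets`, `pvalues` (a `pvalue_curve`
#'   or `NULL`) and `summary` (see [summarize_experiment()]).
#' @export
run_experiment <- function(grid, out_dir = NULL, verbose = FALSE) {
  if (is.character(grid)) grid <- condition_grid(grid)
  stopifnot(inherits(grid, "experiment_grid"))
  sets <- vector("list", length(grid$conditions))
  names(sets) <- names(grid$conditions)
  for (i in seq_along(grid$conditions)) {
    cfg <- grid$conditions[[i]]
    if (verbose)
      message(sprintf("[%s] condition %s (%d replicates)",
                      grid$experiment_id, cfg$label, cfg$n_replicates))
    sets[[i]] <- tryCatch(run_condition(cfg), error = function(e)
      stop(sprintf("condition '%s' failed: %s", cfg$label,
                   conditionMessage(e)), call. = FALSE))
  }
  pv <- if (length(sets) >= 2L) pvalue_curve(sets) else NULL
  summ <- summarize_experiment(sets)
  if (!is.null(out_dir))
    write_experiment(grid, sets, pv, summ, out_dir)
  list(replicate_sets = sets, pvalues = pv, summary = summ)
}

#' Summary table of completed conditions
#'
#' @param replicate_sets A list of `replicate_set` objects (or the
#'   result list of [run_experiment()]).
#' @return A data frame with one row per condition: peak of the
#'   replicate-mean aneuploid fraction, day of the peak, final-day
#'   mean fraction, and the across-replicate standard deviations at
#'   the peak day and the final day.
#' @export
summarize_experiment <- function(replicate_sets) {
  if (!is.null(replicate_sets$replicate_sets))
    replicate_sets <- replicate_sets$replicate_sets
  stopifnot(length(replicate_sets) >= 1L,
            all(vapply(replicate_sets, inherits, logical(1),
                       "replicate_set")))
  rows <- lapply(replicate_sets, function(rs) {
    pk <- peak_of(rs)
    i_pk <- which(rs$days == pk[["day"]])
    i_end <- length(rs$days)
    data.frame(condition = rs$label,
               peak_mean_fraction = pk[["value"]],
               peak_day = as.integer(pk[["day"]]),
               final_mean_fraction = rs$mean_fraction[i_end],
               sd_at_peak = stats::sd(rs$aneu_fraction[i_pk, ],
                                      na.rm = TRUE),
               sd_at_final = stats::sd(rs$aneu_fraction[i_end, ],
                                       na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
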