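# Shared builders and a per-session cache so the heavyweight
# acceptance-scale conditions are simulated once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fun) {
  if (!exists(key, envir = .sim_cache)) assign(key, fun(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

stable_growth <- function(k) growth_profile(k, k, 0)
fixed_sched <- function(d) division_schedule(fixed_interval = d)

mean_at <- function(rs, day) {
  v <- rs$aneu_fraction[day + 1L, ]
  mean(v, na.rm = TRUE)
}

se_at <- function(rs, day) {
  v <- rs$aneu_fraction[day + 1L, ]
  stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
}

se_total_at <- function(rs, day) {
  v <- rs$n_total[day + 1L, ]
  stats::sd(v) / sqrt(length(v))
}

# tiny expanding condition used across io/stats/engine tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(growth = growth_profile(20, 200, 0.165),
                   schedule = division_schedule(3, 20),
                   duration = 40, n_replicates = 3, base_seed = 7,
                   label = "tiny")
  do.call(sim_config, utils::modifyList(defaults, args))
}
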