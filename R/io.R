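.condition_keys <- c("label", "aneu_rate", "fitness_cost", "n_initial",
                     "k_max", "growth_coeff", "interval_fast",
                     "interval_slow", "fixed_interval", "initial_health",
                     "healing_coeff", "duration", "replicates", "seed",
                     "efflux_before_cull", "mutation_per_daughter")
.top_keys <- c("conditions", "experiment", .condition_keys)

condition_from_list <- function(lst, shared = list(), where = "condition") {
  bad <- setdiff(names(lst), .condition_keys)
  if (length(bad))
    stop(sprintf("unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", ")))
  get <- function(key, default) lst[[key]] %||% shared[[key]] %||% default
  growth <- growth_profile(n_initial = get("n_initial", 100),
                           k_max = get("k_max", 10000),
                           growth_coeff = get("growth_coeff", 0.165))
  schedule <- division_schedule(interval_fast = get("interval_fast", 3),
                                interval_slow = get("interval_slow", 40),
                                fixed_interval = get("fixed_interval", NULL))
  healing <- niche_healing(initial_health = get("initial_health", 1),
                           healing_coeff = get("healing_coeff", 0.005))
  sim_config(growth = growth, schedule = schedule, healing = healing,
             aneu_rate = get("aneu_rate", 0.01),
             fitness_cost = get("fitness_cost", 0.01),
             duration = get("duration", 600),
             n_replicates = get("replicates", 100),
             base_seed = get("seed", 1),
             label = get("label", "condition"),
             efflux_before_cull = get("efflux_before_cull", FALSE),
             mutation_per_daughter = get("mutation_per_daughter", FALSE))
}

#' Load a simulation configuration file
#'
#' Reads a YAML description of one or more simulation conditions.  A
#' file with top-level parameter keys describes a single condition; a
#' `conditions:` list describes several (top-level keys then act as
#' shared defaults); an `experiment: <id>` key resolves a named
#' figure-panel sweep via [condition_grid()].  Unknown keys and
#' invariant violations are rejected with the offending key named.
#' All omitted parameters fall back to the standard condition
#' (u = 1% per division, s = 1%, 600 days, 100 replicates, undamaged
#' niche, reconstitution from 100 toward 10,000 cells).
#'
#' @param path Path to a YAML file.
#' @return A [sim_config()], a named list of them, or an
#'   `experiment_grid`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  if (!is.list(lst)) lst <- list()
  bad <- setdiff(names(lst), .top_keys)
  if (length(bad))
    stop("unknown top-level key(s): ", paste(bad, collapse = ", "))
  if (!is.null(lst$experiment)) {
    return(condition_grid(lst$experiment,
                          base_seed = lst$seed %||% 1,
                          n_replicates = lst$replicates %||% 100,
                          duration = lst$duration %||% 600))
  }
  if (!is.null(lst$conditions)) {
    shared <- lst[setdiff(names(lst), "conditions")]
    configs <- lapply(seq_along(lst$conditions), function(i)
      condition_from_list(lst$conditions[[i]] %||% list(), shared,
                          where = sprintf("conditions[%d]", i)))
    names(configs) <- vapply(configs, `[[`, character(1), "label")
    return(configs)
  }
  condition_from_list(lst, where = "config")
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON serialisation,
#' so the hash is invariant to key order in the source file.
#'
#' @param config A [sim_config()].
#' @return A 32-character hash string.
#' @export
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canonical)
      if (!is.null(names(x))) x <- x[order(names(x))]
    }
    x
  }
  json <- jsonlite::toJSON(canonical(unclass_deep(config)),
                           auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

.traj_cols <- c("condition", "replicate", "day", "n_total",
                "n_aneuploid", "aneu_fraction")

#' Write trajectories to a long-format CSV
#'
#' Columns `condition, replicate, day, n_total, n_aneuploid,
#' aneu_fraction`; missing fractions (extinct replicates) are written
#' as empty fields.  A comment header records the config hash and base
#' seed of each condition.
#'
#' @param x A `replicate_set` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  if (inherits(x, "replicate_set")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "replicate_set")))
  header <- vapply(x, function(rs) {
    cfg <- rs$config
    sprintf("# condition=%s config_hash=%s base_seed=%s", rs$label,
            if (is.null(cfg)) "NA" else config_hash(cfg),
            if (is.null(cfg)) "NA" else format(cfg$base_seed))
  }, character(1))
  tab <- do.call(rbind, lapply(x, trajectory_table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# aneusim trajectories v%s",
                       as.character(utils::packageVersion("aneusim"))),
               header), con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read trajectories written by [write_trajectories()]
#'
#' Rebuilds one `replicate_set` per condition.  Counts round-trip
#' exactly; fractions round-trip to full printed precision.  Missing
#' fraction fields are parsed as `NA`, never as zero.  Malformed input
#' is rejected naming the missing column or offending row.
#'
#' @param path CSV path.
#' @return A named list of `replicate_set` objects (their `config`
#'   field is `NULL`).
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(condition = "character"))
  missing_cols <- setdiff(.traj_cols, names(tab))
  if (length(missing_cols))
    stop("malformed trajectory CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (col in c("replicate", "day", "n_total", "n_aneuploid")) {
    if (anyNA(tab[[col]]))
      stop(sprintf("malformed trajectory CSV: missing %s at row %d",
                   col, which(is.na(tab[[col]]))[1L]))
  }
  sets <- lapply(split(tab, tab$condition), function(d) {
    reps <- sort(unique(d$replicate))
    days <- sort(unique(d$day))
    d <- d[order(d$replicate, d$day), ]
    if (nrow(d) != length(reps) * length(days))
      stop("malformed trajectory CSV: ragged replicate/day grid for ",
           "condition ", d$condition[1L])
    shape <- function(col) matrix(d[[col]], length(days), length(reps))
    frac <- shape("aneu_fraction")
    mean_frac <- rowMeans(frac, na.rm = TRUE)
    mean_frac[is.nan(mean_frac)] <- NA_real_
    structure(list(label = d$condition[1L], config = NULL, days = days,
                   n_total = shape("n_total"),
                   n_aneuploid = shape("n_aneuploid"),
                   aneu_fraction = frac, mean_fraction = mean_frac),
              class = "replicate_set")
  })
  sets[unique(tab$condition)]
}

#' Write a p-value curve to CSV
#'
#' Writes columns `day, p_value` plus a one-line companion file
#' `<path>.area_ratio.txt` holding the area-under-p-curve ratio.
#'
#' @param curve A `pvalue_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pvalues <- function(curve, path) {
  stopifnot(inherits(curve, "pvalue_curve"))
  utils::write.csv(data.frame(day = curve$day, p_value = curve$p_value),
                   path, row.names = FALSE, na = "")
  writeLines(sprintf("area_ratio %.15g", curve$area_ratio),
             paste0(path, ".area_ratio.txt"))
  invisible(path)
}

write_experiment <- function(grid, sets, pv, summ, out_dir) {
  dir <- file.path(out_dir, grid$experiment_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(sets, file.path(dir, "trajectories.csv"))
  means <- do.call(rbind, lapply(sets, function(rs)
    data.frame(condition = rs$label, day = rs$days,
               mean_fraction = rs$mean_fraction)))
  utils::write.csv(means, file.path(dir, "means.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(pv)) write_pvalues(pv, file.path(dir, "pvalues.csv"))
  utils::write.csv(summ, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    tool = "aneusim",
    version = as.character(utils::packageVersion("aneusim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    experiment = grid$experiment_id,
    conditions = lapply(grid$conditions, function(cfg)
      list(label = cfg$label, base_seed = cfg$base_seed,
           config_hash = config_hash(cfg))),
    outputs = c("trajectories.csv", "means.csv",
                if (!is.null(pv)) "pvalues.csv", "summary.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Small deterministic desk-test configurations
#'
#' Named fixtures used in tests and examples:
#' \describe{
#'   \item{tiny}{20 cells expanding to a 200-niche capacity, 60 days,
#'     5 replicates; runs in well under a second.}
#'   \item{balance}{stable 2,000-cell pool, fixed 10-day interval,
#'     u = 0.001, s = 0.1, 2,000 days: the long-run mean aneuploid
#'     fraction settles at [equilibrium_frequency()] (about 9e-4).}
#'   \item{null}{two identical conditions differing only in seed;
#'     their p-value curve is uniform, so the area ratio is close to
#'     0.5.}
#' }
#'
#' @param name Fixture name.
#' @return A [sim_config()], or a list of two for `"null"`.
#' @export
make_fixture <- function(name) {
  switch(
    name,
    tiny = sim_config(
      growth = growth_profile(20, 200, 0.165),
      schedule = division_schedule(3, 20),
      duration = 60, n_replicates = 5, base_seed = 101,
      label = "tiny"),
    balance = sim_config(
      growth = growth_profile(2000, 2000, 0),
      schedule = division_schedule(fixed_interval = 10),
      aneu_rate = 0.001, fitness_cost = 0.1,
      duration = 2000, n_replicates = 20, base_seed = 202,
      label = "balance"),
    null = list(
      a = sim_config(
        growth = growth_profile(1000, 1000, 0),
        schedule = division_schedule(fixed_interval = 5),
        aneu_rate = 0.01, fitness_cost = 0.1,
        duration = 600, n_replicates = 40, base_seed = 303,
        label = "null_a"),
      b = sim_config(
        growth = growth_profile(1000, 1000, 0),
        schedule = division_schedule(fixed_interval = 5),
        aneu_rate = 0.01, fitness_cost = 0.1,
        duration = 600, n_replicates = 40, base_seed = 80303,
        label = "null_b")),
    stop("unknown fixture: ", name)
  )
}
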