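#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction, with the p-value taken
#' from the upper tail of the chi-square distribution with
#' `length(groups) - 1` degrees of freedom (the standard approximation
#' for the 100-replicate group sizes used here).  The degenerate case
#' in which every observation is identical is defined to return
#' `p = 1`: the compared samples behave identically.
#'
#' @param groups A list of two or more nonempty numeric vectors.
#' @return A list with elements `statistic` (tie-corrected H), `df`
#'   and `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least two samples")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (!is.numeric(x) || anyNA(x)) stop("groups must be numeric without NA")
  n <- length(x)
  k <- length(groups)
  r <- rank(x)
  grp <- rep.int(seq_len(k), sizes)
  rank_sums <- vapply(split(r, grp), sum, numeric(1))
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) {
    # all observations tied: identical behaviour by convention
    return(list(statistic = 0, df = k - 1L, p_value = 1))
  }
  h <- h / correction
  list(statistic = h, df = k - 1L,
       p_value = stats::pchisq(h, df = k - 1L, lower.tail = FALSE))
}

#' Per-day Kruskal-Wallis p-value curve across conditions
#'
#' For each update day `1..T`, compares the replicate aneuploid
#' fractions of two or more conditions with [kruskal_wallis()].
#' Extinct replicates contribute no observation on a day; a day on
#' which any condition has all replicates extinct yields a missing
#' p-value, excluded from both numerator and denominator of the area
#' ratio.
#'
#' @param conditions A list of two or more `replicate_set` objects
#'   sharing the same duration.
#' @return An object of class `pvalue_curve`: list with `day`
#'   (`1..T`), `p_value` and the `area_ratio` summary (see
#'   [pvalue_area_ratio()]).
#' @export
pvalue_curve <- function(conditions) {
  if (!is.list(conditions) || length(conditions) < 2L)
    stop("need at least two conditions to compare")
  if (!all(vapply(conditions, inherits, logical(1), "replicate_set")))
    stop("`conditions` must be a list of replicate_set objects")
  t_max <- length(conditions[[1L]]$days) - 1L
  if (!all(vapply(conditions, function(x) length(x$days) - 1L,
                  integer(1)) == t_max))
    stop("all conditions must share the same duration")
  p <- rep(NA_real_, t_max)
  mats <- lapply(conditions, `[[`, "aneu_fraction")
  for (t in seq_len(t_max)) {
    groups <- lapply(mats, function(m) {
      v <- m[t + 1L, ]
      v[!is.na(v)]
    })
    if (any(lengths(groups) == 0L)) next
    p[t] <- kruskal_wallis(groups)$p_value
  }
  structure(list(day = seq_len(t_max), p_value = p,
                 area_ratio = mean(p, na.rm = TRUE)),
            class = "pvalue_curve")
}

#' @export
print.pvalue_curve <- function(x, ...) {
  cat(sprintf("<pvalue_curve> %d days, area ratio %.4f (%d missing days)\n",
              length(x$day), x$area_ratio, sum(is.na(x$p_value))))
  invisible(x)
}

#' Normalised area under the p-value curve
#'
#' The paper-style scalar dissimilarity of the compared conditions:
#' the area under the per-day p-value curve divided by the total chart
#' area (1 x T), i.e. the mean of the available daily p-values with
#' unit day spacing.  1 means the conditions behaved identically
#' throughout; values near 0 mean their clonal dynamics were distinct
#' at essentially every time point.
#'
#' @param curve A `pvalue_curve`.
#' @return The area ratio, a fraction in `[0, 1]`.
#' @export
pvalue_area_ratio <- function(curve) {
  stopifnot(inherits(curve, "pvalue_curve"))
  p <- curve$p_value[!is.na(curve$p_value)]
  if (length(p) == 0L) stop("curve has no available p-values")
  mean(p)
}
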