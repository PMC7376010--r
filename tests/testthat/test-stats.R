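test_that("the H statistic and chi-square p-value match hand computation", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-10)   # = 3.8571
  expect_equal(kw$p_value, 0.049535, tolerance = 1e-4)
  expect_equal(kw$df, 1L)
})

test_that("our Kruskal-Wallis agrees with the reference implementation", {
  set.seed(99)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:8, sample(5:20, 1), replace = TRUE))  # heavy ties
    ours <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_len(k), lengths(groups)))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and invalid inputs follow the contract", {
  # all observations identical: identical behaviour, p = 1
  expect_equal(kruskal_wallis(list(rep(2, 5), rep(2, 7)))$p_value, 1)
  expect_error(kruskal_wallis(list(1:5)), "two")
  expect_error(kruskal_wallis(list(1:5, numeric(0))), "nonempty")
  expect_error(kruskal_wallis(list(1:5, c(1, NA))), "NA")
})

test_that("p-values are invariant under monotone transforms and group order", {
  rs_a <- cached_run("tiny_a", function()
    run_condition(tiny_config(n_replicates = 6, duration = 30,
                              aneu_rate = 0.05, base_seed = 21)))
  rs_b <- cached_run("tiny_b", function()
    run_condition(tiny_config(n_replicates = 6, duration = 30,
                              aneu_rate = 0.2, base_seed = 91,
                              label = "tiny_b")))
  pv <- pvalue_curve(list(rs_a, rs_b))
  expect_equal(length(pv$p_value), 30)
  # permutation of conditions
  pv_swap <- pvalue_curve(list(rs_b, rs_a))
  expect_equal(pv$p_value, pv_swap$p_value)
  # strictly monotone transform of the fractions leaves ranks unchanged
  warp <- function(rs) { rs$aneu_fraction <- exp(3 * rs$aneu_fraction); rs }
  pv_warp <- pvalue_curve(list(warp(rs_a), warp(rs_b)))
  expect_equal(pv$p_value, pv_warp$p_value)
})

test_that("identical replicate sets give p = 1 throughout and area 1", {
  rs <- cached_run("tiny_a", function()
    run_condition(tiny_config(n_replicates = 6, duration = 30,
                              aneu_rate = 0.05, base_seed = 21)))
  pv <- pvalue_curve(list(rs, rs))
  expect_true(all(pv$p_value == 1))
  expect_equal(pvalue_area_ratio(pv), 1.0)
})

test_that("days on which a condition is fully extinct are excluded", {
  rs_a <- cached_run("tiny_a", function()
    run_condition(tiny_config(n_replicates = 6, duration = 30,
                              aneu_rate = 0.05, base_seed = 21)))
  rs_dead <- rs_a
  rs_dead$label <- "dead"
  rs_dead$aneu_fraction[12:31, ] <- NA  # extinct from day 11 on
  pv <- pvalue_curve(list(rs_a, rs_dead))
  expect_true(all(is.na(pv$p_value[11:30])))
  expect_equal(pv$area_ratio, mean(pv$p_value[1:10]))
  expect_equal(pvalue_area_ratio(pv), pv$area_ratio)
})

test_that("the area ratio is the mean height of the p-value curve", {
  flat <- structure(list(day = 1:600, p_value = rep(0.5, 600),
                         area_ratio = 0.5), class = "pvalue_curve")
  expect_equal(pvalue_area_ratio(flat), 0.5)
  ones <- structure(list(day = 1:600, p_value = rep(1, 600),
                         area_ratio = 1), class = "pvalue_curve")
  expect_equal(pvalue_area_ratio(ones), 1.0)
  zeros <- structure(list(day = 1:600, p_value = rep(0, 600),
                          area_ratio = 0), class = "pvalue_curve")
  expect_equal(pvalue_area_ratio(zeros), 0.0)
  empty <- structure(list(day = 1:5, p_value = rep(NA_real_, 5),
                          area_ratio = NaN), class = "pvalue_curve")
  expect_error(pvalue_area_ratio(empty), "no available")
})

test_that("null p-values are uniformly distributed", {
  set.seed(13)
  p <- replicate(300, {
    kruskal_wallis(list(rnorm(30), rnorm(30)))$p_value
  })
  # mean of 300 independent null p-values; SE ~ 0.0167
  expect_gt(mean(p), 0.45)
  expect_lt(mean(p), 0.55)
})

test_that("mismatched durations are rejected", {
  rs_a <- cached_run("tiny_a", function()
    run_condition(tiny_config(n_replicates = 6, duration = 30,
                              aneu_rate = 0.05, base_seed = 21)))
  rs_short <- run_condition(tiny_config(n_replicates = 3, duration = 10,
                                        base_seed = 31, label = "short"))
  expect_error(pvalue_curve(list(rs_a, rs_short)), "duration")
  expect_error(pvalue_curve(list(rs_a)), "two")
})
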