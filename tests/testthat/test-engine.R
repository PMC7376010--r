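test_that("retention probabilities implement fitness-weighted culling", {
  # two cells competing for one niche: probabilities split by fitness
  expect_equal(retention_probabilities(c(1, 0.9), 1),
               c(1 / 1.9, 0.9 / 1.9), tolerance = 1e-12)
  # at or below capacity with uniform fitness nothing is removed
  expect_equal(retention_probabilities(rep(1, 50), 50), rep(1, 50))
  expect_equal(retention_probabilities(rep(1, 50), 80), rep(1, 50))
  # overfull pool: expected survivors equal the capacity exactly
  p <- retention_probabilities(rep(1, 12000), 10000)
  expect_equal(unique(p), 10000 / 12000, tolerance = 1e-12)
  expect_equal(sum(p), 10000)
  expect_error(retention_probabilities(c(1, 0), 10), "positive")
})

test_that("capacity cull removes the expected number of cells", {
  cfg <- sim_config(growth = stable_growth(10000),
                    schedule = fixed_sched(20), label = "cull")
  set.seed(42)
  pool <- structure(list(timer = rep(5, 12000),
                         aneu = rep(FALSE, 12000)), class = "cell_pool")
  survivors <- replicate(20, length(capacity_cull(pool, 1, cfg)$timer))
  # 99.9% binomial envelope around the capacity for each draw
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 12000, 10000 / 12000)
  expect_true(all(survivors >= bounds[1] & survivors <= bounds[2]))
  # pool at capacity with uniform fitness is untouched
  at_cap <- structure(list(timer = rep(5, 10000),
                           aneu = rep(FALSE, 10000)), class = "cell_pool")
  expect_identical(capacity_cull(at_cap, 1, cfg), at_cap)
})

test_that("initial pool is euploid with timers drawn at the fast interval", {
  cfg <- sim_config(growth = growth_profile(10000, 20000, 0.165),
                    schedule = division_schedule(3, 40), label = "init")
  set.seed(1)
  pool <- initialize_pool(cfg)
  expect_equal(length(pool$timer), 10000)
  expect_false(any(pool$aneu))
  expect_true(all(pool$timer >= 0.5))
  # sample mean of 10,000 Normal(3, 3/8) draws
  expect_lt(abs(mean(pool$timer) - 3), 3 * (3 / 8) / sqrt(10000))
  expect_equal(length(initialize_pool(tiny_config())$timer), 20)
})

test_that("divisions replace ripe cells by daughter pairs", {
  cfg <- tiny_config(aneu_rate = 0)
  set.seed(2)
  pool <- structure(list(timer = c(0.3, 0.8, 5, 7),
                         aneu = rep(FALSE, 4)), class = "cell_pool")
  out <- perform_divisions(pool, 1, cfg)
  # two cells ripen (timers 0.3 and 0.8 fall to <= 0); each leaves 2 daughters
  expect_equal(length(out$timer), 6)
  expect_true(all(c(4, 6) %in% out$timer))  # survivors decremented, kept
  expect_true(all(out$timer >= 0.5))        # fresh timers truncated
  expect_false(any(out$aneu))               # no mutation source
})

test_that("forced mutation converts exactly one daughter per division", {
  cfg <- tiny_config(aneu_rate = 1)
  set.seed(3)
  pool <- structure(list(timer = rep(0.5, 40), aneu = rep(FALSE, 40)),
                    class = "cell_pool")
  out <- perform_divisions(pool, 1, cfg)
  expect_equal(length(out$timer), 80)
  expect_equal(sum(out$aneu), 40)
  # daughters of aneuploid mothers are all aneuploid (absorbing state)
  pool_a <- structure(list(timer = rep(0.5, 30), aneu = rep(TRUE, 30)),
                      class = "cell_pool")
  out_a <- perform_divisions(pool_a, 1, tiny_config(aneu_rate = 0.5))
  expect_true(all(out_a$aneu))
})

test_that("per-division mutation counts stay within binomial bounds", {
  cfg <- tiny_config(aneu_rate = 0.01)
  set.seed(4)
  pool <- structure(list(timer = rep(0.5, 10000),
                         aneu = rep(FALSE, 10000)), class = "cell_pool")
  out <- perform_divisions(pool, 1, cfg)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.01)
  expect_gte(sum(out$aneu), bounds[1])
  expect_lte(sum(out$aneu), bounds[2])
  # the per-daughter sensitivity switch doubles the expected yield
  cfg2 <- tiny_config(aneu_rate = 0.01, mutation_per_daughter = TRUE)
  out2 <- perform_divisions(pool, 1, cfg2)
  bounds2 <- qbinom(c(0.005, 0.995), 20000, 0.01)
  expect_gte(sum(out2$aneu), bounds2[1])
  expect_lte(sum(out2$aneu), bounds2[2])
})

test_that("niche efflux removes cells at rate 1 - H independent of fitness", {
  intact <- tiny_config()
  pool <- structure(list(timer = rep(5, 10000), aneu = rep(FALSE, 10000)),
                    class = "cell_pool")
  expect_identical(niche_efflux(pool, 1, intact), pool)
  damaged <- tiny_config(healing = niche_healing(0.85, 0))
  set.seed(5)
  kept <- length(niche_efflux(pool, 1, damaged)$timer)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.85)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])
})

test_that("extinction is absorbing and recorded as a missing fraction", {
  empty <- structure(list(timer = numeric(0), aneu = logical(0)),
                     class = "cell_pool")
  step <- daily_update(empty, 1, tiny_config())
  expect_equal(length(step$pool$timer), 0)
  expect_equal(unname(step$record[1:2]), c(0, 0))
  expect_true(is.na(step$record[[3]]))
})

test_that("replicates are deterministic given (config, seed)", {
  cfg <- tiny_config()
  expect_identical(run_replicate(cfg, 99), run_replicate(cfg, 99))
  expect_false(identical(run_replicate(cfg, 99), run_replicate(cfg, 100)))
  tr <- run_replicate(tiny_config(duration = 600), 1)
  expect_equal(nrow(tr), 601)
})

test_that("no mutation source means no aneuploid cells, ever", {
  tr <- run_replicate(tiny_config(aneu_rate = 0, duration = 100), 8)
  expect_true(all(tr$n_aneuploid == 0))
  expect_true(all(tr$aneu_fraction == 0))
})

test_that("trajectories conserve counts and keep fractions in [0, 1]", {
  set.seed(77)
  for (i in 1:4) {
    cfg <- tiny_config(aneu_rate = runif(1, 0, 0.1),
                       fitness_cost = runif(1, 0, 0.2),
                       healing = niche_healing(runif(1, 0.8, 1), 0.01),
                       duration = 50)
    tr <- run_replicate(cfg, 1000 + i)
    expect_true(all(tr$n_aneuploid <= tr$n_total))
    expect_true(all(tr$n_aneuploid >= 0))
    ok <- !is.na(tr$aneu_fraction)
    expect_true(all(tr$aneu_fraction[ok] >= 0 & tr$aneu_fraction[ok] <= 1))
    expect_equal(tr$aneu_fraction[ok],
                 (tr$n_aneuploid / tr$n_total)[ok])
  }
})

test_that("a condition stacks replicates and averages their fractions", {
  cfg <- tiny_config(n_replicates = 4, duration = 30)
  rs <- run_condition(cfg)
  expect_equal(dim(rs$aneu_fraction), c(31, 4))
  expect_equal(rs$mean_fraction, rowMeans(rs$aneu_fraction))
  # a single replicate's mean curve is that replicate
  one <- run_condition(tiny_config(n_replicates = 1, duration = 30))
  expect_equal(one$mean_fraction, one$aneu_fraction[, 1])
  # replicate seeds derive from the base seed: replicate i uses base + i
  tr2 <- run_replicate(cfg, cfg$base_seed + 2)
  expect_equal(rs$aneu_fraction[, 2], tr2$aneu_fraction)
})

test_that("the long-format trajectory table matches the matrices", {
  rs <- run_condition(tiny_config(n_replicates = 3, duration = 20))
  tab <- trajectory_table(rs)
  expect_equal(nrow(tab), 3 * 21)
  expect_equal(names(tab), c("condition", "replicate", "day", "n_total",
                             "n_aneuploid", "aneu_fraction"))
  expect_equal(tab$n_total[tab$replicate == 2], rs$n_total[, 2])
})
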