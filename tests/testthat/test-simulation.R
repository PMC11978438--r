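test_that("runs are bit-reproducible given the master seed", {
  cfg <- sim_config(n = 30, k = 3, r = 0.4, horizon = 200, window = 50,
                    seed = 17)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$agents, s2$agents)
  r1 <- run_simulation(cfg, engine = "r")
  r2 <- run_simulation(cfg, engine = "r")
  expect_identical(r1$metrics, r2$metrics)
  s3 <- run_simulation(update_config(cfg, seed = 18))
  expect_false(identical(s1$metrics, s3$metrics))
})

test_that("both engines satisfy the exact budget ledger and state invariants", {
  cfg <- sim_config(n = 12, k = 3, r = 0.4, horizon = 150, window = 30,
                    seed = 23)
  for (engine in c("cpp", "r")) {
    sim <- run_simulation(cfg, engine = engine, detail = TRUE)
    expect_ledger(sim)
    # per-step ledger from the snapshots, for every agent at every step
    sn <- sim$snapshots
    spent <- cfg$cost_social * sn$n_social + cfg$cost_rec * sn$n_rec +
      cfg$cost_innovate * sn$n_innov
    expect_equal(cfg$budget - sn$budget, spent)
    expect_true(all(sn$budget >= 0))
    # repertoires: contiguous, viable, and Z recomputes exactly
    for (i in seq_len(cfg$n)) {
      rep <- sim$repertoires[[i]]
      expect_identical(nrow(rep), sim$agents$max_level[i])
      expect_true(all(rep[, "payoff"] > 0))
      expect_equal(sum(rep[, "payoff"]), sim$agents$cumulative_payoff[i])
    }
    # world consistency: repertoire payoffs match the global payoff map
    pm <- sim$payoff_map
    key <- function(b, l) paste0(b, ":", l)
    world <- stats::setNames(pm$payoff, key(pm$branch, pm$level))
    for (i in seq_len(cfg$n)) {
      rep <- sim$repertoires[[i]]
      if (nrow(rep) == 0) next
      expect_identical(unname(world[key(rep[, "branch"],
                                        seq_len(nrow(rep)))]),
                       as.integer(rep[, "payoff"]))
    }
    # archive monotonicity and metric sanity
    m <- sim$metrics
    expect_true(all(diff(m$distinct_traits) >= 0))
    expect_true(all(m$mean_payoff >= 0) && all(m$mean_level >= 0))
    expect_equal(m$mean_level, rowMeans(sn$max_level))
  }
})

test_that("the compiled and reference engines agree statistically", {
  run_batch <- function(engine, reps) {
    t(vapply(seq_len(reps), function(j) {
      cfg <- sim_config(n = 15, k = 3, r = 0.3, horizon = 80, window = 20,
                        seed = 5000 + j)
      s <- stationary_summary(run_simulation(cfg, engine = engine))
      c(Z = s$Z_max, L = s$L_max, T = s$T_max)
    }, numeric(3)))
  }
  a <- run_batch("cpp", 30)
  b <- run_batch("r", 30)
  for (col in c("Z", "L", "T")) {
    pooled_se <- sqrt(stats::var(a[, col]) / nrow(a) +
                      stats::var(b[, col]) / nrow(b))
    expect_lt(abs(mean(a[, col]) - mean(b[, col])), 4 * pooled_se)
  }
})

test_that("the replacement process averages q * N agents per step", {
  cfg <- sim_config(n = 50, k = 2, r = 0, horizon = 4000, seed = 31)
  sim <- run_simulation(cfg)
  expect_lt(abs(sim$replacements / cfg$horizon - 50 * (1 / 50)), 0.05)
})

test_that("the dynamics reach a quasi-stationary payoff plateau", {
  # complete graph, pure social learning: per-realization slopes of the
  # mean payoff over the final 200 steps are indistinguishable from zero
  # (3 sigma across realizations; a pooled fit would understate the error
  # because the series is autocorrelated within a realization)
  slopes <- vapply(1:20, function(j) {
    m <- run_simulation(sim_config(n = 100, network = "complete", r = 0,
                                   seed = 700 + j))$metrics
    w <- tail(m$mean_payoff, 200)
    unname(stats::coef(stats::lm(w ~ seq_along(w)))[2])
  }, numeric(1))
  tval <- mean(slopes) / (stats::sd(slopes) / sqrt(length(slopes)))
  expect_lt(abs(tval), 3)
})

test_that("degenerate horizons yield empty series whose summary errors", {
  expect_error(sim_config(n = 10, k = 2, horizon = -1))
  cfg <- sim_config(n = 5, k = 2, horizon = 0, seed = 1)
  sim <- run_simulation(cfg)
  expect_identical(nrow(sim$metrics), 0L)
  expect_error(stationary_summary(sim), "shorter")
  cfg2 <- sim_config(n = 5, k = 2, horizon = 30, window = 50, seed = 1)
  expect_error(stationary_summary(run_simulation(cfg2)), "shorter")
})

test_that("stationary summaries average the final window", {
  mk <- function(z) data.frame(t = seq_along(z), mean_payoff = z,
                               mean_level = z / 2, distinct_traits = z * 2)
  s <- stationary_summary(mk(rep(3, 10)), window = 5)
  expect_equal(s$Z_max, 3)
  expect_equal(s$T_max, 6)
  expect_true(is.na(s$se_Z))
  s2 <- stationary_summary(list(mk(rep(4, 6)), mk(rep(6, 6))), window = 3)
  expect_equal(s2$Z_max, 5)
  expect_equal(s2$se_Z, 1)
  expect_identical(s2$realizations, 2L)
  s3 <- stationary_summary(mk(1:4), window = 2)
  expect_equal(s3$Z_max, 3.5)
})
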