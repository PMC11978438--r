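test_that("death-birth replaces agents with naive newborns in place", {
  a <- make_agent(node_id = 3L, budget = 120, payoffs = c(5L, 9L))
  expect_identical(death_birth(a, q = 0, budget = 1000), a)
  withr::with_seed(1, b <- death_birth(a, q = 1, budget = 1000))
  expect_identical(b$node_id, 3L)            # inherits the network position
  expect_identical(b$max_level, 0L)          # naive
  expect_identical(b$budget, 1000)           # fresh budget
  expect_identical(b$cumulative_payoff, 0)
})

test_that("teacher selection follows the strategy with uniform tie-breaks", {
  nb <- list(make_agent(1, payoffs = 10L),
             make_agent(2, payoffs = c(10L, 20L)),
             make_agent(3, payoffs = 30L))
  focal <- make_agent(9)
  expect_identical(
    select_neighbour("payoff_biased", focal, nb[2])$node_id, 2L)
  expect_null(select_neighbour("payoff_biased", focal, list()))
  # payoff bias: Z = (10, 30, 30) -> each of the tied agents w.p. 1/2
  withr::with_seed(2, {
    picks <- replicate(1e4, select_neighbour("payoff_biased", focal,
                                             nb)$node_id)
  })
  expect_setequal(unique(picks), c(2L, 3L))
  expect_lt(abs(mean(picks == 2L) - 0.5), 0.05)
  # level bias: levels (1, 2, 1) -> always agent 2
  expect_identical(select_neighbour("level_biased", focal, nb)$node_id, 2L)
  # random: roughly uniform
  withr::with_seed(3, {
    rnd <- replicate(6e3, select_neighbour("random_neighbour", focal,
                                           nb)$node_id)
  })
  expect_lt(max(abs(tabulate(rnd, 3) / 6e3 - 1 / 3)), 0.05)
  expect_error(select_neighbour("softmax", focal, nb))
})

test_that("social learning copies the next-level trait and charges on success only", {
  teacher <- make_agent(2, payoffs = c(3L, 8L, 17L, 4L, 2L),
                        branches = c(1L, 2L, 7L, 1L, 3L))
  focal <- make_agent(1, budget = 100, payoffs = c(5L, 5L))
  res <- social_learn(focal, teacher, cost_social = 5)
  expect_identical(res$outcome, "success")
  expect_identical(res$agent$max_level, 3L)
  expect_identical(res$agent$rep_branch[3], 7L)   # the teacher's level-3 trait
  expect_identical(res$agent$rep_payoff[3], 17L)
  expect_identical(res$agent$budget, 95)
  expect_identical(res$agent$cumulative_payoff, 27)

  peer <- make_agent(3, payoffs = c(1L, 1L))      # same level as focal
  res2 <- social_learn(focal, peer, cost_social = 5)
  expect_identical(res2$outcome, "fail_level")
  expect_identical(res2$agent, focal)             # free failure

  poor <- make_agent(1, budget = 3, payoffs = c(5L, 5L))
  res3 <- social_learn(poor, teacher, cost_social = 5)
  expect_identical(res3$outcome, "fail_budget")
  expect_identical(res3$agent, poor)
})

test_that("recommendation returns the archive's best trait at the level", {
  arch <- new_archive()
  archive_add(arch, 1, 3, 4)
  archive_add(arch, 5, 3, 17)
  archive_add(arch, 9, 3, 9)
  archive_add(arch, 2, 1, 30)
  rec <- recommend(arch, 3)
  expect_identical(rec$payoff, 17L)
  expect_identical(rec$branch, 5L)
  expect_null(recommend(arch, 2))
  expect_null(recommend(arch, 99))
})

test_that("recommendation equals a brute-force scan on random archives", {
  withr::with_seed(11, {
    for (case in 1:60) {
      ra <- random_archive(n_traits = sample.int(40, 1))
      for (lvl in 1:6) {
        rec <- recommend(ra$archive, lvl)
        oracle <- brute_recommend(ra$mirror, lvl)
        if (is.null(oracle)) {
          expect_null(rec)
        } else {
          expect_identical(rec$payoff, as.integer(oracle$payoff))
        }
      }
    }
  })
})

test_that("archives are monotone, viable-only and count distinct traits", {
  arch <- new_archive()
  expect_true(archive_add(arch, 1, 1, 10))
  expect_false(archive_add(arch, 1, 1, 10))   # re-innovation: no-op
  expect_true(archive_add(arch, 2, 1, 3))
  expect_identical(archive_count(arch), 2L)
  expect_error(archive_add(arch, 3, 1, 0), "viable")
  expect_identical(nrow(archive_level(arch, 1)), 2L)
})

test_that("algorithmic learning acquires the recommendation or fails free", {
  arch <- new_archive()
  archive_add(arch, 4, 1, 12)
  archive_add(arch, 6, 1, 2)
  naive <- make_agent(1, budget = 50)
  res <- algorithmic_learn(naive, arch, cost_rec = 1)
  expect_identical(res$outcome, "success")
  expect_identical(res$agent$rep_branch[1], 4L)
  expect_identical(res$agent$cumulative_payoff, 12)
  expect_identical(res$agent$budget, 49)

  ahead <- make_agent(1, budget = 50, payoffs = 7L)  # archive has no level 2
  expect_identical(algorithmic_learn(ahead, arch, 1)$outcome, "fail_empty")
  broke <- make_agent(1, budget = 0.5)
  res3 <- algorithmic_learn(broke, arch, cost_rec = 1)
  expect_identical(res3$outcome, "fail_budget")
  expect_identical(res3$agent$budget, 0.5)
})

test_that("innovation charges every funded attempt and archives viable draws", {
  tab <- payoff_table(branch_count = 1, seed = 1)  # single branch: forceable
  arch <- new_archive()

  poor <- make_agent(1, budget = 8)
  res <- innovate(poor, tab, arch, cost_innovate = 10)
  expect_identical(res$outcome, "fail_budget")
  expect_identical(res$agent$budget, 8)            # no attempt, no cost

  assign("1:1", 0L, envir = tab$map)               # force unviable level 1
  assign("1:2", 12L, envir = tab$map)              # force viable level 2
  a <- make_agent(1, budget = 100)
  res1 <- withr::with_seed(1, innovate(a, tab, arch, cost_innovate = 10))
  expect_identical(res1$outcome, "fail_unviable")
  expect_identical(res1$agent$budget, 90)          # cost charged regardless
  expect_identical(res1$agent$max_level, 0L)
  expect_identical(archive_count(arch), 0L)

  b <- make_agent(1, budget = 100, payoffs = 30L)
  res2 <- withr::with_seed(1, innovate(b, tab, arch, cost_innovate = 10))
  expect_identical(res2$outcome, "success")
  expect_identical(res2$agent$rep_payoff[2], 12L)
  expect_identical(archive_count(arch), 1L)
  # a second innovation of the same (branch, level) leaves the count alone
  res3 <- withr::with_seed(2, innovate(b, tab, arch, cost_innovate = 10))
  expect_identical(res3$outcome, "success")
  expect_identical(archive_count(arch), 1L)
})

test_that("the learning channel dispatch follows the mediation ratio", {
  cfg0 <- sim_config(n = 50, k = 4, r = 0, horizon = 100, seed = 1)
  s0 <- run_simulation(cfg0)
  expect_identical(s0$n_mediated, 0)
  cfg1 <- update_config(cfg0, r = 1)
  s1 <- run_simulation(cfg1)
  expect_identical(s1$n_social_dispatch, 0)
  cfg3 <- sim_config(n = 100, k = 4, r = 0.3, horizon = 100, seed = 1)
  s3 <- run_simulation(cfg3)
  frac <- s3$n_mediated / (s3$n_mediated + s3$n_social_dispatch)
  expect_lt(abs(frac - 0.3), 0.01)
})

test_that("an all-naive population acts on the first step", {
  # updates are sequential within a step, so a late-acting agent may already
  # copy a trait an earlier neighbour just innovated; every agent performs
  # exactly one funded acquisition attempt, and the first movers innovate
  cfg <- sim_config(n = 20, k = 4, r = 0, horizon = 1, seed = 8)
  sim <- run_simulation(cfg)
  expect_true(all(sim$agents$n_innov + sim$agents$n_social == 1L))
  expect_gt(sum(sim$agents$n_innov), 0)
  expect_identical(sim$n_mediated, 0)
})

test_that("a lone immortal agent innovates until its budget runs dry", {
  cfg <- sim_config(n = 1, k = 0, r = 0, q = 0, horizon = 150,
                    window = 10, seed = 4)
  sim <- run_simulation(cfg)
  expect_identical(sim$agents$n_innov, 100L)       # B / Ci attempts
  expect_identical(sim$agents$budget, 0)
  # payoff plateaus once the budget is gone
  expect_identical(sim$metrics$mean_payoff[101], sim$metrics$mean_payoff[150])
})
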