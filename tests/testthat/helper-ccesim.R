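# Shared fixtures, built in code.

# An agent with a prescribed repertoire of (branch, payoff) rows.
make_agent <- function(node_id = 1L, budget = 1000,
                       payoffs = integer(), branches = NULL) {
  a <- naive_agent(node_id, budget)
  if (length(payoffs)) {
    branches <- branches %||% rep(1L, length(payoffs))
    a$rep_branch <- as.integer(branches)
    a$rep_payoff <- as.integer(payoffs)
    a$max_level <- length(payoffs)
    a$cumulative_payoff <- as.numeric(sum(payoffs))
  }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force recommendation oracle: linear scan over a flat
# data.frame of every archived trait.
brute_recommend <- function(traits, level) {
  hits <- traits[traits$level == level, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits[which.max(hits$payoff), ]
}

# A random archive together with its flat mirror for oracle comparison.
random_archive <- function(n_traits, max_level = 6L, max_branch = 20L) {
  arch <- new_archive()
  mirror <- data.frame(branch = integer(), level = integer(),
                       payoff = integer())
  for (i in seq_len(n_traits)) {
    b <- sample.int(max_branch, 1L)
    l <- sample.int(max_level, 1L)
    z <- sample.int(40L, 1L)
    if (archive_add(arch, b, l, z)) {
      mirror <- rbind(mirror, data.frame(branch = b, level = l, payoff = z))
    }
  }
  list(archive = arch, mirror = mirror)
}

# Exact budget-conservation ledger on engine output: since its last birth
# each agent has spent Cs per social success, Cr per recommendation and Ci
# per innovation attempt.
expect_ledger <- function(sim) {
  cfg <- sim$config
  spent <- cfg$cost_social * sim$agents$n_social +
    cfg$cost_rec * sim$agents$n_rec +
    cfg$cost_innovate * sim$agents$n_innov
  expect_equal(cfg$budget - sim$agents$budget, spent)
  invisible(sim)
}
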