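#' Create a naive agent
#'
#' A naive agent holds no cultural traits (`max_level` 0), a full effort
#' budget, and zeroed action counters. Agents are plain lists; the
#' repertoire is a pair of parallel integer vectors (`rep_branch[l]`,
#' `rep_payoff[l]` for levels `1..max_level`), always contiguous with
#' exactly one trait per level.
#'
#' @param node_id the agent's (stable) network position.
#' @param budget initial effort budget B.
#' @return a list of class `cce_agent`.
#' @export
naive_agent <- function(node_id, budget) {
  structure(
    list(node_id = as.integer(node_id), budget = as.numeric(budget),
         max_level = 0L, rep_branch = integer(), rep_payoff = integer(),
         cumulative_payoff = 0,
         n_social = 0L, n_rec = 0L, n_innov = 0L),
    class = "cce_agent"
  )
}

# Acquire one trait at level max_level + 1 (internal; callers guarantee the
# trait is viable and the cost has been handled).
agent_acquire <- function(agent, branch, payoff) {
  agent$rep_branch <- c(agent$rep_branch, as.integer(branch))
  agent$rep_payoff <- c(agent$rep_payoff, as.integer(payoff))
  agent$max_level <- agent$max_level + 1L
  agent$cumulative_payoff <- agent$cumulative_payoff + payoff
  agent
}

#' Death-birth process
#'
#' With probability `q` (1/N by default in a simulation) the agent dies and
#' is replaced by a naive agent that inherits its network position and
#' starts with a fresh budget; otherwise the agent is returned unchanged.
#' On average one agent per time step is replaced when `q = 1/N`.
#'
#' @param agent a [naive_agent()]-shaped agent.
#' @param q replacement probability in `[0, 1]`.
#' @param budget the newborn's initial budget B.
#' @return the (possibly replaced) agent.
#' @export
death_birth <- function(agent, q, budget) {
  stopifnot(q >= 0, q <= 1)
  if (q > 0 && stats::runif(1) < q) {
    naive_agent(agent$node_id, budget)
  } else {
    agent
  }
}

#' Select a teacher among the focal agent's neighbours
#'
#' The social-learning strategies:
#' \describe{
#'   \item{`payoff_biased`}{the neighbour with the highest cumulative
#'     payoff Z (the main strategy).}
#'   \item{`level_biased`}{the neighbour with the highest complexity
#'     level.}
#'   \item{`random_neighbour`}{a uniformly random neighbour (unbiased
#'     transmission).}
#' }
#' Ties are broken uniformly at random.
#'
#' @param strategy strategy name.
#' @param focal the focal agent (unused by the shipped strategies, kept in
#'   the signature for custom strategies).
#' @param neighbour_agents list of neighbouring agents.
#' @return the chosen agent, or `NULL` if there are no neighbours.
#' @export
select_neighbour <- function(strategy = c("payoff_biased", "level_biased",
                                          "random_neighbour"),
                             focal, neighbour_agents) {
  strategy <- match.arg(strategy)
  m <- length(neighbour_agents)
  if (m == 0L) return(NULL)
  idx <- switch(strategy,
    payoff_biased = {
      z <- vapply(neighbour_agents, `[[`, numeric(1), "cumulative_payoff")
      which(z == max(z))
    },
    level_biased = {
      l <- vapply(neighbour_agents, `[[`, integer(1), "max_level")
      which(l == max(l))
    },
    random_neighbour = seq_len(m)
  )
  if (length(idx) > 1L) idx <- idx[sample.int(length(idx), 1L)]
  neighbour_agents[[idx]]
}

#' Social learning from a selected teacher
#'
#' The focal agent copies the teacher's trait at level `max_level + 1`.
#' Copying succeeds only if the teacher actually possesses a trait at that
#' level and the focal budget covers the cost `Cs`; the cost is charged on
#' success only — a failed attempt is free and the agent falls through to
#' innovation.
#'
#' @param focal the learning agent.
#' @param teacher the selected neighbour.
#' @param cost_social the social-learning cost Cs.
#' @return list with the updated `agent` and the `outcome`, one of
#'   `"success"`, `"fail_level"` (teacher not ahead), `"fail_budget"`.
#' @export
social_learn <- function(focal, teacher, cost_social) {
  target <- focal$max_level + 1L
  if (teacher$max_level < target) {
    return(list(agent = focal, outcome = "fail_level"))
  }
  if (focal$budget < cost_social) {
    return(list(agent = focal, outcome = "fail_budget"))
  }
  focal <- agent_acquire(focal, teacher$rep_branch[target],
                         teacher$rep_payoff[target])
  focal$budget <- focal$budget - cost_social
  focal$n_social <- focal$n_social + 1L
  list(agent = focal, outcome = "success")
}

#' Learning through algorithmic mediation
#'
#' The algorithm recommends the highest-payoff archived trait at the focal
#' agent's next level (see [recommend()]); the agent acquires it and pays
#' `Cr`. If the archive holds nothing at that level, or the budget is
#' insufficient, no cost is charged and the agent falls through to
#' innovation. The budget check precedes any tie-break randomness.
#'
#' @param focal the learning agent.
#' @param archive the global [new_archive()].
#' @param cost_rec the recommendation cost Cr.
#' @return list with the updated `agent` and the `outcome`, one of
#'   `"success"`, `"fail_empty"`, `"fail_budget"`.
#' @export
algorithmic_learn <- function(focal, archive, cost_rec) {
  target <- focal$max_level + 1L
  lv <- archive_level(archive, target)
  if (nrow(lv) == 0L) {
    return(list(agent = focal, outcome = "fail_empty"))
  }
  if (focal$budget < cost_rec) {
    return(list(agent = focal, outcome = "fail_budget"))
  }
  rec <- recommend(archive, target)
  focal <- agent_acquire(focal, rec$branch, rec$payoff)
  focal$budget <- focal$budget - cost_rec
  focal$n_rec <- focal$n_rec + 1L
  list(agent = focal, outcome = "success")
}

#' Innovation attempt
#'
#' The agent picks a uniformly random branch and attempts to innovate at
#' level `max_level + 1`. The innovation cost `Ci` is charged on every
#' attempt with sufficient budget, successful or not; an unviable draw
#' (payoff 0) ends the agent's time step empty-handed. Viable innovations
#' are acquired and added to the global archive.
#'
#' @param focal the innovating agent.
#' @param table the world [payoff_table()].
#' @param archive the global [new_archive()].
#' @param cost_innovate the innovation cost Ci.
#' @return list with the updated `agent` and the `outcome`, one of
#'   `"success"`, `"fail_unviable"`, `"fail_budget"`.
#' @export
innovate <- function(focal, table, archive, cost_innovate) {
  if (focal$budget < cost_innovate) {
    return(list(agent = focal, outcome = "fail_budget"))
  }
  focal$budget <- focal$budget - cost_innovate
  focal$n_innov <- focal$n_innov + 1L
  branch <- sample.int(table$branch_count, 1L)
  target <- focal$max_level + 1L
  z <- get_payoff(table, branch, target)
  if (z == 0L) {
    return(list(agent = focal, outcome = "fail_unviable"))
  }
  focal <- agent_acquire(focal, branch, z)
  archive_add(archive, branch, target, z)
  list(agent = focal, outcome = "success")
}

#' One full agent cycle
#'
#' Executes, in order: (i) the death-birth process; (ii) learning —
#' dispatched to algorithmic mediation with probability `r` and to social
#' learning (teacher selection + copying) with probability `1 - r`;
#' (iii) innovation, if and only if learning did not succeed. A newborn
#' proceeds with the learning/innovation phases of the same step.
#'
#' @param focal the focal agent.
#' @param net the `social_network`.
#' @param agents the current list of all agents (read for teacher lookup).
#' @param archive the global archive.
#' @param table the world payoff table.
#' @param config a [sim_config()].
#' @return list with the updated `agent` and an `events` record
#'   (`replaced`, `dispatch`, `learn_outcome`, `innov_outcome`).
#' @export
agent_step <- function(focal, net, agents, archive, table, config) {
  # (i) death-birth; the draw is inlined so the event can be recorded exactly
  replaced <- FALSE
  if (config$q > 0 && stats::runif(1) < config$q) {
    focal <- naive_agent(focal$node_id, config$budget)
    replaced <- TRUE
  }
  # (ii) learning: one uniform draw decides the channel
  mediated <- stats::runif(1) < config$r
  if (mediated) {
    res <- algorithmic_learn(focal, archive, config$cost_rec)
  } else {
    nb <- neighbours(net, focal$node_id)
    teacher <- select_neighbour(config$strategy, focal, agents[nb])
    res <- if (is.null(teacher)) {
      list(agent = focal, outcome = "fail_no_neighbour")
    } else {
      social_learn(focal, teacher, config$cost_social)
    }
  }
  focal <- res$agent
  innov_outcome <- NA_character_
  if (res$outcome != "success") {
    ires <- innovate(focal, table, archive, config$cost_innovate)
    focal <- ires$agent
    innov_outcome <- ires$outcome
  }
  list(agent = focal,
       events = list(replaced = replaced,
                     dispatch = if (mediated) "mediated" else "social",
                     learn_outcome = res$outcome,
                     innov_outcome = innov_outcome))
}

#' One population time step
#'
#' Every agent executes [agent_step()] exactly once, in a fresh uniformly
#' random order, with sequential state updates: an agent acting later in
#' the step sees the intra-step changes made by earlier agents.
#'
#' @param agents list of agents (length N, indexed by node id).
#' @param net,archive,table,config as in [agent_step()].
#' @return list with the updated `agents` and per-step `stats`
#'   (`replacements`, `n_mediated`, `n_social_dispatch`).
#' @export
time_step <- function(agents, net, archive, table, config) {
  ord <- sample.int(length(agents))
  replacements <- 0L; n_med <- 0L; n_soc <- 0L
  for (i in ord) {
    res <- agent_step(agents[[i]], net, agents, archive, table, config)
    agents[[i]] <- res$agent
    ev <- res$events
    if (isTRUE(ev$replaced)) replacements <- replacements + 1L
    if (ev$dispatch == "mediated") n_med <- n_med + 1L else n_soc <- n_soc + 1L
  }
  list(agents = agents,
       stats = list(replacements = replacements, n_mediated = n_med,
                    n_social_dispatch = n_soc))
}
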