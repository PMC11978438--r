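#' Run one simulation
#'
#' Initializes an all-naive population on the configured network and an
#' empty archive, executes `horizon` time steps, and records the three
#' population measures after every step: mean payoff Z(t), mean complexity
#' level L(t), and the number of distinct traits innovated so far T(t).
#'
#' The master seed spawns two derived streams — one for network
#' generation, one for the dynamics — so the same topology can be reused
#' across dynamic replicates. Runs are fully deterministic given the
#' master seed.
#'
#' Two engines implement identical rules: `"cpp"` (compiled, the default;
#' used for production-size runs) and `"r"` (the pure-R reference engine
#' composed of the exported per-operation functions [agent_step()],
#' [time_step()] etc.; used for auditing and small problems).
#'
#' @param config a [sim_config()].
#' @param engine `"cpp"` or `"r"`.
#' @param detail if `TRUE`, additionally return final repertoires, the
#'   materialized payoff map, and per-step per-agent state snapshots
#'   (budget, level, cumulative payoff, action counters) for invariant
#'   auditing. Intended for small populations.
#' @return an object of class `cce_sim`: a list with elements `metrics`
#'   (data.frame `t`, `mean_payoff`, `mean_level`, `distinct_traits`),
#'   `agents` (final per-agent states and action counters),
#'   `replacements`, `n_mediated`, `n_social_dispatch`, `archive_count`,
#'   `network`, `config`, and — with `detail = TRUE` — `repertoires`,
#'   `payoff_map`, `snapshots`.
#' @examples
#' cfg <- sim_config(n = 20, k = 4, r = 0.3, horizon = 100, seed = 42)
#' sim <- run_simulation(cfg)
#' tail(sim$metrics)
#' @export
run_simulation <- function(config, engine = c("cpp", "r"), detail = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  if (is.null(config$seed)) {
    config$seed <- as.integer(stats::runif(1, 1, 2^31 - 1))
  }

  net <- resolve_network(config)
  sim_seed <- derive_seed(config$seed, 2L)

  res <- if (engine == "cpp") {
    strat <- match(config$strategy,
                   c("payoff_biased", "level_biased", "random_neighbour")) - 1L
    withr::with_seed(sim_seed,
      engine_run(net$adj, config$n, config$budget, config$cost_innovate,
                 config$cost_social, config$cost_rec, config$branches,
                 config$r, config$q, config$rate, strat, config$horizon,
                 detail))
  } else {
    withr::with_seed(sim_seed, r_engine(net, config, detail))
  }
  res$network <- net
  res$config <- config
  res$engine <- engine
  class(res) <- "cce_sim"
  res
}

# Build (or pass through) the network for a config, on its derived stream.
resolve_network <- function(config) {
  if (inherits(config$network, "social_network")) return(config$network)
  spec <- config$network
  args <- list(family = spec$family, n = config$n,
               seed = derive_seed(config$seed, 1L))
  if (!is.null(spec$k)) args$k <- spec$k
  if (!is.null(spec$rewire_p)) args$rewire_p <- spec$rewire_p
  if (!is.null(spec$edges)) args$edges <- spec$edges
  if (!is.null(spec$file)) args$file <- spec$file
  do.call(build_network, args)
}

# Pure-R reference engine: the same cycle as the compiled engine, driven
# through the exported per-operation functions.  Payoff draws use the
# table's private stream (seeded from the master seed); all other
# randomness uses the dynamics stream the caller seeded.
r_engine <- function(net, config, detail = FALSE) {
  tab <- payoff_table(config$branches, config$rate,
                      seed = derive_seed(config$seed, 3L))
  arch <- new_archive()
  agents <- lapply(seq_len(config$n), naive_agent, budget = config$budget)

  h <- config$horizon
  zbar <- numeric(h); lbar <- numeric(h); tser <- integer(h)
  replacements <- 0; n_med <- 0; n_soc <- 0
  snaps <- NULL
  if (detail) {
    snaps <- list(budget = matrix(0, h, config$n),
                  cumulative_payoff = matrix(0, h, config$n),
                  max_level = matrix(0L, h, config$n),
                  n_social = matrix(0L, h, config$n),
                  n_rec = matrix(0L, h, config$n),
                  n_innov = matrix(0L, h, config$n))
  }

  for (t in seq_len(h)) {
    st <- time_step(agents, net, arch, tab, config)
    agents <- st$agents
    replacements <- replacements + st$stats$replacements
    n_med <- n_med + st$stats$n_mediated
    n_soc <- n_soc + st$stats$n_social_dispatch
    zbar[t] <- mean(vapply(agents, `[[`, numeric(1), "cumulative_payoff"))
    lbar[t] <- mean(vapply(agents, `[[`, integer(1), "max_level"))
    tser[t] <- archive_count(arch)
    if (detail) {
      snaps$budget[t, ] <- vapply(agents, `[[`, numeric(1), "budget")
      snaps$cumulative_payoff[t, ] <-
        vapply(agents, `[[`, numeric(1), "cumulative_payoff")
      snaps$max_level[t, ] <- vapply(agents, `[[`, integer(1), "max_level")
      snaps$n_social[t, ] <- vapply(agents, `[[`, integer(1), "n_social")
      snaps$n_rec[t, ] <- vapply(agents, `[[`, integer(1), "n_rec")
      snaps$n_innov[t, ] <- vapply(agents, `[[`, integer(1), "n_innov")
    }
  }

  out <- list(
    metrics = data.frame(t = seq_len(h), mean_payoff = zbar,
                         mean_level = lbar, distinct_traits = tser),
    agents = data.frame(
      node = seq_len(config$n),
      budget = vapply(agents, `[[`, numeric(1), "budget"),
      max_level = vapply(agents, `[[`, integer(1), "max_level"),
      cumulative_payoff = vapply(agents, `[[`, numeric(1),
                                 "cumulative_payoff"),
      n_social = vapply(agents, `[[`, integer(1), "n_social"),
      n_rec = vapply(agents, `[[`, integer(1), "n_rec"),
      n_innov = vapply(agents, `[[`, integer(1), "n_innov")),
    replacements = replacements, n_mediated = n_med,
    n_social_dispatch = n_soc, archive_count = archive_count(arch))
  if (detail) {
    out$repertoires <- lapply(agents, function(a) {
      m <- cbind(branch = a$rep_branch, payoff = a$rep_payoff)
      m
    })
    out$payoff_map <- materialized_payoffs(tab)
    out$snapshots <- snaps
  }
  out
}

#' @export
print.cce_sim <- function(x, ...) {
  h <- nrow(x$metrics)
  cat("<cce_sim> N = ", x$config$n, ", ", h, " steps (engine ", x$engine,
      ")\n", sep = "")
  if (h > 0) {
    cat("  final: mean payoff ", signif(x$metrics$mean_payoff[h], 5),
        ", mean level ", signif(x$metrics$mean_level[h], 5),
        ", distinct traits ", x$metrics$distinct_traits[h], "\n", sep = "")
  }
  invisible(x)
}

#' Quasi-stationary summaries of one or more runs
#'
#' The simulated system settles into a quasi-stationary regime well before
#' the default horizon of 20 N steps; population measures are summarized
#' by their mean over the final `window` time steps of each realization
#' ("maximally achievable" values), then averaged across realizations with
#' a between-realization standard error.
#'
#' @param x a `cce_sim`, a metrics data.frame, or a list of either (one
#'   element per realization).
#' @param window stationary-window length; defaults to the run
#'   configuration's `window` (200 steps).
#' @return a one-row data.frame of class `cce_summary` with columns
#'   `Z_max`, `L_max`, `T_max`, `se_Z`, `se_L`, `se_T`, `realizations`,
#'   `window`.
#' @export
stationary_summary <- function(x, window = NULL) {
  if (inherits(x, "cce_sim") || is.data.frame(x)) x <- list(x)
  stopifnot(is.list(x), length(x) >= 1L)
  if (is.null(window)) {
    for (s in x) {
      if (inherits(s, "cce_sim")) { window <- s$config$window; break }
    }
  }
  series <- lapply(x, function(s) {
    if (inherits(s, "cce_sim")) s$metrics else as.data.frame(s)
  })
  window <- window %||% 200L
  stop_if_not_count(window, "window")
  per_run <- t(vapply(series, function(m) {
    if (nrow(m) < window) {
      stop("series of length ", nrow(m), " is shorter than window ",
           window, call. = FALSE)
    }
    tail_rows <- m[(nrow(m) - window + 1L):nrow(m), , drop = FALSE]
    c(Z = mean(tail_rows$mean_payoff), L = mean(tail_rows$mean_level),
      T = mean(tail_rows$distinct_traits))
  }, numeric(3)))
  nr <- nrow(per_run)
  se <- function(v) if (nr > 1L) stats::sd(v) / sqrt(nr) else NA_real_
  structure(
    data.frame(Z_max = mean(per_run[, "Z"]), L_max = mean(per_run[, "L"]),
               T_max = mean(per_run[, "T"]), se_Z = se(per_run[, "Z"]),
               se_L = se(per_run[, "L"]), se_T = se(per_run[, "T"]),
               realizations = nr, window = as.integer(window)),
    class = c("cce_summary", "data.frame")
  )
}
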