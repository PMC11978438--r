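#' Simulation configuration
#'
#' Collects and validates every parameter of a run. Defaults are the
#' reference parameter set used throughout the package: N = 100 agents,
#' budget B = 1000, costs Ci = 10 (innovation), Cs = 5 (social learning),
#' Cr = 1 (recommendation), X = 100 branches, replacement probability
#' q = 1/N, horizon 20 N time steps, a 200-step stationary window and 200
#' realizations for sweeps.
#'
#' The cost ordering `0 < Cr < Cs < Ci` is enforced: recommendations are
#' cheaper than copying a peer, which in turn is cheaper than innovating.
#'
#' @param n population size N.
#' @param network either a family name (`"erdos_renyi"`, `"complete"`,
#'   `"small_world"`, `"scale_free"`), a list of arguments for
#'   [build_network()], or a ready-made `social_network` object.
#' @param k target mean degree (ignored for `"complete"` and ready-made
#'   networks).
#' @param r mediation ratio in `[0, 1]`: probability that a learning step
#'   is dispatched to the recommendation algorithm rather than to social
#'   learning.
#' @param budget initial effort budget B.
#' @param cost_innovate,cost_social,cost_rec the costs Ci, Cs, Cr.
#' @param branches number of cultural branches X.
#' @param q per-step replacement probability (default 1/N).
#' @param strategy social-learning strategy, see [select_neighbour()].
#' @param horizon number of time steps (default 20 N).
#' @param window stationary-window length used by [stationary_summary()].
#' @param realizations default number of independent realizations for
#'   [run_sweep()].
#' @param rate rate of the exponential payoff draw (default `2 * log(2)`).
#' @param rewire_p small-world rewiring probability.
#' @param seed master seed; spawns the network and dynamics streams.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n = 50, k = 4, r = 0.3, seed = 1)
#' cfg
#' @export
sim_config <- function(n = 100L, network = "erdos_renyi", k = NULL, r = 0,
                       budget = 1000, cost_innovate = 10, cost_social = 5,
                       cost_rec = 1, branches = 100L, q = NULL,
                       strategy = c("payoff_biased", "level_biased",
                                    "random_neighbour"),
                       horizon = NULL, window = 200L, realizations = 200L,
                       rate = 2 * log(2), rewire_p = 0.1, seed = NULL) {
  stop_if_not_count(n, "n")
  n <- as.integer(n)
  strategy <- match.arg(strategy)
  q_default <- is.null(q)
  horizon_default <- is.null(horizon)
  q <- q %||% (1 / n)
  horizon <- horizon %||% (20L * n)
  if (q < 0 || q > 1) stop("`q` must be in [0, 1]", call. = FALSE)
  if (r < 0 || r > 1) stop("`r` must be in [0, 1]", call. = FALSE)
  if (budget <= 0) stop("`budget` must be positive", call. = FALSE)
  if (!(0 < cost_rec && cost_rec < cost_social &&
        cost_social < cost_innovate)) {
    stop("costs must satisfy 0 < cost_rec < cost_social < cost_innovate",
         call. = FALSE)
  }
  stop_if_not_count(branches, "branches")
  stop_if_not_count(horizon, "horizon", min = 0L)
  stop_if_not_count(window, "window")
  stop_if_not_count(realizations, "realizations")
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)

  if (inherits(network, "social_network")) {
    if (network$n != n) stop("supplied network has ", network$n,
                             " nodes but n = ", n, call. = FALSE)
  } else if (is.character(network)) {
    network <- list(family = network)
  } else if (!is.list(network)) {
    stop("`network` must be a family name, an argument list, or a ",
         "social_network", call. = FALSE)
  }
  if (is.list(network) && !inherits(network, "social_network")) {
    network$family <- match.arg(network$family,
                                c("erdos_renyi", "complete", "small_world",
                                  "scale_free", "user_supplied"))
    if (!is.null(k)) network$k <- k
    if (is.null(network$rewire_p)) network$rewire_p <- rewire_p
    if (network$family != "complete" && network$family != "user_supplied" &&
        is.null(network$k)) {
      stop("`k` is required for network family '", network$family, "'",
           call. = FALSE)
    }
  }

  structure(
    list(n = n, network = network, r = as.numeric(r),
         budget = as.numeric(budget),
         cost_innovate = as.numeric(cost_innovate),
         cost_social = as.numeric(cost_social),
         cost_rec = as.numeric(cost_rec),
         branches = as.integer(branches), q = as.numeric(q),
         strategy = strategy, horizon = as.integer(horizon),
         window = as.integer(window),
         realizations = as.integer(realizations), rate = as.numeric(rate),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         q_default = q_default, horizon_default = horizon_default),
    class = "sim_config"
  )
}

#' Modify a configuration
#'
#' Returns a revalidated copy of `config` with the named fields replaced.
#' Defaults that depend on `n` (`q = 1/n`, `horizon = 20 n`) are re-derived
#' when `n` changes and the field was left at its default.
#'
#' @param config a [sim_config()].
#' @param ... fields to change; `k` and `family` update the network spec.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  changes <- list(...)
  args <- list(
    n = config$n, network = config$network, r = config$r,
    budget = config$budget, cost_innovate = config$cost_innovate,
    cost_social = config$cost_social, cost_rec = config$cost_rec,
    branches = config$branches,
    q = if (config$q_default) NULL else config$q,
    strategy = config$strategy,
    horizon = if (config$horizon_default) NULL else config$horizon,
    window = config$window, realizations = config$realizations,
    rate = config$rate, seed = config$seed
  )
  for (nm in names(changes)) {
    if (nm %in% c("k", "family", "rewire_p")) {
      if (inherits(args$network, "social_network")) {
        stop("cannot change `", nm, "` of a ready-made network",
             call. = FALSE)
      }
      args$network[[nm]] <- changes[[nm]]
      if (nm == "family") args$network$k <- args$network$k  # keep k
    } else {
      args[[nm]] <- changes[[nm]]
    }
  }
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  net <- if (inherits(x$network, "social_network")) {
    paste0("user network (", x$network$family, ")")
  } else {
    paste0(x$network$family,
           if (!is.null(x$network$k)) paste0(", k = ", x$network$k) else "")
  }
  cat("<sim_config>\n",
      "  N = ", x$n, ", network: ", net, "\n",
      "  r = ", x$r, " (", x$strategy, "), q = ", signif(x$q, 4), "\n",
      "  B = ", x$budget, ", Ci = ", x$cost_innovate, ", Cs = ",
      x$cost_social, ", Cr = ", x$cost_rec, ", X = ", x$branches, "\n",
      "  horizon = ", x$horizon, ", window = ", x$window,
      ", realizations = ", x$realizations, "\n",
      "  payoff rate = ", signif(x$rate, 4), ", seed = ",
      x$seed %||% "<unset>", "\n", sep = "")
  invisible(x)
}
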