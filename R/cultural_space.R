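#' Transform exponential draws into integer trait payoffs
#'
#' The cultural space assigns every trait an integer payoff obtained by
#' drawing an exponential variate and then squaring, doubling and rounding
#' it. Squaring the exponential draw makes high-quality innovations rare:
#' at the default rate (`2 * log(2)`) half of all traits end up with payoff
#' 0 (unviable), while payoffs around 50 occur roughly once per thousand
#' draws.
#'
#' Rounding is half-up (`floor(x + 0.5)`), not banker's rounding; the
#' half-integer boundary has probability zero but the convention is fixed
#' for reproducibility.
#'
#' @param draw one or more non-negative exponential variates.
#' @return integer payoffs, same length as `draw`.
#' @examples
#' sample_payoff(5)    # 2 * 25 = 50
#' sample_payoff(0.4)  # 0.32 rounds down to 0: unviable
#' @seealso [payoff_table()], [is_viable()]
#' @export
sample_payoff <- function(draw) {
  if (!is.numeric(draw) || anyNA(draw)) {
    stop("`draw` must be numeric and non-missing", call. = FALSE)
  }
  if (any(draw < 0)) {
    stop("`draw` must be non-negative (it is an exponential variate)",
         call. = FALSE)
  }
  as.integer(floor(2 * draw^2 + 0.5))
}

#' Is a payoff viable?
#'
#' A trait is viable when its payoff is strictly positive; unviable traits
#' (payoff 0) can never be acquired, and an unviable (branch, level) pair
#' stays unviable for the whole run.
#'
#' @param payoff one or more non-negative integer payoffs.
#' @return logical vector.
#' @export
is_viable <- function(payoff) {
  if (!is.numeric(payoff) || anyNA(payoff) || any(payoff < 0)) {
    stop("`payoff` must be a non-negative number", call. = FALSE)
  }
  payoff > 0
}

#' Create a lazily materialized payoff table
#'
#' The cultural space is a grid of `branch_count` branches by an unbounded
#' number of complexity levels. Payoffs are world-level constants: the
#' payoff of a (branch, level) pair is drawn once, on the first query, from
#' the table's own private random stream, and is then shared by all agents
#' for the rest of the run. Nothing is preallocated; the level axis is
#' open-ended.
#'
#' @param branch_count number of cultural branches (X).
#' @param rate rate of the exponential payoff draw. The default
#'   `2 * log(2)` makes the probability of an unviable (payoff-0) trait
#'   exactly 1/2.
#' @param seed integer seed of the table's private stream. Tables built
#'   with the same seed and queried in the same order return identical
#'   payoff maps.
#' @return an object of class `payoff_table`.
#' @examples
#' tab <- payoff_table(branch_count = 10, seed = 1)
#' get_payoff(tab, branch = 3, level = 1)
#' @export
payoff_table <- function(branch_count = 100L, rate = 2 * log(2),
                         seed = NULL) {
  stop_if_not_count(branch_count, "branch_count")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- as.integer(stats::runif(1, 1, 2^31 - 1))
  }
  tab <- new.env(parent = emptyenv())
  tab$branch_count <- as.integer(branch_count)
  tab$rate <- as.numeric(rate)
  tab$seed <- as.integer(seed)
  tab$map <- new.env(parent = emptyenv())
  tab$n_entries <- 0L
  # private stream: capture a fresh RNG state without disturbing the caller's
  tab$rng_state <- withr::with_seed(tab$seed, .Random.seed)
  class(tab) <- "payoff_table"
  tab
}

# Draw one exponential variate from the table's private stream, leaving the
# caller's global RNG state untouched.
table_draw <- function(tab) {
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  assign(".Random.seed", tab$rng_state, envir = genv)
  d <- stats::rexp(1L, rate = tab$rate)
  tab$rng_state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", old, envir = genv)
  }
  d
}

#' Query (and lazily materialize) trait payoffs
#'
#' The first query of a (branch, level) pair draws its payoff through
#' [sample_payoff()]; later queries return the memoized value. Entries are
#' never overwritten, so the world is consistent across agents and time.
#'
#' @param table a [payoff_table()].
#' @param branch branch index in `1..branch_count` (vectorized).
#' @param level complexity level, `>= 1` (vectorized, recycled with
#'   `branch`).
#' @return integer payoffs.
#' @export
get_payoff <- function(table, branch, level) {
  stopifnot(inherits(table, "payoff_table"))
  n <- max(length(branch), length(level))
  branch <- rep_len(as.integer(branch), n)
  level <- rep_len(as.integer(level), n)
  if (anyNA(branch) || any(branch < 1L) || any(branch > table$branch_count)) {
    stop("`branch` out of range 1..", table$branch_count, call. = FALSE)
  }
  if (anyNA(level) || any(level < 1L)) {
    stop("`level` must be >= 1", call. = FALSE)
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- paste0(branch[i], ":", level[i])
    z <- get0(k, envir = table$map, inherits = FALSE)
    if (is.null(z)) {
      z <- sample_payoff(table_draw(table))
      assign(k, z, envir = table$map)
      table$n_entries <- table$n_entries + 1L
    }
    out[i] <- z
  }
  out
}

#' Extract the materialized part of a payoff table
#'
#' @param table a [payoff_table()].
#' @return a data.frame with columns `branch`, `level`, `payoff`, one row
#'   per materialized entry, ordered by branch then level.
#' @export
materialized_payoffs <- function(table) {
  stopifnot(inherits(table, "payoff_table"))
  keys <- ls(table$map)
  if (length(keys) == 0L) {
    return(data.frame(branch = integer(), level = integer(),
                      payoff = integer()))
  }
  parts <- matrix(as.integer(unlist(strsplit(keys, ":", fixed = TRUE))),
                  ncol = 2L, byrow = TRUE)
  df <- data.frame(
    branch = parts[, 1L],
    level = parts[, 2L],
    payoff = vapply(keys, function(k) get(k, envir = table$map), integer(1),
                    USE.NAMES = FALSE)
  )
  df[order(df$branch, df$level), , drop = FALSE]
}

#' Dump / restore a payoff map as CSV
#'
#' For run post-mortems: `write_payoff_table()` saves the materialized
#' entries; `read_payoff_table()` rebuilds a table whose map is prefilled
#' with them (further first-touch queries draw from the new table's own
#' stream).
#'
#' @param table a [payoff_table()].
#' @param path CSV file path.
#' @rdname payoff_table_io
#' @export
write_payoff_table <- function(table, path) {
  utils::write.csv(materialized_payoffs(table), path, row.names = FALSE)
  invisible(path)
}

#' @param branch_count,rate,seed passed to [payoff_table()] for the
#'   restored table.
#' @rdname payoff_table_io
#' @export
read_payoff_table <- function(path, branch_count = 100L,
                              rate = 2 * log(2), seed = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("branch", "level", "payoff") %in% names(df)))
  tab <- payoff_table(branch_count = branch_count, rate = rate, seed = seed)
  for (i in seq_len(nrow(df))) {
    assign(paste0(df$branch[i], ":", df$level[i]),
           as.integer(df$payoff[i]), envir = tab$map)
  }
  tab$n_entries <- nrow(df)
  tab
}

#' @export
print.payoff_table <- function(x, ...) {
  cat("<payoff_table> ", x$branch_count, " branches, rate ",
      signif(x$rate, 4), ", seed ", x$seed, ", ",
      x$n_entries, " materialized entries\n", sep = "")
  invisible(x)
}
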