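#' Create an empty trait archive
#'
#' The archive is the global, monotone knowledge base of all viable traits
#' innovated so far. It survives the death of innovators, feeds the
#' recommendation step of algorithmic mediation, and its size is the
#' population's trait-diversity counter T(t).
#'
#' @return an object of class `trait_archive`.
#' @export
new_archive <- function() {
  a <- new.env(parent = emptyenv())
  a$levels <- list()        # per level: list(branch = int vec, payoff = int vec)
  a$seen <- new.env(parent = emptyenv())
  a$total_count <- 0L
  class(a) <- "trait_archive"
  a
}

#' Add an innovated trait to the archive
#'
#' Only successful innovations reach the archive (copying creates nothing
#' new); only viable traits (payoff > 0) are accepted. Re-innovating an
#' already archived (branch, level) pair is a no-op.
#'
#' @param archive a [new_archive()] object.
#' @param branch,level trait coordinates.
#' @param payoff the trait's (positive) payoff.
#' @return invisibly, `TRUE` if the trait was new to the archive.
#' @export
archive_add <- function(archive, branch, level, payoff) {
  stopifnot(inherits(archive, "trait_archive"))
  branch <- as.integer(branch); level <- as.integer(level)
  payoff <- as.integer(payoff)
  if (payoff <= 0L) {
    stop("only viable traits (payoff > 0) can be archived", call. = FALSE)
  }
  key <- paste0(branch, ":", level)
  if (!is.null(get0(key, envir = archive$seen, inherits = FALSE))) {
    return(invisible(FALSE))
  }
  assign(key, TRUE, envir = archive$seen)
  if (length(archive$levels) < level || is.null(archive$levels[[level]])) {
    archive$levels[[level]] <- list(branch = integer(), payoff = integer())
  }
  lv <- archive$levels[[level]]
  lv$branch <- c(lv$branch, branch)
  lv$payoff <- c(lv$payoff, payoff)
  archive$levels[[level]] <- lv
  archive$total_count <- archive$total_count + 1L
  invisible(TRUE)
}

#' Number of distinct traits archived
#' @param archive a `trait_archive`.
#' @export
archive_count <- function(archive) {
  stopifnot(inherits(archive, "trait_archive"))
  archive$total_count
}

#' Archived traits at one complexity level
#' @param archive a `trait_archive`.
#' @param level complexity level.
#' @return data.frame with columns `branch`, `payoff` (0 rows if empty).
#' @export
archive_level <- function(archive, level) {
  stopifnot(inherits(archive, "trait_archive"), level >= 1)
  if (length(archive$levels) < level || is.null(archive$levels[[level]])) {
    return(data.frame(branch = integer(), payoff = integer()))
  }
  as.data.frame(archive$levels[[level]])
}

#' Recommend the best archived trait at a level
#'
#' The personalization step of algorithmic mediation: among all archived
#' traits at exactly `level`, return the one with the highest payoff, ties
#' broken uniformly at random.
#'
#' @param archive a `trait_archive`.
#' @param level the learner's next level (`max_level + 1`).
#' @return a list `(branch, level, payoff)`, or `NULL` if the archive holds
#'   no trait at that level.
#' @export
recommend <- function(archive, level) {
  stopifnot(inherits(archive, "trait_archive"))
  if (length(level) != 1L || is.na(level) || level < 1L) {
    stop("`level` must be a single integer >= 1", call. = FALSE)
  }
  lv <- if (length(archive$levels) >= level) archive$levels[[level]] else NULL
  if (is.null(lv) || length(lv$payoff) == 0L) return(NULL)
  best <- max(lv$payoff)
  idx <- which(lv$payoff == best)
  if (length(idx) > 1L) idx <- idx[sample.int(length(idx), 1L)]
  list(branch = lv$branch[idx], level = as.integer(level), payoff = best)
}

#' @export
print.trait_archive <- function(x, ...) {
  cat("<trait_archive> ", x$total_count, " distinct traits across ",
      length(x$levels), " levels\n", sep = "")
  invisible(x)
}
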