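#' Build a social network
#'
#' Generates the static, undirected, simple (no self-loops, no multi-edges)
#' social network on which agents live. Node identities are stable for a
#' whole run: a replaced agent's successor inherits its network position.
#'
#' Families and their mean-degree parametrization:
#' \describe{
#'   \item{`complete`}{every pair connected; `k` is ignored.}
#'   \item{`erdos_renyi`}{G(n, p) with `p = k / (n - 1)`, so the expected
#'     mean degree is exactly `k`. Isolated nodes in sparse graphs are kept
#'     as-is: an isolated agent can never learn socially and always falls
#'     through to innovation.}
#'   \item{`small_world`}{Watts-Strogatz ring with `k/2` neighbours on each
#'     side (`k` must be a positive even integer) and rewiring probability
#'     `rewire_p` (default 0.1).}
#'   \item{`scale_free`}{Barabasi-Albert preferential attachment with
#'     `m = round(k / 2)` edges per new node, so the asymptotic mean degree
#'     is approximately `k`.}
#'   \item{`user_supplied`}{edges given directly (`edges` matrix or an edge
#'     list `file`, two whitespace-separated 0-based integer columns, one
#'     undirected edge per line).}
#' }
#'
#' @param family network family, see Details.
#' @param n number of nodes (N >= 1).
#' @param k target mean degree; required for all random families.
#' @param seed optional integer seed; generation happens in an isolated
#'   stream and leaves the caller's RNG state untouched.
#' @param rewire_p small-world rewiring probability.
#' @param edges two-column integer matrix of 0-based node pairs
#'   (`user_supplied`).
#' @param file path to an edge-list file (`user_supplied`).
#' @return an object of class `social_network`.
#' @examples
#' net <- build_network("erdos_renyi", n = 50, k = 4, seed = 1)
#' mean_degree(net)
#' @export
build_network <- function(family = c("erdos_renyi", "complete",
                                     "small_world", "scale_free",
                                     "user_supplied"),
                          n, k = NULL, seed = NULL, rewire_p = 0.1,
                          edges = NULL, file = NULL) {
  family <- match.arg(family)
  stop_if_not_count(n, "n")
  n <- as.integer(n)
  if (family %in% c("erdos_renyi", "small_world", "scale_free")) {
    if (is.null(k) || !is.numeric(k) || length(k) != 1L || is.na(k)) {
      stop("`k` (target mean degree) is required for family '", family, "'",
           call. = FALSE)
    }
    if (k < 0 || k > n - 1) {
      stop("`k` must satisfy 0 <= k <= n - 1", call. = FALSE)
    }
  }

  gen <- function() {
    switch(family,
      complete = igraph::make_full_graph(n, directed = FALSE),
      erdos_renyi = {
        p <- if (n > 1) k / (n - 1) else 0
        igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
      },
      small_world = {
        if (k < 2 || k %% 2 != 0) {
          stop("small_world requires an even `k` >= 2", call. = FALSE)
        }
        g <- igraph::sample_smallworld(1, n, nei = k / 2, p = rewire_p)
        igraph::simplify(g)
      },
      scale_free = {
        m <- max(1L, as.integer(round(k / 2)))
        igraph::sample_pa(n, m = m, directed = FALSE)
      },
      user_supplied = {
        if (is.null(edges) && !is.null(file)) edges <- read_edgelist(file)
        if (is.null(edges)) {
          stop("user_supplied requires `edges` or `file`", call. = FALSE)
        }
        edges <- as.matrix(edges)
        if (ncol(edges) != 2L) stop("`edges` must have two columns",
                                    call. = FALSE)
        storage.mode(edges) <- "integer"
        if (any(edges < 0L) || any(edges > n - 1L)) {
          stop("edge endpoints must be 0-based node ids in 0..n-1",
               call. = FALSE)
        }
        g <- igraph::graph_from_edgelist(edges + 1L, directed = FALSE)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
        igraph::simplify(g)
      }
    )
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())

  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  structure(
    list(graph = g, adj = adj, n = n, family = family,
         k_target = if (family == "complete") n - 1 else k),
    class = "social_network"
  )
}

#' Neighbours of a node
#'
#' @param net a [build_network()] object.
#' @param node node id in `1..n`.
#' @return integer vector of neighbour ids (possibly empty: an isolated
#'   agent always proceeds straight to innovation).
#' @export
neighbours <- function(net, node) {
  stopifnot(inherits(net, "social_network"))
  if (length(node) != 1L || is.na(node) || node < 1L || node > net$n) {
    stop("`node` must be in 1..", net$n, call. = FALSE)
  }
  net$adj[[node]]
}

#' Realized mean degree of a network
#' @param net a `social_network`.
#' @export
mean_degree <- function(net) {
  stopifnot(inherits(net, "social_network"))
  mean(igraph::degree(net$graph))
}

#' Read / write plain-text edge lists
#'
#' Two whitespace-separated integer columns, 0-based node ids, one
#' undirected edge per line, no duplicates.
#'
#' @param path file path.
#' @rdname edgelist_io
#' @export
read_edgelist <- function(path) {
  el <- utils::read.table(path, col.names = c("from", "to"),
                          colClasses = "integer")
  as.matrix(el)
}

#' @param net a `social_network` or a two-column 0-based edge matrix.
#' @rdname edgelist_io
#' @export
write_edgelist <- function(net, path) {
  el <- if (inherits(net, "social_network")) {
    igraph::as_edgelist(net$graph, names = FALSE) - 1L
  } else {
    as.matrix(net)
  }
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.social_network <- function(x, ...) {
  cat("<social_network> family ", x$family, ", ", x$n, " nodes, ",
      igraph::ecount(x$graph), " edges (mean degree ",
      signif(mean_degree(x), 4), ")\n", sep = "")
  invisible(x)
}
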