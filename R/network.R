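#' Binary adjacency matrix of one single-file movement
#'
#' Marks each pair of agents that occupy consecutive positions in the
#' movement: `a_ij = a_ji = 1` when `i` and `j` are adjacent in the order,
#' 0 otherwise, zero diagonal. The result is the adjacency matrix of a
#' Hamiltonian path over the agents, so it always contains exactly
#' `N - 1` unit edges.
#'
#' @param movement An `sfm_movement` (or integer permutation of `1..N`).
#' @return An `N x N` symmetric integer matrix.
#' @examples
#' movement_to_adjacency(c(2L, 1L, 3L))  # edges {1,2} and {1,3}
#' @export
movement_to_adjacency <- function(movement) {
  ord <- validate_movement(unclass(movement))
  N <- length(ord)
  A <- matrix(0L, N, N)
  if (N >= 2L) {
    idx <- cbind(ord[-N], ord[-1L])
    A[idx] <- 1L
    A[idx[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

#' Aggregate movement adjacencies into the weighted social graph
#'
#' Entrywise sum of per-movement binary adjacency matrices: the weight of
#' edge `{i, j}` counts how often agents `i` and `j` were consecutive
#' across the observed movements. Parallel observations accumulate weight
#' on a single edge (no multigraph). Since every movement contributes
#' `N - 1` unit edges, the aggregate's half-weight satisfies
#' `M = (N - 1) * n_exp`.
#'
#' @param adjacencies A list of `N x N` adjacency matrices sharing one `N`,
#'   or a list of `sfm_movement`s (converted internally).
#' @return An object of class `sfm_graph`: an `N x N` symmetric integer
#'   weight matrix with attribute `n_exp` (number of movements summed).
#' @examples
#' mvs <- list(c(2L, 1L, 3L), c(1L, 2L, 3L))
#' G <- aggregate_adjacencies(lapply(mvs, movement_to_adjacency))
#' sum(G) / 2  # M = (3 - 1) * 2 = 4
#' @export
aggregate_adjacencies <- function(adjacencies) {
  stopifnot(is.list(adjacencies), length(adjacencies) >= 1L)
  if (inherits(adjacencies[[1L]], "sfm_movement") ||
      is.null(dim(adjacencies[[1L]])))
    adjacencies <- lapply(adjacencies, movement_to_adjacency)
  N <- nrow(adjacencies[[1L]])
  G <- matrix(0L, N, N)
  for (A in adjacencies) {
    if (!is.matrix(A) || nrow(A) != N || ncol(A) != N)
      stop("all adjacency matrices must share the same dimension",
           call. = FALSE)
    G <- G + A
  }
  structure(G, n_exp = length(adjacencies), class = "sfm_graph")
}

# Fast path used by the simulation runner: accumulate consecutive pairs of
# each movement directly into one dense integer matrix.
accumulate_movements <- function(movements, N) {
  G <- matrix(0L, N, N)
  for (ord in movements) {
    n <- length(ord)
    if (n >= 2L) {
      idx <- cbind(ord[-n], ord[-1L])
      G[idx] <- G[idx] + 1L
      idx2 <- idx[, 2:1, drop = FALSE]
      G[idx2] <- G[idx2] + 1L
    }
  }
  structure(G, n_exp = length(movements), class = "sfm_graph")
}

#' Graph summaries: half-weight M and node strengths
#'
#' `graph_half_weight()` returns `M`, the sum of all edge weights (half the
#' matrix total); `graph_strengths()` returns the per-node strength `k_i`
#' (row sums of the weight matrix).
#'
#' @param graph An `sfm_graph` (or symmetric weight matrix).
#' @return A single number (`graph_half_weight`) or numeric vector
#'   (`graph_strengths`).
#' @export
graph_half_weight <- function(graph) sum(graph) / 2

#' @rdname graph_half_weight
#' @export
graph_strengths <- function(graph) rowSums(unclass(graph))

#' @export
print.sfm_graph <- function(x, ...) {
  N <- nrow(x)
  m <- sum(unclass(x) > 0) / 2
  cat(sprintf(
    "Aggregate social graph: %d nodes, %d weighted edges, M = %g (%s movements)\n",
    N, m, graph_half_weight(x),
    if (is.null(attr(x, "n_exp"))) "?" else attr(x, "n_exp")))
  invisible(x)
}

# sfm_graph -> igraph object (weighted, undirected), used for Louvain and
# GraphML export.
as_igraph <- function(graph) {
  A <- unclass(graph)
  attr(A, "n_exp") <- NULL
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
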