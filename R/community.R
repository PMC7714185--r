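#' Weighted Newman modularity of a partition
#'
#' Computes
#' \deqn{Q = \frac{1}{2M} \sum_{i,j} \left(a_{ij} - \frac{k_i k_j}{2M}\right)
#'   \delta(C(i), C(j))}
#' where `a_ij` are edge weights, `k_i` node strengths, `M` the total edge
#' weight (half the matrix sum), and the Kronecker delta restricts the sum
#' to pairs sharing a community. `Q` lies in `[-0.5, 1)`; the all-in-one
#' partition always scores 0.
#'
#' @param graph An `sfm_graph` or symmetric non-negative weight matrix.
#' @param membership Integer (or factor-like) vector assigning each node a
#'   community label; length must equal the node count.
#' @return A single number `Q`.
#' @examples
#' tri2 <- two_triangles()
#' modularity_q(tri2, c(1, 1, 1, 2, 2, 2))  # 0.5
#' modularity_q(tri2, rep(1, 6))            # 0
#' @export
modularity_q <- function(graph, membership) {
  A <- unclass(graph)
  n <- nrow(A)
  if (length(membership) != n)
    stop("`membership` must assign a community to every node", call. = FALSE)
  two_m <- sum(A)
  if (two_m <= 0)
    stop("modularity is undefined for an edgeless graph (2M = 0)",
         call. = FALSE)
  k <- rowSums(A)
  q <- 0
  for (lab in unique(membership)) {
    idx <- which(membership == lab)
    q <- q + sum(A[idx, idx]) - sum(k[idx])^2 / two_m
  }
  q / two_m
}

#' Louvain community detection on the aggregate graph
#'
#' Runs the Louvain heuristic — greedy single-node moves to the
#' neighbouring community with the largest modularity gain, followed by
#' community aggregation, iterated to convergence — on the weighted graph
#' at resolution 1. Delegates to [igraph::cluster_louvain()]; the node
#' visit order is randomized from R's RNG, so results are deterministic
#' under a fixed seed.
#'
#' Community labels are canonicalized to `1..n_eval` by first appearance
#' in node-ID order, so partitions are comparable across runs.
#'
#' @param graph An `sfm_graph` or symmetric non-negative weight matrix with
#'   positive total weight.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first so the partition is reproducible in isolation.
#' @return An object of class `sfm_partition`: integer vector of community
#'   labels with attributes `n_eval` (number of communities) and
#'   `modularity` (the weighted modularity of the returned partition,
#'   recomputed with [modularity_q()]).
#' @examples
#' G <- two_triangles()
#' louvain_communities(G, seed = 1)
#' @export
louvain_communities <- function(graph, seed = NULL) {
  A <- unclass(graph)
  if (sum(A) <= 0)
    stop("modularity is undefined for an edgeless graph (2M = 0)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(graph)
  # isolated nodes cannot arise on the simulated path (aggregates are
  # unions of Hamiltonian paths) but can in re-ingested data; Louvain
  # leaves them as singleton communities, which is the behaviour we want.
  cl <- igraph::cluster_louvain(g, resolution = 1)
  as_partition(igraph::membership(cl), graph = graph)
}

# Canonicalize labels to 1..n_eval by first appearance and attach the
# partition's modularity when a graph is available.
as_partition <- function(membership, graph = NULL) {
  m <- match(membership, unique(membership))
  structure(as.integer(m),
            n_eval = length(unique(m)),
            modularity = if (is.null(graph)) NULL else modularity_q(graph, m),
            class = "sfm_partition")
}

#' @export
print.sfm_partition <- function(x, ...) {
  q <- attr(x, "modularity")
  cat(sprintf("Partition of %d nodes into %d communities%s\n",
              length(x), attr(x, "n_eval"),
              if (is.null(q)) "" else sprintf(" (Q = %.4f)", q)))
  sizes <- table(unclass(x))
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Exact maximum-modularity partition by exhaustive enumeration
#'
#' Brute-force oracle for small graphs: enumerates every set partition of
#' the nodes (restricted-growth-string order) and returns one maximizing
#' the weighted modularity. Intended as an independent reference for
#' heuristic community detection; refuses more than `max_nodes` nodes
#' (Bell numbers explode).
#'
#' @param graph An `sfm_graph` or symmetric non-negative weight matrix.
#' @param max_nodes Enumeration guard (default 10; Bell(10) = 115975).
#' @return An `sfm_partition` attaining the global maximum of modularity.
#' @examples
#' best_partition_bruteforce(two_triangles())  # recovers the two triangles
#' @export
best_partition_bruteforce <- function(graph, max_nodes = 10L) {
  A <- unclass(graph)
  n <- nrow(A)
  if (n > max_nodes)
    stop(sprintf("brute-force enumeration limited to %d nodes (got %d)",
                 max_nodes, n), call. = FALSE)
  if (n == 1L)  # only one partition exists; modularity plays no role
    return(structure(1L, n_eval = 1L, modularity = NA_real_,
                     class = "sfm_partition"))
  if (sum(A) <= 0)
    stop("modularity is undefined for an edgeless graph (2M = 0)",
         call. = FALSE)
  best_q <- -Inf
  best <- rep(1L, n)
  # iterate restricted growth strings: a[1] = 1, a[i] <= max(a[1..i-1]) + 1
  a <- rep(1L, n)
  repeat {
    q <- modularity_q(A, a)
    if (q > best_q) { best_q <- q; best <- a }
    # advance to the next restricted growth string
    i <- n
    while (i >= 2L) {
      if (a[i] <= max(a[seq_len(i - 1L)])) break
      i <- i - 1L
    }
    if (i < 2L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
  }
  as_partition(best, graph = graph)
}

#' Small fixture graph: two disjoint unit-weight triangles
#'
#' Six nodes, edges (1,2,3) and (4,5,6) forming two triangles of unit
#' weight. Handy as a graph whose optimal partition (the two triangles)
#' has modularity exactly 0.5.
#'
#' @return An `sfm_graph`.
#' @export
two_triangles <- function() {
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  structure(A, class = "sfm_graph")
}
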