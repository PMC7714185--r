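#' Modularity change from merging two communities
#'
#' For a partition with communities `p != q`, merging them changes the
#' modularity by exactly
#' \deqn{Q' - Q = \frac{m}{M} - \frac{K_p K_q}{2 M^2}}
#' where `m` is the total weight on edges between the two communities,
#' `K_p` and `K_q` are the total strengths (sums of node strengths `k_i`)
#' of the communities, and `M` is the graph half-weight. Merging is
#' favourable exactly when `m > K_p K_q / (2M)`; the separated-subgroup
#' analysis argues this fails for true subgroups, so greedy modularity
#' merging stops at the true clustering.
#'
#' @param graph An `sfm_graph` or symmetric non-negative weight matrix.
#' @param partition An `sfm_partition` or membership vector over the
#'   graph's nodes.
#' @param p,q Two distinct community labels present in the partition.
#' @return An object of class `sfm_merge_delta`: list with `m`, `K_p`,
#'   `K_q`, `M`, and `delta` (`Q' - Q`).
#' @examples
#' G <- two_triangles()
#' merge_modularity_delta(G, c(1, 1, 1, 2, 2, 2), 1, 2)$delta  # -0.5
#' @export
merge_modularity_delta <- function(graph, partition, p, q) {
  A <- unclass(graph)
  membership <- unclass(partition)
  if (length(membership) != nrow(A))
    stop("`partition` must cover exactly the graph's nodes", call. = FALSE)
  if (length(p) != 1L || length(q) != 1L || p == q)
    stop("`p` and `q` must be two distinct community labels", call. = FALSE)
  in_p <- membership == p
  in_q <- membership == q
  if (!any(in_p) || !any(in_q))
    stop("both labels must be present in the partition", call. = FALSE)
  M <- sum(A) / 2
  if (M <= 0)
    stop("modularity is undefined for an edgeless graph (2M = 0)",
         call. = FALSE)
  k <- rowSums(A)
  m <- sum(A[in_p, in_q])
  K_p <- sum(k[in_p])
  K_q <- sum(k[in_q])
  structure(list(m = m, K_p = K_p, K_q = K_q, M = M,
                 delta = m / M - (K_p * K_q) / (2 * M^2)),
            class = "sfm_merge_delta")
}

#' @export
print.sfm_merge_delta <- function(x, ...) {
  cat(sprintf("Merge delta: m = %g, K_p = %g, K_q = %g, M = %g\n",
              x$m, x$K_p, x$K_q, x$M))
  cat(sprintf("  Q' - Q = %.6g (%s to merge)\n", x$delta,
              if (x$delta > 0) "favourable" else "unfavourable"))
  invisible(x)
}

#' Expected between-subgroup edge weight in the separated regime
#'
#' Under the separated-subgroup assumption (subgroups form contiguous
#' blocks in every movement, all block orderings equally probable), each
#' movement contributes `n_I - 1` between-subgroup adjacencies. Two values
#' of the expected between weight `m` for one subgroup pair are reported:
#'
#' * `as_printed`: `n_exp / n_I` — the total between weight
#'   `(n_I - 1) * n_exp` divided by the number of *ordered* subgroup pairs
#'   `n_I (n_I - 1)`.
#' * `enumeration`: the expectation for an (unordered) pair obtained by
#'   brute force over all `n_I!` equally likely block orderings, counting
#'   how often the pair is adjacent. This equals `2 n_exp / n_I` — twice
#'   the first value; in a uniform random ordering of `n_I` blocks a given
#'   pair is adjacent with probability `2 / n_I` (for `n_I > enum_limit`,
#'   where full enumeration would be pointless work, the value is computed
#'   from that exact adjacency probability, to which the enumeration
#'   provably sums).
#'
#' Both are returned so the factor-2 normalization discrepancy stays
#' visible rather than being silently resolved either way.
#'
#' @param n_I Number of subgroups (>= 2; with one subgroup no
#'   between-subgroup edge exists).
#' @param n_exp Number of movements.
#' @param enum_limit Largest `n_I` enumerated exhaustively (default 7,
#'   i.e. up to 5040 orderings).
#' @return List with `as_printed`, `enumeration`, and `n_orderings`
#'   (number of block orderings enumerated, or `NA` when the closed form
#'   was used).
#' @examples
#' expected_between_weight(10, 30)$as_printed   # 3
#' expected_between_weight(2, 10)$enumeration   # 10: the pair is always adjacent
#' @export
expected_between_weight <- function(n_I, n_exp, enum_limit = 7L) {
  if (length(n_I) != 1L || !is.finite(n_I) || n_I < 2 || n_I != round(n_I))
    stop("`n_I` must be an integer >= 2 (no between-subgroup edges otherwise)",
         call. = FALSE)
  if (length(n_exp) != 1L || !is.finite(n_exp) || n_exp < 1)
    stop("`n_exp` must be >= 1", call. = FALSE)
  n_I <- as.integer(n_I)
  if (n_I <= enum_limit) {
    perms <- permutations_of(n_I)
    # fraction of orderings in which blocks 1 and 2 are adjacent; by
    # symmetry this is the adjacency probability of every unordered pair
    adj <- vapply(perms, function(p) {
      pos <- match(c(1L, 2L), p)
      abs(pos[1L] - pos[2L]) == 1L
    }, logical(1))
    p_adj <- mean(adj)
    n_orderings <- length(perms)
  } else {
    p_adj <- 2 / n_I
    n_orderings <- NA_integer_
  }
  list(as_printed = n_exp / n_I,
       enumeration = p_adj * n_exp,
       n_orderings = n_orderings)
}

# All permutations of 1..n as a list of integer vectors.
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' Sufficient-condition bound for the true clustering to resist merging
#'
#' In the separated regime each movement assigns at most `n_D` edges to a
#' terminal subgroup block and `n_D + 1` to interior ones, giving the
#' strength bound `K_p, K_q <= n_D * n_exp` (exact for terminal blocks).
#' A sufficient condition for merging any two true subgroups to lower the
#' modularity is then
#' \deqn{m < \frac{(n_D n_{exp})^2}{2M}, \qquad M = (N - 1)\, n_{exp},}
#' and rewriting the right-hand side as a multiple of the expected
#' between weight `n_exp / n_I` gives the prefactor
#' \deqn{\frac{n_D}{2} \cdot \frac{n_D}{(n_D + 1) - 1/n_I}}
#' (approximately `n_D / 2`), so the condition holds comfortably once
#' `n_exp` is large.
#'
#' @param params An [sfm_params()] object (or list with `n_I`, `n_D`,
#'   `n_exp`); needs `N >= 2`.
#' @return List with `M`, `bound` (the right-hand side above), `prefactor`,
#'   `expected_m` (both variants from [expected_between_weight()], `NA`
#'   when `n_I < 2`), and logical `holds_printed` / `holds_enumeration`
#'   saying whether each expected `m` is below the bound.
#' @examples
#' b <- sufficient_condition_bound(sfm_params(10, 5, sigma_I = 10, n_exp = 30))
#' b$bound      # 22500 / 3540 = 6.3559...
#' b$prefactor  # 2.5 * 5 / 5.9 = 2.1186...
#' @export
sufficient_condition_bound <- function(params) {
  if (!inherits(params, "sfm_params"))
    params <- do.call(sfm_params, as.list(params))
  n_I <- params$n_I; n_D <- params$n_D; n_exp <- params$n_exp
  N <- params$N
  if (N < 2L)
    stop("need N >= 2 agents", call. = FALSE)
  M <- (N - 1) * n_exp
  bound <- (n_D * n_exp)^2 / (2 * M)
  prefactor <- if (n_D == 0) 0 else (n_D / 2) * n_D / ((n_D + 1) - 1 / n_I)
  em <- if (n_I >= 2L) expected_between_weight(n_I, n_exp)
        else list(as_printed = NA_real_, enumeration = NA_real_)
  list(M = M, bound = bound, prefactor = prefactor,
       expected_m = list(as_printed = em$as_printed,
                         enumeration = em$enumeration),
       holds_printed = isTRUE(em$as_printed < bound),
       holds_enumeration = isTRUE(em$enumeration < bound))
}

#' Measured between-subgroup weight on a simulated graph
#'
#' Sums the aggregate edge weight crossing the boundary between two true
#' subgroups, together with the total strength incident to each (`K_p`,
#' `K_q`). This is the empirical counterpart of
#' [expected_between_weight()]; in the separated regime
#' (`sigma_I >> sigma_D`) terminal blocks satisfy the strength bound
#' `K <= n_D * n_exp + (boundary terms)`.
#'
#' @param graph An `sfm_graph` over the population's agents.
#' @param population The `sfm_population` carrying true subgroup labels.
#'   (With fresh coordinates per movement, any realization carries the
#'   same labels; memberships are fixed by the parameters.)
#' @param p,q Two distinct subgroup IDs in `1..n_I`.
#' @return List with `m`, `K_p`, `K_q`.
#' @export
empirical_between_weight <- function(graph, population, p, q) {
  stopifnot(inherits(population, "sfm_population"))
  sub <- population$subgroup
  n_I <- population$params$n_I
  ok <- function(s) length(s) == 1L && !is.na(s) && s == round(s) &&
    s >= 1 && s <= n_I
  if (!ok(p) || !ok(q) || p == q)
    stop(sprintf("`p` and `q` must be distinct subgroup IDs in 1..%d", n_I),
         call. = FALSE)
  A <- unclass(graph)
  if (nrow(A) != length(sub))
    stop("graph and population sizes differ", call. = FALSE)
  k <- rowSums(A)
  list(m = sum(A[sub == p, sub == q]),
       K_p = sum(k[sub == p]),
       K_q = sum(k[sub == q]))
}
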