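#' Serialize a population into a single-file movement
#'
#' Produces one "single-file movement": the order in which agents move,
#' generated by the iterative nearest-neighbour rule. The initiator (first
#' mover) is sampled uniformly over all agents unless forced; thereafter
#' the next mover is always the Euclidean-nearest agent, among those that
#' have not yet moved, to the *last* moved agent. Ties in the argmin (a
#' probability-zero event under the continuous placement model) are broken
#' deterministically by lowest agent ID.
#'
#' @param population An `sfm_population` from [generate_population()].
#' @param initiator Optional agent ID to force as first mover (testing /
#'   replay hook); when `NULL` the initiator is drawn uniformly.
#' @return An object of class `sfm_movement`: an integer vector — a
#'   permutation of `1..N` — with attribute `initiator`.
#' @examples
#' set.seed(42)
#' pop <- generate_population(sfm_params(n_I = 3, n_D = 2, sigma_I = 50))
#' serialize(pop)
#' @export
serialize <- function(population, initiator = NULL) {
  stopifnot(inherits(population, "sfm_population"))
  N <- nrow(population$locations)
  if (is.null(initiator)) {
    initiator <- sample.int(N, 1L)
  } else {
    if (length(initiator) != 1L || is.na(initiator) ||
        initiator != round(initiator) || initiator < 1L || initiator > N)
      stop(sprintf("`initiator` must be an agent ID in 1..%d", N),
           call. = FALSE)
    initiator <- as.integer(initiator)
  }
  ord <- greedy_chain(population$locations, initiator)
  structure(ord, initiator = initiator, class = "sfm_movement")
}

# Greedy nearest-neighbour chain over a full pairwise distance matrix.
# which.min() returns the first (lowest-index) minimiser, which implements
# the lowest-agent-ID tie-break.
greedy_chain <- function(locations, start) {
  N <- nrow(locations)
  if (N == 1L) return(1L)
  D <- as.matrix(stats::dist(locations))
  ord <- integer(N)
  remaining <- rep(TRUE, N)
  ord[1L] <- start
  remaining[start] <- FALSE
  cur <- start
  for (i in 2:N) {
    d <- D[, cur]
    d[!remaining] <- Inf
    nxt <- which.min(d)
    ord[i] <- nxt
    remaining[nxt] <- FALSE
    cur <- nxt
  }
  ord
}

#' @export
print.sfm_movement <- function(x, ...) {
  cat(sprintf("Single-file movement of %d agents (initiator: %d)\n",
              length(x), attr(x, "initiator")))
  cat(" ", paste(unclass(x), collapse = " -> "), "\n")
  invisible(x)
}

# Validate that a movement is a permutation of 1..N; used on re-ingested
# records where the invariant is not guaranteed by construction.
validate_movement <- function(order, N = length(order)) {
  order <- as.integer(order)
  if (length(order) != N || anyNA(order) ||
      !identical(sort(order), seq_len(N)))
    stop("movement is not a permutation of 1..N", call. = FALSE)
  structure(order, initiator = order[1L], class = "sfm_movement")
}
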