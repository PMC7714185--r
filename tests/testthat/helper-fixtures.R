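# Build an sfm_population directly from coordinates, for hand-checked
# serializer examples where the spatial model is irrelevant.
fake_population <- function(locations, subgroup = rep(1L, nrow(locations)),
                            n_I = max(subgroup)) {
  locations <- as.matrix(locations)
  colnames(locations) <- c("x", "y")
  N <- nrow(locations)
  n_D <- N / n_I - 1L
  params <- sfm_params(n_I = n_I, n_D = max(n_D, 0L),
                       sigma_I = 1, sigma_D = 1, n_exp = 1, n_reps = 1)
  role <- ifelse(seq_len(N) <= n_I, "independenter", "depender")
  structure(list(locations = locations, subgroup = as.integer(subgroup),
                 role = role, params = params),
            class = "sfm_population")
}

# Random connected-ish weighted graph on n nodes: each edge present with
# probability p, integer weights in 1..max_w; resampled until 2M > 0.
random_weighted_graph <- function(n, p = 0.5, max_w = 5L) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p]
    A[on] <- sample.int(max_w, length(on), replace = TRUE)
    A <- A + t(A)
    if (sum(A) > 0) return(structure(A, class = "sfm_graph"))
  }
}

# Random membership vector with at least k communities (all non-empty).
random_partition <- function(n, k = 2L) {
  repeat {
    m <- sample.int(k, n, replace = TRUE)
    if (length(unique(m)) >= 2L) return(m)
  }
}

# Two unit-weight 4-cliques joined by a single unit edge (nodes 4-5).
two_cliques_bridge <- function() {
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L
  A[5:8, 5:8] <- 1L
  diag(A) <- 0L
  A[4, 5] <- A[5, 4] <- 1L
  structure(A, class = "sfm_graph")
}

# Are the subgroup labels contiguous blocks along the movement order?
blocks_contiguous <- function(movement, subgroup) {
  labs <- subgroup[as.integer(movement)]
  sum(labs[-1] != labs[-length(labs)]) == length(unique(labs)) - 1L
}
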