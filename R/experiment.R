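#' Cluster-count recovery score
#'
#' The score of a cluster estimation is `r = n_eval / n_I`, the ratio of
#' the number of communities found to the true number of subgroups. `r = 1`
#' means the subgroup count was recovered exactly; `r > 1` an
#' overestimation, `r < 1` an underestimation.
#'
#' @param n_eval Number of communities returned by clustering (>= 1).
#' @param n_I True number of subgroups (>= 1).
#' @return The score `r`, a positive number.
#' @examples
#' recovery_score(10, 10)  # 1
#' recovery_score(12, 10)  # 1.2, overestimate
#' @export
recovery_score <- function(n_eval, n_I) {
  if (length(n_eval) != 1L || !is.finite(n_eval) || n_eval < 1 ||
      n_eval != round(n_eval))
    stop("`n_eval` must be a positive integer", call. = FALSE)
  if (length(n_I) != 1L || !is.finite(n_I) || n_I < 1 || n_I != round(n_I))
    stop("`n_I` must be a positive integer", call. = FALSE)
  n_eval / n_I
}

#' Run one complete simulation
#'
#' One end-to-end pass of the pipeline: `n_exp` times, draw a fresh
#' population realization (the subgroup memberships and IDs are fixed by
#' the parameters; the coordinates are redrawn before every movement) and
#' serialize it into a single-file movement; aggregate the `n_exp`
#' consecutive-pair adjacencies into the weighted social graph; cluster
#' the graph with Louvain; and score the recovered community count.
#'
#' @param params An [sfm_params()] object. `N = 1` is rejected: a single
#'   agent yields an edgeless graph on which modularity is undefined.
#' @param seed Optional integer seed governing all randomness of the run
#'   (population draws, initiators, Louvain visit order).
#' @param keep Keep the per-movement populations and movement orders in
#'   the result (memory-heavy; mainly for inspection and testing).
#' @return An object of class `sfm_run`: list with `params`, `seed`,
#'   `graph` (`sfm_graph`), `partition` (`sfm_partition`), `n_eval`,
#'   `score`, and when `keep = TRUE` also `movements` and `populations`.
#' @examples
#' run <- run_single_simulation(
#'   sfm_params(n_I = 5, n_D = 5, sigma_I = 10, n_exp = 10), seed = 1)
#' run$score
#' @export
run_single_simulation <- function(params, seed = NULL, keep = FALSE) {
  stopifnot(inherits(params, "sfm_params"))
  if (params$N < 2L)
    stop(paste("degenerate run: N = 1 gives an edgeless graph with",
               "undefined modularity"), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  movements <- vector("list", params$n_exp)
  populations <- if (keep) vector("list", params$n_exp)
  for (k in seq_len(params$n_exp)) {
    pop <- generate_population(params)
    movements[[k]] <- serialize(pop)
    if (keep) populations[[k]] <- pop
  }
  graph <- accumulate_movements(movements, N)
  partition <- louvain_communities(graph)
  n_eval <- attr(partition, "n_eval")
  out <- list(params = params, seed = seed, graph = graph,
              partition = partition, n_eval = n_eval,
              score = recovery_score(n_eval, params$n_I))
  if (keep) {
    out$movements <- movements
    out$populations <- populations
  }
  structure(out, class = "sfm_run")
}

#' @export
print.sfm_run <- function(x, ...) {
  cat(sprintf(
    "Simulation run: n_I = %d, n_D = %d, sigma_I = %g, n_exp = %d%s\n",
    x$params$n_I, x$params$n_D, x$params$sigma_I, x$params$n_exp,
    if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  cat(sprintf("  communities found: n_eval = %d; score r = %g\n",
              x$n_eval, x$score))
  invisible(x)
}

#' Average recovery score over Monte-Carlo replicates
#'
#' Runs [run_single_simulation()] `n_reps` times with independent derived
#' seeds and returns the arithmetic mean and SD of the score. Replicate
#' seeds are pre-drawn from the master seed, so any execution order (or a
#' parallel backend) reproduces the same result.
#'
#' @param params An [sfm_params()] object.
#' @param n_reps Number of replicates; defaults to `params$n_reps`.
#' @param seed Master seed for the replicate seed stream.
#' @param progress Emit a progress message every `progress` replicates to
#'   stderr (0 = silent).
#' @return List with `mean_r`, `sd_r`, `scores` (per-replicate vector),
#'   `n_reps`, and `params`.
#' @examples
#' p <- sfm_params(n_I = 5, n_D = 5, sigma_I = 100, n_exp = 10)
#' average_score(p, n_reps = 10, seed = 1)$mean_r
#' @export
average_score <- function(params, n_reps = params$n_reps, seed = 1L,
                          progress = 0L) {
  stopifnot(inherits(params, "sfm_params"), n_reps >= 1L)
  seeds <- derive_seeds(seed, n_reps)
  scores <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    rec <- tryCatch(run_single_simulation(params, seed = seeds[i]),
                    error = function(e)
                      stop(sprintf("replicate %d: %s", i, conditionMessage(e)),
                           call. = FALSE))
    scores[i] <- rec$score
    if (progress > 0L && i %% progress == 0L)
      message(sprintf("  replicate %d/%d (running mean r = %.3f)",
                      i, n_reps, mean(scores[seq_len(i)])))
  }
  list(mean_r = mean(scores),
       sd_r = if (n_reps > 1L) stats::sd(scores) else NA_real_,
       scores = scores, n_reps = n_reps, params = params)
}

#' Monte-Carlo sweep over a parameter grid
#'
#' Evaluates [average_score()] at every combination of the supplied axis
#' values and returns one row per grid point, suitable for contour
#' plotting of the score surface.
#'
#' @param n_I,n_D,sigma_I,n_exp Numeric vectors of axis values.
#' @param sigma_D Depender SD, held fixed across the grid (default 1).
#' @param n_reps Replicates per grid cell.
#' @param seed Master seed; each cell gets an independent derived seed.
#' @param progress Log each completed cell to stderr.
#' @return A data frame of class `sfm_sweep` with columns
#'   `n_I, n_D, sigma_I, n_exp, n_reps, mean_r, sd_r` and one row per
#'   combination (row count = product of axis lengths).
#' @examples
#' sw <- sweep_scores(n_I = c(2, 5), n_D = 2, sigma_I = 100, n_exp = 10,
#'                    n_reps = 5, seed = 1)
#' nrow(sw)  # 2
#' @export
sweep_scores <- function(n_I, n_D, sigma_I, n_exp, sigma_D = 1,
                         n_reps = 1000L, seed = 1L, progress = FALSE) {
  stopifnot(length(n_I) >= 1L, length(n_D) >= 1L,
            length(sigma_I) >= 1L, length(n_exp) >= 1L)
  grid <- expand.grid(n_I = n_I, n_D = n_D, sigma_I = sigma_I,
                      n_exp = n_exp, KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(grid))
  grid$n_reps <- as.integer(n_reps)
  grid$mean_r <- NA_real_
  grid$sd_r <- NA_real_
  for (g in seq_len(nrow(grid))) {
    p <- sfm_params(n_I = grid$n_I[g], n_D = grid$n_D[g],
                    sigma_I = grid$sigma_I[g], sigma_D = sigma_D,
                    n_exp = grid$n_exp[g], n_reps = n_reps)
    res <- average_score(p, n_reps = n_reps, seed = cell_seeds[g])
    grid$mean_r[g] <- res$mean_r
    grid$sd_r[g] <- res$sd_r
    if (isTRUE(progress))
      message(sprintf(
        "cell %d/%d: n_I=%d n_D=%d sigma_I=%g n_exp=%d -> mean r = %.3f",
        g, nrow(grid), grid$n_I[g], grid$n_D[g], grid$sigma_I[g],
        grid$n_exp[g], grid$mean_r[g]))
  }
  class(grid) <- c("sfm_sweep", "data.frame")
  grid
}

#' Default sweep grid
#'
#' The reference evaluation grid: `n_I` and `n_D` from 1 to 20,
#' `n_exp` in {10, 30}, `sigma_I` in {1, 2, 5, 10, 100} — 4000 cells.
#'
#' @return Named list of axis vectors accepted by [sweep_scores()].
#' @export
default_sweep_grid <- function() {
  list(n_I = 1:20, n_D = 1:20, n_exp = c(10L, 30L),
       sigma_I = c(1, 2, 5, 10, 100))
}

#' @export
summary.sfm_sweep <- function(object, ...) {
  cat(sprintf("Score sweep over %d parameter combinations (%d reps each)\n",
              nrow(object), object$n_reps[1L]))
  cat(sprintf("  mean r range: [%.3f, %.3f]; cells with |r - 1| <= 0.05: %d\n",
              min(object$mean_r), max(object$mean_r),
              sum(abs(object$mean_r - 1) <= 0.05)))
  invisible(object)
}

#' @description Contour plot of the mean score surface over (n_I, n_D) for
#'   one `sigma_I` / `n_exp` slice of a sweep.
#' @param x An `sfm_sweep`.
#' @param sigma_I,n_exp Slice selectors; default to the first value present.
#' @param ... Passed to [graphics::filled.contour()].
#' @rdname sweep_scores
#' @export
plot.sfm_sweep <- function(x, sigma_I = x$sigma_I[1L], n_exp = x$n_exp[1L],
                           ...) {
  sl <- x[x$sigma_I == sigma_I & x$n_exp == n_exp, , drop = FALSE]
  xs <- sort(unique(sl$n_I)); ys <- sort(unique(sl$n_D))
  if (length(xs) < 2L || length(ys) < 2L)
    stop("need at least a 2 x 2 grid in (n_I, n_D) to draw a contour",
         call. = FALSE)
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(sl$n_I, xs), match(sl$n_D, ys))] <- sl$mean_r
  graphics::filled.contour(
    xs, ys, z, xlab = "n_I (subgroups)", ylab = "n_D (dependers)",
    main = sprintf("mean score r (sigma_I = %g, n_exp = %d)", sigma_I, n_exp),
    ...)
  invisible(x)
}
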