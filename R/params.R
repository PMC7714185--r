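#' Simulation parameters
#'
#' Bundle and validate the knobs of the single-file-movement simulation.
#' A simulated group consists of `n_I` subgroups, each made of one
#' *independenter* (a core agent placed independently of everyone else) and
#' `n_D` *dependers* (followers placed around their independenter), so the
#' total group size is `N = n_I * (n_D + 1)`.
#'
#' @param n_I Number of subgroups / independenters (integer, >= 1).
#' @param n_D Number of dependers per subgroup (integer, >= 0).
#' @param sigma_I Per-axis standard deviation of independenter placement
#'   around the origin (arbitrary distance units, > 0).
#' @param sigma_D Per-axis standard deviation of depender placement around
#'   its independenter (same units, > 0). Defaults to 1, the reference scale
#'   against which `sigma_I` is measured.
#' @param n_exp Number of single-file movements observed per simulation
#'   (integer, >= 1).
#' @param n_reps Number of Monte-Carlo replicates used by
#'   [average_score()] and [sweep_scores()] (integer, >= 1).
#'
#' @return An object of class `sfm_params`: a list with the validated fields
#'   plus the derived total agent count `N`.
#' @examples
#' p <- sfm_params(n_I = 5, n_D = 5, sigma_I = 10, n_exp = 10)
#' p$N  # 30 agents
#' @seealso [generate_population()], [run_single_simulation()]
#' @export
sfm_params <- function(n_I, n_D, sigma_I, sigma_D = 1, n_exp = 10,
                       n_reps = 1000) {
  check_count <- function(x, name, min) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
      stop(sprintf("`%s` must be a single integer >= %d", name, min),
           call. = FALSE)
    as.integer(x)
  }
  check_pos <- function(x, name) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
      stop(sprintf("`%s` must be a single positive number", name),
           call. = FALSE)
    as.numeric(x)
  }
  p <- list(
    n_I     = check_count(n_I, "n_I", 1L),
    n_D     = check_count(n_D, "n_D", 0L),
    sigma_I = check_pos(sigma_I, "sigma_I"),
    sigma_D = check_pos(sigma_D, "sigma_D"),
    n_exp   = check_count(n_exp, "n_exp", 1L),
    n_reps  = check_count(n_reps, "n_reps", 1L)
  )
  p$N <- p$n_I * (p$n_D + 1L)
  structure(p, class = "sfm_params")
}

#' @export
print.sfm_params <- function(x, ...) {
  cat("Single-file movement simulation parameters\n")
  cat(sprintf("  subgroups (n_I):        %d\n", x$n_I))
  cat(sprintf("  dependers each (n_D):   %d\n", x$n_D))
  cat(sprintf("  total agents (N):       %d\n", x$N))
  cat(sprintf("  placement SDs:          sigma_I = %g, sigma_D = %g\n",
              x$sigma_I, x$sigma_D))
  cat(sprintf("  movements per run:      %d\n", x$n_exp))
  cat(sprintf("  Monte-Carlo replicates: %d\n", x$n_reps))
  invisible(x)
}

# Derive a vector of n reproducible sub-seeds from one master seed.
# Pre-drawing the whole table makes results independent of execution order,
# so replicates and sweep cells can run in any order (or in parallel).
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}
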