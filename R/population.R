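#' Generate a clustered agent population
#'
#' Draws the spatial configuration of one animal group from the hierarchical
#' bivariate Gaussian model. Independenter locations are i.i.d. draws from a
#' circular bivariate normal centred at the origin with per-axis SD
#' `sigma_I`; each depender is drawn from a circular bivariate normal centred
#' at its subgroup's independenter with per-axis SD `sigma_D`. Covariances
#' are isotropic diagonal (`sigma^2 * I`); no correlation is modelled.
#'
#' Agent IDs are fixed by construction: independenter of subgroup `i` is
#' agent `i` (IDs `1..n_I`), and depender `j` of subgroup `i` is agent
#' `n_I + (i - 1) * n_D + j`, i.e. dependers are listed after all
#' independenters, grouped by subgroup. Draw order is documented and fixed
#' (independenter coordinates first, then depender offsets, each axis-wise),
#' so a seeded RNG state reproduces locations bit-for-bit.
#'
#' @param params An [sfm_params()] object.
#' @return An object of class `sfm_population`: list with `locations`
#'   (`N x 2` numeric matrix), `subgroup` (integer vector, subgroup ID of
#'   each agent), `role` (character, `"independenter"` or `"depender"`),
#'   and `params`.
#' @examples
#' set.seed(1)
#' pop <- generate_population(sfm_params(n_I = 10, n_D = 5, sigma_I = 100))
#' nrow(pop$locations)    # 60
#' table(pop$subgroup)    # 10 subgroups of 6
#' @export
generate_population <- function(params) {
  if (!inherits(params, "sfm_params"))
    params <- do.call(sfm_params, as.list(params))
  n_I <- params$n_I; n_D <- params$n_D; N <- params$N

  ind_loc <- matrix(stats::rnorm(2L * n_I, mean = 0, sd = params$sigma_I),
                    ncol = 2L)
  subgroup <- c(seq_len(n_I), if (n_D > 0L) rep(seq_len(n_I), each = n_D))
  role <- c(rep("independenter", n_I),
            rep("depender", N - n_I))
  locations <- matrix(NA_real_, nrow = N, ncol = 2L,
                      dimnames = list(NULL, c("x", "y")))
  locations[seq_len(n_I), ] <- ind_loc
  if (n_D > 0L) {
    dep_sub <- subgroup[(n_I + 1L):N]
    locations[(n_I + 1L):N, ] <-
      ind_loc[dep_sub, , drop = FALSE] +
      matrix(stats::rnorm(2L * (N - n_I), mean = 0, sd = params$sigma_D),
             ncol = 2L)
  }
  structure(list(locations = locations,
                 subgroup  = as.integer(subgroup),
                 role      = role,
                 params    = params),
            class = "sfm_population")
}

#' @export
print.sfm_population <- function(x, ...) {
  p <- x$params
  cat(sprintf("Agent population: N = %d (%d subgroups x %d agents each)\n",
              p$N, p$n_I, p$n_D + 1L))
  cat(sprintf("  sigma_I = %g, sigma_D = %g\n", p$sigma_I, p$sigma_D))
  invisible(x)
}

#' @description Plot agent locations coloured by subgroup; independenters
#'   are drawn as filled triangles, dependers as open circles.
#' @param x An `sfm_population`.
#' @param ... Passed to [graphics::plot()].
#' @rdname generate_population
#' @export
plot.sfm_population <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(x$subgroup), "Dark 2")[x$subgroup]
  pch <- ifelse(x$role == "independenter", 17L, 1L)
  graphics::plot(x$locations, col = cols, pch = pch, asp = 1,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Write / read a population table
#'
#' Plain CSV with header `agent_id,subgroup_id,role,x,y`; IDs are 1-based
#' and coordinates are written at full precision.
#'
#' @param population An `sfm_population`.
#' @param path File path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns the table as a data frame.
#' @export
write_population <- function(population, path) {
  stopifnot(inherits(population, "sfm_population"))
  df <- data.frame(agent_id = seq_along(population$subgroup),
                   subgroup_id = population$subgroup,
                   role = population$role,
                   x = format(population$locations[, 1], digits = 17,
                              trim = TRUE, scientific = FALSE),
                   y = format(population$locations[, 2], digits = 17,
                              trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
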