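#' Write and read single-file movement records
#'
#' Movement sets are stored as plain CSV with header
#' `rep,movement_index,position,agent_id` — one row per agent per
#' movement, all indices 1-based. `read_movements()` tolerates arbitrary
#' row order (rows are sorted by `rep`, `movement_index`, `position`
#' before reconstruction) and validates that every movement is a complete
#' permutation with contiguous positions, naming the offending movement
#' on failure.
#'
#' @param movements Either a list of `sfm_movement`s (written as replicate
#'   `rep`) or a list of such lists (one per replicate, written as
#'   replicates `1, 2, ...`).
#' @param path File path.
#' @param rep Replicate index used when `movements` is a flat list.
#' @return `write_movements()` returns `path` invisibly.
#'   `read_movements()` returns a named list of replicates, each a list of
#'   `sfm_movement`s.
#' @examples
#' set.seed(1)
#' pop <- generate_population(sfm_params(n_I = 2, n_D = 2, sigma_I = 50))
#' mvs <- replicate(3, serialize(pop), simplify = FALSE)
#' f <- tempfile(fileext = ".csv")
#' write_movements(mvs, f)
#' identical(read_movements(f)[["1"]], mvs)
#' @export
write_movements <- function(movements, path, rep = 1L) {
  if (length(movements) >= 1L && !is.list(movements[[1L]])) {
    movements <- stats::setNames(list(movements), rep)
  } else if (is.null(names(movements))) {
    names(movements) <- seq_along(movements)
  }
  rows <- do.call(rbind, unlist(lapply(names(movements), function(r) {
    lapply(seq_along(movements[[r]]), function(k) {
      ord <- as.integer(movements[[r]][[k]])
      data.frame(rep = as.integer(r), movement_index = k,
                 position = seq_along(ord), agent_id = ord)
    })
  }), recursive = FALSE))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_movements
#' @export
read_movements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rep", "movement_index", "position", "agent_id")
  if (!all(need %in% names(df)))
    stop("malformed movement file: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[order(df$rep, df$movement_index, df$position), , drop = FALSE]
  out <- list()
  for (r in unique(df$rep)) {
    dr <- df[df$rep == r, , drop = FALSE]
    mvs <- list()
    for (k in unique(dr$movement_index)) {
      dk <- dr[dr$movement_index == k, , drop = FALSE]
      where <- sprintf("rep %s, movement %s", r, k)
      if (anyDuplicated(dk$agent_id))
        stop(sprintf("malformed movement file: duplicate agent %d in %s",
                     dk$agent_id[duplicated(dk$agent_id)][1L], where),
             call. = FALSE)
      if (!identical(as.integer(dk$position), seq_len(nrow(dk))))
        stop(sprintf(
          "malformed movement file: positions not contiguous 1..%d in %s",
          nrow(dk), where), call. = FALSE)
      mvs[[as.character(k)]] <- tryCatch(
        validate_movement(dk$agent_id),
        error = function(e)
          stop(sprintf("malformed movement file: %s in %s",
                       conditionMessage(e), where), call. = FALSE))
    }
    out[[as.character(r)]] <- unname(mvs)
  }
  out
}

#' Export the aggregate graph
#'
#' Writes either a sorted tab-separated edge list
#' (`source_id<TAB>target_id<TAB>weight`, `source_id < target_id`,
#' zero-weight pairs omitted) or GraphML with a `weight` edge attribute
#' (via [igraph::write_graph()]). Output bytes are deterministic for a
#' given graph.
#'
#' @param graph An `sfm_graph` or symmetric weight matrix.
#' @param path File path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  A <- unclass(graph)
  if (format == "edgelist") {
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    df <- data.frame(source_id = idx[, 1L], target_id = idx[, 2L],
                     weight = A[idx])
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}

#' @description `read_edgelist()` rebuilds an `sfm_graph` from an exported
#'   edge list; `n_nodes` must be supplied because isolated nodes carry no
#'   rows.
#' @param n_nodes Number of nodes in the rebuilt graph.
#' @rdname export_graph
#' @export
read_edgelist <- function(path, n_nodes) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  A <- matrix(0L, n_nodes, n_nodes)
  A[cbind(df$source_id, df$target_id)] <- as.integer(df$weight)
  A[cbind(df$target_id, df$source_id)] <- as.integer(df$weight)
  structure(A, class = "sfm_graph")
}

#' Export a partition as CSV
#'
#' Header `agent_id,community_id`; labels are canonicalized to
#' `1..n_eval` by first appearance.
#'
#' @param partition An `sfm_partition` or membership vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_partition <- function(partition, path) {
  m <- unclass(as_partition(unclass(partition)))
  utils::write.csv(
    data.frame(agent_id = seq_along(m), community_id = m),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A small JSON document recording the parameters, master seed, tool
#' version, and artifact paths of a run — everything needed to reproduce
#' the artifacts bit-for-bit with `cli_main()` or
#' [run_single_simulation()].
#'
#' @param params An [sfm_params()] object.
#' @param seed Master seed of the run.
#' @param artifacts Named list/character vector of artifact file paths.
#' @param path Output path for the manifest JSON.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the parsed list.
#' @export
write_manifest <- function(params, seed, artifacts, path) {
  stopifnot(inherits(params, "sfm_params"))
  doc <- list(
    tool = "singlefile",
    version = as.character(utils::packageVersion("singlefile")),
    seed = as.integer(seed),
    params = params[c("n_I", "n_D", "sigma_I", "sigma_D", "n_exp", "n_reps")],
    artifacts = as.list(artifacts))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path)
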