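#' Build the weighted cell graph of a trained map
#'
#' Nodes are the map cells; edges connect 8-neighbors on the rectangular
#' lattice (sides and diagonals), weighted by the Euclidean distance between
#' the two cells' codebook vectors on the model's standardized scale.  Paths
#' across this graph traverse the map itself, so a route can be drawn on the
#' atlas.
#'
#' @param model A trained `som_model`.
#' @return A list of class `som_graph`: `edges` (tibble `from`, `to`,
#'   `weight`, with `from < to`), the grid layout, and the model.
#' @export
som_graph <- function(model) {
  e <- grid_edges(model$config$width, model$config$height)
  w <- sqrt(rowSums((model$codebook[e$from, , drop = FALSE] -
                       model$codebook[e$to, , drop = FALSE])^2))
  structure(list(edges = dplyr::mutate(e, weight = w),
                 grid = model$grid, model = model),
            class = "som_graph")
}

# Bellman-Ford single-source distances over an undirected edge list.
# Vectorized edge relaxation per round, with early exit once no distance
# improves; at most n-1 rounds (non-negative weights, so this is plenty).
bellman_ford_dist <- function(edges, n, source) {
  from <- c(edges$from, edges$to)
  to <- c(edges$to, edges$from)
  w <- rep(edges$weight, 2)
  dist <- rep(Inf, n)
  dist[source] <- 0
  for (round in seq_len(max(n - 1, 1))) {
    cand <- dist[from] + w
    better <- which(cand < dist[to])
    if (length(better) == 0) break
    upd <- tapply(cand[better], to[better], min)
    cells <- as.integer(names(upd))
    dist[cells] <- pmin(dist[cells], unname(upd))
  }
  dist
}

chebyshev <- function(grid, a, b) {
  max(abs(grid$row[a] - grid$row[b]), abs(grid$col[a] - grid$col[b]))
}

#' Weighted shortest path between two map cells
#'
#' Bellman-Ford minimal-weight path over the 8-connected cell graph.  Among
#' equal-length shortest paths the lexicographically smallest cell sequence
#' is returned (at each step the smallest-index neighbor that still lies on a
#' shortest path).  `source == target` yields a single-cell path of length 0.
#'
#' @param graph A [som_graph()] (or a `som_model`, from which the graph is
#'   built).
#' @param from,to Cell indices (1-based, row-major).
#' @return A list of class `path_result`: `cells` (1-based sequence),
#'   `coords` (tibble with 1-based and 0-based row-major coordinates),
#'   `total_length` (sum of codebook edge distances), and `trajectories`
#'   (long tibble of per-feature codebook values along the path, in original
#'   item units).
#' @export
shortest_path <- function(graph, from, to) {
  if (inherits(graph, "som_model")) graph <- som_graph(graph)
  n <- nrow(graph$grid)
  from <- as.integer(from); to <- as.integer(to)
  if (any(c(from, to) < 1L) || any(c(from, to) > n)) {
    abort(sprintf("`from`/`to` must be cell indices in 1..%d.", n))
  }
  if (from == to) {
    return(new_path_result(graph$model, cells = from, total_length = 0))
  }
  dist_s <- bellman_ford_dist(graph$edges, n, from)
  dist_t <- bellman_ford_dist(graph$edges, n, to)
  total <- dist_s[to]
  tol <- 1e-9 * max(1, total)

  # adjacency with weights
  adj_from <- c(graph$edges$from, graph$edges$to)
  adj_to <- c(graph$edges$to, graph$edges$from)
  adj_w <- rep(graph$edges$weight, 2)

  cells <- from
  cur <- from
  for (guard in seq_len(4L * n)) {
    if (cur == to) break
    k <- which(adj_from == cur)
    nb <- adj_to[k]
    w <- adj_w[k]
    on_sp <- abs(dist_s[cur] + w + dist_t[nb] - total) <= tol
    # strict progress: toward the target in path length, or across a
    # zero-weight plateau toward it in grid distance
    cheb_cur <- chebyshev(graph$grid, cur, to)
    cheb_nb <- vapply(nb, chebyshev, numeric(1), grid = graph$grid, b = to)
    progress <- dist_t[nb] < dist_t[cur] - tol | cheb_nb < cheb_cur
    cand <- nb[on_sp & progress]
    if (length(cand) == 0) cand <- setdiff(nb[on_sp], cells)
    if (length(cand) == 0) abort("path reconstruction failed.")
    cur <- min(cand)
    cells <- c(cells, cur)
  }
  if (cur != to) abort("path reconstruction did not terminate.")
  new_path_result(graph$model, cells = cells, total_length = total)
}

new_path_result <- function(model, cells, total_length) {
  grid <- model$grid
  cb <- codebook_units(model)
  coords <- tibble(
    step = seq_along(cells), cell = cells,
    row = grid$row[cells], col = grid$col[cells],
    cell0 = cells - 1L, row0 = grid$row[cells] - 1L, col0 = grid$col[cells] - 1L
  )
  traj <- dplyr::bind_cols(coords[c("step", "cell")],
                           as_tibble(cb[cells, , drop = FALSE])) |>
    tidyr::pivot_longer(-c("step", "cell"),
                        names_to = "feature", values_to = "value")
  structure(list(cells = cells, coords = coords,
                 total_length = total_length, trajectories = traj,
                 feature_names = model$feature_names),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result> %d cell(s), total weighted length %.4f\n",
              length(x$cells), x$total_length))
  cat("  cells:", paste(x$cells, collapse = " -> "), "\n")
  invisible(x)
}

#' @method tidy path_result
#' @export
tidy.path_result <- function(x, ...) x$trajectories

#' Select the depression hotspot and the mental-stability cell
#'
#' The hotspot is the occupied cell with the highest depression odds (ties:
#' most depressed subjects, then lowest cell index); the stable cell is the
#' occupied cell with the lowest odds (ties: most non-depressed subjects,
#' then lowest index).  These are the natural endpoints of a
#' self-improvement path across the atlas.
#'
#' @param overlay A [cell_overlay()].
#' @return A list with `hotspot` and `stable`, each a one-row tibble slice of
#'   the overlay.
#' @export
select_endpoints <- function(overlay) {
  occ <- dplyr::filter(overlay, .data$occupied, !is.na(.data$depression_odds))
  if (!any(occ$n_depressed > 0)) abort("no occupied cells with depressed subjects.")
  if (!any(occ$n_nondepressed > 0)) abort("no occupied cells with non-depressed subjects.")
  hot <- occ[order(-occ$depression_odds, -occ$n_depressed, occ$cell), ][1, ]
  stable <- occ[order(occ$depression_odds, -occ$n_nondepressed, occ$cell), ][1, ]
  list(hotspot = hot, stable = stable)
}

#' Rank the features changing most along a path
#'
#' Orders features by the signed difference between the codebook values at
#' the last and first path cells (original item units) and splits them into
#' the `k` largest increases and `k` largest decreases — the attitudes a
#' subject at the path's start would have to grow into, and out of, to reach
#' the destination psychotype.  Features with zero delta are filtered out.
#'
#' @param path A [shortest_path()] result with at least 2 cells.
#' @param k How many features per direction.
#' @param method `"endpoint"` (default; last minus first cell) or `"range"`
#'   (max minus min along the whole path, signed by the endpoint direction).
#' @return A list: `increasing` and `decreasing` ranked tibbles
#'   (`feature`, `delta`, `rank`), and `deltas` with every feature's signed
#'   change.
#' @export
rank_feature_changes <- function(path, k = 5, method = c("endpoint", "range")) {
  method <- match.arg(method)
  if (length(path$cells) < 2) abort("path must contain at least 2 cells.")
  if (k > length(path$feature_names)) {
    abort(sprintf("`k` (%d) exceeds the number of features (%d).",
                  k, length(path$feature_names)))
  }
  traj <- path$trajectories
  deltas <- traj |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      delta = if (method == "endpoint") {
        .data$value[dplyr::n()] - .data$value[1]
      } else {
        sign(.data$value[dplyr::n()] - .data$value[1] + 1e-300) *
          (max(.data$value) - min(.data$value))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta)))
  pick <- function(df) dplyr::mutate(utils::head(df, k),
                                     rank = dplyr::row_number())
  list(
    increasing = pick(dplyr::arrange(
      dplyr::filter(deltas, .data$delta > 0), dplyr::desc(.data$delta))),
    decreasing = pick(dplyr::arrange(
      dplyr::filter(deltas, .data$delta < 0), .data$delta)),
    deltas = deltas
  )
}
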