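test_that("the cell graph has the lattice edge structure and exact weights", {
  model <- fake_model(matrix(0, 4, 2), 2, 2)
  g <- som_graph(model)
  expect_equal(nrow(g$edges), 6) # 4 sides + 2 diagonals
  expect_equal(g$edges$weight, rep(0, 6))
  set.seed(51)
  cb <- matrix(rnorm(9 * 4), 9, 4)
  g2 <- som_graph(fake_model(cb, 3, 3))
  want <- sqrt(rowSums((cb[g2$edges$from, ] - cb[g2$edges$to, ])^2))
  expect_equal(g2$edges$weight, want, tolerance = 1e-12)
  expect_true(all(g2$edges$weight >= 0))
})

test_that("degenerate and tiny paths behave as specified", {
  set.seed(52)
  model <- fake_model(matrix(rnorm(12), 4, 3), 2, 2)
  p <- shortest_path(som_graph(model), 3, 3)
  expect_equal(p$cells, 3L)
  expect_equal(p$total_length, 0)
  # 1x3 line with equal weights: both hops taken, length 2w
  cb <- matrix(c(0, 1, 2), 3, 1)
  line <- fake_model(cb, 3, 1)
  p2 <- shortest_path(som_graph(line), 1, 3)
  expect_equal(p2$cells, c(1L, 2L, 3L))
  expect_equal(p2$total_length, 2)
})

test_that("Bellman-Ford path lengths match an independent Dijkstra on random grids", {
  set.seed(53)
  cb <- matrix(rnorm(36 * 5), 36, 5)
  model <- fake_model(cb, 6, 6)
  g <- som_graph(model)
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = data.frame(name = 1:36))
  dmat <- igraph::distances(ig, weights = g$edges$weight, algorithm = "dijkstra")
  pairs <- matrix(sample.int(36, 40, replace = TRUE), ncol = 2)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE][1:20, ]
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    p <- shortest_path(g, a, b)
    expect_equal(p$total_length, dmat[as.character(a), as.character(b)],
                 tolerance = 1e-9)
    # symmetry of the length under endpoint swap
    expect_equal(shortest_path(g, b, a)$total_length, p$total_length,
                 tolerance = 1e-9)
    # consecutive path cells are 8-neighbors and lengths decompose exactly
    steps <- cbind(utils::head(p$cells, -1), utils::tail(p$cells, -1))
    dr <- abs(model$grid$row[steps[, 1]] - model$grid$row[steps[, 2]])
    dc <- abs(model$grid$col[steps[, 1]] - model$grid$col[steps[, 2]])
    expect_true(all(pmax(dr, dc) == 1))
    seg <- sqrt(rowSums((cb[steps[, 1], , drop = FALSE] -
                           cb[steps[, 2], , drop = FALSE])^2))
    expect_equal(sum(seg), p$total_length, tolerance = 1e-9)
  }
})

test_that("shortest-path lengths satisfy the triangle inequality", {
  set.seed(54)
  model <- fake_model(matrix(rnorm(25 * 3), 25, 3), 5, 5)
  g <- som_graph(model)
  d <- function(a, b) shortest_path(g, a, b)$total_length
  for (i in 1:12) {
    abc <- sample.int(25, 3)
    expect_lte(d(abc[1], abc[3]), d(abc[1], abc[2]) + d(abc[2], abc[3]) + 1e-9)
  }
})

test_that("trajectories report unscaled codebook values along the path", {
  set.seed(55)
  x <- matrix(rnorm(200, mean = 30, sd = 4), 50, 4)
  m <- train_som(x, som_config(width = 4, height = 4, max_epochs = 10, seed = 9))
  p <- shortest_path(som_graph(m), 1, 16)
  cb <- codebook_units(m)
  wide <- tidyr::pivot_wider(p$trajectories, names_from = "feature",
                             values_from = "value")
  expect_equal(unname(as.matrix(wide[, m$feature_names])),
               unname(cb[p$cells, ]), tolerance = 1e-12)
  # 0-based row-major coordinates accompany the 1-based ones
  expect_equal(p$coords$cell0, p$coords$cell - 1L)
  expect_equal(p$coords$cell, (p$coords$row - 1L) * 4L + p$coords$col)
})

test_that("endpoint selection follows extreme odds with deterministic ties", {
  grid <- psychatlas:::grid_coords(2, 2)
  base <- tibble::tibble(
    cell = 1:4, row = grid$row, col = grid$col, n = 5L,
    n_male = 2L, occupied = TRUE, odds_capped = FALSE, pct_male = 40,
    mean_wb_1 = 4
  )
  ov <- dplyr::mutate(base,
                      n_depressed = c(5L, 0L, 2L, 1L),
                      n_nondepressed = c(0L, 5L, 2L, 4L),
                      depression_odds = c(Inf, 0, 1, 0.25))
  ep <- select_endpoints(ov)
  expect_equal(ep$hotspot$cell, 1L)
  expect_equal(ep$stable$cell, 2L)
  # uniform odds: lowest index wins both ends
  ov2 <- dplyr::mutate(base, n_depressed = 1L, n_nondepressed = 1L,
                       depression_odds = 1)
  ep2 <- select_endpoints(ov2)
  expect_equal(ep2$hotspot$cell, 1L)
  expect_equal(ep2$stable$cell, 1L)
})

test_that("the hotspot lands inside the maximum-odds cluster on a planted cohort", {
  co <- small_cohort(seed = 3, n_train = 1200, n_dep = 200, n_non = 400)
  m <- train_som(cohort_items(co[co$split == "train", ]),
                 som_config(width = 12, height = 12, max_epochs = 30, seed = 4))
  test <- co[co$split == "test", ]
  ov <- cell_overlay(map_cohort(m, test), test)
  cl <- cluster_codebook(m, 3)
  st <- cluster_stats(cl, ov)
  relabel <- attr(st, "relabel")
  ep <- select_endpoints(ov)
  hot_cluster <- relabel[as.character(cl$cluster[ep$hotspot$cell])]
  expect_equal(unname(hot_cluster), 1L)
  # and a path between the endpoints exists with at least two cells
  p <- shortest_path(som_graph(m), ep$hotspot$cell, ep$stable$cell)
  expect_gte(length(p$cells), 2)
})

test_that("feature-change ranking isolates planted gradients", {
  cb <- matrix(4, 9, 3)
  cb[, 2] <- seq(1, 4, length.out = 9) # feature B rises by 3 along cells
  cb[, 3] <- 4 + c(0, 0.05, 0.1, 0.05, 0, -0.05, -0.1, -0.2, -0.4)
  model <- fake_model(cb, 3, 3, feature_names = c("A", "B", "C"))
  p <- shortest_path(som_graph(model), 1, 9)
  rc <- rank_feature_changes(p, k = 2)
  expect_equal(rc$increasing$feature[1], "B")
  expect_equal(rc$increasing$delta[1], 3, tolerance = 1e-12)
  expect_equal(rc$decreasing$feature[1], "C")
  # constant codebook: no nonzero deltas survive the filter
  flat <- fake_model(matrix(2, 9, 3), 3, 3)
  rc0 <- rank_feature_changes(shortest_path(som_graph(flat), 1, 9), k = 3)
  expect_equal(nrow(rc0$increasing), 0)
  expect_equal(nrow(rc0$decreasing), 0)
  expect_error(rank_feature_changes(p, k = 10), "k")
})
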