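test_that("cohort mapping agrees with brute-force BMU per subject", {
  set.seed(41)
  cb <- matrix(rnorm(16 * 4), 16, 4)
  model <- fake_model(cb, 4, 4, feature_names = item_cols(4))
  items <- matrix(rnorm(30 * 4), 30, 4)
  colnames(items) <- item_cols(4)
  cohort <- toy_cohort(cells = rep(1L, 30), depressed = rep(FALSE, 30))
  cohort[item_cols(4)] <- as.data.frame(items)
  got <- map_cohort(model, cohort)
  want <- brute_bmu(cb, items)
  expect_equal(got$cell, unname(want[, "cell"]))
  expect_identical(got$cell, map_cohort(model, cohort)$cell)
  # a subject equal to a codebook vector lands on that cell
  cohort2 <- cohort[1, ]
  cohort2[item_cols(4)] <- as.list(cb[11, ])
  expect_equal(map_cohort(model, cohort2)$cell, 11L)
})

test_that("overlay counts are conserved and odds follow the count ratios", {
  model <- fake_model(matrix(seq_len(8), 4, 2) * 1.0, 2, 2,
                      feature_names = item_cols(2))
  # place 71 depressed + 33 non-depressed on cell 1, 10 non-depressed on 2
  cohort <- toy_cohort(cells = c(rep(1L, 104), rep(2L, 10)),
                       depressed = c(rep(TRUE, 71), rep(FALSE, 33 + 10)),
                       n_items = 2)
  assignments <- tibble::tibble(subject_id = cohort$subject_id,
                                cell = c(rep(1L, 104), rep(2L, 10)))
  attr(assignments, "grid") <- model$grid
  ov <- cell_overlay(assignments, cohort)
  expect_equal(sum(ov$n_depressed), 71)
  expect_equal(sum(ov$n_nondepressed), 43)
  expect_equal(round(ov$depression_odds[1], 2), 2.15)
  expect_equal(ov$depression_odds[2], 0) # no depressed there
  expect_true(is.na(ov$depression_odds[3]) && !ov$occupied[3])
  # depressed-only cell reports capped infinite odds
  a2 <- tibble::tibble(subject_id = cohort$subject_id[1:2], cell = c(4L, 1L))
  attr(a2, "grid") <- model$grid
  ov2 <- cell_overlay(a2, cohort[1:2, ])
  expect_true(is.infinite(ov2$depression_odds[4]) && ov2$odds_capped[4])
})

test_that("codebook clustering recovers planted blobs and matches an independent linkage", {
  blob <- rbind(matrix(0, 5, 3), matrix(10, 6, 3), matrix(-10, 5, 3)) +
    matrix(rnorm(48, sd = 0.1), 16, 3)
  model <- fake_model(blob, 4, 4)
  cl <- cluster_codebook(model, 3)
  expect_true(same_partition(cl$cluster, rep(1:3, c(5, 6, 5))))
  # singleton limit
  expect_equal(sort(unique(cluster_codebook(model, 16)$cluster)), 1:16)
  # random codebook against the hand-rolled agglomerative oracle
  set.seed(43)
  cb <- matrix(rnorm(16 * 4), 16, 4)
  got <- cluster_codebook(fake_model(cb, 4, 4), 3)$cluster
  expect_true(same_partition(got, reference_complete_linkage(cb, 3)))
  expect_error(cluster_codebook(model, 1), "n_clusters")
  expect_error(cluster_codebook(model, 17), "n_clusters")
})

test_that("cluster statistics aggregate counts exactly and label by odds", {
  grid <- psychatlas:::grid_coords(3, 1)
  overlay <- tibble::tibble(
    cell = 1:3, row = 1L, col = 1:3,
    n = c(104L, 440L, 629L),
    n_depressed = c(71L, 179L, 144L),
    n_nondepressed = c(33L, 261L, 485L),
    n_male = c(33L, 176L, 260L),
    mean_wb_1 = c(3, 4, 5),
    occupied = TRUE, depression_odds = NA, odds_capped = FALSE,
    pct_male = NA
  )
  clusters <- dplyr::mutate(grid, cluster = c(2L, 3L, 1L)) # scrambled labels
  st <- cluster_stats(clusters, overlay)
  expect_equal(st$cluster, c("1", "2", "3", "Total"))
  expect_equal(round(st$depression_odds, 2), c(2.15, 0.69, 0.30, 0.51))
  # totals row equals the column sums
  expect_equal(st$n_depressed[4], sum(st$n_depressed[1:3]))
  expect_equal(st$n_nondepressed[4], sum(st$n_nondepressed[1:3]))
  expect_equal(st$n_cells[4], 3L)
  # well-being means are subject-weighted
  expect_equal(st$mean_wb_1[4],
               sum(c(3, 4, 5) * c(104, 440, 629)) / sum(c(104, 440, 629)))
})

test_that("odds-wellbeing correlation handles exact and degenerate structure", {
  grid <- psychatlas:::grid_coords(5, 1)
  base <- tibble::tibble(
    cell = 1:5, row = 1L, col = 1:5, n = 10L,
    n_depressed = 1L, n_nondepressed = 2L, n_male = 5L,
    occupied = TRUE, odds_capped = FALSE, pct_male = 50
  )
  ov <- dplyr::mutate(base, depression_odds = c(0.2, 0.5, 1, 2, 4))
  for (k in 1:6) ov[[paste0("mean_wb_", k)]] <- -ov$depression_odds
  res <- odds_wellbeing_correlation(ov)
  expect_equal(res$estimate, rep(-1, 6))
  # constant odds are reported as degenerate, not an error
  ov2 <- dplyr::mutate(ov, depression_odds = 1)
  res2 <- odds_wellbeing_correlation(ov2)
  expect_true(all(res2$note == "degenerate"))
  expect_true(all(is.na(res2$estimate)))
  expect_error(odds_wellbeing_correlation(ov[1:2, ]), "3")
})

test_that("a planted depressed subpopulation produces the depression-prone cluster", {
  co <- small_cohort(seed = 3, n_train = 1200, n_dep = 200, n_non = 400)
  m <- train_som(cohort_items(co[co$split == "train", ]),
                 som_config(width = 12, height = 12, max_epochs = 30, seed = 4))
  test <- co[co$split == "test", ]
  ov <- cell_overlay(map_cohort(m, test), test)
  cl <- cluster_codebook(m, 3)
  st <- cluster_stats(cl, ov)
  expect_equal(st$n_depressed[4], 200)
  expect_equal(st$n_nondepressed[4], 400)
  top <- st[1, ] # relabeled: cluster 1 is max-odds
  expect_gt(top$depression_odds, 1)
  expect_lt(st$depression_odds[4], 1)
  expect_lt(top$n_cells, 144 / 3) # fewer cells than the map average
  # odds negatively track every well-being dimension across cells
  corr <- odds_wellbeing_correlation(ov)
  expect_true(all(corr$estimate < 0))
  expect_true(all(corr$p_value < 0.01))
})
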