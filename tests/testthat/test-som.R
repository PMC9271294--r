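test_that("a one-cell map collapses onto a single training sample", {
  x <- matrix(c(2, 5, 3), 1, 3)
  m <- train_som(x, som_config(width = 1, height = 1, max_epochs = 20, seed = 1))
  expect_equal(quantization_error(m, x), 0, tolerance = 1e-8)
  expect_equal(find_bmu(m, x[1, ])$cell, 1L)
})

test_that("training is deterministic for a fixed config and seed", {
  set.seed(4)
  x <- matrix(rnorm(120), 30, 4)
  cfg <- som_config(width = 4, height = 3, max_epochs = 8, seed = 42)
  expect_identical(train_som(x, cfg)$codebook, train_som(x, cfg)$codebook)
})

test_that("training reduces quantization error below the initial codebook's", {
  set.seed(8)
  x <- rbind(matrix(rnorm(300, -3), 100, 3), matrix(rnorm(300, 3), 100, 3))
  m <- train_som(x, som_config(width = 5, height = 5, max_epochs = 15, seed = 2))
  xs <- psychatlas:::scale_features(x, m$center, m$scale)
  qe_init <- mean(brute_bmu(m$codebook_init, xs)[, "distance"])
  qe_final <- quantization_error(m, x)
  expect_lt(qe_final, qe_init)
})

test_that("trained quantization error agrees with an independent reference map", {
  set.seed(15)
  x <- rbind(matrix(rnorm(400, -2, 0.7), 100, 4), matrix(rnorm(400, 2, 0.7), 100, 4))
  m <- train_som(x, som_config(width = 5, height = 5, max_epochs = 25, seed = 3))
  xs <- psychatlas:::scale_features(x, m$center, m$scale)
  ref <- reference_som(xs, 5, 5, n_steps = 6000, seed = 5)
  expect_lt(abs(quantization_error(m, x) - ref$qe) / ref$qe, 0.20)
})

test_that("BMU lookup matches exhaustive search and self-matches the codebook", {
  set.seed(21)
  cb <- matrix(rnorm(9 * 5), 9, 5)
  model <- fake_model(cb, width = 3, height = 3)
  x <- matrix(rnorm(50 * 5), 50, 5)
  got <- find_bmu(model, x)
  want <- brute_bmu(cb, x)
  expect_equal(got$cell, unname(want[, "cell"]))
  expect_equal(got$distance, unname(want[, "distance"]), tolerance = 1e-12)
  # exact match to a unique codebook vector is a zero-distance hit
  hit <- find_bmu(model, cb[6, ])
  expect_equal(hit$cell, 6L)
  expect_equal(hit$distance, 0)
  # every codebook vector is its own BMU
  self <- find_bmu(model, cb)
  expect_equal(self$cell, 1:9)
  expect_equal(self$distance, rep(0, 9))
  expect_error(find_bmu(model, rnorm(4)), "features")
})

test_that("quantization error equals the mean brute-force BMU distance", {
  set.seed(22)
  cb <- matrix(rnorm(8 * 3), 8, 3)
  model <- fake_model(cb, width = 4, height = 2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(quantization_error(model, x),
               mean(brute_bmu(cb, x)[, "distance"]), tolerance = 1e-12)
  # codebook mapped onto itself has zero error; a single offset sample has
  # error equal to its own BMU distance
  expect_equal(quantization_error(model, cb), 0)
  s <- cb[3, ] + c(0.3, 0, 0)
  expect_equal(quantization_error(model, matrix(s, 1)), 0.3, tolerance = 1e-12)
})

test_that("the U-matrix equals the brute-force neighbor average", {
  expect_equal(u_matrix(fake_model(matrix(1, 6, 3), 3, 2))$unified_distance,
               rep(0, 6))
  cb2 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE) # distance 5 apart
  expect_equal(u_matrix(fake_model(cb2, 1, 2))$unified_distance, c(5, 5))
  set.seed(23)
  cb <- matrix(rnorm(16 * 4), 16, 4)
  expect_equal(u_matrix(fake_model(cb, 4, 4))$unified_distance,
               brute_umatrix(cb, 4, 4), tolerance = 1e-12)
})

test_that("training stops on a quantization-error plateau and keeps the best state", {
  set.seed(30)
  x <- matrix(rnorm(240), 80, 3)
  cfg <- som_config(width = 4, height = 4, max_epochs = 60,
                    convergence_tol = 1e-4, patience = 5, seed = 6)
  m <- train_som(x, cfg)
  expect_true(m$converged)
  qe <- m$training_log$quantization_error
  # the best-so-far error is non-increasing and has stopped improving by more
  # than the tolerance over the final patience window
  running_best <- cummin(qe)
  expect_true(all(diff(running_best) <= 0))
  window <- utils::tail(running_best, cfg$patience + 1)
  expect_lte(window[1] - window[length(window)], cfg$convergence_tol)
  # the returned codebook is the best epoch's state
  expect_equal(quantization_error(m, x), min(qe), tolerance = 1e-10)
})

test_that("a planted 1-D manifold is laid out monotonically on the grid", {
  set.seed(31)
  t <- seq(0, 1, length.out = 300)
  dir <- c(2, -1, 1.5, 0.5, -2)
  x <- outer(t * 10, dir) + matrix(rnorm(300 * 5, sd = 0.15), 300, 5)
  m <- train_som(x, som_config(width = 10, height = 10, max_epochs = 30, seed = 7))
  pos <- find_bmu(m, x)
  rho <- max(abs(cor(t, pos$row, method = "spearman")),
             abs(cor(t, pos$col, method = "spearman")),
             abs(cor(t, pos$row + pos$col, method = "spearman")),
             abs(cor(t, pos$row - pos$col, method = "spearman")))
  expect_gte(rho, 0.8)
})

test_that("invalid inputs are rejected", {
  expect_error(train_som(matrix(c(1, NA), 1, 2), som_config(2, 2)), "finite")
  expect_error(train_som(matrix(numeric(0), 0, 3), som_config(2, 2)), "sample")
  expect_error(train_som(matrix(1:4, 2, 2), som_config(2, 2),
                         feature_names = "only_one"), "length")
  expect_error(som_config(sigma0 = 0), "sigma0")
  expect_error(som_config(learning_rate0 = 1.5), "learning_rate0")
})
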