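test_that("shadow selection separates planted signal from noise", {
  set.seed(71)
  n <- 500
  x <- matrix(rnorm(n * 11), n, 11)
  colnames(x) <- c(paste0("inf_", 1:3), paste0("noise_", 1:8))
  y <- x[, 1:3] %*% c(1, 0.7, 0.5) + rnorm(n, sd = 0.5)
  rep <- shadow_select(x, y, n_rounds = 30, alpha = 0.01, seed = 2)
  dec <- tidy(rep)
  expect_equal(sum(dec$decision[1:3] == "confirmed"), 3)
  expect_gte(sum(dec$decision[4:11] == "rejected"), 7)
  # duplicated informative feature: both copies stay (all-relevant semantics)
  x2 <- cbind(x[, 1:4], inf_dup = x[, 1])
  rep2 <- shadow_select(x2, y, n_rounds = 30, alpha = 0.01, seed = 3)
  dec2 <- tidy(rep2)
  expect_equal(dec2$decision[dec2$feature == "inf_1"], "confirmed")
  expect_equal(dec2$decision[dec2$feature == "inf_dup"], "confirmed")
})

test_that("an independent target confirms nothing", {
  set.seed(72)
  x <- matrix(rnorm(300 * 8), 300, 8)
  y <- rnorm(300)
  rep <- shadow_select(x, y, n_rounds = 50, alpha = 0.01, seed = 4)
  expect_equal(length(rep$confirmed), 0)
  expect_error(shadow_select(x, rep(1, 300)), "constant")
  expect_error(shadow_select(x, y, n_rounds = 5), "n_rounds")
})

test_that("false-confirmation rate on pure noise stays near the nominal level", {
  confirmed <- 0L
  total <- 0L
  for (r in 1:20) {
    set.seed(700 + r)
    x <- matrix(rnorm(400 * 8), 400, 8)
    y <- rnorm(400)
    rep <- shadow_select(x, y, n_rounds = 20, alpha = 0.01, num_trees = 80,
                         seed = 800 + r)
    confirmed <- confirmed + length(rep$confirmed)
    total <- total + 8L
  }
  expect_lte(confirmed / total, 2 * 0.01)
})

test_that("VIF filtering matches per-feature regressions and removal rules", {
  set.seed(73)
  # orthogonal, mean-centered design: nothing removed, VIFs exactly one
  x <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 4), 100, 4))))[, -1]
  colnames(x) <- paste0("o", 1:4)
  v <- vif_filter(x)
  expect_equal(length(v$removed$feature), 0)
  expect_equal(v$vif$vif, rep(1, 4), tolerance = 1e-8)
  # exact collinearity: one of the trio goes for infinite VIF
  z <- matrix(rnorm(300), 100, 3)
  colnames(z) <- c("A", "B", "C")
  v2 <- vif_filter(cbind(z, D = z[, 1] + z[, 2]))
  expect_equal(nrow(v2$removed), 1)
  expect_true(is.infinite(v2$removed$vif[1]))
  expect_true(all(v2$vif$vif <= 10))
  # correlated design: VIFs equal 1/(1-R^2) from independent lm() fits
  set.seed(74)
  base <- matrix(rnorm(200 * 3), 200, 3)
  w <- cbind(base, base %*% c(0.8, 0.5, 0) + rnorm(200, sd = 0.6))
  colnames(w) <- paste0("v", 1:4)
  got <- vif_filter(w, threshold = 1e9)$vif
  for (j in 1:4) {
    r2 <- summary(stats::lm(w[, j] ~ w[, -j]))$r.squared
    expect_equal(got$vif[got$feature == paste0("v", j)], 1 / (1 - r2),
                 tolerance = 1e-6)
  }
  # column order does not change which variables survive
  v3 <- vif_filter(w[, c(4, 2, 1, 3)], threshold = 2)
  v4 <- vif_filter(w, threshold = 2)
  expect_setequal(v3$kept, v4$kept)
  expect_error(vif_filter(cbind(w, k = rep(1, 200))), "constant")
})

test_that("elastic-net importance identifies the dominant determinant", {
  set.seed(75)
  n <- 400
  co <- toy_cohort(cells = rep(1L, n), depressed = rep(FALSE, n))
  co$age <- runif(n, 25, 74)
  co$sex <- ifelse(runif(n) < 0.4, "male", "female")
  for (k in 1:6) co[[paste0("wb1_", k)]] <- runif(n, 1, 7)
  pred <- matrix(runif(n * 6, 1, 7), n, 6)
  # noise-free link to the predicted value: it must dominate
  for (k in 1:6) co[[paste0("wb2_", k)]] <- pred[, k]
  imp <- en_importance(co, pred, 1, seed = 5)
  expect_equal(imp$winner, "predicted_wb")
  others <- imp$coefficients$estimate[imp$coefficients$term != "predicted_wb"]
  expect_lt(max(abs(others)), 0.05)
  # hedonic-treadmill limit: follow-up identical to baseline
  for (k in 1:6) co[[paste0("wb2_", k)]] <- co[[paste0("wb1_", k)]]
  imp2 <- en_importance(co, pred, 2, seed = 5)
  expect_equal(imp2$winner, "wb1_2")
})

test_that("the degenerate grid point reduces to ordinary least squares", {
  set.seed(76)
  n <- 300
  co <- toy_cohort(cells = rep(1L, n), depressed = rep(FALSE, n))
  co$age <- runif(n, 25, 74)
  co$sex <- ifelse(runif(n) < 0.4, "male", "female")
  for (k in 1:6) co[[paste0("wb1_", k)]] <- runif(n, 1, 7)
  pred <- matrix(runif(n * 6, 1, 7), n, 6)
  co$wb2_3 <- 2 + 0.3 * pred[, 3] + 0.2 * co$wb1_1 + rnorm(n, sd = 0.3)
  imp <- en_importance(co, pred, 3, l1_ratio_grid = 0, penalty_grid = 0,
                       seed = 6)
  xs <- scale(cbind(sex = as.numeric(co$sex == "male"), age = co$age,
                    predicted_wb = pred[, 3],
                    as.matrix(co[sprintf("wb1_%d", 1:6)])))
  ols <- stats::coef(stats::lm(co$wb2_3 ~ xs))[-1]
  expect_equal(imp$coefficients$estimate, unname(ols), tolerance = 1e-6)
})
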