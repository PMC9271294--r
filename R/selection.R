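#' Shadow-feature (all-relevant) feature selection
#'
#' Boruta-style relevance screening: each round, every feature is paired with
#' a permuted "shadow" copy, a random-forest importance model is fitted on
#' the combined design, and a feature scores a hit when its importance beats
#' the best shadow importance of that round.  After `n_rounds` rounds a
#' feature is `confirmed` if its hit count is significantly above chance
#' (one-sided binomial test against 0.5 at level `alpha`, Bonferroni-adjusted
#' across features so that false confirmations stay controlled), `rejected`
#' if significantly below chance at the nominal `alpha` (rejection only
#' prunes, so it is not adjusted), and `tentative` otherwise.  With a multi-column
#' target the rounds run per target and a feature's final decision is the
#' union: confirmed for any target wins, then tentative, then rejected
#' (all-relevant semantics — duplicated informative features are both kept).
#'
#' @param features Data frame or matrix of candidate features (>= 2 columns).
#' @param target Numeric vector, or a matrix/data frame with one column per
#'   target (e.g. the six follow-up well-being dimensions).
#' @param n_rounds Shadow rounds per target (>= 10).
#' @param alpha Significance level of the binomial decision test.
#' @param num_trees Trees per random-forest importance fit.
#' @param seed Integer seed.
#' @return A list of class `selection_report`: `decisions` (tibble with
#'   per-feature hit counts and decisions, per target and overall),
#'   `confirmed` (character vector), and the call parameters.
#' @export
shadow_select <- function(features, target, n_rounds = 50, alpha = 0.01,
                          num_trees = 100, seed = 1L) {
  x <- as.matrix(features)
  if (ncol(x) < 2) abort("`features` must have at least 2 columns.")
  if (n_rounds < 10) abort("`n_rounds` must be at least 10.")
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  y <- as.matrix(target)
  if (any(apply(y, 2, sd) == 0)) abort("`target` contains a constant column.")
  tnames <- colnames(y) %||% paste0("target_", seq_len(ncol(y)))

  seeds <- derive_seeds(seed, ncol(y))
  per_target <- purrr::map2_dfr(seq_len(ncol(y)), tnames, function(j, tn) {
    set.seed(seeds[j])
    hits <- integer(ncol(x))
    for (r in seq_len(n_rounds)) {
      shadows <- apply(x, 2, sample)
      colnames(shadows) <- paste0(".shadow_", colnames(x))
      df <- as.data.frame(cbind(x, shadows))
      df$.y <- y[, j]
      rf <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = num_trees, importance = "impurity",
        seed = seeds[j] + r, num.threads = 1
      )
      imp <- rf$variable.importance
      max_shadow <- max(imp[startsWith(names(imp), ".shadow_")])
      hits <- hits + as.integer(imp[colnames(x)] > max_shadow)
    }
    p_hi <- vapply(hits, function(h)
      binom.test(h, n_rounds, 0.5, alternative = "greater")$p.value, numeric(1))
    p_lo <- vapply(hits, function(h)
      binom.test(h, n_rounds, 0.5, alternative = "less")$p.value, numeric(1))
    alpha_adj <- alpha / ncol(x) # Bonferroni guards the confirmations only
    tibble(target = tn, feature = colnames(x), hits = hits,
           n_rounds = n_rounds,
           decision = dplyr::case_when(p_hi < alpha_adj ~ "confirmed",
                                       p_lo < alpha ~ "rejected",
                                       TRUE ~ "tentative"))
  })
  rank_dec <- c(rejected = 1L, tentative = 2L, confirmed = 3L)
  overall <- per_target |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(hits = sum(.data$hits),
                     decision = names(rank_dec)[max(rank_dec[.data$decision])],
                     .groups = "drop")
  overall <- overall[match(colnames(x), overall$feature), ]
  structure(
    list(decisions = overall, per_target = per_target,
         confirmed = overall$feature[overall$decision == "confirmed"],
         n_rounds = n_rounds, alpha = alpha),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d feature(s): %d confirmed, %d rejected, %d tentative (%d rounds, alpha=%g)\n",
              nrow(x$decisions), sum(x$decisions$decision == "confirmed"),
              sum(x$decisions$decision == "rejected"),
              sum(x$decisions$decision == "tentative"), x$n_rounds, x$alpha))
  invisible(x)
}

#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) x$decisions

#' Variance-inflation-factor collinearity filter
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` from regressing each feature on all
#' others, then iteratively removes the feature with the highest VIF (ties:
#' lowest column index) until every surviving feature has VIF at or below
#' the threshold.  Perfectly collinear features (infinite VIF) are removed
#' first by the same rule.
#'
#' @param features Data frame or matrix with >= 2 non-constant columns.
#' @param threshold Maximum admissible VIF (default 10).
#' @return A list of class `vif_report`: `kept` (surviving feature names),
#'   `removed` (in removal order, with the VIF that evicted each), and
#'   `vif` (tibble of final per-feature VIFs).
#' @export
vif_filter <- function(features, threshold = 10) {
  x <- as.matrix(features)
  if (ncol(x) < 2) abort("`features` must have at least 2 columns.")
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  if (any(apply(x, 2, sd) == 0)) abort("`features` contains a constant column.")
  vifs_of <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      yj <- m[, j]
      fit <- lm.fit(cbind(1, m[, -j, drop = FALSE]), yj)
      r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- tibble(feature = character(), vif = numeric())
  while (ncol(x) > 1) {
    v <- vifs_of(x)
    if (all(v <= threshold)) break
    worst <- which.max(v) # ties: which.max takes the lowest index
    removed <- dplyr::bind_rows(removed,
                                tibble(feature = colnames(x)[worst],
                                       vif = v[worst]))
    x <- x[, -worst, drop = FALSE]
  }
  final <- if (ncol(x) > 1) {
    tibble(feature = colnames(x), vif = vifs_of(x))
  } else {
    tibble(feature = colnames(x), vif = 1)
  }
  structure(list(kept = colnames(x), removed = removed, vif = final),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> kept %d feature(s), removed %d\n",
              length(x$kept), nrow(x$removed)))
  invisible(x)
}

#' @method tidy vif_report
#' @export
tidy.vif_report <- function(x, ...) x$vif

en_penalty_grid <- function() {
  list(l1_ratio = seq(0, 1, by = 0.01),
       penalty = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 0.0, 1.0, 10, 100))
}

#' Elastic-net relative importance of current vs predicted future well-being
#'
#' Regresses one follow-up well-being dimension on sex, age, the
#' model-predicted future value of that dimension, and all six baseline
#' well-being scores, using an elastic net whose L1 ratio (0 to 1 in steps
#' of 0.01) and penalty weight (1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 0.0, 1.0, 10,
#' 100; 0.0 meaning the unpenalized OLS limit) are chosen by k-fold
#' cross-validated MAE over exactly that grid.  Predictors are standardized
#' before fitting, so the coefficient magnitudes are comparable as
#' importances; the winner is the predictor with the largest absolute
#' coefficient.  Under the hedonic-treadmill hypothesis baseline well-being
#' would win; a planted item-driven follow-up makes the predicted value win.
#'
#' @param cohort A cohort tibble (rows to analyse, typically the test split).
#' @param predicted_wb Matrix or data frame of predicted follow-up well-being
#'   with six columns, aligned with `cohort` rows.
#' @param dimension Which well-being dimension (1-6) to analyse.
#' @param cv_folds Folds of the grid-search cross-validation.
#' @param l1_ratio_grid,penalty_grid Hyperparameter grids; default to the
#'   full grid described above.  Restricting both to `0` gives the
#'   unpenalized OLS limit.
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `en_importance`: `coefficients` (tibble
#'   `term`/`estimate` on standardized predictors), `winner`, `l1_ratio`,
#'   `penalty`, `cv_mae`, `ties` flag.
#' @export
en_importance <- function(cohort, predicted_wb, dimension, cv_folds = 5,
                          l1_ratio_grid = NULL, penalty_grid = NULL,
                          seed = 1L) {
  if (!dimension %in% 1:6) abort("`dimension` must be in 1..6.")
  predicted_wb <- as.matrix(predicted_wb)
  if (nrow(predicted_wb) != nrow(cohort) || ncol(predicted_wb) != 6) {
    abort("`predicted_wb` must have six columns aligned with `cohort` rows.")
  }
  if (anyNA(predicted_wb)) abort("`predicted_wb` contains missing values.")
  x <- cbind(sex = as.numeric(cohort$sex == "male"),
             age = cohort$age,
             predicted_wb = predicted_wb[, dimension],
             as.matrix(cohort[wb_cols(1)]))
  x <- scale(x)
  y <- cohort[[wb_cols(2)[dimension]]]
  grid <- en_penalty_grid()
  grid$l1_ratio <- l1_ratio_grid %||% grid$l1_ratio
  grid$penalty <- penalty_grid %||% grid$penalty
  if (length(grid$penalty) == 0 || length(grid$l1_ratio) == 0) {
    abort("hyperparameter grid is empty.")
  }
  lambdas <- sort(unique(grid$penalty), decreasing = TRUE)

  set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
  cv <- purrr::map_dfr(grid$l1_ratio, function(a) {
    err <- matrix(NA_real_, cv_folds, length(lambdas))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = a,
                            lambda = lambdas, standardize = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE], s = lambdas, exact = FALSE)
      err[f, ] <- colMeans(abs(pred - y[!tr]))
    }
    tibble(l1_ratio = a, penalty = lambdas, cv_mae = colMeans(err))
  })
  best <- cv[order(cv$cv_mae, cv$penalty, cv$l1_ratio), ][1, ]
  fit <- glmnet::glmnet(x, y, alpha = best$l1_ratio, lambda = lambdas,
                        standardize = FALSE, thresh = 1e-12)
  beta <- as.numeric(predict(fit, type = "coefficients", s = best$penalty))
  terms <- c("(Intercept)", colnames(x))
  coefs <- tibble(term = terms[-1], estimate = beta[-1])
  top <- order(-abs(coefs$estimate))
  winner <- coefs$term[top[1]]
  ties <- nrow(coefs) > 1 &&
    isTRUE(all.equal(abs(coefs$estimate[top[1]]), abs(coefs$estimate[top[2]])))
  structure(
    list(dimension = dimension, coefficients = coefs, winner = winner,
         ties = ties, l1_ratio = best$l1_ratio, penalty = best$penalty,
         cv_mae = best$cv_mae, intercept = beta[1]),
    class = "en_importance"
  )
}

#' @export
print.en_importance <- function(x, ...) {
  cat(sprintf("<en_importance> dimension %d: winner = %s (l1_ratio %.2f, penalty %g, CV MAE %.4f)\n",
              x$dimension, x$winner, x$l1_ratio, x$penalty, x$cv_mae))
  invisible(x)
}

#' @method tidy en_importance
#' @export
tidy.en_importance <- function(x, ...) {
  dplyr::mutate(x$coefficients, dimension = x$dimension,
                winner = .data$term == x$winner)
}

#' @method glance en_importance
#' @export
glance.en_importance <- function(x, ...) {
  tibble(dimension = x$dimension, winner = x$winner, ties = x$ties,
         l1_ratio = x$l1_ratio, penalty = x$penalty, cv_mae = x$cv_mae)
}
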