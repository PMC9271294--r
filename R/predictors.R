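#' Mean absolute error and mean absolute percentage error
#'
#' `mae()` is the mean of `|true - predicted|`; `mape()` additionally divides
#' each absolute error by its true value and scales by 100, so it is a
#' percentage.  `mape()` refuses targets containing zeros, naming the first
#' offending index.
#'
#' @param true,predicted Numeric vectors of equal length.
#' @return A single number (`mape()` in percent).
#' @export
mae <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    abort("`true` and `predicted` must have equal length.")
  }
  mean(abs(true - predicted))
}

#' @rdname mae
#' @export
mape <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    abort("`true` and `predicted` must have equal length.")
  }
  zero <- which(true == 0)
  if (length(zero) > 0) {
    abort(sprintf("`true` contains zero at index %d; MAPE is undefined.", zero[1]))
  }
  100 / length(true) * sum(abs(true - predicted) / true)
}

#' Configure a feed-forward well-being or age predictor
#'
#' Architecture and training settings for [train_predictor()].  The default
#' is a desk-scale network (2 hidden layers of 64 units); the full-scale
#' published-style architectures (4 x 256 for age, 4 x 400 for the
#' six-dimensional well-being task, with L2 coefficients 1e-6 and 1e-7) are a
#' flag away via `hidden_layers`/`hidden_units`.  Both tasks use leaky-ReLU
#' activations, 25% dropout, the MAE training objective, an Adam-style
#' optimizer (batch 32), 5-fold cross-validation, and early stopping on
#' fold-validation MAE with patience 10.
#'
#' @param task `"age"` (one output) or `"wellbeing6"` (all six follow-up
#'   well-being dimensions predicted simultaneously, multilabel).
#' @param hidden_layers,hidden_units Hidden architecture.
#' @param activation Only `"leaky_relu"`.
#' @param dropout_p Dropout probability after each hidden layer.
#' @param l2_coefficient L2 regularization weight (default 1e-6 for age,
#'   1e-7 for well-being).
#' @param loss Only `"mae"`.
#' @param cv_folds Number of cross-validation folds.
#' @param epochs Maximum training epochs per fit.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience, in epochs.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling folds, initialization and dropout.
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(task = c("age", "wellbeing6"),
                             hidden_layers = 2, hidden_units = 64,
                             activation = "leaky_relu", dropout_p = 0.25,
                             l2_coefficient = NULL, loss = "mae",
                             cv_folds = 5, epochs = 150, batch_size = 32,
                             patience = 10, learning_rate = 1e-3, seed = 1L) {
  task <- match.arg(task)
  activation <- match.arg(activation, "leaky_relu")
  loss <- match.arg(loss, "mae")
  l2_coefficient <- l2_coefficient %||% if (task == "age") 1e-6 else 1e-7
  if (cv_folds < 2) abort("`cv_folds` must be at least 2.")
  structure(
    list(task = task, hidden_layers = as.integer(hidden_layers),
         hidden_units = as.integer(hidden_units), activation = activation,
         dropout_p = dropout_p, l2_coefficient = l2_coefficient, loss = loss,
         cv_folds = as.integer(cv_folds), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "predictor_config"
  )
}

predictor_targets <- function(cohort, task) {
  if (task == "age") {
    y <- matrix(cohort$age, ncol = 1)
    colnames(y) <- "age"
  } else {
    y <- as.matrix(cohort[wb_cols(2)])
  }
  y
}

#' Train a psychological-age or future-well-being predictor
#'
#' Fits the feed-forward regressor of a [predictor_config()] on the cohort's
#' training partition with k-fold cross-validation: per-fold networks are
#' trained on k-1 folds (the held-out fold serving as the early-stopping
#' validation set), out-of-fold predictions are pooled into the evaluation
#' report, and a final model is refit on the whole training partition with a
#' seeded 10% validation split.  Median- and mean-prediction baselines are
#' evaluated out-of-fold alongside.
#'
#' @param cohort A cohort tibble with `item_*` features; only rows with
#'   `split == "train"` are used.
#' @param config A [predictor_config()].
#' @return An object of class `psych_predictor` with the final fit, pooled
#'   and per-fold metrics (MAE, MAPE, Pearson's r), baseline MAEs and the
#'   out-of-fold predictions.  Use [predict()][predict.psych_predictor()],
#'   [tidy()] and [glance()] on it.
#' @export
train_predictor <- function(cohort, config = predictor_config()) {
  train <- cohort[cohort$split == "train", ]
  if (nrow(train) == 0) abort("cohort has no training rows.")
  if (nrow(train) < config$cv_folds) abort("fewer training samples than folds.")
  x <- cohort_items(train)
  y <- predictor_targets(train, config$task)
  hidden <- rep(config$hidden_units, config$hidden_layers)

  seeds <- derive_seeds(config$seed, config$cv_folds + 2L)
  set.seed(seeds[1])
  fold <- sample(rep(seq_len(config$cv_folds), length.out = nrow(x)))

  oof <- matrix(NA_real_, nrow(x), ncol(y), dimnames = list(NULL, colnames(y)))
  per_fold <- vector("list", config$cv_folds)
  base_oof_median <- base_oof_mean <- oof
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    fit <- mlp_fit(x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                   hidden = hidden, dropout = config$dropout_p,
                   l2 = config$l2_coefficient, lr = config$learning_rate,
                   batch_size = config$batch_size, epochs = config$epochs,
                   patience = config$patience,
                   x_val = x[!tr, , drop = FALSE],
                   y_val = y[!tr, , drop = FALSE], seed = seeds[f + 1L])
    pred <- mlp_predict(fit, x[!tr, , drop = FALSE])
    oof[!tr, ] <- pred
    base_oof_median[!tr, ] <- matrix(apply(y[tr, , drop = FALSE], 2, stats::median),
                                     sum(!tr), ncol(y), byrow = TRUE)
    base_oof_mean[!tr, ] <- matrix(colMeans(y[tr, , drop = FALSE]),
                                   sum(!tr), ncol(y), byrow = TRUE)
    per_fold[[f]] <- eval_metrics(y[!tr, , drop = FALSE], pred, fold = f)
  }

  # final refit on all training rows, seeded 10% internal validation split
  # for early stopping
  set.seed(seeds[config$cv_folds + 2L])
  val_idx <- sample.int(nrow(x), max(2L, round(0.1 * nrow(x))))
  final <- mlp_fit(x[-val_idx, , drop = FALSE], y[-val_idx, , drop = FALSE],
                   hidden = hidden, dropout = config$dropout_p,
                   l2 = config$l2_coefficient, lr = config$learning_rate,
                   batch_size = config$batch_size, epochs = config$epochs,
                   patience = config$patience,
                   x_val = x[val_idx, , drop = FALSE],
                   y_val = y[val_idx, , drop = FALSE],
                   seed = seeds[config$cv_folds + 2L])

  metrics <- dplyr::bind_rows(
    eval_metrics(y, oof, fold = "pooled"),
    dplyr::bind_rows(per_fold)
  )
  baselines <- dplyr::bind_rows(
    eval_metrics(y, base_oof_median, fold = "pooled") |>
      dplyr::mutate(baseline = "median"),
    eval_metrics(y, base_oof_mean, fold = "pooled") |>
      dplyr::mutate(baseline = "mean")
  ) |>
    dplyr::select("baseline", "target", "mae", "mape", "pearson_r")

  structure(
    list(config = config, fit = final, feature_names = colnames(x),
         metrics = metrics, baselines = baselines,
         oof = dplyr::bind_cols(tibble(subject_id = train$subject_id,
                                       fold = fold),
                                as_tibble(oof))),
    class = "psych_predictor"
  )
}

eval_metrics <- function(true, pred, fold) {
  true <- as.matrix(true); pred <- as.matrix(pred)
  purrr::map_dfr(seq_len(ncol(true)), function(j) {
    tj <- true[, j]; pj <- pred[, j]
    tibble(fold = as.character(fold),
           target = colnames(true)[j] %||% paste0("y", j),
           mae = mae(tj, pj),
           mape = if (any(tj == 0)) NA_real_ else mape(tj, pj),
           pearson_r = if (sd(pj) > 0 && sd(tj) > 0) stats::cor(tj, pj) else NA_real_)
  })
}

#' Predict from a fitted psychological predictor
#'
#' @param object A `psych_predictor`.
#' @param newdata A cohort tibble (its `item_*` columns are used) or a
#'   numeric feature matrix.
#' @param ... Unused.
#' @return A tibble of predictions, one column per target.
#' @export
predict.psych_predictor <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else cohort_items(newdata)
  if (!identical(colnames(x), object$feature_names) &&
      ncol(x) != length(object$feature_names)) {
    abort("`newdata` features do not match the fitted predictor.")
  }
  as_tibble(as.data.frame(mlp_predict(object$fit, x)))
}

#' @export
print.psych_predictor <- function(x, ...) {
  cat(sprintf("<psych_predictor> task=%s, %d x %d hidden, %d-fold CV\n",
              x$config$task, x$config$hidden_layers, x$config$hidden_units,
              x$config$cv_folds))
  print(dplyr::filter(x$metrics, .data$fold == "pooled"))
  invisible(x)
}

#' @method tidy psych_predictor
#' @export
tidy.psych_predictor <- function(x, ...) x$metrics

#' @method glance psych_predictor
#' @export
glance.psych_predictor <- function(x, ...) {
  pooled <- dplyr::filter(x$metrics, .data$fold == "pooled")
  tibble(task = x$config$task,
         n_targets = nrow(pooled),
         mae = mean(pooled$mae),
         mape = mean(pooled$mape),
         pearson_r = mean(pooled$pearson_r),
         baseline_median_mae = mean(
           x$baselines$mae[x$baselines$baseline == "median"]))
}

#' Reference fit of predicted on chronological age
#'
#' Linear regression of predicted psychological age on chronological age over
#' the training partition; the fit is what [age_correct()] subtracts so that
#' corrected age measures deviation from one's age peers rather than from
#' the whole cohort.
#'
#' @param predicted,chronological Numeric vectors from the training split.
#' @return An object of class `age_reference` (wrapping the linear fit).
#' @export
age_reference_fit <- function(predicted, chronological) {
  if (sd(chronological) == 0) {
    abort("chronological age is constant; reference fit is degenerate.")
  }
  fit <- lm(predicted ~ chronological,
            data = data.frame(predicted = predicted,
                              chronological = chronological))
  structure(list(coef = coef(fit)), class = "age_reference")
}

#' Correct predicted age for chronological age
#'
#' Returns `chronological + (predicted - E[predicted | chronological])`,
#' where the conditional expectation is the [age_reference_fit()] line
#' estimated on training data.  The corrected value keeps each subject's
#' deviation from the typical prediction of their age peers, so the mean
#' deviation from chronological age is (near) zero on the training split and
#' same-age subjects keep their ordering.
#'
#' @param predicted_age,chronological_age Numeric vectors.
#' @param reference_fit An [age_reference_fit()].
#' @return Numeric vector of corrected ages.
#' @export
age_correct <- function(predicted_age, chronological_age, reference_fit) {
  if (!inherits(reference_fit, "age_reference")) {
    abort("`reference_fit` must come from `age_reference_fit()`.")
  }
  expected <- reference_fit$coef[1] + reference_fit$coef[2] * chronological_age
  chronological_age + (predicted_age - expected)
}

#' Age trend of near-ceiling well-being
#'
#' Well-being scores are heavily right-skewed (mass near the scale maximum),
#' so mean levels track age poorly; instead the trend is summarized as the
#' fraction of subjects at or above 90% of the scale maximum within each age
#' bin.  When a second (e.g. model-predicted) score vector is supplied, the
#' two binned curves are compared by MAPE over the bins where both are
#' defined and the actual fraction is nonzero.
#'
#' @param age Numeric vector of ages.
#' @param actual Scores on the declared scale.
#' @param predicted Optional second score vector to compare.
#' @param scale_max Scale maximum defining the 90% threshold.
#' @param bin_width Age bin width in years (default 5).
#' @param breaks Optional explicit bin breaks (override `bin_width`).
#' @return A list: `curve` (tibble with `bin`, `age_mid`, `n`,
#'   `frac_actual`, and `frac_predicted` when supplied) and `trend_mape`
#'   (percent, or `NA` when no second curve).  Empty bins are dropped with a
#'   warning.
#' @export
wellbeing_trend <- function(age, actual, predicted = NULL, scale_max = 7,
                            bin_width = 5, breaks = NULL) {
  breaks <- breaks %||% seq(floor(min(age) / bin_width) * bin_width,
                            ceiling(max(age) / bin_width) * bin_width,
                            by = bin_width)
  if (min(age) < min(breaks) || max(age) > max(breaks)) {
    abort("`breaks` do not cover the observed ages.")
  }
  thr <- 0.9 * scale_max
  bin <- cut(age, breaks, include.lowest = TRUE, right = FALSE)
  curve <- tibble(bin = levels(bin),
                  age_mid = (head(breaks, -1) + tail(breaks, -1)) / 2) |>
    dplyr::left_join(
      tibble(bin = as.character(bin), actual = actual,
             predicted = if (is.null(predicted)) NA_real_ else predicted) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(),
                         frac_actual = mean(.data$actual >= thr),
                         frac_predicted = mean(.data$predicted >= thr),
                         .groups = "drop"),
      by = "bin"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  if (any(curve$n == 0)) {
    warn(sprintf("%d empty age bin(s) excluded from the trend.",
                 sum(curve$n == 0)))
    curve <- dplyr::filter(curve, .data$n > 0)
  }
  trend_mape <- NA_real_
  if (!is.null(predicted)) {
    use <- curve$frac_actual > 0 & !is.na(curve$frac_predicted)
    if (sum(use) < sum(!is.na(curve$frac_predicted))) {
      warn("bins with zero actual fraction excluded from the trend MAPE.")
    }
    if (any(use)) {
      trend_mape <- mape(curve$frac_actual[use], curve$frac_predicted[use])
    }
  }
  if (is.null(predicted)) curve$frac_predicted <- NULL
  list(curve = curve, trend_mape = trend_mape)
}
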