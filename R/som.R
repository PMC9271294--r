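#' Configure a self-organizing map
#'
#' Hyperparameters for [train_som()].  Defaults follow the configuration used
#' throughout this package's atlas workflow: a 25 x 25 rectangular grid,
#' Gaussian neighborhood with initial radius `sigma0 = 1.8`, initial learning
#' rate 0.4, Euclidean activation distance, and training until the
#' quantization error stops decreasing.
#'
#' Both `sigma` and the learning rate decay as `value0 / (1 + t / (T/2))`
#' over the total planned number of sample presentations `T`.  One epoch is
#' `n_iterations_per_epoch` presentations (defaulting to the number of
#' training samples, drawn with replacement); training stops early once the
#' quantization error has failed to improve on its running best by more than
#' `convergence_tol` for `patience` consecutive epochs.
#'
#' @param width,height Grid dimensions in cells.
#' @param sigma0 Initial neighborhood radius, in grid units.
#' @param learning_rate0 Initial learning rate in (0, 1].
#' @param neighborhood Neighborhood kernel; only `"gaussian"` is implemented.
#' @param activation_distance Sample-to-codebook metric; only `"euclidean"`.
#' @param n_iterations_per_epoch Presentations per epoch, or `NULL` for one
#'   pass-worth per epoch (n samples).
#' @param max_epochs Upper bound on training epochs.
#' @param convergence_tol Minimum quantization-error improvement that still
#'   counts as progress (on standardized data).
#' @param patience Consecutive non-improving epochs before stopping.
#' @param seed Integer seed for codebook initialization and presentation order.
#' @return A list of class `som_config`.
#' @export
som_config <- function(width = 25, height = 25, sigma0 = 1.8,
                       learning_rate0 = 0.4, neighborhood = "gaussian",
                       activation_distance = "euclidean",
                       n_iterations_per_epoch = NULL, max_epochs = 50,
                       convergence_tol = 1e-4, patience = 5, seed = 1L) {
  if (width < 1 || height < 1 || width * height < 1) {
    abort("`width` x `height` must be at least one cell.")
  }
  if (sigma0 <= 0) abort("`sigma0` must be > 0.")
  if (learning_rate0 <= 0 || learning_rate0 > 1) {
    abort("`learning_rate0` must be in (0, 1].")
  }
  neighborhood <- match.arg(neighborhood, "gaussian")
  activation_distance <- match.arg(activation_distance, "euclidean")
  if (convergence_tol < 0) abort("`convergence_tol` must be non-negative.")
  if (patience < 1) abort("`patience` must be a positive count.")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         sigma0 = sigma0, learning_rate0 = learning_rate0,
         neighborhood = neighborhood,
         activation_distance = activation_distance,
         n_iterations_per_epoch = n_iterations_per_epoch,
         max_epochs = as.integer(max_epochs),
         convergence_tol = convergence_tol,
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "som_config"
  )
}

# Cell layout: 1-based row-major; cell = (row - 1) * width + col.
grid_coords <- function(width, height) {
  tibble(
    cell = seq_len(width * height),
    row = rep(seq_len(height), each = width),
    col = rep(seq_len(width), times = height)
  )
}

# Squared grid distances between all cell pairs, in grid coordinates.
grid_dist2 <- function(width, height) {
  g <- grid_coords(width, height)
  outer(g$row, g$row, "-")^2 + outer(g$col, g$col, "-")^2
}

scale_features <- function(x, center, scale) {
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Train a Kohonen self-organizing map
#'
#' Sequential (online) Kohonen training: samples are presented one at a time
#' in a seeded random order with replacement; for each presentation the
#' best-matching unit (BMU) is located by Euclidean distance and every cell's
#' codebook vector is pulled toward the sample, weighted by a Gaussian of its
#' grid distance to the BMU.  Features are z-scored internally (the scaler is
#' stored in the model, so [find_bmu()] and friends accept raw-unit samples);
#' the codebook is initialized uniformly within the per-feature data ranges.
#'
#' @param data Numeric matrix or data frame, samples x features; all values
#'   finite.
#' @param config A [som_config()].
#' @param feature_names Feature names; defaults to `colnames(data)`.
#' @return An object of class `som_model`: grid layout, scaled codebook
#'   (the state of the best-quantization-error epoch), scaler, per-epoch
#'   quantization-error log and convergence flag.
#' @seealso [find_bmu()], [quantization_error()], [u_matrix()], [map_cohort()]
#' @export
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' m <- train_som(x, som_config(width = 5, height = 5, max_epochs = 10, seed = 1))
#' glance(m)
train_som <- function(data, config = som_config(), feature_names = NULL) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (nrow(x) < 1 || ncol(x) < 1) abort("`data` must have at least one sample and one feature.")
  if (!all(is.finite(x))) abort("`data` contains non-finite values.")
  feature_names <- feature_names %||% colnames(x) %||% paste0("f", seq_len(ncol(x)))
  if (length(feature_names) != ncol(x)) {
    abort("`feature_names` length does not match the number of features.")
  }

  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale_features(x, center, scl)

  m <- config$width * config$height
  n <- nrow(x)
  per_epoch <- config$n_iterations_per_epoch %||% n
  seeds <- derive_seeds(config$seed, 2L)

  set.seed(seeds[1])
  rng <- apply(xs, 2, range)
  init <- matrix(runif(m * ncol(xs), rep(rng[1, ], each = m),
                       rep(rng[2, ], each = m)), m, ncol(xs))

  set.seed(seeds[2])
  order <- sample.int(n, per_epoch * config$max_epochs, replace = TRUE)

  fit <- som_train_cpp(xs, init, grid_dist2(config$width, config$height),
                       order, per_epoch, config$max_epochs,
                       config$sigma0, config$learning_rate0,
                       config$convergence_tol, config$patience)

  structure(
    list(config = config,
         codebook = fit$codebook,
         codebook_init = init,
         feature_names = feature_names,
         center = center, scale = scl,
         grid = grid_coords(config$width, config$height),
         training_log = tibble(epoch = seq_along(fit$qe_log),
                               quantization_error = as.numeric(fit$qe_log)),
         epochs = fit$epochs,
         converged = fit$converged),
    class = "som_model"
  )
}

n_cells <- function(model) nrow(model$codebook)

#' Codebook in original feature units
#'
#' Undoes the per-feature z-scoring stored in the model.
#'
#' @param model A `som_model`.
#' @return Numeric matrix, cells x features, in the units of the training data.
#' @export
codebook_units <- function(model) {
  cb <- sweep(model$codebook, 2, model$scale, "*")
  cb <- sweep(cb, 2, model$center, "+")
  colnames(cb) <- model$feature_names
  cb
}

scale_samples <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != length(model$feature_names)) {
    abort(sprintf("sample has %d features; model expects %d.",
                  ncol(x), length(model$feature_names)))
  }
  if (!all(is.finite(x))) abort("sample contains non-finite values.")
  scale_features(x, model$center, model$scale)
}

#' Best-matching unit of a sample
#'
#' Finds the cell whose codebook vector is nearest (Euclidean, on the model's
#' standardized scale) to the sample; ties break to the lowest cell index.
#'
#' @param model A `som_model`.
#' @param sample Numeric vector of length `n_features` (raw units), or a
#'   matrix of such rows.
#' @return A tibble with one row per sample: `cell`, `row`, `col`, `distance`.
#' @export
find_bmu <- function(model, sample) {
  xs <- scale_samples(model, sample)
  hit <- bmu_cpp(model$codebook, xs)
  tibble(cell = hit$cell,
         row = model$grid$row[hit$cell],
         col = model$grid$col[hit$cell],
         distance = hit$distance)
}

#' Quantization error of a map on a dataset
#'
#' Mean Euclidean distance between each sample and its best-matching unit, on
#' the model's standardized feature scale — the map-quality and convergence
#' criterion used during training.
#'
#' @param model A `som_model`.
#' @param data Samples x features matrix or data frame, raw units.
#' @return A single non-negative number.
#' @export
quantization_error <- function(model, data) {
  x <- as.matrix(data)
  if (nrow(x) == 0) abort("`data` is empty.")
  mean(find_bmu(model, x)$distance)
}

# 8-connectivity neighbor pairs (from < to) of a width x height lattice.
grid_edges <- function(width, height) {
  g <- grid_coords(width, height)
  offs <- cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r2 <- g$row + offs[k, "dr"]
    c2 <- g$col + offs[k, "dc"]
    ok <- r2 >= 1 & r2 <= height & c2 >= 1 & c2 <= width
    out[[k]] <- tibble(from = g$cell[ok],
                       to = (r2[ok] - 1L) * width + c2[ok])
  }
  dplyr::bind_rows(out)
}

#' Unified-distance matrix of a trained map
#'
#' For every cell, the mean Euclidean codebook distance to its grid neighbors
#' (8-connectivity; edge and corner cells average over the neighbors they
#' have).  Ridges of high unified distance mark psychotype-cluster borders.
#'
#' @param model A `som_model`.
#' @return A tibble with one row per cell: `cell`, `row`, `col`,
#'   `unified_distance`.
#' @export
u_matrix <- function(model) {
  e <- grid_edges(model$config$width, model$config$height)
  d <- sqrt(rowSums((model$codebook[e$from, , drop = FALSE] -
                       model$codebook[e$to, , drop = FALSE])^2))
  both <- tibble(cell = c(e$from, e$to), d = c(d, d))
  agg <- dplyr::summarise(dplyr::group_by(both, .data$cell),
                          unified_distance = mean(.data$d), .groups = "drop")
  dplyr::left_join(model$grid, agg, by = "cell")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d grid (%d cells), %d features\n",
              x$config$width, x$config$height, n_cells(x),
              length(x$feature_names)))
  cat(sprintf("  trained %d epoch(s); quantization error %.4f; %s\n",
              x$epochs, tail(x$training_log$quantization_error, 1),
              if (x$converged) "converged" else "stopped at max_epochs"))
  invisible(x)
}

#' Tidy a trained map into a long cell-feature table
#'
#' @param x A `som_model`.
#' @param units `"original"` (default) or `"scaled"` codebook values.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `row`, `col`, `feature`, `value`.
#' @method tidy som_model
#' @export
tidy.som_model <- function(x, units = c("original", "scaled"), ...) {
  units <- match.arg(units)
  cb <- if (units == "original") codebook_units(x) else x$codebook
  colnames(cb) <- x$feature_names
  dplyr::bind_cols(x$grid, as_tibble(cb)) |>
    tidyr::pivot_longer(-c("cell", "row", "col"),
                        names_to = "feature", values_to = "value")
}

#' One-row training summary of a map
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, cells, features, epochs, final
#'   quantization error, convergence flag.
#' @method glance som_model
#' @export
glance.som_model <- function(x, ...) {
  tibble(width = x$config$width, height = x$config$height,
         n_cells = n_cells(x), n_features = length(x$feature_names),
         epochs = x$epochs,
         quantization_error = tail(x$training_log$quantization_error, 1),
         converged = x$converged)
}
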