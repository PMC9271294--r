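# Independent brute-force / reference oracles used across the suite.
# These deliberately avoid the package's own code paths.

# Exhaustive BMU search by plain loops.
brute_bmu <- function(codebook, x) {
  t(apply(x, 1, function(s) {
    d <- sqrt(colSums((t(codebook) - s)^2))
    k <- which.min(d)
    c(cell = k, distance = d[k])
  }))
}

# Per-cell mean codebook distance over 8-connected neighbor sets, by loops.
brute_umatrix <- function(codebook, width, height) {
  val <- numeric(width * height)
  for (r in seq_len(height)) {
    for (cc in seq_len(width)) {
      i <- (r - 1) * width + cc
      ds <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > height || c2 < 1 || c2 > width) next
        j <- (r2 - 1) * width + c2
        ds <- c(ds, sqrt(sum((codebook[i, ] - codebook[j, ])^2)))
      }
      val[i] <- mean(ds)
    }
  }
  val
}

# Naive-loop online Kohonen reference with a linear decay schedule; shares no
# code (and not the update schedule) with the package implementation.
reference_som <- function(x, width, height, sigma0 = 1.8, lr0 = 0.4,
                          n_steps = 5000, seed = 1) {
  set.seed(seed)
  m <- width * height
  p <- ncol(x)
  rows <- rep(seq_len(height), each = width)
  cols <- rep(seq_len(width), times = height)
  cb <- matrix(runif(m * p, apply(x, 2, min), apply(x, 2, max)),
               m, p, byrow = FALSE)
  for (t in seq_len(n_steps)) {
    s <- x[sample.int(nrow(x), 1), ]
    d <- sqrt(colSums((t(cb) - s)^2))
    b <- which.min(d)
    frac <- 1 - (t - 1) / n_steps
    sig <- max(sigma0 * frac, 0.3)
    lr <- lr0 * frac
    gd2 <- (rows - rows[b])^2 + (cols - cols[b])^2
    h <- exp(-gd2 / (2 * sig^2))
    cb <- cb + lr * h * (matrix(s, m, p, byrow = TRUE) - cb)
  }
  qe <- mean(apply(x, 1, function(s) min(sqrt(colSums((t(cb) - s)^2)))))
  list(codebook = cb, qe = qe)
}

# Hand-rolled agglomerative clustering, complete linkage, Euclidean.
reference_complete_linkage <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        link <- max(d[groups[[i]], groups[[j]]])
        if (link < best[1]) best <- c(link, i, j)
      }
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# A fabricated som_model around a given codebook (identity scaler), so
# brute-force oracles can address package operations directly.
fake_model <- function(codebook, width, height,
                       feature_names = paste0("f", seq_len(ncol(codebook)))) {
  colnames(codebook) <- NULL
  structure(
    list(config = som_config(width = width, height = height, seed = 1L),
         codebook = codebook,
         codebook_init = codebook,
         feature_names = feature_names,
         center = setNames(rep(0, ncol(codebook)), feature_names),
         scale = setNames(rep(1, ncol(codebook)), feature_names),
         grid = psychatlas:::grid_coords(width, height),
         training_log = tibble::tibble(epoch = 1L, quantization_error = 0),
         epochs = 1L, converged = TRUE),
    class = "som_model"
  )
}

# Small planted cohort shared by atlas/pathfinder tests.
small_cohort <- function(seed = 3, n_train = 900, n_dep = 150, n_non = 300) {
  generate_cohort(cohort_spec(n_train = n_train, n_test_depressed = n_dep,
                              n_test_nondepressed = n_non, seed = seed))
}

# Hand-built cohort rows for overlay arithmetic tests.
toy_cohort <- function(cells, depressed, sex = NULL, wb2 = NULL, n_items = 4) {
  n <- length(cells)
  sex <- sex %||% rep("female", n)
  items <- matrix(4, n, n_items)
  colnames(items) <- psychatlas::item_cols(n_items)
  wb <- matrix(if (is.null(wb2)) 4 else wb2, n, 6)
  out <- tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    tibble::as_tibble(items),
    age = 50, sex = sex,
  )
  for (k in 1:6) out[[paste0("wb1_", k)]] <- wb[, k]
  for (k in 1:6) out[[paste0("wb2_", k)]] <- wb[, k]
  out$depressed <- depressed
  out$split <- "test"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
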