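# Compact feed-forward regressor: leaky-ReLU hidden layers, inverted
# dropout, L2 weight decay, Adam, MAE loss.  Inputs and targets are z-scored
# internally; predictions are returned in original units.  Deterministic for
# a fixed seed (all randomness goes through R's RNG).

leaky_relu <- function(z, slope) ifelse(z > 0, z, slope * z)
d_leaky_relu <- function(z, slope) ifelse(z > 0, 1, slope)

mlp_init <- function(p, q, hidden, seed) {
  set.seed(seed)
  sizes <- c(p, hidden, q)
  W <- b <- vector("list", length(sizes) - 1)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, x, slope, dropout = 0, training = FALSE) {
  L <- length(net$W)
  a <- x
  acts <- vector("list", L + 1)
  pre <- masks <- vector("list", L)
  acts[[1]] <- a
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]] + matrix(net$b[[l]], nrow(a), length(net$b[[l]]),
                                   byrow = TRUE)
    if (l < L) {
      a <- leaky_relu(z, slope)
      if (training && dropout > 0) {
        m <- matrix(rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                    nrow(a), ncol(a))
        a <- a * m
        masks[[l]] <- m
      }
    } else {
      a <- z # linear output
    }
    pre[[l]] <- z
    acts[[l + 1]] <- a
  }
  list(pred = a, acts = acts, pre = pre, masks = masks)
}

# One Adam step on a minibatch under MAE loss.
mlp_step <- function(net, state, xb, yb, slope, dropout, l2, lr, t,
                     b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  L <- length(net$W)
  fw <- mlp_forward(net, xb, slope, dropout, training = TRUE)
  nb <- nrow(xb)
  delta <- sign(fw$pred - yb) / (nb * ncol(yb))
  for (l in rev(seq_len(L))) {
    gW <- crossprod(fw$acts[[l]], delta) + l2 * net$W[[l]]
    gb <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * d_leaky_relu(fw$pre[[l - 1]], slope)
      if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
    }
    for (nm in c("W", "b")) {
      g <- if (nm == "W") gW else gb
      state$m[[nm]][[l]] <- b1 * state$m[[nm]][[l]] + (1 - b1) * g
      state$v[[nm]][[l]] <- b2 * state$v[[nm]][[l]] + (1 - b2) * g^2
      mhat <- state$m[[nm]][[l]] / (1 - b1^t)
      vhat <- state$v[[nm]][[l]] / (1 - b2^t)
      net[[nm]][[l]] <- net[[nm]][[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

zeros_like <- function(net) {
  list(W = lapply(net$W, function(w) w * 0), b = lapply(net$b, function(v) v * 0))
}

# Fit the network.  If a validation set is supplied, training stops after
# `patience` epochs without validation-MAE improvement and the best weights
# are restored.
mlp_fit <- function(x, y, hidden = c(64, 64), dropout = 0.25, l2 = 1e-6,
                    lr = 1e-3, batch_size = 32, epochs = 150, patience = 10,
                    slope = 0.01, x_val = NULL, y_val = NULL, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  xc <- colMeans(x); xs <- apply(x, 2, sd); xs[xs == 0 | !is.finite(xs)] <- 1
  yc <- colMeans(y); ys <- apply(y, 2, sd); ys[ys == 0 | !is.finite(ys)] <- 1
  if (all(apply(y, 2, sd) == 0)) {
    # degenerate target: the optimal MAE predictor is the constant itself
    return(structure(list(constant = yc, x_center = xc, x_scale = xs,
                          y_center = yc, y_scale = ys, slope = slope,
                          hidden = hidden, val_history = numeric(0),
                          best_epoch = 0L),
                     class = "psychatlas_mlp"))
  }
  xst <- scale_features(x, xc, xs)
  yst <- scale_features(y, yc, ys)
  has_val <- !is.null(x_val)
  if (has_val) xv <- scale_features(as.matrix(x_val), xc, xs)

  net <- mlp_init(ncol(x), ncol(y), hidden, seed)
  state <- list(m = zeros_like(net), v = zeros_like(net))
  set.seed(seed + 1L)
  n <- nrow(x)
  best <- list(net = net, mae = Inf, epoch = 0L)
  stale <- 0L
  t <- 0L
  history <- numeric(0)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      t <- t + 1L
      stepped <- mlp_step(net, state, xst[idx, , drop = FALSE],
                          yst[idx, , drop = FALSE], slope, dropout, l2, lr, t)
      net <- stepped$net
      state <- stepped$state
    }
    if (has_val) {
      pv <- mlp_forward(net, xv, slope)$pred
      pv <- sweep(sweep(pv, 2, ys, "*"), 2, yc, "+")
      vm <- mean(abs(pv - as.matrix(y_val)))
      history <- c(history, vm)
      if (vm < best$mae - 1e-6) {
        best <- list(net = net, mae = vm, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  if (has_val && is.finite(best$mae)) net <- best$net
  structure(list(net = net, x_center = xc, x_scale = xs,
                 y_center = yc, y_scale = ys, slope = slope,
                 hidden = hidden, val_history = history,
                 best_epoch = if (has_val) best$epoch else length(history)),
            class = "psychatlas_mlp")
}

mlp_predict <- function(fit, x) {
  if (!is.null(fit$constant)) {
    return(matrix(fit$constant, nrow(as.matrix(x)), length(fit$constant),
                  byrow = TRUE))
  }
  xst <- scale_features(as.matrix(x), fit$x_center, fit$x_scale)
  p <- mlp_forward(fit$net, xst, fit$slope)$pred
  sweep(sweep(p, 2, fit$y_scale, "*"), 2, fit$y_center, "+")
}
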