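# Minimal feed-forward network for small tabular problems: fully connected,
# tanh hidden activations, softmax output, cross-entropy loss, full-batch
# Adam, early stopping on a held-out slice of the training pool with
# best-weight restoration. Sized for hundreds-to-thousands of rows and a few
# hundred features; everything is base R matrix algebra (BLAS does the work).

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(1 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, x) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- x
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  A
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(prob, y_idx) {
  -mean(log(pmax(prob[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

# one full-batch gradient of the mean cross-entropy
mlp_grad <- function(par, A, prob, y_idx) {
  L <- length(par$W)
  n <- nrow(prob)
  Y <- matrix(0, n, ncol(prob))
  Y[cbind(seq_len(n), y_idx)] <- 1
  delta <- (prob - Y) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(par$W[[l]])) * (1 - A[[l]]^2)
  }
  list(W = gW, b = gb)
}

# stratified indices for the early-stopping slice; at least one trial per
# class stays in the training part
holdout_indices <- function(y_idx, frac) {
  val <- integer(0)
  for (cl in unique(y_idx)) {
    members <- which(y_idx == cl)
    n_val <- min(length(members) - 1L, max(1L, round(frac * length(members))))
    if (n_val > 0L) val <- c(val, sample(members, n_val))
  }
  val
}

# per-feature min-max map onto [-1, 1], fitted on the training pool; the
# usual input conditioning for tanh networks (constant features map to 0)
mlp_input_map <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

mlp_apply_map <- function(map, x) {
  sweep(sweep(x, 2L, map$lo), 2L, map$span, `/`) * 2 - 1
}

# x: numeric matrix; y_idx: integer class in 1..n_classes
mlp_fit <- function(x, y_idx, n_classes, hidden, seed,
                    max_epochs = 400L, lr = 0.01, patience = 40L,
                    val_frac = 0.15) {
  stopifnot(nrow(x) == length(y_idx))
  map <- mlp_input_map(x)
  x <- mlp_apply_map(map, x)
  sizes <- c(ncol(x), hidden, n_classes)
  with_seed(seed, {
    val <- holdout_indices(y_idx, val_frac)
    par <- mlp_init(sizes)
  })
  fit_idx <- if (length(val)) setdiff(seq_len(nrow(x)), val) else seq_len(nrow(x))
  xf <- x[fit_idx, , drop = FALSE]; yf <- y_idx[fit_idx]
  xv <- x[val, , drop = FALSE];     yv <- y_idx[val]
  L <- length(par$W)
  m <- v <- list(W = lapply(par$W, `*`, 0), b = lapply(par$b, `*`, 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- par; best_loss <- Inf; stall <- 0L; t <- 0L
  for (epoch in seq_len(max_epochs)) {
    A <- mlp_forward(par, xf)
    prob <- softmax_rows(A[[L + 1L]])
    g <- mlp_grad(par, A, prob, yf)
    t <- t + 1L
    for (l in seq_len(L)) {
      m$W[[l]] <- b1 * m$W[[l]] + (1 - b1) * g$W[[l]]
      v$W[[l]] <- b2 * v$W[[l]] + (1 - b2) * g$W[[l]]^2
      m$b[[l]] <- b1 * m$b[[l]] + (1 - b1) * g$b[[l]]
      v$b[[l]] <- b2 * v$b[[l]] + (1 - b2) * g$b[[l]]^2
      mhW <- m$W[[l]] / (1 - b1^t); vhW <- v$W[[l]] / (1 - b2^t)
      mhb <- m$b[[l]] / (1 - b1^t); vhb <- v$b[[l]] / (1 - b2^t)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    monitor <- if (length(val)) {
      pv <- softmax_rows(mlp_forward(par, xv)[[L + 1L]])
      cross_entropy(pv, yv)
    } else {
      pf <- softmax_rows(mlp_forward(par, xf)[[L + 1L]])
      cross_entropy(pf, yf)
    }
    if (monitor < best_loss - 1e-8) {
      best_loss <- monitor; best <- par; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(par = best, sizes = sizes, map = map, val_loss = best_loss,
       epochs = epoch)
}

mlp_predict_prob <- function(fit, x) {
  L <- length(fit$par$W)
  x <- mlp_apply_map(fit$map, x)
  softmax_rows(mlp_forward(fit$par, x)[[L + 1L]])
}
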