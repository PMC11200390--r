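# Low-level feed-forward network: dense -> batch-norm -> ReLU -> dropout
# blocks and a softmax head, trained with Adam on class-weighted categorical
# cross-entropy. Plain matrix code; model state is a list of parameter
# matrices plus batch-norm running statistics.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-7

glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -limit, limit), nrow = fan_in)
}

mlp_init <- function(n_in, widths, n_classes) {
  dims <- c(n_in, widths)
  blocks <- lapply(seq_along(widths), function(b) {
    list(
      W = glorot_uniform(dims[b], dims[b + 1]),
      b = numeric(dims[b + 1]),
      gamma = rep(1, dims[b + 1]),
      beta = numeric(dims[b + 1]),
      run_mean = numeric(dims[b + 1]),
      run_var = rep(1, dims[b + 1])
    )
  })
  out <- list(
    W = glorot_uniform(dims[length(dims)], n_classes),
    b = numeric(n_classes)
  )
  list(blocks = blocks, out = out, n_in = n_in, n_classes = n_classes)
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# Forward pass. training = TRUE uses batch statistics, applies (inverted)
# dropout, and returns the caches needed for backprop together with updated
# running statistics; training = FALSE uses running statistics and no dropout.
mlp_forward <- function(net, X, training = FALSE, dropout = 0) {
  caches <- vector("list", length(net$blocks))
  H <- X
  for (b in seq_along(net$blocks)) {
    blk <- net$blocks[[b]]
    A <- sweep(H %*% blk$W, 2, blk$b, "+")
    if (training) {
      mu <- colMeans(A)
      v <- colMeans(sweep(A, 2, mu)^2)
      net$blocks[[b]]$run_mean <- BN_MOMENTUM * blk$run_mean +
        (1 - BN_MOMENTUM) * mu
      net$blocks[[b]]$run_var <- BN_MOMENTUM * blk$run_var +
        (1 - BN_MOMENTUM) * v
    } else {
      mu <- blk$run_mean
      v <- blk$run_var
    }
    inv_sd <- 1 / sqrt(v + BN_EPS)
    Xc <- sweep(A, 2, mu)
    Xhat <- sweep(Xc, 2, inv_sd, "*")
    Y <- sweep(sweep(Xhat, 2, blk$gamma, "*"), 2, blk$beta, "+")
    R <- pmax(Y, 0)
    if (training && dropout > 0) {
      keep <- 1 - dropout
      M <- matrix(
        (runif(length(R)) < keep) / keep,
        nrow = nrow(R)
      )
      D <- R * M
    } else {
      M <- NULL
      D <- R
    }
    if (training) {
      caches[[b]] <- list(H = H, A = A, mu = mu, inv_sd = inv_sd, Xc = Xc,
        Xhat = Xhat, Y = Y, M = M)
    }
    H <- D
  }
  logits <- sweep(H %*% net$out$W, 2, net$out$b, "+")
  P <- softmax_rows(logits)
  list(P = P, H_last = H, caches = caches, net = net)
}

# Class-weighted categorical cross-entropy, mean-reduced over rows.
weighted_ce <- function(P, y, class_weights) {
  p <- pmax(P[cbind(seq_along(y), y)], 1e-12)
  mean(class_weights[y] * (-log(p)))
}

# One backward pass; returns gradients shaped like the parameter lists.
mlp_backward <- function(net, fwd, y, class_weights, dropout) {
  n <- length(y)
  P <- fwd$P
  Yhot <- matrix(0, n, net$n_classes)
  Yhot[cbind(seq_len(n), y)] <- 1
  dL <- (P - Yhot) * (class_weights[y] / n) # grad wrt logits

  g_out <- list(W = crossprod(fwd$H_last, dL), b = colSums(dL))
  dH <- tcrossprod(dL, net$out$W) # dL %*% t(W)

  g_blocks <- vector("list", length(net$blocks))
  for (b in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[b]]
    cache <- fwd$caches[[b]]
    if (!is.null(cache$M)) dH <- dH * cache$M
    dY <- dH * (cache$Y > 0)
    dgamma <- colSums(dY * cache$Xhat)
    dbeta <- colSums(dY)
    dXhat <- sweep(dY, 2, blk$gamma, "*")
    m <- nrow(dY)
    # batch-norm backward (population variance)
    sum_dXhat <- colSums(dXhat)
    sum_dXhat_xc <- colSums(dXhat * cache$Xc)
    dA <- sweep(dXhat, 2, cache$inv_sd, "*") -
      sweep(matrix(1, m, 1) %*% rbind(sum_dXhat), 2, cache$inv_sd / m, "*") -
      sweep(cache$Xc, 2, cache$inv_sd^3 * sum_dXhat_xc / m, "*")
    g_blocks[[b]] <- list(
      W = crossprod(cache$H, dA),
      b = colSums(dA),
      gamma = dgamma,
      beta = dbeta
    )
    dH <- dA %*% t(blk$W)
  }
  list(blocks = g_blocks, out = g_out)
}

adam_init <- function(net) {
  zero_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(
    t = 0,
    m = list(
      blocks = lapply(net$blocks, function(b) {
        lapply(b[c("W", "b", "gamma", "beta")], zero_like)
      }),
      out = lapply(net$out[c("W", "b")], zero_like)
    ),
    v = list(
      blocks = lapply(net$blocks, function(b) {
        lapply(b[c("W", "b", "gamma", "beta")], zero_like)
      }),
      out = lapply(net$out[c("W", "b")], zero_like)
    )
  )
}

adam_step <- function(net, grads, state, lr) {
  state$t <- state$t + 1
  corr1 <- 1 - ADAM_BETA1^state$t
  corr2 <- 1 - ADAM_BETA2^state$t
  upd <- function(param, grad, m, v) {
    m <- ADAM_BETA1 * m + (1 - ADAM_BETA1) * grad
    v <- ADAM_BETA2 * v + (1 - ADAM_BETA2) * grad^2
    param <- param - lr * (m / corr1) / (sqrt(v / corr2) + ADAM_EPS)
    list(param = param, m = m, v = v)
  }
  for (b in seq_along(net$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      u <- upd(net$blocks[[b]][[nm]], grads$blocks[[b]][[nm]],
        state$m$blocks[[b]][[nm]], state$v$blocks[[b]][[nm]])
      net$blocks[[b]][[nm]] <- u$param
      state$m$blocks[[b]][[nm]] <- u$m
      state$v$blocks[[b]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$out[[nm]], grads$out[[nm]],
      state$m$out[[nm]], state$v$out[[nm]])
    net$out[[nm]] <- u$param
    state$m$out[[nm]] <- u$m
    state$v$out[[nm]] <- u$v
  }
  list(net = net, state = state)
}
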