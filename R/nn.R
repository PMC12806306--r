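# Minimal feed-forward network machinery: dense layers, ReLU, batch
# normalization, inverted dropout, explicit backpropagation and Adam.
# All randomness (weight init, dropout masks) is drawn from R's global RNG
# stream so that a single set.seed() makes a whole training run reproducible.

# Uniform fan-in initialization: W_ij ~ U(-1/sqrt(n_in), 1/sqrt(n_in)).
nn_linear <- function(n_in, n_out) {
  a <- sqrt(1 / n_in)
  list(
    type = "linear",
    W = matrix(stats::runif(n_in * n_out, -a, a), n_in, n_out),
    b = rep(0, n_out)
  )
}

nn_relu <- function() list(type = "relu")

nn_batchnorm <- function(d, momentum = 0.1, eps = 1e-5) {
  list(
    type = "batchnorm",
    gamma = rep(1, d), beta = rep(0, d),
    running_mean = rep(0, d), running_var = rep(1, d),
    momentum = momentum, eps = eps
  )
}

nn_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p)
}

#' @noRd
# Build an MLP: hidden blocks are linear -> relu [-> batchnorm] [-> dropout],
# output layer is a bare linear map (no activation).
nn_mlp <- function(n_in, hidden, n_out, batchnorm = FALSE, dropout = 0) {
  layers <- list()
  d <- n_in
  for (h in hidden) {
    layers[[length(layers) + 1L]] <- nn_linear(d, h)
    layers[[length(layers) + 1L]] <- nn_relu()
    if (batchnorm) layers[[length(layers) + 1L]] <- nn_batchnorm(h)
    if (dropout > 0) layers[[length(layers) + 1L]] <- nn_dropout(dropout)
    d <- h
  }
  layers[[length(layers) + 1L]] <- nn_linear(d, n_out)
  structure(list(layers = layers, n_in = n_in, n_out = n_out), class = "nn_net")
}

# Forward pass. Returns the output, per-layer caches for backprop, and the
# (possibly updated) network: batch-norm running statistics change in
# training mode. A training-mode batch of size 1 under batch norm has no
# defined batch variance and is rejected.
nn_forward <- function(net, X, training = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == net$n_in)
  caches <- vector("list", length(net$layers))
  out <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      caches[[i]] <- list(X = out)
      out <- sweep(out %*% ly$W, 2, ly$b, "+")
    } else if (ly$type == "relu") {
      mask <- out > 0
      caches[[i]] <- list(mask = mask)
      out <- out * mask
    } else if (ly$type == "batchnorm") {
      if (training) {
        if (nrow(out) < 2)
          stop("batch normalization is undefined for a training batch of size 1")
        mu <- colMeans(out)
        xc <- sweep(out, 2, mu)
        v <- colMeans(xc^2)
        inv_sd <- 1 / sqrt(v + ly$eps)
        xhat <- sweep(xc, 2, inv_sd, "*")
        m <- ly$momentum
        nb <- nrow(out)
        net$layers[[i]]$running_mean <- (1 - m) * ly$running_mean + m * mu
        # unbiased variance for the running estimate, biased within the batch
        net$layers[[i]]$running_var <- (1 - m) * ly$running_var +
          m * v * nb / max(nb - 1, 1)
        caches[[i]] <- list(xhat = xhat, inv_sd = inv_sd, xc = xc)
      } else {
        inv_sd <- 1 / sqrt(ly$running_var + ly$eps)
        xhat <- sweep(sweep(out, 2, ly$running_mean), 2, inv_sd, "*")
        caches[[i]] <- list(xhat = xhat, inv_sd = inv_sd)
      }
      out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        keep <- matrix(stats::runif(length(out)) >= ly$p, nrow(out), ncol(out))
        scale <- keep / (1 - ly$p)
        caches[[i]] <- list(scale = scale)
        out <- out * scale
      } else {
        caches[[i]] <- list(scale = NULL)
      }
    }
  }
  list(out = out, caches = caches, net = net)
}

# Backward pass. dOut is dLoss/dOutput; returns dLoss/dInput and one gradient
# entry per layer (NULL for parameter-free layers).
nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  d <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "linear") {
      grads[[i]] <- list(W = crossprod(ca$X, d), b = colSums(d))
      d <- tcrossprod(d, ly$W)
    } else if (ly$type == "relu") {
      d <- d * ca$mask
    } else if (ly$type == "batchnorm") {
      dgamma <- colSums(d * ca$xhat)
      dbeta <- colSums(d)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      if (!is.null(ca$xc)) { # training-mode cache: full batch-norm backprop
        n <- nrow(ca$xhat)
        dxhat <- sweep(d, 2, ly$gamma, "*")
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(ca$xhat, 2, colMeans(dxhat * ca$xhat), "*")
        d <- sweep(t1 - t2, 2, ca$inv_sd, "*")
      } else { # eval-mode: fixed affine map
        d <- sweep(sweep(d, 2, ly$gamma, "*"), 2, ca$inv_sd, "*")
      }
    } else if (ly$type == "dropout") {
      if (!is.null(ca$scale)) d <- d * ca$scale
    }
  }
  list(dX = d, grads = grads)
}

nn_add_grads <- function(grads_a, grads_b) {
  # elementwise sum of two gradient lists (NULL-safe)
  if (is.null(grads_a)) return(grads_b)
  for (i in seq_along(grads_b)) {
    if (is.null(grads_b[[i]])) next
    for (nm in names(grads_b[[i]]))
      grads_a[[i]][[nm]] <- grads_a[[i]][[nm]] + grads_b[[i]][[nm]]
  }
  grads_a
}

nn_scale_grads <- function(grads, s) {
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) grads[[i]][[nm]] <- grads[[i]][[nm]] * s
  }
  grads
}

adam_init <- function(net) {
  st <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      st[[i]] <- list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    } else if (ly$type == "batchnorm") {
      st[[i]] <- list(mg = ly$gamma * 0, vg = ly$gamma * 0,
                      mB = ly$beta * 0, vB = ly$beta * 0)
    }
  }
  list(t = 0L, layers = st)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    s <- state$layers[[i]]
    if (ly$type == "linear") {
      uW <- upd(ly$W, g$W, s$mW, s$vW)
      ub <- upd(ly$b, g$b, s$mb, s$vb)
      net$layers[[i]]$W <- uW$p; state$layers[[i]]$mW <- uW$m; state$layers[[i]]$vW <- uW$v
      net$layers[[i]]$b <- ub$p; state$layers[[i]]$mb <- ub$m; state$layers[[i]]$vb <- ub$v
    } else if (ly$type == "batchnorm") {
      ug <- upd(ly$gamma, g$gamma, s$mg, s$vg)
      uB <- upd(ly$beta, g$beta, s$mB, s$vB)
      net$layers[[i]]$gamma <- ug$p; state$layers[[i]]$mg <- ug$m; state$layers[[i]]$vg <- ug$v
      net$layers[[i]]$beta <- uB$p; state$layers[[i]]$mB <- uB$m; state$layers[[i]]$vB <- uB$v
    }
  }
  list(net = net, state = state)
}

# Write a flat parameter vector (ordered as nn_params) back into a network.
nn_vec_to_params <- function(net, vec) {
  pos <- 0L
  take <- function(k) {
    out <- vec[(pos + 1L):(pos + k)]
    pos <<- pos + k
    out
  }
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      net$layers[[i]]$W <- matrix(take(length(ly$W)), nrow(ly$W), ncol(ly$W))
      net$layers[[i]]$b <- take(length(ly$b))
    } else if (ly$type == "batchnorm") {
      net$layers[[i]]$gamma <- take(length(ly$gamma))
      net$layers[[i]]$beta <- take(length(ly$beta))
    }
  }
  net
}

# Flatten a gradient list in the same order as nn_params.
nn_params_of_grads <- function(net, grads) {
  out <- numeric(0)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      g <- grads[[i]]
      out <- c(out, if (is.null(g)) c(ly$W * 0, ly$b * 0) else c(g$W, g$b))
    } else if (ly$type == "batchnorm") {
      g <- grads[[i]]
      out <- c(out, if (is.null(g)) c(ly$gamma * 0, ly$beta * 0)
               else c(g$gamma, g$beta))
    }
  }
  out
}

# Flatten all parameters of a network into one numeric vector (used for
# change-detection in tests: "parameter hash").
nn_params <- function(net) {
  unlist(lapply(net$layers, function(ly) {
    switch(ly$type,
      linear = c(ly$W, ly$b),
      batchnorm = c(ly$gamma, ly$beta),
      numeric(0)
    )
  }), use.names = FALSE)
}
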