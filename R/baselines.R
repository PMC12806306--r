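#' Linear Cox proportional-hazards model (Newton-Raphson)
#'
#' Maximizes the Breslow partial likelihood over a linear risk score
#' \eqn{h_i = x_i^\top \beta} by Newton-Raphson with step halving. A small
#' ridge penalty stabilizes separation and collinearity. Implemented from
#' first principles so it doubles as an independent check of the deep
#' models' partial-likelihood code: the reported `nll` equals
#' [cox_nll_breslow()] at \eqn{X\hat\beta} (full batch, unnormalized, plus
#' the ridge term's omission — the ridge only steers the iterates).
#'
#' @param covariates numeric matrix without missing cells.
#' @param times observed times.
#' @param events 0/1 event indicators (at least one event).
#' @param tol convergence threshold on the gradient max-norm (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @param ridge L2 penalty weight (default 1e-6).
#' @return Object of class `linear_cph_fit`: `coefficients`, `converged`,
#'   `iterations`, `nll`, a Breslow `baseline` hazard and `feature_names`.
#' @export
fit_linear_cph <- function(covariates, times, events, tol = 1e-8,
                           max_iter = 100, ridge = 1e-6) {
  X <- as.matrix(covariates)
  stopifnot(!anyNA(X), nrow(X) == length(times),
            length(times) == length(events), sum(events) >= 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p)

  penalized_nll <- function(b) {
    cox_nll_breslow(drop(X %*% b), times, events, normalize = FALSE) +
      0.5 * ridge * sum(b^2)
  }
  # gradient and Hessian of the penalized NLL via one descending-time sweep
  score_hessian <- function(b) {
    eta <- drop(X %*% b)
    w <- exp(eta - max(eta))
    ord <- order(times, decreasing = TRUE)
    g <- rep(0, p); H <- matrix(0, p, p)
    S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
    i <- 1
    while (i <= n) {
      j <- i
      while (j < n && times[ord[j + 1]] == times[ord[i]]) j <- j + 1
      grp <- ord[i:j]
      Xg <- X[grp, , drop = FALSE]
      wg <- w[grp]
      S0 <- S0 + sum(wg)
      S1 <- S1 + drop(crossprod(Xg, wg))
      S2 <- S2 + crossprod(Xg * sqrt(wg))
      ev <- grp[events[grp] == 1]
      d <- length(ev)
      if (d > 0) {
        xbar <- S1 / S0
        g <- g - (colSums(X[ev, , drop = FALSE]) - d * xbar)
        H <- H + d * (S2 / S0 - tcrossprod(xbar))
      }
      i <- j + 1
    }
    list(g = g + ridge * b, H_raw = H, H = H + diag(ridge, p))
  }

  converged <- FALSE
  iter <- 0L
  nll <- penalized_nll(beta)
  collinear_warned <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    sh <- score_hessian(beta)
    if (max(abs(sh$g)) < tol) { converged <- TRUE; break }
    if (rcond(sh$H_raw) < 1e-10 && !collinear_warned) {
      warning("near-singular information matrix (collinear covariates); ",
              "fit is ridge-stabilized")
      collinear_warned <- TRUE
    }
    step <- solve(sh$H, sh$g)
    # step halving if the penalized NLL does not decrease
    s <- 1
    repeat {
      cand <- beta - s * step
      cand_nll <- penalized_nll(cand)
      if (cand_nll <= nll + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    if (max(abs(s * step)) < 1e-12) { converged <- max(abs(sh$g)) < 1e-4; break }
    beta <- cand; nll <- cand_nll
  }
  if (!converged)
    warning("Newton-Raphson did not converge in ", max_iter,
            " iterations; returning best iterate")
  eta <- drop(X %*% beta)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    converged = converged, iterations = iter,
    nll = cox_nll_breslow(eta, times, events, normalize = FALSE),
    baseline = breslow_baseline(eta, times, events),
    feature_names = colnames(X)
  ), class = "linear_cph_fit")
}

#' @export
print.linear_cph_fit <- function(x, ...) {
  cat(sprintf("linear_cph_fit: %d coefficients, %s in %d iterations, nll=%.4f\n",
              length(x$coefficients),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$nll))
  invisible(x)
}

.baseline_model_matrix <- function(model, x) {
  x <- if (inherits(x, "trial_table")) x$covariates else as.matrix(x)
  if (!is.null(colnames(x)) && all(model$feature_names %in% colnames(x)))
    x <- x[, model$feature_names, drop = FALSE]
  if (ncol(x) != length(model$feature_names))
    stop("covariate dimension mismatch")
  x
}

#' @export
predict_risk.linear_cph_fit <- function(model, x) {
  drop(.baseline_model_matrix(model, x) %*% model$coefficients)
}

#' @export
predict_curves.linear_cph_fit <- function(model, x, t_grid) {
  predict_survival(model$baseline, predict_risk(model, x), t_grid)
}

#' Plain deep Cox network (DeepSurv baseline)
#'
#' The survival network alone, trained on the raw preprocessed covariates
#' with the Breslow negative partial log-likelihood — no autoencoder, no
#' input corruption. Two hidden layers (default 32, 16), each
#' linear -> rectifier -> batch norm -> dropout, then a single linear
#' output unit. Training loop, early stopping and baseline-hazard fitting
#' are identical to [fit_daedsr()]'s alpha = 1 path.
#'
#' @param train preprocessed training [trial_table()].
#' @param val optional validation table; carved 8:2 from `train` if NULL.
#' @param hidden hidden-layer widths (default c(32, 16)).
#' @param dropout dropout probability (default 0.1).
#' @param batchnorm use batch normalization (default TRUE).
#' @param config a [train_config()].
#' @return Object of class `deepsurv_fit`.
#' @export
fit_deepsurv <- function(train, val = NULL, hidden = c(32, 16),
                         dropout = 0.1, batchnorm = TRUE,
                         config = train_config()) {
  stopifnot(inherits(train, "trial_table"), sum(train$event) >= 1)
  if (anyNA(train$covariates)) stop("training table has missing cells; impute first")
  p <- ncol(train$covariates)
  set.seed(config$seed)
  if (is.null(val)) {
    n <- n_trials(train)
    perm <- sample.int(n)
    n_tr <- floor(0.8 * n)
    val <- table_subset(train, perm[(n_tr + 1):n])
    train <- table_subset(train, perm[seq_len(n_tr)])
  }
  stopifnot(sum(val$event) >= 1)
  identity_net <- structure(list(layers = list(), n_in = p, n_out = p),
                            class = "nn_net")
  net <- nn_mlp(p, hidden, 1, batchnorm = batchnorm, dropout = dropout)
  st <- .train_joint(identity_net, identity_net, net, train, val,
                     alpha = 1, gamma = 0, noise_sd = 0, config = config,
                     freeze_encoder = TRUE)
  scores <- drop(nn_forward(st$head, train$covariates, training = FALSE)$out)
  structure(list(
    head = st$head, hidden = hidden, dropout = dropout,
    batchnorm = batchnorm, config = config,
    baseline = breslow_baseline(scores, train$time, train$event),
    history = st$history, best_epoch = st$best_epoch,
    feature_names = train$column_names
  ), class = "deepsurv_fit")
}

#' @export
print.deepsurv_fit <- function(x, ...) {
  cat(sprintf("deepsurv_fit: p=%d, hidden (%s), best epoch %d/%d\n",
              length(x$feature_names), paste(x$hidden, collapse = ", "),
              x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
predict_risk.deepsurv_fit <- function(model, x) {
  x <- if (inherits(x, "trial_table")) x$covariates else as.matrix(x)
  if (!is.null(colnames(x)) && all(model$feature_names %in% colnames(x)))
    x <- x[, model$feature_names, drop = FALSE]
  drop(nn_forward(model$head, x, training = FALSE)$out)
}

#' @export
predict_curves.deepsurv_fit <- function(model, x, t_grid) {
  predict_survival(model$baseline, predict_risk(model, x), t_grid)
}
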