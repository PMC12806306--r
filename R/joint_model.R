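#' Loss weights for the joint objective
#'
#' The joint loss is \eqn{l = \alpha\, l_{surv} + \gamma\, l_{recon}} with
#' \eqn{\gamma = 1 - \alpha}. Defaults: alpha = 0.6, gamma = 0.4. `beta` is
#' accepted as an alias of `gamma`.
#'
#' @param alpha survival-term weight in [0, 1].
#' @param gamma reconstruction-term weight; defaults to 1 - alpha.
#' @param beta alias of `gamma`.
#' @return List with `alpha` and `gamma` (summing to 1).
#' @export
loss_weights <- function(alpha = 0.6, gamma = NULL, beta = NULL) {
  if (is.null(gamma)) gamma <- if (!is.null(beta)) beta else 1 - alpha
  stopifnot(alpha >= 0, gamma >= 0, abs(alpha + gamma - 1) < 1e-12)
  list(alpha = alpha, gamma = gamma)
}

#' Combine reconstruction and survival losses
#'
#' @param l_recon reconstruction loss (finite scalar).
#' @param l_surv survival loss (finite scalar).
#' @param w a [loss_weights()] list.
#' @return \eqn{\alpha\, l_{surv} + \gamma\, l_{recon}}.
#' @export
joint_loss <- function(l_recon, l_surv, w = loss_weights()) {
  stopifnot(is.finite(l_recon), is.finite(l_surv))
  w$alpha * l_surv + w$gamma * l_recon
}

#' Training configuration
#'
#' @param batch_size minibatch size (default 256). Risk sets for the Cox
#'   term are formed within each batch.
#' @param learning_rate Adam learning rate (default 0.01).
#' @param max_epochs maximum training epochs (default 200).
#' @param patience early-stopping patience on the validation joint loss
#'   (default 20 epochs).
#' @param seed seed covering weight initialization, the validation carve,
#'   batch shuffling, dropout masks and corruption draws.
#' @param normalize_events divide the Cox loss by the number of events in
#'   the batch so the loss weight alpha has a consistent meaning across
#'   batch sizes (default TRUE).
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 256, learning_rate = 0.01,
                         max_epochs = 200, patience = 20, seed = 1L,
                         normalize_events = TRUE) {
  stopifnot(batch_size >= 2, learning_rate > 0, max_epochs >= 1, patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 normalize_events = isTRUE(normalize_events)),
            class = "train_config")
}

# split row indices into minibatches; a trailing batch of size 1 is folded
# into the previous batch (batch norm needs >= 2 rows).
.make_batches <- function(idx, batch_size) {
  n <- length(idx)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  k <- length(batches)
  if (k > 1 && length(batches[[k]]) < 2) {
    batches[[k - 1]] <- c(batches[[k - 1]], batches[[k]])
    batches[[k]] <- NULL
  }
  batches
}

# evaluation-mode losses on clean inputs (deterministic); returns the joint
# loss and the monitor loss used for model selection: the survival loss when
# the survival term is active (the task loss -- the reconstruction term keeps
# improving long after the risk ranking starts to overfit, so monitoring the
# joint loss would systematically stop too late), the reconstruction loss
# otherwise
.eval_losses <- function(enc, dec, head, X, time, event, alpha, gamma,
                         normalize_events) {
  y <- nn_forward(enc, X, training = FALSE)$out
  l_recon <- if (gamma > 0) {
    xp <- nn_forward(dec, y, training = FALSE)$out
    reconstruction_loss(X, xp)
  } else 0
  l_surv <- if (alpha > 0 && sum(event) >= 1) {
    s <- drop(nn_forward(head, y, training = FALSE)$out)
    cox_nll_breslow(s, time, event, normalize = normalize_events)
  } else 0
  list(joint = alpha * l_surv + gamma * l_recon,
       monitor = if (alpha > 0) l_surv else l_recon)
}

#' Fit the joint denoising-autoencoder deep-survival model
#'
#' Trains encoder, decoder and survival head jointly: per minibatch the
#' covariates are corrupted with Gaussian noise, encoded, (a) decoded and
#' scored against the clean input by mean squared reconstruction error and
#' (b) passed through the survival head into the Breslow negative partial
#' log-likelihood, the two losses combined as
#' \eqn{\alpha\, l_{surv} + (1-\alpha)\, l_{recon}} and followed by one Adam
#' step. Early stopping monitors the evaluation-mode joint loss on a
#' validation split (carved 8:2 from the training rows when not supplied);
#' the best-epoch parameters are restored. After training, latent features
#' are recomputed on clean inputs and the Breslow baseline hazard is fitted
#' on the training set, enabling survival-curve prediction.
#'
#' With `two_stage = TRUE` the autoencoder is trained first on the
#' reconstruction loss alone, then frozen while the survival head is
#' trained on the latent features — the sequential variant of the same
#' architecture.
#'
#' @param train a preprocessed [trial_table()] (no missing cells,
#'   normalized numerics); at least one event.
#' @param val optional validation [trial_table()]; if NULL, 20% of the
#'   training rows are carved off for early stopping.
#' @param alpha survival-loss weight (default 0.6; gamma = 1 - alpha).
#' @param ae_spec an [autoencoder_spec()]; defaults to widths (32, 16) with
#'   noise sd 0.1 for the table's covariate dimension.
#' @param head_spec a [survival_head_spec()]; defaults to a 16-unit hidden
#'   layer on the bottleneck with batch norm and dropout 0.1.
#' @param config a [train_config()].
#' @param two_stage train autoencoder first, then the head (default FALSE:
#'   joint training).
#' @return An object of class `daedsr_fit`.
#' @export
fit_daedsr <- function(train, val = NULL, alpha = 0.6, ae_spec = NULL,
                       head_spec = NULL, config = train_config(),
                       two_stage = FALSE) {
  stopifnot(inherits(train, "trial_table"), sum(train$event) >= 1)
  if (anyNA(train$covariates)) stop("training table has missing cells; impute first")
  p <- ncol(train$covariates)
  if (is.null(ae_spec)) ae_spec <- autoencoder_spec(p)
  if (is.null(head_spec)) head_spec <- survival_head_spec(ae_spec$latent_dim)
  stopifnot(ae_spec$input_dim == p, head_spec$input_dim == ae_spec$latent_dim)
  w <- loss_weights(alpha)

  set.seed(config$seed)
  if (is.null(val)) {
    n <- n_trials(train)
    perm <- sample.int(n)
    n_tr <- floor(0.8 * n)
    val <- table_subset(train, perm[(n_tr + 1):n])
    train <- table_subset(train, perm[seq_len(n_tr)])
  }
  stopifnot(sum(val$event) >= 1)
  X <- train$covariates; Xv <- val$covariates

  ae <- init_autoencoder(ae_spec)
  head <- init_survival_head(head_spec)
  if (two_stage) {
    ae <- .train_autoencoder(ae, X, Xv, ae_spec$noise_sd, config)
    st <- .train_joint(ae$encoder, ae$decoder, head, train, val,
                       alpha = 1, gamma = 0, noise_sd = 0,
                       config = config, freeze_encoder = TRUE)
    st$history$stage <- "head"
  } else {
    st <- .train_joint(ae$encoder, ae$decoder, head, train, val,
                       alpha = w$alpha, gamma = w$gamma,
                       noise_sd = ae_spec$noise_sd, config = config)
  }
  enc <- st$encoder; dec <- st$decoder; head <- st$head

  latent <- nn_forward(enc, X, training = FALSE)$out
  scores <- drop(nn_forward(head, latent, training = FALSE)$out)
  baseline <- breslow_baseline(scores, train$time, train$event)

  structure(list(
    encoder = enc, decoder = dec, head = head,
    weights = w, ae_spec = ae_spec, head_spec = head_spec, config = config,
    two_stage = isTRUE(two_stage),
    baseline = baseline, history = st$history, best_epoch = st$best_epoch,
    feature_names = train$column_names
  ), class = "daedsr_fit")
}

# core joint loop; freeze_encoder supports the two-stage variant
.train_joint <- function(enc, dec, head, train, val, alpha, gamma, noise_sd,
                         config, freeze_encoder = FALSE) {
  X <- train$covariates
  st_e <- adam_init(enc); st_d <- adam_init(dec); st_h <- adam_init(head)
  best <- list(loss = Inf, enc = enc, dec = dec, head = head, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    batches <- .make_batches(sample.int(nrow(X)), config$batch_size)
    ep_loss <- 0
    for (b in batches) {
      xb <- X[b, , drop = FALSE]
      xt <- corrupt(xb, noise_sd)$x_tilde
      fe <- nn_forward(enc, xt, training = TRUE)
      enc <- fe$net
      y <- fe$out
      l_recon <- 0
      dY <- matrix(0, nrow(y), ncol(y))
      grads_d <- NULL
      if (gamma > 0) {
        fd <- nn_forward(dec, y, training = TRUE)
        dec <- fd$net
        l_recon <- reconstruction_loss(xb, fd$out)
        bd <- nn_backward(dec, fd$caches, gamma * reconstruction_loss_grad(xb, fd$out))
        grads_d <- bd$grads
        dY <- dY + bd$dX
      }
      l_surv <- 0
      grads_h <- NULL
      if (alpha > 0 && sum(train$event[b]) >= 1) {
        fh <- nn_forward(head, y, training = TRUE)
        head <- fh$net
        s <- drop(fh$out)
        l_surv <- cox_nll_breslow(s, train$time[b], train$event[b],
                                  normalize = config$normalize_events)
        gs <- cox_nll_grad(s, train$time[b], train$event[b],
                           normalize = config$normalize_events)
        bh <- nn_backward(head, fh$caches, matrix(alpha * gs, ncol = 1))
        grads_h <- bh$grads
        dY <- dY + bh$dX
      }
      if (!freeze_encoder) {
        be <- nn_backward(enc, fe$caches, dY)
        up <- adam_step(enc, be$grads, st_e, config$learning_rate)
        enc <- up$net; st_e <- up$state
      }
      if (!is.null(grads_d)) {
        up <- adam_step(dec, grads_d, st_d, config$learning_rate)
        dec <- up$net; st_d <- up$state
      }
      if (!is.null(grads_h)) {
        up <- adam_step(head, grads_h, st_h, config$learning_rate)
        head <- up$net; st_h <- up$state
      }
      bl <- alpha * l_surv + gamma * l_recon
      if (!is.finite(bl))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ep_loss <- ep_loss + bl * length(b)
    }
    vl <- .eval_losses(enc, dec, head, val$covariates, val$time,
                       val$event, alpha, gamma, config$normalize_events)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nrow(X), val_loss = vl$joint,
      val_monitor = vl$monitor))
    if (vl$monitor < best$loss - 1e-9) {
      best <- list(loss = vl$monitor, enc = enc, dec = dec, head = head,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(encoder = best$enc, decoder = best$dec, head = best$head,
       history = history, best_epoch = best$epoch)
}

# stage-1 trainer for the two-stage variant: reconstruction loss only
.train_autoencoder <- function(ae, X, Xv, noise_sd, config) {
  dummy_train <- trial_table(X, rep(1, nrow(X)), rep(1L, nrow(X)))
  dummy_val <- trial_table(Xv, rep(1, nrow(Xv)), rep(1L, nrow(Xv)))
  head <- init_survival_head(survival_head_spec(
    ncol(nn_forward(ae$encoder, X[1:2, , drop = FALSE])$out)))
  st <- .train_joint(ae$encoder, ae$decoder, head, dummy_train, dummy_val,
                     alpha = 0, gamma = 1, noise_sd = noise_sd,
                     config = config)
  list(encoder = st$encoder, decoder = st$decoder)
}

#' @export
print.daedsr_fit <- function(x, ...) {
  cat(sprintf(
    "daedsr_fit: p=%d -> latent %d, alpha=%.2f gamma=%.2f, best epoch %d/%d (%s)\n",
    x$ae_spec$input_dim, x$ae_spec$latent_dim, x$weights$alpha,
    x$weights$gamma, x$best_epoch, nrow(x$history),
    if (x$two_stage) "two-stage" else "joint"))
  invisible(x)
}

# covariate matrix aligned to a fitted model's feature order
.model_matrix <- function(model, x) {
  x <- if (inherits(x, "trial_table")) x$covariates else as.matrix(x)
  if (!is.null(colnames(x)) && all(model$feature_names %in% colnames(x)))
    x <- x[, model$feature_names, drop = FALSE]
  if (ncol(x) != model$ae_spec$input_dim)
    stop("covariate dimension mismatch: expected ", model$ae_spec$input_dim)
  x
}

#' Latent features from a fitted model
#'
#' Clean (uncorrupted) evaluation-mode pass through the fitted encoder.
#'
#' @param model a `daedsr_fit`.
#' @param x covariate matrix or [trial_table()], preprocessed the same way
#'   as the training data.
#' @return n x latent matrix of bottleneck features.
#' @export
encode_features <- function(model, x) {
  stopifnot(inherits(model, "daedsr_fit"))
  nn_forward(model$encoder, .model_matrix(model, x), training = FALSE)$out
}

#' Predicted log-hazard risk scores
#'
#' @param model a fitted model (`daedsr_fit` or `deepsurv_fit`).
#' @param x covariates (matrix or [trial_table()]).
#' @return Numeric vector of risk scores, one per row.
#' @export
predict_risk <- function(model, x) UseMethod("predict_risk")

#' @export
predict_risk.daedsr_fit <- function(model, x) {
  y <- encode_features(model, x)
  drop(nn_forward(model$head, y, training = FALSE)$out)
}

#' Predicted survival curves
#'
#' Curves \eqn{\hat S(t|x) = \exp\{-\hat H_0(t) e^{h(x)}\}} from the
#' model's stored Breslow baseline hazard.
#'
#' @param model a fitted model with a stored baseline hazard.
#' @param x covariates.
#' @param t_grid non-decreasing time grid.
#' @return A `survival_curves` object.
#' @export
predict_curves <- function(model, x, t_grid) UseMethod("predict_curves")

#' @export
predict_curves.daedsr_fit <- function(model, x, t_grid) {
  if (is.null(model$baseline)) stop("model has no fitted baseline hazard")
  predict_survival(model$baseline, predict_risk(model, x), t_grid)
}
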