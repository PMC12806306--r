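#' Survival-head architecture specification
#'
#' A single-hidden-layer MLP mapping latent features to one scalar risk
#' score h(x): linear -> rectifier -> batch normalization -> dropout ->
#' linear output. Dropout (default 0.1) and batch normalization address
#' overfitting; both are active only in training mode.
#'
#' @param input_dim input width (the autoencoder bottleneck, 16 by default).
#' @param hidden_width hidden-layer width (default 16).
#' @param dropout dropout probability in [0, 1) (default 0.1).
#' @param batchnorm use batch normalization (default TRUE).
#' @return An object of class `survival_head_spec`.
#' @export
survival_head_spec <- function(input_dim = 16, hidden_width = 16,
                               dropout = 0.1, batchnorm = TRUE) {
  stopifnot(input_dim >= 1, hidden_width >= 1, dropout >= 0, dropout < 1)
  structure(list(
    input_dim = as.integer(input_dim),
    hidden_width = as.integer(hidden_width),
    dropout = dropout, batchnorm = isTRUE(batchnorm)
  ), class = "survival_head_spec")
}

init_survival_head <- function(spec) {
  nn_mlp(spec$input_dim, hidden = spec$hidden_width, n_out = 1,
         batchnorm = spec$batchnorm, dropout = spec$dropout)
}

#' Risk scores from a survival head
#'
#' Deterministic evaluation-mode forward pass (dropout disabled, running
#' batch-norm statistics): one scalar log-hazard score per row.
#'
#' @param head a survival-head network.
#' @param y latent feature matrix (rows = subjects).
#' @param training if TRUE, run in training mode (batch statistics, active
#'   dropout); a training batch of size 1 under batch norm is rejected.
#' @return Numeric vector of scores.
#' @export
risk_score <- function(head, y, training = FALSE) {
  drop(nn_forward(head, as.matrix(y), training = training)$out)
}

# sort-order helper shared by the Cox loss and the Breslow estimator:
# returns, per subject, the log-sum-exp risk-set denominators via
# reverse-cumulative sums over descending time, with Breslow tie handling
# (tied event times share the full risk set).
.cox_risk_sets <- function(scores, times) {
  n <- length(scores)
  m <- max(scores)
  es <- exp(scores - m)
  ord <- order(times, decreasing = TRUE)
  cum <- cumsum(es[ord])          # sum over {j : T_j >= T_(k)} going down
  # ties: every subject at a tied time gets the full tied-group sum
  t_sorted <- times[ord]
  runs <- rle(t_sorted)$lengths
  last_same <- rep(cumsum(runs), runs)
  S0 <- cum[last_same]            # risk-set sums (shifted scale)
  out <- numeric(n)
  out[ord] <- S0
  list(S0_shifted = out, shift = m)
}

#' Breslow negative partial log-likelihood
#'
#' The Cox partial likelihood under the Breslow tie convention:
#' \deqn{-\sum_{i: E_i = 1}\Big[h_i - \log \sum_{j \in R(T_i)} e^{h_j}\Big]}
#' where the risk set \eqn{R(t) = \{j : T_j \ge t\}} and tied event times
#' share the full risk set. Computed with a shifted (numerically stable)
#' log-sum-exp. With `normalize = TRUE` (default) the sum is divided by the
#' number of events so the loss scale is batch-size invariant.
#'
#' @param scores predicted log-hazard scores.
#' @param times observed times.
#' @param events 0/1 event indicators; at least one event is required.
#' @param normalize divide by the number of events (default TRUE).
#' @return Scalar loss.
#' @export
cox_nll_breslow <- function(scores, times, events, normalize = TRUE) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(times), length(times) == length(events),
            all(events %in% c(0, 1)))
  d <- sum(events)
  if (d < 1)
    stop("batch contains no events; use larger or event-stratified batches")
  rs <- .cox_risk_sets(scores, times)
  ev <- events == 1
  ll <- sum(scores[ev] - (log(rs$S0_shifted[ev]) + rs$shift))
  nll <- -ll
  if (normalize) nll / d else nll
}

#' @rdname cox_nll_breslow
#' @return `cox_nll_grad()`: gradient of the loss with respect to `scores`.
#' @export
cox_nll_grad <- function(scores, times, events, normalize = TRUE) {
  scores <- as.numeric(scores)
  n <- length(scores)
  d <- sum(events)
  if (d < 1) stop("batch contains no events")
  m <- max(scores)
  es <- exp(scores - m)
  ord <- order(times, decreasing = TRUE)
  t_sorted <- times[ord]
  cum <- cumsum(es[ord])
  runs <- rle(t_sorted)$lengths
  ends <- cumsum(runs)
  last_same <- rep(ends, runs)
  first_same <- rep(ends - runs + 1L, runs)
  S0 <- cum[last_same]                       # risk-set sum at T_(k), shifted
  ev_sorted <- (events[ord] == 1)
  # dL/dh_k = e^{h_k} * sum over event times T_i <= T_k of d_i-weighted
  # 1/S0(T_i), minus the event indicator. In descending-time order the
  # event times <= T_k sit at positions from the start of k's tie group on.
  inv_terms <- ifelse(ev_sorted, 1 / S0, 0)
  revcum <- rev(cumsum(rev(inv_terms)))
  A <- revcum[first_same]
  g_sorted <- es[ord] * A - ev_sorted
  g <- numeric(n)
  g[ord] <- g_sorted
  if (normalize) g / d else g
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' \deqn{\hat H_0(t) = \sum_{T_i \le t, E_i = 1} \frac{d_i}{\sum_{j \in
#' R(T_i)} e^{h_j}}} evaluated at the distinct observed event times. At all
#'-zero scores this reduces to the Nelson-Aalen estimator.
#'
#' @param scores fitted log-hazard scores on the training set.
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return An object of class `baseline_hazard` with fields `time` (distinct
#'   event times) and `cumhaz` (non-decreasing step values); evaluate it
#'   with [baseline_cumhaz()].
#' @export
breslow_baseline <- function(scores, times, events) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(times), length(times) == length(events))
  ev_times <- sort(unique(times[events == 1]))
  es <- exp(scores)
  increments <- vapply(ev_times, function(t) {
    d_t <- sum(times == t & events == 1)
    d_t / sum(es[times >= t])
  }, numeric(1))
  structure(list(time = ev_times, cumhaz = cumsum(increments)),
            class = "baseline_hazard")
}

#' Evaluate a cumulative baseline hazard
#'
#' Right-continuous step evaluation: H0(t) = 0 before the first event time.
#'
#' @param baseline a `baseline_hazard` from [breslow_baseline()].
#' @param t times at which to evaluate.
#' @return Numeric vector H0(t).
#' @export
baseline_cumhaz <- function(baseline, t) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  if (length(baseline$time) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, baseline$time)
  c(0, baseline$cumhaz)[idx + 1]
}

#' Predicted survival curves under proportional hazards
#'
#' \deqn{\hat S(t \mid x_i) = \exp\{-\hat H_0(t)\, e^{h_i}\}} evaluated on a
#' common time grid, one curve per subject.
#'
#' @param baseline a `baseline_hazard`.
#' @param scores log-hazard scores, one per subject.
#' @param t_grid non-decreasing evaluation times.
#' @return An object of class `survival_curves`: list with `time` (the grid)
#'   and `surv` (n x length(t_grid) matrix of survival probabilities).
#' @export
predict_survival <- function(baseline, scores, t_grid) {
  stopifnot(!is.unsorted(t_grid))
  H0 <- baseline_cumhaz(baseline, t_grid)
  S <- exp(-outer(exp(as.numeric(scores)), H0))
  structure(list(time = as.numeric(t_grid), surv = S),
            class = "survival_curves")
}

#' @export
print.survival_curves <- function(x, ...) {
  cat(sprintf("survival_curves: %d subjects on a %d-point grid [%g, %g]\n",
              nrow(x$surv), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}
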