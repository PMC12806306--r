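#' Harrell concordance index for right-censored data
#'
#' A pair (i, j) is comparable iff \eqn{T_i < T_j} and subject i had the
#' event; it is concordant when the earlier-event subject carries the
#' higher risk score. Tied risk scores receive half credit; tied times are
#' not comparable. C = 1 is perfect ranking, 0.5 is random.
#'
#' @param risks risk scores (higher = earlier event expected).
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return Object of class `concordance_result`: `c_index`, `concordant`,
#'   `discordant`, `tied_risk`, `comparable`.
#' @export
concordance_index <- function(risks, times, events) {
  risks <- as.numeric(risks)
  stopifnot(length(risks) == length(times), length(times) == length(events),
            all(events %in% c(0, 1)))
  concordant <- 0; discordant <- 0; tied <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    if (!any(later)) next
    d <- risks[i] - risks[later]
    concordant <- concordant + sum(d > 0)
    discordant <- discordant + sum(d < 0)
    tied <- tied + sum(d == 0)
  }
  comparable <- concordant + discordant + tied
  if (comparable == 0)
    stop("no comparable pairs (all censored or all tied times)")
  structure(list(
    c_index = (concordant + 0.5 * tied) / comparable,
    concordant = concordant, discordant = discordant,
    tied_risk = tied, comparable = comparable
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (%d concordant, %d discordant, %d risk ties of %d comparable pairs)\n",
              x$c_index, x$concordant, x$discordant, x$tied_risk, x$comparable))
  invisible(x)
}

#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimator treating censorings (1 - E) as the events:
#' subjects whose trial completed leave the risk set without producing a
#' drop. Used as the inverse-probability-of-censoring weight \eqn{\hat G}.
#'
#' @param times observed times.
#' @param events 0/1 event indicators of the original outcome.
#' @return Object of class `censoring_estimate` with step times and values;
#'   evaluate with [censoring_survival()].
#' @export
km_censoring <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  cens <- 1 - events
  tt <- sort(unique(times[cens == 1]))
  surv <- numeric(length(tt))
  g <- 1
  for (k in seq_along(tt)) {
    at_risk <- sum(times >= tt[k])
    d <- sum(times == tt[k] & cens == 1)
    g <- g * (1 - d / at_risk)
    surv[k] <- g
  }
  structure(list(time = tt, surv = surv), class = "censoring_estimate")
}

#' Evaluate a censoring survival estimate
#'
#' Right-continuous by default: \eqn{\hat G(t)} includes the drop at t.
#' `left = TRUE` gives the left limit \eqn{\hat G(t^-)}, the convention of
#' some references.
#'
#' @param G a `censoring_estimate` from [km_censoring()].
#' @param t evaluation times.
#' @param left evaluate the left limit instead (default FALSE).
#' @return Numeric vector of survival probabilities.
#' @export
censoring_survival <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "censoring_estimate"))
  if (length(G$time) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, G$time, left.open = left)
  c(1, G$surv)[idx + 1]
}

#' Inverse-probability-of-censoring-weighted Brier score at time t
#'
#' \deqn{BS(t) = \frac{1}{N}\sum_i \Big[\frac{\hat S(t|x_i)^2\,
#' 1\{T_i \le t, E_i = 1\}}{\hat G(T_i)} + \frac{(1-\hat S(t|x_i))^2\,
#' 1\{T_i > t\}}{\hat G(t)}\Big]}
#' With no censoring and \eqn{\hat G \equiv 1} this is the plain mean
#' squared error between the survival indicator and \eqn{\hat S}.
#'
#' @param curves a `survival_curves` object covering `t` in its grid (or a
#'   vector of survival probabilities at `t`, one per subject).
#' @param times observed times of the evaluated subjects.
#' @param events 0/1 event indicators.
#' @param t evaluation time.
#' @param G a `censoring_estimate`; defaults to [km_censoring()] on the
#'   evaluated subjects.
#' @param left_limit evaluate weights at the left limit \eqn{\hat G(T_i^-)}
#'   rather than at \eqn{\hat G(T_i)} (default FALSE).
#' @return Scalar Brier score.
#' @export
brier_score <- function(curves, times, events, t, G = NULL,
                        left_limit = FALSE) {
  n <- length(times)
  stopifnot(length(events) == n)
  s_t <- if (inherits(curves, "survival_curves")) {
    j <- match(TRUE, abs(curves$time - t) < 1e-12)
    if (is.na(j)) {
      j <- findInterval(t, curves$time)
      if (j == 0) stop("evaluation time precedes the curve grid")
    }
    curves$surv[, j]
  } else as.numeric(curves)
  stopifnot(length(s_t) == n)
  if (is.null(G)) G <- km_censoring(times, events)
  died <- times <= t & events == 1
  alive <- times > t
  w_i <- censoring_survival(G, times, left = left_limit)
  g_t <- censoring_survival(G, t, left = left_limit)
  if (any(died & w_i == 0))
    stop("censoring survival is zero at an event time needed for t = ", t)
  if (any(alive) && g_t == 0)
    stop("censoring survival is zero at t = ", t, "; truncate the grid")
  terms <- numeric(n)
  terms[died] <- s_t[died]^2 / w_i[died]
  terms[alive] <- (1 - s_t[alive])^2 / g_t
  sum(terms) / n
}

#' Brier score over a time grid, with integrated summary
#'
#' Maps [brier_score()] over a grid (default: 100 equally spaced points
#' from 0 to the 90th percentile of the observed times, avoiding the
#' \eqn{\hat G \to 0} tail) and reports a trapezoid-integrated Brier score
#' normalized by the grid span.
#'
#' @param curves a `survival_curves` object whose grid contains the
#'   evaluation grid.
#' @param times,events test labels.
#' @param grid evaluation times; NULL for the default grid.
#' @param G optional `censoring_estimate` (default: fitted on these labels).
#' @param left_limit see [brier_score()].
#' @return Object of class `brier_curve`: `time`, `bs`, `integrated`.
#' @export
brier_curve <- function(curves, times, events, grid = NULL, G = NULL,
                        left_limit = FALSE) {
  if (is.null(G)) G <- km_censoring(times, events)
  if (is.null(grid))
    grid <- seq(0, stats::quantile(times, 0.9, names = FALSE), length.out = 100)
  ok <- censoring_survival(G, grid, left = left_limit) > 0
  grid <- grid[ok]
  if (length(grid) == 0) stop("no grid points with positive censoring survival")
  if (inherits(curves, "survival_curves")) {
    S <- t(vapply(grid, function(t) {
      j <- findInterval(t, curves$time)
      if (j == 0) rep(1, nrow(curves$surv)) else curves$surv[, j]
    }, numeric(nrow(curves$surv))))  # grid x n
  } else stop("curves must be a survival_curves object")
  bs <- vapply(seq_along(grid), function(k)
    brier_score(S[k, ], times, events, grid[k], G = G,
                left_limit = left_limit), numeric(1))
  integrated <- if (length(grid) > 1) {
    span <- diff(range(grid))
    sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / span
  } else bs
  structure(list(time = grid, bs = bs, integrated = integrated),
            class = "brier_curve")
}

#' @export
print.brier_curve <- function(x, ...) {
  cat(sprintf("brier_curve: %d points on [%g, %g], integrated BS %.4f\n",
              length(x$time), min(x$time), max(x$time), x$integrated))
  invisible(x)
}

#' Export a set of survival curves as a long-format data frame
#'
#' Two-column-per-subject layout for plotting parity: columns `subject`,
#' `time`, `survival`.
#'
#' @param curves a `survival_curves` object.
#' @param ids optional subject identifiers.
#' @return data.frame with one row per (subject, time) pair.
#' @export
curves_to_df <- function(curves, ids = NULL) {
  stopifnot(inherits(curves, "survival_curves"))
  n <- nrow(curves$surv)
  if (is.null(ids)) ids <- seq_len(n)
  data.frame(
    subject = rep(ids, each = length(curves$time)),
    time = rep(curves$time, n),
    survival = as.vector(t(curves$surv))
  )
}
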