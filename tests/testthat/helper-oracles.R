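# Independent oracles: deliberately naive O(n^2) implementations and
# finite-difference gradients, kept free of the package's sorting and
# cumulative-sum tricks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-pairs concordance: pair (i, j) comparable iff T_i < T_j and E_i = 1;
# concordant iff risk_i > risk_j; risk ties get half credit
brute_cindex <- function(risks, times, events) {
  conc <- 0; tie <- 0; comp <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || events[i] != 1 || !(times[i] < times[j])) next
    comp <- comp + 1
    if (risks[i] > risks[j]) conc <- conc + 1
    else if (risks[i] == risks[j]) tie <- tie + 1
  }
  if (comp == 0) return(NULL)
  list(c = (conc + 0.5 * tie) / comp, comparable = comp)
}

# direct Breslow partial likelihood: explicit risk-set sums per event
brute_cox_nll <- function(scores, times, events, normalize = TRUE) {
  ll <- 0
  for (i in seq_along(scores)) {
    if (events[i] != 1) next
    ll <- ll + scores[i] - log(sum(exp(scores[times >= times[i]])))
  }
  nll <- -ll
  if (normalize) nll / sum(events) else nll
}

# central finite differences of a scalar function
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# random survival instance with optional time ties and censoring,
# drawn from the current RNG stream
rand_surv_instance <- function(n, tie = TRUE) {
  times <- if (tie) sample(1:ceiling(n / 2), n, replace = TRUE)
           else stats::rexp(n) + 0.01
  events <- stats::rbinom(n, 1, 0.7)
  if (sum(events) == 0) events[sample(n, 1)] <- 1L
  list(scores = stats::rnorm(n), times = times, events = events)
}

# small fully-observed trial table drawn from the current RNG stream
rand_table <- function(n = 60, p_bin = 4, p_num = 2) {
  X <- cbind(matrix(stats::rbinom(n * p_bin, 1, 0.4), n, p_bin),
             matrix(stats::rnorm(n * p_num), n, p_num))
  colnames(X) <- c(paste0("b", seq_len(p_bin)), paste0("z", seq_len(p_num)))
  trial_table(X, stats::rexp(n) + 0.01, stats::rbinom(n, 1, 0.7),
              numeric_columns = paste0("z", seq_len(p_num)))
}
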