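#' Configuration for the synthetic sparse-registry generator
#'
#' Defines a proportional-hazards data-generating process that emulates the
#' shape of a registry extract of clinical trials: a wide, mostly one-hot
#' covariate matrix (heavy sparsity), a few standardized numeric covariates,
#' right censoring by an administrative horizon, and missing cells injected
#' completely at random. The true log-hazard is linear,
#' \eqn{\eta_i = x_i^\top \beta + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \sigma_\eta^2)}, and the event time follows a
#' Weibull (default exponential) baseline hazard so every downstream model
#' has a known ground truth and a computable Bayes concordance ceiling.
#'
#' @param n_trials number of rows (trials). Default 819, the scale of the
#'   registry extract the generator emulates.
#' @param n_binary number of one-hot binary covariates (default 28).
#' @param n_numeric number of numeric covariates, generated standard normal
#'   (default 5).
#' @param sparsity probability that a binary cell equals 0 (default 0.85).
#' @param true_coefficients log-hazard effects, one per covariate (binary
#'   columns first, then numeric). Default: a handful of strong design
#'   effects among the binary columns and modest effects on the first
#'   numeric columns, the rest zero — emulating a registry where a few
#'   design features (allocation scheme, development index, sample size)
#'   dominate.
#' @param baseline_rate exponential baseline hazard per day (default 1e-3,
#'   i.e. a median event time of ~693 days at zero risk).
#' @param weibull_shape Weibull shape of the baseline hazard; 1 (default)
#'   gives the exponential special case.
#' @param censor_max upper bound of the Uniform(0, censor_max)
#'   administrative censoring time, in days (default 3000).
#' @param missing_rate fraction of covariate cells blanked completely at
#'   random (default 0.05). Never applied to time/event.
#' @param noise_sd standard deviation of the latent noise on the linear
#'   predictor; larger values lower the Bayes concordance ceiling
#'   (default 0.5).
#' @param round_days if TRUE, observed times are rounded up to whole days,
#'   creating ties for tie stress-testing (default FALSE: continuous times,
#'   no ties almost surely).
#' @param seed integer seed making generation deterministic.
#'
#' @return An object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_trials = 100, seed = 7)
#' tab <- generate_registry(cfg)
#' dim(tab$covariates)
generator_config <- function(n_trials = 819, n_binary = 28, n_numeric = 5,
                             sparsity = 0.85, true_coefficients = NULL,
                             baseline_rate = 1e-3, weibull_shape = 1,
                             censor_max = 3000, missing_rate = 0.05,
                             noise_sd = 0.5, round_days = FALSE, seed = 1L) {
  p <- n_binary + n_numeric
  if (is.null(true_coefficients)) {
    beta_bin <- rep(0, n_binary)
    strong <- c(0.8, -0.8, 0.6, -0.6, 0.4)
    k <- min(n_binary, length(strong))
    if (k > 0) beta_bin[seq_len(k)] <- strong[seq_len(k)]
    beta_num <- rep(0, n_numeric)
    mod <- c(0.5, -0.5, 0.3)
    k <- min(n_numeric, length(mod))
    if (k > 0) beta_num[seq_len(k)] <- mod[seq_len(k)]
    true_coefficients <- c(beta_bin, beta_num)
  }
  stopifnot(
    n_trials >= 1, n_binary >= 0, n_numeric >= 0, p >= 1,
    sparsity >= 0, sparsity <= 1,
    missing_rate >= 0, missing_rate < 1,
    censor_max > 0, baseline_rate > 0, weibull_shape > 0, noise_sd >= 0
  )
  if (length(true_coefficients) != p)
    stop("true_coefficients must have length n_binary + n_numeric = ", p)
  if (any(!is.finite(true_coefficients)))
    stop("true_coefficients must be finite")
  structure(list(
    n_trials = as.integer(n_trials), n_binary = as.integer(n_binary),
    n_numeric = as.integer(n_numeric), sparsity = sparsity,
    true_coefficients = as.numeric(true_coefficients),
    baseline_rate = baseline_rate, weibull_shape = weibull_shape,
    censor_max = censor_max, missing_rate = missing_rate,
    noise_sd = noise_sd, round_days = isTRUE(round_days),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Construct a trial table
#'
#' The universal container passed between pipeline stages: an n x p covariate
#' matrix (binary columns in \{0,1\}, numeric columns real-valued, missing
#' cells as NA), a positive observed time per row (days) and an event
#' indicator (1 = completed, 0 = censored).
#'
#' @param covariates numeric matrix with column names.
#' @param time positive observed times (days).
#' @param event 0/1 event indicators.
#' @param numeric_columns names of the real-valued covariate columns.
#' @param covariates_complete optional pre-missingness covariate matrix
#'   retained by the generator so oracles stay computable.
#' @return An object of class `trial_table`.
#' @export
trial_table <- function(covariates, time, event, numeric_columns = character(),
                        covariates_complete = NULL) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  time <- as.numeric(time)
  event <- as.integer(event)
  stopifnot(
    nrow(covariates) == length(time), length(time) == length(event),
    all(is.finite(time)), all(time > 0), all(event %in% c(0L, 1L))
  )
  if (nrow(covariates) > 0 && any(rowSums(!is.na(covariates)) == 0))
    stop("trial_table: a row has no observed covariates")
  stopifnot(all(numeric_columns %in% colnames(covariates)))
  structure(list(
    covariates = covariates, time = time, event = event,
    column_names = colnames(covariates),
    numeric_columns = numeric_columns,
    covariates_complete = covariates_complete
  ), class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf(
    "trial_table: %d trials, %d covariates (%d numeric), %.1f%% events, %.1f%% missing cells\n",
    nrow(x$covariates), ncol(x$covariates), length(x$numeric_columns),
    100 * mean(x$event), 100 * mean(is.na(x$covariates))
  ))
  invisible(x)
}

n_trials <- function(table) nrow(table$covariates)

# subset rows of a trial_table, keeping the oracle matrix aligned
table_subset <- function(table, idx) {
  trial_table(
    table$covariates[idx, , drop = FALSE], table$time[idx], table$event[idx],
    numeric_columns = table$numeric_columns,
    covariates_complete = if (!is.null(table$covariates_complete))
      table$covariates_complete[idx, , drop = FALSE]
  )
}

#' Generate a synthetic sparse clinical-trial registry
#'
#' Draws binary covariates as independent Bernoulli(1 - sparsity), numeric
#' covariates as standard normal, a latent event time from the configured
#' Weibull/exponential proportional-hazards model, and an independent
#' Uniform(0, censor_max) administrative censoring time. The observed time
#' is the minimum of the two; the event indicator marks which came first.
#' Missing cells are then injected completely at random; the pre-missingness
#' matrix is retained in `covariates_complete` so that [true_risk()] remains
#' computable.
#'
#' @param cfg a [generator_config()].
#' @return A [trial_table()]. A warning is raised (and the table still
#'   returned) if censoring removed every event.
#' @export
generate_registry <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_trials
  p <- cfg$n_binary + cfg$n_numeric
  Xb <- matrix(stats::rbinom(n * cfg$n_binary, 1, 1 - cfg$sparsity),
               n, cfg$n_binary)
  Xn <- matrix(stats::rnorm(n * cfg$n_numeric), n, cfg$n_numeric)
  X <- cbind(Xb, Xn)
  bin_names <- if (cfg$n_binary > 0) paste0("bin_", seq_len(cfg$n_binary)) else character()
  num_names <- if (cfg$n_numeric > 0) paste0("num_", seq_len(cfg$n_numeric)) else character()
  colnames(X) <- c(bin_names, num_names)

  lp <- drop(X %*% cfg$true_coefficients)
  eps <- stats::rnorm(n, 0, cfg$noise_sd)
  rate <- cfg$baseline_rate * exp(lp + eps)
  # Weibull PH: H0(t) = rate * t^shape  =>  T = (E / rate)^(1/shape), E ~ Exp(1)
  t_event <- (stats::rexp(n, 1) / rate)^(1 / cfg$weibull_shape)
  t_cens <- stats::runif(n, 0, cfg$censor_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  if (cfg$round_days) time <- pmax(ceiling(time), 1)

  X_obs <- X
  if (cfg$missing_rate > 0) {
    blank <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    # keep at least one observed covariate per row
    all_gone <- rowSums(!blank) == 0
    if (any(all_gone)) blank[all_gone, 1] <- FALSE
    X_obs[blank] <- NA_real_
  }
  if (sum(event) == 0)
    warning("generated registry contains no observed events (all censored)")
  trial_table(X_obs, time, event,
              numeric_columns = num_names, covariates_complete = X)
}

#' True log-hazard of generated subjects
#'
#' Returns the generator's noiseless linear predictor \eqn{x_i^\top \beta}
#' computed on the pre-missingness covariate matrix. Ranking subjects by
#' this score gives the Bayes-optimal concordance for the simulation, an
#' upper reference ceiling for any fitted model.
#'
#' @param cfg the [generator_config()] that produced `table`.
#' @param table a [trial_table()] from [generate_registry()] (must retain
#'   its pre-missingness matrix).
#' @return Numeric vector of true log-hazard scores, one per row.
#' @export
true_risk <- function(cfg, table) {
  stopifnot(inherits(cfg, "generator_config"), inherits(table, "trial_table"))
  X <- table$covariates_complete
  if (is.null(X))
    stop("table does not retain its pre-missingness covariate matrix")
  if (ncol(X) != length(cfg$true_coefficients))
    stop("dimension mismatch between table and cfg$true_coefficients")
  drop(X %*% cfg$true_coefficients)
}

#' Write / read a trial table as CSV
#'
#' Comma-delimited UTF-8 with a header row; reserved column names `time`
#' and `event`, every other column a covariate. Missing cells are written
#' as empty fields. A JSON sidecar (`<path>.json`) records which covariate
#' columns are numeric so that a round trip preserves the metadata.
#'
#' @param table a [trial_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry_csv <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  df <- data.frame(table$covariates, check.names = FALSE)
  df$time <- table$time
  df$event <- table$event
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(numeric_columns = table$numeric_columns),
    paste0(path, ".json"), auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_registry_csv
#' @param numeric_columns names of numeric covariate columns; if NULL the
#'   JSON sidecar written by [write_registry_csv()] is consulted (falling
#'   back to no numeric columns if absent).
#' @export
read_registry_csv <- function(path, numeric_columns = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  for (col in c("time", "event"))
    if (!col %in% names(df))
      stop("registry CSV is missing required column '", col, "'")
  if (is.null(numeric_columns)) {
    sidecar <- paste0(path, ".json")
    numeric_columns <- if (file.exists(sidecar))
      unlist(jsonlite::read_json(sidecar)$numeric_columns)
    else character()
    if (is.null(numeric_columns)) numeric_columns <- character()
  }
  covar_names <- setdiff(names(df), c("time", "event"))
  X <- as.matrix(df[covar_names])
  storage.mode(X) <- "double"
  trial_table(X, df$time, df$event,
              numeric_columns = intersect(numeric_columns, covar_names))
}
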