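#' Remove exact duplicate rows
#'
#' A row is a duplicate only if every covariate cell and both labels
#' (`time`, `event`) coincide; the first occurrence is kept.
#'
#' @param table a [trial_table()].
#' @return The deduplicated [trial_table()].
#' @export
drop_duplicates <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  key <- apply(cbind(table$covariates, table$time, table$event), 1,
               function(r) paste(r, collapse = "\r"))
  table_subset(table, !duplicated(key))
}

#' Drop covariate columns that are mostly missing
#'
#' A column is removed iff its missing fraction is strictly greater than
#' `threshold` (default 0.8: "more than 80% missing").
#'
#' @param table a [trial_table()].
#' @param threshold missing-fraction cutoff in (0, 1].
#' @return A list with elements `table` (filtered) and `dropped` (names of
#'   removed columns).
#' @export
drop_sparse_columns <- function(table, threshold = 0.8) {
  stopifnot(inherits(table, "trial_table"), threshold > 0, threshold <= 1)
  frac <- colMeans(is.na(table$covariates))
  drop <- frac > threshold
  if (all(drop)) stop("all covariate columns exceed the missingness threshold")
  keep <- which(!drop)
  tab <- trial_table(
    table$covariates[, keep, drop = FALSE], table$time, table$event,
    numeric_columns = intersect(table$numeric_columns,
                                table$column_names[keep]),
    covariates_complete = if (!is.null(table$covariates_complete))
      table$covariates_complete[, keep, drop = FALSE]
  )
  list(table = tab, dropped = table$column_names[drop])
}

#' K-nearest-neighbour imputation of missing covariate cells
#'
#' Each missing cell is replaced by the mean of its column over the `k`
#' nearest donor rows (rows with that column observed). Distance between two
#' rows is the Euclidean distance over their mutually observed covariates,
#' rescaled by the fraction of usable coordinates:
#' \eqn{d = \sqrt{(p / p_{obs}) \sum (x_a - x_b)^2}}. Imputed values in
#' binary (non-numeric) columns are rounded to the nearest of \{0, 1\} to
#' preserve the one-hot contract. Observed cells are never modified, so the
#' transform is idempotent.
#'
#' @param table a [trial_table()].
#' @param k number of donor neighbours (default 5; fewer are used when
#'   fewer donors exist).
#' @return The imputed [trial_table()] with no missing cells.
#' @export
knn_impute <- function(table, k = 5) {
  stopifnot(inherits(table, "trial_table"), k >= 1)
  X <- table$covariates
  if (!anyNA(X)) return(table)
  n <- nrow(X); p <- ncol(X)
  if (k >= n) stop("k must be smaller than the number of rows")
  fully_missing <- colSums(!is.na(X)) == 0
  if (any(fully_missing))
    stop("column(s) entirely missing: ",
         paste(table$column_names[fully_missing], collapse = ", "),
         "; apply drop_sparse_columns first")
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0
  Xout <- X
  binary_cols <- setdiff(colnames(X), table$numeric_columns)
  rows_missing <- which(rowSums(!obs) > 0)
  for (i in rows_missing) {
    # distances from row i to all rows over mutually observed coordinates
    oi <- obs[i, ]
    shared <- obs %*% oi                       # count of usable coordinates
    diff <- sweep(X0[, oi, drop = FALSE], 2, X0[i, oi], "-")
    diff[!obs[, oi, drop = FALSE]] <- 0
    ss <- rowSums(diff^2)
    d <- sqrt(ifelse(shared > 0, p / shared, NA_real_) * ss)
    d[shared == 0] <- Inf
    d[i] <- Inf
    for (j in which(!obs[i, ])) {
      donors <- which(obs[, j] & is.finite(d))
      if (length(donors) == 0)
        stop("no donor rows with overlapping covariates for row ", i)
      nb <- donors[order(d[donors])][seq_len(min(k, length(donors)))]
      val <- mean(X[nb, j])
      if (colnames(X)[j] %in% binary_cols) val <- round(val)
      Xout[i, j] <- val
    }
  }
  trial_table(Xout, table$time, table$event,
              numeric_columns = table$numeric_columns,
              covariates_complete = table$covariates_complete)
}

#' Normalize numeric covariate columns
#'
#' Z-score (default) or min-max scaling of the numeric columns; binary
#' columns are left unchanged. Statistics are learned when `state` is NULL
#' and re-used unchanged otherwise, so that scaling fitted on training data
#' is applied verbatim to test data. The z-score uses the population
#' standard deviation (denominator n).
#'
#' @param table a [trial_table()] with no missing numeric cells.
#' @param state a previously returned `state`, or NULL to fit.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return A list with elements `table` and `state`. The state carries one
#'   (center, scale) pair per numeric column.
#' @export
normalize_numeric <- function(table, state = NULL,
                              method = c("zscore", "minmax")) {
  stopifnot(inherits(table, "trial_table"))
  method <- match.arg(method)
  cols <- table$numeric_columns
  X <- table$covariates
  if (is.null(state)) {
    stats_list <- lapply(cols, function(cn) {
      v <- X[, cn]
      if (anyNA(v)) stop("numeric column '", cn, "' has missing values; impute first")
      if (method == "zscore") {
        s <- sqrt(mean((v - mean(v))^2))
        if (s == 0) stop("numeric column '", cn, "' has zero variance")
        c(center = mean(v), scale = s)
      } else {
        r <- range(v)
        if (diff(r) == 0) stop("numeric column '", cn, "' has zero variance")
        c(center = r[1], scale = diff(r))
      }
    })
    names(stats_list) <- cols
    state <- list(method = method, stats = stats_list)
  } else {
    stopifnot(all(cols %in% names(state$stats)))
  }
  for (cn in cols) {
    st <- state$stats[[cn]]
    X[, cn] <- (X[, cn] - st["center"]) / st["scale"]
  }
  tab <- trial_table(X, table$time, table$event,
                     numeric_columns = cols,
                     covariates_complete = table$covariates_complete)
  list(table = tab, state = state)
}

#' SMOTE rebalancing of the event classes
#'
#' Balances the two event classes by synthesising minority-class rows: each
#' synthetic row is \eqn{x_i + u (x_{nn} - x_i)} for a random minority row
#' \eqn{x_i}, one of its `k` nearest minority neighbours \eqn{x_{nn}}, and
#' \eqn{u \sim U(0,1)}. The observed time is interpolated with the same `u`
#' between the two parents' times, keeping (x, T) jointly plausible; the
#' synthetic event label is the minority label. Original rows are preserved
#' verbatim, ahead of the synthetic ones. Apply to training data only.
#'
#' @param covariates numeric matrix (no missing cells).
#' @param event 0/1 labels defining the classes.
#' @param time observed times, interpolated alongside.
#' @param k number of minority neighbours to draw from (default 5).
#' @param seed RNG seed.
#' @return A list with `covariates`, `event`, `time`, and `n_synthetic`.
#' @export
smote_balance <- function(covariates, event, time, k = 5, seed = 1L) {
  covariates <- as.matrix(covariates)
  event <- as.integer(event)
  stopifnot(nrow(covariates) == length(event), length(event) == length(time),
            !anyNA(covariates), all(event %in% c(0L, 1L)))
  tab <- table(factor(event, levels = c(0L, 1L)))
  if (any(tab == 0)) stop("both event classes must be present")
  minority <- as.integer(names(tab)[which.min(tab)])
  n_synth <- as.integer(abs(tab[1] - tab[2]))
  if (n_synth == 0)
    return(list(covariates = covariates, event = event, time = time,
                n_synthetic = 0L))
  idx_min <- which(event == minority)
  if (length(idx_min) < 2)
    stop("minority class has a single member; no neighbour to interpolate")
  Xm <- covariates[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  kk <- min(k, length(idx_min) - 1)
  nn_idx <- apply(D, 1, function(d) order(d)[seq_len(kk)])
  nn_idx <- matrix(nn_idx, nrow = kk)   # kk x n_minority
  set.seed(seed)
  parents <- sample(length(idx_min), n_synth, replace = TRUE)
  pick <- sample.int(kk, n_synth, replace = TRUE)
  u <- stats::runif(n_synth)
  mates <- nn_idx[cbind(pick, parents)]
  Xs <- Xm[parents, , drop = FALSE] +
    u * (Xm[mates, , drop = FALSE] - Xm[parents, , drop = FALSE])
  ts <- time[idx_min][parents] + u * (time[idx_min][mates] - time[idx_min][parents])
  list(
    covariates = rbind(covariates, Xs),
    event = c(event, rep(minority, n_synth)),
    time = c(time, ts),
    n_synthetic = n_synth
  )
}

#' Random train/test split
#'
#' Seeded random permutation; the first `floor(ratio * n)` rows go to the
#' training table, the rest to the test table (disjoint and exhaustive).
#'
#' @param table a [trial_table()].
#' @param ratio training fraction in (0, 1) (default 0.8).
#' @param seed RNG seed.
#' @return A list with `train` and `test` tables.
#' @export
split_train_test <- function(table, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(table, "trial_table"), ratio > 0, ratio < 1)
  n <- n_trials(table)
  n_train <- floor(ratio * n)
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty train or test set")
  set.seed(seed)
  perm <- sample.int(n)
  list(train = table_subset(table, perm[seq_len(n_train)]),
       test = table_subset(table, perm[(n_train + 1):n]))
}

#' Full preprocessing pipeline
#'
#' Fixed leakage-free order: duplicate removal, sparse-column filtering,
#' KNN imputation, train/test split, normalization fitted on the training
#' rows and applied unchanged to the test rows, and finally SMOTE on the
#' training rows only. Test rows are never touched by SMOTE.
#'
#' @param table a raw [trial_table()].
#' @param ratio training fraction (default 0.8).
#' @param seed seed governing the split and SMOTE.
#' @param sparse_threshold missingness cutoff for column filtering.
#' @param k_impute neighbours for [knn_impute()].
#' @param method normalization method, see [normalize_numeric()].
#' @param smote apply [smote_balance()] to the training rows (default TRUE).
#' @param smote_k neighbours for SMOTE.
#' @return A list with `train` (a [trial_table()], possibly containing
#'   synthetic rows), `test` (a [trial_table()]), and `state` (dropped
#'   columns, normalization statistics, imputation and SMOTE settings).
#' @export
preprocess_pipeline <- function(table, ratio = 0.8, seed = 1L,
                                sparse_threshold = 0.8, k_impute = 5,
                                method = "zscore", smote = TRUE, smote_k = 5) {
  tab <- drop_duplicates(table)
  filt <- drop_sparse_columns(tab, sparse_threshold)
  tab <- knn_impute(filt$table, k = k_impute)
  sp <- split_train_test(tab, ratio = ratio, seed = seed)
  norm_train <- normalize_numeric(sp$train, state = NULL, method = method)
  norm_test <- normalize_numeric(sp$test, state = norm_train$state,
                                 method = method)
  train <- norm_train$table
  n_synth <- 0L
  if (smote) {
    sm <- smote_balance(train$covariates, train$event, train$time,
                        k = smote_k, seed = seed)
    train <- trial_table(sm$covariates, sm$time, sm$event,
                         numeric_columns = train$numeric_columns)
    n_synth <- sm$n_synthetic
  }
  list(
    train = train, test = norm_test$table,
    state = list(
      dropped_columns = filt$dropped,
      numeric_stats = norm_train$state,
      k_neighbors = k_impute,
      smote_applied = smote, n_synthetic = n_synth
    )
  )
}
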