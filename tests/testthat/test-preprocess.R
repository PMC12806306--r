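make_table <- function(X, time = NULL, event = NULL, num = character()) {
  n <- nrow(X)
  trial_table(X, time %||% seq_len(n), event %||% rep(1L, n),
              numeric_columns = num)
}

test_that("duplicate removal keeps first occurrences and respects labels", {
  X <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  tab <- make_table(rbind(X, X[1, , drop = FALSE]),
                    time = c(5, 6, 7, 5), event = c(1, 0, 1, 1))
  out <- drop_duplicates(tab)
  expect_equal(nrow(out$covariates), 3)
  # rows differing only in time are NOT duplicates
  tab2 <- make_table(rbind(X[1, , drop = FALSE], X[1, , drop = FALSE]),
                     time = c(5, 9), event = c(1, 1))
  expect_equal(nrow(drop_duplicates(tab2)$covariates), 2)
  # no duplicates => identical table
  expect_equal(drop_duplicates(tab2)$covariates, tab2$covariates)
})

test_that("sparse-column filter uses a strict greater-than boundary", {
  X <- cbind(c(rep(NA, 9), 1), c(rep(NA, 8), 1, 1), 1:10)
  colnames(X) <- c("mostly", "boundary", "full")
  tab <- make_table(X)
  out <- drop_sparse_columns(tab, threshold = 0.8)
  expect_identical(out$dropped, "mostly")       # 0.9 > 0.8: dropped
  expect_true("boundary" %in% out$table$column_names)  # exactly 0.8: kept
  # fully observed table: nothing dropped
  full <- make_table(matrix(1:20, 10, 2, dimnames = list(NULL, c("p", "q"))))
  expect_length(drop_sparse_columns(full)$dropped, 0)
  # degenerate: everything dropped
  sparse2 <- make_table(cbind(g1 = c(1, NA, NA, NA), g2 = c(NA, 1, 1, 1)))
  expect_error(drop_sparse_columns(sparse2, threshold = 0.2), "all")
})

test_that("KNN imputation reproduces the hand-worked neighbour mean", {
  X <- cbind(c = c(1, 1, 9, NA), d = c(0, 0.1, 5, 0))
  tab <- make_table(X, num = c("c", "d"))
  out <- knn_impute(tab, k = 2)
  # neighbours of row 4 by the rescaled mutual-coordinate distance are rows
  # 1 and 2 (d-distances 0 and 0.1 versus 5); mean of c over them is 1.0
  expect_equal(unname(out$covariates[4, "c"]), 1.0)
  expect_false(anyNA(out$covariates))
  # observed cells untouched; idempotent
  expect_equal(out$covariates[1:3, ], X[1:3, ])
  expect_equal(knn_impute(out, k = 2)$covariates, out$covariates)
})

test_that("KNN-imputed values stay in range; binary cells stay binary", {
  set.seed(42)
  tab <- rand_table(n = 50)
  X <- tab$covariates
  X[matrix(c(sample(50, 12), sample(ncol(X), 12, TRUE)), ncol = 2)] <- NA
  tab_m <- trial_table(X, tab$time, tab$event,
                       numeric_columns = tab$numeric_columns)
  out <- knn_impute(tab_m, k = 5)
  for (j in seq_len(ncol(X))) {
    was_na <- is.na(X[, j])
    if (!any(was_na)) next
    rng <- range(X[!was_na, j])
    expect_true(all(out$covariates[was_na, j] >= rng[1] - 1e-12))
    expect_true(all(out$covariates[was_na, j] <= rng[2] + 1e-12))
  }
  bin <- setdiff(colnames(X), tab$numeric_columns)
  expect_true(all(out$covariates[, bin] %in% c(0, 1)))
  # no missing cells: identity
  expect_identical(knn_impute(tab), tab)
  # entirely missing column is pushed to the column filter
  bad <- make_table(cbind(ok = 1:4, gone = NA_real_))
  expect_error(knn_impute(bad, k = 2), "drop_sparse_columns")
})

test_that("z-score normalization is population-sd based and leakage-free", {
  tab <- make_table(cbind(z = c(1, 2, 3), b = c(0, 1, 0)), num = "z")
  fit <- normalize_numeric(tab)
  expect_equal(fit$table$covariates[, "z"],
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(fit$table$covariates[, "b"], tab$covariates[, "b"])
  # test rows transformed with training stats differ from a self-fit
  test_tab <- make_table(cbind(z = c(10, 20, 30), b = c(1, 1, 0)), num = "z")
  reused <- normalize_numeric(test_tab, state = fit$state)
  selffit <- normalize_numeric(test_tab)
  expect_false(isTRUE(all.equal(reused$table$covariates[, "z"],
                                selffit$table$covariates[, "z"])))
  # zero-variance numeric column named in the error
  cons <- make_table(cbind(z = rep(2, 3), b = c(0, 1, 0)), num = "z")
  expect_error(normalize_numeric(cons), "z")
})

test_that("SMOTE balances classes by convex interpolation of minority rows", {
  set.seed(1)
  X <- matrix(rnorm(100), 50, 2)
  event <- rep(c(0L, 1L), c(40, 10))
  time <- rexp(50) + 0.1
  out <- smote_balance(X, event, time, seed = 3)
  expect_equal(out$n_synthetic, 30)
  expect_equal(as.vector(table(out$event)), c(40, 40))
  expect_equal(out$covariates[1:50, ], X)            # originals verbatim
  # every synthetic row is a convex combination of two minority parents,
  # with time interpolated by the same coefficient
  minX <- X[event == 1, ]
  minT <- time[event == 1]
  for (k in 51:80) {
    z <- out$covariates[k, ]
    found <- FALSE
    for (i in 1:10) for (j in 1:10) {
      if (i == j) next
      dpar <- minX[j, ] - minX[i, ]
      u <- if (abs(dpar[1]) > 1e-12) (z[1] - minX[i, 1]) / dpar[1] else NA
      if (is.na(u) || u < -1e-9 || u > 1 + 1e-9) next
      if (max(abs(minX[i, ] + u * dpar - z)) < 1e-9 &&
          abs(minT[i] + u * (minT[j] - minT[i]) - out$time[k]) < 1e-9) {
        found <- TRUE; break
      }
    }
    expect_true(found)
    expect_equal(out$event[k], 1L)
  }
  # reproducible
  out2 <- smote_balance(X, event, time, seed = 3)
  expect_identical(out, out2)
  # already balanced: unchanged
  bal <- smote_balance(X, rep(c(0L, 1L), 25), time, seed = 1)
  expect_equal(bal$n_synthetic, 0L)
  expect_equal(bal$covariates, X)
  # identical parents degenerate to the shared point
  Xd <- matrix(1, 6, 2)
  outd <- smote_balance(Xd, c(0L, 0L, 0L, 0L, 1L, 1L), rep(2, 6), seed = 1)
  expect_true(all(outd$covariates == 1))
  # singleton minority rejected
  expect_error(smote_balance(X, c(1L, rep(0L, 49)), time), "single")
})

test_that("train/test split is seeded, disjoint and exhaustive", {
  cfg <- generator_config(n_trials = 819, missing_rate = 0, seed = 4)
  tab <- generate_registry(cfg)
  sp <- split_train_test(tab, ratio = 0.8, seed = 21)
  expect_equal(nrow(sp$train$covariates), 655)
  expect_equal(nrow(sp$test$covariates), 164)
  sp2 <- split_train_test(tab, ratio = 0.8, seed = 21)
  expect_identical(sp, sp2)
  small <- split_train_test(table_subset(tab, 1:10), ratio = 0.5, seed = 1)
  expect_equal(nrow(small$train$covariates), 5)
  expect_equal(nrow(small$test$covariates), 5)
  expect_error(split_train_test(table_subset(tab, 1:2), ratio = 0.1), "empty")
})

test_that("pipeline never lets SMOTE or normalization stats touch test rows", {
  cfg <- generator_config(n_trials = 300, seed = 8)
  tab <- generate_registry(cfg)
  prep <- preprocess_pipeline(tab, seed = 8)
  # test rows equal the no-SMOTE pipeline's test rows byte for byte
  prep_nosmote <- preprocess_pipeline(tab, seed = 8, smote = FALSE)
  expect_identical(prep$test$covariates, prep_nosmote$test$covariates)
  expect_identical(prep$test$time, prep_nosmote$test$time)
  # training classes balanced, test class fractions untouched
  expect_equal(sum(prep$train$event == 0), sum(prep$train$event == 1))
  # normalization stats come from the training rows only
  st <- prep$state$numeric_stats$stats
  raw <- knn_impute(tab, k = 5)
  sp <- split_train_test(raw, ratio = 0.8, seed = 8)
  for (cn in names(st)) {
    expect_equal(unname(st[[cn]]["center"]), mean(sp$train$covariates[, cn]))
  }
})
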