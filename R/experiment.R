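#' Experiment configuration
#'
#' Bundles the generator settings, preprocessing settings, model roster and
#' training configuration for a seeded multi-model benchmark. Each seed
#' generates one registry; within a seed every model sees the identical
#' preprocessed train/test split.
#'
#' @param generator a [generator_config()] (its `seed` is overridden per
#'   replication seed).
#' @param models subset of `c("cph", "deepsurv", "daedsr")`.
#' @param seeds integer vector of distinct replication seeds.
#' @param alpha survival-loss weight for the joint model (default 0.6).
#' @param noise_sd corruption noise for the joint model's autoencoder
#'   (default 0.1).
#' @param train a [train_config()] (its `seed` is overridden per seed).
#' @param preprocess list of [preprocess_pipeline()] settings.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              models = c("cph", "deepsurv", "daedsr"),
                              seeds = 1:5, alpha = 0.6, noise_sd = 0.1,
                              train = train_config(),
                              preprocess = list()) {
  models <- match.arg(models, c("cph", "deepsurv", "daedsr"),
                      several.ok = TRUE)
  stopifnot(length(models) >= 1, length(seeds) >= 1,
            !anyDuplicated(seeds))
  pp <- utils::modifyList(list(ratio = 0.8, sparse_threshold = 0.8,
                               k_impute = 5, method = "zscore",
                               smote = TRUE, smote_k = 5), preprocess)
  structure(list(generator = generator, models = models,
                 seeds = as.integer(seeds), alpha = alpha,
                 noise_sd = noise_sd, train = train, preprocess = pp),
            class = "experiment_config")
}

.fit_model <- function(kind, train, tc, alpha, noise_sd) {
  switch(kind,
    cph = fit_linear_cph(train$covariates, train$time, train$event),
    deepsurv = fit_deepsurv(train, config = tc),
    daedsr = fit_daedsr(
      train, alpha = alpha,
      ae_spec = autoencoder_spec(ncol(train$covariates),
                                 noise_sd = noise_sd),
      config = tc),
    stop("unknown model kind: ", kind))
}

.with_seed <- function(obj, seed) { obj$seed <- as.integer(seed); obj }

#' Run the seeded multi-model benchmark
#'
#' Per seed: generate a registry, run the preprocessing pipeline once, fit
#' every model in the roster on the identical training table, and evaluate
#' train and test concordance, the test Brier curve and its integrated
#' value. Training concordance is computed on the original (non-synthetic)
#' training rows. The generator's Bayes concordance (true risk score on the
#' test rows) is recorded as a reference ceiling. Survival curves of the
#' first five test subjects are stored for each model on the first seed.
#' A model failure is recorded and the run continues.
#'
#' @param cfg an [experiment_config()].
#' @return Object of class `metric_report`: per-(model, seed) metric rows,
#'   median/IQR summaries, per-model Brier and five-subject survival
#'   curves (first seed), the per-seed splits, and the config echo.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list(); bayes <- list()
  curves <- list(); briers <- list(); splits <- list()
  for (s in cfg$seeds) {
    gen <- .with_seed(cfg$generator, s)
    registry <- generate_registry(gen)
    pp <- cfg$preprocess
    prep <- preprocess_pipeline(registry, ratio = pp$ratio, seed = s,
                                sparse_threshold = pp$sparse_threshold,
                                k_impute = pp$k_impute, method = pp$method,
                                smote = pp$smote, smote_k = pp$smote_k)
    splits[[as.character(s)]] <- list(train = prep$train, test = prep$test)
    n_orig <- n_trials(prep$train) - prep$state$n_synthetic
    train_eval <- table_subset(prep$train, seq_len(n_orig))
    bayes_c <- tryCatch(
      concordance_index(true_risk(gen, prep$test), prep$test$time,
                        prep$test$event)$c_index,
      error = function(e) NA_real_)
    bayes[[length(bayes) + 1]] <- data.frame(seed = s, bayes_c = bayes_c)
    for (kind in cfg$models) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        fit <- .fit_model(kind, prep$train, .with_seed(cfg$train, s),
                          cfg$alpha, cfg$noise_sd)
        r_train <- predict_risk(fit, train_eval)
        r_test <- predict_risk(fit, prep$test)
        c_train <- concordance_index(r_train, train_eval$time,
                                     train_eval$event)$c_index
        c_test <- concordance_index(r_test, prep$test$time,
                                    prep$test$event)$c_index
        grid <- seq(0, stats::quantile(prep$test$time, 0.9, names = FALSE),
                    length.out = 100)
        sc <- predict_curves(fit, prep$test, grid)
        bc <- brier_curve(sc, prep$test$time, prep$test$event, grid = grid)
        if (s == cfg$seeds[1]) {
          k5 <- seq_len(min(5, n_trials(prep$test)))
          curves[[kind]] <- predict_curves(fit, table_subset(prep$test, k5),
                                           grid)
          briers[[kind]] <- bc
        }
        data.frame(model = kind, seed = s, c_train = c_train,
                   c_test = c_test, gap = c_train - c_test,
                   integrated_brier = bc$integrated,
                   runtime = proc.time()[["elapsed"]] - t0,
                   failed = FALSE, error = "")
      }, error = function(e) {
        data.frame(model = kind, seed = s, c_train = NA_real_,
                   c_test = NA_real_, gap = NA_real_,
                   integrated_brier = NA_real_,
                   runtime = proc.time()[["elapsed"]] - t0,
                   failed = TRUE, error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(metrics, metrics$model), function(m) {
    ok <- m[!m$failed, ]
    data.frame(
      model = m$model[1], n_seeds = nrow(ok),
      c_train_median = stats::median(ok$c_train),
      c_test_median = stats::median(ok$c_test),
      c_test_iqr = stats::IQR(ok$c_test),
      gap_median = stats::median(ok$gap),
      integrated_brier_median = stats::median(ok$integrated_brier)
    )
  }))
  rownames(summary) <- NULL
  structure(list(metrics = metrics, summary = summary,
                 bayes = do.call(rbind, bayes),
                 curves = curves, brier = briers, splits = splits,
                 config = cfg),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Benchmark over", length(x$config$seeds), "seeds\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("Bayes ceiling (median): %.4f\n",
              stats::median(x$bayes$bayes_c, na.rm = TRUE)))
  invisible(x)
}

#' Leave-feature-out importance
#'
#' For each named feature (or named group of one-hot columns) the model is
#' refit from scratch with those columns removed, under the identical seed
#' and hyperparameters, and the change in test concordance
#' \eqn{\Delta C = C_{full} - C_{reduced}} is reported; positive values
#' mean the feature helps. `mode = "zero"` instead zeroes the columns at
#' inference time on the already-fitted full model (no retraining).
#'
#' @param cfg an [experiment_config()] (only its first model is used unless
#'   `model` is given).
#' @param features named list mapping a concept name to a character vector
#'   of covariate columns, or a plain character vector of column names.
#' @param model one of `"cph"`, `"deepsurv"`, `"daedsr"`.
#' @param mode `"retrain"` (default) or `"zero"`.
#' @return data.frame with columns `feature`, `seed`, `c_full`,
#'   `c_reduced`, `delta_c`, plus a `median` attribute per feature.
#' @export
feature_importance <- function(cfg, features, model = cfg$models[1],
                               mode = c("retrain", "zero")) {
  stopifnot(inherits(cfg, "experiment_config"))
  mode <- match.arg(mode)
  if (!is.list(features))
    features <- stats::setNames(as.list(features), features)
  stopifnot(length(features) >= 1)
  out <- list()
  for (s in cfg$seeds) {
    gen <- .with_seed(cfg$generator, s)
    registry <- generate_registry(gen)
    pp <- cfg$preprocess
    prep <- preprocess_pipeline(registry, ratio = pp$ratio, seed = s,
                                sparse_threshold = pp$sparse_threshold,
                                k_impute = pp$k_impute, method = pp$method,
                                smote = pp$smote, smote_k = pp$smote_k)
    bad <- setdiff(unlist(features), prep$train$column_names)
    if (length(bad) > 0)
      stop("unknown feature column(s): ", paste(bad, collapse = ", "))
    tc <- .with_seed(cfg$train, s)
    full <- .fit_model(model, prep$train, tc, cfg$alpha, cfg$noise_sd)
    c_full <- concordance_index(predict_risk(full, prep$test),
                                prep$test$time, prep$test$event)$c_index
    for (fn in names(features)) {
      cols <- features[[fn]]
      if (length(setdiff(prep$train$column_names, cols)) == 0)
        stop("removing '", fn, "' would remove all covariates")
      c_red <- if (mode == "retrain") {
        keep <- setdiff(prep$train$column_names, cols)
        sub_tab <- function(tab) trial_table(
          tab$covariates[, keep, drop = FALSE], tab$time, tab$event,
          numeric_columns = intersect(tab$numeric_columns, keep))
        red <- .fit_model(model, sub_tab(prep$train), tc, cfg$alpha,
                          cfg$noise_sd)
        concordance_index(predict_risk(red, sub_tab(prep$test)),
                          prep$test$time, prep$test$event)$c_index
      } else {
        xz <- prep$test$covariates
        xz[, cols] <- 0
        concordance_index(predict_risk(full, xz), prep$test$time,
                          prep$test$event)$c_index
      }
      out[[length(out) + 1]] <- data.frame(
        feature = fn, seed = s, c_full = c_full, c_reduced = c_red,
        delta_c = c_full - c_red)
    }
  }
  do.call(rbind, out)
}

#' Export a benchmark report to files
#'
#' Writes machine-readable metrics (`metrics.csv`, `summary.json`),
#' per-model Brier curves (`brier_<model>.csv`), per-model five-subject
#' survival curves (`curves_<model>.csv`), the first seed's train/test
#' tables (`train_seed<k>.csv`, `test_seed<k>.csv`) and a run log echoing
#' the configuration. Re-export produces identical bytes.
#'
#' @param report a `metric_report` from [run_benchmark()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "metric_report"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory ", dir)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$metrics, "metrics.csv")
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(report$summary, p, digits = 10, pretty = TRUE)
  paths <- c(paths, p)
  for (kind in names(report$brier)) {
    b <- report$brier[[kind]]
    wr(data.frame(time = b$time, brier = b$bs), paste0("brier_", kind, ".csv"))
  }
  for (kind in names(report$curves))
    wr(curves_to_df(report$curves[[kind]]), paste0("curves_", kind, ".csv"))
  s1 <- names(report$splits)[1]
  write_registry_csv(report$splits[[s1]]$train,
                     file.path(dir, paste0("train_seed", s1, ".csv")))
  write_registry_csv(report$splits[[s1]]$test,
                     file.path(dir, paste0("test_seed", s1, ".csv")))
  log_path <- file.path(dir, "run_log.txt")
  cfg <- report$config
  writeLines(c(
    paste("models:", paste(cfg$models, collapse = ", ")),
    paste("seeds:", paste(cfg$seeds, collapse = ", ")),
    paste("alpha:", cfg$alpha), paste("noise_sd:", cfg$noise_sd),
    paste("generator:", paste(deparse(unclass(cfg$generator)), collapse = " ")),
    paste("preprocess:", paste(deparse(cfg$preprocess), collapse = " ")),
    paste("train:", paste(deparse(unclass(cfg$train)), collapse = " "))
  ), log_path)
  paths <- c(paths, log_path)
  invisible(paths)
}
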