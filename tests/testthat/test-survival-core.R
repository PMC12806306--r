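test_that("Breslow partial likelihood reproduces its closed forms", {
  # equal scores: each event contributes log |R(T_i)|
  expect_equal(cox_nll_breslow(c(0, 0), c(1, 2), c(1, 1), normalize = FALSE),
               log(2) + log(1))
  # n distinct event times at equal scores: log(n!)
  expect_equal(cox_nll_breslow(rep(0, 3), 1:3, rep(1, 3), normalize = FALSE),
               log(factorial(3)), tolerance = 1e-12)
  # shift invariance
  set.seed(1)
  inst <- rand_surv_instance(15)
  expect_equal(
    cox_nll_breslow(inst$scores + 5.3, inst$times, inst$events),
    cox_nll_breslow(inst$scores, inst$times, inst$events), tolerance = 1e-9)
  expect_error(cox_nll_breslow(c(0, 0), c(1, 2), c(0, 0)), "event")
})

test_that("partial likelihood and gradient agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    inst <- rand_surv_instance(n, tie = rep %% 2 == 0)
    expect_equal(
      cox_nll_breslow(inst$scores, inst$times, inst$events),
      brute_cox_nll(inst$scores, inst$times, inst$events), tolerance = 1e-10)
    g <- cox_nll_grad(inst$scores, inst$times, inst$events)
    gn <- num_grad(function(s) brute_cox_nll(s, inst$times, inst$events),
                   inst$scores)
    expect_lt(max(abs(g - gn)) / max(1, max(abs(gn))), 1e-5)
  }
})

test_that("Breslow baseline reduces to Nelson-Aalen at null scores", {
  b <- breslow_baseline(rep(0, 3), 1:3, rep(1, 3))
  expect_equal(b$time, 1:3)
  expect_equal(diff(c(0, b$cumhaz)), c(1 / 3, 1 / 2, 1))
  # zero before the first event time
  expect_equal(baseline_cumhaz(b, 0.5), 0)
  # scaling identity: doubling every e^score halves H0 pointwise
  set.seed(3)
  inst <- rand_surv_instance(40, tie = TRUE)
  b1 <- breslow_baseline(inst$scores, inst$times, inst$events)
  b2 <- breslow_baseline(inst$scores + log(2), inst$times, inst$events)
  expect_equal(b2$cumhaz, b1$cumhaz / 2, tolerance = 1e-12)
})

test_that("predicted survival curves obey the proportional-hazards ordering", {
  b <- structure(list(time = c(1, 2), cumhaz = c(0.5, 1)),
                 class = "baseline_hazard")
  grid <- seq(0, 3, by = 0.5)
  sc <- predict_survival(b, c(-50, 0, 1), grid)
  expect_true(all(sc$surv >= 0 & sc$surv <= 1))
  expect_true(all(sc$surv[1, ] > 1 - 1e-10))      # vanishing hazard limit
  expect_equal(sc$surv[2, grid >= 2], rep(exp(-1), sum(grid >= 2)))
  expect_true(all(diff(t(sc$surv)) <= 1e-12))      # non-increasing in t
  expect_true(all(sc$surv[3, ] <= sc$surv[2, ] + 1e-12))  # higher risk, lower S
  expect_equal(sc$surv[, 1], rep(1, 3))            # S(0) = 1
})

test_that("null-score Breslow curves track Kaplan-Meier on uncensored data", {
  set.seed(9)
  times <- rexp(200)
  events <- rep(1, 200)
  b <- breslow_baseline(rep(0, 200), times, events)
  grid <- sort(unique(times))
  s_hat <- predict_survival(b, 0, grid)$surv[1, ]
  # exp(-Nelson-Aalen) versus the empirical KM within 0.02 everywhere
  km <- vapply(grid, function(t) mean(times > t), numeric(1))
  expect_lt(max(abs(s_hat - km)), 0.02)
})

test_that("risk head is deterministic in evaluation mode and guards batch norm", {
  spec <- survival_head_spec(16)
  set.seed(2)
  head <- daesurv:::init_survival_head(spec)
  y <- matrix(runif(5 * 16, -10, 10), 5, 16)
  s1 <- risk_score(head, y)
  s2 <- risk_score(head, y)
  expect_identical(s1, s2)
  expect_true(all(is.finite(s1)))
  expect_error(risk_score(head, y[1, , drop = FALSE], training = TRUE),
               "size 1")
  # zero weights give equal scores (the null model under shift invariance)
  for (i in seq_along(head$layers))
    if (head$layers[[i]]$type == "linear") {
      head$layers[[i]]$W[] <- 0; head$layers[[i]]$b[] <- 0
    }
  expect_equal(diff(range(risk_score(head, y))), 0)
})

test_that("own Newton-Raphson matches the reference Cox implementation", {
  skip_if_not_installed("survival")
  set.seed(14)
  tab <- rand_table(n = 150)
  fit <- fit_linear_cph(tab$covariates, tab$time, tab$event)
  ref <- survival::coxph(
    survival::Surv(tab$time, tab$event) ~ tab$covariates,
    ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  # reported nll equals the package loss at the fitted linear predictor
  eta <- drop(tab$covariates %*% fit$coefficients)
  expect_equal(fit$nll,
               cox_nll_breslow(eta, tab$time, tab$event, normalize = FALSE))
})

test_that("one-covariate Newton solution solves the score equation (bisection)", {
  set.seed(21)
  x <- rbinom(60, 1, 0.5)
  cfg_rate <- 0.01 * exp(x * 1)
  times <- rexp(60, cfg_rate)
  events <- rep(1, 60)
  fit <- fit_linear_cph(matrix(x, ncol = 1), times, events, ridge = 0)
  score <- function(b)
    num_grad(function(bb) brute_cox_nll(x * bb, times, events,
                                        normalize = FALSE), b, eps = 1e-5)
  lo <- -3; hi <- 3
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (score(lo) * score(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(unname(fit$coefficients), (lo + hi) / 2, tolerance = 1e-5)
})

test_that("Newton-Raphson flags collinearity and shrinks null effects with n", {
  set.seed(30)
  x <- rnorm(100)
  X <- cbind(a = x, b = x)
  times <- rexp(100); events <- rbinom(100, 1, 0.8)
  expect_warning(fit_linear_cph(X, times, events), "collinear|converge")
  norm_at <- vapply(c(500, 5000), function(n) {
    set.seed(77)
    Xn <- matrix(rnorm(n * 3), n, 3)
    sqrt(sum(fit_linear_cph(Xn, rexp(n), rbinom(n, 1, 0.7))$coefficients^2))
  }, numeric(1))
  expect_lt(norm_at[2], norm_at[1])
  expect_lt(norm_at[2], 0.1)
})
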