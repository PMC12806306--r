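test_that("concordance index reproduces hand-worked examples", {
  expect_equal(concordance_index(c(3, 2, 1), 1:3, rep(1, 3))$c_index, 1)
  expect_equal(concordance_index(c(1, 2, 3), 1:3, rep(1, 3))$c_index, 0)
  r <- concordance_index(c(0.8, 0.9, 0.5), c(2, 4, 5), c(1, 0, 1))
  expect_equal(r$c_index, 0.5)
  expect_equal(r$comparable, 2)   # pair (2,3) excluded: subject 2 censored
  expect_error(concordance_index(1:3, c(2, 2, 2), c(1, 1, 1)), "comparable")
})

test_that("concordance matches the all-pairs oracle and its symmetries", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    inst <- rand_surv_instance(n, tie = TRUE)
    risks <- round(inst$scores, 1)   # force occasional risk ties
    oracle <- brute_cindex(risks, inst$times, inst$events)
    if (is.null(oracle)) next
    got <- concordance_index(risks, inst$times, inst$events)
    expect_identical(got$c_index, oracle$c)
    expect_identical(got$comparable, oracle$comparable)
    # permutation invariance
    perm <- sample(n)
    expect_equal(concordance_index(risks[perm], inst$times[perm],
                                   inst$events[perm])$c_index, got$c_index)
    # sign flip complements C when there are no risk ties
    if (got$tied_risk == 0)
      expect_equal(concordance_index(-risks, inst$times,
                                     inst$events)$c_index, 1 - got$c_index)
  }
})

test_that("censoring Kaplan-Meier reproduces the product-limit hand examples", {
  # no censoring: G = 1 everywhere
  g0 <- km_censoring(1:5, rep(1, 5))
  expect_equal(censoring_survival(g0, c(0.5, 3, 5)), rep(1, 3))
  # single censoring with one at risk drives G to zero
  g1 <- km_censoring(c(1, 2), c(1, 0))
  expect_equal(censoring_survival(g1, 1.9), 1)
  expect_equal(censoring_survival(g1, 2), 0)
  # two at risk at the censoring time: drop by half
  g2 <- km_censoring(c(1, 2, 3), c(1, 0, 1))
  expect_equal(censoring_survival(g2, 2), 0.5)
  # left limit excludes the drop at t itself
  expect_equal(censoring_survival(g2, 2, left = TRUE), 1)
})

test_that("censoring Kaplan-Meier agrees with the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(8)
  times <- rexp(80); events <- rbinom(80, 1, 0.6)
  G <- km_censoring(times, events)
  ref <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  grid <- sort(unique(times))
  ref_s <- summary(ref, times = grid)$surv
  expect_equal(censoring_survival(G, grid), ref_s, tolerance = 1e-10)
})

test_that("IPCW Brier score reproduces its ground truths", {
  times <- c(1, 2, 4, 6); events <- rep(1, 4); t <- 3
  # oracle predictor: S = 0 for prior deaths, 1 for survivors
  s_oracle <- ifelse(times <= t, 0, 1)
  expect_equal(brier_score(s_oracle, times, events, t), 0)
  # constant 0.5 predictor, no censoring: exactly 0.25
  expect_equal(brier_score(rep(0.5, 4), times, events, t), 0.25)
  # with G = 1 the score is the plain MSE against the survival indicator
  set.seed(2)
  s <- runif(4)
  expect_equal(brier_score(s, times, events, t),
               mean(ifelse(times > t, (1 - s)^2, s^2)))
})

test_that("IPCW Brier score matches the hand-computed censored example", {
  times <- c(2, 4, 5); events <- c(1, 0, 1); t <- 3
  s_t <- c(0.2, 0.7, 0.9)
  # G from km_censoring: single censoring at 4 among 2 at risk -> G(4-)=1,
  # G(t<4)=1. Subject 1 died before t: 0.2^2 / G(2) = 0.04; subjects 2 and 3
  # survive past t: ((1-0.7)^2 + (1-0.9)^2) / G(3) = 0.10
  expect_equal(brier_score(s_t, times, events, t), (0.04 + 0.10) / 3)
  # G = 0 where a weight is needed is an explicit error
  expect_error(brier_score(c(0.5, 0.5), c(1, 3), c(1, 1), t = 2,
                           G = km_censoring(c(1, 2), c(0, 0))), "zero")
})

test_that("Brier curves are flat at the ground-truth constants and integrate exactly", {
  set.seed(4)
  times <- runif(50, 1, 10); events <- rep(1, 50)
  grid <- seq(0, 9, length.out = 20)
  # perfect oracle: step curves dropping at each subject's event time
  s_mat <- t(vapply(times, function(Ti) as.numeric(grid < Ti),
                    numeric(length(grid))))
  oracle_curves <- structure(list(time = grid, surv = s_mat),
                             class = "survival_curves")
  bc <- brier_curve(oracle_curves, times, events, grid = grid)
  expect_true(all(bc$bs < 1e-12))
  # constant 0.5: flat 0.25, trapezoid integral normalized by span = 0.25
  half <- structure(list(time = grid,
                         surv = matrix(0.5, 50, length(grid))),
                    class = "survival_curves")
  bch <- brier_curve(half, times, events, grid = grid)
  expect_equal(bch$bs, rep(0.25, length(grid)))
  expect_equal(bch$integrated, 0.25)
})

test_that("metrics are invariant under row permutation", {
  set.seed(6)
  inst <- rand_surv_instance(40, tie = FALSE)
  perm <- sample(40)
  b1 <- brier_score(runif(40)[order(perm)], inst$times, inst$events, 0.5)
  G <- km_censoring(inst$times, inst$events)
  Gp <- km_censoring(inst$times[perm], inst$events[perm])
  grid <- c(0.2, 0.5, 1)
  expect_equal(censoring_survival(G, grid), censoring_survival(Gp, grid))
})
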