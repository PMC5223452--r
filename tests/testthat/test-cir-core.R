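test_that("rescaling is the affine map onto the unit interval", {
  likert <- response_matrix(matrix(1:5, 5, 2), item_min = 1, item_max = 5)
  expect_equal(unname(rescale(likert)$values[, 1]), c(0, 0.25, 0.5, 0.75, 1))
  pct <- response_matrix(matrix(c(30, 55), 2, 2), 0, 100)
  expect_equal(rescale(pct)$values[1, 1], 0.30)
  unit <- response_matrix(matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2), 0, 1)
  expect_identical(rescale(unit)$values, unit$values)  # idempotent on (0,1) bounds
})

test_that("Rasch probability is the stable logistic of the logit difference", {
  expect_identical(rasch_probability(0, 0), 0.5)
  expect_equal(rasch_probability(c(-3, 0.7, 12), c(-3, 0.7, 12)),
               rep(0.5, 3))  # symmetry at theta = delta
  expect_equal(rasch_probability(log(3), 0), 0.75)
  expect_gt(rasch_probability(30, 0), 0)
  expect_lt(rasch_probability(-30, 0), 1e-12)
  expect_error(rasch_probability(Inf, 0), "finite")
})

test_that("cell residual and floored variance follow the working model", {
  rv <- residual_and_variance(0.5, 0.5)
  expect_equal(rv$residual, 0)
  expect_equal(rv$variance, 0.25)
  rv2 <- residual_and_variance(1, 0.5)
  expect_equal(rv2$residual, 0.5)
  p <- c(0.2, 0.65, 0.91)
  expect_equal(residual_and_variance(p, p)$residual, rep(0, 3))
  expect_equal(residual_and_variance(0, 1e-9, variance_floor = 1e-6)$variance, 1e-6)
})

test_that("Newton half-steps reproduce hand-computed updates and damping", {
  ctl_free <- cir_control(max_step = Inf)
  # from the all-zero start p = 0.5 and Var = 0.25 everywhere
  X <- rbind(c(0.9, 0.7), c(0.5, 0.5))
  P <- matrix(0.5, 2, 2)
  obs <- !is.na(X)
  th <- raschcir:::step_persons(c(0, 0), X, P, obs, c(FALSE, FALSE), ctl_free)
  expect_equal(th[1], 0.6 / 0.5)     # 1.2 logits, undamped
  expect_equal(th[2], 0)             # zero residual leaves theta at 0
  # damping caps the applied step at max_step
  th_damped <- raschcir:::step_persons(c(0, 0), X, P, obs, c(FALSE, FALSE),
                                       cir_control(max_step = 1))
  expect_equal(th_damped[1], 1.0)
  # item update with column mean 0.6 at N = 10
  Xi <- matrix(0.6, 10, 2); Pi <- matrix(0.5, 10, 2)
  de <- raschcir:::step_items(c(0, 0), Xi, Pi, !is.na(Xi), c(FALSE, FALSE), ctl_free)
  expect_equal(de, c(-0.4, -0.4))
  # column equal to expectation stays put
  de2 <- raschcir:::step_items(c(0.3, 0.3), Xi, matrix(0.6, 10, 2), !is.na(Xi),
                               c(FALSE, FALSE), ctl_free)
  expect_equal(de2, c(0.3, 0.3))
})

test_that("difficulty centering subtracts the mean of the free items", {
  expect_equal(center_items(c(0.3, -0.1, 0.1)), c(0.2, -0.2, 0))
  expect_equal(center_items(c(0.2, -0.2, 0)), c(0.2, -0.2, 0))  # idempotent
  expect_equal(center_items(c(5, 10, 0.7), extreme = c(TRUE, TRUE, FALSE)),
               c(5, 10, 0))  # single free item goes to zero
})

test_that("symmetric 2x2 saddle data land both parameters at the origin", {
  f <- cir_fit(response_matrix(matrix(c(1, 0, 0, 1), 2, 2), 0, 1))
  expect_equal(f$theta, c(0, 0))
  expect_equal(f$delta, c(0, 0))
  expect_true(f$converged)
})

test_that("reversing responses negates all estimates", {
  sim <- simulate_cir(40, 5, noise = "beta", seed = 3)
  f1 <- cir_fit(sim$data, cir_control(change_tol = 1e-8))
  rev <- response_matrix(1 - sim$data$values, 0, 1)
  f2 <- cir_fit(rev, cir_control(change_tol = 1e-8))
  expect_equal(f2$theta, -f1$theta, tolerance = 1e-6)
  expect_equal(f2$delta, -f1$delta, tolerance = 1e-6)
})

test_that("fitting raw bounded data equals fitting pre-rescaled data exactly", {
  sim <- simulate_cir(30, 4, noise = "beta", seed = 8)
  raw <- response_matrix(20 + 60 * sim$data$values, item_min = 20, item_max = 80)
  f_raw <- cir_fit(raw)
  f_unit <- cir_fit(sim$data)
  expect_equal(f_raw$theta, f_unit$theta, tolerance = 1e-12)
  expect_equal(f_raw$delta, f_unit$delta, tolerance = 1e-12)
})

test_that("score equations hold at convergence and difficulties sum to zero", {
  for (seed in c(2, 13)) {
    sim <- simulate_cir(100, 6, noise = "beta", seed = seed)
    fit <- cir_fit(sim$data, cir_control(change_tol = 1e-6))
    N <- length(fit$theta)
    person_score <- rowSums(fit$data - fit$expected)
    item_score <- colSums(fit$data - fit$expected)
    tol <- 10 * fit$control$convergence_tol / N
    expect_lt(max(abs(person_score[!fit$extreme_persons])), tol)
    expect_lt(max(abs(item_score[!fit$extreme_items])), tol)
    expect_lt(abs(sum(fit$delta[!fit$extreme_items])), 1e-6)
  }
})

test_that("the residual trace is non-increasing over the final iterations", {
  sim <- simulate_cir(80, 5, noise = "beta", seed = 21)
  fit <- cir_fit(sim$data)
  tr <- tail(fit$sum_abs_residual_trace, 5)
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("expected values stay strictly inside (0,1) and missing cells are skipped", {
  sim <- simulate_cir(40, 5, noise = "beta", seed = 31)
  vals <- sim$data$values
  vals[cbind(c(1, 5, 9), c(2, 3, 1))] <- NA
  fit <- cir_fit(response_matrix(vals, 0, 1))
  expect_true(all(fit$expected > 0 & fit$expected < 1))
  expect_true(all(is.na(fit$residuals$R[is.na(vals)])))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, fit$control$max_iter)
})

test_that("extreme response strings are clamped, flagged and kept out of centering", {
  X <- rbind(rep(0, 5), rep(1, 5),
             matrix(runif(40, 0.2, 0.8), 8, 5))
  set.seed(1)
  fit <- cir_fit(response_matrix(X, 0, 1))
  expect_equal(fit$extreme_persons, c(TRUE, TRUE, rep(FALSE, 8)))
  expect_equal(fit$theta[1], -fit$control$theta_clamp)
  expect_equal(fit$theta[2], fit$control$theta_clamp)
  expect_lt(abs(sum(fit$delta[!fit$extreme_items])), 1e-6)
})

test_that("a person with no observed responses is a validation error", {
  vals <- matrix(runif(12, 0.2, 0.8), 4, 3)
  vals[2, ] <- NA
  expect_error(cir_fit(response_matrix(vals, 0, 1)), "no observed")
})

test_that("non-convergence returns a warned result, not an error", {
  sim <- simulate_cir(50, 5, noise = "beta", seed = 17)
  expect_warning(fit <- cir_fit(sim$data, cir_control(max_iter = 2)),
                 "did not converge")
  expect_s3_class(fit, "cir_fit")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2L)
})
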