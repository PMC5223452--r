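test_that("item selection maximizes information with a lowest-index tie-break", {
  bank <- item_bank(c("a", "b", "c"), c(-1, 0.2, 2))
  state <- cat_start(bank)
  expect_equal(unname(select_next_item(state)), 2L)
  tie <- cat_start(item_bank(c("a", "b"), c(-0.5, 0.5)))
  expect_equal(unname(select_next_item(tie)), 1L)
})

test_that("no item is administered twice and exhaustion selects each exactly once", {
  bank <- item_bank(paste0("q", 1:6), seq(-1, 1, length.out = 6))
  state <- cat_start(bank, cat_control(stop_resi = 1e-9))  # rule never fires
  seen <- integer(0)
  while (!state$stopped) {
    idx <- select_next_item(state)
    seen <- c(seen, idx)
    state <- cat_step(state, 0.6, item = idx)
  }
  expect_equal(sort(unname(seen)), 1:6)
  expect_equal(state$stop_reason, "bank_exhausted")
  expect_error(cat_step(state, 0.5), "stopped")
})

test_that("the provisional measure solves the score equation over administered items", {
  bank <- item_bank(c("x", "y"), c(0, 0))
  s <- cat_start(bank)
  s <- cat_step(s, 0.5, item = 1L)
  expect_equal(s$theta, 0)
  s2 <- cat_step(cat_start(bank), 0.73, item = 1L)
  expect_equal(s2$theta, log(0.73 / 0.27), tolerance = 1e-6)
  # all-bound strings pin at the clamp and flag extreme
  s3 <- cat_start(bank)
  s3 <- cat_step(s3, 1, item = 1L)
  s3 <- cat_step(s3, 1, item = 2L)
  expect_equal(s3$theta, s3$control$theta_clamp)
  expect_true(s3$extreme)
})

test_that("the standard error is 1/sqrt(summed information) and shrinks per item", {
  bank <- item_bank("solo", 0)
  s <- cat_step(cat_start(bank), 0.5, item = 1L)
  expect_equal(s$mse, 2)         # one item at p = 0.5
  # hand case: variances 0.25, 0.21, 0.16
  v <- c(0.25, 0.21, 0.16)
  expect_equal(1 / sqrt(sum(v)), 1.27, tolerance = 1e-3)
  # adding any item strictly decreases the SE at a fixed measure
  bank2 <- item_bank(paste0("q", 1:5), c(0, 1, -1, 2, -2))
  st <- cat_start(bank2, cat_control(stop_resi = 1e-9))
  prev_info <- 0
  for (k in 1:4) {  # the exact-response trail is flat, so the rule stops at 4
    st <- cat_step(st, plogis(0 - st$bank$difficulties[k]), item = k)
    p <- plogis(st$theta - st$bank$difficulties[st$administered])
    info <- sum(p * (1 - p))
    expect_gt(info, prev_info)
    prev_info <- info
  }
})

test_that("the residual trail is the mean of the last three absolute changes", {
  s <- cat_start(demo_bank())
  s$theta_trail <- c(1.00, 1.02, 1.01, 1.015)
  expect_equal(cat_residual(s), mean(c(0.02, 0.01, 0.005)))
  s$theta_trail <- rep(0.4, 6)
  expect_equal(cat_residual(s), 0)
  s$theta_trail <- c(1, 2, 3)
  expect_true(is.na(cat_residual(s)))   # rule inactive before 4 estimates
})

test_that("the trend correlation uses the last three measures against step numbers", {
  s <- cat_start(demo_bank())
  s$theta_trail <- c(0.9, 1.0, 1.1)
  expect_equal(cat_trend_corr(s)$corr, 1)
  s$theta_trail <- c(1.0, 1.1, 1.0)
  expect_equal(cat_trend_corr(s)$corr, 0)
  s$theta_trail <- c(1, 1, 1)
  tc <- cat_trend_corr(s)
  expect_equal(tc$corr, 0)
  expect_true(tc$flat)
})

test_that("the stop rule fires strictly below 0.05 and only once defined", {
  bank <- item_bank(paste0("q", 1:10), rep(0, 10))
  mk <- function(trail) {
    s <- cat_start(bank)
    s$administered <- seq_along(trail); s$responses <- rep(0.6, length(trail))
    s$theta <- tail(trail, 1); s$theta_trail <- trail
    s
  }
  at <- function(resi_target) c(0, 0, 0, resi_target * 3)  # diffs 0,0,3r -> mean r
  expect_equal(cat_residual(mk(at(0.049))), 0.049)
  expect_true(cat_residual(mk(at(0.049))) < 0.05)
  expect_false(cat_residual(mk(at(0.05))) < 0.05)   # boundary: not stopped
  # three estimates: rule inactive, session continues
  s3 <- mk(c(0.1, 0.1, 0.1))
  expect_true(is.na(cat_residual(s3)))
})

test_that("exact-expectation responses recover the true measure within 1e-3", {
  bank <- demo_bank()
  st <- cat_simulate(bank, 0.8, noise = "exact")
  expect_gte(length(st$administered), 3)
  expect_lt(abs(st$theta - 0.8), 1e-3)
  expect_equal(st$stop_reason, "residual")
  expect_lt(length(st$administered), length(bank$item_ids))
  # every provisional estimate from step 1 on is already at the root
  expect_true(all(abs(st$theta_trail - 0.8) < 1e-3))
})

test_that("interval coverage over noisy simulated sessions is at least 85%", {
  bank <- demo_bank()
  set.seed(501)
  thetas <- rnorm(200)
  covered <- vapply(seq_along(thetas), function(s) {
    st <- cat_simulate(bank, thetas[s], noise = "beta", seed = 500 + s)
    abs(st$theta - thetas[s]) <= 1.96 * st$mse
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("session log has one row per administered item", {
  st <- cat_simulate(demo_bank(), 0.3, noise = "beta", seed = 77)
  log <- as.data.frame(st)
  expect_equal(nrow(log), length(st$administered))
  expect_equal(log$theta, st$theta_trail)
  expect_equal(anyDuplicated(log$item), 0L)
})
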