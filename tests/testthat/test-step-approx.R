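test_that("capped-l1 step values match hand computation", {
  expect_equal(eval_step(step_approx("cappedL1", theta = 2), 0), 0)
  expect_equal(eval_step(step_approx("cappedL1", theta = 2), 0.25), 0.5)
  expect_equal(eval_step(step_approx("cappedL1", theta = 1), -3), 1)
  expect_error(step_approx("cappedL1", theta = -1), "positive")
})

test_that("every family is a valid step approximation with an exact DC split", {
  grid <- seq(-5, 5, by = 0.13)
  for (kind in all_step_families) {
    for (theta in c(0.5, 1, 2, 10)) {
      ap <- step_approx(kind, theta)
      psi <- eval_step(ap, grid)
      expect_true(all(psi >= -1e-12 & psi <= 1 + 1e-12), label = kind)
      expect_equal(eval_step(ap, 0), 0, label = kind)
      expect_equal(psi, eval_step(ap, -grid), label = kind) # even
      u <- sort(abs(grid))
      expect_true(all(diff(eval_step(ap, u)) >= -1e-12), label = kind) # monotone
      dc <- dc_decompose(ap, "minimize")
      split_vals <- vapply(grid, function(t) dc$phi(t) - dc$phi2(t), numeric(1))
      expect_lt(max(abs(split_vals - psi)), 1e-10)
    }
  }
})

test_that("capped-l1 maximization split reproduces the co-step sum", {
  for (theta in c(0.5, 1, 2, 10)) {
    ap <- step_approx("cappedL1", theta)
    dc <- dc_decompose(ap, "maximize")
    grid <- seq(-5, 5, by = 0.13)
    got <- vapply(grid, function(t) dc$phi(t) - dc$phi2(t), numeric(1))
    expect_lt(max(abs(got - (1 - eval_step(ap, grid)))), 1e-10)
  }
  expect_error(dc_decompose(step_approx("exp", 1), "maximize"), "exp")
  expect_error(dc_decompose(step_approx("scad", 1), "maximize"), "scad")
})

test_that("subgradient inequality holds at random point pairs", {
  for (kind in all_step_families) {
    pts <- cardopt:::with_preserved_rng(7, matrix(runif(2000, -4, 4), ncol = 2))
    for (theta in c(0.7, 3)) {
      ap <- step_approx(kind, theta)
      dc <- dc_decompose(ap, "minimize")
      t1 <- pts[, 1]; t2 <- pts[, 2]
      g <- dc$subgrad_phi2(t1)
      gap <- vapply(seq_along(t1), function(i) {
        dc$phi2(t2[i]) - dc$phi2(t1[i]) - g[i] * (t2[i] - t1[i])
      }, numeric(1))
      expect_gt(min(gap), -1e-9)
    }
    # symmetric choice at the origin
    expect_equal(subgrad_phi2(step_approx(kind, 1), "minimize", 0), 0)
  }
})

test_that("capped-l1 subgradients match the analytic cases", {
  expect_equal(subgrad_phi2(step_approx("cappedL1", 1), "minimize", 2), 1)
  expect_equal(subgrad_phi2(step_approx("cappedL1", 1), "minimize", 0.5), 0)
  expect_equal(subgrad_phi2(step_approx("cappedL1", 2), "maximize", -1), -2)
})

test_that("the approximate support count sharpens to the exact count", {
  t <- c(0, 0.1, -0.5, 2, 0, -0.1, 3)   # min |nonzero| = 0.1
  exact <- sum(t != 0)
  for (kind in all_step_families) {
    vals <- vapply(10^(1:6), function(theta) {
      sum(eval_step(step_approx(kind, theta), t))
    }, numeric(1))
    # the logarithmic family converges like 1/log(theta): slower, still
    # monotone; the others are essentially exact at theta = 1e6
    tol_final <- if (kind == "log") 0.5 else 0.05
    expect_lt(abs(vals[length(vals)] - exact), tol_final)
    expect_true(all(diff(abs(vals - exact)) <= 1e-9))
  }
})
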