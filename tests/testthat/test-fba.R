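test_that("flux balance analysis solves the uptake-limited chain", {
  m <- chain_model(uptake_ub = 5)
  m$obj[3] <- 1                      # maximize export of B
  f <- fba(m)
  expect_equal(f$status, "optimal")
  expect_equal(f$rho_star, 5)
  # closed model: optimum zero
  m2 <- m; m2$ub[1] <- 0
  expect_equal(fba(m2)$rho_star, 0)
  # contradictory bounds: infeasible, candidate for relaxation
  m3 <- m; m3$lb[3] <- 10; m3$ub[3] <- 10  # export 10 but uptake capped at 5
  expect_equal(fba(m3)$status, "infeasible")
})

test_that("sparse FBA picks the shorter of two alternative routes", {
  # A --r1--> B  (one step)  versus  A --r2--> C --r3--> B (two steps)
  S <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 1, 3, 3, 2, 2),
    j = c(1, 2, 2, 3, 3, 4, 4, 5),
    x = c(1, -1, 1, -1, 1, -1, 1, -1),
    dims = c(3, 5)
  )
  m <- metabolic_model(S, lb = rep(0, 5), ub = c(5, rep(1000, 4)),
                       met_ids = c("A", "B", "C"),
                       rxn_ids = c("EX_A_in", "r1", "r2", "r3", "EX_B"))
  m$obj[5] <- 1
  sf <- sparse_fba(m)
  expect_equal(sf$rho_star, 5)
  expect_same_set(sf$support, c("EX_A_in", "r1", "EX_B"))
  bf <- brute_force_min_card(cardinality_problem(
    5, A = rbind(S, matrix(m$obj, 1, 5)), sense = c(rep("=", 3), ">="),
    rhs = c(m$b, 5 - 1e-6), lb = m$lb, ub = m$ub, minimize = 1:5))
  expect_equal(length(sf$support), bf$card)
  expect_false(any(sf$removability$removable))
})

test_that("a unique-flux chain has a non-removable full support", {
  m <- chain_model(uptake_ub = 5)
  m$obj[3] <- 1
  sf <- sparse_fba(m)
  expect_same_set(sf$support, c("EX_A_in", "A2B", "EX_B"))
  expect_false(any(sf$removability$removable))
  expect_equal(sum(m$obj * sf$v), 5, tolerance = 1e-6)
})

test_that("isolated ATP hydrolysis is found, sized, and eliminated", {
  loopy <- make_atp_cycle_model(loop_len = 3)
  res <- atp_cycle_test(loopy, "ATPM")
  expect_false(identical(res, "none"))
  expect_equal(length(res$rxns), 4L)   # hydrolysis + 3 regeneration steps
  expect_true("ATPM" %in% res$rxns)
  # an irreversibility repair removes the cycle
  fixed <- make_atp_cycle_model(loop_len = 3, break_cycle = TRUE)
  expect_identical(atp_cycle_test(fixed, "ATPM"), "none")
  # a plain closed chain admits no isolated hydrolysis analogue
  chain <- chain_model()
  expect_identical(atp_cycle_test(chain, "A2B"), "none")
  expect_error(atp_cycle_test(loopy, "NO_SUCH_RXN"), "NO_SUCH_RXN")
})

test_that("relaxed FBA leaves feasible models untouched", {
  fx <- make_consistent_network(m = 5, n_internal = 6, n_external = 2,
                                seed = 13)
  rf <- relaxed_fba(fx$model)
  expect_equal(rf$total_card, 0L)
  expect_true(rf$relaxed_feasible)
})

test_that("forced dead-end fluxes need exactly one bound relaxation each", {
  for (k in 1:2) {
    fx <- make_infeasible_fba(
      make_consistent_network(m = 5, n_internal = 6, n_external = 2, seed = k),
      n_conflicts = k, seed = k)
    expect_equal(fba(fx$model)$status, "infeasible")
    rf <- relaxed_fba(fx$model)
    expect_equal(rf$total_card, fx$min_relax_card)
    expect_true(rf$relaxed_feasible)
    expect_equal(sum(rf$p > 0), k)     # all repairs are lower-bound relaxations
    expect_equal(sum(rf$q > 0), 0L)
    td <- tidy(rf)
    expect_equal(nrow(td), k)
    expect_true(all(td$constraint == "lower_bound"))
  }
})

test_that("relaxation weights steer the repair class", {
  # one steady-state row can be broken either by r (mass balance) or by a
  # bound relaxation; weights decide
  fx <- make_infeasible_fba(
    make_consistent_network(m = 5, n_internal = 6, n_external = 2, seed = 5),
    n_conflicts = 1, seed = 5)
  heavy_bounds <- relaxed_fba(fx$model, lambda = 1, alpha = 100,
                              allow_r = TRUE)
  expect_equal(sum(heavy_bounds$r != 0) > 0 || heavy_bounds$total_card >= 1,
               TRUE)
  expect_true(heavy_bounds$relaxed_feasible)
  heavy_ss <- relaxed_fba(fx$model, lambda = 100, alpha = 1, allow_r = TRUE)
  expect_equal(sum(heavy_ss$r != 0), 0L)   # steady state too expensive
  expect_equal(sum(heavy_ss$p > 0), 1L)
  expect_true(heavy_ss$relaxed_feasible)
})

test_that("applying the returned relaxation always restores feasibility", {
  for (seed in 1:4) {
    fx <- make_infeasible_fba(
      make_consistent_network(m = 6, n_internal = 8, n_external = 2,
                              seed = seed),
      n_conflicts = 2, seed = seed)
    rf <- relaxed_fba(fx$model)
    expect_true(rf$relaxed_feasible)
    # upper-bound sanity: never worse than relaxing every forced bound
    expect_lte(rf$total_card, sum(fx$model$lb > 0) + sum(fx$model$ub < 0))
  }
})
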