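test_that("generated networks are consistent by construction and deterministic", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 1)
  N <- fx$model$S[, fx$truth$class == "consistent"]
  expect_true(all(abs(Matrix::t(N) %*% fx$ell) == 0))  # exact integer balance
  expect_true(check_full_consistency(N)$consistent)
  # the constructed masses solve the minimal-relaxation problem with zero cost
  expect_equal(length(min_conservation_relaxation(N)$support), 0L)
  fx2 <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 1)
  expect_identical(as.matrix(fx$model$S), as.matrix(fx2$model$S))
  expect_identical(fx$model$lb, fx2$model$lb)
  fx3 <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 2)
  expect_false(identical(as.matrix(fx$model$S), as.matrix(fx3$model$S)))
  expect_true(all(abs(fx$model$S@x) <= 4))   # well-conditioned coefficients
})

test_that("fixture generation rejects impossible specifications", {
  expect_error(make_consistent_network(m = 1), "two metabolites")
  expect_error(make_consistent_network(m = 6, n_internal = 2), "connected")
  expect_error(make_consistent_network(m = 4, n_internal = 5, n_external = 9),
               "exceed")
})

test_that("injected inconsistencies are re-detected by the exact checker", {
  fx <- make_consistent_network(m = 8, n_internal = 12, n_external = 3,
                                seed = 17)
  fx2 <- inject_inconsistency(fx, k = 3, seed = 17)
  expect_false(check_full_consistency(
    fx2$model$S[, fx2$truth$class != "external"])$consistent)
  # removing exactly the corrupted columns restores consistency
  keep <- fx2$truth$class == "consistent"
  expect_true(check_full_consistency(fx2$model$S[, keep])$consistent)
  # corrupted reactions are elementally imbalanced when flagged
  part <- split_internal_external(fx2$model)
  imb <- elemental_imbalance(fx2$model, part)
  bad <- fx2$truth$rxn_id[fx2$truth$class == "inconsistent"]
  expect_true(all(imb$status[imb$rxn_id %in% bad] == "imbalanced"))
  # without the flag they are undetermined instead
  fx3 <- inject_inconsistency(fx, k = 3, imbalanced_formulas = FALSE,
                              seed = 17)
  imb3 <- elemental_imbalance(fx3$model, split_internal_external(fx3$model))
  expect_true(all(imb3$status[imb3$rxn_id %in% bad] == "undetermined"))
  # k = 0 is a no-op
  expect_identical(inject_inconsistency(fx, 0)$truth, fx$truth)
})

test_that("injected blocked reactions stay stoichiometrically consistent", {
  fx <- inject_blocked(
    make_consistent_network(m = 7, n_internal = 10, n_external = 3, seed = 19),
    k = 3, seed = 19)
  blk <- fx$truth$rxn_id[fx$truth$class == "blocked"]
  oracle <- cardopt:::flux_consistency_oracle(fx$model)
  expect_true(all(blk %in% oracle$blocked))
  # blocked is independent of stoichiometric inconsistency
  keep <- fx$truth$class %in% c("consistent", "blocked")
  expect_true(check_full_consistency(fx$model$S[, keep])$consistent)
})

test_that("injected cycles circulate even when the boundary is closed", {
  fx <- inject_internal_cycle(
    make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 23),
    cycle_len = 2, seed = 23)
  mdl <- fx$model
  part <- split_internal_external(mdl)
  closed <- cardopt:::close_externals(mdl, part)
  cyc_idx <- match(sprintf("CYC_%03d", 1:2), mdl$rxn_ids)
  lb <- closed$lb; lb[cyc_idx[1]] <- 1   # force circulation through the loop
  s <- lp_solve(lp_problem(rep(0, ncol(mdl$S)), lb, closed$ub, A = mdl$S,
                           sense = "=", rhs = mdl$b))
  expect_equal(s$status, "optimal")
  # loop reactions remain mass balanced
  expect_true(check_full_consistency(
    mdl$S[, c(which(fx$truth$class == "consistent"), cyc_idx)])$consistent)
})

test_that("forced infeasibilities carry their constructed repair bound", {
  fx0 <- make_consistent_network(m = 5, n_internal = 6, n_external = 2,
                                 seed = 29)
  expect_equal(make_infeasible_fba(fx0, 0)$min_relax_card, 0L)
  for (k in c(1L, 3L)) {
    fx <- make_infeasible_fba(fx0, n_conflicts = k, seed = 29)
    expect_equal(fx$min_relax_card, k)
    expect_equal(fba(fx$model)$status, "infeasible")
  }
})

test_that("the mid preset has the advertised dimensions", {
  fx <- preset_fixture("mid", seed = 1)
  expect_equal(nrow(fx$model$S), 300L)
  expect_equal(sum(!startsWith(fx$model$rxn_ids, "EX_")), 500L)
  expect_equal(sum(startsWith(fx$model$rxn_ids, "EX_")), 60L)
  expect_true(check_full_consistency(
    fx$model$S[, !startsWith(fx$model$rxn_ids, "EX_")])$consistent)
})
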