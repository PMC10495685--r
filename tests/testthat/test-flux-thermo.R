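test_that("flux consistency matches intuition on tiny networks", {
  # A <-> B with open exchanges for both: everything can carry flux
  S <- Matrix::sparseMatrix(i = c(1, 2, 1, 2), j = c(1, 1, 2, 3),
                            x = c(-1, 1, -1, -1), dims = c(2, 3))
  m <- metabolic_model(S, lb = c(-1000, -1000, -1000), ub = rep(1000, 3),
                       met_ids = c("A", "B"), rxn_ids = c("AB", "EX_A", "EX_B"))
  fc <- find_flux_consistent_subset(m)
  expect_same_set(fc$consistent, m$rxn_ids)

  # dead-end metabolite blocks its reaction
  S2 <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2),
                             x = c(-1, -1, 1), dims = c(2, 2))
  m2 <- metabolic_model(S2, lb = c(-1000, -1000), ub = c(1000, 1000),
                        met_ids = c("A", "DEAD"), rxn_ids = c("EX_A", "A2D"))
  fc2 <- find_flux_consistent_subset(m2)
  # the dead end blocks its reaction, and with it the only exchange
  expect_true("A2D" %in% fc2$blocked)
})

test_that("the amalgamated flux-consistent set equals the per-reaction oracle", {
  for (seed in 1:6) {
    fx <- inject_blocked(
      make_consistent_network(m = 7, n_internal = 10, n_external = 3,
                              seed = seed),
      k = 2, seed = seed)
    fc <- find_flux_consistent_subset(fx$model)
    oracle <- cardopt:::flux_consistency_oracle(fx$model)
    expect_same_set(fc$consistent, oracle$consistent)
    expect_true(all(c("BLK_001", "BLK_002") %in% fc$blocked))
  }
})

test_that("flux consistency is invariant under column rescaling and bound growth", {
  fx <- make_consistent_network(m = 6, n_internal = 9, n_external = 3, seed = 2)
  base <- find_flux_consistent_subset(fx$model)
  # positive rescale of a column with rescaled bounds
  mdl <- fx$model
  mdl$S[, 2] <- 5 * mdl$S[, 2]
  mdl$lb[2] <- mdl$lb[2] / 5; mdl$ub[2] <- mdl$ub[2] / 5
  expect_same_set(find_flux_consistent_subset(mdl)$consistent, base$consistent)
  # enlarging bounds never shrinks the set
  mdl2 <- fx$model
  mdl2$lb <- pmin(mdl2$lb, -2000); mdl2$ub <- pmax(mdl2$ub, 2000)
  expect_true(all(base$consistent %in%
                    find_flux_consistent_subset(mdl2)$consistent))
})

test_that("chemical potentials certify chains and reject directed cycles", {
  chainN <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2)
  r <- sign_pattern_admits_potentials(chainN, c(1, 1))
  expect_true(r$feasible)
  # certificate inequality: potentials strictly decrease along active flux
  expect_true(all(t(chainN) %*% r$y <= -1 + 1e-8))

  cycN <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3)
  r2 <- sign_pattern_admits_potentials(cycN, c(1, 1, 1))
  expect_false(r2$feasible)
  expect_true(!is.null(r2$cycle))
  expect_lt(max(abs(cycN %*% r2$cycle)), 1e-8)   # a genuine cycle
  expect_true(all(r2$cycle >= -1e-9))            # sign-concordant

  r3 <- sign_pattern_admits_potentials(cycN, c(0, 0, 0))
  expect_true(r3$feasible)
})

test_that("exactly one of potentials and cycle certificate exists", {
  disagreements <- 0L
  for (seed in 1:40) {
    env <- cardopt:::with_preserved_rng(seed, {
      m <- sample(3:8, 1); n <- sample(3:12, 1)
      N <- matrix(0, m, n)
      for (j in seq_len(n)) {
        rows <- sample(m, sample(2:min(3, m), 1))
        N[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
      }
      sigma <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
      list(N = N, sigma = sigma)
    })
    r <- sign_pattern_admits_potentials(env$N, env$sigma)
    if (r$feasible) {
      active <- env$sigma != 0
      if (any(active)) {
        lhs <- as.numeric(t(env$N[, active, drop = FALSE]) %*% r$y) *
          env$sigma[active]
        disagreements <- disagreements + any(lhs > -1 + 1e-7)
      }
    } else {
      c_ <- r$cycle
      ok <- !is.null(c_) &&
        max(abs(env$N %*% c_)) < 1e-7 &&
        all(env$sigma * c_ >= -1e-9) &&
        sum(env$sigma * c_) > 0.5
      disagreements <- disagreements + !ok
    }
  }
  expect_equal(disagreements, 0L)
})

test_that("balanced internal cycles are flux consistent but not thermo consistent", {
  fx <- inject_internal_cycle(
    make_consistent_network(m = 6, n_internal = 8, n_external = 3, seed = 3,
                            reversible_frac = 1),
    cycle_len = 3, seed = 3)
  cyc <- sprintf("CYC_%03d", 1:3)
  fc <- find_flux_consistent_subset(fx$model)
  expect_true(all(cyc %in% fc$consistent))
  th <- find_thermo_flux_consistent_subset(fx$model, flux = fc)
  expect_true(all(cyc %in% th$inconsistent_internal))
  expect_true(all(th$index %in% fc$index))        # thermo subset of flux
})

test_that("breaking a cycle member restores thermodynamic consistency of the rest", {
  fx <- inject_internal_cycle(
    make_consistent_network(m = 6, n_internal = 8, n_external = 3, seed = 6,
                            reversible_frac = 1),
    cycle_len = 2, seed = 6, break_cycle = TRUE)
  fc <- find_flux_consistent_subset(fx$model)
  # the broken loop cannot circulate: its reactions are blocked
  expect_true(all(sprintf("CYC_%03d", 1:2) %in% fc$blocked))
})

test_that("thermo witnesses re-verify independently", {
  fx <- make_consistent_network(m = 7, n_internal = 10, n_external = 4,
                                seed = 9)
  part <- split_internal_external(fx$model)
  th <- find_thermo_flux_consistent_subset(fx$model, partition = part)
  expect_gt(length(th$witnesses), 0L)
  for (w in th$witnesses) {
    # steady state
    expect_lt(max(abs(fx$model$S %*% w$v - fx$model$b)), 1e-6)
    # second-law certificate for the active internal sign pattern
    int <- part$internal
    sigma <- rep(0, length(int))
    z <- w$v[int]
    sigma[z > 1e-6] <- 1; sigma[z < -1e-6] <- -1
    N <- fx$model$S[, int, drop = FALSE]
    if (any(sigma != 0)) {
      Na <- as.matrix(N[, sigma != 0, drop = FALSE])
      lhs <- as.numeric(crossprod(Na, w$y)) * sigma[sigma != 0]
      expect_true(all(lhs <= -1 + 1e-7))
    }
  }
  # a fully open chain-like model: thermo set equals the flux set
  fc <- find_flux_consistent_subset(fx$model)
  expect_true(all(th$index %in% fc$index))
})
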