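test_that("full-consistency certificates match hand-worked cases", {
  # A -> B admits unit masses
  r <- check_full_consistency(matrix(c(-1, 1), 2, 1))
  expect_true(r$consistent)
  expect_true(all(r$ell >= 1))
  expect_equal(as.numeric(t(matrix(c(-1, 1), 2, 1)) %*% r$ell), 0)
  # A -> nothing, mislabelled internal: -ell_A = 0 contradicts ell >= 1
  expect_false(check_full_consistency(matrix(-1, 1, 1))$consistent)
  # A -> 2B together with B -> A forces ell to zero
  expect_false(check_full_consistency(matrix(c(-1, 2, 1, -1), 2, 2))$consistent)
})

test_that("minimal conservation relaxation counts match enumeration", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 1)
  N <- fx$model$S[, 1:8]
  rel <- min_conservation_relaxation(N)
  expect_equal(length(rel$support), 0L)    # fully consistent
  expect_true(all(rel$w >= 1 - 1e-9))

  # consistent chain plus one mass-destroying column
  N2 <- cbind(N, Matrix::sparseMatrix(i = 1, j = 1, x = -1,
                                      dims = c(nrow(N), 1)))
  rel2 <- min_conservation_relaxation(N2)
  expect_equal(rel2$support, ncol(N2))

  # two coupled inconsistent columns: relaxing either one suffices
  N3 <- matrix(c(-1, 2, 1, -1), 2, 2)
  rel3 <- min_conservation_relaxation(N3)
  expect_equal(length(rel3$support), 1L)
})

test_that("sequential omission recovers exactly the injected inconsistencies", {
  for (seed in c(11, 23)) {
    fx <- inject_inconsistency(
      make_consistent_network(m = 8, n_internal = 12, n_external = 3,
                              seed = seed),
      k = 3, seed = seed)
    res <- find_stoich_consistent_subset(fx$model, criterion = "elemental")
    injected <- sort(fx$truth$rxn_id[fx$truth$class == "inconsistent"])
    flagged <- sort(res$reactions$rxn_id[
      res$reactions$label %in% c("stoich_inconsistent", "omitted_unknown")])
    expect_equal(flagged, injected)
    clean <- res$reactions$rxn_id[res$reactions$label == "stoich_consistent"]
    expect_same_set(clean,
                    setdiff(fx$truth$rxn_id[fx$truth$class == "consistent"],
                            character(0)))
    # soundness certificate: the claimed consistent set has a positive mass
    idx <- match(clean, fx$model$rxn_ids)
    expect_true(check_full_consistency(fx$model$S[, idx])$consistent)
  }
})

test_that("a fully consistent model converges in one round with no omissions", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 4)
  res <- find_stoich_consistent_subset(fx$model)
  expect_equal(length(res$omitted), 0L)
  expect_equal(nrow(res$log), 1L)
  expect_equal(sum(res$reactions$label == "stoich_consistent"), 8L)
})

test_that("the maxnnz criterion is used as fallback without formulae", {
  fx <- inject_inconsistency(
    make_consistent_network(m = 8, n_internal = 12, n_external = 3, seed = 8),
    k = 2, seed = 8)
  mdl <- fx$model
  mdl$met_formula <- NULL
  expect_warning(res <- find_stoich_consistent_subset(mdl, "elemental"),
                 "maxnnz")
  expect_s3_class(res, "consistency_partition")
})

test_that("stoichiometric labels are invariant to flux bounds", {
  fx <- inject_inconsistency(
    make_consistent_network(m = 8, n_internal = 12, n_external = 3, seed = 5),
    k = 2, seed = 5)
  base <- find_stoich_consistent_subset(fx$model)
  for (rep in 1:4) {
    mdl <- fx$model
    n <- ncol(mdl$S)
    mdl$lb <- cardopt:::with_preserved_rng(rep, -runif(n, 0, 500))
    mdl$ub <- cardopt:::with_preserved_rng(rep + 100, runif(n, 0, 500))
    res <- find_stoich_consistent_subset(mdl)
    expect_equal(res$reactions$label, base$reactions$label)
  }
})

test_that("closed consistent networks have no leaks or siphons", {
  for (seed in 1:6) {
    fx <- make_consistent_network(m = 6, n_internal = 9, n_external = 3,
                                  seed = seed)
    ls <- find_leaks_siphons(fx$model, closed = TRUE)
    expect_equal(length(ls$leaks), 0L)
    expect_equal(length(ls$siphons), 0L)
  }
})

test_that("generator and drain reactions appear as leaks and siphons", {
  # nothing -> A, mislabelled internal (closed network has only this column)
  gen <- metabolic_model(Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                              dims = c(1, 1)),
                         lb = 0, ub = 10, met_ids = "A", rxn_ids = "GEN")
  ls <- find_leaks_siphons(gen, closed = FALSE)
  expect_equal(ls$leaks, "A")
  expect_equal(length(ls$siphons), 0L)
  mode <- find_leaks_siphons(gen, closed = FALSE, minimal_for = "A",
                             type = "leak")
  expect_equal(mode$minimal_mode$rxns, "GEN")

  drain <- metabolic_model(Matrix::sparseMatrix(i = 1, j = 1, x = -1,
                                                dims = c(1, 1)),
                           lb = 0, ub = 10, met_ids = "A", rxn_ids = "DRAIN")
  ls2 <- find_leaks_siphons(drain, closed = FALSE)
  expect_equal(ls2$siphons, "A")
  expect_equal(length(ls2$leaks), 0L)
})

test_that("metabolite labels follow their reactions' labels", {
  fx <- inject_inconsistency(
    make_consistent_network(m = 8, n_internal = 12, n_external = 3, seed = 13),
    k = 2, seed = 13)
  res <- find_stoich_consistent_subset(fx$model)
  mets <- res$metabolites
  expect_true(all(mets$label %in% c("stoich_consistent", "not_consistent",
                                    "omitted", "external")))
  # every metabolite labelled consistent touches only consistent internal cols
  Spat <- fx$model$S != 0
  cons_rxn <- match(res$reactions$rxn_id[res$reactions$label ==
                                           "stoich_consistent"],
                    fx$model$rxn_ids)
  bad_rxn <- setdiff(match(
    res$reactions$rxn_id[res$reactions$label != "external"],
    fx$model$rxn_ids), cons_rxn)
  for (i in which(mets$label == "stoich_consistent")) {
    expect_true(any(Spat[i, cons_rxn]))
    if (length(bad_rxn)) expect_false(any(Spat[i, bad_rxn]))
  }
})
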