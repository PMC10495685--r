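test_that("TSV triplet models round-trip bit-for-bit", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(fx$model, path, "tsv")
  m2 <- read_model(path)
  expect_identical(as.matrix(fx$model$S), as.matrix(m2$S))
  expect_identical(fx$model$lb, m2$lb)
  expect_identical(fx$model$ub, m2$ub)
  expect_identical(fx$model$met_formula, m2$met_formula)
})

test_that("a 2-metabolite 3-reaction triplet reads with the expected nonzeros", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("met_id\trxn_id\tcoefficient",
               "A\tr1\t-1", "B\tr1\t1", "A\tr2\t-1", "B\tr3\t1"), path)
  m <- read_model(path)
  expect_equal(dim(m$S), c(2L, 3L))
  expect_equal(Matrix::nnzero(m$S), 4)
  expect_equal(m$lb, rep(-1000, 3))   # defaults when no bounds table
})

test_that("JSON models round-trip exactly", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 2)
  mdl <- fx$model
  mdl$obj[3] <- 1
  path <- withr::local_tempfile(fileext = ".json")
  write_model(mdl, path, "json")
  m2 <- read_model(path)
  expect_identical(as.matrix(mdl$S), as.matrix(m2$S))
  expect_identical(mdl$lb, m2$lb)
  expect_identical(mdl$ub, m2$ub)
  expect_identical(mdl$obj, m2$obj)
  expect_identical(mdl$met_formula, m2$met_formula)
})

test_that("SBML FBC models round-trip within numeric tolerance", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 3)
  mdl <- fx$model
  mdl$obj[2] <- 1
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(mdl, path, "sbml")
  m2 <- read_model(path)
  expect_lt(max(abs(as.matrix(mdl$S) - as.matrix(m2$S))), 1e-12)
  expect_lt(max(abs(mdl$lb - m2$lb)), 1e-12)
  expect_lt(max(abs(mdl$ub - m2$ub)), 1e-12)
  expect_identical(mdl$met_formula, m2$met_formula)
  expect_identical(mdl$met_charge, m2$met_charge)
  expect_identical(mdl$obj, m2$obj)
})

test_that("the SBML writer is readable by an independent SBML parser", {
  py <- Sys.which("python")
  skip_if(py == "", "no python interpreter")
  has_cobra <- system2(py, c("-c", shQuote("import cobra")),
                       stdout = NULL, stderr = NULL) == 0
  skip_if_not(has_cobra, "cobrapy not installed")
  fx <- make_consistent_network(m = 5, n_internal = 6, n_external = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(fx$model, path, "sbml")
  script <- sprintf(
    "import warnings; warnings.filterwarnings('ignore'); import cobra; m = cobra.io.read_sbml_model('%s'); print(len(m.metabolites), len(m.reactions))",
    path)
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(out[length(out)], "5 8")
})

test_that("malformed files and duplicate ids are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path)
  expect_error(read_model(path), "malformed")
  expect_error(read_model("/nonexistent/model.json"), "no such file")
  S <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = 1, dims = c(2, 2))
  expect_error(metabolic_model(S, met_ids = c("A", "A"), rxn_ids = c("r1", "r2")),
               "duplicate metabolite")
  expect_error(metabolic_model(S, met_ids = c("A", "B"), rxn_ids = c("r", "r")),
               "duplicate reaction")
  expect_error(metabolic_model(S, lb = c(1, 1), ub = c(0, 2)), "lb > ub")
})

test_that("the internal/external split follows both heuristics", {
  S <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 1, 2),
    j = c(1, 2, 2, 3, 3),
    x = c(-1, -1, 1, -1, 2),
    dims = c(2, 3)
  )
  m <- metabolic_model(S, met_ids = c("glc__D_e", "pyr"),
                       rxn_ids = c("single", "internal", "EX_glc__D_e"))
  part <- split_internal_external(m)
  expect_equal(part$external, c(1L, 3L))   # single nonzero; prefix (2 nonzeros)
  expect_equal(part$internal, 2L)
  reasons <- tidy(part)
  expect_equal(reasons$reason, c("single nonzero", "internal", "id prefix"))
})

test_that("the split is invariant to column order and flags empty columns", {
  fx <- make_consistent_network(m = 6, n_internal = 8, n_external = 2, seed = 5)
  mdl <- fx$model
  perm <- rev(seq_len(ncol(mdl$S)))
  mp <- metabolic_model(mdl$S[, perm], lb = mdl$lb[perm], ub = mdl$ub[perm],
                        met_ids = mdl$met_ids, rxn_ids = mdl$rxn_ids[perm])
  p1 <- split_internal_external(mdl)
  p2 <- split_internal_external(mp)
  expect_same_set(mdl$rxn_ids[p1$external], mp$rxn_ids[p2$external])
  S <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 2))
  m0 <- metabolic_model(S, met_ids = "A", rxn_ids = c("r1", "zero"))
  expect_warning(split_internal_external(m0), "all-zero")
})

test_that("reports serialize partitions with identifiers, not indices", {
  fx <- make_consistent_network(m = 5, n_internal = 6, n_external = 2, seed = 6)
  res <- find_stoich_consistent_subset(fx$model)
  jp <- withr::local_tempfile(fileext = ".json")
  write_report(res, jp, "json")
  parsed <- jsonlite::fromJSON(jp)
  expect_true(all(c("rxn_id", "label") %in% names(parsed$rows)))
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, tp, "tsv")
  tab <- utils::read.delim(tp)
  expect_equal(sort(tab$rxn_id), sort(fx$model$rxn_ids))
})
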