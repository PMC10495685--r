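# shared scaffolding for the suite; everything is generated in code

# chain model  EX_A -> A -> B -> EX_B  with unit stoichiometry
chain_model <- function(uptake_ub = 5) {
  S <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 2),
    j = c(1, 2, 2, 3),
    x = c(1, -1, 1, -1),
    dims = c(2, 3)
  )
  metabolic_model(S, lb = c(0, 0, 0), ub = c(uptake_ub, 1000, 1000),
                  met_ids = c("A", "B"), rxn_ids = c("EX_A_in", "A2B", "EX_B"),
                  met_formula = c("C2H4", "C2H4"))
}

# toy problems used across solver tests
toy_min_unit <- function() {
  cardinality_problem(2, A = matrix(1, 1, 2), sense = "=", rhs = 1,
                      lb = c(0, 0), ub = c(1, 1), minimize = 1:2)
}
toy_min_sum3 <- function() {
  cardinality_problem(3, A = matrix(1, 1, 3), sense = ">=", rhs = 3,
                      lb = rep(0, 3), ub = rep(2, 3), minimize = 1:3)
}
toy_max_equal <- function() {
  cardinality_problem(2, A = matrix(c(1, -1), 1, 2), sense = "=", rhs = 0,
                      lb = c(0, 0), ub = c(1, 1), maximize = 1:2)
}

all_step_families <- c("cappedL1", "exp", "scad", "log", "lpPos", "lpNeg")

expect_same_set <- function(a, b) expect_true(setequal(a, b))
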