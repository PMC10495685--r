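#' Flux-consistent reaction subset
#'
#' A reaction is flux consistent when it admits a nonzero steady-state flux
#' within the bounds (`S v = b`, `lb <= v <= ub`). The set is built by
#' repeated DCCO cardinality maximization over the not-yet-covered reactions
#' (each feasible solution certifies every reaction in its support), after
#' which each still-ambiguous reaction is settled exactly by a pair of LPs
#' (maximize then minimize its flux). The result is exact, the DCCO rounds
#' only reduce the number of per-reaction LPs.
#'
#' @param model a [metabolic_model()].
#' @param eps flux threshold for "nonzero".
#' @param max_rounds cap on DCCO amalgamation rounds.
#' @inheritParams solve_cardinality
#' @return A list with `consistent` (reaction ids), `index` (column
#'   indices), and `blocked` (ids of reactions with no nonzero flux).
#' @export
find_flux_consistent_subset <- function(model, eps = 1e-6, max_rounds = 10L,
                                        backend = lp_backend(), ...) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- ncol(model$S)
  covered <- logical(n)
  for (round in seq_len(max_rounds)) {
    todo <- which(!covered)
    if (length(todo) == 0L) break
    delta <- numeric(n); delta[todo] <- 1
    prob <- cardinality_problem(
      n = n, A = model$S, sense = "=", rhs = model$b,
      lb = model$lb, ub = model$ub,
      maximize = todo, delta = 1, names = model$rxn_ids
    )
    sol <- solve_cardinality(prob, backend = backend, seed = round, ...)
    if (sol$status == "infeasible") break
    newly <- abs(sol$x) > eps & !covered
    if (!any(newly)) break
    covered <- covered | newly
  }
  # settle the remainder exactly with per-reaction LPs
  todo <- which(!covered)
  if (length(todo)) {
    lps <- purrr::flatten(lapply(todo, function(j) {
      obj <- numeric(n); obj[j] <- 1
      list(lp_problem(obj, model$lb, model$ub, A = model$S, sense = "=",
                      rhs = model$b, maximize = TRUE),
           lp_problem(obj, model$lb, model$ub, A = model$S, sense = "=",
                      rhs = model$b, maximize = FALSE))
    }))
    sols <- lp_solve_batch(lps, backend = backend)
    for (k in seq_along(todo)) {
      mx <- sols[[2L * k - 1L]]; mn <- sols[[2L * k]]
      covered[todo[k]] <-
        (mx$status == "optimal" && mx$obj > eps) ||
        (mn$status == "optimal" && mn$obj < -eps)
    }
  }
  list(consistent = model$rxn_ids[covered], index = which(covered),
       blocked = model$rxn_ids[!covered])
}

# exact per-reaction oracle (2n LPs), used as an independent cross-check
flux_consistency_oracle <- function(model, eps = 1e-6, backend = lp_backend()) {
  n <- ncol(model$S)
  lps <- purrr::flatten(lapply(seq_len(n), function(j) {
    obj <- numeric(n); obj[j] <- 1
    list(lp_problem(obj, model$lb, model$ub, A = model$S, sense = "=",
                    rhs = model$b, maximize = TRUE),
         lp_problem(obj, model$lb, model$ub, A = model$S, sense = "=",
                    rhs = model$b, maximize = FALSE))
  }))
  sols <- lp_solve_batch(lps, backend = backend)
  ok <- vapply(seq_len(n), function(k) {
    mx <- sols[[2L * k - 1L]]; mn <- sols[[2L * k]]
    (mx$status == "optimal" && mx$obj > eps) ||
      (mn$status == "optimal" && mn$obj < -eps)
  }, logical(1))
  list(consistent = model$rxn_ids[ok], index = which(ok),
       blocked = model$rxn_ids[!ok])
}

#' Can a sign pattern be supported by chemical potentials?
#'
#' Energy conservation and the second law require the flux through every
#' active internal reaction to run against its chemical-potential difference:
#' `z_j > 0 => N_j' y < 0` and `z_j < 0 => N_j' y > 0` for a potential vector
#' `y`. Feasibility of `{sigma_j * (N' y)_j <= -eps_pot : sigma_j != 0}` is
#' tested by LP (potentials are scale-free, so the strict inequality is
#' normalized to `<= -1`). When infeasible, the dual alternative is returned:
#' a sign-concordant internal cycle `c` with `N c = 0`, `sigma_j c_j >= 0`,
#' `c != 0` on the active set — exactly one of the two systems is feasible.
#'
#' @param N internal stoichiometric submatrix.
#' @param sigma sign vector over the columns of `N` (`-1`, `0`, `1`).
#' @param eps_pot normalization of the strict inequality (default 1).
#' @inheritParams solve_cardinality
#' @return A list with `feasible`, and either `y` (potential certificate) or
#'   `cycle` (sign-concordant cycle certificate over the columns of `N`).
#' @export
sign_pattern_admits_potentials <- function(N, sigma, eps_pot = 1,
                                           backend = lp_backend()) {
  N <- as_sparse_C(N)
  m <- nrow(N); n <- ncol(N)
  stopifnot(length(sigma) == n, all(sigma %in% c(-1, 0, 1)))
  active <- which(sigma != 0)
  if (length(active) == 0L) {
    return(list(feasible = TRUE, y = rep(0, m), cycle = NULL))
  }
  Na <- N[, active, drop = FALSE]
  sa <- sigma[active]
  # sigma_j * N_j' y <= -eps_pot
  A <- Matrix::Diagonal(x = sa) %*% Matrix::t(Na)
  lp <- lp_problem(rep(0, m), lb = rep(-Inf, m), ub = rep(Inf, m),
                   A = A, sense = "<=", rhs = rep(-eps_pot, length(active)))
  sol <- lp_solve(lp, backend = backend)
  if (sol$status == "optimal") {
    return(list(feasible = TRUE, y = sol$x, cycle = NULL))
  }
  # alternative: c with N c = 0, sigma_j c_j >= 0, sum sigma_j c_j >= 1
  k <- length(active)
  clb <- ifelse(sa > 0, 0, -Inf)
  cub <- ifelse(sa > 0, Inf, 0)
  Ac <- rbind(Na, matrix(sa, 1, k))
  lp2 <- lp_problem(rep(0, k), lb = clb, ub = cub, A = Ac,
                    sense = c(rep("=", m), ">="), rhs = c(rep(0, m), 1))
  sol2 <- lp_solve(lp2, backend = backend)
  cyc <- rep(0, n)
  if (sol2$status == "optimal") cyc[active] <- sol2$x
  list(feasible = FALSE, y = NULL,
       cycle = if (sol2$status == "optimal") cyc else NULL)
}

#' Thermodynamically flux-consistent reaction subset
#'
#' The largest reaction set admitting fluxes that also satisfy energy
#' conservation and the second law is amalgamated from certified
#' thermodynamically consistent flux vectors: (1) propose a flux `v` by
#' cardinality maximization over the uncovered flux-consistent reactions;
#' (2) project `v` onto a cycle-free flux with the same exchange part by
#' minimizing the internal one-norm subject to `N z = -B w` and
#' `sign(z_j) in {0, sign(v_j)}`; (3) certify the resulting sign pattern
#' with a chemical-potential LP ([sign_pattern_admits_potentials()]),
#' deactivating any returned sign-concordant cycle and re-projecting until
#' certified; (4) add the certified support to the covered set. Internal
#' reactions never covered after the rounds are reported thermodynamically
#' flux inconsistent. Because the feasible set is nonconvex the result is an
#' under-estimate of the true maximal set.
#'
#' @param model a [metabolic_model()].
#' @param partition internal/external split; computed when omitted.
#' @param flux precomputed [find_flux_consistent_subset()] result (computed
#'   when omitted); the thermo set is a subset of the flux-consistent set.
#' @param rounds candidate-generation rounds (each seeded perturbation may
#'   cover new reactions).
#' @param eps flux threshold.
#' @param seed seed for the randomized candidate objectives (recorded in the
#'   result).
#' @inheritParams solve_cardinality
#' @return A list with `consistent` (ids, internal and external),
#'   `index`, `inconsistent_internal` (flux-consistent internal reactions
#'   never certified), a per-reaction `directions` tibble (forward/reverse
#'   coverage), and `witnesses` (list of certified `(v, y)` pairs).
#' @export
find_thermo_flux_consistent_subset <- function(model,
                                               partition = split_internal_external(model),
                                               flux = NULL, rounds = 20L,
                                               eps = 1e-6, seed = 1L,
                                               backend = lp_backend(), ...) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(flux)) flux <- find_flux_consistent_subset(model, eps = eps,
                                                         backend = backend)
  n <- ncol(model$S); m <- nrow(model$S)
  internal <- intersect(partition$internal, flux$index)
  external <- intersect(partition$external, flux$index)
  fwd <- rev_ <- logical(n)   # covered directions
  covered <- logical(n)
  witnesses <- list()
  stale <- 0L
  for (round in seq_len(rounds)) {
    todo <- which(!covered & seq_len(n) %in% c(internal, external))
    if (length(todo) == 0L) break
    prob <- cardinality_problem(
      n = n, A = model$S, sense = "=", rhs = model$b,
      lb = model$lb, ub = model$ub,
      maximize = todo, delta = 1, names = model$rxn_ids
    )
    cand <- solve_cardinality(prob, backend = backend,
                              seed = seed + round - 1L, ...)
    if (cand$status == "infeasible") break
    v <- cand$x
    proj <- thermo_project(model, partition, v, eps = eps, backend = backend,
                           prefer = todo)
    newly <- FALSE
    if (!is.null(proj)) {
      newly <- any(proj$active & !covered)
      witnesses[[length(witnesses) + 1L]] <-
        list(v = proj$v, y = proj$y, round = round)
      fwd <- fwd | (proj$v > eps)
      rev_ <- rev_ | (proj$v < -eps)
      covered <- covered | proj$active
    }
    stale <- if (newly) 0L else stale + 1L
    if (stale >= 5L) break
  }
  idx <- which(covered)
  inconsistent_internal <- setdiff(internal, idx)
  structure(list(
    consistent = model$rxn_ids[idx], index = idx,
    inconsistent_internal = model$rxn_ids[inconsistent_internal],
    directions = tibble::tibble(rxn_id = model$rxn_ids,
                                forward = fwd, reverse = rev_),
    witnesses = witnesses, seed = seed,
    flux_consistent_index = sort(c(internal, external))
  ), class = "thermo_subset")
}

# one-norm projection of a candidate flux onto a cycle-free, certified flux
# with the same exchange part; any strictly positive weights remove
# sign-concordant cycles, so reactions in `prefer` get a small weight to keep
# them in the projected support when possible; returns NULL when nothing
# survives
thermo_project <- function(model, partition, v, eps = 1e-6,
                           backend = lp_backend(), max_fix = 25L,
                           prefer = integer(0)) {
  n <- ncol(model$S); m <- nrow(model$S)
  int <- partition$internal
  ext <- partition$external
  allowed <- sign(v) * (abs(v) > eps)   # -1/0/+1 per reaction
  w_ext <- v[ext]
  wt <- ifelse(int %in% prefer, 0.01, 1)
  for (it in seq_len(max_fix)) {
    # variables: [z over internal (n_int), t (n_int) epigraph of |z|]
    ni <- length(int)
    lbz <- ifelse(allowed[int] > 0, 0, ifelse(allowed[int] < 0, model$lb[int], 0))
    ubz <- ifelse(allowed[int] > 0, model$ub[int], ifelse(allowed[int] < 0, 0, 0))
    rhs <- as.numeric(model$b - model$S[, ext, drop = FALSE] %*% w_ext)
    A <- rbind(
      cbind(model$S[, int, drop = FALSE], Matrix::Matrix(0, m, ni)),
      cbind(Matrix::Diagonal(ni), Matrix::Diagonal(ni)),          # t + z >= 0
      cbind(-Matrix::Diagonal(ni), Matrix::Diagonal(ni))          # t - z >= 0
    )
    lp <- lp_problem(c(rep(0, ni), wt),
                     lb = c(lbz, rep(0, ni)), ub = c(ubz, rep(Inf, ni)),
                     A = A, sense = c(rep("=", m), rep(">=", 2L * ni)),
                     rhs = c(rhs, rep(0, 2L * ni)))
    sol <- lp_solve(lp, backend = backend)
    if (sol$status != "optimal") return(NULL)
    z <- sol$x[seq_len(length(int))]
    sigma <- rep(0, length(int))
    sigma[z > eps] <- 1; sigma[z < -eps] <- -1
    cert <- sign_pattern_admits_potentials(model$S[, int, drop = FALSE], sigma,
                                           backend = backend)
    if (cert$feasible) {
      vfull <- numeric(n)
      vfull[int] <- z
      vfull[ext] <- w_ext
      active <- abs(vfull) > eps
      return(list(v = vfull, y = cert$y, active = active))
    }
    # deactivate the reactions on the certified cycle and re-project
    bad <- int[abs(cert$cycle[seq_along(int)]) > eps]
    if (length(bad) == 0L) return(NULL)
    allowed[bad] <- 0
  }
  NULL
}
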