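#' Flux balance analysis
#'
#' Maximizes the linear objective `obj' v` over the steady-state polyhedron
#' `{S v = b, lb <= v <= ub}`.
#'
#' @param model a [metabolic_model()] with a nonzero objective.
#' @param maximize direction (default `TRUE`).
#' @inheritParams solve_cardinality
#' @return A list with `status`, the optimum `rho_star` and a witness flux
#'   `v`. An infeasible status signals a candidate for [relaxed_fba()].
#' @export
fba <- function(model, maximize = TRUE, backend = lp_backend()) {
  stopifnot(inherits(model, "metabolic_model"))
  lp <- lp_problem(model$obj, model$lb, model$ub, A = model$S, sense = "=",
                   rhs = model$b, maximize = maximize)
  sol <- lp_solve(lp, backend = backend)
  list(status = sol$status, rho_star = sol$obj, v = sol$x,
       message = sol$message)
}

#' Sparse flux balance analysis
#'
#' Minimizes the number of nonzero fluxes subject to attainment of the flux
#' balance optimum: `min ||v||_0  s.t.  S v = b, lb <= v <= ub,
#' obj' v >= rho* - feas_tol`. Solved by capped-l1 DCCO; the support is then
#' screened one-at-a-time for removability ([verify_support_minimality()]).
#'
#' @param model a [metabolic_model()] with a nonzero objective.
#' @param approx a [step_approx()].
#' @param feas_tol attainment slack on the optimal objective.
#' @param prune polish the DCCO support by greedily fixing removable members
#'   to zero until the support is locally minimal (default `TRUE`); the
#'   polishing LPs are reported in `prune_lp_count`, separate from the DCA
#'   `lp_count`.
#' @param restarts DCA starts (default 1: a single capped-l1 run needs only
#'   two or three linear optimizations even at genome scale).
#' @inheritParams solve_cardinality
#' @param ... passed to [solve_cardinality()].
#' @return A `sparse_fba` object: `rho_star`, flux `v`, `support` (ids),
#'   `removability` tibble, `lp_count` (outer linear optimizations), and the
#'   underlying `solution`.
#' @export
sparse_fba <- function(model, approx = step_approx("cappedL1", 0.5),
                       feas_tol = 1e-6, prune = TRUE, restarts = 1L,
                       backend = lp_backend(), ...) {
  stopifnot(inherits(model, "metabolic_model"))
  if (all(model$obj == 0)) stop("sparse FBA needs a nonzero objective")
  base <- fba(model, backend = backend)
  if (base$status != "optimal") {
    stop("FBA is ", base$status, "; consider relaxed_fba()")
  }
  n <- ncol(model$S)
  A <- rbind(model$S, matrix(model$obj, 1, n))
  sense <- c(rep("=", nrow(model$S)), ">=")
  rhs <- c(model$b, base$rho_star - feas_tol)
  prob <- cardinality_problem(
    n = n, A = A, sense = sense, rhs = rhs, lb = model$lb, ub = model$ub,
    minimize = seq_len(n), lambda = 1, names = model$rxn_ids
  )
  sol <- solve_cardinality(prob, approx = approx, backend = backend,
                           restarts = restarts, ...)
  support <- sol$support_min
  v <- sol$x
  prune_lps <- 0L
  if (prune && length(support)) {
    # greedily drop members that are removable within the remaining support
    # (all off-support fluxes held at zero), until none is
    zero_ok <- model$lb <= 0 & model$ub >= 0
    repeat {
      dropped <- FALSE
      within_lp <- function(keep) {
        lb <- model$lb; ub <- model$ub
        off <- setdiff(seq_len(n), keep)
        lb[off] <- 0; ub[off] <- 0
        lp_problem(rep(0, n), lb, ub, A = A, sense = sense, rhs = rhs)
      }
      cand <- support[zero_ok[support]]
      if (length(cand)) {
        lps <- lapply(cand, function(j) within_lp(setdiff(support, j)))
        sols <- lp_solve_batch(lps, backend = backend)
        prune_lps <- prune_lps + length(lps)
        ok <- which(vapply(sols, function(s) s$status == "optimal", logical(1)))
        if (length(ok)) {
          j <- cand[ok[1]]
          v <- sols[[ok[1]]]$x
          support <- setdiff(support, j)
          support <- support[abs(v[support]) > 1e-6 |
                               model$lb[support] > 0 | model$ub[support] < 0]
          dropped <- TRUE
        }
      }
      if (!dropped) break
    }
  }
  removability <- verify_support_minimality(prob, support, backend = backend)
  structure(list(
    rho_star = base$rho_star, v = v,
    support = model$rxn_ids[support],
    support_index = support,
    removability = removability,
    lp_count = sol$lp_count, prune_lp_count = prune_lps, solution = sol
  ), class = "sparse_fba")
}

#' @export
print.sparse_fba <- function(x, ...) {
  cat(sprintf("<sparse_fba: rho* = %g, |support| = %d (%d removable), %d LPs>\n",
              x$rho_star, length(x$support), sum(x$removability$removable),
              x$lp_count))
  invisible(x)
}

#' Minimal stoichiometrically balanced cycle admitting isolated hydrolysis
#'
#' With every external reaction closed (bounds zeroed), the only admissible
#' net flux runs around stoichiometrically balanced cycles. Requiring at
#' least unit flux through an energy-dissipating reaction (typically
#' cytoplasmic ATP hydrolysis, `atp + h2o -> adp + pi + h`) while minimizing
#' the cardinality of the internal fluxes either exposes a minimal cycle
#' that regenerates ATP for free — thermodynamically infeasible and a bug in
#' the bounds — or proves no such cycle exists (`"none"`, the desired
#' state). Converting one reversible cycle member to irreversible removes
#' the cycle.
#'
#' @param model a [metabolic_model()].
#' @param hydrolysis_rxn id of the hydrolysis (dissipation) reaction.
#' @param partition internal/external split; computed when omitted.
#' @inheritParams solve_cardinality
#' @param ... passed to [solve_cardinality()].
#' @return `"none"` (character) when no cycle admits isolated hydrolysis;
#'   otherwise a list with the cycle `rxns`, the flux mode `v` and the
#'   underlying solution.
#' @export
atp_cycle_test <- function(model, hydrolysis_rxn,
                           partition = split_internal_external(model),
                           backend = lp_backend(), ...) {
  stopifnot(inherits(model, "metabolic_model"))
  j <- match(hydrolysis_rxn, model$rxn_ids)
  if (is.na(j)) stop("no reaction with id `", hydrolysis_rxn, "` in the model")
  work <- close_externals(model, partition)
  lb <- work$lb; ub <- work$ub
  lb[j] <- 1                      # force unit hydrolysis (scale-invariant)
  ub[j] <- max(ub[j], 1)
  prob <- cardinality_problem(
    n = ncol(work$S), A = work$S, sense = "=", rhs = work$b,
    lb = lb, ub = ub,
    minimize = setdiff(partition$internal, j), lambda = 1,
    names = model$rxn_ids
  )
  sol <- solve_cardinality(prob, backend = backend, ...)
  if (sol$status == "infeasible") return("none")
  support <- sort(union(sol$support_min, j))
  list(rxns = model$rxn_ids[support], v = sol$x, solution = sol)
}

#' Relaxed flux balance analysis
#'
#' When the flux balance problem is infeasible, finds a minimum-cardinality
#' set of constraints to relax: `min lambda ||r||_0 + alpha ||p||_0 +
#' alpha ||q||_0  s.t.  S v + r = b, lb - p <= v <= ub + q, p, q >= 0`,
#' where `p`/`q` relax lower/upper flux bounds and `r` relaxes steady-state
#' (mass balance) rows. Weights apply globally or per constraint.
#' Steady-state relaxation is off by default (`allow_r = FALSE`): relaxing
#' mass balance conceals stoichiometric errors and is opt-in.
#'
#' @param model a [metabolic_model()].
#' @param lambda weight(s) on steady-state relaxations (length 1 or `m`).
#' @param alpha weight(s) on bound relaxations (length 1 or `n`).
#' @param allow_r,allow_p,allow_q enable each relaxation class.
#' @param feas_tol relaxations below this are reported as zero.
#' @inheritParams solve_cardinality
#' @param ... passed to [solve_cardinality()].
#' @return A `relaxation_solution`: vectors `v`, `r`, `p`, `q`, tibbles of
#'   the nonzero relaxations, the `relaxed_model`, and the DCCO `solution`.
#' @export
relaxed_fba <- function(model, lambda = 1, alpha = 1, allow_r = FALSE,
                        allow_p = TRUE, allow_q = TRUE, feas_tol = 1e-6,
                        backend = lp_backend(), ...) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- nrow(model$S); n <- ncol(model$S)
  lambda <- rep_len(lambda, m); alpha <- rep_len(alpha, n)
  if (!allow_r && !allow_p && !allow_q) stop("no relaxation class allowed")
  # variables: [v (n), r (m), p (n), q (n)]
  ntot <- n + m + 2L * n
  iv <- seq_len(n); ir <- n + seq_len(m); ip <- n + m + seq_len(n)
  iq <- n + m + n + seq_len(n)
  fin_l <- which(is.finite(model$lb)); fin_u <- which(is.finite(model$ub))
  Dl <- Matrix::Diagonal(n)[fin_l, , drop = FALSE]
  Du <- Matrix::Diagonal(n)[fin_u, , drop = FALSE]
  A <- rbind(
    cbind(model$S, Matrix::Diagonal(m), Matrix::Matrix(0, m, 2L * n)),
    cbind(Dl, Matrix::Matrix(0, length(fin_l), m), Dl,
          Matrix::Matrix(0, length(fin_l), n)),          # v + p >= lb
    cbind(Du, Matrix::Matrix(0, length(fin_u), m),
          Matrix::Matrix(0, length(fin_u), n), -Du)      # v - q <= ub
  )
  sense <- c(rep("=", m), rep(">=", length(fin_l)), rep("<=", length(fin_u)))
  rhs <- c(model$b, model$lb[fin_l], model$ub[fin_u])
  lb <- c(rep(-Inf, n), if (allow_r) rep(-Inf, m) else rep(0, m), rep(0, 2L * n))
  ub <- c(rep(Inf, n), if (allow_r) rep(Inf, m) else rep(0, m),
          if (allow_p) rep(Inf, n) else rep(0, n),
          if (allow_q) rep(Inf, n) else rep(0, n))
  minimize <- c(if (allow_r) ir else integer(0),
                if (allow_p) ip else integer(0),
                if (allow_q) iq else integer(0))
  wts <- c(if (allow_r) lambda else numeric(0),
           if (allow_p) alpha else numeric(0),
           if (allow_q) alpha else numeric(0))
  prob <- cardinality_problem(
    n = ntot, A = A, sense = sense, rhs = rhs, lb = lb, ub = ub,
    minimize = minimize, lambda = wts,
    names = c(model$rxn_ids, paste0("r_", model$met_ids),
              paste0("p_", model$rxn_ids), paste0("q_", model$rxn_ids))
  )
  sol <- solve_cardinality(prob, backend = backend, ...)
  if (sol$status == "infeasible") {
    stop("relaxation problem infeasible; enable more relaxation classes")
  }
  clean <- function(x) ifelse(abs(x) < feas_tol, 0, x)
  v <- sol$x[iv]; r <- clean(sol$x[ir])
  p <- clean(pmax(sol$x[ip], 0)); q <- clean(pmax(sol$x[iq], 0))
  relaxed <- model
  relaxed$lb <- model$lb - p
  relaxed$ub <- model$ub + q
  relaxed$b <- model$b - r
  recheck <- lp_solve(lp_problem(rep(0, n), relaxed$lb, relaxed$ub,
                                 A = relaxed$S, sense = "=", rhs = relaxed$b),
                      backend = backend)
  structure(list(
    v = v, r = r, p = p, q = q,
    lambda = lambda, alpha = alpha,
    relaxed_bounds = tibble::tibble(
      rxn_id = model$rxn_ids,
      lower_relax = p, upper_relax = q
    ) |> dplyr::filter(.data$lower_relax > 0 | .data$upper_relax > 0),
    relaxed_steady_state = tibble::tibble(
      met_id = model$met_ids, relax = r
    ) |> dplyr::filter(.data$relax != 0),
    total_card = sum(r != 0) + sum(p > 0) + sum(q > 0),
    relaxed_model = relaxed,
    relaxed_feasible = recheck$status == "optimal",
    solution = sol
  ), class = "relaxation_solution")
}

#' @export
print.relaxation_solution <- function(x, ...) {
  cat(sprintf(
    "<relaxation_solution: %d steady-state, %d lower-bound, %d upper-bound relaxations; relaxed model %s>\n",
    sum(x$r != 0), sum(x$p > 0), sum(x$q > 0),
    if (x$relaxed_feasible) "feasible" else "STILL INFEASIBLE"))
  invisible(x)
}
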