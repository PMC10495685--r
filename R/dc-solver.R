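#' Cardinality optimization problem over a polyhedron
#'
#' Describes `min sum(lambda_j * step(x_j)) - sum(delta_j * step(y_j)) + cost'v`
#' over `A v (sense) rhs`, `lb <= v <= ub`, where the `minimize` block `x` is
#' the set of variables whose support is penalized, the `maximize` block `y`
#' is the set whose support is rewarded, and all remaining variables enter
#' only through the linear `cost`. Entries of the cardinality blocks with
#' zero weight are treated as free variables (dropped from the block).
#'
#' @param n number of variables.
#' @param A,sense,rhs linear constraints as in [lp_problem()]; `A` may be `NULL`.
#' @param lb,ub variable bounds.
#' @param minimize,maximize integer indices of the two cardinality blocks
#'   (disjoint).
#' @param lambda,delta nonnegative weights, recycled over the respective block.
#' @param cost linear cost over all variables (default 0).
#' @param names optional variable names (used in reports).
#' @return A `cardinality_problem` object.
#' @export
cardinality_problem <- function(n, A = NULL, sense = character(), rhs = numeric(),
                                lb, ub, minimize = integer(), maximize = integer(),
                                lambda = 1, delta = 1, cost = 0, names = NULL) {
  stopifnot(length(lb) == n, length(ub) == n, all(lb <= ub))
  minimize <- as.integer(minimize); maximize <- as.integer(maximize)
  if (length(intersect(minimize, maximize))) {
    stop("minimize and maximize blocks must be disjoint")
  }
  lambda <- rep_len(as.numeric(lambda), length(minimize))
  delta <- rep_len(as.numeric(delta), length(maximize))
  if (any(lambda < 0) || any(delta < 0)) stop("cardinality weights must be >= 0")
  keep <- lambda > 0
  minimize <- minimize[keep]; lambda <- lambda[keep]
  keep <- delta > 0
  maximize <- maximize[keep]; delta <- delta[keep]
  cost <- rep_len(as.numeric(cost), n)
  if (!is.null(A)) {
    A <- as_sparse_T(A)
    stopifnot(ncol(A) == n, length(rhs) == nrow(A))
    sense <- rep_len(sense, nrow(A))
  }
  structure(
    list(n = n, A = A, sense = sense, rhs = as.numeric(rhs),
         lb = as.numeric(lb), ub = as.numeric(ub),
         minimize = minimize, maximize = maximize,
         lambda = lambda, delta = delta, cost = cost,
         names = names %||% paste0("v", seq_len(n))),
    class = "cardinality_problem"
  )
}

#' @export
print.cardinality_problem <- function(x, ...) {
  cat(sprintf(
    "<cardinality_problem: %d vars, %d rows, |min block| = %d, |max block| = %d>\n",
    x$n, if (is.null(x$A)) 0L else nrow(x$A), length(x$minimize),
    length(x$maximize)))
  invisible(x)
}

# stack the problem rows with the epigraph rows for |x| and max(theta|y|, 1).
# variable layout: [v (n), a (nmin), e (nmax)]
dcco_lp_skeleton <- function(prob, theta) {
  n <- prob$n
  nmin <- length(prob$minimize); nmax <- length(prob$maximize)
  ntot <- n + nmin + nmax
  ti <- list(); tj <- list(); tx <- list()
  sense <- character(); rhs <- numeric()
  row0 <- 0L
  if (!is.null(prob$A) && nrow(prob$A) > 0L) {
    ti[[1]] <- prob$A@i; tj[[1]] <- prob$A@j; tx[[1]] <- prob$A@x
    sense <- prob$sense; rhs <- prob$rhs
    row0 <- nrow(prob$A)
  }
  add_rows <- function(i, j, x, sn, rh) {
    ti[[length(ti) + 1L]] <<- i; tj[[length(tj) + 1L]] <<- j
    tx[[length(tx) + 1L]] <<- x
    sense <<- c(sense, sn); rhs <<- c(rhs, rh)
  }
  if (nmin > 0L) {
    # a_k - x_j >= 0 and a_k + x_j >= 0
    k <- seq_len(nmin)
    acol <- n + k - 1L
    xcol <- prob$minimize - 1L
    add_rows(i = c(row0 + k - 1L, row0 + k - 1L,
                   row0 + nmin + k - 1L, row0 + nmin + k - 1L),
             j = c(acol, xcol, acol, xcol),
             x = c(rep(1, nmin), rep(-1, nmin), rep(1, nmin), rep(1, nmin)),
             sn = rep(">=", 2L * nmin), rh = rep(0, 2L * nmin))
    row0 <- row0 + 2L * nmin
  }
  if (nmax > 0L) {
    # e_k - theta y_j >= 0 and e_k + theta y_j >= 0 (e_k >= 1 via its bound)
    k <- seq_len(nmax)
    ecol <- n + nmin + k - 1L
    ycol <- prob$maximize - 1L
    add_rows(i = c(row0 + k - 1L, row0 + k - 1L,
                   row0 + nmax + k - 1L, row0 + nmax + k - 1L),
             j = c(ecol, ycol, ecol, ycol),
             x = c(rep(1, nmax), rep(-theta, nmax), rep(1, nmax),
                   rep(theta, nmax)),
             sn = rep(">=", 2L * nmax), rh = rep(0, 2L * nmax))
    row0 <- row0 + 2L * nmax
  }
  A <- Matrix::sparseMatrix(i = unlist(ti) + 1L, j = unlist(tj) + 1L,
                            x = unlist(tx), dims = c(row0, ntot))
  lb <- c(prob$lb, rep(0, nmin), rep(1, nmax))
  ub <- c(prob$ub, rep(Inf, nmin), rep(Inf, nmax))
  list(A = A, sense = sense, rhs = rhs, lb = lb, ub = ub, ntot = ntot)
}

# approximate objective F_theta(v): weighted psi on min block, co-step on max
# block, plus the linear cost
dcco_objective <- function(prob, approx, v) {
  val <- sum(prob$cost * v)
  if (length(prob$minimize)) {
    val <- val + sum(prob$lambda * step_r(approx, abs(v[prob$minimize])))
  }
  if (length(prob$maximize)) {
    val <- val + sum(prob$delta * (1 - step_r(approx, abs(v[prob$maximize]))))
  }
  val
}

#' Solve a cardinality optimization problem by DCA over LPs
#'
#' Approximates the step functions with the chosen family, splits the
#' objective into a difference of convex functions, and at each outer
#' iteration linearizes the subtracted component at the incumbent, yielding a
#' linear subproblem (the convex parts used here are LP-representable via
#' epigraph variables). The sharpness `theta` is increased geometrically
#' between outer iterations (progressive sharpening). The first iterate comes
#' from the weighted one-norm LP on the minimized block — the convex l1
#' relaxation — with a seeded random-sign objective on the maximized block.
#'
#' @param prob a [cardinality_problem()].
#' @param approx a [step_approx()]; its `theta` is the starting sharpness.
#' @param theta_factor multiplicative sharpness update per outer iteration.
#' @param theta_max sharpness cap.
#' @param tol stop when the support sets are unchanged and the approximate
#'   objective moves by less than `tol` between iterations.
#' @param max_outer outer iteration cap.
#' @param eps_supp support threshold: `|v| > eps_supp` counts as nonzero.
#' @param backend LP backend name (see [lp_backend()]).
#' @param seed seed for the randomized initializations.
#' @param restarts number of seeded DCA starts; the first uses the plain
#'   one-norm initialization, later ones perturb its weights, and the start
#'   with the lowest weighted exact cardinality objective wins. DCA is a
#'   local method, so a few restarts noticeably improve the support quality;
#'   set `restarts = 1` when the LP count itself is of interest.
#' @return A `cardinality_solution` with fields `x` (all variables),
#'   `support_min`, `support_max` (indices into the problem variables),
#'   `trace` (approximate objective per outer iteration of the winning
#'   start), `descent` (DCA descent margins pooled over all starts,
#'   theoretically `<= 0`), `iterations`, `lp_count` (total LPs across
#'   starts), `status`, and `feas_violation`.
#' @export
solve_cardinality <- function(prob, approx = step_approx("cappedL1", theta = 0.5),
                              theta_factor = 1.5, theta_max = 1e3, tol = 1e-6,
                              max_outer = 50L, eps_supp = 1e-6,
                              backend = lp_backend(), seed = 1L,
                              restarts = 3L) {
  stopifnot(inherits(prob, "cardinality_problem"), inherits(approx, "step_approx"))
  if (length(prob$maximize) > 0L && approx$kind != "cappedL1") {
    dc_decompose(approx, "maximize") # raises the informative error
  }
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    # later starts perturb the l1 weights and sharpen the initial theta, so
    # the local searches explore different basins
    ap_r <- if (r > 1L) step_with_theta(approx, approx$theta * 4^(r - 1L)) else approx
    runs[[r]] <- dcco_once(prob, ap_r, theta_factor, theta_max, tol,
                           max_outer, eps_supp, backend,
                           seed = seed + (r - 1L) * 1009L,
                           perturb = r > 1L)
    if (runs[[r]]$status == "infeasible") {
      sol <- runs[[r]]
      sol$lp_count <- sum(vapply(runs[seq_len(r)], `[[`, integer(1),
                                 "lp_count"))
      return(sol)
    }
  }
  # exact (limit) objective of each start: weighted supports + linear cost
  score <- vapply(runs, function(s) {
    sum(prob$lambda[match(s$support_min, prob$minimize)]) -
      sum(prob$delta[match(s$support_max, prob$maximize)]) +
      sum(prob$cost * s$x)
  }, numeric(1))
  best <- runs[[which.min(score)]]
  best$descent <- unlist(lapply(runs, `[[`, "descent"))
  best$lp_count <- sum(vapply(runs, `[[`, integer(1), "lp_count"))
  best$restarts <- restarts
  if (restarts > 1L && length(best$support_min)) {
    best <- dcco_polish_min(prob, best, backend)
  }
  best
}

# greedy local-minimality polish of a minimized-block support: drop members
# whose removal (with all off-support block variables held at zero) leaves
# the problem feasible, preferring the costliest members first
dcco_polish_min <- function(prob, sol, backend) {
  support <- sol$support_min
  x <- sol$x
  eps <- sol$eps_supp
  repeat {
    ord <- order(-prob$lambda[match(support, prob$minimize)])
    rem <- verify_support_minimality(prob, support[ord], backend = backend)
    drop <- rem$index[rem$removable]
    if (length(drop) == 0L) break
    j <- drop[1]
    lb <- prob$lb; ub <- prob$ub
    off <- setdiff(prob$minimize, setdiff(support, j))
    off <- off[prob$lb[off] <= 0 & prob$ub[off] >= 0]
    lb[off] <- 0; ub[off] <- 0
    re <- lp_solve(lp_problem(rep(0, prob$n), lb, ub, A = prob$A,
                              sense = prob$sense, rhs = prob$rhs),
                   backend = backend)
    if (re$status != "optimal") break
    x <- re$x
    support <- setdiff(support, j)
    support <- support[abs(x[support]) > eps |
                         prob$lb[support] > 0 | prob$ub[support] < 0]
  }
  sol$x <- x
  sol$support_min <- sort(support)
  sol$feas_violation <- constraint_violation(prob, x)
  sol
}

# one DCA run: l1-type initialization, then linearize-and-solve outer loop
# with geometric sharpening of theta
dcco_once <- function(prob, approx, theta_factor, theta_max, tol, max_outer,
                      eps_supp, backend, seed, perturb = FALSE) {
  n <- prob$n
  nmin <- length(prob$minimize); nmax <- length(prob$maximize)
  theta <- approx$theta
  wmin <- if (perturb) {
    1 + with_preserved_rng(seed + 1L, runif(nmin, 0, 1))
  } else rep(1, nmin)

  build_obj <- function(theta, h, g, init) {
    ap <- step_with_theta(approx, theta)
    s0 <- step_s0(ap)
    obj <- c(prob$cost, rep(0, nmin + nmax))
    if (nmin) {
      obj[prob$minimize] <- obj[prob$minimize] - prob$lambda * h
      obj[n + seq_len(nmin)] <- s0 * prob$lambda *
        (if (init) wmin else rep(1, nmin))
    }
    if (nmax) {
      obj[prob$maximize] <- obj[prob$maximize] - prob$delta * g
      obj[n + nmin + seq_len(nmax)] <- prob$delta
    }
    obj
  }

  support <- function(v) {
    list(mn = prob$minimize[abs(v[prob$minimize]) > eps_supp],
         mx = prob$maximize[abs(v[prob$maximize]) > eps_supp])
  }

  trace <- numeric(0); descent <- numeric(0)
  lp_count <- 0L
  v_prev <- NULL; supp_prev <- NULL
  status <- "iteration-limit"

  for (k in seq_len(max_outer)) {
    ap_k <- step_with_theta(approx, theta)
    s0 <- step_s0(ap_k)
    init <- is.null(v_prev)
    if (init) {
      h <- rep(0, nmin)
      g <- if (nmax) {
        # push each maximized variable toward the bound with more headroom;
        # a seeded jitter diversifies supports across restarts, and for
        # reversible (two-sided) variables it is wide enough to flip the
        # favored direction between restarts
        ylb <- prob$lb[prob$maximize]; yub <- prob$ub[prob$maximize]
        base <- ifelse(pmin(yub, 1e4) + pmax(ylb, -1e4) >= 0, 1, -1)
        two_sided <- ylb < 0 & yub > 0
        jit <- with_preserved_rng(seed, runif(nmax, -1, 1)) *
          ifelse(two_sided, 1.5, 0.4)
        theta * (base + jit)
      } else numeric(0)
    } else {
      h <- if (nmin) {
        t_ <- v_prev[prob$minimize]
        sign(t_) * (s0 - step_rprime(ap_k, abs(t_)))
      } else numeric(0)
      g <- if (nmax) theta * sign(v_prev[prob$maximize]) else numeric(0)
    }
    skel <- dcco_lp_skeleton(prob, theta)
    lb <- skel$lb; ub <- skel$ub
    if (init) {
      # clip cardinality-block bounds in the initialization LP so the
      # random-sign reward cannot make it unbounded
      blk <- c(prob$minimize, prob$maximize)
      lb[blk] <- pmax(lb[blk], -1e4); ub[blk] <- pmin(ub[blk], 1e4)
    }
    lp <- lp_problem(build_obj(theta, h, g, init), lb, ub, A = skel$A,
                     sense = skel$sense, rhs = skel$rhs)
    sol <- lp_solve(lp, backend = backend)
    lp_count <- lp_count + 1L
    if (sol$status == "infeasible") {
      return(new_cardinality_solution(prob, NULL, trace, descent, k, lp_count,
                                      "infeasible", eps_supp, approx, backend,
                                      message = sol$message))
    }
    if (sol$status == "unbounded") {
      stop("DCCO subproblem unbounded: the linear-cost block is malformed ",
           "(cardinality objectives are bounded)")
    }
    if (sol$status != "optimal") {
      stop("LP backend failure in DCCO: ", sol$status, " (", sol$message, ")")
    }
    v <- sol$x[seq_len(n)]
    f_new <- dcco_objective(prob, ap_k, v)
    trace <- c(trace, f_new)
    if (!init) {
      descent <- c(descent, f_new - dcco_objective(prob, ap_k, v_prev))
    }
    supp <- support(v)
    if (!is.null(supp_prev) &&
        identical(supp$mn, supp_prev$mn) && identical(supp$mx, supp_prev$mx) &&
        length(descent) && abs(descent[length(descent)]) < tol) {
      v_prev <- v
      status <- "optimal-approx"
      break
    }
    v_prev <- v; supp_prev <- supp
    theta <- min(theta * theta_factor, theta_max)
  }
  new_cardinality_solution(prob, v_prev, trace, descent,
                           iterations = length(trace), lp_count = lp_count,
                           status = status, eps_supp = eps_supp,
                           approx = approx, backend = backend)
}

new_cardinality_solution <- function(prob, v, trace, descent, iterations,
                                     lp_count, status, eps_supp, approx,
                                     backend, message = NULL) {
  viol <- NA_real_
  supp_min <- supp_max <- integer(0)
  if (!is.null(v)) {
    viol <- constraint_violation(prob, v)
    supp_min <- prob$minimize[abs(v[prob$minimize]) > eps_supp]
    supp_max <- prob$maximize[abs(v[prob$maximize]) > eps_supp]
  }
  structure(
    list(x = v, support_min = supp_min, support_max = supp_max,
         trace = trace, descent = descent, iterations = iterations,
         lp_count = lp_count, status = status, eps_supp = eps_supp,
         approx = approx, backend = backend, feas_violation = viol,
         message = message, problem = prob),
    class = "cardinality_solution"
  )
}

constraint_violation <- function(prob, v) {
  viol <- max(c(0, prob$lb - v, v - prob$ub))
  if (!is.null(prob$A) && nrow(prob$A) > 0L) {
    Av <- as.numeric(prob$A %*% v)
    d <- numeric(length(Av))
    d[prob$sense == "="] <- abs(Av - prob$rhs)[prob$sense == "="]
    d[prob$sense == "<="] <- pmax(0, Av - prob$rhs)[prob$sense == "<="]
    d[prob$sense == ">="] <- pmax(0, prob$rhs - Av)[prob$sense == ">="]
    viol <- max(viol, d)
  }
  viol
}

#' @export
print.cardinality_solution <- function(x, ...) {
  cat(sprintf(
    "<cardinality_solution: status %s, |supp(min)| = %d, |supp(max)| = %d, %d LPs>\n",
    x$status, length(x$support_min), length(x$support_max), x$lp_count))
  invisible(x)
}

#' Exact minimum-cardinality oracle by support enumeration
#'
#' Enumerates supports of the minimized block in increasing size; for each
#' candidate support the off-support variables are fixed to zero and an LP
#' feasibility problem is solved. The first feasible size is the exact
#' minimum cardinality. Exponential in the block size — a verification oracle
#' for small instances, mirroring a mixed-integer check.
#'
#' @param prob a [cardinality_problem()] with an empty maximize block.
#' @param max_n refuse problems with more than this many cardinality
#'   variables (default 20).
#' @inheritParams solve_cardinality
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `card`,
#'   `support` and a `witness` vector.
#' @export
brute_force_min_card <- function(prob, max_n = 20L, backend = lp_backend()) {
  stopifnot(inherits(prob, "cardinality_problem"))
  if (length(prob$maximize) > 0L) {
    stop("the brute-force oracle handles cardinality minimization only")
  }
  blk <- prob$minimize
  if (length(blk) > max_n) stop("too many cardinality variables for enumeration")
  # excluding a variable whose bounds forbid zero is infeasible outright
  zero_ok <- prob$lb <= 0 & prob$ub >= 0
  base_lp <- function(off) {
    if (!all(zero_ok[off])) return(NULL)
    lb <- prob$lb; ub <- prob$ub
    lb[off] <- 0; ub[off] <- 0
    lp_problem(rep(0, prob$n), lb, ub, A = prob$A, sense = prob$sense,
               rhs = prob$rhs)
  }
  for (size in 0:length(blk)) {
    supports <- if (size == 0L) list(integer(0)) else {
      lapply(asplit(utils::combn(seq_along(blk), size), 2L),
             function(ii) blk[ii])
    }
    lps <- lapply(supports, function(s) base_lp(setdiff(blk, s)))
    keep <- !vapply(lps, is.null, logical(1))
    supports <- supports[keep]; lps <- lps[keep]
    if (length(lps) == 0L) next
    for (chunk in split(seq_along(lps), ceiling(seq_along(lps) / 512))) {
      sols <- lp_solve_batch(lps[chunk], backend = backend)
      ok <- which(vapply(sols, function(s) s$status == "optimal", logical(1)))
      if (length(ok)) {
        idx <- chunk[ok[1]]
        return(list(status = "optimal", card = size,
                    support = sort(as.integer(supports[[idx]])),
                    witness = sols[[ok[1]]]$x))
      }
    }
  }
  list(status = "infeasible", card = NA_integer_, support = integer(0),
       witness = NULL)
}

#' Test a candidate support for one-at-a-time removability
#'
#' For each member of the support, that variable and every cardinality-block
#' variable outside the support are fixed to zero (all other constraints,
#' including any objective-attainment rows, are kept) and feasibility is
#' re-tested. A member is removable when the remaining support alone still
#' satisfies the problem; the support is locally minimal iff no member is
#' removable.
#'
#' @param prob a [cardinality_problem()] (or any problem whose constraints
#'   encode attainment).
#' @param support integer indices of the candidate support, or a
#'   `cardinality_solution` whose minimized-block support is used.
#' @inheritParams solve_cardinality
#' @return A tibble with `index`, `name`, `removable`.
#' @export
verify_support_minimality <- function(prob, support, backend = lp_backend()) {
  stopifnot(inherits(prob, "cardinality_problem"))
  if (inherits(support, "cardinality_solution")) support <- support$support_min
  support <- as.integer(support)
  if (length(support) == 0L) {
    return(tibble::tibble(index = integer(0), name = character(0),
                          removable = logical(0)))
  }
  off <- setdiff(prob$minimize, support)
  off <- off[prob$lb[off] <= 0 & prob$ub[off] >= 0]
  zero_ok <- prob$lb[support] <= 0 & prob$ub[support] >= 0
  removable <- logical(length(support))
  if (any(zero_ok)) {
    lps <- lapply(support[zero_ok], function(j) {
      lb <- prob$lb; ub <- prob$ub
      lb[c(off, j)] <- 0; ub[c(off, j)] <- 0
      lp_problem(rep(0, prob$n), lb, ub, A = prob$A, sense = prob$sense,
                 rhs = prob$rhs)
    })
    sols <- lp_solve_batch(lps, backend = backend)
    removable[zero_ok] <- vapply(sols, function(s) s$status == "optimal",
                                 logical(1))
  }
  tibble::tibble(index = support, name = prob$names[support],
                 removable = removable)
}
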