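#' @importFrom methods as is new
#' @importFrom stats runif setNames
#' @importFrom utils head modifyList
NULL

.cardopt <- new.env(parent = emptyenv())

BIG_BOUND <- 1e30

#' Linear program container
#'
#' A minimal description of a linear program in the form
#' `optimize c'x  s.t.  A x (sense) rhs,  lb <= x <= ub`, where `sense` is a
#' character vector over `"="`, `"<="`, `">="`. All solver calls in the
#' package go through this container so that the LP backend can be swapped
#' (see [lp_solve()]).
#'
#' @param obj numeric objective vector (length `n`).
#' @param lb,ub numeric bound vectors; `-Inf`/`Inf` allowed.
#' @param A constraint matrix (dense or `Matrix` sparse), or `NULL`.
#' @param sense character vector of constraint senses, one of `"="`, `"<="`,
#'   `">="`, recycled to `nrow(A)`.
#' @param rhs numeric right-hand side, length `nrow(A)`.
#' @param maximize logical; `TRUE` maximizes `obj`.
#' @return An object of class `lp_problem`.
#' @export
lp_problem <- function(obj, lb, ub, A = NULL, sense = character(), rhs = numeric(),
                       maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (!is.null(A)) {
    A <- as_sparse_T(A)
    stopifnot(ncol(A) == n, length(rhs) == nrow(A))
    sense <- rep_len(sense, nrow(A))
    stopifnot(all(sense %in% c("=", "<=", ">=")))
  }
  structure(
    list(obj = as.numeric(obj), lb = as.numeric(lb), ub = as.numeric(ub),
         A = A, sense = sense, rhs = as.numeric(rhs),
         maximize = isTRUE(maximize)),
    class = "lp_problem"
  )
}

#' Get or set the LP backend
#'
#' Two concrete backends are provided: `"highs"` (the default) solves through
#' the HiGHS implementation in SciPy's `linprog`, run in a persistent Python
#' worker process, and `"dense"` is a pure-R dense two-phase tableau simplex
#' (Bland's rule), suitable for small instances and cross-checks.
#'
#' @param backend `NULL` to query, or one of `"highs"`, `"dense"` to set.
#' @return The active backend name, invisibly when setting.
#' @export
lp_backend <- function(backend = NULL) {
  if (is.null(backend)) {
    return(getOption("cardopt.lp_backend", "highs"))
  }
  backend <- match.arg(backend, c("highs", "dense"))
  options(cardopt.lp_backend = backend)
  invisible(backend)
}

#' Solve one linear program
#'
#' @param lp an [lp_problem()].
#' @param backend backend name; defaults to [lp_backend()].
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"limit"` or `"error"`), `x`, `obj` and the backend `message`.
#' @export
lp_solve <- function(lp, backend = lp_backend()) {
  lp_solve_batch(list(lp), backend = backend)[[1L]]
}

#' Solve a batch of linear programs
#'
#' Batching amortizes the round trip to the solver worker; all problems are
#' independent.
#'
#' @param lps list of [lp_problem()] objects.
#' @inheritParams lp_solve
#' @return A list of solution lists, one per problem (see [lp_solve()]).
#' @export
lp_solve_batch <- function(lps, backend = lp_backend()) {
  stopifnot(all(vapply(lps, inherits, logical(1), "lp_problem")))
  if (length(lps) == 0L) return(list())
  switch(match.arg(backend, c("highs", "dense")),
    highs = lp_solve_highs(lps),
    dense = lapply(lps, lp_solve_dense)
  )
}

## ---- canonical minimize form -----------------------------------------------

# Split constraint rows into equality and <= triplets (>= rows negated),
# objective negated when maximizing.
lp_canonical <- function(lp) {
  n <- length(lp$obj)
  obj <- if (lp$maximize) -lp$obj else lp$obj
  eq <- le <- NULL
  if (!is.null(lp$A) && nrow(lp$A) > 0L) {
    A <- lp$A
    i <- A@i; j <- A@j; x <- A@x
    row_sense <- lp$sense
    keep_eq <- row_sense == "="
    keep_le <- row_sense == "<="
    keep_ge <- row_sense == ">="
    pick <- function(keep, flip) {
      rows <- which(keep)
      if (length(rows) == 0L) return(NULL)
      sel <- A@i %in% (rows - 1L)
      remap <- integer(nrow(A)); remap[rows] <- seq_along(rows)
      sgn <- if (flip) -1 else 1
      list(m = length(rows), i = remap[A@i[sel] + 1L] - 1L, j = A@j[sel],
           x = sgn * A@x[sel], rhs = sgn * lp$rhs[rows])
    }
    eq <- pick(keep_eq, flip = FALSE)
    le1 <- pick(keep_le, flip = FALSE)
    le2 <- pick(keep_ge, flip = TRUE)
    le <- if (is.null(le1)) le2 else if (is.null(le2)) le1 else {
      list(m = le1$m + le2$m, i = c(le1$i, le2$i + le1$m), j = c(le1$j, le2$j),
           x = c(le1$x, le2$x), rhs = c(le1$rhs, le2$rhs))
    }
  }
  list(n = n, c = obj, lb = lp$lb, ub = lp$ub, eq = eq, le = le)
}

## ---- HiGHS worker backend --------------------------------------------------

lp_python <- function() {
  p <- getOption("cardopt.python", Sys.which("python"))
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no `python` interpreter found for the highs backend; ",
                       "use lp_backend(\"dense\") or set options(cardopt.python=)")
  p
}

lp_worker <- function() {
  w <- .cardopt$worker
  if (!is.null(w) && w$is_alive()) return(w)
  server <- system.file("python", "lp_server.py", package = "cardopt",
                        mustWork = TRUE)
  w <- processx::process$new(lp_python(), c("-u", server),
                             stdin = "|", stdout = "|", stderr = "|")
  .cardopt$worker <- w
  w
}

#' Shut down the background LP worker
#'
#' The HiGHS backend keeps one Python worker alive per session; this stops it.
#' It restarts on demand.
#' @return Invisibly `TRUE`.
#' @export
lp_worker_stop <- function() {
  w <- .cardopt$worker
  if (!is.null(w) && w$is_alive()) {
    try(w$write_input('{"cmd": "quit"}\n'), silent = TRUE)
    try(w$wait(500), silent = TRUE)
    try(w$kill(), silent = TRUE)
  }
  .cardopt$worker <- NULL
  invisible(TRUE)
}

worker_request <- function(payload) {
  w <- lp_worker()
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  w$write_input(paste0(json, "\n"))
  buf <- ""
  deadline <- Sys.time() + getOption("cardopt.lp_timeout", 600)
  while (!grepl("\n", buf, fixed = TRUE)) {
    if (!w$is_alive()) {
      err <- tryCatch(w$read_all_error(), error = function(e) "")
      .cardopt$worker <- NULL
      stop("LP worker died: ", err)
    }
    if (Sys.time() > deadline) {
      lp_worker_stop()
      stop("LP worker timed out")
    }
    w$poll_io(1000)
    buf <- paste0(buf, w$read_output())
  }
  jsonlite::fromJSON(sub("\n.*$", "", buf), simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

lp_solve_highs <- function(lps) {
  probs <- lapply(lps, function(lp) {
    cn <- lp_canonical(lp)
    clamp <- function(v) pmin(pmax(v, -BIG_BOUND * 10), BIG_BOUND * 10)
    p <- list(n = cn$n, c = I(cn$c), lb = I(clamp(cn$lb)), ub = I(clamp(cn$ub)))
    tri <- function(t) list(m = t$m, i = I(t$i), j = I(t$j), x = I(t$x),
                            rhs = I(t$rhs))
    if (!is.null(cn$eq)) p$eq <- tri(cn$eq)
    if (!is.null(cn$le)) p$le <- tri(cn$le)
    p
  })
  ans <- worker_request(list(problems = probs))
  if (!isTRUE(ans$ok)) stop("LP worker error: ", ans$error)
  purrr::map2(ans$results, lps, function(r, lp) {
    status <- switch(as.character(r$status), "0" = "optimal", "1" = "limit",
                     "2" = "infeasible", "3" = "unbounded", "error")
    out <- list(status = status, x = NULL, obj = NA_real_,
                message = r$message %||% "")
    if (status == "optimal") {
      out$x <- as.numeric(unlist(r$x))
      out$obj <- if (lp$maximize) -r$obj else r$obj
    }
    out
  })
}

## ---- dense pure-R backend (boot::simplex) ----------------------------------

# The dense path rewrites the LP over nonnegative shifted/split variables
# (general bounds become shifts, upper-bound rows, or plus/minus splits) and
# hands the standard-form problem to the two-phase simplex below. Intended
# for small dense instances.
lp_solve_dense <- function(lp) {
  cn <- lp_canonical(lp)
  n <- cn$n
  lb <- cn$lb; ub <- cn$ub
  # column mapping: list of (var, sign, shift) per simplex column
  cols_var <- integer(0); cols_sgn <- numeric(0)
  shift <- numeric(n)
  extra_ub <- list() # rows s_k <= ub-lb
  for (k in seq_len(n)) {
    if (lb[k] > -BIG_BOUND) {
      shift[k] <- lb[k]
      cols_var <- c(cols_var, k); cols_sgn <- c(cols_sgn, 1)
      if (ub[k] < BIG_BOUND) {
        extra_ub[[length(extra_ub) + 1L]] <- c(length(cols_var), ub[k] - lb[k])
      }
    } else if (ub[k] < BIG_BOUND) {
      shift[k] <- ub[k]
      cols_var <- c(cols_var, k); cols_sgn <- c(cols_sgn, -1)
    } else {
      shift[k] <- 0
      cols_var <- c(cols_var, k, k); cols_sgn <- c(cols_sgn, 1, -1)
    }
  }
  ns <- length(cols_var)
  expand <- function(row) { # dense row over x -> row over s
    row[cols_var] * cols_sgn
  }
  a <- expand(cn$c)
  const <- sum(cn$c * shift)

  rows_le <- list(); rhs_le <- numeric(0)
  rows_eq <- list(); rhs_eq <- numeric(0)
  add_tri <- function(tri, eq) {
    if (is.null(tri)) return()
    M <- matrix(0, tri$m, n)
    M[cbind(tri$i + 1L, tri$j + 1L)] <- tri$x
    for (r in seq_len(tri$m)) {
      rr <- M[r, ]
      b <- tri$rhs[r] - sum(rr * shift)
      if (eq) {
        rows_eq[[length(rows_eq) + 1L]] <<- expand(rr)
        rhs_eq[length(rhs_eq) + 1L] <<- b
      } else {
        rows_le[[length(rows_le) + 1L]] <<- expand(rr)
        rhs_le[length(rhs_le) + 1L] <<- b
      }
    }
  }
  add_tri(cn$eq, eq = TRUE)
  add_tri(cn$le, eq = FALSE)
  for (e in extra_ub) {
    rr <- numeric(ns); rr[e[1]] <- 1
    rows_le[[length(rows_le) + 1L]] <- rr
    rhs_le[length(rhs_le) + 1L] <- e[2]
  }
  # boot::simplex requires nonnegative rhs: flip rows as needed
  A1 <- NULL; b1 <- numeric(0); A2 <- NULL; b2 <- numeric(0)
  for (r in seq_along(rows_le)) {
    if (rhs_le[r] >= 0) {
      A1 <- rbind(A1, rows_le[[r]]); b1 <- c(b1, rhs_le[r])
    } else {
      A2 <- rbind(A2, -rows_le[[r]]); b2 <- c(b2, -rhs_le[r])
    }
  }
  A3 <- NULL; b3 <- numeric(0)
  for (r in seq_along(rows_eq)) {
    s <- if (rhs_eq[r] >= 0) 1 else -1
    A3 <- rbind(A3, s * rows_eq[[r]]); b3 <- c(b3, s * rhs_eq[r])
  }
  Acon <- rbind(A1, A2, A3)
  bcon <- c(b1, b2, b3)
  scon <- c(rep("<=", length(b1)), rep(">=", length(b2)), rep("=", length(b3)))
  if (length(bcon) == 0L) {           # only nonnegativity: origin is optimal
    s <- rep(0, ns)
    if (any(a < -1e-12)) {
      return(list(status = "unbounded", x = NULL, obj = NA_real_,
                  message = "dense simplex"))
    }
  } else {
    res <- simplex_two_phase(a, Acon, bcon, scon)
    if (res$status != "optimal") {
      return(list(status = res$status, x = NULL, obj = NA_real_,
                  message = paste("dense simplex:", res$status)))
    }
    s <- res$x[seq_len(ns)]
  }
  x <- shift
  for (kk in seq_len(ns)) x[cols_var[kk]] <- x[cols_var[kk]] + cols_sgn[kk] * s[kk]
  obj <- sum(cn$c * x)
  if (lp$maximize) obj <- -obj
  list(status = "optimal", x = x, obj = obj, message = "dense simplex")
}

# minimal two-phase dense tableau simplex with Bland's rule:
# min c'x  s.t.  A x (sense) b,  x >= 0. For small instances only.
simplex_two_phase <- function(cvec, A, b, sense, tol = 1e-9,
                              max_iter = 50000L) {
  m <- nrow(A)
  for (r in seq_len(m)) {
    if (b[r] < 0) {
      A[r, ] <- -A[r, ]; b[r] <- -b[r]
      sense[r] <- switch(sense[r], "<=" = ">=", ">=" = "<=", "=" = "=")
    }
  }
  n0 <- ncol(A)
  basis <- integer(m)
  # slacks/surplus
  for (r in seq_len(m)) {
    if (sense[r] == "<=") {
      col <- rep(0, m); col[r] <- 1
      A <- cbind(A, col); basis[r] <- ncol(A)
    } else if (sense[r] == ">=") {
      col <- rep(0, m); col[r] <- -1
      A <- cbind(A, col)
    }
  }
  n1 <- ncol(A)
  # artificials where no basic slack exists
  art <- integer(0)
  for (r in seq_len(m)) {
    if (basis[r] == 0L) {
      col <- rep(0, m); col[r] <- 1
      A <- cbind(A, col); basis[r] <- ncol(A)
      art <- c(art, ncol(A))
    }
  }
  run <- function(A, b, basis, costs) {
    for (iter in seq_len(max_iter)) {
      red <- costs - as.numeric(costs[basis] %*% A)
      red[basis] <- 0
      enter <- which(red < -tol)
      if (length(enter) == 0L) {
        return(list(status = "optimal", A = A, b = b, basis = basis))
      }
      j <- min(enter)                               # Bland's rule
      col <- A[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(status = "unbounded"))
      ratios <- b[pos] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      r <- cand[which.min(basis[cand])]
      piv <- A[r, j]
      A[r, ] <- A[r, ] / piv; b[r] <- b[r] / piv
      adj <- which(abs(A[, j]) > 0)
      for (i in setdiff(adj, r)) {
        f <- A[i, j]
        A[i, ] <- A[i, ] - f * A[r, ]
        b[i] <- b[i] - f * b[r]
      }
      basis[r] <- j
    }
    list(status = "limit")
  }
  if (length(art)) {
    costs1 <- rep(0, ncol(A)); costs1[art] <- 1
    p1 <- run(A, b, basis, costs1)
    if (p1$status != "optimal") return(list(status = p1$status))
    if (sum(p1$b[p1$basis %in% art]) > 1e-7) return(list(status = "infeasible"))
    A <- p1$A; b <- p1$b; basis <- p1$basis
    # pivot remaining zero-level artificials out, or drop redundant rows
    keep <- rep(TRUE, m)
    for (r in which(basis %in% art)) {
      j <- which(abs(A[r, seq_len(n1)]) > tol)[1]
      if (is.na(j)) { keep[r] <- FALSE; next }
      piv <- A[r, j]
      A[r, ] <- A[r, ] / piv; b[r] <- b[r] / piv
      for (i in setdiff(which(abs(A[, j]) > 0), r)) {
        f <- A[i, j]
        A[i, ] <- A[i, ] - f * A[r, ]
        b[i] <- b[i] - f * b[r]
      }
      basis[r] <- j
    }
    A <- A[keep, seq_len(n1), drop = FALSE]
    b <- b[keep]; basis <- basis[keep]
    m <- nrow(A)
  }
  costs2 <- c(cvec, rep(0, n1 - length(cvec)))
  p2 <- run(A, b, basis, costs2)
  if (p2$status != "optimal") return(list(status = p2$status))
  x <- rep(0, n1)
  x[p2$basis] <- p2$b
  list(status = "optimal", x = x[seq_len(n0)],
       obj = sum(cvec * x[seq_len(length(cvec))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# robust coercion of any numeric matrix-like to general sparse triplet/csc
as_sparse_T <- function(A) {
  if (is.matrix(A)) A <- Matrix::Matrix(A, sparse = TRUE)
  as(as(as(A, "dMatrix"), "generalMatrix"), "TsparseMatrix")
}
as_sparse_C <- function(A) {
  if (is.matrix(A)) A <- Matrix::Matrix(A, sparse = TRUE)
  as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
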