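#' Generate a stoichiometrically consistent synthetic network
#'
#' Builds a connected network of `n_internal` internal reactions over `m`
#' metabolites whose internal part satisfies `N' ell = 0` exactly in integer
#' arithmetic: every metabolite gets a positive integer mass `ell_i` in
#' 1..4, a chain backbone connects consecutive metabolites with mass
#' balanced pairs (`a M_i -> b M_{i+1}`, `a ell_i = b ell_{i+1}`,
#' coefficients at most 4), extra reactions connect random pairs or
#' mass-compatible triples, and `n_external` single-coefficient exchange
#' columns (`EX_` ids) open the boundary. Formulae `C{ell}H{2*ell}` encode
#' the masses, so elemental balance coincides with mass balance by
#' construction. Fully deterministic given the seed.
#'
#' @param m number of metabolites (>= 2).
#' @param n_internal number of internal reactions (>= m - 1, for
#'   connectivity).
#' @param n_external number of exchange reactions (<= m).
#' @param seed RNG seed; identical arguments give identical models.
#' @param reversible_frac fraction of internal reactions that are
#'   reversible.
#' @return A list with the `model` ([metabolic_model()]), the integer mass
#'   vector `ell`, and a `truth` tibble of per-reaction ground-truth labels.
#' @export
make_consistent_network <- function(m = 6L, n_internal = 8L, n_external = 2L,
                                    seed = 1L, reversible_frac = 0.5) {
  if (m < 2L) stop("need at least two metabolites")
  if (n_internal < m - 1L) {
    stop("need n_internal >= m - 1 to keep the network connected")
  }
  if (n_external > m) stop("n_external cannot exceed m")
  with_preserved_rng(seed, {
    ell <- sample(1:4, m, replace = TRUE)
    ti <- list(); tj <- list(); tx <- list()
    rxn <- 0L
    add_col <- function(rows, coefs) {
      rxn <<- rxn + 1L
      ti[[rxn]] <<- rows; tj[[rxn]] <<- rep(rxn, length(rows))
      tx[[rxn]] <<- coefs
    }
    pair_col <- function(i, j) {
      g <- gcd2(ell[i], ell[j])
      add_col(c(i, j), c(-ell[j] / g, ell[i] / g))
    }
    for (i in seq_len(m - 1L)) pair_col(i, i + 1L)
    while (rxn < n_internal) {
      if (runif(1) < 0.4 && m >= 3L) {
        # try a mass-compatible triple i + j -> k
        ij <- sample(m, 2L)
        k <- which(ell == ell[ij[1]] + ell[ij[2]])
        k <- setdiff(k, ij)
        if (length(k)) {
          add_col(c(ij, k[1]), c(-1, -1, 1))
          next
        }
      }
      ij <- sample(m, 2L)
      pair_col(ij[1], ij[2])
    }
    n_int <- rxn
    ext_mets <- if (n_external == 0L) integer(0) else {
      cand <- c(1L, m, setdiff(sample(m), c(1L, m)))  # boundary mets first
      sort(unique(cand)[seq_len(n_external)])
    }
    for (i in ext_mets) add_col(i, -1)
    S <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                              dims = c(m, rxn))
    rev <- c(runif(n_int) < reversible_frac, rep(TRUE, rxn - n_int))
    lb <- ifelse(rev, -1000, 0)
    ub <- rep(1000, rxn)
    rxn_ids <- c(sprintf("R%03d", seq_len(n_int)),
                 sprintf("EX_M%03d", ext_mets))
    met_ids <- sprintf("M%03d", seq_len(m))
    model <- metabolic_model(S, lb = lb, ub = ub, met_ids = met_ids,
                             rxn_ids = rxn_ids,
                             met_formula = sprintf("C%dH%d", ell, 2L * ell),
                             met_charge = rep(0L, m))
    truth <- tibble::tibble(
      rxn_id = rxn_ids,
      class = c(rep("consistent", n_int), rep("external", rxn - n_int))
    )
    list(model = model, ell = ell, truth = truth)
  })
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Inject stoichiometric inconsistencies with known ground truth
#'
#' For each of `k` picked backbone pairs, adds a consistent duplicate of an
#' existing reaction on the pair (so the mass ratio of the pair stays
#' enforced even if one copy is relaxed) plus a corrupted column whose
#' coefficient is perturbed so that no positive mass vector can balance it.
#' The minimal mass-conservation relaxation is then exactly the set of
#' corrupted columns. With `imbalanced_formulas = TRUE` (default) the
#' corrupted reactions are also elementally imbalanced under the generated
#' formulae (which encode the masses); with `FALSE`, the formula of one
#' participant is blanked instead, so the elemental check reports them
#' undetermined rather than imbalanced.
#'
#' @param fx a fixture as returned by [make_consistent_network()].
#' @param k number of inconsistencies.
#' @param imbalanced_formulas make the corrupted reactions detectably
#'   imbalanced (default) or formula-less.
#' @param seed RNG seed.
#' @return The fixture with updated `model` and `truth` (corrupted reactions
#'   labelled `"inconsistent"`).
#' @export
inject_inconsistency <- function(fx, k, imbalanced_formulas = TRUE, seed = 1L) {
  if (k == 0L) return(fx)
  model <- fx$model
  m <- nrow(model$S)
  with_preserved_rng(seed + 1000L, {
    pairs <- sample(m - 1L, k)   # backbone reaction t connects mets t, t+1
    Sadd <- list(); ids <- character(0); lb <- numeric(0); ub <- numeric(0)
    for (t in pairs) {
      col <- model$S[, t, drop = FALSE]  # backbone column t
      rows <- which(col[, 1] != 0); coefs <- col[rows, 1]
      Sadd[[length(Sadd) + 1L]] <- cbind(rows, coefs)            # duplicate
      bad <- coefs
      bad[2] <- bad[2] + sample(c(1, 2), 1L)                     # corrupt
      Sadd[[length(Sadd) + 1L]] <- cbind(rows, bad)
      ids <- c(ids, sprintf("DUP_%03d", t), sprintf("BAD_%03d", t))
      lb <- c(lb, -1000, -1000); ub <- c(ub, 1000, 1000)
    }
    ti <- unlist(lapply(Sadd, function(a) a[, 1]))
    tj <- unlist(lapply(seq_along(Sadd), function(s) rep(s, nrow(Sadd[[s]]))))
    tx <- unlist(lapply(Sadd, function(a) a[, 2]))
    Snew <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                 dims = c(m, length(Sadd)))
    form <- fx$model$met_formula
    if (!imbalanced_formulas) {
      for (t in pairs) form[t + 1L] <- NA_character_
    }
    model2 <- metabolic_model(
      cbind(model$S, Snew),
      lb = c(model$lb, lb), ub = c(model$ub, ub),
      met_ids = model$met_ids, rxn_ids = c(model$rxn_ids, ids),
      met_formula = form, met_charge = model$met_charge
    )
    truth <- dplyr::bind_rows(
      fx$truth,
      tibble::tibble(rxn_id = ids,
                     class = rep(c("consistent", "inconsistent"), k))
    )
    fx$model <- model2; fx$truth <- truth
    fx
  })
}

#' Inject blocked (flux-inconsistent) reactions
#'
#' Adds `k` reactions, each converting an existing metabolite into a fresh
#' dead-end metabolite of the same mass. The new reactions are mass balanced
#' (stoichiometrically consistent) but can never carry steady-state flux —
#' the two defect classes are independent.
#'
#' @inheritParams inject_inconsistency
#' @return The fixture with updated `model` and `truth` (new reactions
#'   labelled `"blocked"`).
#' @export
inject_blocked <- function(fx, k, seed = 1L) {
  if (k == 0L) return(fx)
  model <- fx$model
  m <- nrow(model$S)
  with_preserved_rng(seed + 2000L, {
    src <- sample(m, k, replace = TRUE)
    Snew <- Matrix::sparseMatrix(
      i = c(src, m + seq_len(k)),
      j = rep(seq_len(k), 2L),
      x = c(rep(-1, k), rep(1, k)),
      dims = c(m + k, k)
    )
    Sold <- rbind(model$S, Matrix::Matrix(0, k, ncol(model$S)))
    ids <- sprintf("BLK_%03d", seq_len(k))
    dead_ids <- sprintf("DEAD_%03d", seq_len(k))
    form <- c(model$met_formula, model$met_formula[src])
    model2 <- metabolic_model(
      cbind(Sold, Snew),
      lb = c(model$lb, rep(-1000, k)), ub = c(model$ub, rep(1000, k)),
      met_ids = c(model$met_ids, dead_ids),
      rxn_ids = c(model$rxn_ids, ids),
      met_formula = form,
      met_charge = if (is.null(model$met_charge)) NULL else
        c(model$met_charge, model$met_charge[src])
    )
    truth <- dplyr::bind_rows(
      fx$truth, tibble::tibble(rxn_id = ids, class = "blocked")
    )
    fx$model <- model2; fx$truth <- truth
    fx$ell <- c(fx$ell, fx$ell[src])
    fx
  })
}

#' Inject a stoichiometrically balanced internal cycle
#'
#' Adds `cycle_len` fresh unit-mass metabolites connected in a directed loop
#' of internal reactions whose bounds admit circulation. The loop reactions
#' are stoichiometrically consistent and flux consistent (they can
#' circulate) but thermodynamically flux inconsistent: net flux around a
#' balanced cycle dissipates no potential difference. One member is written
#' against the loop direction and left reversible; tightening it to
#' irreversible (`break_cycle = TRUE`) removes the circulation.
#'
#' @inheritParams inject_inconsistency
#' @param cycle_len loop length (>= 2).
#' @param break_cycle make the counter-oriented member irreversible, which
#'   blocks the loop.
#' @return The fixture with updated `model` and `truth` (loop reactions
#'   labelled `"cycle"`, or `"cycle_broken"` when blocked).
#' @export
inject_internal_cycle <- function(fx, cycle_len = 3L, seed = 1L,
                                  break_cycle = FALSE) {
  stopifnot(cycle_len >= 2L)
  model <- fx$model
  m <- nrow(model$S)
  ids <- sprintf("CYC_%03d", seq_len(cycle_len))
  cyc_mets <- sprintf("CMET_%03d", seq_len(cycle_len))
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (t in seq_len(cycle_len)) {
    nxt <- if (t == cycle_len) 1L else t + 1L
    if (t == cycle_len) {
      # written against the loop: C_1 -> C_len; circulation needs v < 0
      ti <- c(ti, m + nxt, m + t); tj <- c(tj, t, t); tx <- c(tx, -1, 1)
    } else {
      ti <- c(ti, m + t, m + nxt); tj <- c(tj, t, t); tx <- c(tx, -1, 1)
    }
  }
  Snew <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                               dims = c(m + cycle_len, cycle_len))
  Sold <- rbind(model$S, Matrix::Matrix(0, cycle_len, ncol(model$S)))
  lb_new <- c(rep(0, cycle_len - 1L), if (break_cycle) 0 else -1000)
  ub_new <- rep(1000, cycle_len)
  model2 <- metabolic_model(
    cbind(Sold, Snew),
    lb = c(model$lb, lb_new), ub = c(model$ub, ub_new),
    met_ids = c(model$met_ids, cyc_mets),
    rxn_ids = c(model$rxn_ids, ids),
    met_formula = c(model$met_formula, rep("C1H2", cycle_len)),
    met_charge = if (is.null(model$met_charge)) NULL else
      c(model$met_charge, rep(0L, cycle_len))
  )
  truth <- dplyr::bind_rows(
    fx$truth,
    tibble::tibble(rxn_id = ids,
                   class = if (break_cycle) "cycle_broken" else "cycle")
  )
  fx$model <- model2; fx$truth <- truth
  fx$ell <- c(fx$ell, rep(1L, cycle_len))
  fx
}

#' Make a flux balance problem infeasible with known minimal repair
#'
#' Adds `n_conflicts` internal reactions between fresh dead-end metabolite
#' pairs, each with a forced positive lower bound. No steady-state flux can
#' satisfy the forced bound (both ends are dead), and for each conflict the
#' unique single-constraint repair is to relax that lower bound — so the
#' minimal relaxation cardinality equals `n_conflicts`.
#'
#' @inheritParams inject_inconsistency
#' @param n_conflicts number of forced infeasibilities.
#' @return The fixture with updated `model`, `truth` (new reactions labelled
#'   `"forced_infeasible"`) and `min_relax_card`.
#' @export
make_infeasible_fba <- function(fx, n_conflicts = 1L, seed = 1L) {
  if (n_conflicts == 0L) { fx$min_relax_card <- 0L; return(fx) }
  model <- fx$model
  m <- nrow(model$S)
  k <- n_conflicts
  ids <- sprintf("FRC_%03d", seq_len(k))
  new_mets <- c(sprintf("INA_%03d", seq_len(k)), sprintf("INB_%03d", seq_len(k)))
  Snew <- Matrix::sparseMatrix(
    i = c(m + seq_len(k), m + k + seq_len(k)),
    j = rep(seq_len(k), 2L),
    x = c(rep(-1, k), rep(1, k)),
    dims = c(m + 2L * k, k)
  )
  Sold <- rbind(model$S, Matrix::Matrix(0, 2L * k, ncol(model$S)))
  model2 <- metabolic_model(
    cbind(Sold, Snew),
    lb = c(model$lb, rep(1, k)), ub = c(model$ub, rep(1000, k)),
    met_ids = c(model$met_ids, new_mets),
    rxn_ids = c(model$rxn_ids, ids),
    met_formula = c(model$met_formula, rep("C1H2", 2L * k)),
    met_charge = if (is.null(model$met_charge)) NULL else
      c(model$met_charge, rep(0L, 2L * k))
  )
  truth <- dplyr::bind_rows(
    fx$truth, tibble::tibble(rxn_id = ids, class = "forced_infeasible")
  )
  fx$model <- model2; fx$truth <- truth
  fx$min_relax_card <- as.integer(k)
  fx$ell <- c(fx$ell, rep(1L, 2L * k))
  fx
}

#' Preset fixture sizes
#'
#' `"tiny"` (6 metabolites, 8 internal reactions) for unit tests, `"mid"`
#' (300 metabolites, 500 internal reactions, 60 exchanges) for
#' iteration-count and runtime experiments.
#'
#' @param preset `"tiny"` or `"mid"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [make_consistent_network()].
#' @return A fixture list (see [make_consistent_network()]).
#' @export
preset_fixture <- function(preset = c("tiny", "mid"), seed = 1L, ...) {
  args <- switch(match.arg(preset),
    tiny = list(m = 6L, n_internal = 8L, n_external = 2L),
    mid = list(m = 300L, n_internal = 500L, n_external = 60L)
  )
  do.call(make_consistent_network,
          modifyList(c(args, seed = seed), list(...)))
}

#' ATP hydrolysis / regeneration toy model
#'
#' Five cytoplasmic metabolites (atp, adp, pi, h, h2o, plus loop
#' intermediates) with the hydrolysis reaction `atp + h2o -> adp + pi + h`
#' (id `ATPM`), a regeneration path of `loop_len` lumped reactions closing
#' the cycle, and exchange reactions for all species. With the loop intact,
#' isolated ATP hydrolysis is admissible in the closed network; making the
#' final regeneration step irreversible (`break_cycle = TRUE`) removes it.
#'
#' @param loop_len number of regeneration reactions (>= 1).
#' @param break_cycle make the last regeneration step irreversible-forward
#'   only in the hydrolysis-opposing sense, eliminating the cycle.
#' @return A [metabolic_model()].
#' @export
make_atp_cycle_model <- function(loop_len = 3L, break_cycle = FALSE) {
  stopifnot(loop_len >= 1L)
  mets <- c("atp", "h2o", "adp", "pi", "h")
  ell <- c(atp = 6, h2o = 2, adp = 5, pi = 2, h = 1)
  inter <- if (loop_len > 1L) sprintf("x%d", seq_len(loop_len - 1L)) else character(0)
  mets <- c(mets, inter)
  ell <- c(ell, setNames(rep(8, length(inter)), inter))   # adp+pi+h mass
  midx <- setNames(seq_along(mets), mets)
  cols <- list()
  ids <- character(0)
  add <- function(id, stoich) {
    cols[[length(cols) + 1L]] <<- stoich
    ids <<- c(ids, id)
  }
  add("ATPM", c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1))
  # regeneration chain: adp + pi + h -> x1 -> ... -> x_{L-1} -> atp + h2o
  chain <- c("start", inter, "end")
  for (t in seq_len(loop_len)) {
    from <- chain[t]; to <- chain[t + 1L]
    st <- c()
    if (from == "start") st <- c(adp = -1, pi = -1, h = -1) else {
      st <- setNames(-1, from)
    }
    if (to == "end") st <- c(st, atp = 1, h2o = 1) else {
      st <- c(st, setNames(1, to))
    }
    add(sprintf("REGEN_%d", t), st)
  }
  for (mm in c("atp", "h2o", "adp", "pi", "h")) {
    add(paste0("EX_", mm), setNames(-1, mm))
  }
  ti <- unlist(lapply(cols, function(s) unname(midx[names(s)])))
  tj <- unlist(lapply(seq_along(cols), function(k) rep(k, length(cols[[k]]))))
  tx <- unlist(cols)
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(length(mets), length(cols)))
  n <- length(cols)
  lb <- rep(-1000, n); ub <- rep(1000, n)
  lb[1] <- 0                      # hydrolysis runs forward only
  if (break_cycle) {
    # last regeneration step made irreversible against the cycle direction
    lb[1L + loop_len] <- -1000
    ub[1L + loop_len] <- 0
  }
  metabolic_model(S, lb = lb, ub = ub, met_ids = mets, rxn_ids = ids,
                  met_formula = sprintf("C%dH%d", ell, 2 * ell),
                  met_charge = rep(0L, length(mets)))
}

#' Random feasible cardinality minimization problem
#'
#' Generates a small random polyhedron that is feasible by construction (the
#' right-hand sides are derived from a hidden random feasible point with a
#' sparse support), with every variable in the minimized cardinality block.
#' Used to benchmark the DCA heuristic against the exact enumeration oracle
#' ([brute_force_min_card()]).
#'
#' @param seed RNG seed.
#' @param n_card number of cardinality variables (kept small enough for
#'   enumeration).
#' @param m_rows number of linear constraints.
#' @return A [cardinality_problem()].
#' @export
random_cardinality_problem <- function(seed, n_card = 10L, m_rows = 4L) {
  with_preserved_rng(seed, {
    n <- n_card
    lb <- ifelse(runif(n) < 0.3, -2, 0)
    ub <- rep(2, n)
    A <- matrix(0, m_rows, n)
    for (r in seq_len(m_rows)) {
      nz <- sample(n, max(2L, rbinom(1, n, 0.4)))
      A[r, nz] <- sample(c(-2, -1, 1, 2), length(nz), replace = TRUE)
    }
    x0 <- ifelse(runif(n) < 0.6, 0, runif(n, pmax(lb, -2), ub))
    sense <- sample(c("=", "<=", ">="), m_rows, replace = TRUE,
                    prob = c(0.3, 0.35, 0.35))
    Ax0 <- as.numeric(A %*% x0)
    rhs <- Ax0 + ifelse(sense == "<=", runif(m_rows, 0, 1),
                 ifelse(sense == ">=", -runif(m_rows, 0, 1), 0))
    cardinality_problem(n = n, A = A, sense = sense, rhs = rhs,
                        lb = lb, ub = ub, minimize = seq_len(n), lambda = 1)
  })
}
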