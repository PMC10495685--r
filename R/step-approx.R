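#' Approximate step functions for cardinality optimization
#'
#' The zero norm of a vector is a sum of step functions of its components.
#' Each family here is a continuous approximation `psi(t)` of the step
#' function with `psi(0) = 0`, `0 <= psi <= 1`, even in `t`, nondecreasing in
#' `|t|`, and converging pointwise to the exact step as the sharpness `theta`
#' grows. All families are concave in `|t|` with a finite slope at the
#' origin, which is what makes the difference-of-convex split in
#' [dc_decompose()] work with a linear convex part.
#'
#' Families:
#' * `cappedL1`: `min(1, theta*|t|)` (the default; its DC subproblems are LPs
#'   in both minimization and maximization mode).
#' * `exp`: `1 - exp(-theta*|t|)`.
#' * `scad`: the smoothly clipped absolute deviation penalty with knot
#'   parameter `a` (> 2), rescaled to `[0, 1]`.
#' * `log`: `min(1, log(1 + theta*|t|) / log(1 + theta))`.
#' * `lpPos`: `min(1, (theta*|t| + eps)^p - eps^p)` with `0 < p < 1`; the
#'   offset `eps > 0` keeps the slope at the origin finite.
#' * `lpNeg`: `1 - (1 + theta*|t|)^p` with `p < 0`.
#'
#' @param kind family name.
#' @param theta positive sharpness parameter.
#' @param p exponent for `lpPos` (default 0.5) / `lpNeg` (default -1).
#' @param a SCAD knot parameter, default 3.7.
#' @param eps offset for `lpPos`, default 0.1.
#' @return A `step_approx` object.
#' @examples
#' ap <- step_approx("cappedL1", theta = 2)
#' eval_step(ap, c(0, 0.25, -3))
#' @export
step_approx <- function(kind = c("cappedL1", "exp", "scad", "log", "lpPos", "lpNeg"),
                        theta = 0.5, p = NULL, a = 3.7, eps = 0.1) {
  kind <- match.arg(kind)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be a positive scalar")
  }
  if (is.null(p)) p <- switch(kind, lpPos = 0.5, lpNeg = -1, NA_real_)
  if (kind == "lpPos" && (p <= 0 || p >= 1)) stop("lpPos needs 0 < p < 1")
  if (kind == "lpNeg" && p >= 0) stop("lpNeg needs p < 0")
  if (kind == "scad" && a <= 2) stop("scad needs a > 2")
  if (kind == "lpPos" && eps <= 0) stop("lpPos needs eps > 0")
  structure(list(kind = kind, theta = theta, p = p, a = a, eps = eps),
            class = "step_approx")
}

#' @export
print.step_approx <- function(x, ...) {
  extra <- switch(x$kind, scad = sprintf(", a = %g", x$a),
                  lpPos = sprintf(", p = %g, eps = %g", x$p, x$eps),
                  lpNeg = sprintf(", p = %g", x$p), "")
  cat(sprintf("<step_approx %s, theta = %g%s>\n", x$kind, x$theta, extra))
  invisible(x)
}

# update the sharpness, preserving shape parameters
step_with_theta <- function(approx, theta) {
  approx$theta <- theta
  approx
}

# psi on u = |t| >= 0
step_r <- function(approx, u) {
  th <- approx$theta
  switch(approx$kind,
    cappedL1 = pmin(1, th * u),
    exp = 1 - exp(-th * u),
    log = pmin(1, log1p(th * u) / log1p(th)),
    scad = {
      lam <- 1 / th; a <- approx$a
      pen <- ifelse(u <= lam, lam * u,
             ifelse(u <= a * lam, (2 * a * lam * u - u^2 - lam^2) / (2 * (a - 1)),
                    lam^2 * (a + 1) / 2))
      2 * pen / (lam^2 * (a + 1))
    },
    lpPos = pmin(1, (th * u + approx$eps)^approx$p - approx$eps^approx$p),
    lpNeg = 1 - (1 + th * u)^approx$p
  )
}

# right derivative of psi w.r.t. u = |t| (a valid sub/supergradient at kinks)
step_rprime <- function(approx, u) {
  th <- approx$theta
  switch(approx$kind,
    cappedL1 = ifelse(th * u < 1, th, 0),
    exp = th * exp(-th * u),
    log = ifelse(log1p(th * u) < log1p(th), th / ((1 + th * u) * log1p(th)), 0),
    scad = {
      lam <- 1 / th; a <- approx$a
      d <- ifelse(u <= lam, lam,
           ifelse(u <= a * lam, (a * lam - u) / (a - 1), 0))
      2 * d / (lam^2 * (a + 1))
    },
    lpPos = {
      capped <- (th * u + approx$eps)^approx$p - approx$eps^approx$p >= 1
      ifelse(capped, 0, approx$p * th * (th * u + approx$eps)^(approx$p - 1))
    },
    lpNeg = -approx$p * th * (1 + th * u)^(approx$p - 1)
  )
}

# slope of psi at the origin; the linear majorant used as the convex part
step_s0 <- function(approx) {
  th <- approx$theta
  switch(approx$kind,
    cappedL1 = th,
    exp = th,
    log = th / log1p(th),
    scad = 2 * th / (approx$a + 1),
    lpPos = approx$p * th * approx$eps^(approx$p - 1),
    lpNeg = -approx$p * th
  )
}

#' Evaluate an approximate step function
#'
#' @param approx a [step_approx()].
#' @param t numeric vector.
#' @return Componentwise `psi(t)`, values in `[0, 1]`.
#' @export
eval_step <- function(approx, t) {
  stopifnot(inherits(approx, "step_approx"))
  step_r(approx, abs(t))
}

#' Difference-of-convex decomposition of a step-approximation sum
#'
#' For cardinality *minimization* the objective `sum_j psi(t_j)` is written
#' as `phi(t) - phi2(t)` with `phi(t) = s0 * sum |t_j|` (linear once `|t|` is
#' modelled in the LP) and `phi2(t) = sum (s0*|t_j| - psi(t_j))`, both convex;
#' `s0` is the slope of `psi` at the origin. For cardinality *maximization*
#' the co-step sum `sum_j (1 - psi(t_j))` is decomposed instead; only the
#' capped-l1 family keeps the convex part LP-representable
#' (`phi(t) = sum max(theta*|t_j|, 1)`, `phi2(t) = theta * sum |t_j|`), so the
#' other families raise a not-implemented error in that mode.
#'
#' @param approx a [step_approx()].
#' @param mode `"minimize"` or `"maximize"`.
#' @return A list with functions `phi`, `phi2`, `subgrad_phi2`, the origin
#'   slope `s0`, and `target(t)`, the approximated objective
#'   (`sum psi` or `sum (1 - psi)`).
#' @export
dc_decompose <- function(approx, mode = c("minimize", "maximize")) {
  stopifnot(inherits(approx, "step_approx"))
  mode <- match.arg(mode)
  s0 <- step_s0(approx)
  if (mode == "minimize") {
    list(
      mode = mode, s0 = s0,
      phi = function(t) s0 * sum(abs(t)),
      phi2 = function(t) sum(s0 * abs(t) - step_r(approx, abs(t))),
      subgrad_phi2 = function(t) sign(t) * (s0 - step_rprime(approx, abs(t))),
      target = function(t) sum(step_r(approx, abs(t)))
    )
  } else {
    if (approx$kind != "cappedL1") {
      stop("maximization-mode DC decomposition is not implemented for the `",
           approx$kind, "` family (its convex part is not LP-representable); ",
           "use cappedL1")
    }
    th <- approx$theta
    list(
      mode = mode, s0 = s0,
      phi = function(t) sum(pmax(th * abs(t), 1)),
      phi2 = function(t) th * sum(abs(t)),
      subgrad_phi2 = function(t) th * sign(t),
      target = function(t) sum(1 - step_r(approx, abs(t)))
    )
  }
}

#' Subgradient of the subtracted convex component
#'
#' Returns a vector `g` with `phi2(t') >= phi2(t) + g . (t' - t)` for all
#' `t'`, where `phi2` is the subtracted component of [dc_decompose()]. At the
#' origin the symmetric choice `0` is returned. The outer DCA iteration
#' linearizes `phi2` with this subgradient.
#'
#' @inheritParams dc_decompose
#' @param t numeric point.
#' @return Numeric vector, one subgradient component per entry of `t`.
#' @export
subgrad_phi2 <- function(approx, mode = c("minimize", "maximize"), t) {
  dc <- dc_decompose(approx, match.arg(mode))
  dc$subgrad_phi2(t)
}
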