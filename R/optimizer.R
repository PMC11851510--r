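# Gradient-based optimizer shared by calibration and dosage optimization:
# bound normalization, forward-difference gradients, the arctan-smoothed
# step function, and a sequential strictly convex separable (MMA-style)
# approximation method with asymptote adaptation and a dual subproblem
# solve.

#' Normalize / denormalize design variables
#'
#' Affine bijection between physical values and the unit cube:
#' `x_unit = (x - LO) / (UP - LO)`.
#'
#' @param x Physical (or unit) values.
#' @param lo,up Lower/upper bounds, `lo < up` elementwise.
#' @return The mapped vector.
#' @export
normalize_design <- function(x, lo, up) {
  if (any(lo >= up)) stop("normalize_design: lo must be < up")
  (x - lo) / (up - lo)
}

#' @rdname normalize_design
#' @export
denormalize_design <- function(x, lo, up) {
  if (any(lo >= up)) stop("denormalize_design: lo must be < up")
  lo + x * (up - lo)
}

#' Arctan-smoothed step function
#'
#' `H(x) = 0.5 + atan(10 k x) / pi`: strictly increasing, `H(0) = 0.5`,
#' limits 0 and 1, and `H(x) + H(-x) = 1`. Used as the differentiable
#' substitute for the conventional step function in the envelope
#' constraints.
#'
#' @param x Argument.
#' @param k Sharpness (> 0).
#' @param normalized If FALSE, omit the `1/pi` factor (a raw arctan
#'   offset whose limits are not 0/1).
#' @return Values in (0, 1) (vectorized).
#' @export
smooth_heaviside <- function(x, k = 1, normalized = TRUE) {
  if (k <= 0) stop("smooth_heaviside: k must be > 0")
  if (normalized) 0.5 + atan(10 * k * x) / pi else 0.5 + atan(10 * k * x)
}

#' Forward-difference gradient
#'
#' `g_i = (f(x + h e_i) - f(x)) / h`; the probe evaluations are independent
#' of each other.
#'
#' @param f Scalar-valued function.
#' @param x Evaluation point.
#' @param h Step (> 0).
#' @param f0 Optional precomputed `f(x)`.
#' @return Gradient vector.
#' @export
fd_gradient <- function(f, x, h = 1e-4, f0 = NULL) {
  if (h <= 0) stop("fd_gradient: h must be > 0")
  if (is.null(f0)) f0 <- f(x)
  if (!is.finite(f0)) stop("fd_gradient: f not finite at x")
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + h
    fi <- f(xp)
    if (!is.finite(fi)) {
      stop("fd_gradient: f not finite at probe of coordinate ", i)
    }
    g[i] <- (fi - f0) / h
  }
  g
}

# jacobian of a combined evaluator fn(x) -> list(f, g): rows = c(f, g)
.fd_jacobian <- function(fn, x, h, v0) {
  n <- length(x)
  m <- length(v0$g)
  J <- matrix(0, m + 1L, n)
  for (i in seq_len(n)) {
    xp <- x
    xp[i] <- xp[i] + h
    vi <- fn(xp)
    J[1L, i] <- (vi$f - v0$f) / h
    if (m) J[-1L, i] <- (vi$g - v0$g) / h
  }
  J
}

#' Define an optimization problem on the unit cube
#'
#' @param fn Combined evaluator: `fn(x)` returns `list(f = <scalar>,
#'   g = <numeric vector of constraint values>)` with the convention
#'   `g <= 0` feasible; `g` may be length 0.
#' @param n Number of design variables.
#' @param maxit Iteration cap.
#' @param move Move limit per iteration (unit space).
#' @param tol_f Objective-change tolerance.
#' @param tol_g Constraint-violation tolerance.
#' @param tol_x Step-norm tolerance.
#' @param h Forward-difference step (unit space).
#' @param asy0 Initial asymptote distance (unit space).
#' @return List of class `opt_problem`.
#' @export
opt_problem <- function(fn, n, maxit = 200, move = 0.2, tol_f = 1e-6,
                        tol_g = 1e-6, tol_x = 1e-5, h = 1e-4, asy0 = 0.5) {
  stopifnot(is.function(fn), n >= 1, asy0 > 0)
  structure(list(fn = fn, n = n, maxit = maxit, move = move, tol_f = tol_f,
                 tol_g = tol_g, tol_x = tol_x, h = h, asy0 = asy0),
            class = "opt_problem")
}

# dual of the separable convex subproblem: x_j(lambda) in closed form
.mma_dual_x <- function(lam, p0, q0, Pg, Qg, L, U, alpha, beta) {
  P <- p0 + if (length(lam)) drop(crossprod(Pg, lam)) else 0
  Q <- q0 + if (length(lam)) drop(crossprod(Qg, lam)) else 0
  x <- (L * sqrt(P) + U * sqrt(Q)) / (sqrt(P) + sqrt(Q))
  pmin(pmax(x, alpha), beta)
}

#' Solve a problem by sequential convex separable approximation
#'
#' Builds strictly convex separable subproblems of the moving-asymptotes
#' family around the current iterate (asymptotes adapted from the iterate
#' history), solves each via its dual under move limits, and iterates until
#' the objective change, constraint violation and step size fall below
#' tolerance or the iteration cap is hit. Gradients are forward differences
#' of the combined evaluator. Deterministic given `x0` and the settings.
#'
#' @param problem An [opt_problem()].
#' @param x0 Start point in `[0,1]^n`.
#' @param verbose Print one log line per iteration.
#' @return List with `x` (best iterate), `f`, `g`, `feasible` (logical),
#'   `iterations`, `converged`, and `history` (data.frame: iter, f,
#'   max_violation, step_norm).
#' @export
approx_solve <- function(problem, x0, verbose = FALSE) {
  stopifnot(inherits(problem, "opt_problem"))
  n <- problem$n
  if (length(x0) != n || any(x0 < -1e-12) || any(x0 > 1 + 1e-12)) {
    stop("x0 must lie in the unit cube of dimension ", n)
  }
  x <- pmin(pmax(x0, 0), 1)
  fn <- problem$fn
  v <- fn(x)
  m <- length(v$g)
  viol <- if (m) max(0, max(v$g)) else 0
  best <- list(x = x, f = v$f, g = v$g, feasible = viol <= problem$tol_g)
  least_inf <- list(x = x, f = v$f, g = v$g, viol = viol)
  hist <- data.frame(iter = 0L, f = v$f, max_violation = viol,
                     step_norm = NA_real_)
  x_old <- x_old2 <- x
  Lb <- x - problem$asy0
  Ub <- x + problem$asy0
  lam <- rep(1, m)
  converged <- FALSE
  it <- 0L
  stall <- 0L
  rho0 <- 1e-6
  while (it < problem$maxit) {
    it <- it + 1L
    J <- .fd_jacobian(fn, x, problem$h, v)
    # asymptote adaptation from the two most recent iterates
    if (it > 2L) {
      osc <- (x - x_old) * (x_old - x_old2)
      gam <- ifelse(osc > 0, 1.2, ifelse(osc < 0, 0.7, 1.0))
      Lb <- x - gam * (x_old - Lb)
      Ub <- x + gam * (Ub - x_old)
    } else {
      Lb <- x - problem$asy0
      Ub <- x + problem$asy0
    }
    Lb <- pmin(pmax(Lb, x - 10), x - 1e-6)
    Ub <- pmax(pmin(Ub, x + 10), x + 1e-6)
    alpha <- pmax(0, x - problem$move, Lb + 0.1 * (x - Lb))
    beta <- pmin(1, x + problem$move, Ub - 0.1 * (Ub - x))

    du2 <- (Ub - x)^2
    dl2 <- (x - Lb)^2
    mk <- function(grad) {
      list(p = du2 * (pmax(grad, 0) + 0.001 * abs(grad) + rho0),
           q = dl2 * (pmax(-grad, 0) + 0.001 * abs(grad) + rho0))
    }
    o <- mk(J[1L, ])
    p0 <- o$p; q0 <- o$q
    if (m) {
      Pg <- matrix(0, m, n); Qg <- matrix(0, m, n)
      rg <- numeric(m)
      for (i in seq_len(m)) {
        ci <- mk(J[i + 1L, ])
        Pg[i, ] <- ci$p; Qg[i, ] <- ci$q
        rg[i] <- v$g[i] - sum(ci$p / (Ub - x) + ci$q / (x - Lb))
      }
      dual <- function(l) {
        xs <- .mma_dual_x(l, p0, q0, Pg, Qg, Lb, Ub, alpha, beta)
        P <- p0 + drop(crossprod(Pg, l)); Q <- q0 + drop(crossprod(Qg, l))
        sum(P / (Ub - xs) + Q / (xs - Lb)) + sum(l * rg)
      }
      dual_grad <- function(l) {
        xs <- .mma_dual_x(l, p0, q0, Pg, Qg, Lb, Ub, alpha, beta)
        rg + drop(Pg %*% (1 / (Ub - xs)) + Qg %*% (1 / (xs - Lb)))
      }
      op <- stats::optim(pmin(lam, 1e4), dual, dual_grad,
                         method = "L-BFGS-B", lower = 0, upper = 1e8,
                         control = list(fnscale = -1, maxit = 100))
      lam <- op$par
      x_new <- .mma_dual_x(lam, p0, q0, Pg, Qg, Lb, Ub, alpha, beta)
    } else {
      x_new <- .mma_dual_x(numeric(0), p0, q0, NULL, NULL, Lb, Ub,
                           alpha, beta)
    }
    # backtracking acceptance on a simple merit function: halve the step
    # toward the incumbent while the trial point is strictly worse
    merit <- function(vv) {
      vl <- if (m) max(0, max(vv$g)) else 0
      vv$f + 1e2 * vl
    }
    m_inc <- merit(v)
    v_new <- fn(x_new)
    bt <- 0L
    while (merit(v_new) >= m_inc && bt < 6L) {
      x_new <- x + 0.5 * (x_new - x)
      v_new <- fn(x_new)
      bt <- bt + 1L
    }
    step <- sqrt(sum((x_new - x)^2))
    x_old2 <- x_old
    x_old <- x
    f_prev <- v$f
    x <- x_new
    v <- v_new
    viol <- if (m) max(0, max(v$g)) else 0
    if (viol <= problem$tol_g &&
        (!best$feasible || v$f < best$f)) {
      best <- list(x = x, f = v$f, g = v$g, feasible = TRUE)
    }
    if (viol < least_inf$viol) {
      least_inf <- list(x = x, f = v$f, g = v$g, viol = viol)
    }
    hist <- rbind(hist, data.frame(iter = it, f = v$f, max_violation = viol,
                                   step_norm = step))
    if (verbose) {
      message(sprintf("iter %3d  g0 = %.6e  viol = %.3e  step = %.3e",
                      it, v$f, viol, step))
    }
    small_change <- abs(v$f - f_prev) < problem$tol_f * max(1, abs(f_prev))
    stall <- if (small_change) stall + 1L else 0L
    if (small_change && viol <= problem$tol_g &&
        (step < problem$tol_x || stall >= 3L)) {
      converged <- TRUE
      break
    }
  }
  out <- if (best$feasible) {
    list(x = best$x, f = best$f, g = best$g, feasible = TRUE)
  } else {
    list(x = least_inf$x, f = least_inf$f, g = least_inf$g, feasible = FALSE)
  }
  c(out, list(iterations = it, converged = converged, history = hist))
}
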