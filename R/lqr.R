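#' Solve the discrete algebraic Riccati equation for the expression model
#'
#' Solves A'PA - P - A'P(P+I)^{-1}PA + I = 0, the Riccati equation of the
#' infinite-horizon LQR problem with state cost Q = I, control cost R = I
#' and control matrix B = I (the treatment enters the dynamics additively,
#' x(t) = A x(t-1) + u(t-1)). Because B = I the pair (A, B) is always
#' stabilizable and Q = I makes the state fully observable, so a unique
#' stabilizing positive-definite solution exists even at the marginal
#' spectral radius 1 produced by eigenvalue normalization.
#'
#' The solver is the fixed-point (value) iteration
#' P <- A'PA - A'P(P+I)^{-1}PA + I starting from P = I, stopped when the
#' max-abs update falls below \code{tol}. Convergence failure is an error
#' carrying the last residual, never a silent fallback.
#'
#' @param A square dynamics matrix with spectral radius <= 1 + 1e-9.
#' @param tol max-abs update threshold (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return a \code{riccati_solution}: list with \code{P} (symmetric
#'   positive-definite), \code{residual} (max-abs of the equation's left
#'   side at P), \code{iterations}, and \code{closed_loop_radius}
#'   (spectral radius of A - (I+P)^{-1}PA, certifying stabilization).
#' @examples
#' solve_dare(matrix(0))$P        # == I: equation reduces to -P + I = 0
#' solve_dare(matrix(1))$P        # golden ratio (1 + sqrt(5)) / 2
#' @export
solve_dare <- function(A, tol = 1e-10, max_iter = 10000L) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("dynamics matrix must be square")
  if (!all(is.finite(A))) stop("dynamics matrix must be finite")
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho > 1 + 1e-9)
    stop("spectral radius ", format(rho), " exceeds 1: normalize first")

  I <- diag(n)
  P <- I
  riccati_step <- function(P) {
    PA <- P %*% A
    t(A) %*% PA - crossprod(PA, solve(P + I, PA)) + I
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Pn <- riccati_step(P)
    Pn <- (Pn + t(Pn)) / 2     # kill asymmetric round-off drift
    delta <- max(abs(Pn - P))
    P <- Pn
    if (delta < tol) break
    if (iter >= max_iter) {
      res <- max(abs(riccati_step(P) - P))
      stop(sprintf(
        "Riccati iteration did not converge in %d steps (last update %.3e, residual %.3e)",
        max_iter, delta, res))
    }
  }
  residual <- max(abs(riccati_step(P) - P))
  K <- solve(I + P, P %*% A)
  clr <- max(Mod(eigen(A - K, only.values = TRUE)$values))
  structure(list(P = P, residual = residual, iterations = iter,
                 closed_loop_radius = clr),
            class = "riccati_solution")
}

#' @export
print.riccati_solution <- function(x, ...) {
  cat(sprintf(
    "riccati_solution: %dx%d, %d iterations, residual %.2e, closed-loop radius %.4f\n",
    nrow(x$P), ncol(x$P), x$iterations, x$residual, x$closed_loop_radius))
  invisible(x)
}

#' Compute the optimal first intervention (the "hypo-treatment")
#'
#' Evaluates u(0) = -(I+P)^{-1} P A x(0), the first step of the optimal
#' LQR feedback. Later control steps decay quickly, so u(0) carries the
#' per-gene pattern of the ideal intervention: its sign says whether each
#' gene should be pushed up (+) or down (-) to stabilize the dysregulated
#' state back toward equilibrium.
#'
#' @param P Riccati solution matrix (or a \code{riccati_solution}).
#' @param A dynamics matrix.
#' @param x0 initial condition vector (the disease signature).
#' @param sign_tol entries with |u0| at or below this threshold get sign 0
#'   (default 1e-12; u0 entries are generically nonzero floats, exact zeros
#'   arise only for structurally unreachable genes).
#' @return a \code{hypo_treatment}: list with \code{u0}, \code{x0}, and
#'   \code{sign_pattern} in \{-1, 0, +1\}.
#' @export
hypo_treatment <- function(P, A, x0, sign_tol = 1e-12) {
  if (inherits(P, "riccati_solution")) P <- P$P
  A <- as.matrix(A)
  x0 <- as.numeric(x0)
  n <- nrow(A)
  stopifnot(ncol(A) == n, nrow(P) == n, ncol(P) == n, length(x0) == n,
            sign_tol >= 0)
  ip <- diag(n) + P
  # I + P is positive definite whenever P is PSD, hence invertible
  u0 <- as.numeric(-solve(ip, P %*% A %*% x0))
  sp <- sign(u0)
  sp[abs(u0) <= sign_tol] <- 0
  structure(list(u0 = u0, x0 = x0, sign_pattern = sp),
            class = "hypo_treatment")
}

#' Simulate the controlled (or free) expression trajectory
#'
#' Iterates x(t) = A x(t-1) + u(t-1) for \code{horizon} steps under one of
#' three policies: \code{"lqr"} (u = -(I+P)^{-1}PA x, requires \code{P}),
#' \code{"zero"} (no treatment), or \code{"gain"} (u = -gain \%*\% x).
#' The reported cost J sums x(t)'x(t) over all stored states x(0..T) and
#' u(t)'u(t) over all controls u(0..T-1), i.e. the infinite-horizon LQR
#' objective truncated at T with terminal state cost. A warning is issued
#' when the final state has not decayed below 1e-8 (truncation bias).
#'
#' @param A dynamics matrix.
#' @param x0 initial state.
#' @param policy one of \code{"lqr"}, \code{"zero"}, \code{"gain"}.
#' @param P Riccati solution (for \code{"lqr"}).
#' @param gain feedback gain matrix (for \code{"gain"}).
#' @param horizon number of steps T >= 1 (default 500).
#' @return a \code{trajectory}: list with \code{states} ((T+1) x N matrix),
#'   \code{controls} (T x N), and \code{cost}.
#' @export
simulate_trajectory <- function(A, x0, policy = c("lqr", "zero", "gain"),
                                P = NULL, gain = NULL, horizon = 500L) {
  policy <- match.arg(policy)
  A <- as.matrix(A)
  x0 <- as.numeric(x0)
  n <- nrow(A)
  stopifnot(ncol(A) == n, length(x0) == n, horizon >= 1L)
  K <- switch(policy,
    zero = matrix(0, n, n),
    gain = { stopifnot(!is.null(gain)); as.matrix(gain) },
    lqr = {
      if (inherits(P, "riccati_solution")) P <- P$P
      stopifnot(!is.null(P))
      solve(diag(n) + P, P %*% A)
    })
  states <- matrix(0, horizon + 1L, n)
  controls <- matrix(0, horizon, n)
  states[1L, ] <- x0
  x <- x0
  for (t in seq_len(horizon)) {
    u <- as.numeric(-K %*% x)
    x <- as.numeric(A %*% x + u)
    controls[t, ] <- u
    states[t + 1L, ] <- x
  }
  if (sqrt(sum(x^2)) > 1e-8)
    warning("state norm ", format(sqrt(sum(x^2))),
            " at the horizon: truncated cost may underestimate J",
            call. = FALSE)
  structure(list(states = states, controls = controls,
                 cost = sum(states^2) + sum(controls^2)),
            class = "trajectory")
}
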