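golden <- (1 + sqrt(5)) / 2

test_that("solve_dare matches the scalar closed forms", {
  # a = 0: equation reduces to -P + I = 0
  expect_equal(solve_dare(matrix(0))$P, matrix(1))
  # a = 1: p^2 - p - 1 = 0, the golden ratio
  expect_equal(solve_dare(matrix(1))$P[1, 1], golden, tolerance = 1e-8)

  expect_error(solve_dare(matrix(1:6, 2)), "square")
  expect_error(solve_dare(matrix(c(2, 0, 0, 0.5), 2)), "spectral radius")
  expect_error(solve_dare(matrix(NaN)), "finite")
  expect_error(solve_dare(matrix(1), max_iter = 3L), "did not converge")
})

test_that("solve_dare satisfies its solution invariants on random systems", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    A <- random_stable_matrix(n, rho = stats::runif(1, 0.3, 1.0))
    sol <- solve_dare(A)
    expect_lt(max(abs(sol$P - t(sol$P))), 1e-8)
    expect_gt(min(eigen(sol$P, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_lt(sol$residual, 1e-8)
    expect_lt(sol$closed_loop_radius, 1)
  }
})

test_that("solve_dare agrees with the backward-recursion oracle", {
  set.seed(5)
  A <- random_stable_matrix(5, rho = 0.9)
  expect_lt(max(abs(solve_dare(A)$P - dare_backward(A, 500L))), 1e-6)
})

test_that("solve_dare agrees with scipy's dedicated DARE solver", {
  set.seed(99)
  script <- '
import sys, numpy as np
from scipy.linalg import solve_discrete_are
a = np.loadtxt(sys.argv[1], delimiter=",")
p = solve_discrete_are(a, np.eye(a.shape[0]), np.eye(a.shape[0]),
                       np.eye(a.shape[0]))
np.savetxt(sys.argv[2], p, delimiter=",")
'
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(2:10, 1)
    A <- random_stable_matrix(n, rho = stats::runif(1, 0.5, 0.99))
    fa <- withr::local_tempfile(fileext = ".csv")
    fp <- withr::local_tempfile(fileext = ".csv")
    utils::write.table(A, fa, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    status <- system2("python", c(py, fa, fp))
    expect_identical(status, 0L)
    P_ref <- as.matrix(utils::read.table(fp, sep = ","))
    dimnames(P_ref) <- NULL
    expect_lt(max(abs(solve_dare(A)$P - P_ref)), 1e-6)
  }
})

test_that("hypo_treatment evaluates the optimal first intervention", {
  # linear in x0: zero state needs no treatment
  P <- solve_dare(matrix(1))$P
  h0 <- hypo_treatment(P, matrix(1), 0)
  expect_identical(h0$u0, 0)
  expect_identical(h0$sign_pattern, 0)

  # scalar closed form: u0 = -p / (1 + p)
  h <- hypo_treatment(P, matrix(1), 1)
  expect_equal(h$u0, -golden / (1 + golden), tolerance = 1e-8)
  expect_identical(h$sign_pattern, -1)

  # odd symmetry
  set.seed(8)
  A <- random_stable_matrix(6, 0.95)
  sol <- solve_dare(A)
  for (rep in 1:5) {
    x0 <- stats::rnorm(6)
    expect_equal(hypo_treatment(sol, A, -x0)$u0,
                 -hypo_treatment(sol, A, x0)$u0)
  }
})

test_that("simulate_trajectory obeys the dynamics and cost definitions", {
  # A = 0, no control: the state decays in one step, J = x0'x0
  x0 <- c(1, -2)
  tr <- simulate_trajectory(matrix(0, 2, 2), x0, "zero", horizon = 5L)
  expect_equal(tr$states[2, ], c(0, 0))
  expect_equal(tr$cost, sum(x0^2))

  # trajectory satisfies x(t) = A x(t-1) + u(t-1) exactly
  set.seed(2)
  A <- random_stable_matrix(4, 0.9)
  sol <- solve_dare(A)
  tr <- simulate_trajectory(A, stats::rnorm(4), "lqr", P = sol,
                            horizon = 50L)
  for (t in 1:50) {
    expect_equal(tr$states[t + 1, ],
                 as.numeric(A %*% tr$states[t, ]) + tr$controls[t, ],
                 tolerance = 1e-10)
  }
})

test_that("LQR cost matches the value function x0' P x0", {
  # scalar marginal case: optimal cost is the golden ratio
  tr <- simulate_trajectory(matrix(1), 1, "lqr", P = solve_dare(matrix(1)),
                            horizon = 200L)
  expect_equal(tr$cost, golden, tolerance = 1e-6)

  set.seed(13)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    A <- random_stable_matrix(n, 0.9)
    sol <- solve_dare(A)
    x0 <- stats::rnorm(n)
    tr <- simulate_trajectory(A, x0, "lqr", P = sol, horizon = 500L)
    expect_equal(tr$cost, drop(t(x0) %*% sol$P %*% x0),
                 tolerance = 1e-4)
  }
})

test_that("open-loop stability and closed-loop convergence hold", {
  set.seed(21)
  for (rep in 1:5) {
    A <- random_stable_matrix(6, 0.8)
    x0 <- stats::rnorm(6)
    # free dynamics with spectral radius < 1: bounded and decaying
    free <- simulate_trajectory(A, x0, "zero", horizon = 300L)
    norms <- sqrt(rowSums(free$states^2))
    expect_lt(norms[length(norms)], 1e-6 * norms[1])
    # controlled dynamics: convergence to equilibrium
    sol <- solve_dare(A)
    ctl <- simulate_trajectory(A, x0, "lqr", P = sol, horizon = 300L)
    expect_lt(sqrt(sum(ctl$states[301, ]^2)), 1e-6 * sqrt(sum(x0^2)))
  }
})
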