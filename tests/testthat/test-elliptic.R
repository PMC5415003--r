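test_that("vertex-centred transfers reproduce constants and linear fields", {
  cfield <- array(2.5, dim = c(5, 5, 1))
  expect_true(all(restrict_grid(cfield) == 2.5))
  expect_true(all(prolong_grid(restrict_grid(cfield), c(5, 5, 1)) == 2.5))

  ramp <- array(outer(0:4, rep(1, 3)), dim = c(5, 3, 1))
  coarse <- restrict_grid(ramp)               # values 0, 2, 4
  fine <- prolong_grid(coarse, c(5, 3, 1))
  expect_equal(fine, ramp)                    # linear interpolation is exact

  set.seed(12)
  rc <- array(rnorm(3 * 2 * 1), dim = c(3, 2, 1))
  rp <- restrict_grid(prolong_grid(rc, c(5, 3, 1)))
  expect_equal(rp, rc)                        # injection: identity at coarse
})

test_that("a hand-computed Gauss-Seidel sweep on a 3-node cable", {
  g <- make_box(3, 1, 1, h = 1)
  prob <- elliptic_problem(g, 1, rhs = array(c(0, 1, 1), dim = c(3, 1, 1)),
                           xpin = 0, ypin = 0, upin = 0)
  # operator rows: node2: x1 - 2 x2 + x3; node3: x2 - x3 (node1 pinned).
  # red-black order updates node2 (even parity) then node3:
  #   x2 <- 0 + (1 - 0)/(-2) = -0.5 ; x3 <- 0 + (1 - (-0.5))/(-1) = -1.5
  x <- smoother_sweep(array(0, dim = c(3, 1, 1)), prob, "gauss_seidel")
  expect_equal(as.vector(x), c(0, -0.5, -1.5))
  # exact solution is a fixed point of the sweep
  xstar <- array(c(0, -2, -3), dim = c(3, 1, 1))
  expect_equal(as.vector(smoother_sweep(xstar, prob)), c(0, -2, -3),
               tolerance = 1e-14)
})

test_that("Jacobi residual norm is non-increasing on the model problem", {
  # Dirichlet model Poisson problem (uniform diagonal): the Jacobi
  # iteration matrix is symmetric with spectral radius < 1
  g <- make_box(11, 11, 1, h = 1)
  shell <- array(FALSE, dim = c(11, 11, 1))
  shell[c(1, 11), , 1] <- TRUE; shell[, c(1, 11), 1] <- TRUE
  set.seed(21)
  rhs <- array(rnorm(121), dim = c(11, 11, 1))
  prob <- elliptic_problem(g, 1, rhs = rhs, fixed = shell,
                           fixed_values = array(0, dim = c(11, 11, 1)))
  lv <- prob$levels[[1]]
  x <- numeric(121)
  resl2 <- function(x) sqrt(sum(cardiogrid:::level_residual(lv, x, prob$b)^2))
  res <- resl2(x)
  for (i in 1:10) {
    x <- as.vector(smoother_sweep(x, prob, "jacobi"))
    res2 <- resl2(x)
    expect_lte(res2, res + 1e-12)
    res <- res2
  }
})

test_that("zero sources give the constant pinned solution", {
  g <- make_disk(1, 0.25)
  prob <- elliptic_problem(g, 1, rhs = array(0, dim = c(g$nx, g$ny, 1)),
                           xpin = 5, ypin = 5, upin = 1.25, vcycles = 60)
  sol <- solve_elliptic(prob)
  expect_true(sol$converged)
  tis <- g$status != 0
  expect_equal(sol$phi[tis], rep(1.25, sum(tis)), tolerance = 1e-9)
})

test_that("manufactured solutions are recovered to tolerance", {
  set.seed(33)
  g <- make_disk(1, 0.2, c(0.2, 0.6))
  tn <- build_tensor(g, 2, 1)
  W <- build_weights(g, tn)
  phi_star <- array(0, dim = c(g$nx, g$ny, 1))
  xs <- (0:(g$nx - 1)) * g$h
  phi_star[, , 1] <- outer(sin(xs), cos(xs))
  S <- apply_diffusion(phi_star, W)
  pin <- which(g$status != 0, arr.ind = TRUE)[5, ] - 1L
  prob <- elliptic_problem(g, tn, rhs = S, xpin = pin[1], ypin = pin[2],
                           upin = phi_star[pin[1] + 1, pin[2] + 1, 1],
                           tolerance = 1e-10, vcycles = 80)
  sol <- solve_elliptic(prob)
  expect_true(sol$converged)
  tis <- g$status != 0
  expect_lt(max(abs(sol$phi[tis] - phi_star[tis])), 1e-7)
  expect_equal(sol$phi[pin[1] + 1, pin[2] + 1, 1],
               phi_star[pin[1] + 1, pin[2] + 1, 1])   # pin imposed exactly
})

test_that("multigrid agrees with a dense direct solve on tiny grids", {
  set.seed(41)
  g <- make_box(5, 5, 5, h = 0.4)
  tn <- build_tensor(g, 1.5, 0.5)
  W <- build_weights(g, tn)
  rhs <- array(rnorm(125), dim = c(5, 5, 5))
  prob <- elliptic_problem(g, tn, rhs = rhs, xpin = 2, ypin = 2, zpin = 2,
                           upin = 0.3, tolerance = 1e-12, upper_level = 1)
  sol <- suppressWarnings(solve_elliptic(prob))
  A <- W$sparse
  n <- 125
  pin <- 1 + 2 + 5 * (2 + 5 * 2)
  free <- setdiff(seq_len(n), pin)
  Ad <- as.matrix(A[free, free])
  bd <- as.vector(rhs)[free] - as.vector(A[free, pin]) * 0.3
  xd <- numeric(n); xd[pin] <- 0.3; xd[free] <- solve(Ad, bd)
  expect_lt(max(abs(as.vector(sol$phi) - xd)), 1e-8)
})

test_that("shifting the pin value shifts the solution by the same constant", {
  set.seed(55)
  g <- make_disk(1, 0.25, c(0.2, 0.2))
  W <- build_weights(g, 1)
  phi_star <- array(rnorm(g$nx * g$ny), dim = c(g$nx, g$ny, 1))
  S <- apply_diffusion(phi_star, W)
  mk <- function(upin) {
    prob <- elliptic_problem(g, 1, rhs = S, xpin = 5, ypin = 5, upin = upin,
                             tolerance = 1e-11, vcycles = 60)
    solve_elliptic(prob)$phi
  }
  p0 <- mk(0); p1 <- mk(2.5)
  tis <- g$status != 0
  expect_equal(p1[tis] - p0[tis], rep(2.5, sum(tis)), tolerance = 1e-8)
})

test_that("multigrid beats plain Gauss-Seidel in fine-grid sweep equivalents", {
  g <- make_box(65, 65, 1, h = 1 / 64)
  set.seed(77)
  rhs <- array(0, dim = c(65, 65, 1))
  rhs[2:64, 2:64, 1] <- rnorm(63^2)
  prob <- elliptic_problem(g, 1, rhs = rhs, xpin = 32, ypin = 32, upin = 0,
                           tolerance = 1e-6, vcycles = 40)
  sol <- solve_elliptic(prob)
  expect_true(sol$converged)
  # pure Gauss-Seidel from the same start, allowed the same sweep budget
  x <- numeric(65 * 65)
  lv <- prob$levels[[1]]
  for (i in seq_len(sol$sweeps)) x <- cardiogrid:::sweep_gs_rb(lv, x, prob$b)
  res_gs <- cardiogrid:::level_residual_max(lv, x, prob$b)
  expect_gt(res_gs, sol$residual * 10)
})
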