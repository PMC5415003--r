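decay <- rhs_model("decay", 1, function(s, p) -s)
frozen <- rhs_model("frozen", 1, function(s, p) 0)

test_that("forward Euler performs the textbook update", {
  expect_equal(euler_step(1, decay, k = 0.1), 0.9)
  expect_equal(euler_step(euler_step(1, decay, k = 0.1), decay, k = 0.1), 0.81)
  expect_equal(euler_step(c(2.5), frozen, k = 0.3), 2.5)
  bad <- rhs_model("bad", 2, function(s, p) c(0, NaN))
  expect_error(euler_step(c(1, 1), bad, k = 0.1), "variable index 2")
})

test_that("euler delegates to direct-step models", {
  dm <- rhs_model("direct", 1, rhs = NULL,
                  step = function(s, p, k) s * exp(-k))
  expect_equal(euler_step(2, dm, k = 0.5), 2 * exp(-0.5))
})

test_that("RK4 matches the degree-4 Taylor polynomial on linear problems", {
  # scalar: 1 - 0.1 + 0.1^2/2 - 0.1^3/6 + 0.1^4/24
  expect_equal(rk4_step(1, decay, k = 0.1), 0.9048375, tolerance = 1e-12)
  expect_equal(rk4_step(3.2, frozen, k = 0.7), 3.2)
  # system: one RK4 step = degree-4 truncation of the matrix exponential
  set.seed(3)
  A <- matrix(rnorm(9), 3, 3)
  lin <- rhs_model("lin", 3, function(s, p) as.vector(A %*% s))
  y0 <- rnorm(3)
  k <- 0.05
  T4 <- diag(3) + k * A + (k * A) %*% (k * A) / 2 +
    (k * A) %*% (k * A) %*% (k * A) / 6 +
    (k * A) %*% (k * A) %*% (k * A) %*% (k * A) / 24
  expect_equal(rk4_step(y0, lin, k = k), as.vector(T4 %*% y0),
               tolerance = 1e-12)
})

test_that("measured convergence orders: Euler near 1, RK4 near 4", {
  ks <- 0.2 / 2^(0:4)
  err <- sapply(ks, function(k) {
    n <- round(1 / k)
    ye <- 1; yr <- 1
    for (i in seq_len(n)) {
      ye <- euler_step(ye, decay, k = k)
      yr <- rk4_step(yr, decay, k = k)
    }
    c(e = abs(ye - exp(-1)), r = abs(yr - exp(-1)))
  })
  fit <- function(e) unname(coef(lm(log(e) ~ log(ks)))[2])
  expect_equal(fit(err["e", ]), 1, tolerance = 0.1)
  expect_equal(fit(err["r", ]), 4, tolerance = 0.2)
})

test_that("Rush-Larsen gate step is exact, stable, and bounded", {
  expect_equal(rush_larsen_gate_step(0, 1, 1, log(2)), 0.375,
               tolerance = 1e-14)
  expect_equal(rush_larsen_gate_step(0.2, 3, 1, 1e4), 0.75,
               tolerance = 1e-12)                  # k -> inf limit is y_inf
  yinf <- 0.6
  expect_equal(rush_larsen_gate_step(yinf, 3, 2, 0.1), yinf)
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5); y <- runif(1)
    k <- runif(1, 0, 10)
    y2 <- rush_larsen_gate_step(y, a, b, k)
    expect_true(y2 >= 0 && y2 <= 1)
    expect_lte(abs(y2 - a / (a + b)), abs(y - a / (a + b)))
  }
  # alpha + beta = 0: no dynamics, gate returned unchanged
  expect_identical(suppressMessages(rush_larsen_gate_step(0.4, 0, 0, 0.1)),
                   0.4)
})

test_that("matrix Rush-Larsen equals the dense matrix exponential", {
  expect_equal(matrix_rush_larsen_step(c(0.3, 0.7), matrix(0, 2, 2), 1),
               c(0.3, 0.7))
  M <- matrix(c(-1, 1, 1, -1), 2, 2)
  u <- matrix_rush_larsen_step(c(1, 0), M, 0.5)
  expect_equal(u, c((1 + exp(-1)) / 2, (1 - exp(-1)) / 2), tolerance = 1e-12)
  expect_equal(matrix_rush_larsen_step(c(1, 0), M, 1e3), c(0.5, 0.5),
               tolerance = 1e-12)
  set.seed(8)
  for (n in 2:6) {
    M <- random_rate_matrix(n)
    u0 <- runif(n); u0 <- u0 / sum(u0)
    k <- runif(1, 0.05, 1)
    oracle <- as.vector(as.matrix(Matrix::expm(k * M)) %*% u0)
    expect_lt(max(abs(matrix_rush_larsen_step(u0, M, k) - oracle)), 1e-10)
    expect_equal(sum(matrix_rush_larsen_step(u0, M, k)), 1, tolerance = 1e-12)
  }
})

test_that("defective matrices fall back to scaling-and-squaring", {
  J <- matrix(c(1, 0, 1, 1), 2, 2)      # Jordan block, not diagonalizable
  expect_warning(Tm <- rl_step_matrix(J, 1), "falling back")
  expect_equal(Tm, as.matrix(Matrix::expm(J)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("tabulation reproduces grid nodes exactly and clamps out of range", {
  tab <- tabulate_rates(list(f = function(v) exp(v), g = function(v) v^2),
                        -1, 1, n = 21)
  v <- seq(-1, 1, length.out = 21)
  expect_identical(table_lookup(tab, "f", v[7]), exp(v[7]))
  # nearest-node semantics with ties to the lower index
  tab2 <- tabulate_rates(list(f = function(v) v), 0, 1, n = 2)
  expect_identical(table_lookup(tab2, "f", 0.5), 0)   # midpoint -> lower
  expect_identical(table_lookup(tab2, "f", 0.51), 1)
  expect_equal(table_clamp_count(tab2), 0)
  expect_identical(table_lookup(tab2, "f", 2), 1)     # clamped to end entry
  expect_equal(table_clamp_count(tab2), 1)
})

test_that("ionic step composes Euler, gate RL and matrix RL correctly", {
  # a single univariate Markov part with no remainder = plain matrix RL
  M <- random_rate_matrix(3)
  spec <- toy_markov_channel(3, M)
  u0 <- c(0.2, 0.5, 0.3)
  st <- ionic_step(c(0, u0), spec, k = 0.4)
  expect_equal(st[-1], matrix_rush_larsen_step(u0, M, 0.4), tolerance = 1e-13)

  # two commuting parts: Lie splitting is exact
  spec2 <- toy_markov_channel(3, M, 0.5 * M, sigma = function(w) 1)
  st2 <- ionic_step(c(0, u0), spec2, k = 0.4)
  oracle <- as.vector(as.matrix(Matrix::expm(0.4 * 1.5 * M)) %*% u0)
  expect_lt(max(abs(st2[-1] - oracle)), 1e-10)

  # clamped-voltage gates relax along the exact exponential
  hh <- hodgkin_huxley_ionic()
  Vc <- -40
  st <- c(Vc, 0.1, 0.9, 0.2)
  hh$other_rhs <- function(state, params) 0    # clamp V
  out <- ionic_step(st, hh, k = 0.7)
  for (gi in 1:3) {
    g <- hh$gates[[gi]]
    a <- g$alpha(Vc); b <- g$beta(Vc)
    exact <- a / (a + b) + (st[1 + gi] - a / (a + b)) * exp(-(a + b) * 0.7)
    expect_equal(out[1 + gi], exact, tolerance = 1e-14)
  }
})

test_that("tabulated stepping tracks direct stepping through an action potential", {
  hh <- get_model("hh")
  tab <- ionic_tables(hh, k = 0.01, vmin = -100, vmax = 60, n = 1e5)
  s1 <- s2 <- hh_rest_state()
  maxdv <- 0
  vpeak <- -100
  for (i in 1:2000) {
    p <- list(I = if (i * 0.01 < 1) 15 else 0)
    s1 <- ionic_step(s1, hh, p, 0.01, tables = tab)
    s2 <- ionic_step(s2, hh, p, 0.01)
    maxdv <- max(maxdv, abs(s1[1] - s2[1]))
    vpeak <- max(vpeak, s2[1])
  }
  expect_gt(vpeak, 0)               # an action potential actually fired
  # nearest-node lookup error, largest at the upstroke; self-comparison
  # bound frozen at 2e-3 mV over a ~105 mV action potential
  expect_lt(maxdv, 2e-3)
})

test_that("the solver registry resolves device names", {
  expect_identical(get_solver("euler")(1, decay, list(), 0.1), 0.9)
  expect_error(get_solver("nope"), "unknown solver")
})
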