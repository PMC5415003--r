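# ---------------------------------------------------------------------------
# Exact-solution verification benchmarks and convergence-order estimation.
#   1. Isotropic diffusion of the first radial Bessel mode on a disk with
#      no-flux boundaries: u = J0(gamma*r) exp(-gamma^2 t), gamma the first
#      positive root of J0'.
#   2. Bidomain plane-wave propagation of bistable (ZFK/Nagumo) kinetics on
#      a square with Dirichlet boundary data from the exact front solution.
# Errors are measured in the L-infinity and L2 norms, with all time/space
# integrals by the trapezoidal rule, and convergence orders by least-squares
# slopes of log(error) against log(h).
# ---------------------------------------------------------------------------

#' First positive root of the derivative of the Bessel function J0
#'
#' The decay-rate parameter of the disk verification problem: the smallest
#' `gamma > 0` with `J0'(gamma) = 0` (equivalently the first zero of `J1`,
#' since `J0' = -J1`), found by bracketing on (0, 5) and bisection to 1e-12.
#'
#' @param tol bisection half-width target (default 1e-12).
#' @return the root, approximately 3.8317.
#' @export
gamma_root <- function(tol = 1e-12) {
  f <- function(r) -besselJ(r, 1)   # J0'(r)
  lo <- NA; hi <- NA
  xs <- seq(0.05, 5, by = 0.05)
  fx <- f(xs)
  for (i in seq_len(length(xs) - 1)) {
    if (fx[i] < 0 && fx[i + 1] >= 0) { lo <- xs[i]; hi <- xs[i + 1]; break }
  }
  if (is.na(lo)) stop("no sign change of J0' found in (0, 5)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Error norms over a space-time history
#'
#' `L-infinity`: maximum absolute error over all times and tissue nodes.
#' `L2`: `sqrt( (T * mu(D))^-1 * int_0^T int_D eps^2 )` with trapezoidal
#' weights in time and the tissue area `mu(D) = n_tissue * h^2` (or `h^3`);
#' spatial integration is `h^d * sum` over tissue nodes.
#'
#' @param num,exact numeric matrices `(n_times x n_nodes)` of the numeric
#'   and exact solutions at the tissue nodes (matching sampling grids).
#' @param k time step between consecutive rows.
#' @param h space step.
#' @param d spatial dimension entering the volume element (default 2).
#' @return named numeric `c(Linf, L2)`.
#' @export
error_norms <- function(num, exact, k, h, d = 2) {
  num <- as.matrix(num); exact <- as.matrix(exact)
  if (!all(dim(num) == dim(exact))) stop("sampling grids do not match")
  if (nrow(num) < 2) stop("history must contain at least two time levels")
  eps <- num - exact
  nt <- nrow(eps); nn <- ncol(eps)
  wt <- rep(1, nt); wt[c(1, nt)] <- 0.5
  Tlen <- (nt - 1) * k
  mu <- nn * h^d
  sq <- rowSums(eps^2) * h^d          # spatial integral per time level
  L2 <- sqrt(sum(wt * sq) * k / (Tlen * mu))
  c(Linf = max(abs(eps)), L2 = L2)
}

# online accumulator used by the benchmark runs (identical arithmetic)
norm_accumulator <- function(n_tissue, h, d = 2) {
  e <- new.env(parent = emptyenv())
  e$maxabs <- 0; e$sumsq <- 0; e$prev_sq <- NA; e$nt <- 0L; e$k <- NA
  e$add <- function(eps, w) {
    e$maxabs <- max(e$maxabs, max(abs(eps)))
    e$sumsq <- e$sumsq + w * sum(eps^2) * h^d
    e$nt <- e$nt + 1L
  }
  e$norms <- function(Tlen) {
    mu <- n_tissue * h^d
    c(Linf = e$maxabs, L2 = sqrt(e$sumsq * e$k / (Tlen * mu)))
  }
  e
}

#' Disk-diffusion verification run
#'
#' Solves `u_t = Laplacian(u)` on the unit disk (tissue indicator geometry
#' from [make_disk()], no-flux boundaries from the stencil) with initial
#' condition `u = J0(gamma*r)`, by forward Euler with the 19-point stencil,
#' and accumulates the error against the exact solution
#' `u = J0(gamma*r) exp(-gamma^2 t)` at every step.
#'
#' @param h space step (<= 0.5).
#' @param offset disk-centre offset `(dx, dy)` in units of `h`.
#' @param T final time (default 0.2).
#' @param k time step (default `h^2/80`).
#' @return named numeric `c(Linf, L2)`; attributes `centre_final`
#'   (numerical amplitude at the node nearest the centre at `T`) and
#'   `n_tissue`.
#' @export
bessel_disk_run <- function(h, offset = c(0, 0), T = 0.2, k = h^2 / 80) {
  stopifnot(h <= 0.5)
  gam <- gamma_root()
  geom <- make_disk(1, h, offset)
  ctr <- attr(geom, "centre")
  W <- build_weights(geom, 1, h)
  tis <- which(geom$status != 0)
  xs <- (0:(geom$nx - 1)) * h
  r2 <- outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`)
  u0_spatial <- besselJ(gam * sqrt(as.vector(r2)), 0)
  u <- numeric(geom$nx * geom$ny)
  u[tis] <- u0_spatial[tis]
  A <- W$sparse
  nsteps <- round(T / k)
  acc <- norm_accumulator(length(tis), h, d = 2)
  acc$k <- k
  acc$add(numeric(length(tis)), 0.5)          # t = 0: zero error
  decay <- exp(-gam^2 * k)
  efac <- 1
  for (n in seq_len(nsteps)) {
    u <- u + k * as.vector(A %*% u)
    if (any(!is.finite(u[tis]))) stop("disk run unstable: non-finite field")
    efac <- efac * decay
    eps <- u[tis] - u0_spatial[tis] * efac
    acc$add(eps, if (n == nsteps) 0.5 else 1)
  }
  out <- acc$norms(nsteps * k)
  ci <- round(ctr / h) + 1
  attr(out, "centre_final") <- array(u, dim = c(geom$nx, geom$ny))[ci[1], ci[2]]
  attr(out, "n_tissue") <- length(tis)
  out
}

#' Bidomain plane-wave verification run
#'
#' Runs the four-substep bidomain splitting scheme for the bistable
#' one-variable kinetics on the square `[0, L]^2`, with initial and
#' (non-homogeneous Dirichlet) boundary conditions taken from the exact
#' travelling-front solution; the boundary values on the one-node shell
#' surrounding the interior subgrid are refreshed from the exact solution
#' every step.  Errors are measured on V against the exact front over the
#' interior nodes at every step.
#'
#' @param h space step (`L/h` integral).
#' @param theta propagation angle (default 0: axis-aligned).
#' @param L,T domain size and final time.
#' @param alpha kinetics threshold.
#' @param Di_par,Di_trans,De_par,De_trans diffusivities.
#' @param s initial front phase.
#' @param k time step (default `3 h^2 / (16 De_par)`, the stability-limited
#'   choice scaled with `h^2`).
#' @param tolerance elliptic residual tolerance per step.
#' @return named numeric `c(Linf, L2)`; attributes `speed` (measured front
#'   speed from mid-row crossings) and `n_interior`.
#' @export
bidomain_planewave_run <- function(h, theta = 0, L = 10, T = 40,
                                   alpha = 0.13, Di_par = 2, Di_trans = 0.2,
                                   De_par = 8, De_trans = 2, s = -5,
                                   k = 3 * h^2 / (16 * De_par),
                                   tolerance = 1e-7) {
  stopifnot(abs(L / h - round(L / h)) < 1e-9, h <= 1)
  N <- round(L / h) + 1                     # interior nodes per axis
  n <- N + 2                                # plus the Dirichlet shell
  geom <- make_box(n, n, 1, h = h, rind = FALSE)
  pw <- planewave_params(alpha, Di_par, Di_trans, De_par, De_trans, theta)
  idx0 <- 0:(n - 1)
  X <- outer(idx0 - 1, rep(1, n)) * h       # physical x, interior x in [0,L]
  Y <- outer(rep(1, n), idx0 - 1) * h
  shell <- array(FALSE, dim = c(n, n, 1))
  shell[c(1, n), , 1] <- TRUE
  shell[, c(1, n), 1] <- TRUE
  kin <- function(V) V * (V - alpha) * (1 - V)
  cfg <- bidomain_config(geom, Di_par, Di_trans, De_par, De_trans, kin,
                         h = h, fixed = shell, tolerance = tolerance)
  ex0 <- planewave_exact(X, Y, 0, s, pw, theta)
  V <- array(ex0$V, dim = c(n, n, 1))
  Phi <- array(ex0$Phi, dim = c(n, n, 1))
  interior <- which(!shell)
  nsteps <- round(T / k)
  acc <- norm_accumulator(length(interior), h, d = 2)
  acc$k <- k
  acc$add(numeric(length(interior)), 0.5)
  state <- list(V = V, Phi = Phi)
  midj <- (n + 1) %/% 2
  speed_t <- numeric(0); speed_x <- numeric(0)
  sample_every <- max(1L, nsteps %/% 200L)
  exn <- planewave_exact(X, Y, 0, s, pw, theta)
  for (nstep in seq_len(nsteps)) {
    state$V[shell] <- exn$V[shell]
    phi_fix <- array(0, dim = dim(state$Phi))
    phi_fix[shell] <- exn$Phi[shell]
    state <- bidomain_substep_sequence(state, cfg, k,
                                       phi_fixed_values = phi_fix)
    tn1 <- nstep * k
    exn1 <- planewave_exact(X, Y, tn1, s, pw, theta)
    exn <- exn1
    eps <- state$V[interior] - exn1$V[interior]
    if (any(!is.finite(eps))) stop("plane-wave run unstable: non-finite field")
    acc$add(eps, if (nstep == nsteps) 0.5 else 1)
    if (theta == 0 && nstep %% sample_every == 0) {
      row <- state$V[2:(n - 1), midj, 1]
      xr <- (0:(N - 1)) * h
      ic <- which(row[-N] >= 0.5 & row[-1] < 0.5)
      if (length(ic) == 1) {
        fr <- (row[ic] - 0.5) / (row[ic] - row[ic + 1])
        xc <- xr[ic] + fr * h
        if (xc > 1 && xc < L - 1) {
          speed_t <- c(speed_t, tn1); speed_x <- c(speed_x, xc)
        }
      }
    }
  }
  out <- acc$norms(nsteps * k)
  attr(out, "n_interior") <- length(interior)
  if (length(speed_t) >= 3) {
    attr(out, "speed") <- unname(coef(lm(speed_x ~ speed_t))[2])
  }
  out
}

#' Assemble a convergence table for the disk benchmark
#'
#' Runs [bessel_disk_run()] for every combination of space step and centre
#' offset and collects the error norms.
#'
#' @param hs decreasing space steps (default the sqrt(2)-refinement
#'   sequence 0.4 ... 0.0707).
#' @param offsets matrix of `(dx, dy)` centre offsets in units of `h`
#'   (default the four standard placements).
#' @param T final time.
#' @return a `convergence_table` data.frame with columns `h`, `dx`, `dy`,
#'   `Linf`, `L2`.
#' @export
disk_convergence <- function(hs = c(0.4, 0.283, 0.2, 0.141, 0.1, 0.0707),
                             offsets = rbind(c(0, 0), c(0.2, 0.2),
                                             c(0.2, 0.6), c(0.6, 0.6)),
                             T = 0.2) {
  rows <- list()
  for (h in hs) for (r in seq_len(nrow(offsets))) {
    e <- bessel_disk_run(h, offsets[r, ], T)
    rows[[length(rows) + 1]] <- data.frame(h = h, dx = offsets[r, 1],
                                           dy = offsets[r, 2],
                                           Linf = e[["Linf"]], L2 = e[["L2"]])
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("convergence_table", "data.frame")
  tab
}

#' Assemble a convergence table for the bidomain plane-wave benchmark
#'
#' @param hs decreasing space steps (default 1, 0.5, 0.25).
#' @param theta propagation angle.
#' @param ... passed to [bidomain_planewave_run()].
#' @return a `convergence_table` data.frame.
#' @export
planewave_convergence <- function(hs = c(1, 0.5, 0.25), theta = 0, ...) {
  rows <- lapply(hs, function(h) {
    e <- bidomain_planewave_run(h, theta = theta, ...)
    data.frame(h = h, dx = 0, dy = 0, Linf = e[["Linf"]], L2 = e[["L2"]])
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("convergence_table", "data.frame")
  tab
}

#' Fitted convergence orders of a convergence table
#'
#' Ordinary least-squares slope of `log(error)` against `log(h)`, pooling
#' all `(h, offset)` points, per norm.
#'
#' @param table a `convergence_table` (columns `h`, `Linf`, `L2`), or any
#'   data.frame shaped like one with at least 3 distinct `h` values.
#' @return named numeric `c(Linf, L2)` of fitted slopes.
#' @export
fit_order <- function(table) {
  if (length(unique(table$h)) < 3) stop("need at least 3 h values")
  if (any(table$Linf <= 0) || any(table$L2 <= 0)) {
    stop("errors must be positive for log-log fitting")
  }
  c(Linf = unname(coef(lm(log(table$Linf) ~ log(table$h)))[2]),
    L2 = unname(coef(lm(log(table$L2) ~ log(table$h)))[2]))
}

#' Plot a convergence table (log-log, with fitted slopes)
#'
#' @param x a `convergence_table`.
#' @param ... ignored.
#' @export
plot.convergence_table <- function(x, ...) {
  sl <- fit_order(x)
  graphics::plot(x$h, x$Linf, log = "xy", pch = 19, col = "firebrick",
                 xlab = "h", ylab = "error norm",
                 ylim = range(c(x$Linf, x$L2)))
  graphics::points(x$h, x$L2, pch = 17, col = "navy")
  graphics::legend("topleft",
                   legend = sprintf(c("Linf (slope %.3f)", "L2 (slope %.3f)"),
                                    sl),
                   pch = c(19, 17), col = c("firebrick", "navy"), bty = "n")
  invisible(x)
}
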