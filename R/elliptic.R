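# ---------------------------------------------------------------------------
# Elliptic solver for the bidomain equation  div((De+Di) grad Phi) = S  with
# no-flux boundaries from the tissue indicator and either a single-point
# pinning condition Phi(pin) = upin (fixing the additive constant of the
# pure-Neumann problem) or a set of fixed (Dirichlet) nodes.
#
# Method: full multigrid (FMG) with vertex-centred transfers -- injection
# restriction, bi/tri-linear prolongation -- red-black Gauss-Seidel or
# Jacobi smoothing, and rediscretized coarse operators built from the
# coarsened tissue indicator.  The discrete operator is the same 19-point
# stencil as the diffusion module (shared code path).
# ---------------------------------------------------------------------------

# ---- vertex-centred grid transfer operators (exported, full-box surface) --

coarse_len <- function(nf) as.integer(ceiling(nf / 2))

#' Restrict a fine-grid layer to the next coarser vertex-centred grid
#'
#' Coarse nodes coincide with the even-index fine nodes (0-based); the
#' transfer is injection, so restriction after prolongation is the identity
#' at coarse nodes and constants are reproduced exactly.
#'
#' @param fine numeric array (1D/2D/3D layer).
#' @return coarse array of dimensions `ceiling(dim(fine)/2)`.
#' @export
restrict_grid <- function(fine) {
  d <- dim(fine)
  if (is.null(d)) d <- c(length(fine), 1, 1)
  fine <- array(fine, dim = d)
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2)
  iz <- seq(1, d[3], by = 2)
  fine[ix, iy, iz, drop = FALSE]
}

axis_restrict_matrix <- function(nc, nf) {
  # full-weighting row [1/4, 1/2, 1/4] about the coincident fine node,
  # renormalized at the ends; used for defect transfer inside the V-cycle
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (c in seq_len(nc)) {
    f <- 2 * c - 1
    w <- c(0.25, 0.5, 0.25)
    fs <- f + (-1:1)
    ok <- fs >= 1 & fs <= nf
    wv <- w[ok] / sum(w[ok])
    rows <- c(rows, rep(c, sum(ok))); cols <- c(cols, fs[ok])
    vals <- c(vals, wv)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nc, nf))
}

restrict_fw <- function(fine) {
  d <- dim(fine)
  out <- fine
  for (ax in 1:3) {
    if (d[ax] > 1) {
      out <- apply_axis(out, axis_restrict_matrix(coarse_len(d[ax]), d[ax]), ax)
    } else if (coarse_len(d[ax]) != d[ax]) {
      out <- restrict_grid(out)
    }
  }
  out
}

axis_prolong_matrix <- function(nf, nc) {
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (f in seq_len(nf)) {
    if (f %% 2 == 1) {
      c1 <- (f + 1) / 2
      rows <- c(rows, f); cols <- c(cols, c1); vals <- c(vals, 1)
    } else {
      c1 <- f / 2; c2 <- c1 + 1
      if (c2 <= nc) {
        rows <- c(rows, f, f); cols <- c(cols, c1, c2); vals <- c(vals, 0.5, 0.5)
      } else {
        rows <- c(rows, f); cols <- c(cols, c1); vals <- c(vals, 1)
      }
    }
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nf, nc))
}

apply_axis <- function(a, M, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  res <- as.matrix(M %*% m)
  dp <- d[perm]; dp[1] <- nrow(M)
  out <- array(res, dim = dp)
  aperm(out, order(perm))
}

#' Prolong a coarse-grid layer to the finer vertex-centred grid
#'
#' Bi/tri-linear interpolation: coincident fine nodes copy the coarse value,
#' in-between nodes average their coarse neighbours.  Linear fields on a
#' full box are prolonged exactly.
#'
#' @param coarse numeric array.
#' @param fine_dim integer target dimensions (per axis, compatible with 2:1
#'   vertex-centred coarsening of the target).
#' @return fine array of dimensions `fine_dim`.
#' @export
prolong_grid <- function(coarse, fine_dim) {
  d <- dim(coarse)
  if (is.null(d)) d <- c(length(coarse), 1, 1)
  coarse <- array(coarse, dim = d)
  fine_dim <- as.integer(fine_dim)
  if (length(fine_dim) < 3) fine_dim <- c(fine_dim, rep(1L, 3 - length(fine_dim)))
  stopifnot(all(coarse_len(fine_dim) == d))
  out <- coarse
  for (ax in 1:3) {
    if (fine_dim[ax] != dim(out)[ax]) {
      out <- apply_axis(out, axis_prolong_matrix(fine_dim[ax], dim(out)[ax]), ax)
    }
  }
  out
}

# ---- solver hierarchy -----------------------------------------------------

coarsen_indicator <- function(psi) {
  d <- dim(psi)
  dc <- coarse_len(d)
  out <- array(0, dim = dc)
  # coarse node tissue if any fine parent (3^d footprint around the
  # coincident fine node) is tissue
  for (qx in -1:1) for (qy in -1:1) for (qz in -1:1) {
    out <- pmax(out, restrict_grid(shift_array(psi, c(qx, qy, qz))))
  }
  array(out, dim = dc)
}

coarsen_tensor <- function(D6, psi) {
  d <- dim(psi)
  dc <- coarse_len(d)
  Dc <- array(0, dim = c(dc, 6))
  wsum <- array(0, dim = dc)
  acc <- vector("list", 6)
  for (m in 1:6) acc[[m]] <- array(0, dim = dc)
  for (qx in -1:1) for (qy in -1:1) for (qz in -1:1) {
    q <- c(qx, qy, qz)
    w <- restrict_grid(shift_array(psi, q))
    # coincident fine node dominates: give it a large weight
    if (all(q == 0)) w <- w * 100
    wsum <- wsum + w
    for (m in 1:6) {
      plane <- array(D6[, , , m], dim = d)
      acc[[m]] <- acc[[m]] + w * restrict_grid(shift_array(plane, q))
    }
  }
  wpos <- wsum > 0
  for (m in 1:6) {
    plane <- acc[[m]]
    plane[wpos] <- plane[wpos] / wsum[wpos]
    Dc[, , , m] <- plane
  }
  Dc
}

make_level <- function(status, D6, h, fixed, pin_lin, A = NULL) {
  d <- dim(status)
  if (is.null(A)) {
    wr <- build_weights_raw(status, D6, h)
    A <- weights_to_sparse(wr)
  }
  n <- prod(d)
  dg <- Matrix::diag(A)
  tissue <- as.vector(status != 0)
  fixedv <- as.vector(fixed)
  free <- tissue & !fixedv
  if (!is.null(pin_lin)) free[pin_lin] <- FALSE
  idx <- arrayInd(seq_len(n), d)
  col2 <- (rowSums(idx) %% 2) == 0
  isolated <- free & dg == 0
  if (any(isolated)) free[isolated] <- FALSE
  lv <- new.env(parent = emptyenv())
  lv$dim <- d; lv$status <- status; lv$D6 <- D6; lv$h <- h
  lv$A <- A; lv$diag <- dg; lv$free <- free; lv$fixed <- fixedv
  lv$pin <- pin_lin; lv$red <- col2; lv$isolated_count <- sum(isolated)
  # colour-split row blocks for fast red-black sweeps
  lv$redi <- which(free & col2)
  lv$blacki <- which(free & !col2)
  lv$freei <- which(free)
  lv$Ared <- A[lv$redi, , drop = FALSE]
  lv$Ablack <- A[lv$blacki, , drop = FALSE]
  lv$Afree <- A[lv$freei, , drop = FALSE]
  if (!is.null(pin_lin)) {
    # free rows coupled to the pin: the only rows where the (otherwise
    # residual-invisible) constant error mode shows up
    col <- as.vector(A[, pin_lin])
    nbr <- which(col != 0 & free)
    lv$pin_nbr <- nbr
    lv$pin_w <- col[nbr]
  }
  lv
}

# constant-mode correction for pinned pure-Neumann problems: a constant
# error c on the free nodes leaves zero residual except in the pin-neighbour
# rows (r_i -> r_i + c*a_ip); pick the least-squares shift and apply it
pin_constant_fix <- function(lv, x, b) {
  if (is.null(lv$pin) || !length(lv$pin_nbr)) return(x)
  r <- b[lv$pin_nbr] - as.vector(lv$A[lv$pin_nbr, , drop = FALSE] %*% x)
  chat <- sum(r * lv$pin_w) / sum(lv$pin_w^2)
  x[lv$freei] <- x[lv$freei] - chat
  x
}

# full 3D transfer matrices between a level pair (built lazily, cached).
# Prolongation is masked to coarse tissue: interpolation weights reaching
# coarse void nodes are dropped and the remaining row weights renormalized,
# so boundary-adjacent fine nodes never average in meaningless void zeros.
level_transfers <- function(lvf, lvc) {
  if (is.null(lvf$Rmat)) {
    df <- lvf$dim; dc <- lvc$dim
    Rx <- axis_restrict_matrix(dc[1], df[1])
    Ry <- axis_restrict_matrix(dc[2], df[2])
    Rz <- axis_restrict_matrix(dc[3], df[3])
    R <- Matrix::kronecker(Rz, Matrix::kronecker(Ry, Rx))
    if (!is.null(lvf$status) && any(lvf$status == 0)) {
      # drop full-weighting contributions from void fine nodes and
      # renormalize, so boundary defects are not diluted by zeros
      keep <- as.numeric(as.vector(lvf$status != 0))
      R <- R %*% Matrix::Diagonal(x = keep)
      rs <- as.vector(R %*% rep(1, ncol(R)))
      R <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% R
    }
    lvf$Rmat <- R
    Px <- axis_prolong_matrix(df[1], dc[1])
    Py <- axis_prolong_matrix(df[2], dc[2])
    Pz <- axis_prolong_matrix(df[3], dc[3])
    P <- Matrix::kronecker(Pz, Matrix::kronecker(Py, Px))
    if (!is.null(lvc$status) && any(lvc$status == 0)) {
      keep <- as.numeric(as.vector(lvc$status != 0))
      P <- P %*% Matrix::Diagonal(x = keep)
      rs <- as.vector(P %*% rep(1, ncol(P)))
      scale <- ifelse(rs > 0, 1 / rs, 0)
      P <- Matrix::Diagonal(x = scale) %*% P
    }
    lvf$Pmat <- P
  }
  invisible(NULL)
}

build_hierarchy <- function(status, D6, h, fixed, pin_lin, upper_level) {
  levels <- list(make_level(status, D6, h, fixed, pin_lin))
  if (levels[[1]]$isolated_count > 0) {
    warning("elliptic: ", levels[[1]]$isolated_count,
            " isolated tissue node(s) held at their current value")
  }
  psi <- array(as.numeric(status != 0), dim = dim(status))
  fx <- fixed
  pl <- pin_lin
  depth <- 0
  while (depth < upper_level) {
    d <- dim(psi)
    dc <- coarse_len(d)
    if (all(dc == d) || any(dc[d > 1] < 3)) {
      if (depth < upper_level) {
        warning(sprintf(
          "elliptic: grid not coarsenable below level %d (requested %d)",
          depth, upper_level))
      }
      break
    }
    statc <- coarsen_indicator(psi)
    D6c <- coarsen_tensor(levels[[length(levels)]]$D6, psi)
    fxc <- restrict_grid(array(as.numeric(fx), dim = d)) > 0
    plc <- NULL
    if (!is.null(pl)) {
      p0 <- arrayInd(pl, d) - 1L
      pc <- round(p0 / 2)
      plc <- 1L + pc[1] + dc[1] * (pc[2] + dc[2] * pc[3])
      if (statc[plc] == 0) statc[plc] <- 1   # keep the pin on tissue
    }
    # Galerkin coarse operator A_H = R A_h P: keeps the no-flux boundary
    # rows consistently scaled with the full-weighting defect transfer
    # (rediscretizing from the coarse indicator loses a factor at the
    # boundary rows and stalls the V-cycle)
    lvf <- levels[[length(levels)]]
    lvc_stub <- new.env(parent = emptyenv())
    lvc_stub$dim <- dc; lvc_stub$status <- statc
    level_transfers(lvf, lvc_stub)
    # constrained projection: corrections vanish at fixed/pinned fine
    # nodes, so their rows and columns are masked out of the product
    Zf <- Matrix::Diagonal(x = as.numeric(lvf$free))
    Ac <- lvf$Rmat %*% (Zf %*% lvf$A %*% Zf) %*% lvf$Pmat
    levels[[length(levels) + 1]] <- make_level(statc, D6c, 2 * h, fxc, plc,
                                               A = Ac)
    psi <- array(as.numeric(statc != 0), dim = dc)
    fx <- array(fxc, dim = dc)
    pl <- plc
    depth <- depth + 1
  }
  levels
}

# ---- smoothing ------------------------------------------------------------

level_residual <- function(lv, x, b) {
  r <- numeric(length(x))
  r[lv$freei] <- b[lv$freei] - as.vector(lv$Afree %*% x)
  r
}

level_residual_max <- function(lv, x, b) {
  if (!length(lv$freei)) return(0)
  max(abs(b[lv$freei] - as.vector(lv$Afree %*% x)))
}

sweep_jacobi <- function(lv, x, b) {
  i <- lv$freei
  x[i] <- x[i] + (b[i] - as.vector(lv$Afree %*% x)) / lv$diag[i]
  x
}

sweep_gs_rb <- function(lv, x, b) {
  i <- lv$redi
  if (length(i)) {
    x[i] <- x[i] + (b[i] - as.vector(lv$Ared %*% x)) / lv$diag[i]
  }
  i <- lv$blacki
  if (length(i)) {
    x[i] <- x[i] + (b[i] - as.vector(lv$Ablack %*% x)) / lv$diag[i]
  }
  x
}

#' One smoother sweep of the elliptic solver
#'
#' Performs a single full relaxation sweep on the fine level of an elliptic
#' problem: red-black (two-colour) Gauss-Seidel or Jacobi.  Pinned/fixed
#' nodes are left at their imposed values; isolated tissue nodes (zero
#' centre weight) are held with a warning at setup.
#'
#' @param phi current iterate (array or vector over the grid).
#' @param problem an `elliptic_problem`.
#' @param kind `"gauss_seidel"` (default) or `"jacobi"`.
#' @return the updated iterate, same shape as `phi`.
#' @export
smoother_sweep <- function(phi, problem, kind = c("gauss_seidel", "jacobi")) {
  kind <- match.arg(kind)
  lv <- problem$levels[[1]]
  x <- as.vector(phi)
  x <- impose_bc(lv, x, problem)
  x <- if (kind == "jacobi") sweep_jacobi(lv, x, problem$b) else
    sweep_gs_rb(lv, x, problem$b)
  if (!is.null(dim(phi))) array(x, dim = dim(phi)) else x
}

impose_bc <- function(lv, x, problem) {
  if (any(lv$fixed)) x[lv$fixed] <- problem$fixed_values[lv$fixed]
  if (!is.null(lv$pin)) x[lv$pin] <- problem$upin
  x
}

# ---- V-cycle and FMG ------------------------------------------------------

coarsest_solve <- function(lv, x, b, sweeps = 60) {
  nfree <- length(lv$freei)
  if (nfree == 0) return(x)
  if (nfree <= 600) {
    if (is.null(lv$Ainv)) {
      Af <- as.matrix(lv$A[lv$freei, lv$freei, drop = FALSE])
      lv$Ainv <- tryCatch(solve(Af), error = function(e) NULL)
      lv$Abound <- lv$A[lv$freei, -lv$freei, drop = FALSE]
    }
    if (!is.null(lv$Ainv)) {
      rhs <- b[lv$freei] - as.vector(lv$Abound %*% x[-lv$freei])
      x[lv$freei] <- as.vector(lv$Ainv %*% rhs)
      return(x)
    }
  }
  for (i in seq_len(sweeps)) x <- sweep_gs_rb(lv, x, b)
  x
}

vcycle <- function(levels, l, x, b, preiter, postiter, counter) {
  lv <- levels[[l]]
  if (l == length(levels)) {
    counter$sweeps <- counter$sweeps + 5
    return(coarsest_solve(lv, x, b))
  }
  for (i in seq_len(preiter)) x <- sweep_gs_rb(lv, x, b)
  counter$sweeps <- counter$sweeps + preiter
  lvc <- levels[[l + 1]]
  level_transfers(lv, lvc)
  r <- level_residual(lv, x, b)
  rc <- as.vector(lv$Rmat %*% r)
  rc[!lvc$free] <- 0
  ec <- numeric(prod(lvc$dim))
  ec <- vcycle(levels, l + 1, ec, rc, preiter, postiter, counter)
  ef <- as.vector(lv$Pmat %*% ec)
  x[lv$freei] <- x[lv$freei] + ef[lv$freei]
  for (i in seq_len(postiter)) x <- sweep_gs_rb(lv, x, b)
  counter$sweeps <- counter$sweeps + postiter
  x <- pin_constant_fix(lv, x, b)
  x
}

#' Define an elliptic problem
#'
#' Sets up `div((De+Di) grad Phi) = S` over the tissue of a geometry, with
#' the discrete operator shared with the diffusion module, and either a
#' single-point pin (`xpin`/`ypin`/`zpin`/`upin`, fixing the additive
#' constant of the no-flux problem) or a mask of fixed-value (Dirichlet)
#' nodes.
#'
#' @param geom a `geometry_grid`.
#' @param tensor a `diffusion_tensor` (the summed intra+extracellular
#'   tensor) or a scalar diffusivity.
#' @param rhs right-hand-side layer S (array over the grid).
#' @param xpin,ypin,zpin 0-based grid coordinates of the pin node (must be
#'   tissue); ignored when `fixed` is given.
#' @param upin value imposed at the pin node (default 0).
#' @param fixed optional logical array marking Dirichlet nodes.
#' @param fixed_values numeric array of imposed values where `fixed`.
#' @param tolerance residual max-norm target.
#' @param upper_level number of coarsening levels (default 3).
#' @param vcycles maximum V-cycles per level (default 20).
#' @param preiter,postiter pre-/post-smoothing sweeps per level (1 and 2).
#' @param maxiter cap on total smoother sweeps (default 1e6).
#' @param delta required residual-reduction factor per V-cycle before
#'   leaving a level during the full-multigrid ascent (default 0.5).
#' @param h space step (defaults to `geom$h`).
#' @return an object of class `elliptic_problem`.
#' @export
elliptic_problem <- function(geom, tensor, rhs = NULL,
                             xpin = NULL, ypin = NULL, zpin = 0, upin = 0,
                             fixed = NULL, fixed_values = NULL,
                             tolerance = 1e-8, upper_level = 3, vcycles = 20,
                             preiter = 1, postiter = 2, maxiter = 1e6,
                             delta = 0.5, h = geom$h) {
  if (is.numeric(tensor) && length(tensor) == 1) {
    D6 <- array(0, dim = c(geom$nx, geom$ny, geom$nz, 6))
    D6[, , , 1:3] <- tensor
    tensor <- structure(list(Dpar = tensor, Dtrans = tensor, D = D6),
                        class = "diffusion_tensor")
  }
  pin_lin <- NULL
  if (is.null(fixed)) {
    if (is.null(xpin) || is.null(ypin)) {
      stop("either a pin location or a fixed-node mask is required")
    }
    pin_lin <- 1L + xpin + geom$nx * (ypin + geom$ny * zpin)
    if (geom$status[pin_lin] == 0) stop("pin location is not a tissue node")
    fixed <- array(FALSE, dim = c(geom$nx, geom$ny, geom$nz))
    fixed_values <- numeric(geom$nx * geom$ny * geom$nz)
  } else {
    fixed <- array(as.logical(fixed), dim = c(geom$nx, geom$ny, geom$nz))
    if (is.null(fixed_values)) stop("fixed_values required with fixed mask")
  }
  levels <- build_hierarchy(geom$status, tensor$D, h, fixed, pin_lin,
                            upper_level)
  b <- if (is.null(rhs)) numeric(prod(levels[[1]]$dim)) else as.vector(rhs)
  structure(list(geom = geom, tensor = tensor, levels = levels, b = b,
                 upin = upin, fixed_values = as.vector(fixed_values),
                 tolerance = tolerance, vcycles = vcycles,
                 preiter = preiter, postiter = postiter,
                 maxiter = maxiter, delta = delta),
            class = "elliptic_problem")
}

#' Residual max-norm of an iterate
#' @param problem an `elliptic_problem`.
#' @param phi iterate (array or vector).
#' @param rhs optional right-hand side overriding the one in the problem.
#' @return max-norm of the residual over free tissue nodes.
#' @export
elliptic_residual <- function(problem, phi, rhs = NULL) {
  b <- if (is.null(rhs)) problem$b else as.vector(rhs)
  level_residual_max(problem$levels[[1]], as.vector(phi), b)
}

#' Solve an elliptic problem by full multigrid
#'
#' Full-multigrid schedule: the right-hand side is restricted to the
#' coarsest level, solved there, and the solution prolonged upward; on each
#' level V-cycles (with `preiter`/`postiter` red-black Gauss-Seidel sweeps)
#' run while each cycle still reduces the residual by the factor `delta`;
#' the finest level iterates until the residual max-norm reaches
#' `tolerance` or `vcycles` cycles / `maxiter` sweeps are spent.  When an
#' initial guess is supplied (time-stepping warm start) the FMG descent is
#' skipped and fine-level V-cycles start from it.
#'
#' @param problem an `elliptic_problem`.
#' @param rhs optional right-hand-side layer overriding the stored one.
#' @param init optional initial guess (warm start).
#' @return list with `phi` (solution array), `residual`, `converged`,
#'   `sweeps` (total smoother sweeps), `vcycles` used.
#' @export
solve_elliptic <- function(problem, rhs = NULL, init = NULL) {
  levels <- problem$levels
  nl <- length(levels)
  b <- if (is.null(rhs)) problem$b else as.vector(rhs)
  counter <- new.env(); counter$sweeps <- 0L
  fine <- levels[[1]]
  ncycles <- 0L

  if (is.null(init)) {
    # FMG descent: restrict rhs, solve coarsest, work upward
    bs <- vector("list", nl)
    bs[[1]] <- b
    for (l in 2:max(2, nl)) {
      if (l > nl) break
      bs[[l]] <- as.vector(restrict_grid(array(bs[[l - 1]],
                                               dim = levels[[l - 1]]$dim)))
      bs[[l]][!levels[[l]]$free] <- 0
    }
    x <- numeric(prod(levels[[nl]]$dim))
    x <- impose_bc(levels[[nl]], x, problem)
    x <- coarsest_solve(levels[[nl]], x, bs[[nl]])
    l <- nl - 1
    while (l >= 1) {
      xf <- as.vector(prolong_grid(array(x, dim = levels[[l + 1]]$dim),
                                   levels[[l]]$dim))
      x <- impose_bc(levels[[l]], xf, problem)
      if (l > 1) {
        res <- level_residual_max(levels[[l]], x, bs[[l]])
        for (cyc in seq_len(problem$vcycles)) {
          x <- vcycle(levels, l, x, bs[[l]], problem$preiter,
                      problem$postiter, counter)
          newres <- level_residual_max(levels[[l]], x, bs[[l]])
          if (newres <= problem$tolerance || newres > problem$delta * res) break
          res <- newres
        }
      }
      l <- l - 1
    }
  } else {
    x <- impose_bc(fine, as.vector(init), problem)
  }

  res <- level_residual_max(fine, x, b)
  minres <- res
  converged <- res <= problem$tolerance
  while (!converged && ncycles < problem$vcycles &&
         counter$sweeps < problem$maxiter) {
    x <- vcycle(levels, 1, x, b, problem$preiter, problem$postiter, counter)
    ncycles <- ncycles + 1L
    res <- level_residual_max(fine, x, b)
    if (res < minres) minres <- res
    if (res > 10 * minres && res > problem$tolerance) {
      stop(sprintf(
        "elliptic solver diverging: residual %.3e grew 10x from minimum %.3e after %d cycles",
        res, minres, ncycles))
    }
    converged <- res <= problem$tolerance
  }
  if (!converged) {
    warning(sprintf(
      "elliptic: tolerance %.2e not reached (residual %.3e, %d cycles, %d sweeps)",
      problem$tolerance, res, ncycles, counter$sweeps))
  }
  list(phi = array(x, dim = fine$dim), residual = res, converged = converged,
       sweeps = counter$sweeps, vcycles = ncycles)
}
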