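# ---------------------------------------------------------------------------
# Anisotropic 19-point diffusion operator L u = div(D grad u) with no-flux
# boundaries encoded by the tissue indicator psi: every stencil weight that
# would reach a void node carries a psi factor and is annihilated, and the
# centre weight is the negative sum of the others, so constants are in the
# kernel and no flux leaks through the tissue boundary.
#
# Weight definitions (h = space step, D evaluated at the centre node p
# unless stated otherwise):
#   faces  q = +-e_j           : psi_{p+q} * D_jj / h^2
#   edges  q = +-(e_j + e_k)   : psi_{p+q} * ( 1/2) D_jk / h^2   (j != k)
#   edges  q = +-(e_j - e_k)   : psi_{p+q} * (-1/2) D_jk / h^2
#   corners (all three nonzero): 0
# plus the variable-tensor face correction
#   q = +-e_k: psi_{p+q} psi_{p-q} / (4 h^2) * (+-) sum_j (D_jk^{p+e_j} - D_jk^{p-e_j})
# where a j-term is dropped when either probe node p+-e_j is void.
# 2D grids (nz = 1) restrict offsets to the z = 0 plane.
# ---------------------------------------------------------------------------

# tensor components stored as 6 planes: 11, 22, 33, 12, 13, 23
tensor_plane <- c("11" = 1, "22" = 2, "33" = 3, "12" = 4, "13" = 5, "23" = 6)

#' Build a transversely isotropic diffusion tensor field
#'
#' `D_jk = Dtrans * delta_jk + (Dpar - Dtrans) * f_j * f_k` with `f` the
#' per-node fibre unit vector: eigenvalues `Dpar` (along the fibre, simple)
#' and `Dtrans` (across, double).
#'
#' @param geom a `geometry_grid`.
#' @param Dpar along-fibre diffusivity (should be >= Dtrans; a warning is
#'   issued otherwise and construction proceeds).
#' @param Dtrans cross-fibre diffusivity (> 0).
#' @return object of class `diffusion_tensor`: list with `Dpar`, `Dtrans`
#'   and `D`, an array `c(nx, ny, nz, 6)` of components (11,22,33,12,13,23).
#' @export
build_tensor <- function(geom, Dpar, Dtrans) {
  stopifnot(Dtrans > 0)
  if (Dpar < Dtrans) {
    warning("build_tensor: Dpar < Dtrans (fibre direction is the slow axis)")
  }
  f <- geom$fibre
  D <- array(0, dim = c(geom$nx, geom$ny, geom$nz, 6))
  dd <- Dpar - Dtrans
  D[, , , 1] <- Dtrans + dd * f[, , , 1]^2
  D[, , , 2] <- Dtrans + dd * f[, , , 2]^2
  D[, , , 3] <- Dtrans + dd * f[, , , 3]^2
  D[, , , 4] <- dd * f[, , , 1] * f[, , , 2]
  D[, , , 5] <- dd * f[, , , 1] * f[, , , 3]
  D[, , , 6] <- dd * f[, , , 2] * f[, , , 3]
  structure(list(Dpar = Dpar, Dtrans = Dtrans, D = D),
            class = "diffusion_tensor")
}

#' Per-node diffusion tensor as a 3x3 matrix
#' @param tensor a `diffusion_tensor`.
#' @param i,j,l 1-based node indices.
#' @return symmetric 3x3 matrix.
#' @export
tensor_at <- function(tensor, i, j, l = 1) {
  d <- tensor$D[i, j, l, ]
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

# shift an array by grid offset q: result[p] = a[p + q], zero outside
shift_array <- function(a, q) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    if (q[ax] >= 0) {
      if (q[ax] >= n) return(out)
      dst[[ax]] <- seq_len(n - q[ax])
      src[[ax]] <- seq_len(n - q[ax]) + q[ax]
    } else {
      if (-q[ax] >= n) return(out)
      dst[[ax]] <- seq_len(n + q[ax]) - q[ax]
      src[[ax]] <- seq_len(n + q[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

stencil_offsets <- function(three_d) {
  faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  edges <- rbind(c(1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0),
                 c(1, 0, 1), c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1),
                 c(0, 1, 1), c(0, -1, -1), c(0, 1, -1), c(0, -1, 1))
  q <- rbind(faces, edges)
  if (!three_d) q <- q[q[, 3] == 0, , drop = FALSE]
  q
}

# internal constructor working on raw arrays (reused on multigrid coarse
# levels where there is no geometry_grid object)
build_weights_raw <- function(status, D6, h) {
  d <- dim(status)
  psi <- array(as.numeric(status != 0), dim = d)
  three_d <- d[3] > 1
  Q <- stencil_offsets(three_d)
  nq <- nrow(Q)
  W <- vector("list", nq)
  comp <- function(j, k) {
    key <- paste0(min(j, k), max(j, k))
    array(D6[, , , tensor_plane[[key]]], dim = d)
  }
  for (o in seq_len(nq)) {
    q <- Q[o, ]
    psi_q <- shift_array(psi, q)
    nz <- which(q != 0)
    if (length(nz) == 1) {
      j <- nz
      w <- psi_q * comp(j, j) / h^2
      # variable-tensor correction for face offsets
      k_ax <- j
      s <- q[k_ax]
      psi_mq <- shift_array(psi, -q)
      corr <- array(0, dim = d)
      probe_axes <- if (three_d) 1:3 else 1:2
      for (jj in probe_axes) {
        ej <- c(0, 0, 0); ej[jj] <- 1
        ok <- shift_array(psi, ej) * shift_array(psi, -ej)
        Djk <- comp(jj, k_ax)
        corr <- corr + ok * (shift_array(Djk, ej) - shift_array(Djk, -ej))
      }
      w <- w + psi_q * psi_mq * s * corr / (4 * h^2)
    } else {
      j <- nz[1]; k <- nz[2]
      sgn <- q[j] * q[k]
      w <- psi_q * sgn * 0.5 * comp(j, k) / h^2
    }
    W[[o]] <- w * psi       # weights exist only at tissue nodes
  }
  Wsum <- Reduce(`+`, W)
  centre <- -Wsum * psi
  list(offsets = Q, W = W, centre = centre, h = h, dim = d, psi = psi)
}

weights_to_sparse <- function(wr) {
  d <- wr$dim
  n <- prod(d)
  idx <- array(seq_len(n), dim = d)
  rows <- list(); cols <- list(); vals <- list()
  for (o in seq_len(nrow(wr$offsets))) {
    q <- wr$offsets[o, ]
    w <- wr$W[[o]]
    nzp <- which(w != 0)
    if (!length(nzp)) next
    tgt <- shift_array(idx, q)     # node index of p+q stored at p
    rows[[length(rows) + 1]] <- nzp
    cols[[length(cols) + 1]] <- tgt[nzp]
    vals[[length(vals) + 1]] <- w[nzp]
  }
  nzc <- which(wr$centre != 0)
  rows[[length(rows) + 1]] <- nzc
  cols[[length(cols) + 1]] <- nzc
  vals[[length(vals) + 1]] <- wr$centre[nzc]
  Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols), x = unlist(vals),
                       dims = c(n, n))
}

#' Build the 19-point stencil weights of the diffusion operator
#'
#' Computes, for every tissue node, the face/edge/centre weights of the
#' anisotropic diffusion operator with no-flux boundary closure by the
#' tissue indicator.  The centre weight is the negative sum of the others,
#' so every row sums to zero and constant fields are annihilated exactly.
#'
#' @param geom a `geometry_grid`.
#' @param tensor a `diffusion_tensor` from [build_tensor()], or a single
#'   scalar diffusivity for the isotropic case.
#' @param h space step (defaults to `geom$h`).
#' @return object of class `stencil_weights` with `offsets` (rows of grid
#'   increments), `W` (list of per-node weight arrays), `centre`, and a
#'   cached sparse-matrix form used by [apply_diffusion()].
#' @export
build_weights <- function(geom, tensor, h = geom$h) {
  stopifnot(h > 0)
  if (is.numeric(tensor) && length(tensor) == 1) {
    D6 <- array(0, dim = c(geom$nx, geom$ny, geom$nz, 6))
    D6[, , , 1:3] <- tensor
    tensor <- structure(list(Dpar = tensor, Dtrans = tensor, D = D6),
                        class = "diffusion_tensor")
  }
  wr <- build_weights_raw(geom$status, tensor$D, h)
  wr$sparse <- weights_to_sparse(wr)
  class(wr) <- "stencil_weights"
  wr
}

#' Apply the diffusion operator to a field layer
#'
#' `(Lu)_p = sum_q W_q^p u_{p+q}` at tissue nodes; the result is 0 at void
#' nodes.  Constant fields map to zero exactly (zero row sums).
#'
#' @param u numeric array with the same spatial dimensions as the geometry
#'   (a single layer), or a vector of matching length.
#' @param weights a `stencil_weights` object.
#' @return array of the same shape containing `L u`.
#' @export
apply_diffusion <- function(u, weights) {
  d <- weights$dim
  if (length(u) != prod(d)) stop("layer does not match the stencil geometry")
  v <- as.vector(weights$sparse %*% as.vector(u))
  array(v, dim = d)
}

#' Forward-Euler diffusion substep
#'
#' `u' = u + k * L u` at tissue nodes (void nodes unchanged): the operator-
#' splitting substep that advances the field as if diffusion were the whole
#' right-hand side.
#'
#' @param u field layer (array or vector).
#' @param weights a `stencil_weights` object.
#' @param k time step (>= 0).
#' @return advanced layer, same shape as `u`.
#' @export
diffstep <- function(u, weights, k) {
  stopifnot(k >= 0)
  out <- u + k * apply_diffusion(u, weights)
  out
}
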