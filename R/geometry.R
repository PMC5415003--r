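#' @importFrom methods as is
#' @importFrom stats lm coef rnorm runif
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# GeometryGrid: regular cuboid grid with a tissue indicator and per-node fibre
# orientation vectors.  Grid coordinates are 0-based integers; the physical
# coordinate of node (i, j, l) is (i*h, j*h, l*h).
# ---------------------------------------------------------------------------

#' Construct a geometry grid
#'
#' A geometry grid holds the tissue indicator (`status`, 0 = void, nonzero =
#' tissue) and the fibre orientation unit vector for every node of a regular
#' `nx` x `ny` x `nz` grid with space step `h`.  Fibre vectors are only
#' meaningful at tissue nodes; they are renormalised to unit length on
#' construction.
#'
#' @param nx,ny,nz positive node counts per axis.
#' @param h space step (model length units).
#' @param status integer array (or vector) of `nx*ny*nz` node statuses.
#' @param fibre numeric array `c(nx, ny, nz, 3)` of fibre vectors, or `NULL`
#'   for the default `(1, 0, 0)` everywhere.
#' @param normalize logical; renormalise fibre vectors at tissue nodes.
#' @return an object of class `geometry_grid`.
#' @export
geometry_grid <- function(nx, ny, nz, h, status, fibre = NULL,
                          normalize = TRUE) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, h > 0)
  status <- array(as.numeric(status), dim = c(nx, ny, nz))
  if (is.null(fibre)) {
    fibre <- array(0, dim = c(nx, ny, nz, 3))
    fibre[, , , 1] <- 1
  } else {
    fibre <- array(as.numeric(fibre), dim = c(nx, ny, nz, 3))
  }
  g <- structure(list(nx = nx, ny = ny, nz = nz, h = h,
                      status = status, fibre = fibre),
                 class = "geometry_grid")
  if (normalize) g <- normalize_fibres(g)
  validate_geometry(g)
  g
}

normalize_fibres <- function(g) {
  tis <- g$status != 0
  if (!any(tis)) return(g)
  f <- matrix(g$fibre, ncol = 3)
  idx <- which(tis)
  nrm <- sqrt(rowSums(f[idx, , drop = FALSE]^2))
  if (any(nrm == 0)) {
    stop("tissue point(s) with zero-length fibre vector: node(s) ",
         paste(head(idx[nrm == 0], 5), collapse = ", "))
  }
  f[idx, ] <- f[idx, , drop = FALSE] / nrm
  g$fibre <- array(f, dim = c(g$nx, g$ny, g$nz, 3))
  g
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "geometry_grid"))
  n <- g$nx * g$ny * g$nz
  if (length(g$status) != n || length(g$fibre) != 3 * n) {
    stop("status/fibre arrays do not match grid dimensions")
  }
  if (!any(g$status != 0)) stop("geometry has no tissue points")
  tis <- which(g$status != 0)
  f <- matrix(g$fibre, ncol = 3)
  nrm <- sqrt(rowSums(f[tis, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("fibre vectors at tissue points are not unit length")
  }
  invisible(g)
}

#' @export
print.geometry_grid <- function(x, ...) {
  nt <- sum(x$status != 0)
  cat(sprintf("geometry_grid: %d x %d x %d, h = %g, %d tissue points (%.1f%%)\n",
              x$nx, x$ny, x$nz, x$h, nt,
              100 * nt / (x$nx * x$ny * x$nz)))
  invisible(x)
}

#' Number of tissue points of a geometry
#' @param geom a `geometry_grid`.
#' @return integer count of nodes with nonzero status.
#' @export
tissue_count <- function(geom) sum(geom$status != 0)

# ---------------------------------------------------------------------------
# .bbg reading and writing.  ASCII, one node per line:
#   x, y, z, status, fibre_x, fibre_y, fibre_z
# Only tissue points need be listed; absent nodes are void.  4-field lines
# (no fibre) are accepted for isotropic runs, with fibre defaulting to (1,0,0).
# ---------------------------------------------------------------------------

#' Read a .bbg geometry file
#'
#' Reads the plain-text geometry format: one node per line with
#' comma-separated fields `x, y, z, status, fibre_x, fibre_y, fibre_z`
#' (0-based integer coordinates).  Lines with only 4 fields get the default
#' fibre `(1, 0, 0)`.  Nodes absent from the file have status 0 (void); the
#' fibre vectors on void lines are ignored.  Fibre vectors at tissue points
#' are renormalised to unit length.
#'
#' @param path path to the file.
#' @param dim optional `c(nx, ny, nz)`; if missing, dimensions are inferred
#'   as the maximum coordinate + 1 (reported via a message).
#' @param h space step to attach to the grid (default 1).
#' @return a `geometry_grid`.
#' @export
read_bbg <- function(path, dim = NULL, h = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#.*)?$", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("geometry has no tissue points (empty file)")
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fld <- strsplit(lines[[i]], ",")[[1]]
    vals <- suppressWarnings(as.numeric(trimws(fld)))
    if (!(length(vals) %in% c(4L, 7L)) || anyNA(vals)) {
      stop(sprintf("parse error in %s at line %d: expected 4 or 7 numeric fields",
                   path, lineno[i]))
    }
    if (any(vals[1:3] < 0) || any(vals[1:3] != floor(vals[1:3]))) {
      stop(sprintf("parse error in %s at line %d: x,y,z must be non-negative integers",
                   path, lineno[i]))
    }
    if (length(vals) == 4L) vals <- c(vals, 1, 0, 0)
    rows[[i]] <- vals
  }
  m <- do.call(rbind, rows)
  if (is.null(dim)) {
    dim <- apply(m[, 1:3, drop = FALSE], 2, max) + 1
    message(sprintf("read_bbg: grid dimensions inferred as %d x %d x %d",
                    dim[1], dim[2], dim[3]))
  }
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  if (any(m[, 1] >= nx | m[, 2] >= ny | m[, 3] >= nz)) {
    stop("node coordinates exceed declared grid dimensions")
  }
  status <- array(0, dim = c(nx, ny, nz))
  fibre <- array(0, dim = c(nx, ny, nz, 3))
  fibre[, , , 1] <- 1
  lin <- 1 + m[, 1] + nx * (m[, 2] + ny * m[, 3])
  if (anyDuplicated(lin)) {
    warning("duplicate coordinates in ", path, "; last occurrence wins")
  }
  n <- nx * ny * nz
  for (i in seq_len(nrow(m))) {
    status[lin[i]] <- m[i, 4]
    if (m[i, 4] != 0) {
      fibre[lin[i]] <- m[i, 5]
      fibre[lin[i] + n] <- m[i, 6]
      fibre[lin[i] + 2 * n] <- m[i, 7]
    }
  }
  geometry_grid(nx, ny, nz, h, status, fibre, normalize = TRUE)
}

#' Write a .bbg geometry file
#'
#' Emits one line per tissue point (`x, y, z, status, fx, fy, fz`); void
#' nodes are omitted.  `read_bbg(write_bbg(g))` reproduces the status and
#' (normalised) fibre fields exactly.
#'
#' @param geom a valid `geometry_grid`.
#' @param path output file path.
#' @export
write_bbg <- function(geom, path) {
  validate_geometry(geom)
  idx <- which(geom$status != 0, arr.ind = TRUE) - 1L
  ord <- order(idx[, 3], idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  lin <- which(geom$status != 0)[ord]
  n <- geom$nx * geom$ny * geom$nz
  lines <- sprintf("%d, %d, %d, %s, %s, %s, %s",
                   idx[, 1], idx[, 2], idx[, 3],
                   format(geom$status[lin], digits = 17, trim = TRUE),
                   format(geom$fibre[lin], digits = 17, trim = TRUE),
                   format(geom$fibre[lin + n], digits = 17, trim = TRUE),
                   format(geom$fibre[lin + 2 * n], digits = 17, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Synthetic geometry generators
# ---------------------------------------------------------------------------

#' Disk geometry
#'
#' Generates the 2D disk domain used by the diffusion verification problem:
#' status 1 exactly where `(x-x0)^2 + (y-y0)^2 <= radius^2`, with the disk
#' centre offset from a grid node by `centre_offset` (in units of `h`), and a
#' one-node rind of void surrounding the disk.  `nz = 1`; fibres default to
#' `(1, 0, 0)`.
#'
#' @param radius disk radius (> 0), physical units.
#' @param h space step; must satisfy `h <= radius`.
#' @param centre_offset numeric length-2, offsets `(dx, dy)` of the disk
#'   centre from the central grid node, in units of `h` (each in `[0, 1)`).
#' @return a `geometry_grid` with attributes `centre` (physical coordinates
#'   of the disk centre) and `radius`.
#' @export
make_disk <- function(radius, h, centre_offset = c(0, 0)) {
  stopifnot(radius > 0, h > 0, length(centre_offset) == 2)
  if (radius < h) stop("degenerate domain: radius < h")
  m <- ceiling(radius / h)
  ngrid <- 2 * m + 3
  ic <- m + 1                 # 0-based index of the central node
  x0 <- (ic + centre_offset[1]) * h
  y0 <- (ic + centre_offset[2]) * h
  xs <- (0:(ngrid - 1)) * h
  dx2 <- outer((xs - x0)^2, (xs - y0)^2, `+`)
  status <- array(as.numeric(dx2 <= radius^2), dim = c(ngrid, ngrid, 1))
  g <- geometry_grid(ngrid, ngrid, 1, h, status)
  attr(g, "centre") <- c(x0, y0)
  attr(g, "radius") <- radius
  g
}

#' Full box geometry
#'
#' A solid cuboid of tissue, optionally surrounded by a one-node void rind.
#'
#' @param nx,ny,nz node counts (including the rind if requested).
#' @param h space step.
#' @param rind logical; if `TRUE` the outermost node shell is void.
#' @param fibre optional constant fibre vector for the whole box.
#' @return a `geometry_grid`.
#' @export
make_box <- function(nx, ny, nz = 1, h = 1, rind = FALSE, fibre = NULL) {
  status <- array(1, dim = c(nx, ny, nz))
  if (rind) {
    # void the outermost shell along every axis long enough to have one
    inner <- array(0, dim = c(nx, ny, nz))
    xr <- if (nx >= 3) 2:(nx - 1) else seq_len(nx)
    yr <- if (ny >= 3) 2:(ny - 1) else seq_len(ny)
    zr <- if (nz >= 3) 2:(nz - 1) else seq_len(nz)
    inner[xr, yr, zr] <- 1
    status <- inner
  }
  fa <- NULL
  if (!is.null(fibre)) {
    fa <- array(0, dim = c(nx, ny, nz, 3))
    for (d in 1:3) fa[, , , d] <- fibre[d]
  }
  geometry_grid(nx, ny, nz, h, status, fa)
}

#' Ball geometry
#'
#' 3D analogue of [make_disk()]: tissue where
#' `(x-x0)^2 + (y-y0)^2 + (z-z0)^2 <= radius^2`.
#'
#' @inheritParams make_disk
#' @param centre_offset numeric length-3 offset of the centre in units of `h`.
#' @return a `geometry_grid`.
#' @export
make_ball <- function(radius, h, centre_offset = c(0, 0, 0)) {
  stopifnot(radius > 0, h > 0, length(centre_offset) == 3)
  if (radius < h) stop("degenerate domain: radius < h")
  m <- ceiling(radius / h)
  ngrid <- 2 * m + 3
  ic <- m + 1
  ctr <- (ic + centre_offset) * h
  xs <- (0:(ngrid - 1)) * h
  d2 <- outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`), (xs - ctr[3])^2, `+`)
  status <- array(as.numeric(d2 <= radius^2), dim = c(ngrid, ngrid, ngrid))
  g <- geometry_grid(ngrid, ngrid, ngrid, h, status)
  attr(g, "centre") <- ctr
  attr(g, "radius") <- radius
  g
}

#' Thickness-step geometry
#'
#' A slab whose thickness jumps from `z1` to `z2` nodes at `x = x_step`
#' (useful for scroll-wave drift studies along a thickness step).
#'
#' @param nx,ny lateral node counts.
#' @param z1,z2 slab thickness (nodes) before and after the step.
#' @param x_step 0-based x index where the thickness changes.
#' @param h space step.
#' @return a `geometry_grid` with a one-node void rind in z above the slab.
#' @export
make_thickness_step <- function(nx, ny, z1, z2, x_step, h = 1) {
  nz <- max(z1, z2) + 1
  status <- array(0, dim = c(nx, ny, nz))
  for (i in seq_len(nx)) {
    depth <- if ((i - 1) < x_step) z1 else z2
    status[i, , seq_len(depth)] <- 1
  }
  geometry_grid(nx, ny, nz, h, status)
}

# ---------------------------------------------------------------------------
# Domain partition planning (MPI-free): split the grid into near-equal
# subintervals per axis; subdomains without tissue are flagged unallocated.
# ---------------------------------------------------------------------------

split_axis <- function(n, s) {
  # subinterval lengths differing by at most 1, remainder to lowest indices
  base <- n %/% s
  sizes <- rep(base, s)
  r <- n %% s
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  sizes
}

#' Plan a domain partition
#'
#' Splits each grid axis into `splits = c(sx, sy, sz)` subintervals of
#' near-equal length (any remainder goes to the lowest-index subintervals),
#' counts tissue points per subdomain and flags idle (zero-tissue) subdomains
#' as unallocated, mimicking the load layout of a distributed run.
#'
#' @param geom a `geometry_grid`.
#' @param splits integer length-3 subinterval counts per axis.
#' @return an object of class `subdomain_plan`: a list with `splits`, a
#'   data.frame `subdomains` (index ranges, `tissue` count, `allocated`),
#'   and `load` statistics (max/mean tissue per allocated subdomain).
#' @export
partition_plan <- function(geom, splits) {
  stopifnot(length(splits) == 3)
  dims <- c(geom$nx, geom$ny, geom$nz)
  if (any(splits < 1) || any(splits > dims)) {
    stop("splits must be between 1 and the axis size")
  }
  ax <- lapply(1:3, function(d) {
    sizes <- split_axis(dims[d], splits[d])
    ends <- cumsum(sizes)
    data.frame(lo = c(1, head(ends, -1) + 1), hi = ends)
  })
  grid <- expand.grid(ix = seq_len(splits[1]), iy = seq_len(splits[2]),
                      iz = seq_len(splits[3]))
  tissue <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    xr <- ax[[1]][grid$ix[r], ]; yr <- ax[[2]][grid$iy[r], ]
    zr <- ax[[3]][grid$iz[r], ]
    tissue[r] <- sum(geom$status[xr$lo:xr$hi, yr$lo:yr$hi, zr$lo:zr$hi] != 0)
  }
  sub <- cbind(grid,
               x0 = ax[[1]]$lo[grid$ix] - 1L, x1 = ax[[1]]$hi[grid$ix] - 1L,
               y0 = ax[[2]]$lo[grid$iy] - 1L, y1 = ax[[2]]$hi[grid$iy] - 1L,
               z0 = ax[[3]]$lo[grid$iz] - 1L, z1 = ax[[3]]$hi[grid$iz] - 1L,
               tissue = tissue, allocated = tissue > 0)
  alloc <- sub$tissue[sub$allocated]
  structure(list(splits = splits, subdomains = sub,
                 load = list(max = max(alloc), mean = mean(alloc),
                             allocated = sum(sub$allocated),
                             idle = sum(!sub$allocated))),
            class = "subdomain_plan")
}

#' @export
print.subdomain_plan <- function(x, ...) {
  cat(sprintf("subdomain_plan: %d x %d x %d = %d subdomains, %d allocated, %d idle\n",
              x$splits[1], x$splits[2], x$splits[3], nrow(x$subdomains),
              x$load$allocated, x$load$idle))
  cat(sprintf("  tissue load per allocated subdomain: max %d, mean %.1f\n",
              x$load$max, x$load$mean))
  invisible(x)
}
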