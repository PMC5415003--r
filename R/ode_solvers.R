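# ---------------------------------------------------------------------------
# Time stepping of cell kinetics.
#   explicit:    forward Euler, classical RK4 (rhs-format models)
#   exponential: Rush-Larsen for gates, matrix Rush-Larsen for Markov chains
#                (ionic-format models), with start-up tabulation of all
#                univariate coefficient functions / step matrices.
# ---------------------------------------------------------------------------

check_finite_deriv <- function(d, where) {
  bad <- which(!is.finite(d))
  if (length(bad)) {
    stop(sprintf("%s: non-finite derivative at variable index %d",
                 where, bad[1]))
  }
  d
}

#' Forward Euler step
#'
#' `state' = state + k * rhs(state)`.  Models that declare a direct-step
#' function (kinetics not naturally expressed as ODEs) have the step
#' delegated to them.
#'
#' @param state numeric state vector.
#' @param model an `rhs_model`.
#' @param params parameter list (merged over the model defaults).
#' @param k time step (> 0).
#' @return the advanced state.
#' @export
euler_step <- function(state, model, params = list(), k) {
  stopifnot(k > 0)
  p <- merge_params(model$defaults, params)
  if (!is.null(model$step)) return(model$step(state, p, k))
  d <- check_finite_deriv(model$rhs(state, p), "euler_step")
  state + k * d
}

#' Classical fourth-order Runge-Kutta step
#'
#' Four-stage RK4; local error O(k^5) for smooth right-hand sides.
#'
#' @inheritParams euler_step
#' @return the advanced state.
#' @export
rk4_step <- function(state, model, params = list(), k) {
  stopifnot(k > 0)
  p <- merge_params(model$defaults, params)
  f <- function(s) check_finite_deriv(model$rhs(s, p), "rk4_step")
  k1 <- f(state)
  k2 <- f(state + k / 2 * k1)
  k3 <- f(state + k / 2 * k2)
  k4 <- f(state + k * k3)
  state + k / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Rush-Larsen step for a gating variable
#'
#' Advances `dy/dt = alpha*(1-y) - beta*y` with rates frozen over the step:
#' `y' = y_inf + (y - y_inf) * exp(-(alpha+beta)*k)` with
#' `y_inf = alpha/(alpha+beta)`.  Exact when the controlling voltage is
#' constant over the step, and unconditionally stable; `y'` stays in [0, 1]
#' whenever `y` does.  When `alpha + beta == 0` there are no dynamics and
#' `y` is returned unchanged (logged once per session).
#'
#' @param y gate value(s) in [0, 1].
#' @param alpha,beta opening/closing rates (same length as `y` or scalar).
#' @param k time step (> 0).
#' @return the advanced gate value(s).
#' @export
rush_larsen_gate_step <- function(y, alpha, beta, k) {
  stopifnot(k > 0)
  s <- alpha + beta
  zero <- s == 0
  if (any(zero)) {
    note_once("rush_larsen_gate_step: alpha + beta = 0 encountered; gate frozen")
    s[zero] <- 1       # placeholder, result overwritten below
  }
  yinf <- alpha / s
  out <- yinf + (y - yinf) * exp(-s * k)
  if (any(zero)) out[zero] <- if (length(y) > 1) y[zero] else y
  out
}

.note_env <- new.env(parent = emptyenv())
note_once <- function(msg) {
  if (!isTRUE(.note_env[[msg]])) {
    message(msg)
    .note_env[[msg]] <- TRUE
  }
}

# --- dense matrix exponential by scaling and squaring (Taylor), used as the
#     fallback when the eigen-decomposition of a rate matrix is defective or
#     ill-conditioned -----------------------------------------------------
expm_taylor_ss <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.eps))))
  B <- A / 2^s
  X <- diag(n)
  term <- diag(n)
  for (j in 1:20) {
    term <- term %*% B / j
    X <- X + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

#' Step matrix of the matrix Rush-Larsen scheme
#'
#' Computes `T = exp(k*M)` through the eigen-decomposition
#' `T = S exp(Lambda k) S^-1` (possibly complex; the imaginary residue of
#' the reconstructed real matrix must be below 1e-10).  If the
#' decomposition is defective or ill-conditioned the function falls back to
#' a scaling-and-squaring Taylor exponential with a warning.
#'
#' @param M rate matrix (square).
#' @param k time step (> 0).
#' @return the real step matrix `exp(k*M)`.
#' @export
rl_step_matrix <- function(M, k) {
  stopifnot(k > 0, nrow(M) == ncol(M))
  if (all(M == 0)) return(diag(nrow(M)))
  Tm <- tryCatch({
    e <- eigen(M)
    S <- e$vectors
    Tc <- S %*% diag(exp(k * e$values), nrow(M)) %*% solve(S)
    if (max(abs(Im(Tc))) > 1e-10) stop("imaginary residue too large")
    Re(Tc)
  }, error = function(err) {
    warning("rl_step_matrix: diagonalization failed (", conditionMessage(err),
            "); falling back to scaling-and-squaring exponential")
    expm_taylor_ss(k * M)
  })
  Tm
}

#' Matrix Rush-Larsen step for a Markov chain
#'
#' Advances the master equation `du/dt = M u` with the rate matrix frozen
#' over the step: `u' = exp(k*M) u`.  If `M` has zero column sums the total
#' probability `sum(u)` is conserved.
#'
#' @param u state-probability vector.
#' @param M rate matrix (frozen over the step).
#' @param k time step (> 0).
#' @return the advanced probability vector.
#' @export
matrix_rush_larsen_step <- function(u, M, k) {
  drop(rl_step_matrix(M, k) %*% u)
}

# ---------------------------------------------------------------------------
# Tabulation: precompute univariate coefficient functions (or step matrices)
# on an equidistant grid of the control variable; lookups snap to the
# nearest grid node (ties to the lower index) and out-of-range queries clamp
# to the end entries, counted and reported at the end of a run.
# ---------------------------------------------------------------------------

#' Tabulate a family of univariate functions
#'
#' @param fn_family named list of univariate functions of the control
#'   variable (vectorised), or functions returning matrices (tabulated
#'   entry-by-entry into a 3D array).
#' @param vmin,vmax control-variable range.
#' @param n number of grid entries (>= 2; default 20000).
#' @return object of class `rate_table` with elements `vmin`, `vmax`, `n`,
#'   `values` (named list of length-`n` vectors or `n`-slice arrays) and a
#'   clamp counter environment.
#' @export
tabulate_rates <- function(fn_family, vmin, vmax, n = 20000) {
  stopifnot(n >= 2, vmax > vmin)
  v <- seq(vmin, vmax, length.out = n)
  values <- lapply(fn_family, function(f) {
    probe <- f(v[1])
    if (is.matrix(probe)) {
      arr <- array(0, dim = c(dim(probe), n))
      for (i in seq_len(n)) arr[, , i] <- f(v[i])
      arr
    } else {
      f(v)
    }
  })
  structure(list(vmin = vmin, vmax = vmax, n = n, grid = v, values = values,
                 clamps = local({e <- new.env(); e$count <- 0L; e})),
            class = "rate_table")
}

#' Index of the nearest tabulation node
#'
#' Nearest-node lookup with ties resolved to the lower index; out-of-range
#' queries clamp to the end entries and increment the table's clamp counter.
#'
#' @param table a `rate_table`.
#' @param v query value(s) of the control variable.
#' @return integer index (vector) into the table grid.
#' @export
table_lookup_index <- function(table, v) {
  step <- (table$vmax - table$vmin) / (table$n - 1)
  # ties (exact midpoints) go to the lower index: round half down
  raw <- (v - table$vmin) / step
  i <- ceiling(raw - 0.5) + 1
  out_of_range <- sum(v < table$vmin | v > table$vmax)
  if (out_of_range > 0) {
    table$clamps$count <- table$clamps$count + out_of_range
  }
  pmin(pmax(i, 1L), table$n)
}

#' Look up one tabulated function
#' @param table a `rate_table`.
#' @param name function name inside the table.
#' @param v query value(s).
#' @return tabulated value(s) (vector entries) or matrix (matrix entries,
#'   scalar `v` only).
#' @export
table_lookup <- function(table, name, v) {
  i <- table_lookup_index(table, v)
  val <- table$values[[name]]
  if (is.array(val) && length(dim(val)) == 3) {
    stopifnot(length(i) == 1)
    val[, , i]
  } else {
    val[i]
  }
}

#' Number of clamped (out-of-range) lookups recorded by a table
#' @param table a `rate_table`.
#' @return integer count.
#' @export
table_clamp_count <- function(table) table$clamps$count

# ---------------------------------------------------------------------------
# ionic step: exponential integration of an ionic-format model
# ---------------------------------------------------------------------------

#' Build the tabulation set for an ionic model
#'
#' Tabulates, for every univariate gate, the Rush-Larsen coefficients
#' (exponential factor `E = exp(-(alpha+beta)k)` and equilibrium `yinf`),
#' and for every univariate Markov part the step matrices `exp(k*M_i(v))`,
#' over the declared control range.  The time step is baked into the table.
#'
#' @param spec an `ionic_model`.
#' @param k time step the table is built for.
#' @param vmin,vmax control-variable range.
#' @param n number of entries (default 20000).
#' @return a `rate_table` (or NULL if nothing is univariate).
#' @export
ionic_tables <- function(spec, k, vmin, vmax, n = 20000) {
  fams <- list()
  for (gi in seq_along(spec$gates)) {
    g <- spec$gates[[gi]]
    if (isTRUE(g$univariate)) {
      local({
        a <- g$alpha; b <- g$beta
        fams[[paste0("gate", gi, "_E")]] <<- function(v) exp(-(a(v) + b(v)) * k)
        fams[[paste0("gate", gi, "_yinf")]] <<- function(v) {
          s <- a(v) + b(v)
          ifelse(s == 0, 0, a(v) / ifelse(s == 0, 1, s))
        }
      })
    }
  }
  for (ci in seq_along(spec$markov_chains)) {
    ch <- spec$markov_chains[[ci]]
    for (pi in seq_along(ch$parts)) {
      local({
        mf <- ch$parts[[pi]]$matrix_fn
        fams[[paste0("chain", ci, "_part", pi)]] <<-
          function(v) rl_step_matrix(mf(v), k)
      })
    }
  }
  if (!length(fams)) return(NULL)
  tabulate_rates(fams, vmin, vmax, n)
}

#' Exponential (Rush-Larsen family) step for an ionic model
#'
#' Non-gate variables advance by forward Euler on `other_rhs`; gates by the
#' Rush-Larsen exponential update (tabulated coefficients when available);
#' Markov chains by Lie splitting over the declared univariate parts, each
#' integrated with the (tabulated) matrix Rush-Larsen step in declaration
#' order, followed by a forward Euler substep on the multivariate remainder
#' if one is declared.
#'
#' @param state full state vector (others, gates, chains).
#' @param spec an `ionic_model`.
#' @param params parameter list.
#' @param k time step (> 0).
#' @param tables optional `rate_table` from [ionic_tables()] (built with the
#'   same `k`); when absent everything is evaluated on the fly.
#' @return the advanced state vector.
#' @export
ionic_step <- function(state, spec, params = list(), k, tables = NULL) {
  stopifnot(k > 0)
  p <- merge_params(spec$defaults, params)
  out <- state
  V <- state[1]
  # other variables: forward Euler
  if (spec$n_other > 0 && !is.null(spec$other_rhs)) {
    d <- check_finite_deriv(spec$other_rhs(state, p), "ionic_step")
    out[seq_len(spec$n_other)] <- state[seq_len(spec$n_other)] + k * d
  }
  # gates: Rush-Larsen
  for (gi in seq_along(spec$gates)) {
    g <- spec$gates[[gi]]
    idx <- spec$gate_index[gi]
    if (!is.null(tables) && isTRUE(g$univariate)) {
      E <- table_lookup(tables, paste0("gate", gi, "_E"), V)
      yinf <- table_lookup(tables, paste0("gate", gi, "_yinf"), V)
      out[idx] <- yinf + (state[idx] - yinf) * E
    } else {
      out[idx] <- rush_larsen_gate_step(state[idx], g$alpha(V), g$beta(V), k)
    }
  }
  # Markov chains: sequential matrix RL over declared parts, then remainder
  for (ci in seq_along(spec$markov_chains)) {
    ch <- spec$markov_chains[[ci]]
    idx <- spec$markov_index[[ci]]
    u <- state[idx]
    for (pi in seq_along(ch$parts)) {
      part <- ch$parts[[pi]]
      w <- state[part$control]
      if (!is.null(tables)) {
        Tm <- table_lookup(tables, paste0("chain", ci, "_part", pi), w)
        u <- drop(Tm %*% u)
      } else {
        u <- matrix_rush_larsen_step(u, part$matrix_fn(w), k)
      }
    }
    if (!is.null(ch$remainder)) {
      R <- ch$remainder(state)
      u <- u + k * drop(R %*% u)
    }
    out[idx] <- u
  }
  out
}

# ---------------------------------------------------------------------------
# Solver registry, mirroring device names
# ---------------------------------------------------------------------------

solver_registry <- list(
  euler = function(state, model, params, k, ...) euler_step(state, model, params, k),
  rk4 = function(state, model, params, k, ...) rk4_step(state, model, params, k),
  rushlarsen = function(state, model, params, k, tables = NULL, ...)
    ionic_step(state, model, params, k, tables))

#' Look up an ODE solver by device name
#' @param name one of `"euler"`, `"rk4"`, `"rushlarsen"`.
#' @return stepping function `(state, model, params, k, ...)`.
#' @export
get_solver <- function(name) {
  s <- solver_registry[[name]]
  if (is.null(s)) stop("unknown solver: ", name)
  s
}
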