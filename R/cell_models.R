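# ---------------------------------------------------------------------------
# Cell excitation kinetics in two formats:
#   rhs   -- a plain right-hand-side function (state, params) -> derivative,
#            used by the generic explicit solvers (euler, rk4);
#   ionic -- the state is partitioned into "other" (non-gate) variables,
#            gating variables with alpha/beta rates, and Markov chains with a
#            declared rate-matrix decomposition, used by the exponential
#            (Rush-Larsen) solver.
# Parameters may be bound to grid layers ("@layer"); the engine resolves
# those to per-node values before the rhs call.
# ---------------------------------------------------------------------------

#' Construct an rhs-format model
#'
#' @param name model name (registry key).
#' @param n_var state dimension.
#' @param rhs function `(state, params) -> derivative vector` of length
#'   `n_var`.  Both vectorised evaluation (state as an `n x n_var` matrix)
#'   and single-state evaluation must be supported.
#' @param defaults named list of default parameter values.
#' @param step optional direct-step function `(state, params, k) -> state'`
#'   for models not naturally expressed as ODE right-hand sides.
#' @param rhs_vec optional vectorised evaluator `(U matrix of n states x
#'   n_var, params with scalar or per-node entries) -> derivative matrix`,
#'   used by the grid engine for whole-layer stepping.
#' @return object of class `rhs_model`.
#' @export
rhs_model <- function(name, n_var, rhs, defaults = list(), step = NULL,
                      rhs_vec = NULL) {
  structure(list(name = name, n_var = n_var, rhs = rhs,
                 defaults = defaults, step = step, rhs_vec = rhs_vec),
            class = "rhs_model")
}

merge_params <- function(defaults, params) {
  out <- defaults
  for (nm in names(params)) out[[nm]] <- params[[nm]]
  out
}

#' Cubic FitzHugh-Nagumo right-hand side
#'
#' `du/dt = (u - u^3/3 - v)/eps + Iu`; `dv/dt = eps*(u + bet - gam*v) + Iv`.
#' The external currents `Iu`, `Iv` default to 0 and are typically bound to
#' the diffusion-term layer in tissue simulations.
#'
#' @param u,v activator and inhibitor values (vectors allowed).
#' @param params list with `eps` (> 0), `bet`, `gam`, optional `Iu`, `Iv`.
#' @return list `(du, dv)`.
#' @export
fhncub_rhs <- function(u, v, params) {
  eps <- params$eps
  if (is.null(eps) || any(eps <= 0)) stop("fhncub: eps must be > 0")
  Iu <- if (is.null(params$Iu)) 0 else params$Iu
  Iv <- if (is.null(params$Iv)) 0 else params$Iv
  list(du = (u - u^3 / 3 - v) / eps + Iu,
       dv = eps * (u + params$bet - params$gam * v) + Iv)
}

#' Barkley model right-hand side
#'
#' `du/dt = u*(1-u)*(u-(v+b)/a)/eps`; `dv/dt = u - v`.  The standard
#' two-variable caricature of excitable media used for spiral-wave studies.
#'
#' @param u,v activator and inhibitor values.
#' @param params list with `a` (nonzero), `b`, `eps` (> 0), optional `Iu`.
#' @return list `(du, dv)`.
#' @export
barkley_rhs <- function(u, v, params) {
  if (is.null(params$eps) || any(params$eps <= 0)) stop("fhnbkl: eps must be > 0")
  if (is.null(params$a) || any(params$a == 0)) stop("fhnbkl: a must be nonzero")
  Iu <- if (is.null(params$Iu)) 0 else params$Iu
  list(du = u * (1 - u) * (u - (v + params$b) / params$a) / params$eps + Iu,
       dv = u - v)
}

#' Zeldovich-Frank-Kamenetsky (Nagumo) right-hand side
#'
#' Single-variable bistable kinetics `dV/dt = V*(V-alpha)*(1-V) + Iu`, the
#' cell model of the bidomain plane-wave verification problem.
#'
#' @param V voltage value(s).
#' @param params list with `alpha`, optional `Iu`.
#' @return `dV/dt`.
#' @export
zfk_rhs <- function(V, params) {
  Iu <- if (is.null(params$Iu)) 0 else params$Iu
  V * (V - params$alpha) * (1 - V) + Iu
}

# ---------------------------------------------------------------------------
# ionic format
# ---------------------------------------------------------------------------

#' Construct an ionic-format model specification
#'
#' The state vector is partitioned as: `n_other` non-gate variables first
#' (the first of which is the transmembrane voltage V), then gates, then
#' Markov-chain blocks.
#'
#' @param name model name.
#' @param n_other number of non-gate, non-Markov variables (V first).
#' @param gates list of gates; each a list with `name`, `alpha`, `beta`
#'   (functions of V, vectorised) and `univariate = TRUE` if the rates depend
#'   on V only (enables tabulation).
#' @param markov_chains list of Markov blocks; each a list with `n_states`,
#'   `parts` (list of univariate parts, each `list(matrix_fn = function(w)
#'   -> rate matrix, control = index of the controlling variable in the full
#'   state)`) and optional `remainder` (`function(state) -> matrix`, small
#'   multivariate residual integrated by forward Euler).
#' @param other_rhs function `(state, params) -> derivatives of the "other"
#'   block` (length `n_other`).
#' @param defaults default parameter list.
#' @return object of class `ionic_model`.
#' @export
ionic_model <- function(name, n_other, gates = list(), markov_chains = list(),
                        other_rhs = NULL, defaults = list()) {
  n_markov <- sum(vapply(markov_chains, function(m) m$n_states, numeric(1)))
  n_var <- n_other + length(gates) + n_markov
  # index bookkeeping: others 1..n_other, gates follow, then chains
  gi <- if (length(gates)) n_other + seq_along(gates) else integer(0)
  mi <- list()
  off <- n_other + length(gates)
  for (j in seq_along(markov_chains)) {
    mi[[j]] <- off + seq_len(markov_chains[[j]]$n_states)
    off <- off + markov_chains[[j]]$n_states
  }
  structure(list(name = name, n_var = n_var, n_other = n_other,
                 gates = gates, gate_index = gi,
                 markov_chains = markov_chains, markov_index = mi,
                 other_rhs = other_rhs, defaults = defaults),
            class = "ionic_model")
}

validate_markov_matrix <- function(M, tol = 1e-12) {
  if (any(M[row(M) != col(M)] < 0)) {
    stop("Markov rate matrix has negative off-diagonal entries")
  }
  cs <- colSums(M)
  if (any(abs(cs) > tol)) {
    stop("Markov rate matrix columns do not sum to zero (max |sum| = ",
         format(max(abs(cs))), ")")
  }
  invisible(M)
}

# Rate functions of the squid-axon excitation model (modern sign convention,
# resting potential near -65 mV).  Removable singularities of the
# (V - V0)/(1 - exp(-(V - V0)/s)) form are filled with their limit value s.
vtrap <- function(x, s) {
  # x/(1 - exp(-x/s)), continuous at x = 0 where the limit is s
  out <- ifelse(abs(x / s) < 1e-7, s / (1 - x / (2 * s)), x / (1 - exp(-x / s)))
  out
}

hh_alpha_m <- function(V) 0.1 * vtrap(V + 40, 10)
hh_beta_m  <- function(V) 4 * exp(-(V + 65) / 18)
hh_alpha_h <- function(V) 0.07 * exp(-(V + 65) / 20)
hh_beta_h  <- function(V) 1 / (1 + exp(-(V + 35) / 10))
hh_alpha_n <- function(V) 0.01 * vtrap(V + 55, 10)
hh_beta_n  <- function(V) 0.125 * exp(-(V + 65) / 80)

#' Hodgkin-Huxley model in ionic format
#'
#' Four state variables: V (mV), and gates m, h, n, with the classical
#' voltage-dependent opening/closing rates (modern sign convention, resting
#' potential about -65 mV).  All gate rates are univariate in V and tagged
#' for tabulation.  Currents: fast sodium (gNa m^3 h), delayed-rectifier
#' potassium (gK n^4) and leak; an external current `I` (uA/cm^2) can be
#' supplied as a parameter.
#'
#' @return an `ionic_model` with state `(V, m, h, n)`.
#' @export
hodgkin_huxley_ionic <- function() {
  defaults <- list(gNa = 120, ENa = 50, gK = 36, EK = -77,
                   gL = 0.3, EL = -54.387, Cm = 1, I = 0)
  other_rhs <- function(state, params) {
    V <- state[1]; m <- state[2]; h <- state[3]; n <- state[4]
    INa <- params$gNa * m^3 * h * (V - params$ENa)
    IK <- params$gK * n^4 * (V - params$EK)
    IL <- params$gL * (V - params$EL)
    (params$I - INa - IK - IL) / params$Cm
  }
  gates <- list(
    list(name = "m", alpha = hh_alpha_m, beta = hh_beta_m, univariate = TRUE),
    list(name = "h", alpha = hh_alpha_h, beta = hh_beta_h, univariate = TRUE),
    list(name = "n", alpha = hh_alpha_n, beta = hh_beta_n, univariate = TRUE))
  ionic_model("hh", n_other = 1, gates = gates, other_rhs = other_rhs,
              defaults = defaults)
}

#' Initial (resting) state for the Hodgkin-Huxley model
#' @param V resting voltage (mV).
#' @return numeric state `(V, m_inf, h_inf, n_inf)` with gates at their
#'   steady-state values for that voltage.
#' @export
hh_rest_state <- function(V = -65) {
  c(V,
    hh_alpha_m(V) / (hh_alpha_m(V) + hh_beta_m(V)),
    hh_alpha_h(V) / (hh_alpha_h(V) + hh_beta_h(V)),
    hh_alpha_n(V) / (hh_alpha_n(V) + hh_beta_n(V)))
}

#' Toy Markov-chain channel model
#'
#' Fixture-grade ionic model containing a single Markov chain whose rate
#' matrix is declared as a sum of univariate parts
#' `M(w) = M0 + sigma(w) * M1` (both column sums zero), with the first state
#' variable V acting as the control variable, plus an optional multivariate
#' remainder.  Used to exercise the matrix Rush-Larsen machinery.
#'
#' @param n_states number of chain states.
#' @param M0,M1 rate matrices (`n_states` square, zero column sums,
#'   non-negative off-diagonals).
#' @param sigma scalar function of the control variable (default logistic).
#' @param remainder optional `function(state) -> matrix`.
#' @param v_rhs right-hand side for V (default 0: clamped control variable).
#' @return an `ionic_model` with state `(V, u_1..u_n)`.
#' @export
toy_markov_channel <- function(n_states, M0, M1 = NULL,
                               sigma = function(w) 1 / (1 + exp(-w)),
                               remainder = NULL,
                               v_rhs = function(state, params) 0) {
  M0 <- as.matrix(M0)
  validate_markov_matrix(M0)
  parts <- list(list(matrix_fn = function(w) M0, control = 1L))
  if (!is.null(M1)) {
    M1 <- as.matrix(M1)
    cs <- colSums(M1)
    if (any(abs(cs) > 1e-12)) stop("M1 columns do not sum to zero")
    parts <- c(parts,
               list(list(matrix_fn = function(w) sigma(w) * M1, control = 1L)))
  }
  chain <- list(n_states = n_states, parts = parts, remainder = remainder)
  ionic_model(paste0("toy_markov_", n_states), n_other = 1,
              markov_chains = list(chain), other_rhs = v_rhs)
}

# ---------------------------------------------------------------------------
# Model registry, addressed by name as in simulation configs (ode = fhncub).
# ---------------------------------------------------------------------------

model_registry <- new.env(parent = emptyenv())

#' Register a cell model
#' @param model an `rhs_model` or `ionic_model`.
#' @export
register_model <- function(model) {
  assign(model$name, model, envir = model_registry)
  invisible(model)
}

#' Look up a cell model by name
#' @param name registry key, e.g. `"fhncub"`, `"fhnbkl"`, `"zfk"`, `"hh"`.
#' @return the model object.
#' @export
get_model <- function(name) {
  if (!exists(name, envir = model_registry, inherits = FALSE)) {
    stop("unknown cell model: ", name)
  }
  get(name, envir = model_registry, inherits = FALSE)
}

#' Names of all registered cell models
#' @return character vector.
#' @export
list_models <- function() ls(model_registry)

register_builtin_models <- function() {
  register_model(rhs_model("fhncub", 2, function(state, params) {
    d <- fhncub_rhs(state[1], state[2], params)
    c(d$du, d$dv)
  }, defaults = list(eps = 0.3, bet = 0.71, gam = 0.5, Iu = 0, Iv = 0),
    rhs_vec = function(U, params) {
      d <- fhncub_rhs(U[, 1], U[, 2], params)
      cbind(d$du, d$dv)
    }))
  register_model(rhs_model("fhnbkl", 2, function(state, params) {
    d <- barkley_rhs(state[1], state[2], params)
    c(d$du, d$dv)
  }, defaults = list(a = 0.8, b = 0.01, eps = 0.02, Iu = 0),
    rhs_vec = function(U, params) {
      d <- barkley_rhs(U[, 1], U[, 2], params)
      cbind(d$du, d$dv)
    }))
  register_model(rhs_model("zfk", 1, function(state, params) {
    zfk_rhs(state[1], params)
  }, defaults = list(alpha = 0.13, Iu = 0),
    rhs_vec = function(U, params) {
      cbind(zfk_rhs(U[, 1], params))
    }))
  register_model(hodgkin_huxley_ionic())
}
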