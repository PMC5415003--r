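# ---------------------------------------------------------------------------
# Bidomain operator splitting.  One time step is the four-substep sequence
#   diff(1):  S1 = div(De grad V)
#   elliptic: div((De+Di) grad Phi_i) = S1
#   diff(2):  S2 = div(Di grad Phi_i)
#   euler:    V_t = kinetics(V) + S2
# with the scratch layer S recycled between the two diffusion substeps.
# When the extracellular tensor is proportional to the intracellular one
# (De = nu*Di) the scheme reduces exactly, in discrete arithmetic, to a
# monodomain run with D_eff = nu/(1+nu)*Di.
# ---------------------------------------------------------------------------

#' Configure a bidomain stepping scheme
#'
#' Precomputes the intra- and extracellular stencil weights and the elliptic
#' problem for the summed tensor, over a common geometry.  The additive
#' constant of the elliptic solution is fixed either by a single-point pin
#' (no-flux problems) or by a mask of Dirichlet nodes whose values the
#' caller refreshes every step (verification problems with exact boundary
#' data).
#'
#' @param geom a `geometry_grid`.
#' @param Di_par,Di_trans intracellular diffusivities along/across fibres.
#' @param De_par,De_trans extracellular diffusivities.
#' @param kinetics function `(V) -> dV/dt` (vectorised) giving the reaction
#'   term of the parabolic equation.
#' @param h space step (defaults to `geom$h`).
#' @param fixed optional logical array of Dirichlet nodes for the elliptic
#'   solve (e.g. a one-node boundary shell).
#' @param xpin,ypin,zpin,upin pin condition used when `fixed` is absent.
#' @param tolerance,upper_level,vcycles,preiter,postiter,maxiter,delta
#'   elliptic solver controls (see [elliptic_problem()]).
#' @return an object of class `bidomain_config`.
#' @export
bidomain_config <- function(geom, Di_par, Di_trans, De_par, De_trans,
                            kinetics, h = geom$h, fixed = NULL,
                            xpin = NULL, ypin = NULL, zpin = 0, upin = 0,
                            tolerance = 1e-7, upper_level = 3, vcycles = 20,
                            preiter = 1, postiter = 2, maxiter = 1e6,
                            delta = 0.5) {
  stopifnot(Di_par > 0, Di_trans > 0, De_par > 0, De_trans > 0)
  Ti <- build_tensor(geom, Di_par, Di_trans)
  Te <- build_tensor(geom, De_par, De_trans)
  Tsum <- Te
  Tsum$D <- Te$D + Ti$D
  Tsum$Dpar <- Te$Dpar + Ti$Dpar
  Tsum$Dtrans <- Te$Dtrans + Ti$Dtrans
  Wi <- build_weights(geom, Ti, h)
  We <- build_weights(geom, Te, h)
  fixed_values <- if (!is.null(fixed)) numeric(prod(dim(geom$status))) else NULL
  prob <- elliptic_problem(geom, Tsum, xpin = xpin, ypin = ypin, zpin = zpin,
                           upin = upin, fixed = fixed,
                           fixed_values = fixed_values,
                           tolerance = tolerance, upper_level = upper_level,
                           vcycles = vcycles, preiter = preiter,
                           postiter = postiter, maxiter = maxiter,
                           delta = delta, h = h)
  structure(list(geom = geom, h = h, Wi = Wi, We = We, problem = prob,
                 kinetics = kinetics, fixed = fixed),
            class = "bidomain_config")
}

#' One bidomain operator-splitting step
#'
#' Executes the four substeps (extracellular diffusion source, elliptic
#' solve for the intracellular potential, intracellular diffusion source,
#' forward-Euler kinetics step) once.  With a Dirichlet shell, the caller
#' supplies `fixed_values` for the potential boundary; the previous `Phi`
#' warm-starts the multigrid solve.
#'
#' @param state list with arrays `V` (transmembrane voltage) and `Phi`
#'   (intracellular potential), full-grid shaped.
#' @param config a `bidomain_config`.
#' @param k time step (> 0).
#' @param phi_fixed_values optional array of Dirichlet values for `Phi`.
#' @return updated `state` list, with the scratch source `S` attached.
#' @export
bidomain_substep_sequence <- function(state, config, k,
                                      phi_fixed_values = NULL) {
  stopifnot(k > 0)
  V <- state$V
  S1 <- apply_diffusion(V, config$We)                       # diff(1)
  if (!is.null(phi_fixed_values)) {
    config$problem$fixed_values <- as.vector(phi_fixed_values)
  }
  sol <- solve_elliptic(config$problem, rhs = S1,
                        init = as.vector(state$Phi))        # elliptic
  Phi <- sol$phi
  S2 <- apply_diffusion(Phi, config$Wi)                     # diff(2)
  msk <- config$Wi$psi != 0
  if (!is.null(config$fixed)) msk <- msk & !config$fixed
  V[msk] <- V[msk] + k * (config$kinetics(V[msk]) + S2[msk])  # euler
  list(V = V, Phi = Phi, S = S2, elliptic = sol[c("residual", "converged",
                                                  "vcycles")])
}

#' Parameters of the exact plane-wave solution of the bidomain benchmark
#'
#' For the one-variable bistable (Nagumo/ZFK) bidomain system with axis
#' diffusivities `(D_par, D_trans)` in both domains and propagation angle
#' `theta`, the directional diffusivities are
#' `D*_i = Di_par cos^2(theta) + Di_trans sin^2(theta)` (same for e), the
#' harmonic combination `D* = D*_i D*_e / (D*_i + D*_e)`, the front speed
#' `c = sqrt(2 D*) (1/2 - alpha)` and the potential ratio
#' `K = D*_e / (D*_i + D*_e)`; the front profile is
#' `V* = 1/(1 + exp((x cos(theta) + y sin(theta) - s - c t)/sqrt(2 D*)))`,
#' `Phi_i* = K V*`.
#'
#' @param alpha excitation threshold of the bistable kinetics.
#' @param Di_par,Di_trans,De_par,De_trans domain diffusivities.
#' @param theta propagation angle (radians; 0 = along x).
#' @return list with `Dstar_i`, `Dstar_e`, `Dstar`, `c`, `K`, `width`.
#' @export
planewave_params <- function(alpha = 0.13, Di_par = 2, Di_trans = 0.2,
                             De_par = 8, De_trans = 2, theta = 0) {
  Dsi <- Di_par * cos(theta)^2 + Di_trans * sin(theta)^2
  Dse <- De_par * cos(theta)^2 + De_trans * sin(theta)^2
  Dstar <- Dsi * Dse / (Dsi + Dse)
  list(Dstar_i = Dsi, Dstar_e = Dse, Dstar = Dstar,
       c = sqrt(2 * Dstar) * (0.5 - alpha),
       K = Dse / (Dsi + Dse),
       width = sqrt(2 * Dstar))
}

#' Exact plane-wave fields
#'
#' @param x,y physical coordinates (vectors/arrays of equal shape).
#' @param t time.
#' @param s initial phase of the front.
#' @param pw parameter list from [planewave_params()].
#' @param theta propagation angle.
#' @param alpha kinetics threshold (unused beyond `pw`; kept for clarity).
#' @return list with `V` and `Phi` of the same shape as `x`.
#' @export
planewave_exact <- function(x, y, t, s, pw, theta = 0, alpha = 0.13) {
  xi <- (x * cos(theta) + y * sin(theta) - s - pw$c * t) / pw$width
  V <- 1 / (1 + exp(xi))
  list(V = V, Phi = pw$K * V)
}
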