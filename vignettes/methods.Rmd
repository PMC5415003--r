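---
title: "Models, numerics and design choices in cardiogrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in cardiogrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiogrid)
```

# The tissue models

`cardiogrid` simulates electrical excitation of cardiac tissue (and other
excitable media) on regular 2D/3D grids. Two tissue descriptions are
supported.

The **bidomain** model treats the intracellular and extracellular spaces as
interpenetrating conductors separated by the cell membrane:

$$
C_m \frac{\partial V}{\partial t}
  = -I_{\mathrm{ion}}(V,\mathbf g) + \frac1\chi \nabla\!\cdot\hat\sigma_i\nabla\Phi_i,
\qquad
\nabla\!\cdot(\hat\sigma_i+\hat\sigma_e)\nabla\Phi_i
  = \nabla\!\cdot\hat\sigma_e\nabla V - I_{\mathrm{ext}},
$$

with transmembrane voltage $V$, intracellular potential $\Phi_i$, gating and
concentration variables $\mathbf g$ obeying pointwise ODEs. The first
equation is parabolic, the second elliptic: the elliptic equation must be
solved at every time step, which is what makes bidomain runs expensive. When
$\hat\sigma_e = \nu\hat\sigma_i$ the system collapses to the **monodomain**
reaction–diffusion model with
$\hat\sigma_\mathrm{eff} = \tfrac{\nu}{1+\nu}\hat\sigma_i$; the package's
proportional-tensor test verifies this reduction holds *exactly* in discrete
arithmetic (up to the elliptic solver tolerance), because the discrete
operators inherit the proportionality.

Membrane capacitance $C_m$ and surface-to-volume ratio $\chi$ default to 1
and are folded into the diffusivity tensors; all cell models use their
traditional model-specific units (the Hodgkin–Huxley model uses mV and ms,
the FitzHugh–Nagumo-class models are dimensionless).

# Cell kinetics: two model formats

**rhs format** — a plain derivative function, integrated by the explicit
`euler` and `rk4` devices. Shipped models: cubic FitzHugh–Nagumo (`fhncub`),
Barkley (`fhnbkl`), and the bistable Zeldovich–Frank-Kamenetsky/Nagumo
kinetics (`zfk`). A model may instead declare a direct-step function (taking
the time step) for kinetics not expressible as ODE right-hand sides. New
models are added with `rhs_model()` and `register_model()`.

**ionic format** — the state is partitioned into *gates* (with
$\alpha(V),\beta(V)$ rates), *Markov chains* (with a declared rate-matrix
decomposition into univariate parts), and *other* variables. This structure
is what the exponential solver exploits:

* gates advance by the Rush–Larsen update
  $y' = y_\infty + (y-y_\infty)e^{-(\alpha+\beta)k}$, exact for frozen
  voltage and unconditionally stable, keeping $y\in[0,1]$;
* each Markov block advances by the matrix Rush–Larsen step
  $\mathbf u' = e^{kM}\mathbf u$, computed through the eigen-decomposition
  of the frozen rate matrix, with Lie splitting across the declared
  univariate parts (in declaration order) and a forward-Euler substep for
  any small multivariate remainder;
* other variables advance by forward Euler.

The printed form of the scalar Rush–Larsen update in the source literature
swaps the roles of its two coefficients between the update formula and the
coefficient definitions; the implementation uses the mathematically exact
update (equilibrium term additive, exponential factor multiplying the old
value), which is the only reading consistent with exactness at constant
voltage.

**Tabulation.** All univariate coefficient functions (gate exponential
factor and equilibrium; Markov part step matrices) are precomputed at
start-up on an equidistant grid of the control variable. Lookups snap to
the *nearest* grid node, ties to the lower index; out-of-range queries clamp
to the end entries and are counted. The default table size is 20 000
entries over the declared control range — with the Hodgkin–Huxley model at
$k=0.01$ ms this keeps the voltage difference against untabulated stepping
near $10^{-3}$ mV through an action potential (the self-comparison test
freezes a 2·10⁻³ bound at table size 10⁵). Nearest-node (rather than
interpolated) lookup is chosen because its cost is one index computation
and the error is already negligible at the default table size.

If a rate matrix proves defective or its eigenbasis ill-conditioned (the
imaginary residue of the reconstructed step matrix exceeds $10^{-10}$), the
solver falls back to a scaling-and-squaring Taylor exponential, with a
warning.

# The anisotropic diffusion operator

Fibre anisotropy enters through the transversely isotropic tensor
$D_{jk} = D_\perp\delta_{jk} + (D_\parallel - D_\perp) f_j f_k$ with the
per-node fibre unit vector $\mathbf f$ (renormalised on load; the geometry
format does not promise unit vectors but the tensor construction requires
them). The operator $\nabla\!\cdot\hat D\nabla$ is discretised on a
19-point stencil (6 faces, 12 edges, centre): face weights
$\psi_{p+q}D_{jj}/h^2$, edge weights $\pm\tfrac12\psi_{p+q}D_{jk}/h^2$, a
face correction of the form
$\psi_{p+q}\psi_{p-q}(4h^2)^{-1}\sum_j(D_{jk}^{p+e_j}-D_{jk}^{p-e_j})$ for
spatially varying tensors, and the centre weight defined as the negative
sum of all others. Two consequences are load-bearing:

* every weight that would reach a void node carries a tissue-indicator
  factor $\psi$ and vanishes — no-flux boundary conditions *emerge* from
  the indicator function, so irregular anatomies need no boundary meshing;
* rows sum to zero exactly, so constants are annihilated and no charge
  leaks through the boundary.

In the variable-tensor correction term, a probe value $D^{p\pm e_j}$ at a
void node zeroes that $j$-contribution (one-sided drop); the indicator
prefactor in the stated scheme covers only the $\pm q$ pair, and dropping
the void probes keeps the scheme well defined at boundaries without
inventing tensor extrapolations. Tensor components in the edge terms are
evaluated at the centre node, the literal reading of the scheme. On 2D
grids offsets are restricted to the plane. Weights are precomputed once per
run (geometry and tensors are static) and applied through a cached sparse
matrix.

# The elliptic solver

The bidomain elliptic equation uses the same 19-point stencil (shared code
path) for $\nabla\!\cdot(\hat D_e+\hat D_i)\nabla$. The pure-Neumann
problem is singular (constants span the kernel); the additive constant is
fixed by a single-point pin $\Phi_i(x_\mathrm{pin}) = u_\mathrm{pin}$,
imposed exactly. Verification problems instead fix a one-node Dirichlet
shell refreshed from the exact solution.

The solver is full multigrid: vertex-centred 2:1 coarsening, red–black
Gauss–Seidel (default) or Jacobi smoothing with `preiter = 1` pre- and
`postiter = 2` post-sweeps, nested descent of the right-hand side, and
V-cycles on each level of the ascent. Controls mirror the device
parameters: `tolerance` is the residual max-norm target; `vcycles` caps
cycles per level; `maxiter` caps total smoothing sweeps; `delta` is
interpreted as the residual-reduction factor a V-cycle must achieve for
cycling to continue during the ascent (the meaning of this control was
genuinely open; the interpretation is documented here and configurable).
Divergence (residual growing tenfold from its minimum) raises an error
with diagnostics.

Three design points were settled empirically and deserve a record:

* **Transfers.** The exported vertex-centred transfer pair is injection
  (restriction) and bi/tri-linear interpolation (prolongation), so
  restriction after prolongation is the identity at coarse nodes. Inside
  the V-cycle, however, the *defect* is restricted by full weighting:
  injection of the defect loses too much information and measurably
  degrades convergence for anisotropic operators.
* **Coarse operators are Galerkin.** Rebuilding the stencil from the
  coarsened indicator looks natural but scales the no-flux boundary rows
  inconsistently with the restricted defect (boundary rows are flux-like,
  $O(1/h)$), and the V-cycle factor degraded towards 1 with each added
  level. The Galerkin product $A_H = R\,Z_f A Z_f\,P$ (with fixed and
  pinned rows/columns masked, since corrections vanish there) restores
  textbook behaviour: measured per-cycle residual-reduction factors are
  0.1–0.4 on boxes, about 0.27 for the strongly anisotropic Dirichlet
  problem, and about 0.6 on disk geometries with a void rind.
* **Irregular coarse grids.** A coarse node is tissue if any fine node in
  its 3×3×3 footprint is tissue; prolongation rows are masked to coarse
  tissue and renormalised, so boundary-adjacent nodes never average in
  meaningless void zeros.

On disk-like irregular geometries the asymptotic cycle factor (~0.6) is
the known price of a staircase boundary on coarse levels; tight tolerances
there simply need more V-cycles (the controls allow it), and time-stepping
uses warm starts from the previous step's potential, which typically needs
2–4 cycles per step.

# The device ring

A simulation is an ordered list of *devices* executed once per time step
(one turn = one step), each gated by a `when` global variable and
optionally restricted to a subgrid or to global variables only
(`nowhere`). Execution order is declaration order; the step counter `t`
increments after the last device; `stop` terminates immediately at its
ring position. This mirrors how complex protocols — feedback-controlled
stimulation, measurement electrodes, conditional output — are assembled
from the same small vocabulary without touching solver code.

Device parameters and `k_func` programs use a small expression language
(`+ - * /`, parentheses, unary minus, `eq ne gt ge lt le` returning exactly
0/1, `mod`, `ifle0`, `abs`, `min`, `max`); identifiers are checked at parse
time, and `mod(a,0)` or division by zero abort with the device name and
time step. Parameters may be literals, expressions over globals, or
`@layer` bindings resolved per node (e.g. the diffusion current entering a
cell model as `Iu = @2`).

Semantics decided here and regression-locked: the crossing detector
(`k_poincare`, sign +1) fires when the previous value was negative and the
current is non-negative; byte discretisation in `ppmout` rounds half up
after clamping; the stacked-slice binary PPM writes width `nx`, height
`ny*nz`, pixels x-fastest; `record` writes fixed-width `%+.7e` values,
subgrid flattened x-fastest, layers slowest; `dump`/`load` use raw 8-byte
little-endian IEEE-754 in x-fastest, layer-slowest order and round-trip
bit-exactly. Geometry-less states void the outermost node shell, which is
the conventional one-extra-row-per-direction construction for no-flux
boundaries on a plain box.

# Verification problems

**Disk diffusion.** $u_t = \nabla^2 u$ on the unit disk with no-flux
boundaries has the exact solution $u = J_0(\gamma r)e^{-\gamma^2 t}$ where
$\gamma \approx 3.8317$ is the first positive root of $J_0'$
(`gamma_root()`, bracketing plus bisection to $10^{-12}$). The benchmark
(`bessel_disk_run`) uses forward Euler with $k = h^2/80$ to $T = 0.2$, four
disk-centre offsets against the grid, and accumulates the error at every
step in the $L^\infty$ and $L^2$ norms with trapezoidal quadrature in time
and $\mu(D) = (\text{tissue count})\,h^2$ in space, over all tissue nodes.
The default refinement sequence is
$h \in \{0.4, 0.283, 0.2, 0.141, 0.1, 0.0707\}$ ($\sqrt2$ steps), pooled
over the four offsets in an ordinary least-squares log–log fit
(`fit_order`).

What this shows — and does not: with these norms the $L^2$ error converges
at a fitted order ≈1.5 (between 1 and 2), while the $L^\infty$ error is
dominated by an $O(h)$ boundary-staircase transient, peaking early in the
run at nodes on the disk boundary, and fits an order ≈1.0 over this
range. The error of the scheme at a staircase Neumann boundary is
genuinely first order in the maximum norm, so the $L^\infty$ fitted order
depends strongly on the $h$-range; the $L^2$ norm converges faster because
the dominant error is localised in a boundary strip of width $O(h)$. An
`exclude_boundary`-style variant (dropping boundary-adjacent nodes from the
norms) was evaluated and rejected: it does not change the orders materially
and departs from the norm definitions.

**Bidomain plane wave.** The one-variable bistable bidomain system has an
exact travelling-front family
$V^* = \bigl[1+\exp\bigl((x\cos\theta+y\sin\theta-s-ct)/\sqrt{2D^*}\bigr)\bigr]^{-1}$,
$\Phi_i^* = K V^*$, with
$D^* = D^*_iD^*_e/(D^*_i+D^*_e)$, $c = \sqrt{2D^*}(\tfrac12-\alpha)$ and
$K = D^*_e/(D^*_i+D^*_e)$ (directional diffusivities
$D^*_{i,e} = D_\parallel\cos^2\theta + D_\perp\sin^2\theta$). These
constants follow by substituting the logistic front ansatz into the
system: the profile width must satisfy $2D^*\lambda^2 = 1$ and the speed
$c = (\tfrac12-\alpha)/\lambda$. With the benchmark parameters
($\alpha = 0.13$, $D_i = (2, 0.2)$, $D_e = (8, 2)$, $\theta = 0$) this
gives $D^* = 1.6$, $c \approx 0.66188$, $K = 0.8$.

`bidomain_planewave_run` integrates the four-substep splitting scheme —
extracellular diffusion source, multigrid elliptic solve (warm-started,
scratch layer recycled), intracellular diffusion source, forward-Euler
kinetics — on $[0,10]^2$ to $T = 40$ with $k = 3h^2/(16 D_{e\parallel})$
and Dirichlet data on the one-node shell refreshed from the exact solution
every step. The propagation angle for the convergence experiment is
$\theta = 0$ (axis-aligned, configurable); oblique angles reuse the same
exact family. Errors on $V$ over the interior, both norms, at every step;
$h \in \{1, 0.5, 0.25\}$. Both fitted orders come out at 2.1–2.2 —
quadratic convergence with mild preasymptotic steepening from the coarsest
grid, where the front width $\sqrt{2D^*} \approx 1.8$ spans fewer than two
nodes. The measured front speed (mid-row crossings of $V = 0.5$) agrees
with $c$ to a few tenths of a percent at $h \le 0.5$.

Problem sizes throughout (disk grids up to 33², plane-wave grids up to
43², a few thousand to a few tens of thousands of steps) are desk-scale
choices: large enough to sit in the asymptotic regime the fits need, small
enough that the full verification suite runs in minutes on one core.

# Synthetic geometries and what the tests do not show

All test inputs are generated: disks, balls, boxes, thickness steps, random
tissue blobs with random fibre fields, and the in-code exact solutions
above. These exercise irregular boundaries, anisotropy, and device
protocols, but none of them has the topological complexity, fibre twist, or
heterogeneity of a DT-MRI anatomy; passing tests demonstrate correctness of
the operators and protocols, not physiological realism of any particular
simulation. Real anatomies enter through the same plain-text geometry
format (one node per line: coordinates, status, fibre vector; only tissue
points listed), and everything downstream is format-agnostic.

# Degenerate inputs and numeric edge cases

Gates with $\alpha+\beta = 0$ are frozen (logged once). Isolated tissue
nodes (zero stencil centre) are held at their value with a warning in the
elliptic solver. Tie-breaks: tabulation midpoints resolve to the lower
index; partition remainders go to the lowest-index subintervals. Duplicate
geometry-file nodes resolve last-wins with a warning; 4-field lines (no
fibre) default to (1,0,0) for isotropic use. The `mod`/division guards make
expression errors abort with the offending device and time step rather
than propagate NaNs.

# Known limitations

Orthotropic (three-eigenvalue) diffusion tensors are not implemented, only
transverse isotropy. The ionic library ships the classic squid-axon model
and fixture-grade Markov channels; complex human ventricular/atrial models
are out of scope, though the two model formats are the extension points.
The multigrid cycle factor on rind-bounded irregular geometries (~0.6) is
serviceable but not textbook; strongly disconnected tissue components other
than the pinned one are not separately gauged. The engine favours clarity
over throughput: production-scale 3D anatomies would need compiled inner
loops, which the device contracts deliberately leave room for.
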