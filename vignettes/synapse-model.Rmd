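---
title: "Passive elastohydrodynamics of synapse patterning: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive elastohydrodynamics of synapse patterning: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smacsim)
```

## The physical picture

When a T cell engages an antigen-presenting surface, two families of
receptor–ligand bonds bridge the ~tens-of-nanometres fluid cleft between the
membranes: short TCR–pMHC bonds (natural length $l_1 \approx 15$ nm) and
long LFA-1–ICAM-1 bonds ($l_2 \approx 45$ nm). Over tens of minutes the
bound receptors organise into the bulls-eye of the mature immunological
synapse — a central TCR-rich domain (cSMAC) ringed by LFA-1 (pSMAC).
`smacsim` simulates the hypothesis that the early stages of this patterning
need no active cytoskeletal machinery: membrane bending, bond springs,
height-gated binding kinetics and slow viscous drainage of the cleft fluid
suffice.

The model couples three fields on the contact zone: the cleft height
$h(x,y,t)$, and the bound densities $C_1, C_2$ of the two bond species.

**Mechanics.** The membrane, an elastic plate with bending modulus
$B_m = E b^3 / 12(1-\nu^2)$, responds to bond springs whose stiffness
scales inversely with bond length ($\kappa_i = (l_1/l_i)\kappa$):
$$p = B_m \nabla^4 h - \gamma \nabla^2 h
  + \kappa C_1 (h - l_1) + \kappa_2 \tfrac{l_1}{l_2} C_2 (h - l_2),$$
with membrane tension $\gamma$ optional (zero by default; switching it on
smooths sub-cluster features).

**Hydrodynamics.** The cleft is thin ($l_2/L \approx 4.5\times10^{-3}$)
and viscous, so lubrication theory reduces the flow to
$$\partial_t h = \nabla\cdot\!\big(\tfrac{h^3}{12\mu}\nabla p\big).$$
Fluid permeation through the membrane, Darcy-type obstruction by the
glycocalyx, and thermal undulations are all outside the model.

**Kinetics and transport.** Bound receptors are advected by the
pressure-driven flow, diffuse in the membrane ($D_i = (l_1/l_i) D$), drift
down height-deformation gradients (Einstein-relation flux
$-(D_i \kappa_i / k_BT)\, C_i (h - l_i)\nabla h$), and bind/unbind with
Gaussian height gates centred on each bond's natural length:
$$K^{on}_i = \tfrac{1}{\tau_k}
  e^{-\left(\frac{l_i - h}{\sigma_{on} l_i}\right)^2},\qquad
  K^{off}_i = \tfrac{1}{3\tau_k}
  e^{-\left(\frac{l_i - h}{\sigma_{off} l_i}\right)^2},$$
with $\sigma_{on} = 0.2 < \sigma_{off} = 0.6$ and bonds breaking three
times slower than they form. A constant off-rate variant
($\sigma_{off} = \infty$) is provided. The narrow on-gate is what sorts the
species: at $h = l_2$ the TCR on-rate carries a factor $e^{-100}$, so mixed
patches are kinetically forbidden. The free receptor pool is treated as
well mixed: the source is $(C_{i,0} - C_i) K^{on}_i$ with constant totals
$C_{1,0} = C_0$, $C_{2,0} = 2 C_0$.

## Dimensionless form

Scaling $x, y \sim L$, $h \sim l_2$, $p \sim p_0 = C_0\kappa l_2$,
$t \sim \tau_\mu = \mu / (C_0 \kappa l_2)$ and $C_i \sim C_0$ gives the
groups in `dimensionless_groups()`:

```{r groups}
tidy(dimensionless_groups(physical_params()))
```

Two of them organise the phase diagram: $B = B_m/(\kappa C_0 L^4)$ (bending
vs spring pressure) and $\tau = \tau_\mu/\tau_k$ (drainage vs kinetics).
The paper-facing equations carry only dimensional quantities, so the
dimensionless right-hand sides used internally were derived from these
scalings: the drainage equation picks up a prefactor $\epsilon^2/12$
(with $\epsilon = l_2/L$, using $p_0 \tau_\mu = \mu$), the advective term
$\epsilon^2 \lambda_i\, h\, \nabla p\cdot\nabla C_i$, diffusion
$(\lambda_1/\lambda_i)\,Pe^{-1}$, the sliding flux
$(\epsilon^2/M)(\lambda_1/\lambda_i)^2\,
\nabla\cdot(C_i (h-\lambda_i)\nabla h)$, and the tension term
$-\Gamma\epsilon^2\nabla^2 h$. The sliding coefficient follows the
Einstein-relation reading of the drift term — the printed prefactor of the
source equations is not dimensionally consistent as typeset, and the
Einstein form is the one in which the group $M$ appears at all.

### Scaling laws

Balancing bending against spring pressure gives the micro-cluster length
$l_c = (B_m/(C_0\kappa))^{1/4}$ (70–200 nm across the plausible $B_m$
range, i.e. $l_c = B^{1/4} L$). Drainage on a patch of size $\ell$ takes
$12(\ell/l_2)^2\tau_\mu$, giving a cluster-nucleation time
$\tau_c \approx 0.1$–$1$ s and a cell-scale coarsening time
$\tau_L \approx 40$ min:

```{r scales}
tidy(scaling_predictions(physical_params()))
```

The prefactor 12 in both drainage times is the one that reproduces the
dimensional values printed alongside the theory (a $\tfrac12$ prefactor
does not); the package standardises on 12.

## Discretisation

Fields live on a uniform collocated grid (`make_grid()`), either a periodic
square (cheap; sweeps and operator tests) or a disk of diameter $L$ masked
out of a padded square (the physical geometry; the exterior nodes form a
ghost ring). Operators are second-order centred differences: a 5-point
Laplacian, the biharmonic as its composition with the torque-free closure
$\nabla^2 h = 0$ on the ring, and conservative face-flux divergences with
arithmetic-mean face coefficients (the gap never approaches zero — springs
prop the membrane — so harmonic means buy nothing). Advection of bound
receptors is first-order upwind for monotonicity; the sliding flux is
donor-cell upwinded in conservative form, which keeps densities
non-negative under the CFL cap.

Two boundary variants (`boundary_condition()`):

* `open_pinned` — $h = 0.5\,l_2$, $p = 0$, $C_i = 0.01\,C_0$ on the ring,
  zero bending moment; fluid drains through the edge and the late-time
  equilibrium is a flat membrane saturated by one species.
* `closed_free` — no fluid flux ($\nabla p\cdot n = 0$), no receptor flux,
  zero moment; fluid volume is conserved and the pattern arrests.

Under the closed variant every implicit operator is assembled in flux form
with boundary faces dropped, so conservation holds through the linear
solves to round-off (measured drift $\sim 10^{-13}$ over a full run), not
just in the explicit terms.

## Time integration

The drainage equation is sixth-order in space and stiff; explicit stepping
would need $\Delta t \sim \Delta x^6$. The engine (`step_state()`,
`run_simulation()`) uses an IMEX splitting per step:

1. **Height.** The default `stabilized` scheme treats a
   constant-coefficient majorant of the linearised drainage operator
   implicitly — $\bar A = \tfrac{\epsilon^2}{12}\bar m\,(B\nabla^6 +
   \bar c\,\nabla^2)$ with $\bar m \ge \max h^3$ and
   $\bar c \ge \max(C_1 + \lambda_1 C_2)$ rounded up to powers of two —
   and the true nonlinear rate explicitly. The majorant operator is
   factorised once and reused until $\Delta t$ or a majorant changes;
   this is the standard stabilisation for thin-film and Cahn–Hilliard
   problems and is exact for uniform films. The `full` scheme (lagged
   $h^3$, frozen densities, theta scheme; refactorises every step) is kept
   for verification runs.
2. **Densities.** Advection and sliding explicit (CFL-capped with Courant
   number 0.8); diffusion implicit with a cached factorisation; the
   binding/unbinding reaction integrated *exactly* pointwise
   ($C \to C_{eq} + (C - C_{eq})e^{-(K^{on}+K^{off})\Delta t}$), which
   matters because kinetics at $\tau = 15$ is thousands of times faster
   than cell-scale drainage.

Steps are accepted only if $h > h_{\min} = 10^{-3}$ (reaching the floor
signals a resolution problem, not physics), densities stay in
$[0, C_{i,0}]$ (tolerance $10^{-9}$, then clamped), and — for the
stabilized scheme — the height change stays below $\Delta h_{\max} = 0.05$
per step, which is the accuracy throttle that lets $\Delta t$ grow to
hundreds of $\tau_\mu$ during slow coarsening. Rejected steps halve
$\Delta t$; five consecutive accepts grow it by 1.2x up to `dt_max`.
Everything is deterministic given the seed: rerunning a configuration, or
restarting from a snapshot (`restart_run()`), reproduces the trajectory
bit-for-bit.

The solver was verified against the closed-form dispersion relation of the
linearised system,
$\omega(k) = -\tfrac{\epsilon^2}{12} h_0^3 k^2 (B k^4 + \Gamma\epsilon^2
k^2 + C_1 + \lambda_1 C_2)$: simulated decay of a small sinusoid matches
within 1%.

## Initial conditions

`initial_condition()` reproduces the canonical starting state: a uniform
film at $h = 0.5\,l_2$ with six Gaussian bumps of width $\approx 0.1 L$
(per-bump widths drawn within ±20%) and amplitudes in
$(0.075, 0.1)\,l_2$, densities uniform at $0.01\,C_0$. Bump centres sit on
a hexagonal ring of radius $0.3 L$ — the source work does not specify
centres — with a seeded random alternative. This emulates incipient
membrane contacts; it does not emulate measured cell topography, receptor
pre-clustering, or glycocalyx heterogeneity, so passing tests show the
model's internal dynamics are right, not that any particular cell will
follow them.

## Pattern metrics

The source work describes regimes qualitatively; the package fixes
operational definitions (all thresholds are exposed arguments):
clusters are 8-connected components of $C_i > 0.3\,C_{i,0}$ of at least 4
pixels; `no_pattern` means $\max C_1 < 0.2\,C_{1,0}$; `bullseye` needs a
TCR cluster covering the domain centre plus an LFA annulus spanning ≥ 60%
of angular bins at larger radius; `kinetic_clusters` needs ≥ 3 disjoint
TCR clusters. The regime *labels* are resolution-sensitive: at the desk
resolutions used here (32²–64²) the grid spacing (~0.16–0.31 µm) exceeds
the elastic cluster scale $l_c \approx 70$ nm, so only the ordering of
regimes along $\tau$ is meaningful — at $\tau = 0.03$ the synapse fails to
organise (a single weak diffuse patch; by 40 min even slow kinetics has
equilibrated the bound fraction, so the density itself is not small), while
at $\tau = 15$ organised bulls-eye/kinetic-cluster patterns form.
Interfacial pixels also overlap the two species at these resolutions
(overlap index ~0.1–0.25 during pattern formation) even though the kinetic
equilibria themselves are mutually exclusive
($C_1^{eq} C_2^{eq} < 0.05\,C_{1,0}C_{2,0}$ at every height).

## Problem sizes and numerical choices used in the tests

The shipped tests integrate the baseline synapse (B = 2×10⁻⁹, τ = 15,
open pinned edge) on a 64² disk for 40 dimensional minutes — the bound-TCR
count peaks near 4 minutes and decays while bound LFA grows monotonically,
and the final state classifies as a bulls-eye. The (τ, B) sweep runs 3×3
cells on a 48² disk (32² is too coarse: pixel-scale diffusion can no longer
out-compete binding at small τ and spurious clusters appear). The
closed-boundary arrest run uses a 32² disk to t = 10⁶ τ_μ.

Cluster-size scaling deserves a caveat. The elastic prediction
$l_c = B^{1/4} L$ spans 0.007–0.021 $L$ over the tested two decades of $B$
— at or below one grid cell at these resolutions — so the measurable
"cluster diameter" at the mature stage is dominated by coalesced
macro-domains and the fitted log–log slope comes out ≈ 0.12–0.14 rather
than 0.25. The regression machinery is exercised against synthetic cluster
sets with exact power laws; recovering the quarter-power from simulations
requires grids fine enough to resolve $l_c$ (n ≳ 300 for the softest
membrane), beyond the sizes used here.

## Known limitations

* The advective term acts on bound complexes in non-divergence form
  ($u\cdot\nabla C$, as modelled); it exchanges receptors with the
  well-mixed free pool implicitly and does not by itself conserve the
  domain total — conservation statements apply to the diffusive and
  sliding fluxes (exact under the closed boundary).
* First-order upwinding smears cluster interfaces over 1–2 cells;
  quantitative interface widths need resolutions ≳ L/l_c, far beyond desk
  scale.
* The free receptor pool is not a transported field; depletion halos
  around large clusters are outside the model.
* No active processes: cytoskeletal transport, endo-/exocytosis and
  microvesicle release — all of which the source work itself excludes —
  mean the post-20-minute fate of the real synapse is outside scope; with
  the open boundary every simulation ends in a flat single-phase membrane.
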