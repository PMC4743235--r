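---
title: "The 0D peripheral-resistance outflow model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 0D peripheral-resistance outflow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritree)
```

## The problem

Patient-specific blood-flow simulation of the carotid bifurcation and the
external carotid branches must truncate the vasculature at imaging
resolution: everything downstream of each outlet — small arteries,
arterioles, capillaries — is cut away, yet it is precisely this peripheral
bed that sets how flow distributes among the branches.  A bare
zero-pressure outlet ignores the periphery entirely and lets geometry
alone decide the split, which badly misestimates branch velocities.  The
remedy used here is a zero-dimensional (0D, lumped-parameter) resistance
model of the peripheral network attached to every outlet, giving each
outlet a pressure–flow relation instead of a fixed pressure.

`peritree` builds these boundary conditions and, because a full 3D
finite-volume domain is out of scope, couples them to a lumped Poiseuille
surrogate of the imaged region so the whole exchange can be exercised and
tested end to end at desk scale.

## The peripheral tree

Each outlet of radius $r_0$ spawns a symmetric binary tree.  At every
bifurcation the flow halves, $q_{i+1} = q_i/2$, and the daughter diameters
follow the minimum-energy power law

$$d_i^{\varepsilon} = 2\, d_{i+1}^{\varepsilon}
  \quad\Longrightarrow\quad d_{i+1} = 2^{-1/\varepsilon} d_i ,$$

with $\varepsilon = 3.0$ for laminar flow (the Reynolds numbers in this
territory stay well below 1000; $\varepsilon = 2.33$ is accepted as a
parameter for turbulent regimes but is not a default).  Generations are
added until the radius reaches the capillary stopping radius, 12 µm by
default; for exact power-law radii the generation count is
$\lceil \varepsilon \log_2 (r_0/r_{\mathrm{term}}) \rceil$.  For
$\varepsilon = 3$ the total cross-sectional area grows by $2^{1/3}$ per
generation, reproducing the anatomical expansion from arteries to the
arteriolar bed.

Segment lengths are not imageable, so each generation's length comes from
its vessel group through the length-to-radius ratio $\lambda = l/r$.  The
packaged group table (large arteries, main artery branches, terminal
artery branches, arterioles, capillaries, plus a special ICA row) carries
average and minimum diameters, lengths and $\lambda$; every non-special
row satisfies $\lambda = l/(d_{\mathrm{avg}}/2)$ to better than $10^{-3}$.
Two table entries needed editorial decisions, taken once and kept:

* the arterioles row's printed length cell is ambiguous, so $\lambda=240$
  (the unambiguous column) is authoritative and the length is
  back-computed as $\lambda r = 12$ mm;
* the ICA row's printed $\lambda = 50.0154$ is not reproducible from its
  printed length and mean diameter (which give ≈ 42.8); the printed
  $\lambda$ is used verbatim, and the table validator exempts the ICA row.

Classification boundaries come from the minimum-diameter column, boundary
points belonging to the larger-vessel group.  The sole exception is the
large-artery/main-branch pair, whose printed categories overlap (large
arteries reach down to 2 mm while main branches average 2.4 mm): there the
boundary is raised to the main-branch average, kept within the
main-branch group, so that every interior group average classifies into
its own row.  The terminal-branch (1.2 mm) and arteriole (0.1 mm)
averages sit exactly on printed boundaries and therefore take the
larger group's $\lambda$ under the tie-break; this is a deliberate
consequence of the convention, not an accident.

The internal carotid artery does not branch before entering the skull, so
an ICA-flagged outlet takes the measured-data $\lambda$ at generation 0
only; deeper generations — which the measured length says nothing about —
fall back to group lookup.

## Diameter-dependent viscosity

Blood is Newtonian in large and medium arteries but strongly
non-Newtonian in the microcirculation.  The model chains four empirical
relations in tube diameter $d$ (µm):

1. tube haematocrit: $Hct = 0.45$ for $d > 300$, else
   $0.45\,(0.196 \log_{10} d - 0.117)$, clamped at zero below
   $d \approx 3.95$ µm (negative haematocrit is unphysical; the clamp is
   unreachable from a 12 µm terminal radius but defended anyway).  The
   discontinuity at 300 µm is part of the empirical law and is not
   smoothed; the boundary belongs to the small-diameter branch.  The
   logarithm is base-10 — the underlying haematocrit–diameter fits are
   conventionally base-10, and a natural log gives unphysical values at
   capillary scale — with an `"ln"` switch exposed for sensitivity checks;
2. a shape exponent $C_d$ which moves from ≈ 1 at capillary scale to
   −0.8 in large vessels.  ($C_d$ is not monotone on the way: it dips to
   ≈ −1.18 near $d \approx 12$ µm before settling at −0.8; tests check
   the two limits and dense-grid agreement with a term-by-term oracle
   rather than monotonicity);
3. the relative viscosity at the reference haematocrit,
   $\mu_{0.45}(d) = 6 e^{-0.085 d} + C_\infty - 2.44
   e^{-0.06 d^{0.645}}$, whose minimum near $d \approx 45$ µm is the
   Fåhraeus–Lindqvist effect;
4. the apparent viscosity
   $\mu_{app} = \bigl[1 + (\mu_{0.45}-1)\,
   \tfrac{(1-Hct)^{C_d}}{(1-0.45)^{C_d}}\, w\bigr]\, w$ with wall-layer
   factor $w = (d/(d-1.1))^2$, singular at $d = 1.1$ µm (hence the
   domain restriction $d > 1.1$).

As stated, relation 3 mixes an absolute constant into an otherwise
relative formula.  The default **calibrated** mode therefore evaluates
the chain in relative units with the classical large-diameter constant
$C_\infty = 3.2$ and rescales by $\mu_{\mathrm{lim}}/3.2$ so that
$\mu_{app}(d \to \infty, 0.45)$ equals the configured Newtonian limit
$4.06\times10^{-3}$ Pa·s; a **literal** mode keeps the mixed-unit form
for traceability but is flagged dimensionally inconsistent.  Similarly,
the haematocrit-ratio factor is implemented exactly as stated
(`"printed"`), with the classical in-vitro form
$((1-Hct)^{C_d}-1)/((1-0.45)^{C_d}-1)$ available behind
`hct_ratio = "classical"`; no worked number exists to discriminate the
two, so the printed form is the default.

At the reference haematocrit the ratio factor is exactly 1, so
$\mu_{app}(d, 0.45) = [1 + (\mu_{0.45}-1)w]\,w$ — an algebraic identity
the tests assert to $10^{-12}$.

```{r viscosity}
apparent_viscosity(c(24, 100, 1e4))
```

## Resistance recursion and the terminal fixed point

Each generation contributes the Poiseuille resistance of one segment,
$R_{seg,i} = 8\mu_i\lambda_i/(\pi r_i^3)$ (i.e. $8\mu l/(\pi r^4)$ with
$l = \lambda r$), with $\mu_i$ the apparent viscosity at that
generation's own diameter.  Working upward from the leaves, with
symmetric daughters the parallel reduction is a halving:

$$R_n(L) = R_{\mathrm{term}}, \qquad
  R_i(0) = R_{seg,i} + R_i(L), \qquad
  R_{i-1}(L) = \tfrac12 R_i(0).$$

All bookkeeping is per single vessel; parallelism enters only through
the $\tfrac12$.  The resistance seen at the outlet is $R_0(0)$, and
because each generation's parallel count exactly cancels the radius
shrinkage for $\varepsilon = 3$, every generation contributes comparably
to the total — the model is sensitive to the whole $\lambda$ schedule,
not just the first generations.

The terminal resistance is what makes the pressure level (not just the
pressure drop) physiological: it is set so the pressure at the capillary
generation equals 30 mmHg.  In standalone use the symmetric split fixes
the leaf flow at $q_0/2^n$, so the fixed point is closed form,
$R_{\mathrm{term}} = P_{\mathrm{term}} 2^n / q_0$.  The conventional
comparison variant instead uses a constant $\lambda = 30$ at every
generation and closes with zero terminal resistance.

An explicit-network reference implementation
(`explicit_network_resistance()`) materialises all $2^i$ resistors per
generation and reduces them pairwise; the recursion is required to agree
with it to $10^{-10}$ relative on randomized trees up to 15 generations.

```{r tree}
tr <- build_tree(1e-3) # a 1 mm-radius outlet
tr
sol <- solve_terminal_fixed_point(tr, 1e-6) # 1 mL/s
c(root_mmHg = pa_to_mmhg(sol$pressures$p_inlet[1]),
  terminal_mmHg = pa_to_mmhg(sol$pressures$p_terminal))
```

## Coupling to the domain surrogate

The imaged 3D domain is deliberately replaced by a lumped surrogate: a
tree of Poiseuille segments (Newtonian viscosity 0.0046 Pa·s, density
1050 kg/m³) from a common-carotid inlet to every outlet, each segment
five diameters long — the same truncation length used when cutting
imaged branches.  This is the package's central simplification: it
preserves the coupling contract and the qualitative variant comparisons,
but patient-specific 3D velocities are **not** reproduced and no claim
about them is made.

The exchange mirrors the 3D↔0D contract: the domain solve hands outlet
flows to the 0D models; they return outlet pressures (equivalently
lumped resistances); iterate until the largest relative change of any
outlet flow is below $10^{-4}$ (mirroring a residual-oscillation
criterion of that order; the update schedule itself is unspecified in
the source setting, so plain successive substitution with automatic 0.5
under-relaxation on residual growth is this package's choice, capped at
1000 iterations).  The domain solve uses exact tree reduction — at every
junction the branch shares sum to one — so mass is conserved to
rounding at each iteration; a one-shot dense nodal-analysis solver
(`solve_network_nodal()`) provides the independent cross-check for
fixed resistances.

For steady flow the terminal-pressure update has a notable structural
property: adding $P_{\mathrm{term}}/q_i$ to every outlet's lumped
resistance shifts all node pressures by exactly $P_{\mathrm{term}}$ and
leaves every flow unchanged, so the successive substitution lands on
the fixed point in a single update (machine-precision residual at the
second iteration).  The iteration loop still exists — and is exercised —
because the contract it implements is the one a nonlinear domain solver
needs, where the flow field does shift with outlet pressure levels.

Flow↔velocity conversion uses the uniform-profile convention
$Q = v\,\pi r^2$ at inlet and outlets (matching a
uniform-velocity inlet prescription); a parabolic profile would differ
by a factor 2 on centreline velocity and is intentionally not applied.

```{r coupled}
fx <- fixture_config(seed = 7, n_branches = 9)
sg <- make_surrogate(make_outlet_set(fx), fx)
cmp <- compare_variants(sg)
subset(cmp$table, name == "STA",
       select = c(variant, velocity_cm_s, pressure_mmhg))
```

On any fixture the outlet pressures order as structured model ≥
conventional model ≥ zero pressure (identically 0): the structured
$\lambda$ schedule concentrates far more resistance in the arteriolar
generations ($\lambda = 240$) than the constant $\lambda = 30$, and its
terminal closure adds the 30 mmHg floor.

## Synthetic fixtures

The generator emulates the carotid analysis anatomy: one ICA outlet with
diameter jittered about the anatomical mean 5.4834 mm, plus 7–9
external-carotid branches (nine-branch sets use the full branch pool;
seven-branch sets drop the two branches most often unresolved in coarse
imaging).  Branch diameters are drawn uniformly within the
main/terminal-branch group intervals — a modelling choice, not patient
statistics — so generated outlets always classify back into their
declared groups.  The common-carotid inlet defaults to a 3.5 mm radius
and a 0.3 m/s mean velocity, a typical resting CCA value.
Pseudo-measurements perturb simulated velocities by multiplicative
Gaussian noise (default 5 % relative, the same order as validation
errors reported for models of this kind); with noise $\sigma$ the mean
relative error of the generating model against its own pseudo-
measurements must recover the folded-normal mean
$\sigma\sqrt{2/\pi}$, which the tests check over 200 seeds.

Everything is a deterministic function of an integer seed (R's default
Mersenne-Twister generator, with the caller's RNG state saved and
restored); the outlet-set, surrogate and measurement stages use fixed
seed offsets so they can be regenerated independently.

What passing these tests shows — and does not show: the machinery
(classification, recursion, fixed point, conservation, coupling) is
correct on anatomically plausible synthetic networks.  It does not show
agreement with patient-specific 3D haemodynamics, which requires the
imaged geometry and measured inflow this package intentionally excludes.

## Numerical choices and degenerate inputs

* SI units internally (m, Pa, Pa·s, m³/s); mm, µm, mmHg and cm/s only at
  I/O boundaries, with 1 mmHg = 133.322 Pa fixed.
* Generation indexing is 0-based at the outlet.
* Trees refuse outlets at or below the terminal radius ("outlet smaller
  than capillary"); the viscosity law refuses $d \le 1.1$ µm and
  $Hct \ge 1$; terminal resistance refuses non-positive flow (an
  unperfused outlet).
* The explicit-network reference caps enumeration at 18 generations
  (2¹⁸ resistors); deeper trees are refused rather than approximated.
* Non-convergence of the coupled loop raises a structured error
  carrying the residual history instead of returning a partial result.
* Problem sizes used by the shipped tests: trees to ~26 generations
  (5 mm outlets), 50-tree randomized oracle sweeps at ≤ 15 generations,
  20 random fixtures for variant ordering, and 200 measurement seeds
  for the recovery experiment — sizes chosen so the full suite runs in
  seconds while still exercising every property at meaningful scale.

## Known limitations

* Resistance only: no compliance, inertance or wave propagation — the
  peripheral bed here is small, stiff vessels where resistance
  dominates; pulsatile simulation is out of scope (steady flow matches
  the hour-scale time frame of intra-arterial drug administration).
* A stated reduction of arteriole/capillary elasticity in the source
  setting has no accompanying formula; no elasticity term is
  implemented.
* No plasma skimming at bifurcations, shear-rate rheology
  (Carreau/Casson) or temperature dependence.
* Symmetric bifurcations only; asymmetric trees and named branch
  anatomy below the outlet level are out of scope.
* The domain surrogate is resistive and linear; it stands in for, and
  cannot validate against, 3D CFD.
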