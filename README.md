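# peritree

0D peripheral-resistance outflow boundary conditions for carotid
blood-flow models.

When a patient-specific arterial model of the carotid bifurcation and the
external carotid branches is truncated at imaging resolution, everything
downstream of each outlet — small arteries, arterioles, capillaries — is
lost, yet that peripheral bed is what governs how flow splits among the
branches (and hence, in intra-arterial chemotherapy planning, how an
agent distributes to the tumour-feeding arteries).  `peritree` builds a
lumped (zero-dimensional) resistance model of that periphery for every
outlet and turns it into an outflow boundary condition, for use by
anyone running truncated-domain haemodynamic simulations who needs
physiological outlet pressures without modelling the whole circulation.

## The model

Each outlet of radius *r₀* spawns a symmetric binary tree.  Flow halves
at every bifurcation and daughter diameters follow the minimum-energy
power law

    dᵢᵋ = 2 dᵢ₊₁ᵋ ,   ε = 3.0 (laminar)

down to a capillary stopping radius of 12 μm.  Generation *i* carries
the Poiseuille resistance of one segment whose length comes from its
vessel group's length-to-radius ratio λ = l/r (large arteries 61.5385,
main branches 83.3333, terminal branches 16.6667, arterioles 240,
capillaries 250; the ICA is special-cased with its measured λ), using
the apparent blood viscosity at the generation's own diameter — a
Fåhraeus–Lindqvist law μ_app(d, Hct) calibrated so that
μ_app(d → ∞, 0.45) = 4.06 × 10⁻³ Pa·s.  The recursion

    Rₙ(L) = R_term ,   Rᵢ(0) = 8 μᵢ λᵢ /(π rᵢ³) + Rᵢ(L) ,
    Rᵢ₋₁(L) = ½ Rᵢ(0)

yields the resistance seen at the outlet, and the terminal resistance is
set so the capillary-generation pressure equals 30 mmHg — the step that
makes the pressure *level*, not just the drop, physiological.  Three
outflow variants are supported and compared: zero pressure, the
conventional constant-λ = 30 model with zero terminal resistance, and
the structured model above.  A lumped Poiseuille surrogate stands in for
the imaged 3D domain so the flow↔pressure coupling loop can be solved
end to end; patient-specific 3D velocities are deliberately out of
scope.

## Worked example

```r
library(peritree)

tr <- build_tree(1e-3)          # a 1 mm-radius outlet
tr
#> <peripheral_tree>
#>   root radius : 1 mm
#>   generations : 0..20 (21 levels, 1,048,576 leaf vessels)
#>   leaf radius : 9.843 um (terminal 12 um)
#>   groups      : main_artery_branches > terminal_artery_branches > arterioles

sol <- solve_terminal_fixed_point(tr, 1e-6)   # 1 mL/s root flow
sol$profile$root_resistance
#> [1] 20594641925          # Pa·s/m³ seen at the outlet
pa_to_mmhg(c(sol$pressures$p_inlet[1], sol$pressures$p_terminal))
#> [1] 154.473  30.000      # outlet pressure; capillary pressure (exact)
```

The tree needs 20 generations to reach the capillary radius; the outlet
sees ≈ 2.06 × 10¹⁰ Pa·s/m³ of peripheral resistance, which at 1 mL/s
puts the outlet at ≈ 154 mmHg while the terminal generation sits at
exactly the physiological 30 mmHg.

Comparing the three outflow variants on a synthetic carotid-like domain:

```r
fx  <- fixture_config(seed = 7, n_branches = 9)
sg  <- make_surrogate(make_outlet_set(fx), fx)
cmp <- compare_variants(sg)
subset(cmp$table, name == "STA",
       select = c(variant, velocity_cm_s, pressure_mmhg))
#>            variant velocity_cm_s pressure_mmhg
#>      zero_pressure         8.093          0.00
#>    conventional_0d        12.161         20.69
#>         present_0d        10.433         87.64
```

Superficial-temporal velocities land in the physiological ~10 cm/s
range under both 0D models, but only the structured model also puts the
outlet *pressure* in the physiological range — the zero-pressure outlet
is pinned at 0 and the constant-λ model stays low because nothing
anchors its pressure level.

A thin command-line wrapper is installed under `exec/`:

```sh
peritree fixtures --seed 3 --n-branches 7 --out-outlets outlets.csv
peritree build-bc --outlets outlets.csv --variant present_0d --out bc.csv
peritree compare  --outlets outlets.csv --seed 3
```

`bc.csv` carries, per outlet, the lumped resistance, terminal resistance
and reference pressures (Pa and mmHg) plus a provenance header (version,
seed, config hash) — the file a flow solver's user-defined outlet
function would consume.

## Package layout

| Where | What |
| --- | --- |
| `R/viscosity.R` | haematocrit, shape exponent, μ₀.₄₅, apparent viscosity |
| `R/vessel_groups.R`, `inst/extdata/vessel_groups.csv` | group table, classification, λ lookup |
| `R/tree.R` | fractal tree construction |
| `R/resistance.R` | resistance recursion, terminal fixed point, explicit-network reference |
| `R/surrogate.R`, `R/coupling.R` | domain surrogate, coupled solver, variant comparison |
| `R/fixtures.R` | seeded synthetic carotid fixtures |
| `R/io.R`, `R/config.R`, `exec/peritree` | file formats, YAML config, CLI |
| `vignettes/peripheral-resistance-model.Rmd` | full model description and design rationale |
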