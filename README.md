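# gbasolve

Growth balance analysis (GBA) for coarse-grained, self-replicating cell
models in R: build a model as a handful of parameter matrices, validate it,
and solve for the optimal balanced-growth state — growth rate, fluxes,
metabolite concentrations, and the full proteome allocation — in each
growth condition.

## Who this is for

Systems biologists studying whole-cell resource allocation: growth laws,
ribosome allocation, proteome partitioning, overflow-type strategy shifts.
Unlike flux balance analysis, GBA needs **no biomass composition as input**
— composition is an output, predicted from optimality under three
constraints: mass conservation, saturable (nonlinear) kinetics, and a fixed
total cell density. The intended scale is coarse-grained models of at most
20 reactions, which is enough to capture the major trade-offs while keeping
the nonlinear program tractable.

## The model

A GBA model is five matrices in consistent mass units (g/L, h⁻¹):

- **M** — mass-fraction stoichiometry: entry `M[i, α]` is the mass fraction
  of reactant *i* consumed (negative) or produced (positive) by reaction
  *α*. Each column's positive entries sum to 1 and negative entries to −1,
  so every reaction conserves mass. External reactants carry the `x_`
  prefix; the last row `P` is total protein; the last column `r` is the
  ribosome reaction producing it.
- **K** — Michaelis constants (g/L), same layout.
- **KA**, **KI** — activation/inhibition constants (g/L) of internal
  reactants; 0 means no effect.
- **kcat** — forward and backward turnover numbers (h⁻¹, mass of product
  per mass of catalyst per hour); `kcat_b = 0` marks an irreversible
  reaction.

plus a conditions table (cell density ρ and external concentrations *a*
per growth condition).

Each reaction follows convenience kinetics. The protein cost of carrying
flux v_α is p_α = v_α · τ_α(a, c), where the turnover time τ_α is the
reciprocal specific rate; for an irreversible reaction with activators,

    τ_α = (1/kcat_α) · Π_s (1 + K_αs / x_s) · Π_ι (1 + KA_αι / c_ι).

At balanced growth, production offsets dilution (M v = μ c). Writing
ξ_α = v_α/μ gives c = M_I ξ and the solver maximizes

    μ(ξ) = c_P / Σ_α ξ_α τ_α(a, c)

subject to Σ c = ρ, c ≥ 0, p ≥ 0, and ξ_α ≥ 0 for irreversible reactions —
an augmented-Lagrangian method with multistart and per-condition warm
starts.

## Worked example

```r
library(gbasolve)

ex <- gba_example()          # 5 reactions: transport, 3 enzymes, ribosome
check_model(ex$model, ex$conditions)$is_valid
#> [1] TRUE

res <- solve_all(ex$model, ex$conditions, gba_options(n_starts = 3))
print(res)
#> GBA results: 4 condition(s), 4 converged
#>   condition       mu converged
#> 1     cond1 1.179111      TRUE
#> 2     cond2 4.350051      TRUE
#> 3     cond3 6.167416      TRUE
#> 4     cond4 6.449838      TRUE
```

The four conditions sweep the external substrate from 0.1 to 100 g/L at
ρ = 300 g/L; the predicted growth rate rises and saturates — the classic
Monod-like growth curve, emerging here from optimal proteome allocation
rather than from a fitted rate law. Each solution also carries the full
composition; for instance the proteome fraction of the ribosome,
`res$solutions[[1]]$phi[["r"]]`, grows with the growth rate across
conditions (the ribosome growth law).

Models travel as ODS spreadsheets (one tab per matrix) or as plain CSV
bundles:

```r
write_gba(ex$model, ex$conditions, "example.ods")
md <- read_gba("example.ods")
write_results(res, "results/")          # tidy TSVs + summary.json
plot_sweep(res, "mu", "growth.svg")
export_flux_map(ex$model, res$solutions[[1]], "fluxmap.graphml")
```

There is also a command-line front end (installed at `exec/gba`):

```sh
gba template model.ods --reactants 5 --reactions 4
gba validate model.ods            # exit code 0 iff valid
gba solve model.ods --starts 10 --seed 42 --out results/
```

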