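---
title: "Growth balance analysis: model, solver, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth balance analysis: model, solver, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbasolve)
```

## The modeling problem

Growth balance analysis (GBA) asks: given the stoichiometry and kinetics of
a small self-replicating reaction network, and a fixed total density of
cellular dry mass, what allocation of fluxes and protein maximizes the
balanced growth rate? The decisive feature is that biomass composition —
metabolite pools and the partitioning of the proteome across catalytic
tasks — is an *output* of the optimization, not an input. Three
constraints shape the answer:

1. **Mass conservation** within each reaction, encoded in the mass-fraction
   matrix `M`;
2. **Saturable kinetics**: carrying flux requires protein, and more protein
   is needed when substrates are dilute;
3. **Finite cell density**: metabolites and proteins compete for the same
   ρ grams per liter of cell volume.

All quantities are in mass units — concentrations and Michaelis constants
in g/L, turnover numbers in h⁻¹ (mass of product per mass of catalyst per
hour). This removes any need to assign molecular weights to the idealized
"lumped" reactants of a coarse-grained model: instead of requiring a weight
vector `w` with `w S = 0`, the mass-fraction matrix builds mass
conservation into its ±1 column-sum rule. For genuine mol-based
stoichiometries with known weights, `mass_fraction_matrix()` performs the
conversion (and errors on any column that cannot conserve mass).

## Rate laws

Reaction kinetics follow convenience kinetics in mass units. For reaction
α with substrate set `sub(α)` (negative entries of column α of `M`) and
product set `prod(α)` (positive entries), the specific rate — flux per
unit mass of catalyst, h⁻¹ — is

$$k_\alpha = \mathrm{reg}_\alpha \cdot
  \frac{k^{cat}_{f} \prod_{s} (x_s/K_{\alpha s}) -
        k^{cat}_{b} \prod_{p} (x_p/K_{\alpha p})}
       {\prod_{s} (1 + x_s/K_{\alpha s}) +
        \prod_{p} (1 + x_p/K_{\alpha p}) - 1},$$

with the regulation prefactor
$\mathrm{reg}_\alpha = \prod_{\iota:\,KA>0} \frac{c_\iota}{KA + c_\iota}
\prod_{\iota:\,KI>0} \frac{KI}{KI + c_\iota} \in (0, 1]$ over internal
reactants only. For an irreversible reaction ($k^{cat}_b = 0$) the product
side drops out and the reciprocal — the turnover time
$\tau_\alpha = 1/k_\alpha$ — takes the familiar product form
$(1/k^{cat}) \prod_s (1 + K/x_s) \prod_\iota (1 + KA/c_\iota)$. A single
substrate with no regulation is exactly Michaelis–Menten; this reduction
is verified to $10^{-12}$ relative accuracy in the test suite.

Design choices in the kinetics, made where the published description is
incomplete and documented here as this package's own:

- **Saturation factors are reciprocal in concentration**, $(1 + K/x)$ in
  τ: the unique reading under which $\tau \cdot k^{cat} \to 1$ at
  saturation and the Michaelis–Menten reduction holds.
- **Stoichiometric weight does not exponentiate saturation**: a substrate
  with mass fraction −0.6 still contributes one first-order factor. Mass
  units give no natural cooperativity exponent, and none is imposed.
- **Concentrations are clamped at ε = 10⁻¹² g/L** inside the kinetics so
  every evaluation is finite during optimization. Gradient-based solvers
  need total objective functions; the optimum of a growing cell never sits
  at a clamped substrate of an active reaction, so the clamp is inert at
  solutions.
- **External reactants cannot regulate**: activation/inhibition constants
  are defined over internal reactants only; all-zero external rows in
  `KA`/`KI` input are dropped with a warning, nonzero ones are an error.

## The growth program and its solver

The protein catalyzing reaction α must satisfy
$p_\alpha = v_\alpha \tau_\alpha(a, c)$. At balanced growth every internal
component is diluted at rate μ and replaced by synthesis: $M v = \mu c$.
The change of variables $\xi = v/\mu$ (growth-scaled flux, g/L) makes this
implicit: $c = M_I\,\xi$ with $M_I$ the internal rows of `M`, and protein
closure ($\sum_\alpha p_\alpha = c_P$) pins the growth rate to

$$\mu(\xi) = \frac{c_P}{\sum_\alpha \xi_\alpha \tau_\alpha(a, c)}.$$

The program solved per condition is: maximize μ(ξ) subject to
$\mathbf{1}^\top M_I \xi = \rho$ (density, linear in ξ), $c \ge 0$,
$p \ge 0$ (only binding for reversible reactions, which may not be forced
against their net thermodynamic direction), and $\xi_\alpha \ge 0$ for
irreversible reactions.

Numerical choices:

- **Equality elimination by projection.** Every candidate ξ is rescaled by
  the positive factor $\rho / (\mathbf{1}^\top M_I \xi)$, which maps onto
  the density surface exactly while preserving all sign constraints. The
  reported solutions therefore satisfy $\sum c = \rho$ to machine
  precision, and the augmented Lagrangian only carries inequalities.
- **Augmented Lagrangian + quasi-Newton inner solver.** Inequalities enter
  via Rockafellar multiplier terms; the inner minimizer is
  `stats::optim` L-BFGS-B by default (options: BFGS, Nelder–Mead), with
  central-difference gradients at relative step 10⁻⁷. The environment's
  guaranteed package set offers no SLSQP implementation, so the
  augmented-Lagrangian + L-BFGS route — one of the standard solver choices
  for this problem class — is the default here.
- **Scaling.** Decision variables are optimized as $u = \xi/\rho$, making
  the problem O(1) regardless of density.
- **Multistart and warm starts.** Default 10 log-uniform starts (base seed
  42), each rescaled onto the density surface; condition *k+1* warm-starts
  from condition *k*. The best converged start wins; ties break toward
  lower constraint residual, then lower start index. Everything is
  deterministic given the seed.
- **Tolerances.** Objective relative tolerance 10⁻⁹, constraint tolerance
  10⁻⁸ (scaled), 2000 inner iterations per start. Infeasible evaluations
  ($\sum \xi\tau \le 0$) return a large penalty rather than raising.
- **Degenerate inputs.** A model with no mass-importing column is rejected
  as structurally infeasible before solving. A starved condition (external
  substrate 0) typically converges to μ ≈ 0 or reports
  `converged = FALSE`; either way the per-condition result is recorded and
  the sweep continues.

Correctness is established against *independent oracles*: for 2-reaction
self-replicators the density constraint leaves a 1-D problem solved by
exhaustive grid plus golden-section (rel. agreement < 10⁻⁶ required,
~10⁻¹⁰ observed); for 3-reaction chains, nested 2-D grid refinement
(< 10⁻⁴ required, ~10⁻⁷ observed). The oracles restate the
Michaelis–Menten algebra from scratch and share no code with the solver or
the kinetics module.

## Validation pipeline

`check_model()` runs, in order: data integrity (every cell numeric),
dimensional consistency, sign constraints (ρ > 0, a ≥ 0), mass
conservation (±1 column sums, absolute tolerance 10⁻⁶ — spreadsheet
precision), Michaelis-constant repair, and the 20-reaction size limit.
Later checks still run when earlier ones fail where structurally possible,
so one validation pass reports as much as it can. Failures are results,
not exceptions; `is_valid` is true iff nothing failed (repairs don't
fail).

The repair rule: any *substrate* cell (M < 0) with a zero Michaelis
constant gets the default 0.1 g/L. This package extends the same default
to *product* cells of reversible reactions, because the reversible rate
law needs product saturation constants; products of irreversible reactions
never enter the rate law and are left at zero. The ribosome's own protein
product falls under the same product rule. The size limit reflects current
solver capability, not the formalism, and can be lifted
(`allow_large = TRUE`, CLI `--allow-large`).

## The synthetic generator: what it emulates, what it does not

`generate_model()` draws random valid models for property testing: one
transport per external reactant, a connected enzymatic conversion chain
with optional branch substrates and split products, and a ribosome
consuming the last metabolite(s). Column supports are drawn first, then
magnitudes normalized to the ±1 rule — validity by construction, never by
rejection sampling. Defaults are biologically plausible magnitudes for
mass-unit coarse-grained models: kcat ∈ [1, 100] h⁻¹, K ∈ [0.1, 10] g/L,
ρ ∈ [200, 400] g/L (bacterial cytoplasmic dry-mass density), external
substrate ∈ [1, 50] g/L; tests do not depend on the exact ranges.

What a green generator-based test establishes: structural validity,
round-trip fidelity, validator behavior, and solver correctness on chain
topologies up to 20 reactions. What it does not: realism of any particular
parameter combination, network motifs beyond chains-with-branches (no
cycles except trivial recycle columns, no cofactor pairing), or
thermodynamic consistency between forward and backward parameters (Haldane
relationships are deliberately out of scope).

`lump_kcat()` (arithmetic mean for parallel merges, harmonic mean for
serial) and `lump_km()` (half the summed substrate concentration) provide
the standard rules of thumb for estimating effective parameters when
coarse-graining; they are conveniences, not guarantees of biological
realism.

## The packaged example

`gba_example()` ships a five-reaction model — transport, three enzymatic
steps, ribosome — with all reactions irreversible and unregulated, so
every rate law is plain Michaelis–Menten. Its parameter values are
fixtures chosen for a well-conditioned optimum (kcat 20–80 h⁻¹, K 1–5
g/L, ρ = 300 g/L), not calibrated to any published dataset; quantitative
tests against it are structural or oracle-derived.

```{r example}
ex <- gba_example()
res <- solve_all(ex$model, ex$conditions, gba_options(n_starts = 3))
data.frame(mu = sapply(res$solutions, `[[`, "mu"),
           phi_ribosome = sapply(res$solutions, function(s) s$phi[["r"]]))
```

The ribosomal proteome fraction rises with growth rate across the nutrient
sweep — the canonical growth law, emerging from optimization.

## Interchange formats

The canonical interchange format is ODS, one sheet per matrix (`M`, `K`,
`KA`, `KI`, `kcat`, `conditions` — the matrix names themselves, fixed so
files are self-documenting). The package writes the ODS ZIP container
itself (stored entries, pure-R CRC32) and reads `content.xml` with xml2,
tolerating the repeated-cell markup spreadsheet applications emit; this
keeps the guaranteed dependency set small. A CSV bundle dialect (one file
per tab, identical layout) exists because plain-text fixtures are easier
to diff and to edit in tests. Numeric cells are serialized with 17
significant digits, so write-then-read round-trips are bit-exact.

`KA`/`KI` are stored over internal rows only. The kcat sheet has two rows,
`kcat_f` and `kcat_b`. The conditions sheet has `rho` first, then one row
per `x_` reactant. Multiple transport columns importing the same external
reactant are permitted — the reader imposes no uniqueness rule.

## Known limitations

- Local, not global, optimality: multistart mitigates but cannot certify.
  For the desk-scale models targeted here all starts converge to the same
  optimum in practice.
- No SBML, no external kinetic-parameter database integration, no
  interactive visualization; plots are static SVG/PNG and the flux map is
  a GraphML file (edge weight = mass flux `|v·M|`, node weight =
  concentration).
- No thermodynamic consistency checks; reversible parameters are taken as
  given.
- The YAML config of the CLI's options is JSON here (`--config
  file.json`), as no YAML parser is in the guaranteed dependency set.
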