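---
title: "From frequency calculations to kinetic predictions: the models behind rxnkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From frequency calculations to kinetic predictions: the models behind rxnkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnkin)
```

# Scope

`rxnkin` covers the post-processing stages between a converged
quantum-chemistry frequency calculation and an experimentally comparable
kinetic prediction: ideal-gas rigid-rotor harmonic-oscillator (RRHO)
thermochemistry, reference-based relative energies over reaction networks,
Eyring transition-state-theory rate constants, and transient microkinetic
simulation with selectivity, apparent-activation-energy and reaction-order
extraction. It does not run electronic-structure calculations, does not
locate transition states, and models batch isothermal reactors only (no
inflow/outflow terms).

# Thermochemistry: the RRHO model

For a species with electronic energy $E_{el}$ (Hartree), harmonic
wavenumbers $\tilde\nu_i$ (cm$^{-1}$), molecular mass $m$, principal
moments of inertia $I_A \le I_B \le I_C$ and spin multiplicity $g$, the
package assembles, at temperature $T$ and pressure $P$:

* **Zero-point energy** $\mathrm{ZPE} = \sum_i N_A h c\,\tilde\nu_i/2$
  over real modes. Imaginary modes, carried as negative wavenumbers
  end-to-end, are excluded from every vibrational sum — so a transition
  state (exactly one imaginary mode) is handled by the same code path as a
  minimum.
* **Translational entropy** by Sackur–Tetrode,
  $S_{tr} = R\left[\ln\!\big((2\pi m k_B T/h^2)^{3/2}\,k_B T/P\big) + 5/2\right]$.
* **Rotational entropy** from the rigid-rotor partition function,
  $q_{rot} = T/(\sigma\theta_r)$ (linear) or
  $q_{rot} = \frac{\sqrt\pi}{\sigma}\sqrt{T^3/(\theta_A\theta_B\theta_C)}$
  (nonlinear), with $S = R(\ln q + 1)$ and $R(\ln q + 3/2)$ respectively;
  monoatomics contribute zero.
* **Vibrational thermal energy and entropy** per mode with
  $x = h c\tilde\nu/(k_B T)$: $E = RTx/(e^x - 1)$,
  $S = R[x/(e^x-1) - \ln(1 - e^{-x})]$.
* **Electronic entropy** $S_{el} = R\ln g$.

Enthalpy and Gibbs free energy follow the ideal-gas assembly
$H = E_{el} + \mathrm{ZPE} + \tfrac32 RT + E_{rot} + E_{vib} + RT$ (the
final $RT$ is the pV work; $E_{rot}$ is $0$, $RT$ or $\tfrac32 RT$ for
atoms, linear and nonlinear rotors) and $G = H - TS_{total}$. The identity
$G = H - TS$ is enforced by construction and re-checked to
$10^{-9}$ kcal/mol in the test suite.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `T` | 298.15 K | temperature of all thermal corrections |
| `P` | 101325 Pa | pressure in Sackur–Tetrode |
| `frequency_scale` | 1.0 | uniform harmonic-frequency scale factor |
| `low_freq_treatment` | `"none"` | low-frequency entropy model (below) |
| `nu0` | 100 cm$^{-1}$ | threshold for `"floor"`/`"qrrho"` |
| `standard_state` | `"gas_1atm"` | reference state of $S_{tr}$ |
| `symmetry_number` | 1 | rotational symmetry number $\sigma$ |

Plain RRHO (`"none"`) is the default because it is the convention a
frequency-calculation output itself prints, which makes results directly
comparable against the quantum-chemistry code's own free energies. Two
optional low-frequency entropy treatments are provided, both entropy-only:
`"floor"` replaces wavenumbers below $\tilde\nu_0$ by $\tilde\nu_0$, and
`"qrrho"` interpolates each mode between its harmonic and free-rotor
entropy with the damping weight $w = 1/(1 + (\tilde\nu_0/\tilde\nu)^4)$
and an averaged rotor moment $B_{av} = 10^{-44}$ kg m$^2$. Low modes in
flexible or microsolvated systems are where harmonic entropies are least
trustworthy; these switches bracket that uncertainty.

Atomic masses are most-abundant-isotope values from a pinned internal
table; linearity is inferred from moment-of-inertia degeneracy
(tolerance $10^{-6}$, with degenerate geometries rejected loudly) unless
the user sets the flag. The `solution_1M` standard state is implemented as
an effective pressure $P_{eff} = C^\circ R T$ with
$C^\circ = 1000$ mol m$^{-3}$ inside Sackur–Tetrode.

# Reference-based relative energies

A network assigns each species a combination of *reference species* with
coefficients; the relative energy is
$\Delta E = E(\text{species}) - \sum_j c_j E(\text{ref}_j)$, converted at
627.5094740631 kcal/mol per Hartree. The necessary-and-sufficient validity
rule implemented here is element-wise composition balance: any operation
that would compare states of different stoichiometric content fails with
an error listing the imbalance, never returns a number. Merged
intermediates (`merge_intermediates()`) sum electronic energies,
compositions and, when present, thermochemical components; a state merged
from exactly its own reference fragments therefore sits at 0 by
construction. Reference coefficients are explicit user input; a helper
(`solve_reference_coefficients()`) solves for them by composition balance
when the linear system is uniquely determined.

# Eyring rate constants

Rate constants follow the Eyring equation
$k = \kappa \frac{k_B T}{h} e^{-\Delta G^\ddagger / RT}$ with
transmission coefficient $\kappa = 1$ by default (no tunneling model is
included). For molecularity $m > 1$ the pressure-based gas-phase free
energy is converted to concentration units by $(RT/P^\circ)^{m-1}$;
the solution standard state uses $(1/C^\circ)^{m-1}$ with
$C^\circ = 1$ M. `eyring_rate()` defaults to the solution convention so
that forward/reverse pairs satisfy
$k_f/k_r = e^{-\Delta G_{rxn}/RT}$ exactly regardless of a step's
molecularities; the gas-phase conversions are available per call.
Negative computed barriers — which plain RRHO can legitimately produce
when a transition state falls below a connecting state in free energy —
warn and compute rather than stop, since capping them would silently bias
branching ratios.

# Microkinetic engine

Steps with rate constants become a mass-action ODE system
$\dot c = \nu r(c)$, $r_j = k_{f,j}\prod_i c_i^{|\nu^{re}_{ij}|} -
k_{r,j}\prod_i c_i^{|\nu^{pr}_{ij}|}$, integrated with `deSolve`'s
`lsoda` (adaptive, switching to BDF for stiff phases) at defaults
`rtol` $10^{-8}$ / `atol` $10^{-12}$. TST rate constants in one network
easily span ten or more orders of magnitude, so stiffness is treated as
the normal case. Numerical choices:

* **Output grid**: 0 plus 200 logarithmically spaced points to `t_end`,
  so both the fast initial transient and the slow approach to equilibrium
  are resolved.
* **Equilibrium detection**: $\lVert \dot c \rVert_\infty <$ `eq_tol`
  (default $10^{-12}\max c_0$ s$^{-1}$) sustained over one output
  interval.
* **Negativity**: undershoots within `-atol` are clipped to zero
  silently; anything larger clips with a warning.
* **Conservation audit**: every simulation reports the worst relative
  drift of the conserved moieties, obtained as an exact rational basis of
  the left null space of $\nu$ (hand-written fraction-exact Gauss–Jordan
  elimination; floating SVD null spaces serve only as a cross-check in
  the tests).

**Selectivity** generalizes the two-product concentration ratio:
$S = c_{target}/(c_{target} + \sum c_{competitors})$, evaluated at the
detected equilibrium point (or forced at `t_end` with a warning).

**Apparent activation energies and reaction orders** are operational
quantities; the probe is defined as the initial rate measured by finite
difference over the earliest window in which the limiting reactant
converts by at most 5%. The window end is chosen from the initial
right-hand side, which makes the window factor a constant across the
scanned temperatures or concentrations, so it cancels exactly in the
fitted slopes. `ln r` vs $1/T$ gives $E_a = -R \times$ slope; `ln r` vs
`ln c0` gives the order. For a single-step Eyring process the apparent
$E_a$ equals $\Delta H^\ddagger + R\bar T$, which the tests recover.

# Synthetic fixtures: what they emulate and what they do not

The generators in the fixtures module stand in for real
quantum-chemistry outputs so the whole pipeline is testable offline:

* `make_species()` builds random species with jittered-lattice geometries,
  energies in the −250 to −50 Hartree window, real modes in
  60–3400 cm$^{-1}$ and (for the transition-state template) exactly one
  imaginary mode in −1800 to −200 cm$^{-1}$ — ranges typical of organic
  main-group chemistry. Numeric fields are rounded to the precision the
  ORCA-like emitter prints, so parser round trips are exact. The
  geometries are *plausible, not optimized*: they exercise parsing,
  composition and rotor code, while thermochemical correctness is pinned
  by closed forms, not by real molecules. Passing tests therefore
  demonstrate the formulas and plumbing, not the accuracy of any
  electronic-structure method.
* `make_first_order_network()` and `make_competing_network()` attach
  closed-form solutions ($c_0 e^{-kt}$; branching selectivity
  $1/(1+e^{-\Delta\Delta G^\ddagger/RT})$) used as oracles.
* `make_arrhenius_dataset()` produces exact or log-normally noised rate
  tables under an explicit seed; the engine itself is deterministic.

Problem sizes used in the shipped tests and the acceptance script —
networks of up to 5 species against the matrix-exponential oracle,
5-temperature Arrhenius scans, 200–1000 parser round-trip records —
were chosen to exercise every code path while keeping the default check
runs comfortably fast on a laptop.

# Design decisions that were genuinely open

* **Mechanism steps from entry order.** The mechanism JSON stores
  species, roles and references, not explicit step connectivity;
  `mechanism_step_table()` interprets each network's entry order as the
  reaction coordinate and pairs every transition state with its nearest
  non-TS neighbors. This mirrors how such mechanisms are laid out in
  spreadsheet-style tools and keeps the file format minimal.
* **Validation over inference for references.** Reference combinations
  are validated by composition balance rather than auto-resolved; an
  explicit solver helper exists for the uniquely determined case.
* **CLI fit subcommands operate on tables.** `arrhenius` and `orders`
  fit CSV rate tables; the simulation-driven scans are library functions
  (`apparent_activation_energy()`, `reaction_order()`) since they need an
  R closure as the problem factory.

# Known limitations

* Harmonic frequencies only: no anharmonicity, no hindered-rotor models,
  no condensed-phase solvation corrections.
* No tunneling corrections (Wigner/Eckart) or variational TST; $\kappa$
  is a user-supplied constant.
* Batch isothermal reactor only; no flow, no heat balance.
* The ORCA-like parser supports the pinned fixture grammar (energy line,
  frequency block, Cartesian block, multiplicity line); real outputs whose
  sections match also parse, but no attempt is made to cover every
  quantum-chemistry package's dialect.
* Initial-rate probes assume the probe species changes monotonically in
  the 5%-conversion window; oscillatory networks would need a custom
  probe.
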