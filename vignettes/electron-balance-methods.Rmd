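---
title: "Methods: stoichiometric electron balance and kinetic simulation of NDFO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometric electron balance and kinetic simulation of NDFO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndfo)
```

## The problem

Nitrate-dependent Fe(II) oxidation (NDFO) couples the microbial reduction
of nitrate to the oxidation of ferrous iron under anoxic, circumneutral
conditions. An incubation assay delivers three replicate-averaged deltas —
nitrate consumed, nitrite accumulated, Fe(II) oxidized — and the scientific
question is whether the observed Fe(II) oxidation is fully explained by
the electron-accepting capacity of the observed nitrogen transformations,
or whether reactive nitrogen species (HNO₂, NO₂, NO) oxidized additional
Fe(II) abiotically, either in the medium or during the acidic iron
extraction step of the ferrozine workflow.

## The electron balance

Each Fe²⁺ → Fe³⁺ transition donates one electron. Nitrate reduced only to
nitrite accepts two; nitrate reduced all the way to dinitrogen accepts
five. The analysis therefore partitions consumed nitrate into a nitrite
branch (`to_nitrite = d_no2`, the accumulated nitrite) and an N₂ branch
(`to_n2 = d_no3 - d_no2`), prices them at 2 and 5 mol Fe(II) per mol
nitrate, and subtracts the total demand from the observed Fe(II)
oxidation:

$$D = 2\,\Delta\mathrm{NO_2^-} + 5\,(\Delta\mathrm{NO_3^-} -
\Delta\mathrm{NO_2^-}) = 5\,\Delta\mathrm{NO_3^-} - 3\,\Delta\mathrm{NO_2^-},
\qquad E = \Delta\mathrm{Fe^{2+}} - D.$$

Gaseous intermediates (NO, N₂O) are deliberately not given separate
electron prices in the analysis: the incubation-scale budget books all
nitrate that did not stop at nitrite as reduced to N₂. The simulator (not
the analysis) carries the intermediates, and on simulated data with
nitrogen still in flight at the end of the interval this convention
over-prices the in-flight pool slightly (about 0.008 mM Fe-equivalents at
the default settings — far below measurement noise).

Internally all arithmetic is double precision without intermediate
rounding; only reporting rounds, half away from zero at two decimals, so
the canonical chain 1.89 − 0.76 = 1.13, 2 × 0.76 = 1.52, 5 × 1.13 = 5.65,
1.52 + 5.65 = 7.17 mM reproduces digit for digit.

A negative nitrite delta (net nitrite consumption, physically possible
late in an incubation) is clamped to zero with a warning rather than
rejected; nitrite accumulation exceeding nitrate consumption is an error.

### Uncertainty

Replicate tubes are independent, so SDs propagate first-order with
independence across the three deltas: `sd(to_n2) = sqrt(sd_no3² + sd_no2²)`
and, because the total demand is algebraically `5 d_no3 − 3 d_no2` (the
two branch demands share the nitrite delta and are anticorrelated),
`sd(D) = sqrt((5 sd_no3)² + (3 sd_no2)²)`; the excess adds `sd_fe2` in
quadrature. Within-tube covariance is not recoverable from replicate
summaries and is deferred. The verdict is a plain sign test by default;
an uncertainty-aware screen `E − z·sd(E) > 0` with configurable `z`
(default 2, a conventional one-sided ~95% cut) is reported alongside.

## The reaction network

The eight-reaction network couples the two biotic couples with the abiotic
chemodenitrification chain (nitrous acid formation and disproportionation,
Fe(II) oxidation by NO₂ and NO, HNO dimerisation to N₂O, NO re-oxidation
by O₂). Coefficients are exact rationals end to end — the N₂ coefficient
of the five-electron couple is ½ and must not accumulate rounding — and
floats appear only at the ODE boundary.

Balance checking assigns an oxidation state to every atom from a fixed
per-species lookup (H +1, O −2, elemental forms 0, Fe and N as tabulated);
the network is closed over 13 species, so a general oxidation-state
assigner would be over-engineering. Under this standard assignment the
states of each species sum to its charge, which is exactly the condition
that lets the electron ledger close on an element- and charge-balanced
reaction — including the NO + O₂ channel, where oxygen itself is the
acceptor. Donors and acceptors are paired per element by matching atoms in
oxidation-state order (the minimal-transfer convention), which is what
makes the HNO₂ disproportionation count one electron per formula unit
rather than zero.

The NO channel as commonly printed, `Fe²⁺ + 2 NO + H⁺ → Fe³⁺ + HNO`, does
not conserve N or O. The package's default network uses the one-to-one
correction `Fe²⁺ + NO + H⁺ → Fe³⁺ + HNO` (one electron each side); the
doubled form `2 Fe²⁺ + 2 NO + 2 H⁺ → 2 Fe³⁺ + 2 HNO` would balance equally
well, and choosing the reduced form is a normalisation, not a claim about
intent. The printed form ships as a fixtures file and is exercised by the
validation tests, never silently edited.

## The simulator

`simulate_ndfo()` integrates mass-action kinetics (rate = k·Π reactant
concentrations, order = molecularity) with `deSolve::lsoda` at
`rtol 1e-8`, `atol 1e-10` mM, dense output on the user grid. H⁺ and H₂O
participate in balance checks but are not state variables — the medium is
PIPES-buffered at pH 7 — and O₂ enters as a fixed external concentration
(zero under anoxia), so the NO + O₂ channel is present but silent in
anoxic scenarios.

Biotic channels are the two ferrous couples plus three Fe(II)-coupled
denitrification steps carrying nitrite onward (NO₂⁻ → NO → N₂O → N₂, one
electron per Fe as always). They scale linearly with cell density, held
constant at 5 × 10⁷ cells mL⁻¹ because no growth occurs over the
incubation. An endogenous stored-carbon donor (`c_nar` … `c_nos`, off by
default) models late nitrate reduction when Fe(II) and stored substrates
are depleting; with it enabled the Fe-donated/N-accepted electron identity
becomes an inequality, which the tests assert in both regimes.

No rate constants are available for this system, so the defaults were
tuned once against the incubation's qualitative timescales and then
frozen: from 10 mM Fe(II) and 5 mM nitrate the default trajectory consumes
1.90 mM nitrate by day 7 with 0.75 mM nitrite standing, and about 80% of
the eventual 7-day Fe(II) loss happens within the first 2 days (Fe(II)
halves by day 1). Note a hard consistency constraint: the 7-day electron
budget (7.17 mM Fe-equivalents of N reduction) caps true Fe(II) loss at
72% of the initial 10 mM, so "most Fe(II) oxidized within 2 d" can only
ever mean most of the *eventual* loss — apparent near-complete early Fe(II)
loss in measured data is partly the extraction artifact. The fifth-order
Fe dependence of the five-electron channel (its mass-action molecularity)
is what gives the fast-early/stalled-late Fe profile.

Solution-phase rate constants for the abiotic chain default to zero: at
pH 7 in buffered medium nitrous acid formation is negligible, and the
chemistry belongs to the acidified extraction aliquot. The
`extraction_kinetics()` preset activates the chain; integrated to
completion it oxidizes exactly 2 mol Fe(II) per mol nitrite
(NO₂⁻ → HNO₂ → ½NO₂ + ½NO, NO₂ + 2 Fe, NO + Fe, HNO → ½N₂O), the
stoichiometric ceiling the measurement model uses — verified in the tests
by actual integration, not by assumption.

## The measurement layer

`measure_assay()` converts an exact trajectory into what the lab would
record. The acid-extraction artifact applies at measurement time only: a
fraction `f ∈ [0, 1]` of the residual nitrite in the acidified Fe aliquot
reacts during extraction, lowering the Fe2 reading by `2·f·[NO₂⁻]` (capped
at the Fe(II) present) and leaving FeTot unchanged. Nitrate and nitrite
are measured by ion chromatography on a separately filtered,
*non-acidified* aliquot, so their readings carry no artifact — this
protocol detail matters, because it is what makes the artifact surface as
a *positive* abiotic excess `+2·f·[NO₂⁻]` in the balance. (Were the
nitrite reading also depleted by the artifact, the lost nitrite would be
booked at 5 electrons instead of 2 and the net excess would come out
negative, contradicting the designed behaviour of the scenario.)

Gaussian noise is then added per analyte and replicate — defaults 0.08 mM
for the N species and 0.37 mM for the iron readings, the replicate-SD
magnitudes of the reference incubation — truncated at zero, with FeTot
floored at Fe2 within each tube (a total-iron assay cannot report less
than its ferrous component). A single integer seed fans out
deterministically to the replicate streams. Zero-truncation has one
visible consequence: readings whose truth is ~0 (nitrite blanks at t = 0)
acquire a small positive bias, which shrinks the recovered excess by
roughly 0.1 mM at default settings; this is a property of any
non-negative noise model and is left in deliberately.

`scenario_fig1()` bundles the default network, kinetics, medium, a 10-day
half-daily grid, 3 replicates, the default noise, and `f = 0.25`, chosen
small but nonzero so the designed (noiseless) excess is positive
(≈ 0.37 mM at day 7). The measured reference incubation itself implies a
much larger artifact (excess 1.61 mM ≈ 2 × 0.76, i.e. f near 1); the
scenario deliberately represents a milder, partial artifact.

### What the generator does and does not emulate

It reproduces the design (initial 10 mM Fe(II) + 5 mM NO₃⁻, triplicates,
10-day anoxic incubation at constant cells), the qualitative timescales,
the replicate noise magnitudes, and the extraction artifact as a
controlled injection. It does not attempt Fe(III) mineral speciation,
sorption of Fe(II) to precipitates, pH drift, gas-phase partitioning of NO
and N₂O, or growth — so a passing recovery test shows the *pipeline* is
sound, not that real incubations are free of those processes.

### Statistical power at the study's noise level

The measurement-model SD of the mean excess over 3 replicates is
`sqrt(2·(0.37² + 25·0.08² + 9·0.08²)/3) ≈ 0.49 mM`. Against a designed
excess of ≈ 0.37 mM (f = 0.25) the plain sign verdict therefore has only
~70–80% per-run power; detection of small artifacts is a property of the
expectation, not of every noisy realisation. The tests reflect this: the
verdict-versus-f claim is checked on the noiseless pipeline, and the noisy
claim is a 3σ recovery screen across 100 seeds (tolerating at most one
excursion, expected count 0.27) plus a positive mean, which has ~8σ power.
Problem sizes throughout (half-daily 10-day grids, 100 seeds, 10⁵
Monte-Carlo draws) keep every routine run in seconds while leaving the
statistical assertions comfortably powered.

## qPCR plumbing

The growth check uses the standard-curve algebra: efficiency
`E = 10^(−1/slope) − 1`, quantification `copies = 10^((Cq − b)/m)` flagged
against the linear dynamic range (default 20–2 × 10⁶ copies µL⁻¹, the
assay's validated range; the reference assay ran at E = 76%,
slope ≈ −4.073). The growth verdict compares the last/first fold change
with a configurable threshold, default 2.0 over the incubation — the
qualitative no-growth conclusion needs a quantitative cut, and a doubling
is the natural one for cell counts; any point outside the dynamic range
yields `below_range` rather than a verdict. Standard-curve intercepts and
raw Cq values are not tabulated anywhere public, so all Cq examples in
the package are synthetic by construction.

## Numerical and design notes

- Exact rationals (reduced integer pairs, hand-rolled — the need is tiny
  and localized) carry all stoichiometry; doubles appear at the ODE
  boundary and in the statistics.
- The solver clamps concentrations at zero in the rate evaluation and
  errors if any state goes below −10⁻⁶ mM; conservation of N and Fe holds
  to ~10⁻¹⁴ in practice, versus the 10⁻⁶ tolerance asserted.
- `compute_deltas` uses the sampled time nearest each requested bound, and
  refuses intervals outside the sampled range and tables missing an
  analyte or a bracketing observation.
- The default balance interval is days 0–7 of the 10-day grid, matching
  the reference incubation's reporting window.
- Deferred by design: thermodynamics (ΔG, redox potentials), pH dynamics,
  kinetic parameter fitting to data, gas-phase N mass balance, and any
  statistics beyond the z-screen.
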