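---
title: "Modelling prolyl-isomerization-gated channel kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prolyl-isomerization-gated channel kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolineswitch)
```

## The model

A cyclic nucleotide-modulated channel is treated as a continuous-time
Markov chain over a small set of named states. Three ingredients give
the proline-switch phenomenology:

1. **Two channel species.** The peptidyl-prolyl bond before a conserved
   proline in the ligand-binding domain is either *trans* or *cis*,
   giving two channel forms with different cAMP affinities and opening
   kinetics. The trans form binds tightly (Kd 24 µM here) and gates in
   milliseconds; the cis form binds weakly and gates in seconds.
2. **A slow isomerization layer.** The two forms interconvert on the
   tens-to-hundreds-of-seconds time scale typical of uncatalysed prolyl
   isomerization, in the apo layer and in the open layer of the scheme.
3. **Ligand-dependent binding.** Binding transitions carry second-order
   rates; the effective rate is `k_on · [cAMP]` (µM⁻¹s⁻¹ × µM). Binding
   is a single step per species — nothing in the data constrains how
   many of the four subunits must switch, so no subunit-resolved
   (MWC-style) expansion is attempted.

The six-state *modulatory* scheme is

```
 apo_trans (1)  <->  bound_trans (3)  <->  open_trans (5)
     ^                                          ^
     | iso                                      | iso
     v                                          v
 apo_cis   (2)  <->  bound_cis   (4)  <->  open_cis   (6)
```

with states 5 and 6 conducting. Isomerization in the bound layer
(3↔4) is omitted by default to keep the parameter count down; adding it
with the open-layer rates changes every simulated output by well under
1% (asserted in the test suite). The *on/off switch* alternative removes
state 6 (the cis form never opens), and the *trans-only* scheme models a
proline-to-alanine mutant with a single three-state branch.

Units package-wide: time s, first-order rates s⁻¹, second-order rates
µM⁻¹s⁻¹, concentrations µM, temperature K, energies kJ/mol.

## The default rate set and its calibration

Microscopic rates are not observable in the flux assay, so the default
`proline_rates()` set is a calibration against qualitative requirements
rather than a fit. Any replacement set can be checked with
`calibration_check()`, which asserts the same three requirements
programmatically:

| parameter | value | why |
|---|---|---|
| apo isomerization `k_ct_apo`/`k_tc_apo` | 0.02 / 0.03 s⁻¹ | 40% trans at rest; uncatalysed interconversion over tens of seconds |
| trans binding `k_on`/`k_off` | 10 / 240 | Kd 24 µM, the affinity of the trans-mimic mutant |
| trans gating opening/closing | 100 / 900 s⁻¹ | open probability 0.1 with ~1 ms open dwells |
| cis binding `k_on`/`k_off` | 10 / 8000 | low-affinity species (Kd 800 µM); see below |
| cis gating | sum 1.24 s⁻¹, ratio from cycle closure | second-range slow activation phase |
| open-layer isomerization | 9×10⁻⁴ / 10⁻⁴ s⁻¹ | 90% trans in the open state; re-equilibration over tens of minutes |

Two of these choices deserve explanation.

**Thermodynamic cycle closure.** The six-state scheme contains one
cycle. This package checks detailed balance (`detailed_balance_check`)
but, more importantly, *builds* the default set to satisfy it: the cis
gating equilibrium is derived as

```
K_gate_cis = K_gate_trans · (Kd_cis/Kd_trans) / (K_iso_open/K_iso_apo)
```

rather than chosen freely. The reason is physical and practical at
once. Physically, the cycle exchanges no energy with its surroundings
(the ligand bath is common to both branches), so microscopic
reversibility should hold at equilibrium. Practically, an enzyme
cannot shift an equilibrium: `apply_ppiase()` multiplies both directions
of every isomerization pair by one factor, and on a single-cycle
topology the stationary distribution is invariant under that scaling
*only if* the cycle is balanced (zero net flux through one edge of a
stationary cycle forces zero through all). The invariance is asserted
to 10⁻⁹ for factors up to 10⁶ in the tests, and it is exact here by
construction.

**The cis affinity.** Cycle closure couples the four equilibria. With
the apo layer fixed at 40/60, the open layer at 90/10 (these two pin
the cis/trans free-energy shift at RT·ln 13.5 ≈ 6.5 kJ/mol), and the
trans branch fixed by the mutant data, the remaining freedom is how the
13.5-fold shift is split between the binding and gating steps of the
cis branch. Splitting it mostly into binding (Kd 800 µM, gating
equilibrium 0.055) is what makes the *delay-dependent EC50 decrease*
reproducible: at a 2.5 s delay the weakly-binding cis pool still
contributes amplitude at high cAMP (high apparent EC50 ≈ 480 µM), while
at equilibrium the population has drained into the tight-binding trans
branch (EC50 ≈ 51 µM). With a smaller affinity separation the frozen
and equilibrated dose-response curves have nearly identical midpoints
and the shift — the observation that discriminates the modulatory from
the on/off mechanism — disappears. The simulated EC50 values are
therefore deliberately qualitative; only their ordering and shifts are
asserted, never their absolute values, and fitted Hill coefficients are
~1 because binding is a single step.

**PPIase acceleration.** `apply_ppiase()` defaults to 10⁶. The factor
needed to abolish the slow phase within the 12 ms mixing dead time is
set by a competition: at 100 µM cAMP the cis species spends only ~11%
of its pre-opening time in the apo layer where isomerization acts
(ligand capture into `bound_cis` is fast), so the effective conversion
rate is ~0.1 × the catalysed apo rate. Reaching completion inside 12 ms
needs an apo-layer rate of a few hundred per second, i.e. a factor of
order 10⁵–10⁶ over the 0.05 s⁻¹ uncatalysed sum. The factor is a free
parameter of `apply_ppiase()`; the default encodes "saturating
isomerase", not a measured enzymatic turnover.

## Numerical choices

- **Equilibria** come from the SVD null space of the transposed
  generator, normalised to a probability vector — never from long-time
  integration. A chain with several closed communicating classes has no
  unique stationary distribution and is an error that names the
  classes; a chain with transient states but one closed class (any
  liganded scheme at 0 µM) is fine, which is exactly how the apo
  cis/trans equilibrium used as the initial condition of every jump is
  computed.
- **Relaxations** use the eigen-decomposition of the generator, so the
  conducting fraction is an exact weighted sum of k−1 exponentials and
  the reported spectrum (bᵢ, τᵢ) satisfies Σbᵢ = I(0) − I(eq) to
  10⁻⁹. Complex eigenvalue pairs (possible for unbalanced user models)
  are merged into single real damped components; a defective generator
  triggers a flagged fallback to stiff integration (`deSolve::lsoda`).
  Output values are therefore independent of the output grid.
- **Stochastic simulation** is the exact Gillespie algorithm with one
  explicit integer seed per call (`withr::with_seed`, no global RNG
  state touched). Absorbing and frozen chains are legal and end in one
  long dwell.
- **Fitters** are deterministic functions of their inputs: bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol = ptol = 10⁻¹⁵) with
  fixed initialisation rules — τ from time-to-half-quench and β
  starting at 0.8 (bounded to (0, 1]: heterogeneous liposome
  populations broaden, never compress, the decay); Hill EC50 from the
  concentration nearest half-maximum with n_H starting at 2; the
  double-exponential from a fixed log-spaced rate grid (10³, 10¹, 10⁻¹
  s⁻¹) with amplitudes initialised by linear least squares and
  best-of-start selection, which also makes the fit invariant to input
  point order. Rate-like parameters are fit on a log scale.
- **Degenerate data** is flagged, not forced: traces that do not decay
  over the analysis window pin β at 1 with a warning; activation curves
  indistinguishable from a single exponential (rate ratio < 3 or a
  vanishing amplitude) return a flagged single-component fit; flat
  inhibition series set `unbounded`.
- **Analysis window and evaluation time** default to the assay's
  conventions — the first 100 ms of a 1 s, 5000-point trace, with the
  influx rate evaluated at 2 ms — and both are arguments.

## What the synthetic data does and does not emulate

`gen_stopped_flow_experiment()` maps model occupancy to traces through
a two-parameter measurement model: the target initial rate is
`k* = leak + k_max · conducting_fraction(delay)` and the
stretched-exponential τ is obtained by inverting the influx-rate
relation at fixed β = 0.8 (closed form; the inversion is exact and
monotone). Defaults: leak 0.5 s⁻¹ (the ligand-free control is a small
nonzero quench) and k_max 250 s⁻¹, which places saturating activity
near 15–20 s⁻¹ at 2 ms so that quenching is largely complete within the
analysis window — the dynamic range in which the stretched-exponential
inversion is well conditioned. Noise is i.i.d. Gaussian on
fluorescence; real instruments add correlated noise, mixing artifacts
and drift, none of which are modelled, so passing recovery tests here
validates the *pipeline*, not robustness to instrument pathology.
Double-mixing dead time and photobleaching are likewise out of scope,
and β is generated fixed while fitting frees it.

Problem sizes used throughout the tests and drivers were chosen for
statistical sufficiency at interactive run times: 200 s single-channel
records (≈10⁵ events each, three seeds), ensembles of 1500–3000
channels for the stochastic-vs-deterministic cross-checks (binomial
standard errors of ~0.005), 8-point delay grids matching the 12 ms–10 s
protocol, and 8–12-point concentration grids for dose-response fits.

## Known limitations and open choices

- The mapping of the scheme's two rows to cis and trans is a
  convention; nothing in the package depends on which row is which
  beyond the labels.
- Two estimates of the resting trans fraction circulate (amplitude
  ratios suggest ~0.5; the 40% figure is used as the calibration
  default). The package exposes both routes — amplitudes via
  `fit_double_exponential`, algebra via `solve_mixture_affinity` — and
  does not reconcile them.
- Whether PPIases also act on the ligand-bound (3↔4) layer is untested
  experimentally; `apply_ppiase()` scales whatever isomerization
  transitions the model contains.
- Hill coefficients of ~3 in measured dose-response curves reflect
  cooperative subunit behaviour that a single-binding-step scheme
  cannot produce; simulated curves have n_H ≈ 1 by construction.
- No dwell-time maximum-likelihood fitting of single-channel records
  and no fitting of microscopic rates to experimental traces is
  provided; the schemes are forward models for hypothesis
  discrimination, not estimators.
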