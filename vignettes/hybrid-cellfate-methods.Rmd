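---
title: "Hybrid Petri net simulation and simulative model checking of p53-driven cell fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Petri net simulation and simulative model checking of p53-driven cell fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpnfate)
```

## The scientific problem

When a cell is irradiated, DNA double-strand breaks (DSBs) activate the ATM
checkpoint kinase, which stabilises the transcription factor p53. p53 drives
its own negative regulators (Mdm2, which degrades p53, and Wip1, which
deactivates ATM), so while damage persists the nuclear p53 level *pulses*
rather than settling. The number of pulses a cell produces is stochastic,
depends on the radiation dose, and feeds the cytoplasmic apoptosis pathway:
cells with repeated pulses accumulate pro-apoptotic targets (Bax, PIDD) and
activate caspase-3; cells with few pulses survive. The question the package
addresses quantitatively is: *given a dose, what is the probability that a
cell shows zero, one, or two-or-more p53 pulses?*

`hpnfate` implements the full chain as a reusable pipeline:

1. a **hybrid Petri net (HPN)** formalism and simulator (`hpn_model()`,
   `simulate_hpn()`),
2. the **cell-fate model** itself (`build_cellfate_model()`): a stochastic
   nuclear subnet, a continuous cytoplasmic subnet, and stochastic mRNA
   transport bridging them,
3. a **PLTL** (probabilistic linear temporal logic) layer that classifies
   finite simulation traces (`parse_pltl()`, `check_trace()`), and
4. a **simulative model-checking** pipeline that estimates per-dose pulse
   probabilities over seeded trace ensembles (`run_ensemble()`,
   `verify_ensemble()`).

## The hybrid Petri net formalism

A hybrid Petri net is a tuple $(P, T, h, \mathrm{Pre}, \mathrm{Post}, M_0)$:
places and transitions partitioned by the hybrid kind function $h$ into
discrete and continuous nodes, weighted input/output incidence maps, and an
initial marking. Discrete places hold non-negative integer token counts
(molecules); continuous places hold non-negative reals (nM).

* **Stochastic transitions** fire after an exponentially distributed delay
  whose rate — the *propensity* — is a mass-action-style expression over the
  markings of their pre-places and modifier places (e.g. $f \cdot A \cdot B$
  for an association, $k \cdot A_n$ for transport).
* **Continuous transitions** define flows: each continuous place obeys
  $\dot m_p = \sum_t \mathrm{Post}(p,t)\,v_t - \sum_t \mathrm{Pre}(p,t)\,v_t$,
  i.e. the difference between the rates of its producing and consuming
  transitions — an ODE system assembled from the net structure.
* **Immediate transitions** fire in zero time as soon as enabled, ordered by
  priority then id, at $t = 0$ and after every stochastic firing. A marking
  revisited within a zero-time cascade aborts the run with a livelock
  diagnostic (cap: 10,000 zero-time firings).
* **Modifier arcs** expose a marking to a rate law without consumption and
  never disable a transition.

Rate laws and arc weights use a small arithmetic expression language
(`+ - * / ^`, parentheses, and `round`, `floor`, `ceiling`, `min`, `max`,
`abs`, `exp`). Marking-dependent weights are evaluated on the pre-firing
marking; weights written onto discrete places must evaluate to integers.

## Execution semantics and numerics

Two execution paths produce statistically identical results:

* **Decoupled two-phase path.** When no stochastic or immediate element
  reads or consumes a continuous place, and no continuous element reads a
  discrete place, the total propensity is piecewise constant between
  firings. The jump process is then simulated exactly (direct-method SSA),
  recording every discrete-to-continuous jump (mRNA transport adds the
  trans-ratio weight to a continuous place), and the ODE system is
  integrated once over the whole horizon with those jumps applied as solver
  events. The cell-fate model satisfies these conditions by construction.
* **Integrated-hazard path (general).** Otherwise the ODEs are integrated
  jointly with the cumulative total propensity $\Lambda(t)$; with
  $u \sim \mathrm{Exp}(1)$ the next firing time is the root of
  $\Lambda(t) = u$, located by `deSolve::lsodar`'s root detection, and the
  firing transition is drawn proportionally to the propensities at that
  time. Freezing propensities between grid points would bias firing times
  whenever rates depend on evolving continuous markings; the integrated
  hazard avoids that.

Integration uses the stiff-capable `lsoda` family with default tolerances
`rtol = 1e-6`, `atol = 1e-8` (tightenable per run through
`hpn_sim_config()`). Continuous markings are clamped at zero: derivatives
are evaluated at $\max(m, 0)$ and recorded values at grid points are
truncated at zero, because mass-action flows can numerically undershoot.

The inner loops (propensity evaluation, the SSA pass, the ODE right-hand
side) are compiled: rate expressions are translated to a small stack-machine
bytecode executed in C++. The R event loop remains the reference
implementation; both consume the RNG stream identically, and the test suite
asserts bit-identical traces between the two. Reproducibility contract: the
same model, configuration and seed always produce the identical trace, and
ensemble run $i$ uses seed $\texttt{base\_seed} + i - 1$, recorded in the
output manifest.

Traces are recorded on a fixed grid of `n_intervals + 1` points (default
2000 intervals); temporal properties are evaluated on grid-sampled values
only, with no interpolation, matching offline checking of stored CSV
traces.

## PLTL on finite traces

The property layer implements LTL with numeric atoms under a probability
operator: `P=? [ phi ]` (estimate the probability of the path formula) or
`P>=x [ phi ]` (compare the estimate to a bound). Finite-trace semantics
with **strong next**: at position $i$ of an $n$-row trace, `X phi` requires
a successor row; `G phi` means *phi at every $j \ge i$* (degenerating to
the atom at the last row); `F` and `U` are existential as usual. Operator
precedence is unary (`!`, `X`, `G`, `F`) over `&` over `|` over `->` over
`U`; `a -> b` is accepted and desugared to `!a | b` at parse time.

The three built-in pulse properties over the total-p53 column, with
thresholds $T_L < T_M < T_U$ (defaults 920, 1200, 1800 trace units):

* **P1** (no pulse): `G (p53 < T_L)`;
* **P2** (one pulse): the trace starts below $T_M$, eventually exceeds
  $T_U$, eventually settles for good below $T_M$, and after any excursion
  above $T_U$ stays above $T_M$ until it drops below $T_U$ for good;
* **P3** (two or more pulses): neither P1 nor P2.

By construction the three are mutually exclusive and exhaustive, so the
estimated probabilities sum to one exactly. Note the deliberate asymmetry
of P1 and P2 near the thresholds: a trace that oscillates strictly between
$T_L$ and $T_U$ violates P1 (it crosses $T_L$) without ever producing a
countable pulse, and is classified multi-pulse by the formulas while the
two-threshold counting oracle (`count_pulses()`) reports zero. The test
suite restricts oracle/formula agreement claims to traces whose excursions
are unambiguous.

The probability estimate is the satisfying fraction over the ensemble: each
run contributes a 0/1 indicator, mirroring offline checking of one stored
CSV trace at a time. No multiple-testing correction is applied; reports
carry exact binomial 95% confidence intervals per estimate.

## The cell-fate model

`build_cellfate_model()` wires 29 discrete places and 52 stochastic
transitions (nucleus), one immediate transition, and 45 continuous places
with 69 continuous transitions (cytoplasm):

* **DSB input.** The sampled DSB count (Poisson with mean 35 per Gray) is
  written to the `DSB` place and the `IR` place is marked. The immediate
  transition `Div_IR` consumes both and distributes `round(0.7 * DSB)`
  tokens to simple breaks and the remainder to complex breaks through
  marking-dependent arc weights — exactly the split `sample_dsb()` reports.
  It fires once at $t = 0$ and never at dose zero.
* **Repair.** MRN complexes bind either break type; repair returns MRN
  (recycled) and moves the break to the fixed-DSB pool. Complex breaks
  repair at half the simple-break rate.
* **Checkpoint.** DSB–MRN complexes catalyse ATM trans-autophosphorylation
  (autocatalytic in ATMP, so activation is switch-like while damage
  persists); Wip1 deactivates ATMP cooperatively. Active ATM
  phosphorylates p53 (Ser15) and destabilises Mdm2.
* **p53 core.** p53 is translated from its mRNA; the unphosphorylated form
  turns over basally and through Mdm2-mediated complexes (Mdm2 recycled);
  phosphoforms have reduced Mdm2 affinity. p53-P induces Mdm2, Wip1,
  p53DINP1 and p21 mRNA; p53-PP (the DINP1-promoted second site) induces
  Bax and PIDD mRNA and represses Bcl2 mRNA.
* **Transport.** Four stochastic transitions carry the p21/Bax/PIDD/Bcl2
  mRNAs to the cytoplasm; each firing consumes one nuclear token and adds
  `trans_ratio` nM to the continuous mRNA place.
* **Cytoplasm.** Translation of the four targets; the PIDD→PIDDosome→
  caspase-2→tBid axis; Bax translocation, dimerisation and pore (Bax4)
  assembly opposed by Bcl2 in both compartments; pore-dependent release of
  cytochrome c and SMAC; ATP-dependent apoptosome assembly; caspase-9 and
  caspase-3 activation; XIAP inhibition of procaspase-9 and caspase-3 and
  its sequestration by SMAC; the p21 brake on procaspase-3 and its
  caspase-3-mediated removal; CAD/ICAD and PARP as execution readouts.

The `p53` observable used by all properties is
`p53_scale * (p53 + p53_P + p53_PP + complexes)` — the summation over every
p53-containing place, scaled into arbitrary trace units so that the
conventional thresholds (920/1200/1800) sit inside the model's dynamic
range. The binding of the property column to this observable is a
configuration entry, not hard-coded.

**Units.** Discrete markings are molecule counts, continuous markings nM;
conversion happens only on transport arcs. The conversion formula
$C = N/(N_A V_c)$ with $V_c = 1.96\,\mathrm{pL}$ gives
$8.47\times10^{-4}$ nM per molecule; the conventional trans ratio used on
the arcs is the constant 0.00847. The order-of-magnitude discrepancy
between the formula and the conventional constant is preserved as-is: the
constant wins, the formula is documented and available as
`concentration_from_count()`.

## The surrogate parameterization

The original kinetic constants of the underlying literature model are not
redistributable, so the package ships a *surrogate* parameter set
(`surrogate_params()`, stored as plain text in `inst/extdata/`). It was
calibrated once, against qualitative regime targets only:

* at dose 0, total p53 stays below $T_L$ (no-stress control);
* single-cell traces show crisp, full-amplitude pulses whose number grows
  with dose (repair duration sets the number of checkpoint cycles:
  roughly 1 pulse at 0.3 Gy, 1–3 at 2.5 Gy, several at 6 Gy over the 48 h
  horizon);
* the population mean at 2.5 Gy is a damped oscillation: a dominant first
  pulse (cells are synchronised by the onset of damage) followed by
  attenuated later maxima as runs desynchronise.

Three design choices give the surrogate a clean relaxation oscillator
within the mass-action idiom: autocatalytic ATM activation (a damage-gated
switch), cooperative (quadratic) Wip1 quenching of ATMP (so reignition is
blocked until Wip1 decays), and phospho-protection of p53 from both basal
turnover and Mdm2 (so the quiet baseline is strongly damped while the pulse
pool is not). Time is measured in hours; the default horizon is 48 h with
2000 output intervals.

The surrogate is **not** a reproduction of the published constants, and its
per-dose probabilities are not comparable to published probability tables;
only the qualitative dose trend is a designed property. Loading an
externally transcribed parameter file through `read_parameter_set()`
switches the model to that regime (`provenance` field: `surrogate`,
`iwamoto`, `user`).

Because population averaging attenuates desynchronised pulses, the second
population-mean maximum at 2.5 Gy falls below the single-cell middle
threshold; the package's own damping check therefore smooths the mean with
a 1 h moving average and detects maxima above a population-level threshold
(700 trace units, about twice the no-stress baseline), asserting
non-increasing amplitudes.

## File formats

**Model files** (`read_hpn_model()` / `write_hpn_model()`) are plain text
with five sections; `#` starts a comment, double quotes group expressions:

```
hpn "name"
[constants]
k = 0.5                       # name = value
[places]
A_n discrete 4                # id kind initial-marking
A_c continuous 0
[transitions]
transport stochastic "k * A_n"   # id kind "rate expression"
Div_IR immediate 1               # id immediate priority
[arcs]
A_n -> transport standard 1      # source -> target kind weight
transport -> A_c standard 0.00847
A_n -> transport modifier        # modifier arcs carry no weight
[observables]
total = "A_n + A_c"
```

Reading validates the net and reports diagnostics with line numbers;
writing then reading preserves structure, expressions and constants.

**Parameter files** (`read_parameter_set()`) are flat `name = value` text
with an optional `provenance =` line and `[constants]` / `[initial]`
sections. **Trace CSVs** have a `Time` first column, one column per
observable, plain decimals in the shortest representation that round-trips
each double exactly, and LF line endings — so identical seeds give
byte-identical files. **Report CSVs** carry `dose, P1, P2, P3, n` and
per-property binomial confidence bounds. **Property files** hold one PLTL
formula per line in ASCII spelling (`G F X U & | ! -> P=? P>=x`), with
column names matching the trace CSV headers.

## What the synthetic fixtures do and do not show

`gen_fixtures()` writes analytically solvable nets (exponential decay;
birth–death with Poisson stationary law; the transport motif with mean
$w N_0 (1 - e^{-kt})$), pulse traces with declared pulse counts, and the
surrogate parameter file, plus a JSON manifest of ground truths. These
validate the simulator against closed forms and the logic layer against
construction-guaranteed classifications. They do not validate the
biological realism of the cell-fate parameterization: passing tests show
that the machinery is correct and that the surrogate regime has the
designed qualitative shape, not that the model reproduces any particular
cell line's measured pulse statistics.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen once: 200 runs per dose at
doses 0, 0.3, 2.5 and 6 Gy for the dose-trend and control checks (base
seed 42); 200 runs for the birth–death stationary comparisons; 300 runs
for the transport-mean and time-varying-hazard laws; 1000 random
formula/trace pairs for the logic-oracle agreement; 500 noise-free and
1000 noisy generator traces for classification. Binomial noise at these
sizes is far smaller than the effects asserted (e.g. the P3 gap between
0.3 and 6 Gy is ~0.5 with a standard error of ~0.035).

## Known limitations

* Deterministic-delay and scheduled transitions, read/inhibitor/equal
  arcs, and coloured nets are out of scope; the cell-fate model needs none
  of them.
* Immediate transitions gated by continuous places are rejected (their
  enabling cannot be root-detected reliably); gate immediates with
  discrete places.
* The decoupled fast path requires the structural conditions above; nets
  that couple regimes in both directions fall back to the slower
  integrated-hazard loop.
* Atoms are evaluated at grid points only; pulses narrower than the grid
  spacing can be missed. At the default 2000 intervals over 48 h the grid
  spacing (86 s) is two orders of magnitude below the pulse width.
* The surrogate's absolute probabilities are calibration artefacts; only
  structure, units and qualitative trends carry scientific meaning.
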