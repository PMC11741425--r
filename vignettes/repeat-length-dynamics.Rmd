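---
title: "Modeling the evolution of simple repeat length distributions"
author: "repeatflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of simple repeat length distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatflux)
```

## The scientific problem

Short tandem repeats (STRs, microsatellites) are vastly over-represented
in genomes relative to random sequence: run lengths in an i.i.d. sequence
decay geometrically, yet real genomes carry a heavy tail of long repeats,
up to lengths that seed repeat-expansion disorders.  `repeatflux` asks
whether mutation alone — without selection — can generate and maintain
the observed genome-wide distribution of contiguous repeat lengths, and
provides the machinery to answer it: repeat cataloguing from assemblies,
mutation-rate estimation from parent-offspring trio calls, a
deterministic mutation kernel that evolves the length distribution over
billions of generations, grid-search inference of instability-rate
parameters, and analytic steady-state approximations.

Throughout, a *repeat* is a maximal run of complete copies of a motif
with no interruptions and no partial motifs; an interrupted repeat is
treated as several distinct repeats.  For the dynamical model the genome
is abstracted to a binary alphabet: `A` is the focal repeat unit and `B`
is any other unit, and the model tracks the two count vectors
`NA(L)` (repeats of length `L`, in units) and `NB(l)` (non-motif strings
of length `l`) up to a boundary length.

## The mutation kernel

Every mutational process moves expected counts between integer length
bins, simultaneously and deterministically (a Jacobi update computed
from the pre-step state).  Substitutions are classified by their
three-unit context and conserve total genome length:

* **lengthening** (`ABB>AAB`): target is the two boundary-adjacent `B`
  units per repeat, restricted to the `ABB` context.  A boundary unit
  belonging to a length-1 `B` string sits in the `ABA` *fusion* context
  instead, so the per-repeat target of two is scaled by the fraction of
  `B` strings with length at least two.  This context-faithful form is
  what makes the two-way substitution equilibrium exactly geometric with
  ratio $\mu/(\mu+\nu)$ — with a flat target of two the `B1` junctions
  are double-counted between the lengthening and fusion channels and a
  residual per-bin influx shifts the equilibrium visibly.
* **shortening** (`AAB>ABB`): target two per repeat for $L \ge 2$; the
  adjacent `B` string grows by one unit (allocated across occupied `B`
  bins in proportion to occupancy, any length — a `B` string of any
  length can grow, whereas only `B` strings of length $\ge 2$ can donate
  a unit to a lengthening repeat).
* **fission** (`AAA>ABA`): target $L-2$ interior units; the two
  fragments are spread evenly over bins $\le L-2$ and one `B1` is
  created.
* **fusion** (`ABA>AAA`): proportional to the `B1` count; the two fused
  repeats are drawn occupancy-weighted from the length distribution
  (ordered pairs $(j,k)$ with weight $N_j N_k / (\sum N)^2$, product
  length $j+k+1$).  The alternative per-event reading — subtract the two
  counts evenly from all bins the product could have drawn from — is
  retained as `fusionMode = "even"`; the two modes have identical event
  counts and expected length budgets and occupancy weighting is the
  default because fusion samples the distribution twice.
* **`A1` creation/loss** (`BBB>BAB`, `BAB>BBB`): the same fission and
  fusion mechanics applied to the `B` distribution.

Indels do not conserve genome length.  **Expansions** and
**contractions** act locally ($L \to L \pm 1$) with per-repeat target
size $L$; **non-motif insertions** split a repeat, spreading the two
fragments evenly over bins $\le L-1$; `B`-string insertions, deletions
and `B1`-deletion fusion use length-independent per-unit rates.  Gains
above the boundary length (default 100) reflect onto the boundary bin.

### Rates and the instability parameterization

De novo per-target rates are reliable only up to $L = 8$; above that the
curves are parameterized by a multiplier $m$ at $L = 9$ and power laws
$\mathrm{rate}(L) = m\,\mathrm{rate}(8)\,(L/9)^{\tau}$ with exponents
$\tau_\epsilon$ (expansion) and $\tau_\kappa$ (contraction); non-motif
insertion shares $\tau_\epsilon$.  Every per-length value is capped at
0.1.  `defaultRateSet()` provides the package's reference calibration:
the six context substitution rates as reported from pooled trio data
(lengthening $4.77\times10^{-9}$, shortening $8.08\times10^{-9}$, fusion
$2.87\times10^{-9}$, fission $4.54\times10^{-9}$, `A1` creation
$3.97\times10^{-9}$, loss $6.45\times10^{-9}$, plus the measured
`B`-string indel rates), and de novo instability curves for $L=1..8$
chosen once to reproduce the qualitative features of trio estimates: a
steep rise through $L=5..8$ crossing the substitution scale near
$L=7$, a mild initial expansion bias
($\epsilon_8/\kappa_8 \approx 1.23$, which places the
expansion–contraction balance near $L^* = 18$ at
$\Delta\tau = 0.3$), and non-motif insertion about five-fold below
expansion, roughly parallel to it.

### Time rescaling and the progressive schedule

Per-generation rates are $O(10^{-9})$, so the kernel multiplies all
rates by $10^r$ and lets one iteration stand for $10^r$ generations.
The aggregated update is faithful while the summed per-repeat rate stays
below 0.1 (`checkLinearBound()`).  The default schedule runs $10^4$
iterations at $r = 5, 4, 3, 2$, then $10^5$ at $r=1$ and $10^6$ at
$r=0$ — at least $10^9$ generations, refined at progressively finer
steps; the `"fast"` preset keeps the $r = 5..3$ stages, which already
represent $1.11\times10^9$ generations and resolve every bin whose
per-repeat rate is at most $10^{-4}$.

During high-$r$ burn-in stages high-length bins are super-linear.  Two
safeguards keep the update meaningful there: when a bin's total expected
outflux exceeds half its stock, all events sourced from that bin are
scaled down proportionally (the limiter is inactive — bit-for-bit — in
the linear regime), and a count above 1000 in the boundary bin advances
the schedule to its next stage early.  A boundary count of at least 1000
at the end of a run flags a non-equilibrating, expansion-dominated
parameter combination.

### What "steady state" means here

All kernel processes are homogeneous of degree one in the counts, so the
late-time state is a *self-similar growing mode*, not a fixed point: the
normalized shape $P(L)$ freezes while total counts grow at a rate
$\lambda$ set by the small imbalance between indel length production and
tail contraction (about $2\times10^{-10}$ per generation under the
reference calibration — an e-folding every ~5 billion generations;
nothing forces $\lambda$ to zero exactly).  Consequently raw per-bin net
fluxes floor at $\lambda N_L$, about $10^{-2}$ of the per-bin gross flux
at $L = 1$; after correcting for the global growth mode a residual of
order $10^{-5}$ remains because the nearly decoupled short
(substitution-dominated) and long (instability-dominated) regimes grow
at slightly different rates, a spread that decays only on
$\sim 10^{13}$-generation timescales.  Exact per-bin flux balance (we
measure below $10^{-10}$ of gross) is obtained only for two-way
substitutions alone, where the geometric distribution is a true fixed
point.  The same near-degeneracy bounds how closely equilibria reached
from different initial conditions agree: a few $10^{-4}$ relative
per bin across the instability tail, $10^{-5}$ in the
substitution-dominated bins.

The `B`-string background indel rates are biased (insertion
$1.44\times10^{-10}$ per unit versus deletion $4.6\times10^{-12}$), so
with them active the `B` distribution drifts upward indefinitely and
drags the repeat side through its coupling to the `B1` count; analyses
that interrogate steady-state structure therefore switch the `B`
background indels off — they model non-repeat sequence turnover, not
repeat instability.

## Inference

The distance between a model and an empirical distribution is a
least-squares metric in log space over bins $1..L_\mathrm{boundary}$,
computed on raw counts after adding a pseudocount of one and
normalizing; the log scale upweights the sparsely populated tail, which
carries the information about instability.  Because the pseudocount
floor makes the metric sensitive to the overall count scale, model
counts are rescaled to the empirical genome-wide repeat total before
comparison (this also removes the arbitrary $e^{\lambda T}$ growth
factor).  `gridSearch()` scores every combination of
$m \in \{1,2,4,8,16,32\}$ and $\tau_\epsilon, \tau_\kappa \in [0,5]$.
The metric surface is nearly flat along lines of constant
$\Delta\tau = \tau_\kappa - \tau_\epsilon$ (strictly so for large $m$),
so with Poisson sampling noise on the empirical counts the argmin
wanders along that ridge between noise realizations; closed-loop
recovery of the generating parameters to within one grid step is a
property of the noiseless loop, and the effect of count noise on the
set of acceptable parameters is quantified by the consistency interval
instead.
`consistencyInterval()` propagates the Poisson uncertainty of the input
mutation counts to a one-sided 95% metric threshold (200 resamples,
top 5% discarded) and per-bin envelopes.

## Steady-state analysis

For short repeats ($L \lesssim 10$) substitutions dominate and the
steady state is geometric with ratio $\mu/(\mu+\nu)$
(`geometricEquilibrium()`).  For long repeats, with fusion neglected,
the continuum steady-state equation in per-target rates is

$$0 \approx \tfrac12 \partial_L^2[(\epsilon_L+\kappa_L) L P_L]
  - \partial_L[(\epsilon_L-\kappa_L) L P_L]
  - (\nu + \iota_L) L P_L + 2\int_L^\infty (\nu+\iota_\lambda) P_\lambda\, d\lambda.$$

`solveSteadyODE()` solves three nested truncations between
$L_1 = \mathrm{round}(L^*)$ (the expansion–contraction crossing,
$L^* = 9 (\epsilon_8/\kappa_8)^{1/\Delta\tau}$) and $L_2 = L_\mathrm{max}$
(where the genome expects fewer than one repeat), pinned to a reference
kernel state at those lengths:

* `"local"` — diffusion and directional flux only;
* `"fission_out"` — adds the fission loss term;
* `"full_fission"` — the third-order length-derivative form that also
  retains fission influx, with the vanishing-net-flux constraint imposed
  through a third reference value at $L_\mathrm{max}-1$.

Numerically the equations are solved as linear boundary-value problems
on a uniform grid by finite differences (second-order central stencils,
one-sided at the edges; the third derivative is composed as
$D_1 D_2$).  Solutions decay over several orders of magnitude across
the domain, so the solver works in units of the log-interpolated
reference profile — plain collocation at the default 0.25-unit grid
leaves $(h\, d\log P/dL)^2 \approx 0.36$ truncation errors; a 0.05-unit
grid brings the full equation to percent-level agreement.  Negative
solution values are flagged rather than suppressed.

Under the reference calibration the full third-order equation matches
the kernel within 10% in all three contraction-bias regimes (measured
8%, 2.8% and 0.9% at $\Delta\tau = 3, 1, 0.3$), and accuracy is ordered
by the terms retained.  The two tighter truncations, however, do not
reach 10% even in their nominal regimes (80% for the local equation at
$\Delta\tau = 3$; 24% for the fission-out equation at $\Delta\tau = 1$):
with non-motif insertion at one fifth of expansion, the fission terms
are a 10–20% coefficient correction near $L^*$ for *every*
$\Delta\tau$ — the crossing point pins expansion and contraction to a
common scale there — and the exponential sensitivity of the solution
integrates that correction across the domain.  The qualitative nesting
pattern (tighter approximations failing in weaker-bias regimes) is
robust; the quantitative adequacy of the tighter truncations depends on
how far the fission scale sits below the local scale, which is a
property of the rate calibration, not of the solver.

Regime labels (`classifyRegime()`) use $\Delta\tau \le 0$ for
non-equilibrating dynamics (the $\tau_\kappa = \tau_\epsilon$ edge case
is asymptotically expansion-biased because $\epsilon_8 > \kappa_8$) and
heuristic cut points 0.5 and 1 between weakly, intermediate and strongly
contraction-biased — qualitative markers of where fission influx and
outflux stop being negligible, not sharp boundaries.

## The synthetic-data generators

`generateIIDGenome()`, `generateTrioTable()`, `generatePopstrTable()`
and `generatePseudoEmpirical()` produce every input the pipeline needs
with known ground truth, seed-deterministically.  Design points worth
knowing:

* Trio tables emit events for *each* member of the motif equivalence
  class (A and T) at the same truth rates, matching the estimator's
  pooled counting.  Substituted or inserted non-motif bases are drawn
  from outside the class, and gain events are placed on non-class
  reference bases (while keeping the event total proportional to the
  full context-site count), which eliminates cross-member
  reclassification of substitutions.  Residual couplings remain for
  indels: a contraction's deleted member bases register as B-string
  deletions for the partner member, mildly inflating the background
  B-rate estimates — context and per-length instability rates are
  unbiased, B-string rates are upper bounds on synthetic data.
* The per-category event streams are placed by context, so recovery
  tests are calibrated with moderate per-bin counts (tens to a few
  hundred events), where the Poisson interval width dominates the
  few-percent stream-overlap effects.
* Pseudo-empirical distributions are the kernel's late-time state scaled
  to a target genome-wide repeat total with optional per-bin Poisson
  noise.  What these fixtures do *not* emulate: mutation-rate
  heterogeneity along the genome, calling and mapping error structure,
  population polymorphism, or selection — passing recovery tests shows
  the estimators invert the generative model, not that real trio data
  are this clean.

## Problem sizes used by the tests

The test-suite and acceptance runs use reduced, fully synthetic scales
chosen to finish comfortably on one CPU: boundary length 60 (100 for
conservation checks), genome-scale repeat totals of $10^7$–$3\times10^9$
units, the `"fast"` three-stage schedule (extended to an $8\times10^5$
iteration coarse burn for stability-dichotomy runs, about
$8\times10^{10}$ generations, so that the slow similarity-mode growth of
mildly unstable parameter combinations — about $3\times10^{-10}$ per
generation — carries the boundary bin well past the 1000-count flag),
closed-loop grids of $3 \times 21 \times 21$ combinations at
$\tau$ step 0.25, twenty replicate datasets for estimator-coverage
checks, and $10^4$ replicates for stochastic-mean checks.

## Known limitations

* The instability model is the mononucleotide A/B abstraction; general
  motifs are supported for counting (any unit length 1–6) but not for
  the kernel's rate model.
* Stochastic mode Poisson-samples per-bin influx and outflux without
  constraining individual transitions; with fractional expected counts
  the zero floor biases near-empty bins upward, so stochastic runs are
  meaningful for integer-valued, well-populated states.
* The deterministic kernel ignores genetic drift and selection by
  construction.
* Fusion enters the kernel but is deliberately absent from the
  steady-state ODEs (it is subdominant for long repeats in the
  parameter region of interest); the ODE domain starts at the continuum
  scale $L > 10$, below which the geometric solution applies.
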