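---
title: "Fluxomer-based 13C metabolic flux analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluxomer-based 13C metabolic flux analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fia)
```

## The problem

Steady-state ^13^C metabolic flux analysis (MFA) infers intracellular
reaction rates from two sources of information: stoichiometric balances
(at metabolic steady state the inflows and outflows of every
intracellular pool cancel, `S u = 0`) and the isotope-labeling patterns
that an isotopically labeled feed imprints on intermediate metabolites.
Because the number of fluxes exceeds the number of independent balances
— in particular when reversible reactions are represented as separate
forward/reverse rates — the labeling data are essential for
identification.

Classical formulations carry two kinds of state: fluxes and per-pool
isotopomer fractions. This package instead uses a single composite
state, the **fluxomer**: the rate `x[f, w]` at which unidirectional
flux `f` converts substrate molecules carrying the specific label word
`w` (one bit per tracked carbon; atom 1 is the least significant bit,
printed leftmost). Fluxes are then linear in the state, `u = U x`, and
each pool's isotopomer fraction is the ratio of slot-restricted
fluxomers to their flux.

## The balance equations

Enzymes do not distinguish isotopomers, so the isotopomers inside a
pool distribute uniformly over all of its outgoing fluxes. Writing the
inflow of a given label pattern into a pool as a 0/1 row over all
fluxomers, every fluxomer obeys a trilinear steady-state relation

```
x = g(u) * (H1 x) * (H2 x)          (elementwise products)
```

where `H1` sums the incoming fluxomers that deliver the pattern the
fluxomer draws from its first ("left") source pool, `H2` the same for
the second pool, and `g(u) = (G1 u) / ((G2 u)(G3 u))` is a rational
prefactor whose denominators are the source pools' total outfluxes.
Three conventions make this form exact for every row:

* **Augmentation.** A constant slot (value 1) and a unit flux are
  appended; single-substrate fluxomers point `H2` at the constant and
  `G3` at the unit flux, so no row needs a special case. Internally the
  constant enters as an additive offset rather than a matrix column.
* **Boundary rows.** Fluxomers of a flux that drains an input substrate
  are clamped to `u_uptake * feed_fraction(w)` by putting the feed
  fraction into their `G1` row and pointing both `H` rows at the
  constant slot. The relation then holds identically and the rows are
  constant in `x`.
* **Multiplicity.** A reaction emitting two molecules of the same pool
  (an aldolase) contributes an entry of 2 where both product molecules
  match; without it the balances would leak mass.

A structural caveat discovered while validating the solver: the
trilinear system admits non-physical extra fixed points. The physical
root is singled out by the partition closure `U x = u`, which the
"natural" iteration `x <- g(u) * (H1 x) * (H2 x)` preserves *exactly*
provided the start already satisfies it. The solver therefore starts
from the **unlabeled steady state** — each flux carries its full value
on the all-zero word — with the feed rows clamped, not from a zero
vector.

## Solving: hybrid Newton/fixed-point in reduced coordinates

The natural iteration mimics how labeling spreads through the organism
and converges unconditionally from the unlabeled start, but slowly when
recycle loops or fast exchange reactions push its contraction rate
towards 1. Newton's method on `F(x, u) = g∘(H1x)∘(H2x) − x`, whose
Jacobian has the closed form `D(g∘H1x) H2 + D(g∘H2x) H1 − I`, converges
quadratically.

Before any solve, the two source matrices are stacked and factored once
per network, `[H1; H2] = [L1; L2] U_H`, by a hand-written tall sparse
LU with Markowitz-style pivoting (minimum row fill, then sparsest
column, then largest pivot). On labeling networks most rows of `H` are
duplicates — all fluxomers of a reaction that share a source pattern
share a row — so elimination cancels them outright: on the
pathway example below the factors hold about 69k nonzeros versus 1.19M
in the originals. Columns that never pivot (fluxomers nothing consumes)
receive unit rows, keeping `U_H` invertible. In the variables
`y = U_H x` the propagation is `y <- U_H (g ∘ (L1 y) ∘ (L2 y))` and the
Newton systems stay sparse; the same factorization also turns the
implicit-function sensitivity solve (below) from minutes into
milliseconds.

The solve alternates propagation with Newton corrections: always during
the first `newton_first = 2` passes, then whenever the squared step
change exceeds `eps_newton = 1e-6`, and additionally — a guard this
implementation adds — whenever the plain propagation's contraction
ratio stays above 0.3 while the change is still above the final
tolerance `eps_final = 1e-12` (squared change; a max-change metric is
also available). Without the guard the tail from `1e-6` to `1e-12`
can cost hundreds of sweeps on strongly exchanging networks. With the
reduction active the pathway example converges in 4 hybrid iterations.

Degenerate inputs are handled conservatively: a pool whose total
outflux is numerically zero has its fluxomers set to zero (and is an
error if it still receives inflow); fluxes are clipped to `1e-9` before
inner solves so `g` stays finite.

## Measurements and the scaling-invariant objective

Each measured quantity is a linear functional of the fluxomers, built
on a *reporter* outflux of the measured pool (the first declared
consumer; at steady state all outfluxes carry identical label
proportions, so the choice only scales the rows — this is asserted by a
test). Mass isotopomer M+k sums the reporter fluxomers whose fragment
restriction has weight k; positional enrichments and multiplet patterns
are wildcard sums.

Raw MS (and ^13^C NMR) intensities are only known up to a per-group
scale. Instead of estimating normalization factors, the residual for
group row j is formed as

```
eps_j = (T x)_j − yhat_j * (d x),      yhat_j = m_j / sum_i m_i
```

with `d` the group-sum row, which annihilates any common factor on the
group — multiplying a group's raw intensities by an arbitrary positive
constant changes neither the residual nor the fitted fluxes (tested to
1e-10 and 1e-6 relative, respectively). ^1^H NMR enrichments are
absolute fractions (both isotopes appear in the spectrum), so their
denominator row is the full reporter sum and `yhat` is the reported
value itself. Rows are weighted by their reported standard deviations
(diagonal `1/sd`); the exact within-group residual covariance is
implemented behind `cov_weighting = TRUE` but is not the default, since
reported residual conventions in this field are diagonal. Flux
measurements enter as `(u_meas − (U x)_f)/sd` and contribute the only
nonzero entries of the constant vector `b` in the objective
`||A x(u) − b||^2`.

When a measured fragment's molecular formula is supplied, a
lower-triangular convolution matrix built from fixed natural-abundance
constants (^13^C 0.0107, ^2^H 0.000115, ^15^N 0.00364, ^17^O/^18^O
0.00038/0.00205, ^33^S/^34^S/^36^S 0.0075/0.0425/0.0001,
^29^Si/^30^Si 0.0468/0.0310, P monoisotopic; overridable) maps the
backbone-only mass distribution to the observed one and premultiplies
the group transform.

## The optimization problem

Fluxes are estimated by minimizing `||A x(u) − b||^2` over the polytope
`Q = {u : S u = 0, 0 ≤ u ≤ u_ub}`. Labeling is degree-0 homogeneous in
`u` (the steady state scales as `x(cu) = c x(u)`), so at least one
absolute flux measurement is required; this is validated up front.

* **Initial point.** A convex QP maximizes the interior margin `s`
  (all free fluxes at least `s` away from both bounds) minus
  `lambda ||u_meas − u_hat||^2`, with `lambda` starting at `1e3` and
  halved until the optimal margin is positive. A `1e-8` ridge makes the
  Hessian positive definite for the QP solver.
* **Outer loop.** Deterministic sequential least squares: at each
  iterate the residual is linearized through the sensitivities
  `dx/du` (implicit function theorem: `F'_x (dx/du) = −F'_u`, with
  `F'_u` from quotient-rule differentiation of `g`; both verified
  against central finite differences), and a convex QP with the exact
  equality constraints, the bounds, and a trust-region box is solved.
  Steps are accepted on a decrease of the true objective; the radius
  grows when the quadratic model predicts well and shrinks otherwise.
  The trust region matters: unrestricted Gauss-Newton steps send the
  weakly identified exchange fluxes of the pathway example into a
  non-global basin. No random restarts are used anywhere; fitting the
  same problem twice returns bit-identical estimates.
* **Stopping.** Relative objective decrease below `1e-9` with a step
  below `1e-8 (1 + max|u|)`, capped at 500 outer iterations.

## The example networks and the synthetic generator

`toy_fixture()` is a five-pool demonstration network: input A (4
carbons) splits into B and C, an internal B→D→B cycle, a reversible
B↔C exchange, and a condensation D+C→E with efflux. Stoichiometry
forces `f1 = f4 = fout`, `f2 = f3 + f4`, `f5 = f5r`, leaving the scale,
the cycle flux `f3`, and the exchange magnitude `f5` free. One property
deserves emphasis: because D's only producer maps B's carbons
identically, D's labeling always equals B's, and the cycle split
`f2/f3` is *structurally unidentifiable* from labeling — only the
difference `f2 − f3` is determined. Recovery statistics on this network
therefore show essentially exact recovery of `f1`, `f4`, `fout` and the
exchange, while `f2`/`f3` individually sit wherever the optimizer's
path leaves them along the flat direction; the median relative error
over all unidirectional fluxes stays small because the identifiable
majority dominates. This is a property of the network, not of the
estimator.

`empp_fixture()` encodes upper glycolysis plus the pentose-phosphate
pathway of *E. coli* with standard carbon maps (the oxidative branch
releases carbon 1 as CO2; the aldolase's DHAP-derived triose is
carbon-reversed; the transketolase/transaldolase block recycles triose
and hexose carbon into the pentoses). The labeling experiment it
carries — 50% [1-^13^C] glucose with 1.1% single-label at each other
position, positional enrichments of Rul5P, Ery4P, GA3P and PEP with
sd 0.002, uptake measured as 1.02 (sd 0.001) — is self-consistent: at
the fixture's reference flux table the model reproduces every stored
measurement to the printed precision (2e-3), which is itself a test.
Two encoding choices could not be read off the pathway diagram alone
and were pinned by that reproduction requirement: the strongly
exchanging reversible pair must be transketolase 2 (its reverse carries
hexose C1 label back into the pentose block; with transketolase 1 in
that position the Rul5P C1 enrichment comes out threefold too low), and
the assignment between transketolase 1 and transaldolase is not
determined by the data (both reproduce the measurements; their net
fluxes are equal and their exchanges nearly so) and was fixed by
convention. The default upper flux bound is 20: the exchange magnitudes
of the reversible pairs are weakly identified and need a finite search
box; the unidirectional estimates are insensitive to this choice.

`simulate_measurements()` is the synthetic generator: it solves the
steady state at known fluxes, reads the group intensities through the
measurement transforms, adds seeded Gaussian noise with standard
deviation `sigma` on the fraction scale (matching the sd conventions of
the stored experiment), optionally multiplies each group by a random
constant to emulate non-normalized intensities, and anchors the scale
with an uptake measurement (sd 0.001). It emulates fraction-scale
Gaussian noise on integrated, already-deconvolved intensities; it does
not model peak overlap, drift, missing peaks, or non-Gaussian count
noise, so passing tests say nothing about those aspects of real
spectra.

The independent cross-check, `brute_force_oracle()`, iterates the
classical per-pool isotopomer balances directly (dense mixtures and
outer-product condensations, no shared code with the fluxomer solver),
projecting each distribution back onto the simplex every sweep — the
quadratic condensation terms otherwise amplify roundoff in the
distribution sums. Solver and oracle agree to 1e-9 on both fixtures.

## Problem sizes and runtime choices

The demonstration network has 64 fluxomers; the pathway network 5594
(19 unidirectional fluxes). Matrix preparation (including the tall LU)
runs once per network in ~10 s; a steady-state solve takes a fraction
of a second and the full pathway fit ~15 s on one core. The packaged
tests run the noise study at 10 replicates and the recovery study at
20 synthetic problems with sd 0.002 — the spread contrast between
unidirectional and exchange fluxes is already decisive at that size
(the former's replicate standard deviations sit two orders of
magnitude below the latter's).

## Known limitations

* Only a two-state ^12^C/^13^C carbon alphabet; no other isotopes.
* At most two substrate pools per reaction; condensations of three
  pools must be rewritten with an explicit intermediate.
* A reaction may consume at most one molecule of a given pool.
* No transient (isotopically nonstationary) labeling dynamics: the
  natural iteration is a solver device, not a kinetic model.
* No cumomer or elementary-metabolite-unit decompositions; the
  reduction here is the purely linear LU change of variables.
* The FTBL reader targets the tutorial-level subset of that dialect;
  unknown sections are skipped with a warning.
* No profile-likelihood or Monte-Carlo confidence intervals beyond the
  replicate noise study.
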