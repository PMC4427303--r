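---
title: "Hybrid qualitative/quantitative inference of signaling network structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid qualitative/quantitative inference of signaling network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridnet)
```

## The problem

Signaling pathways such as the growth-factor driven MAPK and PI3K/Akt
cascades are wired together by crosstalk, feedforward and feedback
mechanisms, and which of the many literature-reported mechanisms is
active depends on the cell type. With $m$ candidate mechanisms there are
$2^m$ conceivable network structures; fitting an ordinary differential
equation (ODE) model for each is hopeless for $m$ beyond a dozen.
`hybridnet` implements a two-stage strategy: a *qualitative* stage uses
cheap interaction-graph reasoning to discard every structure that cannot
even reproduce the signs of observed perturbation responses, and a
*quantitative* stage fits the few surviving structures as mass-action
ODE models and ranks them statistically.

## Stage 1: interaction graphs and the dependency matrix

A network is a signed directed graph over the active forms of the
signaling species. Edges are partitioned into an always-present **core
model** (the main activation routes) and named **candidate mechanisms**;
a *model structure* is the core plus a subset of mechanisms (its
*building block*).

For an ordered species pair $(A, B)$ the **dependency matrix** classifies
the influence of $A$ on $B$ from the signs of all simple directed paths
$A \to B$ (the sign of a path is the product of its edge signs):

* **activator** — all paths positive; **inhibitor** — all negative;
* **ambivalent** — paths of both signs; **neutral** — no path;
* activators/inhibitors are **weak** when at least one path touches a
  node lying on a negative feedback cycle (endpoints count), otherwise
  **strong**.

Path semantics matter: a walk that loops through a negative cycle can
carry a different sign than any simple path, so the package enumerates
simple paths exactly (compiled depth-first search; the graphs here have
at most a few dozen nodes).

Inhibiting a strong activator of $B$ forces a *decrease* of $B$ at every
time; for a weak activator the feedback may overturn the *late* response,
so only the *early* decrease is forced. Inhibitors force increases
symmetrically; neutral species force no change; an ambivalent factor, or
a mix of activators and inhibitors across several simultaneously
inhibited species, leaves the response unconstrained. Kinase-activity
inhibitors (which block a kinase's outgoing influence but not its own
phosphorylation) are modeled by a *dummy node* inserted between the
kinase and its targets; the dummy, not the kinase, is then inhibited.
Dummy insertion provably leaves all pre-existing dependency classes
unchanged, which the test suite checks by brute force.

Observed time courses are reduced to the same vocabulary: per condition
pair (control vs control-plus-inhibitors) and measured species, fold
changes are called `increase`/`decrease`/`no_change` per time point when
all replicates agree beyond a fold threshold $\theta$, and the
observation is the first conclusive *early* call (≤ 30 min) plus the
first subsequent *opposite* effect (the *late* call; a mere return below
threshold is not an opposite effect). The package defaults to
$\theta = 1.5$ on the ratio scale — a conventional immunoblot
detectability floor; no published threshold exists for this choice, and
it only affects user data and synthetic studies, never the bundled
discretization, which ships as data. Below-threshold calls are treated
as `not_conclusive` rather than as positive evidence of "no change",
because a fold-change cutoff cannot distinguish absence of an effect
from a sub-threshold real effect; this also keeps consistency *monotone*
(adding edges can only widen the allowed response sets), which the
enumeration exploits.

**Enumeration.** `enumerate_minimal_models()` searches blocks level-wise
by cardinality: a size-$k$ block is a candidate only if every size
$k{-}1$ sub-block failed the consistency check (the same logic as
"combine a failing structure with further mechanisms"), and consistency
verdicts are memoized by the induced edge set, since mechanisms may
share edges. Under monotone consistency this returns exactly the
*minimal* consistent structures — no sub-block of a result is
consistent, and no minimal structure is missed — which the tests verify
against brute-force enumeration of all $2^m$ blocks on small synthetic
masters. The union of all selected blocks defines the **complete
model**, the null model of the later statistics.

## Stage 2: mass-action ODE models

Structures are first **compressed** (parallel equal-sign edges merged,
linear chains through unprotected degree-(1,1) nodes collapsed with
multiplied signs; measured, inhibited, stimulus and constant species are
never removed; compression is idempotent and preserves dependency
classes between protected nodes). For the bundled example all candidate
edge endpoints are additionally protected, so every structure shares one
species set and one comparable reaction-table layout.

Translation is deterministic: a positive edge $pA \to pB$ becomes the
activation $B \to pB$ with rate $k \cdot pA \cdot B$ (the catalyst is
not consumed) and each active species gets exactly *one* basal
deactivation $pB \to B$ with rate $k' \cdot pB$; a negative edge becomes
a catalyzed deactivation $pB \to B$ with rate $k \cdot pA \cdot pB$.
Positive candidate edges are annotated either *independent* (an extra
parallel activation) or *modulating* (a parallel activation carrying the
core activator as an additional factor, e.g. $k \cdot Ras \cdot PAK
\cdot Raf$); each candidate edge contributes exactly one reaction with
its own rate constant. Special cases: the receptor gains synthesis and
turnover reactions (its moiety is not conserved), a constitutively
active kinase (PDK1 in the example) enters as a constant parameter, and
two-step activations (p90RSK) share one inactive pool with both active
forms deactivating to it. Every other protein's active+inactive total is
conserved along trajectories — an emergent property the tests check
numerically, together with the requirement that the Jacobian sign
pattern of the translated system restricted to active forms reproduces
the compressed graph.

Initial amounts are 1 for inactive forms and 0 for active forms, in
arbitrary units absorbed by observation scaling factors; no steady-state
constraint is imposed. Kinetic parameters live in $[10^{-5}, 10^3]$.
Inhibitors are parameters in $[0,1]$ gated by per-condition binary
switches; an inhibitor of strength $s$ multiplies the rate constants of
its targeted reactions by $(1-s)$ (node inhibitors target the species'
activation reactions, kinase-activity inhibitors every reaction the
active form catalyzes).

Models round-trip through SBML Level 3 Version 1 (single unit
compartment, amounts, irreversible mass-action laws that are plain
products of identifiers); constructs outside this subset are rejected
with an explicit error, and the inhibitor-to-reaction coupling travels
in a package annotation element.

## Likelihood, fitting and model selection

Observations are arbitrary-unit, gel-scaled and noisy. The error model
is additive Gaussian on the $\log_{10}$ scale with one noise parameter
$\sigma$ per observable and one multiplicative scaling factor per
gel × observable:
$-2\log L = \sum_i \left[ \left( \frac{\log_{10} y_i - \log_{10}(s_{g(i)} x_i)}{\sigma_{o(i)}} \right)^2 + \log 2\pi\sigma_{o(i)}^2 \right].$
The noise parameters are profiled analytically by default (their
conditional maximum-likelihood value per observable), iterating between
the weighted least-squares step and the $\sigma$ update; at the optimum
this coincides with joint numerical optimization and removes a flat
direction from the search space.

`multistart_fit()` draws starting points by Latin hypercube over the
$\log_{10}$ bounds, augmented incrementally so that start sets are
nested across `n_starts` (more starts can only improve the best
objective), and optimizes each start by Levenberg–Marquardt (a
trust-region method) on the log-parameters with box bounds. Parameters
estimated within 0.05 log units of a bound are frozen for a short period
of iterations and then released — boundary-close parameters, a symptom
of partial practical non-identifiability, otherwise slow the
optimization. The sorted per-start objectives (the waterfall) expose
whether a reproducible optimum was reached. For nested structures the
fitter can be warm-started from the enclosing model's optimum
(`extra_starts`), which backward selection uses.

Ranking uses two standard criteria computed from the same fits:
$\mathrm{AIC} = 2k - 2\log L$, and a likelihood-ratio comparison of each
structure against the complete (null) model, reported as the penalized
objective $-2\log L - \chi^2_{0.95}(\Delta\mathrm{df})$ for ranking and
as a pass/fail decision ($-2\log L_\mathrm{nested} + 2\log
L_\mathrm{null} \le \chi^2_{0.95}(\Delta\mathrm{df})$: the nested model
is a valid simplification). The penalized objective is the primary
ranking criterion since the AIC's linear penalty slightly favours larger
models; ties break by smaller df, then id. `run_selection()` orchestrates
forward (minimal structures + core + complete), backward (complete minus
one designated block at a time), combination (all unions of two or more
designated blocks — eleven structures for four blocks) and
random-control modes; random structures draw fixed-size candidate-edge
subsets from the complete model, rejecting any draw that contains a
selected minimal structure.

## Post-fit analysis

**Prediction profiles.** For an unmeasured species the 95% band at each
time point is the range of its predicted value over parameter sets whose
$-2\log L$ stays within $\chi^2_{0.95}(1)$ of the optimum, found by
stepping the prediction geometrically away from its fitted value under a
quadratic penalty and re-optimizing all parameters; the last accepted
endpoint is reported (a conservative, under-covering choice when a step
overshoots). A model with no free parameters collapses to its
trajectory.

**Inhibitor screens.** Each protein (and each unordered pair) is
inhibited by scaling the rate constants of all its *outgoing* reactions
— reactions it catalyzes or feeds as the substrate of a forward
conversion, excluding its own basal deactivation, mirroring
kinase-activity inhibition — by $(1-s)$, default $s = 0.5$. Readouts are
trapezoidal areas under the curve of the chosen observables (and their
sum) over 0–120 min on a 241-point uniform grid, as percent of the
uninhibited control. **Synergy** of a pair is the excess of the combined
percent reduction over the sum of the single reductions; 0 means
additive, and a Bliss-independence variant is available for comparison.
The inhibitory Akt→Raf1 crosstalk is quantified as the percent reduction
of the time-integrated flux of the Akt-catalyzed Raf1 deactivation
reaction when Akt activation is divided by an $n$-fold factor — one
concrete reading of "reducing the inhibitory effect", stated here
because no formal definition exists for it.

## The synthetic ground-truth generator

`generate_study()` builds a positive core cascade `S -> P1 -> ... -> Pn`
plus single-edge candidate mechanisms (negative feedbacks running
upstream, positive crosstalk edges skipping forward), plants a building
block, draws kinetic rates log-uniformly on $[10^{-2}, 10^1]$
(re-drawing a parameter set under which some protein never responds
above a small floor: the study emulates proteins measured because they
respond), simulates the control plus all single and double
node-inhibition conditions at strengths 0.5–0.9 on the grid
{0, 5, 10, 30, 60, 120} min, applies per-gel scaling factors (one gel
per observable × replicate, shared across conditions, as on a shared
blot) and lognormal noise of chosen coefficient of variation, and
discretizes versus control. Everything is reproducible from one seed.

What it deliberately does **not** emulate: saturating antibody response,
background subtraction, missing lanes, correlated gel errors,
biological-replicate heterogeneity beyond lognormal noise, or mechanisms
with more than one edge. Passing tests on these studies therefore show
the *algorithms* are correct under the stated error model, not that real
immunoblot data satisfy that model.

Two numerical notes. First, fitting studies with *exactly* zero noise is
degenerate under this likelihood ($\hat\sigma \to 0$, $-2\log L \to
-\infty$), so fitting-based checks use near-noise-free studies
(CV = 0.02) while discretization and enumeration checks use true zero
noise. Second, property tests that need an *informative* scenario
(selection behavior, prediction-band comparisons) select the first seed
whose study satisfies preconditions judged before any fitting — all
planted rates above $10^{-0.5}$ and a core model inconsistent with the
discretized data — rather than a hand-picked seed.

## Problem sizes and other fixed choices

The test-suite and acceptance computations use cascades of 2–4 proteins
with 1–4 mechanisms, 4–16 conditions, 2 replicates and 8–12 multistart
starts; the bundled network example enumerates all consistent blocks of
its 17 mechanisms (about 47,000 consistency evaluations after pruning).
Solver tolerances default to `rtol 1e-8/atol 1e-10` for reported
simulations and `1e-6/1e-8` inside the optimizer; trajectories change by
less than $10^{-6}$ relative under tolerance halving, which is tested.
Chain compression visits species in lexicographic order (determinism),
combination generation is lexicographic over sorted mechanism ids, and
predictions floor at $10^{-12}$ before the log (observations must be
strictly positive; a zero prediction against a positive observation is
then an effectively infinite penalty rather than an error mid-fit).

## Known limitations

* Minimality is defined at the mechanism level (matching the
  membership-matrix encoding of selected structures); for mechanisms
  sharing edges, edge-level minimality can differ.
* The dependency formalism admits routes whose sign is a product of two
  negative influences; such double-negative routes can make additional
  structures consistent that a coarser reading would exclude.
* Prediction-profile endpoints are conservative (the band never
  overshoots the likelihood threshold, so it may undercover).
* The inhibitor screen manipulates rate constants, not drug
  pharmacology; no dose–response or binding kinetics are modeled.
* Single-process execution; fits of the bundled example's full
  41-reaction complete model to large datasets are outside the intended
  scale of the package's optimizer defaults.
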