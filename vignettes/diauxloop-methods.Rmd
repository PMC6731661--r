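---
title: "Closed-loop improvement of hybrid diauxic-shift models: methods and design"
author: "diauxloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop improvement of hybrid diauxic-shift models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diauxloop)
```

# The modelling problem

When *Saccharomyces cerevisiae* grows in aerated batch culture on glucose it
ferments first — fast growth, ethanol secreted — and, once glucose is
exhausted, remodels its metabolism to respire the accumulated ethanol: the
diauxic shift, visible as a biphasic OD curve with a faster pre-shift and a
slower post-shift phase. Capturing this transformation requires two coupled
layers: a signalling layer that carries information (which regulators and
enzymes are active) and a metabolic layer that carries mass (which fluxes
are feasible). `diauxloop` implements such a hybrid model together with the
machinery needed to *improve* one from data: structure inference, active and
discriminative experiment selection, growth-curve phenotyping, greedy
validated revision, and an in-silico laboratory so that complete
design–execute–refine cycles can be run and evaluated at desk scale.

# The hybrid model

## Signalling layer: a two-slice linear-Gaussian DBN

Every gene/protein $g$ has a Gaussian activity state per time slice,
nominally in $[0,1]$. Regulators may have children; enzymes are leaves wired
to reactions. The conditional is

$$X_{g,t+1} \mid X_{\cdot,t} \sim N\Big(b_g + \sum_{p \in pa(g)} w_{pg}
X_{p,t},\; \sigma_g^2\Big),$$

with a fixed one-slice lag. One slice equals one phenotype sampling interval
(default `dt = 0.5` h — sub-hour, matching automated plate-reader cadence).
Forward propagation treats genes as independent within a slice (diagonal
covariance): means are exact, variances are the diagonal approximation
$sd'^2 = \sum_p w_p^2 sd_p^2 + \sigma^2$. Exact joint covariances are
retained where conditioning demands them (see backward inference).

## Metabolic layer: flux balance analysis

A stoichiometric matrix $S$, flux bounds in mmol·gDW⁻¹·h⁻¹, and a biomass
reaction whose flux is the specific growth rate $\mu$ (h⁻¹). Each
step solves $\max \mu$ s.t. $S v = 0$, $lb \le v \le ub$, with a
parsimonious secondary objective ($\min \sum_i |v_i|$) so degenerate optima
resolve deterministically and without futile cycles. The LP solver is a
dense two-phase simplex with Bland's rule (compiled); at the toy scale used
here (tens of reactions) this is faster than any generic sparse machinery
and is verified in the test suite against brute-force vertex enumeration of
the flux polytope.

## Coupling

* **Genes → reactions.** Boolean gene–reaction rules are evaluated fuzzily
  (AND = min, OR = max over gene means clipped to $[0,1]$); the resulting
  activity linearly scales the reaction's default bounds. Linear scaling is
  the minimal monotone coupling; it is isolated in `geneStatesToBounds()` so
  it can be replaced wholesale.
* **Metabolites → genes.** Threshold rules ("glucose < 0.75 mM sets the
  shift regulator to (1, 0.05)") overwrite target states after each
  metabolic step, for the next slice. This is the regularisation step that
  closes the loop and produces diauxie: the two bundled rules form a
  complementary glucose switch on CAT8.
* **Dynamics.** `simulateStrain()` repeats: regulatory forward step →
  bound scaling → one DFBA step (Michaelis–Menten uptake caps, availability
  caps, exponential biomass update with interval-average biomass for medium
  bookkeeping) → rule application. Knockouts clamp a gene to $(0,0)$ *and*
  zero its rule literals, severing signal and mass flow at once.

# Backward inference and active experiment selection

`backwardInfer()` conditions the DBN on Gaussian observations of (gene,
time) pairs by Kalman filtering plus Rauch–Tung–Striebel smoothing over the
whole gene vector — exact for the linear-Gaussian process, with
pseudo-inverses so deterministic nodes and exact evidence are admissible.
Rule-overwritten states enter as *dynamic clamps* (an independent redraw at
the clamped slice, exactly as the rule acts in simulation), not as evidence;
this keeps the unobserved posterior identical to the hybrid forward
trajectory.

`adactiveRank()` scores genes by
$D(g) = \sum_t KL(\text{forward}_{g,t} \,\|\, \text{backward}_{g,t})$
(the forward reference is the smoother's own exact prior, whose means equal
the mean-field simulation). Evidence is derived from observed growth by
fixed-growth FBA (`boundsFromGrowth()`): with the biomass flux pinned to the
observed rate, flux variability per rule-bearing reaction is translated into
a required-activity interval per enzyme gene.

Growth constrains activities only one-sidedly — an expressed enzyme can idle
without substrate — so intervals become evidence in exactly two situations:

* **capacity deficit**: the forward activity lies below the minimum activity
  *any* feasible flux distribution needs at the observed rate (evidence
  pulls it up to that minimum);
* **capacity excess**: the model's own predicted rate in a slice exceeds the
  observed one, in which case the genes gating the flux-carrying reactions
  are pulled down proportionally.

A model whose predictions match the observations triggers neither, so its
divergence is exactly zero — the self-consistency property the selection
logic is tested against. Evidence is applied per phase (pre-shift rate with
the full medium, post-shift rate with glucose closed), with a 2 h settling
buffer after the observed shift because the regulatory cascade genuinely
needs a few slices to re-equip the cell. KL is summed over time (the
per-gene maximum is available via `summary = "max"`); SDs are floored at
$10^{-3}$ before each term.

# Structure inference and revision

* **Ensemble ranking** (`ensembleRank()`): K components, each the Edmonds
  maximum spanning arborescence (implemented from scratch; no installed R
  package provides it) of a dependency graph built by double sampling — a
  bootstrap over transitions crossed with a subsample of candidate parents.
  Dependency weight is the absolute lagged Pearson correlation, the natural
  score for a linear-Gaussian model class. A virtual root at weight
  $10^{-6}$ avoids designating a biological root. Edges are aggregated by
  frequency, prior-network edges floored at 0.5, and a ridge refit on the
  full data drops edges with $|w| < 0.05$. Defaults: $K = 200$, row fraction
  0.8, parent fraction 0.7; ties break lexicographically everywhere.
* **Forward selection** (`forwardSelect()`): ranked edges are added only if
  the leave-one-out one-step prediction error of the child strictly
  improves by at least 1% relative. The LOO error uses the penalised
  hat-matrix identity, which equals explicit per-fold refitting (verified in
  the tests); the margin keeps chance fluctuations of the cross-validated
  error from adding noise edges.
* **Revision** (`refineModel()`): the error currency is the mean absolute
  post-shift growth-rate error over observed deletant strains, predicted and
  observed curves being phenotyped by the *same* estimator. Because
  simulation is the expensive step, candidate removals are first ranked by a
  cheap structural score: over the worst-predicted strains (top error
  quartile by count, errors above tolerance), an edge scores $|w|$ whenever
  it lies on a directed path out of the strain's deleted gene or into a
  rule-clamped gene. Autoregressive self-edges are excluded — they encode
  degradation kinetics, not regulatory hypotheses. Candidates are then
  tentatively removed, greedily, with
  re-ranking after each acceptance, a tabu list over rejections, an
  acceptance threshold of $10^{-4}$ h⁻¹ (guards against float noise), and a
  hard budget of error evaluations. Only removals are enacted.

# Growth-curve phenotyping

`preprocessCurve()` blanks, clips at zero, median-smooths (window 5) and
averages replicates (a warning, not an error, below 8 replicates).
`growthParameters()` works on log OD within the growth window (lag to
saturation): the shift time is the glucose-depletion time (first reading
below 0.1 mM) when glucose was assayed, otherwise the breakpoint of a
two-segment piecewise-linear fit; the segment rates are the *median*
pointwise slopes with a one-grid-step trim around the shift, which is exact
on clean exponential phases and robust to transition samples; lag is the
time to exceed 1.05× the initial OD; yield is the final OD. A shift is
declared only when the two-segment fit beats the single line in an F-test at
$\alpha = 0.05$ *and* the slopes differ by more than 0.01 h⁻¹ (instrument
resolution — a numerically perfect exponential must not be declared
biphasic). `compareModels()` reports the relative error reduction
$(\bar e_A - \bar e_B)/\bar e_A$ and a two-sided Wilcoxon signed-rank
p-value, exact for $n \le 25$ without ties.

# The virtual laboratory

`generateGroundTruth()` builds the study system: a fermentation route (fast,
low yield per carbon: glc → 1.6 ethanol + 1.6 CO₂ + biomass) and a
respiration route (slow, high yield: ethanol + 2 O₂ → CO₂ + biomass), both
carbon-balanced so conservation can be asserted per step; glucose transport
and fermentation gated by constitutive enzymes; respiration gated by the
CAT8 → HAP4 cascade, with CAT8 switched by the glucose rules. Default
medium: 20 mM glucose, 0.05 gDW/L inoculum, 45 h horizon at 0.5 h sampling —
the wild type ferments at ≈ 0.32 h⁻¹, shifts at ≈ 8.5 h, respires at
≈ 0.10 h⁻¹ and saturates near 1.9 OD. Every generated truth is simulated
and only returned if it actually shows a diauxic shift (detected shift,
glucose depleted at it, pre-rate > post-rate).

Three design choices deserve explanation:

* **Self-persistence.** Source regulators (and extra regulators) carry an
  autoregressive self-edge (0.85), representing protein stability across a
  half-hour slice, with biases solved so stationary means are unchanged.
  Without it, a constitutive regulator's stationary variance equals its
  process noise and no finite time course can pin its outgoing weights to
  ±0.05; with it, stationary fluctuations are informative. Self-edges are
  treated as known kinetics, not as structure to be inferred (they are
  excluded from candidate edges and from recovery scoring).
* **Repressor pairs.** Three repressor→activator pairs (MIG1 ⊣ SIP4,
  NRG1 ⊣ ADR1, RGT1 ⊣ STD1) keep three regulators near-silent in the wild
  type. `plantSpuriousEdges()` uses them to construct "wrong" working
  models whose defects have a small wild-type signature but a large
  signature in the repressor's deletant — the regime in which growth-curve
  driven revision is identifiable at all, and the regime the closed-loop
  comparison of hypothesis-led vs random designs is run in.
* **Sparse peripheral wiring.** Extra nodes get at most one incoming cross
  edge, wired as a DAG (stability is then guaranteed despite
  self-persistence) with the bias re-centred to keep the drawn stationary
  mean.

Observation noise is additive Gaussian on OD readings (default SD 0.01,
floored at 0) and on glucose (0.05 mM); expression courses are one sampled
stochastic trajectory (300 slices by default, running past saturation so
late samples carry stationary fluctuations) plus measurement noise
(SD 0.02). What the generator does **not** emulate: plate edge effects,
probe-level microarray artifacts, growth-medium batch variation, multi-gene
epistasis beyond the boolean rules, and any metabolic regulation faster than
one slice. Passing tests therefore demonstrate correctness of the machinery
under the stated noise model, not robustness to every artifact of real
plate data.

# Closed-loop cycles

`runCycle()` chains the stages with full seeding: held-out evaluation
strains are drawn first (from all knockable genes, so they bite minimally
into the regulator design pool) and the design may only select from the
remainder — evaluation strains are always disjoint from refinement strains,
audited in the report. Design methods: `adactive` (divergence against the
observed wild-type curve), `coregmine` (border regulators of antagonistic
dense coregulation subgraphs, padded with top divergence when short),
`adana` (largest predicted post-shift disagreement with a rival model), and
`random` (the control). The evaluation currency is the held-out post-shift
MAE before vs after refinement, summarised with `compareModels()`.

# Numerical choices and problem sizes

Tolerances: LP feasibility 10⁻⁹; carbon balance asserted to 10⁻⁶ per step;
smoothing checked against brute-force joint-Gaussian conditioning to 10⁻⁶;
KL SD floor 10⁻³; revision acceptance 10⁻⁴ h⁻¹; forward-selection margin 1%
relative. Ties break lexicographically (edge ranking, divergence ranking,
removal scores). Degenerate inputs: flat curves phenotype to zero rates with
no shift; infeasible DFBA steps fall back to zero growth and are flagged;
infeasible observed growth rates fall back to the achievable maximum with a
warning.

The bundled studies run at deliberately small sizes chosen to give each
check clear statistical power on one CPU: ground truths of 12–52 genes and
9 reactions; 300-slice expression courses; ensembles of K = 200; 50-seed
Monte-Carlo suites for recovery and repair; 10 paired cycles of k = 20
experiments for the design comparison. The acceptance script
(`scripts/acceptance.R`) re-runs the same studies at moderately reduced
replication and records the problem size beside every number it reports.

# Known limitations

* The gene→bound coupling and the metabolite rules are deliberately simple;
  neither saturating kinetics of gene action nor combinatorial promoter
  logic beyond AND/OR is represented.
* Backward inference uses growth (and glucose) as the only phenotypes; the
  evidence construction from fixed-growth flux variability is an explicit
  interpretation, isolated behind `boundsFromGrowth()`.
* Credit assignment from growth evidence is only gene-resolved, not
  edge-resolved: when an enzyme has several regulators, the smoother spreads
  the blame for a capacity mismatch in proportion to each parent's prior
  variance, so a perturbed weight into a multi-parent enzyme may rank the
  wrong (higher-variance) parent first. The localisation study therefore
  perturbs the respiratory weight whose child has a single parent.
* The mean-field forward pass underestimates the variance of genes with
  correlated parents; the active-learning scorer therefore uses the exact
  smoother prior as its reference.
* Edge additions during revision are architecturally possible but disabled:
  only removals are enacted, matching the refinement regime the package is
  designed and tested for.
* Wilcoxon p-values fall back to the normal approximation in the presence
  of ties.
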