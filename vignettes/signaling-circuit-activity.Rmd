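---
title: "Mechanistic signaling-circuit activity: model, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic signaling-circuit activity: model, assumptions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcircuit)
```

# The model

`sigcircuit` estimates the activity of *signaling circuits* — the subgraphs
of a signaling pathway that connect receptor proteins to one effector
protein — from bulk gene expression. The premise is mechanistic rather than
enrichment-based: expression is treated as a proxy for protein availability,
and a signal is propagated from receptors to the effector along the
pathway's signed topology. The effector's signal intensity is the circuit's
activity, a number in $[0, 1]$ per sample that can be compared between
conditions, and the same machinery evaluates counterfactuals such as "what
happens to every circuit if this drug's targets are silenced?".

## Signal propagation

A pathway is a signed directed graph: nodes hold one or more genes, edges
are *activation* or *inhibition*. For each node $n$ with normalized
expression value $v_n \in [0,1]$, the transmitted signal is

$$
S_n \;=\; v_n \cdot \Bigl(1 - \prod_{s_a \in A}(1 - s_a)\Bigr)
        \cdot \prod_{s_i \in I}(1 - s_i),
$$

where $A$ and $I$ are the signals arriving over activation and inhibition
edges. The activation factor is a probabilistic OR — one strong activating
input suffices — and each inhibiting input attenuates by its complement.
Receptors receive a constant activation input of 1 (an arbitrary initial
signal), so $S_{\text{receptor}} = v_{\text{receptor}}$, and the circuit's
activity is $S_{\text{effector}}$.

Three conventions complete the rule:

* **Activation-starved nodes.** A non-receptor node reachable only through
  inhibition edges has an empty activation set; its empty-product factor is
  0, because inhibition alone cannot create signal. A circuit whose effector
  is unreachable from every receptor through activation-only edges is
  therefore structurally silent: its activity is 0 and it is flagged
  (`starved` in the convergence report) rather than silently reported.
* **Standalone updates.** `nodeUpdate()` exposes the bare update rule; used
  in isolation (outside a circuit, where no receptor convention applies) an
  empty activation set yields factor 1 so the rule reduces to the familiar
  receptor case.
* **Cycles.** Signaling pathways contain feedback loops, and the recursion
  above does not define an evaluation order for them. Acyclic circuits are
  evaluated exactly in one topological sweep. Cyclic circuits are evaluated
  by synchronous (Jacobi) fixed-point iteration started at $S_n = v_n$,
  stopping when the largest absolute change falls below `tol` (default
  `1e-6`, well under any biologically meaningful activity difference) or
  after `maxIter` (default 100) sweeps. The update map is continuous on
  $[0,1]^V$, so iteration is well defined; on acyclic graphs it provably
  reaches the topological answer because upstream signals stabilize within
  $|V|$ sweeps (a property the test suite checks against an independent
  fixed-point oracle). Non-convergence is reported, not fatal: the caller
  decides.

One numerical detail: for a node with a single activation parent the OR
factor $1 - (1 - s)$ is evaluated analytically as $s$. The subtraction form
loses about six significant digits when $s \approx 10^{-6}$ (catastrophic
cancellation against 1), which is exactly the regime of long chains of
moderate values; the analytic form keeps activation-only chains equal to
$\prod v_n$ to machine precision.

## Circuit decomposition

Within a validated pathway graph, receptors default to in-degree-0 nodes
and effectors to out-degree-0 nodes; explicit `receptor`/`effector`
annotation columns override topology (needed for fully cyclic graphs, where
neither is derivable and an unannotated graph is a structural error). One
circuit is built per effector: its members are every node and edge on some
receptor-to-effector directed walk, computed as the intersection of the
forward-reachable set from the receptors with the backward-reachable set
from the effector. An edge with both endpoints in that intersection always
lies on such a walk, so membership needs no path enumeration — though the
test suite verifies it against exhaustive enumeration on small graphs. A
circuit granularity of one-per-effector (merging all receptors) matches the
convention of naming circuits "pathway: effector gene"; repeated effector
genes within one pathway are disambiguated with `*`, `**` suffixes in
display names only, since node ids already make circuit ids unique.
Isolated nodes, and effectors unreachable from every receptor, yield no
circuit (a warning notes the omission).

# From counts to node values

The propagation rule needs per-node values in $[0,1]$. The normalization
chain is deliberately minimal and each step is a separate, testable
operation:

1. `logTransform()` — $\log_2(x + 1)$ on non-negative input.
2. `truncateQuantile()` — values above the 0.99 quantile are capped at it.
   The quantile is global over the matrix by default (one cap for the whole
   data set); a per-gene mode exists because the appropriate scope is
   genuinely debatable for heterogeneous data.
3. `scaleUnit()` — per-gene min–max scaling across samples. Genes constant
   across samples carry no ranking information and map to 0.5: mapping them
   to 0 would annihilate every downstream signal through the multiplicative
   rule for a purely technical reason, and 1 would assert full activity on
   no evidence.
4. `nodeValues()` — per node, the mean (default; min and max available) of
   its genes' unit values. Gene-free nodes (metabolites, unmeasured
   complexes) and nodes with no measured gene transmit neutrally (value 1)
   so that missing evidence does not destroy circuit signal; every such
   node is listed in a flag report so the choice is auditable per run.

Upstream count normalization (library-size/TMM-type corrections, batch
correction) is out of scope: inputs are assumed library-size comparable.
The synthetic generator guarantees this by construction; real-data users
normalize upstream with standard tools before import.

Min–max scaling has a consequence worth stating plainly: it erases each
gene's absolute scale, stretching even biologically flat genes across the
full unit interval. That makes every gene equally able to carry signal —
the property the multiplicative rule assumes — at the cost of amplifying
noise from uninformative genes. The recovery analyses below quantify what
that costs in statistical power.

# Differential signaling activity

`differentialSignaling()` compares circuit activities between two sample
groups (e.g. male vs. female cohorts) with a two-sided Wilcoxon rank-sum
test per circuit, Benjamini–Hochberg correction *jointly across all
circuits of all supplied pathways* (results are typically reported
genome-wide, not per pathway), and direction assigned post hoc from group
means at `fdr_p < alpha` (default 0.05). Two-sided testing with post-hoc
direction lets one analysis report both "higher in group 1" and "higher in
group 2" counts. Circuits with zero variance across all samples are
excluded before testing — the rank test is degenerate there — and reported
in an attribute.

The Wilcoxon policy is fixed and tested: exact null distribution when the
pooled sample size is at most 20 and there are no ties, normal
approximation with tie and continuity correction otherwise. The paired
variant (`wilcoxonSignedRank()`) drops zero differences per the standard
signed-rank convention and returns $p = 1$ when every pair ties. Both are
validated against exhaustive enumeration of group assignments and sign
patterns at small $n$, and the BH step against a brute-force step-up.

# Drug simulation

A drug is specified by its target genes. `applyKnockdown()` replaces each
target's unit-scale expression, in every sample, by 0.001 — a near-zero
value rather than 0, standing for strong but not absolute inhibition and
preserving a basal activity that keeps downstream comparisons informative.
The knockdown is applied after unit scaling because that is the scale the
model consumes. `simulateDrug()` then recomputes activities for the
untouched (reference) and pseudo-treated profiles and forms per-patient
fold changes $\log_2((\text{treated} + \varepsilon)/(\text{reference} +
\varepsilon))$ with $\varepsilon = 10^{-6}$ guarding zero activities;
$\log_2$ symmetrizes up- and down-effects.

Two tests follow. `pairedDrugTest()` asks, per circuit, whether the drug
changed activity at all (signed-rank on the paired patient profiles — the
reference and treated samples are the same patients). For group-specific
drug effects, `differentialDrugEffect()` compares the per-patient fold
changes between the two groups: it reports the group mean fold changes and
their difference (the direct comparison of means), and additionally a
rank-sum test with BH correction so the output table carries a defensible
significance column. Both the raw mean difference and the test are emitted;
the comparison of means alone is available to users who want it.

`hallmarkSummary()` and `pervasiveness()` summarize results at the level of
effector functions and cancer hallmarks, via user-supplied annotation
tables (packaged examples under `inst/extdata/`; the hallmark map shipped
there is a constructed stand-in, marked `synthetic` in its filename, not a
mined literature resource). A circuit annotated with $k$ hallmarks counts
toward all $k$ — the aggregation rule is declared in the output's
`counting` attribute since other conventions are defensible.

# The synthetic study generator

Real inputs for this kind of analysis are tumor expression cohorts and
curated pathway collections; neither is reproducible at desk scale. The
generator replaces them with scenarios in which the correct answer is known
by construction, so every stage can be validated end to end.

* **Graphs** (`generatePathway()`). Layered DAGs: receptors, intermediate
  layers of width 2, effectors; every non-receptor node receives an
  activation backbone edge from the previous layer (so every effector is
  activation-reachable), and each remaining adjacent-layer pair is wired
  with probability `pEdge = 0.25`, inhibitory with probability
  `pInhibition = 0.15`. These densities give branching, mostly tree-like
  circuits of 6–11 nodes at the default 12-node size — the shape of curated
  signaling maps — rather than densely chorded graphs whose OR gates
  saturate. Feedback edges are injected only on request (`allowCycles`).
* **Expression** (`generateExpression()`). Negative-binomial counts with
  log-normal baseline means (median 200, `sdlog` 1 — a typical spread of
  bulk RNA-seq expression levels) and dispersion 0.1, a mid-range value for
  bulk tumor cohorts; the Poisson limit is taken at dispersion 0. Counts
  rather than unit values, so the full normalization chain is exercised.
  A chosen set of group-biased genes has its mean multiplied by
  $2^{\text{lfc}}$ in group 1 only. Library sizes are equal by
  construction, which is what justifies skipping count normalization in
  the synthetic path.
* **Ground truth** (`generateScenario()`). A circuit is *expected
  differential* when at least one member node holds a biased gene with an
  activation-only path to the effector and the planted effect is at least
  one log2 unit; circuits containing no biased gene form the *null* set.
  Circuits whose biased genes reach the effector only through inhibition
  are left unlabeled and excluded from recovery metrics: their shift
  direction is sign-ambiguous, and they are exercised by direction-specific
  property tests instead.

All generators are seed-deterministic: the same seed and parameters
reproduce byte-identical output (sub-seeds for graphs and expression are
derived arithmetically from the master seed).

## What the scenarios do and do not emulate

The generator reproduces the *statistical structure* the analysis assumes —
two groups, a biased gene subset over a shared baseline, known topology —
but not covariate structure (age, stage, purity), batch effects, matched
cohort assembly, varying library sizes, or correlated gene modules. Passing
recovery tests therefore demonstrates that the pipeline detects planted
topology-consistent effects at realistic noise, not that it is robust to
confounding in observational cohorts.

## Power and calibration, measured

At the scenario size used throughout the validation suite (5 pathways × 12
nodes, one gene per node, 10 biased genes at log2 fold change 2, 30 samples
per group), the suite and `scripts/acceptance.R` observe:

* **Calibration.** With no planted effect, the mean fraction of circuits
  called at FDR < 0.05 across 20 replicate scenarios is far below the
  nominal level (usually exactly 0), within the binomial bound
  $0.05 + 3\sqrt{0.05 \cdot 0.95 / (20m)}$.
* **Error control.** The observed FDR among labeled positive calls stays
  at or near 0, and power is non-decreasing in the planted effect size
  across lfc ∈ {0.5, 1, 2}.
* **Sensitivity.** Recovery of expected-differential circuits averages
  about 0.74 across seeds (commonly 0.6–0.9) at lfc = 2. The misses are
  systematic, not random: a biased gene planted deep in a chain reaches the
  effector through a product of several min–max-stretched node values and
  possibly a shared OR gate, which can shrink its activity correlation
  to ~0.1. This is the honest ceiling of the model-plus-normalization
  combination at these sample sizes, and it is why sensitivity is reported
  as a measured quantity rather than asserted as a constant.

Problem sizes in the test suite (graph counts, node counts, seed counts)
are the package's validation defaults, chosen so the full suite completes
in well under a minute while keeping every enumeration exhaustive at the
sizes where exhaustiveness is the point ($n_1+n_2 \le 8$ rank-sum splits,
$2^n$ sign patterns to $n = 10$).

# Degenerate inputs and tie-breaks

* Duplicate identical edges collapse with a warning; duplicate edges with
  *conflicting* signs are an integrity error — the update rule defines no
  combination for simultaneous activation and inhibition on one edge.
* Self-loops are rejected at load time; the sign vocabulary is extensible
  through a user alias map (case-insensitive).
* Constant genes → 0.5; gene-free or unmeasured nodes → 1, flagged.
* All-tied paired comparisons → $p = 1$; zero-variance circuits are
  excluded from group testing and reported.
* Output ordering is deterministic everywhere (circuits by effector id,
  conditions by name), so repeated runs are byte-identical — a property the
  pipeline test verifies with checksums.

# Known limitations

* Activities are steady-state scores, not kinetics: no time course, no
  dose–response, no fitted edge weights.
* Node values inherit every limitation of expression-as-proxy-for-activity;
  post-translational regulation is invisible except through its downstream
  transcriptional footprint.
* Min–max scaling trades scale information for comparability; see the
  power analysis above.
* Multi-pathway runs require globally unique node ids across the supplied
  graphs (the generator prefixes ids with the pathway id; importers of
  shared-node collections should prefix likewise).
* The cycle policy (synchronous iteration, `tol` 1e-6, cap 100) is a
  declared convention; alternatives (damped, asynchronous) would give
  slightly different fixed points on strongly coupled loops.
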