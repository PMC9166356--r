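---
title: "Methods: constraint-based modelling with expression and insertion data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based modelling with expression and insertion data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadyflux)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic benchmark does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Steady-state flux modelling

A metabolic network is represented by its stoichiometric matrix $N$
($m$ internal metabolites $\times$ $n$ reactions). The central assumption
is pseudo-steady state: internal metabolite concentrations are constant on
the timescale of growth, so $Nv = 0$, and concentrations themselves never
appear. Fluxes carry units of mmol gDCW$^{-1}$ h$^{-1}$ and are bounded,
$v_{lb} \le v \le v_{ub}$; structural bounds are $\pm 1000$, with uptakes
written in the import direction so that the upper bound of a transporter
(`_tx` suffix) is the allowed uptake rate. External pool species (`x_`
prefix) are excluded from the balanced rows.

FBA maximizes $Z = c^\top v$ over this polytope; pFBA re-solves with
$c^\top v = Z$ fixed while minimizing $\sum_i |v_i|$ via the split
$v = v^+ - v^-$, $v^\pm \ge 0$ — the parsimony argument being that
enzymatically cheaper flux states are physiologically preferred. Since
alternative minimal-sum optima can exist, downstream code asserts objective
values and flux ranges rather than full flux vectors. FVA minimizes and
maximizes each flux with growth held at a fraction of its optimum: 0.9
when comparing flux ranges against external estimates, 0 when detecting
blocked reactions.

All programs run on a dense two-phase simplex with Bland's rule written
for this package (no LP solver is part of its dependency set), with
branch-and-bound on top for the iMAT integer program. Feasibility and
pivot tolerance is $10^{-9}$; "zero flux" and steady-state residuals are
judged at $10^{-6}$. These sizes (tens of reactions, a handful of
binaries) are far below anything that requires a production solver, and
the test suite cross-checks every optimum against exhaustive enumeration
of basic feasible solutions on networks of up to 8 reactions.

## Theoretical validation

Three checks certify a model before analysis:

* **Elemental balance** of C, H, N, O, P, S per reaction, excluding
  transporters, the biomass reaction and the ATP-maintenance (ATPM)
  reaction, which are artificial by construction. Charge is not checked;
  protons are tracked per compartment as ordinary species.
* **Unconserved metabolites**: a metabolite is unconserved if no
  conservation relation $m^\top N_{\text{int}} = 0$ with $m > 0$ supports
  it. The package maximizes the number of metabolites whose weight can
  reach 1 in a single LP; the tests confirm the flagged set against a
  per-metabolite LP oracle. Molecular weights are one valid conservation
  vector, so a fully balanced network passes.
* **Energy cycles**: with every uptake closed, the maximal ATPM flux must
  be zero; anything positive is a thermodynamically impossible
  ATP-from-nothing loop, usually a directionality error.

## Gene deletions and essentiality

GPR rules are boolean trees: AND for multi-subunit complexes (minimum
function for expression, conjunction for presence), OR for isoenzymes
(sum, disjunction). Deleting a gene disables exactly the reactions whose
GPR evaluates false; pFBA then gives the knockout growth rate. The
essentiality threshold is an absolute 0.05 h$^{-1}$ and the
growth-limiting band is importance (knockout/wild-type growth) at or below
0.85 — both package defaults chosen as the field's conventional cut-offs
for this organism class. GAM and NGAM maintenance demands are retained in
knockout simulations; a knockout changes catalysis, not the maintenance
physiology.

Isoenzyme annotations are frequently too permissive: a nominal backup gene
that is transcriptionally silent cannot rescue a deletion *in vivo*. For
every reaction essential at the reaction level that carries an OR rule,
`deactivate_lowly_expressed_isoenzymes()` keeps the top-expressed gene and
marks partners expressed at least 5-fold lower (default) as inactive,
which converts such false-negative predictions into true essentials.

## TraDIS essentiality calling

Insertions within the first 5% or last 20% of a CDS, measured from the
translational start on the coding strand, are discarded: terminal
insertions often leave enough functional protein that essential-gene
mutants survive. The boundary convention is $f \in (0, 0.05]$ discarded,
$f \in (0.80, 1]$ discarded. The per-gene index is
$\log_2(\mathrm{IPKM_c} + 1)$, where IPKM normalizes insertions by CDS
length (kb) and library size (per million insertions); the library total
defaults to the uncurated count so curation can only lower a gene's index.

Thresholds are anchored on a trusted reference essential set: the 65th
percentile of its index distribution is the essential cut-off, the 75th
the non-essential one (linear-interpolation percentiles; at least 20
values are required, and identical values are rejected as degenerate).
Genes in between stay unclassified, and a caller-supplied exclusion list
handles low-coverage genes — no coverage model is fitted.

## Expression integration (iMAT)

Reaction expression follows the GPR recursively; reactions without a GPR
stay in the moderate category, neither rewarded nor penalized. For the
nitrogen-limited condition the absolute expression is multiplied by its
fold change against the growth condition (pseudocount 1 RPKM), an
up-weighting of reactions that are high in absolute terms and/or strongly
induced. The high category is the 95th expression percentile; the low
cut-off is the minimal expression among model-essential reactions after
discarding outliers below $Q_1 - 1.5\,\mathrm{IQR}$ — guaranteeing that
essential reactions are not penalized for moderate expression.

The iMAT MILP maximizes the count of high reactions with $|v| \ge
\varepsilon$ plus low reactions with $|v| < \varepsilon$, subject to
steady state, bounds, a growth-rate floor and nutrient caps. The activity
threshold $\varepsilon$ is not something the integration literature fixes;
the package default is 0.1 mmol gDCW$^{-1}$ h$^{-1}$ — small against
substrate-scale fluxes, large enough to be robust to solver tolerance.
Among equal-objective solutions any optimum is accepted: downstream
analysis uses flux sampling over the constrained polytope, never the
single MILP vertex. In the returned condition-specific model, suppressed
low reactions are clamped to $(-\varepsilon, \varepsilon)$.

Growth-rate constraints for the two phases come from curve fits:
a logistic model for the growth phase (returning the exponential rate
constant) and a straight line for the nitrogen-depleted phase (slope over
mean biomass as the specific rate), via `minpack.lm` nonlinear least
squares.

## Flux sampling and differential flux

Sampling is an artificial-centering hit-and-run chain over
$\{v : Nv = 0,\ lb \le v \le ub\}$: warmup points are the FVA vertices,
directions are drawn as (stored point $-$ running center) projected into
the null space of $N$, and the step is uniform over the feasible segment.
Each retained point therefore satisfies steady state to numerical
precision, which the tests assert directly. Function defaults are 10,000
samples at thinning 1000 — the conventional settings for production GSM
analyses; the tests and the pipeline default to hundreds of samples at
thinning 4–20, which the package's own convergence screen shows is
adequate for the toy-scale polytopes used there (these are the problem
sizes at which the whole suite was calibrated).

Two independent runs per model feed a per-reaction KS screen: reactions
whose two runs differ at $p < 0.05$ are unstable and excluded. Between
conditions, per-reaction KS $p$-values are BH-adjusted and combined with
the flux change $FC = (\bar S_{26} - \bar S_{16})/(\bar S_{26} + \bar
S_{16})$; calls require strictly $q < 0.05$ **and** $|FC| > 1/3$ (the
exact 2-fold point, conventionally printed as 0.33 — the strict inequality
means a reaction must change by more than 2-fold). With thousands of samples the KS test is hypersensitive,
so the FC magnitude filter is the effective effect-size gate — $q$ alone
should not be interpreted. When the two means cancel
($|\bar S_a + \bar S_b| < 10^{-9}$), the reaction is marked unstable
instead of reporting a diverging FC. Reactions present in only one
condition get a percentile bootstrap CI of the mean; zero outside the 95%
interval makes the call, with the sign of the mean giving the direction.

Regulatory classification compares flux direction with the reaction-level
expression log2 fold change: concordant beyond 1 log2 unit (a package
default; the classification literature names no universal threshold) is
transcriptional control, a flux change without an expression change is
post-translational, discordant signs are mixed.

## The synthetic benchmark and its limits

`generate_toy_model()` returns a fixed, hand-audited 26-reaction network —
seeds vary only the data layers, never the wiring, so recovery tests are
stable. It reproduces the motifs that matter for the analyses: a sugar
uptake feeding a catabolic lump that yields NADH and NADPH, pyruvate
dehydrogenase behind an isoenzyme pair, a TCA lump, acetate overflow, two
ETC branches with P/O ratios of 2 and 1 (so losing the efficient branch is
growth-limiting, not lethal), an ATP-coupled transhydrogenase, a
nitrogen-requiring biomass precursor behind a second isoenzyme pair with
one silent partner, and a PHB synthesis/secretion/degradation cycle whose
synthesis arm consumes NADPH while degradation regenerates NADH. All
species carry real elemental formulas, so the validation checks pass
exactly. Biomass composition (1.5 alanine-equivalents, 0.5 pyruvate,
30.166 mmol ATP GAM, 3 NADPH per gDCW) was set once so that ATP demand,
not carbon, limits wild-type growth — the property that makes the ETC and
TCA genes growth-limiting.

The planted nitrogen-limitation truth shifts the PHB synthesis/secretion
reactions up 4-fold and represses acetate overflow **and** the PHB
degradation arm (storage conditions favour net accumulation); that
repression is also what makes the condition-specific polytope genuinely
narrow, so the convergence screen flags far fewer reactions than on the
unconstrained model.

The expression generator draws log-normal baselines (meanlog $\log 200$,
sdlog 1, observation sigma 0.25) and applies the planted folds; silent
isoenzymes sit 10-fold under their partner, comfortably past the 5-fold
deactivation rule. The insertion generator places unique insertion sites
Bernoulli-per-bp at 0.2/bp in non-essential genes (giving the several
hundred insertions per gene typical of a >10^6-mutant library), 1% of
that in strictly essential genes (cross-feeding survivors), and 5% in the
reference anchor genes. The anchor set stands in for a homolog-mapped
essential reference: it is modelled as essential genes whose mutants die
slowly and therefore retain clearly more insertions than strictly lethal
genes. This separation is what lets percentile thresholds drawn from the
anchors sit above the strictly lethal genes' indexes; had the reference
been statistically identical to the scored set, a 65th-percentile
threshold could never recover more than ~65–75% of it. Gene lengths are
drawn in 600–1400 bp (mean ~1 kb) — besides realism, length variation
keeps the index distribution continuous so the two percentiles cannot
collapse onto one tied value.

What the benchmark does **not** emulate: genome composition and sequence
context (no insertion-site bias), read-level noise (unique insertion
sites, not read counts), operon structure and polar effects, regulatory
feedback on expression, and the scale of a real GSM (a thousand-fold
larger LP). Passing the recovery tests therefore demonstrates the
correctness of the statistical machinery and its wiring, not performance
on real sequencing data.

## Degenerate inputs and tie-breaks

Infeasible or unbounded LPs propagate as statuses, never silently; the
energy-cycle check reports an infeasible closed model as flux 0 with a
status flag. A zero-volume sampling polytope (all fluxes fixed) is an
error. Percentile thresholds with `lower >= upper` are rejected. Genes
missing from an expression profile count as zero with a warning; genes
unclassified on either side of an essentiality comparison are dropped
from the confusion counts. The interface to all of this is the R
function surface plus `run_pipeline()`; the shell wrapper under
`inst/scripts/` only parses flags, so scripted and interactive use cannot
diverge.

## Known limitations

The simplex core is dense and Bland-ruled: correct and adequate at toy
scale, but not suitable for genome-scale models with thousands of
reactions. SBML import is out of scope (the JSON schema is the exchange
format). Thermodynamic loop-law filtering is not applied to samples, and
the regulatory classification is a two-threshold heuristic, not a fitted
model.
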