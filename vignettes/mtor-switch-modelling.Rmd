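---
title: "Dynamic modelling of mTORC1/2 coordination by the MLST8 ubiquitination switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic modelling of mTORC1/2 coordination by the MLST8 ubiquitination switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtorswitch)
```

## The model

mTOR is the catalytic subunit of two complexes with distinct substrates:
mTORC1 (with raptor) phosphorylates S6K1, and mTORC2 (with SIN1)
phosphorylates AKT at S473. The subunit MLST8 is shared by both, and its
K63 ubiquitination state decides which complex it can join: the E3 ligase
TRAF2 ubiquitinates MLST8 on the surface that SIN1 would bind, steering it
toward raptor and mTORC1 assembly, while the insulin-activated
deubiquitinase OTUD7B reverses the modification and frees MLST8 for SIN1
binding and mTORC2 assembly. `mtorswitch` encodes this switch inside an
ordinary-differential-equation model of the insulin/PI3K/AKT/mTOR network,
together with the canonical feedback structure: the S6K1 → IRS1/2 negative
feedback (phosphorylation of the inhibitory S636/639 sites, with slow
recovery), the mTORC1 → INSR negative feedback (lumping the Grb10 route),
and the AKT → SIN1-T86 positive feedback that enhances mTORC2 activity.

Kinetic conventions follow standard practice for signalling models:
protein–protein association/dissociation by mass action, enzyme-catalyzed
(de)phosphorylation and (de)ubiquitination by Michaelis–Menten kinetics,
reversals first order, no Hill coefficients. TSC2's repression of mTORC1
is an inhibitory factor $1/(1 + [\mathrm{TSC2a}]/k_{i1})$ on the mTORC1
activation rate. The upstream IRS1/2 → PI3K → PIP3 → PDK1 → pAKT T308
cascade is lumped into a single catalytic step, so PI3K, PIP3 and PDK1 are
not explicit species; DEPTOR, PRAS40 and Grb10 are likewise absorbed into
effective rates. Units are nM and minutes throughout; insulin enters as a
100 nM step held constant after mandatory pre-equilibration at insulin 0
(a serum-starved basal state).

## The variant family

Two structural questions are left open by the biology and encoded as model
variants:

* is OTUD7B activated at the receptor (INSR) or downstream of IRS1/2 —
  i.e. under one negative feedback loop or two?
* is MLST8 required for mTORC1 assembly and activity, or is mTORC1 a
  plain raptor pool?

`build_network()` constructs the four combinations (variants 1–4; variant
4 = IRS-wired OTUD7B + MLST8-gated mTORC1) plus variant `"4P"`, which
replaces the AKT → mTORC2 positive feedback by activation through pIRS
(a PIP3-proxy wiring). In the gated variants mTORC1 pools are
raptor–MLST8ub complexes (association constant `k_f5`); in variants 1–2
ubiquitinated MLST8 acts purely as a SIN1-sequestration sink, which makes
"MLST8 is not required for mTORC1" literal. All variants share one
24-species state vector and conserve ten moieties (INSR, IRS, OTUD7B,
MLST8, SIN1, raptor, AKT, TSC2, S6K1 and the constant catalyst TRAF2);
conservation along any trajectory is enforced structurally and verified to
1e-6 relative in the tests.

## Parameters, totals and the reference set

Protein totals default to order 10–120 nM with the mean over the ten model
proteins fixed at exactly 100 nM — the same anchor the nanomolar
conversion of the proteomics pipeline preserves, so a cohort cell line
with average expression reproduces the base model. TRAF2 is deliberately
low (10 nM), acting as a catalytic E3 pool.

The curated nominal kinetics (`default_parameters()`) were chosen so the
stimulated network operates in the regime the blot-style data suggest:
receptor and IRS phosphorylation saturating within minutes, pS6K1 induced
about an order of magnitude over basal with a 20–40 min overshoot driven
by the negative feedback, and the deubiquitinated-MLST8 curve showing the
strong overshoot characteristic of the IRS-wired variants. Two choices
matter for the emergent biphasic behaviour and deserve explanation:

* TSC2 phosphorylation is dominated by doubly phosphorylated AKT
  (`k_f12b` ≫ `k_f12a`), with pAKT T308 alone a weak TSC2 kinase. Since
  ppAKT requires mTORC2, this places the "activity per mTORC1 molecule"
  arm under SIN1 control, while the T308-only route provides the small
  SIN1-independent basal drive seen in SIN1-null cells.
* raptor–MLST8ub binding is moderately avid (Kd a few nM), so mTORC1
  abundance is partially buffered against loss of ubiquitinated MLST8 —
  enough that TRAF2 knockdown trades abundance against per-molecule
  activity rather than collapsing pS6K1.

The shipped per-variant reference parameterizations
(`reference_parameters()`, `inst/extdata/`) are produced by
`make_reference_parameters()`: a log-uniform draw within 0.1 decades of
the nominal set, rejected and redrawn until a qualitative screen passes
(the insulin step induces pAKT S473 and pS6K1; deubiquitinated MLST8
overshoots, required only of the IRS-wired variants that can show it; the
model-4 SIN1 → pS6K1 scan is biphasic; the SIN1 → pAKT S473 scan is
monotone increasing). The JSON provenance sidecars record the generating
seed (929) and the screen outcome. We prefer this screened sampler over
shipping a GA fit because a trajectory fit does not guarantee the
qualitative behaviours that downstream analyses (knockout discrimination,
sensitivity ranking, cohort scans) presuppose, whereas the screen enforces
them by construction; all five variants share one draw so cross-variant
comparisons are not confounded by kinetic differences.

## Simulation and steady states

Integration uses `deSolve::lsoda` on a C implementation of the right-hand
side (relative tolerance 1e-8, absolute 1e-10), with a pure-R
reaction-list evaluator kept as the independent oracle. Pathologically
stiff corners of parameter space (1000-fold perturbations in scans) fall
back to looser tolerances and then to `radau`; a scan point that still
fails is flagged invalid rather than aborting the scan. Steady states
relax the system in growing time chunks (budget 1e5 min) until
`max |dx/dt| < 1e-9` nM/min, then apply one damped-Newton refinement using
a minimum-norm pseudo-inverse step, which respects the singular conserved
directions of the Jacobian. Dose–response scans warm-start each fold from
its neighbour's steady state (continuation), with moieties rescaled to the
perturbed totals. Halving the tolerances moves steady-state observables by
less than 1e-4 relative (tested). The tolerances and the steady-state
criterion are package choices, not literature values.

## Calibration

The objective is the unweighted (weights default 1, configurable per
dataset) sum of squared residuals between data and simulation, with
simulated observables peak-normalized per condition before comparison —
mirroring how quantified blots are processed. Free scaling factors per
observable are deliberately not used. Optimization is a real-coded genetic
algorithm in log10 parameter space: Latin-hypercube initialization within
log-uniform bounds (default 1e-3 to 1e3 fold of nominal), tournament
selection, blend crossover, Gaussian mutation (0.15 decades), elitism;
deterministic under its seed. Desk scale (population 40, 100 generations,
5 independent starts, fitting the 12 switch-proximal constants) is the
default and what the tests run; the full protocol (population 200, 800
generations, 500 starts, all constants free) is available via
`ga_config(scale = "paper")`.

Ensemble selection uses an objective cut-off plus automated feature checks
standing in for visual inspection of fit quality: the
deubiquitinated-MLST8 curve must overshoot (max > 1.2 × final) and pS6K1
must rise after pAKT S473. Both are configurable and logged per fit. The
cut-off is a user input — the model family is non-identifiable, so
calibration is assessed by trajectory recovery (pS6K1 RMSE on normalized
curves), not parameter recovery; accepted ensembles are summarized by
pointwise mean ± sd envelopes and by average-linkage hierarchical
clustering of the log10 parameter vectors.

## The biphasic index

A dose–response curve is peak-normalized and summarized by
$BI = \hat y(\text{first fold}) - \hat y(\text{last fold})$. This
reproduces every stated property of the index: −1 for a curve rising from
0 to a terminal peak, +1 for a curve falling from an initial peak to 0,
interior values for biphasic shapes (more pronounced nearer 0), and
$|BI| \le 1$ for any non-negative normalized curve. Curves are classified
with margin ε = 0.05: increasing (BI ≤ −0.95), decreasing (BI ≥ 0.95),
biphasic otherwise; a curve whose peak sits at an endpoint but which
wiggles internally is classified by its BI alone. The index is invariant
under positive rescaling of the raw curve. Sensitivity ranking sweeps each
kinetic parameter or protein total over 0.001–1000-fold of nominal,
recomputes the SIN1 → pS6K1 BI at each setting, and scores the item by the
BI range (max − min; variance is a available alternative); the default
grids are 61-point scans and 21-point sweeps, reduced to 31/9 in the test
suite where only the ordering is asserted.

The mechanism behind the biphasic SIN1 dependence is a competition for
MLST8: raising SIN1 sequesters MLST8 into mTORC2, increasing AKT S473/
ppAKT phosphorylation and hence the activity of each mTORC1 molecule
(through TSC2 inactivation), while simultaneously draining ubiquitinated
MLST8 and reducing mTORC1 abundance. `mtorc1_total_activity()` exposes
exactly this decomposition — total activity = abundance × per-molecule
potential, the potential normalized to 1 at a nominal state.

## Synthetic data

`simulate_blot_data()` emulates quantified Western-blot time courses:
6 observables (pooled phospho-forms, e.g. pAKT S473 + ppAKT), 8 time
points over 0–120 min, conditions WT / TRAF2 knockdown (fold 0.1, the
90%-silencing convention) / SIN1 null (set to 0), multiplicative
log-normal noise (sd 0.1 on the log scale — densitometry is positive and
right-skewed), peak normalization per curve. Observable–condition pairs
whose true signal never exceeds 1 pM (pAKT S473 without SIN1) are skipped
and recorded. What it does not emulate: blot saturation and background,
replicate-to-replicate gel variability, unequal time grids across
observables, and total-protein normalization error — so passing recovery
tests demonstrate correctness of the pipeline on well-behaved positive
multiplicative noise, not robustness to real blot artefacts.

`make_proteomics_tables()` generates a cohort: ground-truth absolute
abundances log-normal around the base expression profile (sd 0.3 on the
natural-log scale, a realistic ~30% cell-to-cell coefficient of
variation), a relative table obtained by per-protein proportionality
constants, reference (iBAQ-like) tables as the truth restricted to
reference lines, and optional missingness (recorded, never imputed;
reference lines stay complete). The proportionality constants are
per-protein because the anchored inference
$\mathrm{IBAQ}(i,j)\cdot\mathrm{REL}(i,x)/\mathrm{REL}(i,j)$ cancels
exactly per-protein scalings — the property that makes relative tables
usable at all; a per-line scaling would bias every inference by the ratio
of line constants. The nanomolar conversion then rescales each line so
the model-protein mean is 100 nM; whether the real normalization averaged
over a larger protein set is unknowable from the printed formula, so the
formula is implemented as printed, over the model proteins the pipeline
possesses.

## Desk-scale study sizes

The test-suite and acceptance studies use: 31-point dose–response grids
for screening and cohort scans (61 points for the headline model-4 scan),
9-point sweeps in the ranking study, a 25-line synthetic cohort, and the
desk-scale GA above. These sizes were chosen so the full synthetic study
— generation, calibration, response analysis — composes into an offline
end-to-end run well under 15 minutes on one CPU while leaving every
qualitative conclusion unchanged at the full grids.

## Known limitations

* The reaction scheme is an abstraction: TRAF2 is a constant catalytic
  pool with no basal turnover, only active (T86-enhanced) mTORC2
  phosphorylates AKT S473 (with a small basal, insulin-independent
  mTORC2 activation rate so S473 signal can seed the positive feedback),
  and complexes dissociate only from their inactive forms.
* The provisional homes of `k_f11b` (mTORC1a → S6K1 catalytic constant)
  and `k_i1` (TSC2a inhibition constant) are package decisions; the
  sensitivity analysis confirms both rank below the MLST8-switch
  constants, but their mechanistic identity should not be over-read.
* Events beyond the single insulin step (dose ramps, pulses, delays),
  spatial effects and stochasticity are out of scope, as are SBML
  interchange and survival analyses on patient cohorts.
* Real CCLE/iBAQ ingestion is supported only as plain CSV exports with
  user-supplied identifier mapping; no identifier harmonization is
  attempted.
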