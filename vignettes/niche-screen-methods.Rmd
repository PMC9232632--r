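---
title: "Methods: multiparametric readout of niche-like AML drug screens"
author: "nicheDSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric readout of niche-like AML drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheDSS)
```

## The assay and its readout model

Primary AML mononuclear cells are co-cultured with GFP-tagged mesenchymal
stromal cells (MSCs) under hypoxia, exposed to drugs in 96-well plates
(50,000 cells seeded per well; DMSO 0.1% wells are the negative controls),
and acquired on a flow cytometer with a six-role panel: a viability stain
that labels dead cells, GFP marking the stromal feeder layer, CD45, GPR56,
a pooled differentiation dump channel (CD11b/CD14/CD15) and a pooled
lymphocyte dump channel (CD3/CD19). The readout is a count vector per well:
viable lymphocytes, the viable leukemic bulk, and within the bulk the
GPR56+/Diff− LSC-enriched state, the GPR56−/Diff+ differentiating state
(DIFF), the GPR56−/Diff− basal state, and GPR56+/Diff+ double positives.
LSC is a *strict* quadrant: double positives sit inside the bulk but count
toward neither LSC nor DIFF.

Everything downstream is built on those counts: counts are normalized to
the same-sample vehicle mean, dose-response profiles of normalized counts
are summarized by the untruncated trapezoidal area over the curve (AOC),
fixed-dose screens are classified into response patterns, and
lymphocyte-referenced calls and combination-benefit tests turn activities
into decisions.

## Automated gating

The original assay gates manually; a testable pipeline needs a
deterministic, automated substitute. Per channel, `estimateThresholds()`
fits a two-component one-dimensional Gaussian mixture to pooled vehicle-well
log10 intensities by EM, with a *fixed* initialization (component means at
the 25th/75th percentiles, equal weights, common SD of half the pooled SD),
so the result is a pure function of the data. The cutoff is the
equal-posterior point between the two component means, obtained in closed
form from the posterior-equality quadratic; if no root lies between the
means the midpoint of the component means (their medians, for Gaussians) is
used. The viability channel is fit on all pooled events; all other channels
on viable events only, mirroring the gate hierarchy. A channel whose fitted
components are separated by less than twice the sum of the component SDs is
declared unresolved — this is what a single-component channel (e.g. GFP on
a plate without stroma) looks like — and requires a manual override.
Overrides always win and are flagged `configured` in the JSON audit trail.

Hierarchy and conventions, applied in fixed order by `gateWell()`:
events **above** the viability cutoff are dead (the stain labels dead
cells); viable GFP+ events are excluded as MSCs; the remainder splits into
lymphocytes (dump channel positive) versus bulk; bulk is assigned by the
GPR56 × Diff quadrants. Every viable GFP− event lands in exactly one
terminal population, so the partition identities
`bulk = lsc + diff + basal + dp` and `lymph + bulk = viable − msc` hold by
construction for arbitrary input. CD45 is carried in the panel but is not a
decision node by default (synthetic plates have no debris); an optional
CD45+ gate before the lymphocyte split is exposed for real data.

## Normalization and activity scoring

Counts in each gate are divided by the arithmetic mean (configurable to
median) of the same-sample vehicle wells. Within-bulk proportions
(`prop_lsc`, `prop_diff`) are reported raw, not vehicle-normalized: the
pattern module applies its own scaling, and raw proportions keep the
heatmap readouts interpretable as compositional fractions. Replicate wells
stay separate until `summarizeReplicates()` (mean ± SD; single wells are
flagged with SD 0).

Drug activity is the **untruncated trapezoidal AOC**: with doses mapped to
log10 and affinely rescaled to [0, 1] and v(x) the normalized count curve,
AOC = ∫(1 − v) dx under the piecewise-linear interpolant. Deliberately, no
parametric dose-response model is fitted, no value is clipped, and negative
AOCs (outgrowth above vehicle) are legal outputs. Unit rescaling of the
log-dose axis makes AOCs comparable across drugs with different dose
ranges and bounds AOC in [0, 1] whenever v is; the unscaled log10 width is
available via `rescale = FALSE` for sensitivity analyses. Replicates are
averaged *before* the AOC (mean per dose), the default of `aocByGroup()`;
AOC-then-average is available by calling `computeAOC()` per replicate.

Screening concentrations follow the clinical bounding rules: the maximal
testing concentration is min(Cmax, IC₄₀ on healthy CD34+ cells) and the
fixed low dose for third agents is min(0.2·Cmax, IC₁₀), with ICₓ obtained
by linear interpolation of v against log10 concentration between the first
bracketing dose pair; an unbracketed level is an error naming the level,
never an extrapolation. Fixed-ratio combination series (e.g. a 1:20
daunorubicin–cytarabine backbone over a 5-point, 10-fold dilution) preserve
the ratio exactly at every dilution point.

## Response patterns

For fixed-dose screens the three readouts per drug (residual bulk, %LSC,
%DIFF) are standardized per column after sign flips so that larger always
means more active (fewer bulk cells, lower LSC proportion, higher DIFF
proportion); constant columns map to zeros with a warning. Drugs are
clustered by Ward/Euclidean agglomerative clustering cut at k = 3 — the
linkage, metric and k are not dictated by the assay, so all three are
configurable — and each cluster is labelled by the argmax coordinate of its
centroid (bulk → cytotoxic, lsc → stemness-specific, diff →
differentiating). Exact centroid ties break in the fixed priority
bulk > lsc > diff; when two clusters contest a label, the larger centroid
coordinate wins and the loser takes its next-best free coordinate. Rows are
canonicalized to sorted drug-id order before clustering, so labels are
invariant to input row order. For a single drug, where clustering is
undefined, `classifyPattern()` applies the argmax rule directly with an
`inactive` call when all |scaled| values sit below a threshold (default
0.5 column SDs).

## Decision statistics

*Chemosensitivity calls* use the patient's own lymphocytes as an internal
reference: sensitive ⇔ AOC(population) > AOC(lymphocytes), with ties
resistant. The call is invariant to adding a constant to both activities.

*Combination benefit* is the per-patient delta between a triplet's AOC on
the LSC count and the backbone's, tested per third agent by a one-sample
two-sided t test of the deltas against zero (identical to a paired
two-sample formulation) with Benjamini–Hochberg correction across agents.
Agents with fewer than three paired patients are reported without p/q;
zero-variance deltas are flagged degenerate rather than tested. Per-patient
nomination is the argmax delta, `"no benefit"` when no delta is positive,
with exact ties going to the lexicographically smallest agent id and
flagged.

The 2×2 exact test and the rank-sum test are implemented as explicit
kernels with pinned conventions, because the screen's headline calls rest
on them: `fisherExact2x2()` sums hypergeometric probabilities of all
fixed-margin tables no more probable than the observed one (relative
tolerance 1e−7 on the comparison, guarding against floating-point
near-ties); `mannWhitney()` enumerates the exact U distribution whenever
min(n) ≤ 8 without ties and otherwise uses the tie-corrected normal
approximation with continuity correction, recording which path was taken.
`bhFDR()` is the BH step-up with monotonicity enforcement. The test suite
cross-checks all three against `fisher.test`, `wilcox.test` and `p.adjust`
and against brute-force enumeration. The chemogenomic scan applies the
rank-sum kernel per (agent, readout, gene) with BH across the whole scan,
skipping (and listing) pairs with fewer than three patients per genotype.

## The synthetic generator

`GroundTruth()` fixes the study conditions the generator emulates: 50,000
cells seeded per well partitioned into stroma (5%), lymphocytes (10%), LSC
(8%), DIFF (12%) and basal (55%), the remaining 10% dead at baseline;
technical replicate noise as a per-well multiplicative log-normal seeding
factor with CV 10% (matching technical-triplicate variability); per-drug
Hill survival models (max-kill E, EC50, slope h) per population; and an
optional differentiation-induction model that moves basal/LSC cells into
the Diff+ state *before* survival is applied, transitioning LSCs retaining
GPR56 (becoming double positive) with a retention probability of 0 by
default, so LSC remains a strict GPR56+/Diff− state. The composition
fractions are not reported per well by the assay; the defaults are typical
of a blast-rich AML aspirate co-culture and are fixed once here.

Intensities are simulated post-compensation on the log10 scale as
two-component Gaussians per channel; no spillover, doublets or time drift
are modelled — gating operates on compensated data, so these add no test
value. Dead events carry a high viability-stain signal and negative signal
elsewhere. The panel's `separation` parameter is defined as the distance
from each component mean to the midpoint gate boundary in SD units (so
`separation = 4` puts 8 SDs between the means and single-channel error near
`pnorm(-4)`); this is the quantity that controls gating recovery. Acquired
events per well are a binomial `acquiredFraction` subsample, exposed as a
parameter because acquisition depth is instrument- and run-dependent; the
expectation identities are unaffected.

All randomness flows from one integer seed: `simulatePlate()` seeds a
single stream and draws one sub-seed per well, so a plate is exactly
reproducible and wells are independently perturbed. Every simulated event
keeps its generating label in a `.truth` column (ignored by gating), and
`expectedCounts()` gives the closed-form expectation
`seeding × fraction × Π(1 − E·cʰ/(cʰ + EC50ʰ))` (after transitions) that
recovery tests compare against.

What passing tests show — and what they do not: recovery results certify
the pipeline's correctness on data matching the generator's assumptions
(log-Gaussian channels, independent events, no spectral artefacts). Real
plates add debris, doublets, autofluorescence shifts and inter-patient
marker variability; the override mechanism and the audit trail exist
precisely because automated thresholds should be reviewed on real data.

## Numerical choices and problem sizes

Degenerate inputs are contracts, not accidents: empty event tables gate to
all-zero counts; a missing vehicle well is a hard error while a zero
vehicle mean disables only the affected readout; AOC requires ≥ 2 strictly
increasing positive doses; unbracketed ICₓ levels error by name. EM runs to
a relative log-likelihood tolerance of 1e−10 (max 500 iterations) with
component SDs floored at 1e−6.

The validation suites run at fixed sizes chosen to make the statistical
assertions sharp while keeping the default test run light: 50 wells (~5,000
events each) for gating recovery; 100 simulated fixed-dose screens of 15
drugs (5 per archetype, near-saturating effects, ~2,000 events per well via
`acquiredFraction = 0.04`) for pattern recovery; 100 screens of 20 patients
× 23 agents (one agent with +0.3 AOC benefit, noise SD 0.1) plus 100
sign-flip permutation nulls for benefit ranking; 1,000 random profiles
against a 10⁵-point Riemann refinement for the AOC; and full enumeration of
every 2×2 table with N ≤ 60 for the exact-test kernel.

## Known limitations

No plate-position (edge) effect correction; no doublet discrimination,
compensation or 2D polygon gating; no parametric dose-response fitting (by
design — the activity score is the model-free AOC); survival and
mixed-effects modelling of clinical endpoints are out of scope, with
clinical covariates handled only as pass-through tables. The generator's
drug effects compose multiplicatively across agents (Bliss-like
independence) and carry no pharmacological interaction terms, so synergy
estimation is not a supported use.
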