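---
title: "algaeGEM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{algaeGEM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algaeGEM)
```

## Scope

algaeGEM turns an uncompartmentalized draft metabolic network of a green
alga into a functional genome-scale model and analyzes its flux phenotypes.
The pipeline stages are: consensus protein localization and reaction voting;
mixed-integer compartmentalization; elimination of thermodynamically
infeasible cycles (TICs); condition-specific biomass construction and media
attachment; MILP gap-filling; GECKO-style enzyme constraints; and the
downstream flux analyses (FBA, pFBA, FVA, active-reaction calling,
essentiality, growth-correlation screening, hit-and-run flux sampling and
homolog flux comparison). Draft reconstruction from genome annotation,
running the localization predictors, and kcat prediction are out of scope:
their outputs are inputs here.

All optimization problems are assembled in R as explicit matrices and
solved with HiGHS (reached through `scipy.optimize` via reticulate). The
formulations themselves — the compartmentalization MILP, the TIC hitting-set
MILP, gap-filling, and the LP analyses — live in this package.

## Data model

`MetabolicModel` is an S4 container holding metabolite and reaction tables
in registration with a sparse stoichiometric matrix (metabolites x
reactions). Flux bounds are in mmol g⁻¹ DW h⁻¹. Exchange reactions follow
the COBRA convention "met ↔ ∅" with **uptake as negative flux**: a published
"lower bound of 10" for a nutrient uptake is interpreted as uptake capacity
10, i.e. `lb = -10`. Gene–protein–reaction (GPR) rules are boolean
and/or expressions over gene ids; evaluation under knockouts and gene-set
extraction are deterministic (`parseGPR`, `evalGPR`, `gprGenes`).

Two file dialects are supported: an SBML Level 3 + FBC v2 subset (species,
compartments, flux-bound parameters, gene-product associations, the active
objective; subsystem/kind/molecular weight travel in notes) and a compact
JSON dialect for fixtures. Both round-trip field by field; no installed R
package binds libSBML, so the SBML subset is written directly on xml2 and
deliberately covers only what the pipeline reads back.

## Growth conditions

Four standard conditions mirror the experimental setups for fast-growing
desert algae: photoautotrophic low light (`auto_100`), photoautotrophic
high light (`auto_3k`), mixotrophic (`mixo`) and heterotrophic (`hetero`).
Each sets the eight nutrient uptakes (H2O, H+, Pi, NH4, SO4, Fe²⁺, Mg²⁺,
O2) to capacity 10 mmol g⁻¹ DW h⁻¹; the photon exchange to 100, 100, 3000
and 0 respectively; acetate uptake to 2 mmol g⁻¹ DW h⁻¹ under `mixo` and
`hetero` (0 otherwise); and CO2 uptake open except heterotrophically. The
printed light intensity (μmol photons m⁻² s⁻¹) is applied directly as the
photon-uptake bound magnitude: no defensible unit conversion to a flux is
published for these cultures, so the number is passed through, which
preserves the ordering and ratios between conditions that the analyses rely
on. Each condition selects its own biomass reaction
(`biomass_auto_100`, ..., `biomass_hetero`), so all four coexist in one
consensus model.

## Localization consensus and voting

Per-tool localization predictions (protein x compartment probabilities from
up to five tools) are renormalized per tool, averaged with equal weights,
and renormalized again — the simplest order-independent crowd estimator; no
tool-reliability weighting is applied because no calibration data ships with
the predictions. A reaction's vote for compartment c is the mean consensus
probability of c over its GPR genes (normalization by gene count, regardless
of and/or structure). A reaction is retained in every compartment taking
**strictly more than 25%** of its vote; "above" is read as a strict
inequality, with lexicographic tie-breaks for reproducibility. If nothing
clears the threshold the top-voted compartment wins; reactions without a
GPR default to the cytoplasm (transporters typically lack gene support);
curated pathway–compartment constraints can be pinned via `fixed`.

## Compartmentalization MILP

`replicateByAssignment` instantiates each reaction once per assigned
compartment over compartment-specific metabolite pools (exchanges attach to
the extracellular pool), `enumerateTransportCandidates` adds a reversible
1:1 carrier for every unordered compartment pair sharing a metabolite
(`choose(k, 2)` per metabolite in k compartments), and `pruneMinimal`
solves: minimize the number of retained replicated instances and transports
subject to steady state, big-M flux/indicator coupling, simultaneous
production of all designated precursors at `eps = 1e-3` mmol g⁻¹ DW h⁻¹,
at least one retained instance per parent reaction, and any fixed-keep
constraints. Design choices worth calling out:

* **eps and big-M.** `eps = 1e-3`, `M = 1000` (both exposed). M exceeds any
  flux reachable under uptake capacities of 10; the solver's integrality
  and feasibility tolerances are pinned at 1e-9 because eps/M = 1e-6 sits
  exactly at HiGHS's default integrality tolerance, where a fractional
  indicator can masquerade as an integral zero.
* **Joint precursor feasibility.** All precursor demands must be satisfied
  simultaneously (one LP block), with a per-precursor mode behind a flag.
* **Parent coverage.** Every parent reaction keeps at least one instance:
  the MILP decides *where* content lives, not *whether* it exists; a switch
  (`requireParentCoverage = FALSE`) drops this if a leaner reading is
  preferred.
* **Equal weights and tie-breaks.** Instances and transports count equally;
  alternate optima are broken towards the lexicographically smallest
  retained-id set by a secondary weight of 1e-6 per rank, far below the
  unit objective step.

The worked two-reaction toy (`makeTwoReactionToy`) encodes R1: a → b + d and
R2: b → c + f over five shared metabolites and three compartments, with a
natively supplied in C1/C2 and b in C3 and precursor demands {c,d,f}@C1,
{b,d}@C2, {c,f}@C3. Hand enumeration over all instance subsets shows the
unique optimum retains R1@{C1,C2} and R2@{C1,C3} (4 reactions, 0
transports) — every alternative costs at least 5 — so the MILP must remove
exactly R1@C3 and R2@C2 and prune all fifteen candidate transports, which
is what the acceptance suite asserts.

## TIC elimination

A TIC is an internal loop able to carry flux with every boundary reaction
closed. Identification closes exchanges and demands, caps internal fluxes
at ±1 (any circulation scales, so unit caps lose nothing) and sweeps
per-direction LPs, short-circuiting directions already seen carrying flux.
Removal splits reversible reactions into direction pairs and runs a lazy
hitting-set MILP: an inner LP searches for a surviving circulation and its
support becomes a covering cut; the master MILP minimizes removed
directions subject to all cuts plus an embedded flux block that forces
biomass ≥ eps to survive. Because there are finitely many supports the loop
terminates, and the final set is minimum-cardinality — verified against
exhaustive enumeration on all planted instances. Removing one direction of
a reversible reaction converts it to irreversible rather than deleting it
(a whole-reaction switch exists); this is why de-looped models show far
fewer reversible reactions than their templates. When per-condition
solutions disagree, the consensus keeps the union of retained directions
with per-condition bound masks — an explicit assumption, as no merge rule
is published.

## Biomass and media

Class mass fractions (protein, DNA, RNA, carbohydrate, chlorophyll, lipid;
g g⁻¹ DW) are rescaled to sum to exactly 1. Polymer classes expand into
monomer coefficients from genome-derived molar fractions — amino-acid
frequencies over the proteome; dNTPs from double-stranded base counts
(dATP = dTTP, dGTP = dCTP); NTPs from the coding strand with T read as U —
using residue weights (monomer MW − 18.02 g mol⁻¹ of polymerization water,
released stoichiometrically); explicit precursors (starch units, sugars,
chlorophylls, a lipid pool mapped from a curated reference model) use full
molecular weights. The resulting coefficients satisfy
Σ coeff × MW = 1000 mg g⁻¹ DW by construction, which makes growth rates
comparable across models; the mass-closure identity is asserted to 0.1% in
the tests. Growth-associated ATP maintenance defaults to 0 (no published
value) and is configurable. `attachMedia` guarantees exactly eleven media
exchanges, idempotently.

## Gap-filling and enzyme constraints

Gap-filling merges a universal candidate pool (ids disjoint from the
model), couples each candidate's flux to a binary by big-M and minimizes
(optionally weighted) additions subject to biomass ≥ eps; infeasibility is
reported per biomass precursor via demand probes. Enzyme constraints follow
the GECKO formulation: each constrained reaction consumes its enzyme
pseudo-metabolite at 1/(3600·kcat) per flux unit (kcat input in s⁻¹);
enzymes draw from a common protein pool at their molecular weight in kDa
(= g mmol⁻¹); the pool exchange is capped at the measured total protein
content P (g g⁻¹ DW). Saturation and mass-fraction factors are collapsed
into P, since a single measured content is the published interface. Isozyme
alternatives (top-level OR) become parallel reaction copies; complex
subunits (AND) are each consumed at flux/kcat, with the pair-specific kcat
applied per subunit and un-parameterized subunits left unconstrained. A
single-reaction model then has the closed-form optimum 3600·kcat·P/MW,
asserted to 1e-9 relative in the acceptance suite.

## Flux analyses

FBA, pFBA (total |v| minimized at fixed growth via an auxiliary-variable
LP) and FVA are standard. Active-reaction calling works on the split model:
a direction is active when its feasible maximum exceeds 1e-6, and split
pairs whose forward and backward maxima agree within 1e-6 relative are
excluded as cycle artifacts (the published exclusion rule; the tolerance is
ours, as none is printed). Essentiality knocks out genes through GPR
evaluation or closes single reactions, with essential defined as growth
below 1% of wild type (exposed flag; the source states only "impact on
growth"). Growth-correlation screening fixes growth at k/100 of the optimum
(k = 1..100), computes pFBA distributions, and selects reactions whose
absolute flux has Pearson r > 0.8 with growth and an adjusted p < 0.01
(t transform, n − 2 df); absolute fluxes make scaling uptakes, which are
negative, count as positively associated. Benjamini–Hochberg is the default
correction with a Bonferroni switch — the named correction elsewhere in the
workflow is Bonferroni, but the screening step does not name one. pFBA
admits alternate optima, so tests assert objective-level quantities except
on toys with unique solutions.

## Flux sampling

`sampleFluxes` implements artificial-centering hit-and-run in the affine
hull of the FVA warmup vertices (which is the null space of S, so no
projection is needed); the line search only touches the box bounds, the
center is updated with every iterate, and every `thinning`-th state is kept
(defaults n = 5000, thinning = 1000). The chain core is compiled (Rcpp) and
consumes R's RNG, so a fixed seed yields a bit-identical sample matrix. The
default samples the full feasible polytope under the condition bounds; a
fraction-of-optimum growth floor is available, since the published chains
do not state one. Homolog comparison applies Welch's t-test per reaction
pair with Bonferroni adjustment over pairs; the high-vs-low-light contrast
is the same operation with identity pairing across two conditions.

## What the synthetic generators emulate — and what they do not

The generators produce localization profiles with planted truth
(per tool: (1−η)·e_true + η·w with w uniform on the simplex, so the truth
holds ≥ 1−η mass and the seed is meaningful), pathway backbones with
planted internal cycles and gaps with matching pool entries, and small
replication instances whose optima are exhaustively checkable. They are
deliberately small and clean: real draft networks have correlated
localization errors across tools, thousands of reactions, mass-unbalanced
legacy reactions and many overlapping cycles. Green tests therefore certify
the algorithms (optimality, soundness, recovery under the stated noise
model), not performance on any particular organism's data.

## Problem sizes and numerics

The test and acceptance runs use 50 random compartmentalization toys
(≤ ~12 removable elements, verified against exhaustive enumeration), 50
planted-TIC models, 50-protein localization panels, and 5000-sample chains
at thinning 1000 — sizes chosen so every oracle is exact and the whole
suite re-runs in minutes on one core. LP optima are read at 1e-6 tolerance
(1e-9 for solver feasibility); big-M is 1000 throughout; degenerate inputs
(empty models, zero-variance flux series, unlocalized proteins, flat votes)
take documented fallbacks rather than erroring where a neutral answer
exists.

## Known limitations

* The SBML subset ignores groups, annotations and units beyond what the
  pipeline round-trips.
* Transport candidates are uncharged 1:1 carriers; proton/charge-balanced
  transport stoichiometries are out of scope.
* The light bound is a numeric passthrough of the printed intensity; revisit
  if a flux conversion for the cultures becomes available.
* Compartmentalization quality is bounded by the localization predictions;
  the `fixed` mechanism exists precisely because prediction errors propagate.
* Published whole-model benchmark numbers require the authors' model files,
  which are not redistributed here; `reproduceBenchmark()` reruns the full
  analysis once a local copy is supplied.
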