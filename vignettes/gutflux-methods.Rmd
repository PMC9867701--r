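---
title: "Methods: models, statistics and design choices in gutflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in gutflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

gutflux implements a complete analysis chain for paired (before/after)
intervention studies of the gut microbiome: from gene counts to
metagenomic-species (MSP) abundances, differential abundance and
enterotypes; from species abundances and genome-scale metabolic models
(GEMs) to diet-constrained growth, secretion and pathway-level
functional shifts; and compositionality-corrected co-occurrence
networks per timepoint. This vignette documents the models behind each
stage, the parameters that matter, the numerical choices, and the
limits of what the synthetic tests demonstrate.

## Abundance profiling

**MSP abundance.** The signal of an MSP in a sample is the arithmetic
mean of its marker-gene counts; relative abundance divides by the sum
of signals over MSPs in that sample. No gene-length normalization is
applied: the package's gene universe (real or synthetic) is treated as
length-free, which is the correct reading for count tables produced by
a catalog mapper that already reports per-gene counts. MSPs with no
marker gene present in the table are dropped with a warning rather
than silently scored zero.

**Rarefaction.** Sequencing depth varies between samples and both
richness and presence calls are depth-sensitive, so `downsize_counts()`
subsamples each sample *without replacement* to a fixed depth — an
exact multivariate hypergeometric draw, so column sums hit the target
exactly. Richness is the number of MSPs detected per draw, averaged
over `n_draws` (default 10; the averaging count is a package choice —
enough to stabilize the mean without dominating runtime).

**Paired testing.** Each MSP is tested with a Wilcoxon signed-rank
test on paired within-subject differences. Conventions, stated because
they matter and are often left implicit:

* zero differences are dropped before ranking (Wilcoxon's original
  convention); if all differences are zero the test is vacuous and
  p = 1;
* differences with absolute value below `zero_tol = 1e-12` count as
  zero — quantities that are constant by construction (for example a
  reaction carried by every MSP, whose summed abundance is identically
  1) otherwise generate spurious rankings from floating-point residue;
* for up to 25 non-zero pairs the two-sided p-value comes from the
  exact sign-flip distribution of the statistic conditional on the
  observed absolute ranks, computed by a shift-algorithm convolution
  over doubled average ranks (ties handled exactly); beyond that a
  normal approximation with continuity correction is used;
* two-sided throughout; multiple testing across MSPs is controlled by
  Benjamini-Hochberg FDR at 0.05, and the reported direction is the
  sign of the median paired difference.

The mean paired log2 fold change uses a pseudocount of half the
smallest positive abundance in the table for zero entries — a
conventional choice for compositional data; only the test decides
significance, the fold change is descriptive.

**Compositional spillover.** Relative abundances are closed: planting
a strong increase on some species mechanically depresses every other
species' relative abundance. With several strongly planted species, a
truly unchanged species can show a significant compositional decrease.
This is not an artefact of the implementation but of compositionality
itself; the global-null calibration tests therefore use an all-null
panel, and ground-truth recovery is scored on the planted species'
directions.

## Enterotyping by Dirichlet-multinomial mixture

Genus counts are overdispersed relative to a multinomial, so each
mixture component is a Dirichlet-multinomial (DM). `fit_dmm()` runs EM:
E-step responsibilities from component DM log-likelihoods (computed on
the log scale with `lgamma`, log-sum-exp stabilized), M-step mixture
weights in closed form and component alpha vectors by
minorize-maximize fixed-point sweeps (three per M-step), which keep
the observed-data log-likelihood non-decreasing. Should a step
decrease the log-likelihood numerically, it is reverted and the fit
declared converged — the reported trace is non-decreasing by
construction, and the tests assert it. The best of `n_init` random
restarts (default 5) by final log-likelihood is returned; convergence
is declared when the increase falls below `1e-6`.

`k = 3` components is the default, matching the three-enterotype view
of gut communities; components are named after the genus with the
largest fitted Dirichlet mean (a Bacteroides-, Prevotella- or
Firmicutes-genus-dominated component in typical data).

A fit is flagged *degenerate* (with a warning and a `degenerate`
field) when a component's weight falls below `1/(10 n)` or when two
components' mean compositions are closer than total-variation distance
0.25 — components that similar are not distinct enterotypes, which is
what happens when `k` exceeds the number of real components. Model
selection over `k` is deliberately out of scope; `k` is fixed by the
user.

## Constraint-based modelling

**The model.** A GEM is metabolites-with-compartments, reactions with
flux bounds and optional KO/EC annotations, and a biomass reaction
whose flux is read as growth rate (1/h analogue). Serialized
metabolite ids carry the compartment suffix (`glc[e]`), which makes
community merging unambiguous. Exchange reactions are written
`1 M[e] <-> 0`; negative flux is uptake, positive is secretion — the
dominant convention in constraint-based modelling, stated here because
nothing else in the file format implies it. The native interchange
format is a canonical JSON schema (sorted ids, fixed key order, full
precision, so serialization is reproducible byte-for-byte); a small
SBML Level-3/fbc subset can be imported.

**Diets.** A diet is a named map from extracellular metabolite to
maximal uptake flux plus an anaerobic flag. `apply_diet()` sets each
matching exchange lower bound to minus the uptake bound, closes uptake
for everything else, leaves secretion (upper bounds) free, and forces
oxygen uptake to zero under anaerobiosis. The six built-in diets (HPO,
HPP, HFP, HFO, WESTERN, KETO) are all anaerobic and live on a fixed
arbitrary flux scale with maximal bound 10 mmol/gDW/h analogue:
fiber-rich diets put the large bounds on the polysaccharide analogue,
protein-rich diets on the peptide analogue. Only this relative
structure is meaningful; absolute values are not calibrated to any
measured diet.

**FBA.** `solve_fba()` maximizes the objective flux subject to the
steady state S·v = 0 and the bounds. The LP is solved by a
bounded-variable two-phase primal simplex written for this package:
artificial variables give a trivially feasible start, Bland's
smallest-index rule guarantees termination under the heavy degeneracy
typical of metabolic networks, and the basis inverse is maintained by
eta updates with periodic refactorization. Pivot tolerance is 1e-9;
results are asserted in tests to satisfy max|S·v| ≤ 1e-6 and bound
feasibility within 1e-9, and the objective is checked against an
independent brute-force vertex-enumeration oracle to 1e-6 on random
small models. All model bounds are finite (±1000 by convention), so
genuinely unbounded problems cannot arise from well-formed models.

**FVA and alternate optima.** FBA flux vectors are not unique.
`solve_fva()` reports, per reaction, the flux range compatible with
retaining at least `objective_fraction` of the optimum (default 1.0 —
no relaxation, since nothing in the analysis calls for suboptimal
growth). All *reported* metabolite classifications go through FVA at
the optimum: a metabolite is called produced only when its minimal
exchange flux on the optimal face exceeds `eps = 1e-6` (production is
forced), consumed when the maximal flux is below −eps; cases the
optimal face leaves open are resolved by the single FBA solution and
flagged ambiguous. This makes producer/consumer calls deterministic
and solver-independent.

## Community models

`assemble_community()` merges up to 10 member GEMs (the cap mirrors
the community size used for per-subject personalized models, chosen
there for tractability; abundances are renormalized over the selected
members): each member keeps its own cellular compartment (`c_<sp>`),
all extracellular metabolites map to a shared lumen `lu`, and a
secretion/fecal compartment `fe` collects community output. Diet
exchanges feed `lu` and are uptake-only; every lumen metabolite has an
irreversible `lu -> fe` export and a free `fe` exchange, so everything
that leaves the community exits through `fe`, where
`community_secretions()` measures it (with the same FVA-at-optimum
determinism as above).

**Abundance coupling is hard.** Each member's biomass reaction
co-produces one unit of a member-biomass metabolite; the community
biomass reaction consumes them in proportions equal to the members'
relative abundances. At steady state member *i* therefore grows at
exactly `a_i` times the community rate. This is the simplest reading
of "biomass constrained on the observed abundance", and it has a sharp
consequence worth knowing: a community cannot grow at all if any
member cannot grow at its required share — a starved specialist zeroes
the community objective. Cross-feeding through the lumen can rescue
it, and a test demonstrates a strict butyrate consumer sustained
entirely by a producer member, but only when the abundance split is
within what the producer's secretion can support. Diet fluxes are
fixed per community, not rescaled by community size.

## Reaction abundance and pathway enrichment

The reaction abundance of reaction *r* in a sample is the summed
relative abundance of the MSPs whose GEM contains *r* (exchange
plumbing excluded — reaction content is what is annotated). Presence
is strict positivity: a reaction is present when at least one MSP
carries it. Reactions map to KOs, falling back to EC numbers where no
KO exists; a reaction with several KOs belongs to every pathway any of
them belongs to.

Pathway enrichment is the one-sided upper-tail hypergeometric test of
the overlap between a selected reaction set and each pathway's
reactions within the universe. The default selected set is the
reactions significant in the paired per-reaction test (exact Wilcoxon
with Bonferroni correction, the stricter convention used for
reaction-level dysbiosis calls), and the universe is the pooled
reaction content of all models; both are arguments, since the chaining
of the two analyses is a choice, not a theorem. Bonferroni is the
default correction for pathway results, BH is available.

CAZyme summaries are deliberately simple bookkeeping: genes to CAZy
families (consumed as a table), families to substrate classes
(mucin, host glycan, pectin, ...; unmapped families under "other"),
counted per species and summed per direction group.

## Co-occurrence networks

The similarity is a checkerboard score: both abundance vectors are cut
into `n_bins = 4` quantile bins and all sample pairs are scored
+1 / −1 / 0 for co-variation / co-exclusion / ties; the sum is
normalized by the maximum attainable given each vector's marginal tie
structure (the tie-aware Kendall normalization), giving a value in
[−1, 1] that is exactly ±1 on monotone/anti-monotone bin-aligned
inputs and 0 (flagged) for constant vectors. This is a documented
re-derivation of the co-variation/co-exclusion score idea; agreement
with the original implementation is claimed at the level of sign and
null behaviour, not decimal equality.

Significance accounts for compositionality: per MSP pair, the score's
bootstrap distribution (samples resampled with replacement, rows
renormalized) is compared with a permutation null in which each MSP's
values are permuted independently and the rows renormalized —
renormalization restores compositional closure, so the null carries
the same closure-induced dependence as the data. The pooled-variance
z-statistic `(mean_boot − mean_perm) / sqrt(var_boot + var_perm)` is
referred to the standard normal, two-sided; BH FDR across the tested
pairs gates the edges, and the edge sign is the Spearman correlation
of the pair. Defaults are `n_boot = n_perm = 1000` (tests and the
acceptance script use 200, where the calibration already holds);
resampling is deterministic for a fixed seed. The z-test is
conservative under the null (the bootstrap spread enters the
denominator twice over), which the calibration tests confirm — edge
discovery errs toward fewer false edges. Edges are tested among the
top-10 increased and top-10 decreased MSPs, matching the selection
used for the modelling stages.

`compare_networks()` reduces two timepoint networks to common, lost,
gained and sign-flipped edge sets on canonical pair ids.

## The synthetic study generator

The generator produces every input the pipeline consumes, with ground
truth attached, emulating the study conditions end-to-end:

* **Cohort**: 22 paired subjects by default (M0/M4), gene counts drawn
  multinomially at a fixed depth of 100,000 reads per sample. The
  full-size analysis this emulates rarefies to 4 million reads; the
  desk-scale default keeps the identical mechanics (the rarefaction
  code is depth-agnostic) at 40× less cost, and the depth is a
  `cohort_spec` parameter for anyone wanting the full figure.
  Pangenomes have 40 genes, 10 of them markers; both are config, since
  real profilers differ and no single value is canonical.
* **Effects**: planted species' abundances are multiplied by
  `2^(log2_effect + N(0, 0.25))` per subject and renormalized; ±2.5 is
  the default planted effect, comfortably inside what strong
  responders show. The per-subject noise SD of 0.25 keeps paired
  t-like signal realistic rather than deterministic.
* **Species models**: every species can use all four carbon substrates
  (glucose, fiber, peptide, mucin analogues) unless declared an
  exclusive specialist; secreted metabolites are stoichiometrically
  coupled to biomass (0.3 units per unit growth), so secretion is
  forced whenever the species grows. Biomass yields are drawn from
  disjoint ranges by direction (increased 0.80–0.95, decreased
  0.35–0.50, null 0.55–0.70), planting the growth-rate contrast
  between guilds that the growth-matrix stage is meant to recover.
* **Genus mixture**: a 3-component Dirichlet-multinomial with mass 30
  on each component's dominant genera (Bacteroides/Alistipes,
  Prevotella, and a Firmicutes block) over 12 genera at depth 5,000 —
  well-separated components, as enterotype structure is in practice.
* **Pathways and CAZymes**: random KO subsets with one
  enriched-by-construction pathway; annotation tables biased so
  decreased species carry mucin/host-glycan families.

What the generator does **not** emulate: sequencing error, read
length and mapping ambiguity (counts are ideal multinomials), gene
length effects, real KEGG content, strain-level variation, or any
biological covariance between the planted abundance effects and the
planted metabolic traits beyond what the trait plan specifies. Passing
tests therefore demonstrate that the machinery is correct and
calibrated under clean compositional sampling — not that the pipeline
is robust to mapping artefacts or that effect sizes in real cohorts
behave this cleanly.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run panels of 8–10
species, cohorts of 20 subjects at depth 100,000, 60-sample
enterotype fits, 120-reaction enrichment universes, and resampling at
`n_boot = n_perm = 200` over 8–10 MSP networks — sizes chosen so the
whole suite completes in about a minute on one core while every
statistical check retains enough replicates (20–50 seeds where rates
are estimated) for its stated tolerance.

## Known limitations

* Hard abundance coupling is one defensible reading of
  abundance-constrained community biomass; soft coupling (member
  biomass bounded by, rather than fixed to, its share) would admit
  partial communities and is not implemented.
* The simplex is designed for the small, heavily degenerate LPs of
  desk-scale models; genome-scale reconstructions with tens of
  thousands of reactions would want a sparse industrial solver.
* The DM mixture fixes `k`; no information-criterion selection.
* Enrichment treats pathways as flat KO sets; no topology.
* The network score's agreement with the original co-variation/
  co-exclusion implementation is qualitative (sign, calibration), by
  design.
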