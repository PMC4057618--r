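---
title: "Methods: ortholog-guided flux balance analysis of active-site variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog-guided flux balance analysis of active-site variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoflux)
```

## The problem and the modeling strategy

A nonsynonymous variant that replaces an enzyme's catalytic (active-site)
residue is very likely to abolish or strongly reduce catalysis. The
phenotypic consequence of that loss, however, depends on the surrounding
metabolic network, which cannot be probed directly in human cells.
orthoflux implements a proxy strategy: when the human enzyme has a
one-to-one yeast ortholog with the same active-site residue and the same
pathway chemistry, an in-silico (and eventually wet-lab) yeast knockout is a
defensible model of the human loss of function. The package chains four
stages — reciprocal best-hit orthology, active-site conservation, a
candidate filter cascade, and constraint-based knockout simulation — each
usable on its own.

## Reciprocal best hits

Two proteins in different species are reciprocal best hits (RBH) when each
is the other's highest-scoring match. `best_hit_per_query()` keeps, per
query, the hit with maximal bit score among hits with E-value below the
threshold; ties break by lower E-value, then lexicographically smaller
subject accession, so reruns are byte-identical. The default significance
threshold is `evalue = 1e-5`, exposed as an argument (a threshold of 1e-4
is also common in RBH work; the choice matters only for borderline hits).

Every query receives exactly one label. `NO_HIT` and `RECIPROCAL` are
unambiguous. The remaining queries split into `PARALOGOUS` — the query's
best subject is also the best subject of a *different, higher-scoring*
query (a many-to-one collision, the signature of a duplicated family) —
and `ONE_WAY_BEST` otherwise. Operationalizing "paralogous" as a best-hit
collision resolved in favor of the top scorer is a design choice: curated
workflows make this call by inspecting alignments manually, and no single
rule reproduces manual judgement exactly. The same applies to
`paralog_screen()`, which replaces manual alignment inspection with two
explicit thresholds: the ortholog is unique if the runner-up hit is at
least `min_bit_margin = 50` bits weaker, or scores less than
`max_second_ratio = 0.9` of the best hit. Both defaults are deliberately
conservative and configurable; they are approximations of expert
inspection, not reproductions of it.

The built-in aligner (`align_pair()`) is Needleman–Wunsch / Smith–Waterman
with BLOSUM62 and affine gaps (open 11, extend 1; a gap of length L costs
11 + L). It stands in for an external search tool when precomputed hit
tables are not supplied. Raw scores are mapped to bit scores with fixed
Karlin–Altschul-style constants (λ = 0.267, K = 0.041, the standard gapped
BLOSUM62/11/1 values) and E-values use the product of sequence lengths
(or query length × database length in `align_proteomes()`) as the search
space. These E-values are calibrated for ranking and thresholding within
this package; agreement with an external tool's heuristically corrected
values is a non-goal.

## Active-site conservation

Positions are mapped through gapped alignments column by column
(`map_position()`): sequence positions are 1-based, alignment columns
0-based, and every TSV output uses 1-based sequence coordinates. A human
site is *conserved* (`active_site_conserved()`) iff it maps to a residue
(not a gap), the aligned residues are identical, and — when the yeast
protein has its own curated site annotation — the mapped position agrees
with an annotated yeast site. When no yeast annotation exists, identity
alone decides and the record is flagged `annotation_absent`; a site falling
outside the aligned span is recorded as unconserved with a gap mapping
rather than raised as an error, because that outcome is an answer, not a
failure.

The conserved block around a site (`conservation_block()`) expands in both
directions while columns are gap-free and score positively under the
substitution matrix, rendering identities as the residue letter and
positive non-identical columns as `'+'` (the alignment-midline convention).
Gap columns and non-positive scores terminate the block. Published
conservation-block strings are typically reported without a stated
termination rule, so block strings produced here are well-defined but need
not match such tables character for character.

## The candidate filter cascade

`run_filter_cascade()` applies five stages in a fixed order: the
1 enzyme : 1 pathway : 1 reaction restriction, intersection with the RBH
pairs, the active-site conservation requirement, the paralog screen, and
the pathway-chemistry comparison. Stages can be omitted but never
reordered; survivor sets are strictly nested, and each dropped accession
carries exactly one reason — its first failing stage. A candidate reaching
the conservation stage without a conservation verdict is a hard error: the
cascade must not silently pass records it could not evaluate.

`pathway_compare()` treats "same chemistry" as exact equality of
namespaced compound-ID sets (`CID:`/`SID:`); no chemical-similarity
matching is attempted. A pathway annotated only in the yeast ortholog does
not break the match when its reaction chemistry equals the shared
reaction's — pathway databases annotate species asymmetrically, and
penalizing the better-annotated species would be perverse.

## Constraint-based core

Flux balance analysis maximizes the objective (by default the biomass
reaction, whose flux is the growth rate in hr⁻¹) subject to steady-state
mass balance $Sv = 0$ and bounds $lb \le v \le ub$ (fluxes in
mmol·gCDW⁻¹·hr⁻¹). The LP layer reduces this box-bounded polytope to
computational standard form and solves it with a dense two-phase simplex
using Bland's anti-cycling rule. Bland's rule makes every pivot
deterministic, which gives byte-stable reports, and guarantees termination
on the highly degenerate bases that FBA produces (most right-hand sides
are zero). Optimal vertices satisfy $\max|Sv| \le 10^{-9}\max(1, \max|v|)$;
the test suite checks the solver against brute-force vertex enumeration of
the flux polytope on random networks of up to 8 reactions (tolerance
1e-7). Infinite bounds are capped at $10^6$ internally and a solution
pinned to such a cap on an objective variable is reported `UNBOUNDED`.

Taxicab (L1) minimization is a second LP at the attained optimum: split
variables $v = v^+ - v^-$, minimize $\sum (v^+ + v^-)$, with the
first-stage objective fixed as an equality constraint (drift tolerance
1e-9 absolute). The split boxes $v^+ \in [\max(lb,0), \max(ub,0)]$,
$v^- \in [\max(-ub,0), \max(-lb,0)]$ reproduce the original bounds for
every sign pattern, and at the optimum the two parts are never
simultaneously positive, so the objective equals $\sum|v|$. Futile cycles
carry zero flux in this solution — any internal loop can be removed
without changing the objective.

Gene knockouts evaluate gene-protein-reaction rules (`evaluate_gpr()`:
AND = complex subunits, OR = isozymes, empty rule = always active) with
deleted genes set false; every inactivated reaction gets bounds `[0, 0]`,
a total loss of function. Reaction-level knockouts zero bounds directly.
Both entry points exist because gene-level propagation is the biologically
meaningful operation while reaction-level zeroing is what "limit the flux
of the affected reaction to zero" literally prescribes; panels record
which was used. A knockout is classified `NO_GROWTH` below
`epsilon = 1e-6` hr⁻¹ — small enough that any plausible numerical residue
of a truly blocked biomass flux falls under it, large enough to catch
solver-level noise; published analyses rarely state this cutoff.

### Biomass augmentation

Genome-scale biomass functions omit some true requirements (heme-like
cofactors, charged mitochondrial tRNAs), which silences knockouts of the
corresponding synthesis genes. `augment_biomass()` restores such
requirements at a conventionally small magnitude (0.0005 per metabolite)
in either of two modes. *Coefficient* mode (the default) adds the
metabolite as a biomass reactant, so demand scales with growth — this
matches the intent of "adding the requirement to the biomass function".
*Demand* mode adds a sink reaction with the requirement as its lower
bound, a fixed flux independent of growth — this matches the unit
mmol·gCDW⁻¹·hr⁻¹ literally, since a biomass coefficient would carry
mmol·gCDW⁻¹. The printed unit conflates the two readings, so both are
implemented and recorded in the model provenance; at 0.0005 the numerical
difference is negligible for viable strains, and the qualitative
growth/no-growth verdicts agree.

## What the synthetic generators emulate

`simulate_proteomes()` plants ortholog pairs by evolving both copies
independently from a common ancestor: per-site substitutions are drawn
from BLOSUM62-conditional probabilities
($P(b \mid a) \propto f_b \, 2^{s(a,b)/2}$, favoring conservative
exchanges so realized identity tracks the configured target), plus
geometric deletions at rate 0.008/site. Each copy diverges with
substitution probability $1 - \sqrt{t}$ so the pair's expected identity is
the target $t$. Below $t = 0.35$ the mutual-nearest property of planted
pairs is no longer guaranteed (random high-scoring matches compete), so
the generator refuses. Paralog decoys are within-species duplicates at
95% identity to their source, which reliably triggers the many-to-one
best-hit collision. The generator does **not** emulate domain
architecture, compositional bias, repeat regions, alternative splicing, or
realistic paralog family structure — passing tests on simulated proteomes
therefore demonstrates the correctness of the RBH/conservation machinery,
not its error rate on real proteomes, where short or repetitive sequences
are the known failure modes.

`generate_toy_model()` builds branched uptake networks whose wild-type
growth has the closed form $\sum_i c_i y_i$ (capacity × yield over open
branches), and the packaged 14-reaction model (`toy_model_path()`) adds
the two motifs the knockout panel needs: an isomerase on the sole pentose
route (lethal when knocked out, the ribose-5-phosphate-isomerase
analogue) and a two-gene cofactor branch required only by the augmented
biomass (silent knockout that turns lethal on augmentation, the
ferroheme-b analogue). Its wild-type growth is $(10 + 4 - 0.5)/2.5 = 5.4$:
each biomass unit costs 2.5 hexose equivalents and maintenance a fixed
0.5.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100 random flux models of
4–8 reactions for the vertex-enumeration comparison; 6 planted ortholog
pairs (identity 0.6, lengths 120–240) for pipeline recovery; the
14-reaction packaged model for every knockout scenario. These sizes keep
the brute-force oracles exact and the whole suite fast while covering
every code path; the algorithms themselves are size-independent, and the
dense simplex is appropriate for models up to a few hundred reactions.
Genome-scale models (thousands of reactions) load and validate through the
same SBML/JSON readers, but their LPs are large and dense solving is slow;
full-scale runs are best scheduled offline (see below).

All generators are pure functions of (configuration, seed): the RNG state
is saved and restored around each call, identical configs give
byte-identical output, and the pipeline manifest checksums make rerun
stability testable.

## Reproducing the full-scale published quantities

Two reference quantities need external data that cannot be bundled: the
genome-scale consensus yeast model (Yeast 7.0.0 SBML; wild-type growth
0.1405 hr⁻¹ on its default aerobic glucose minimal bounds, with zero
wild-type flux through the glutathione-synthetase reaction `r_0485`), and
the UniProt sequences of the 11 candidate ortholog pairs (10 of 11
conserved at the active site; the delta-aminolevulinic acid dehydratase
pair maps human position 221 to yeast 232). Drop the files at
`yeast7_model_path()` and `inst/extdata/external/candidate_pairs.faa`
respectively and the corresponding acceptance tests run against them;
`yeast7_wildtype_check()` is the entry point for the first. Sequence
databases move: active-site coordinates in current UniProt releases can
drift from the curated table positions, in which case the conservation
report flags the disagreement rather than papering over it.

## Known limitations

* Chemistry comparison is exact compound-ID set equality; tautomers or
  differently-normalized IDs count as mismatches.
* The paralog screen's thresholds approximate manual curation; borderline
  duplicated families can be classified either way.
* The dense simplex targets small and mid-sized models; genome-scale LPs
  want a sparse solver.
* The aligner's E-values are internally consistent ranking scores, not
  database-corrected significance estimates.
* Conservation-block strings depend on the stated termination rule and on
  the alignment; they are stable within the package but not comparable
  character-for-character across tools.
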