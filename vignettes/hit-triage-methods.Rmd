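---
title: "Methods: post-generation hit triage for de novo molecule libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-generation hit triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hittriage)
```

## The problem this package addresses

Structure-based generative models can emit hundreds of thousands of 3-D
molecules for a single protein pocket. Almost none of them can be bought or
easily synthesised, and most are not drug-like. `hittriage` implements the
post-generation half of that workflow: it turns a raw de novo molecule set
into a short, chemically diverse list of testable hit scaffolds, and then
maps those scaffolds into a purchasable compound library. Every stage
operates on a tidy molecule table (one row per molecule, annotations as
columns that round-trip through SDF data tags), so stages compose with the
pipe and any stage can be resumed from a previously written SDF.

The stage order is fixed: structure validation, chemical-physical property
filtering, hit calling (synthetic accessibility, drug-likeness, binding
score), Bemis–Murcko scaffold clustering of the property-filter survivors,
Fisher-test chemotype (SAR) enrichment with a dynamic binding-score cutoff
sweep, per-cluster top-scaffold selection, similarity-based library search,
and a 2-D chemical-space overlap map.

## Primary property filter

Four descriptors gate everything downstream: molecular weight ≤ 800 Da,
AlogP in [−1, 7], topological PSA < 125 Å², and fewer than 12 rotatable
bonds. The boundary semantics are deliberate: the weight bound is
inclusive, the PSA and rotatable-bond bounds strict. The AlogP bounds are
read as inclusive but configurable (`property_thresholds()`), because the
protocol phrasing "between −1 and 7" does not fix them.

Molecular weight, logP and topological PSA come from OpenBabel's
atomic-contribution implementations. OpenBabel's logP is not numerically
identical to the commercial AlogP descriptor the original protocol used;
thresholds are therefore configurable so a user can compensate if they have
reference values. Rotatable bonds are counted on the molecular graph
directly: non-ring single bonds between two non-terminal heavy atoms, with
the amide C–N bond excluded. We count on the graph rather than by SMARTS
because common rotatable-bond SMARTS patterns also exclude N–alkyl bonds on
amide nitrogens, which contradicts the definition above (for
`CCC(=O)NCC` the graph definition gives 2, the usual SMARTS gives 1).
Records whose descriptors cannot be computed fail the filter closed.

## Hit calling

Three scores define a *virtual hit*, all boundaries inclusive: SAscore ≤ 4,
QED ≥ 0.5, and binding ΔG ≤ −6 kcal/mol.

**QED** is the weighted geometric mean of eight desirability functions
(molecular weight, AlogP, hydrogen-bond acceptors and donors, PSA,
rotatable bonds, aromatic rings, structural alerts), each an asymmetric
double sigmoid with the published parameterisation. The published "mean"
weight set is the default; "max" and "unit" sets are selectable, and QED is
invariant under proportional rescaling of the weights. Because our
underlying descriptors (OpenBabel HBA/HBD/logP, graph rotatable bonds, a
compact alert list) differ from other toolkits, absolute QED values differ
slightly too; the functional form, range and boundary behaviour are exact.
A zero desirability maps to QED 0 by the limit convention, with a warning.

**SAscore** follows the fragment-contribution-minus-complexity-penalty
scheme: the fragment score is the mean log10 relative frequency of each
circular atom environment (radius 2) under a frequency table; the
complexity penalty adds size, ring-fusion, declared-stereocentre and
macrocycle terms. The frequency table is derived at load time from a
bundled reference set of ~170 common drugs and fragments
(`inst/extdata/reference_smiles.txt`), so scores are reproducible offline
and a user can substitute a table derived from their own corpus
(`default_fragment_table(path)`). The raw score is mapped monotonically
(decreasing) onto [1, 10] with fixed anchors (−6, 1.5) chosen once so that
routine acyclic chemistry lands below 3 and heavily penalised rare
chemistry saturates near 10. Scores from different tables are comparable
only in rank, not in value — the cutoff of 4 is meaningful relative to the
bundled table.

**Binding score.** The scorer has the combined functional form

$$\Delta G = c + \alpha\left[\tfrac{2}{3}(E_\mathrm{Coul} + E_\mathrm{sol})
 + E_\mathrm{vdW} + \beta\,\Delta SA_\mathrm{weighted}\right]$$

with point-charge Coulomb electrostatics at interior dielectric 1
(Gasteiger ligand charges from OpenBabel; receptor charges from an optional
CSV sidecar), generalized-Born solvation with HCT-style pairwise
descreening, Lennard-Jones 6-12 van der Waals with UFF-like parameters and
geometric mixing (per-pair repulsion softened at +10 kcal/mol so clashes
stay finite and comparable; clashing poses are flagged), and an
exposure-weighted ligand surface term expressed as a change on binding so
that a non-interacting pose scores exactly `c`. The trained constants of
the commercial scorer are proprietary and unpublished; the defaults
`c = 0, α = 1, β = 0.1` are this package's own surrogate values, so
absolute scores are not comparable to the commercial tool — only the
functional form, the threshold logic, and orderings (bound vs displaced)
are meaningful. When a record already carries a `GBVI_WSA_dG` tag
(precomputed externally), that value always wins and the surrogate is
skipped.

## Scaffold clustering

Scaffolds are Bemis–Murcko *assemblies*: ring systems plus chains linking
two or more rings, computed by iterative leaf pruning of the heavy-atom
graph, with atoms attached to the framework by a double or triple bond
restored (keeping exocyclic carbonyls). Acyclic molecules map to the empty
scaffold and are pooled into a `NO_SCAFFOLD` pseudo-cluster that is
excluded from enrichment by default (configurable); the protocol we follow
is silent on them.

Scaffolds are fingerprinted with a circular (Morgan-style) fingerprint of
diameter 6 folded to 2048 bits, implemented with deterministic integer
hashing so bit assignments are platform-stable. Distance is 1 − Tanimoto on
the scaffold fingerprint, never on the whole molecule. Clustering is greedy
maximum-dissimilarity with a 0.625 distance cap; since the commercial
implementation of "maximum dissimilarity" is unpublished, the variant is
fixed and fully tie-broken so results are deterministic and testable:

1. the first centre is the point with the largest summed distance to all
   others (ties: lexicographically lowest record id);
2. the point farthest from its nearest centre is promoted while that
   distance exceeds 0.625 (same tie-break);
3. every point is assigned to its nearest centre (ties: earlier centre).

This guarantees the two structural invariants asserted throughout the test
suite: every member is within 0.625 of its centre and centres are pairwise
more than 0.625 apart.

## SAR enrichment and the cutoff sweep

Per cluster, a 2×2 contingency table counts hits against non-hits, inside
against outside the cluster, and Fisher's exact test yields a p-value;
clusters with p ≤ 0.05 are *enriched*. The test is implemented from the
hypergeometric point probability in log-factorial arithmetic; the printed
single-table formula is the *point* probability, and the test sums the tail
over all tables with the observed margins — the two are distinct quantities
and both are exposed (`fisher_point_probability()`, `fisher_exact()`). The
default alternative is one-sided "greater", since the question is whether
hits are over-represented; two-sided is available. No multiple-testing
correction is applied by default (raw p ≤ 0.05, as in the protocol we
follow); Benjamini–Hochberg is available behind a flag.

The hit predicate during the sweep is ΔG ≤ cutoff AND SAscore pass AND QED
pass (the `dg_only` flag restricts it to ΔG alone). The sweep starts at
−6 kcal/mol, steps by −0.1, and stops at the first cutoff whose *selected
scaffold* count (one top-ΔG representative per enriched cluster; ties by
lowest record id) falls inside the 100–200 target band; if no cutoff lands
in the band within `max_steps`, the closest cutoff is chosen and the result
flagged. Counting selected scaffolds rather than enriched clusters matches
the target's phrasing ("100 to 200 top diverse hit scaffolds").

## Library search

Top scaffolds are mapped into a library by a shape + pharmacophore
similarity surrogate. Conformers are rigidly aligned by volume-weighted
centring and principal axes, testing all four proper axis-flip
combinations and keeping the best; there is no torsional sampling, because
the workflow scores existing conformations. Shape overlap integrates
Grant–Pickup Gaussian atom volumes (product form, amplitude 2.7) on a
0.4 Å grid; the shape Tanimoto is the overlap volume over the union. The
feature Tanimoto overlaps typed pharmacophore points (donor, acceptor,
aromatic-ring centroid, hydrophobe, cation, anion) with unit-width
Gaussians pooled across types. Electrostatic similarity is represented by
the cation/anion types rather than a field comparison — a deliberate scope
control. The combo score is their sum (range 0–2), cut at 1.0 by default;
because the surrogate's absolute values differ from the commercial shape
tool, the cutoff is configurable everywhere. One best query is kept per
candidate. Survivors are rescored with the binding scorer (or their
external score tag), filtered at the sweep's chosen cutoff, and passed
through user-supplied named predicates (availability, QC, solubility —
arbitrary Boolean functions or Boolean SDF tags) in declared order, with
per-stage counts recorded.

## Chemical-space map

Each molecule is described by the four standardized chemical-physical
properties concatenated with its 2048-bit circular fingerprint (properties
z-scored, fingerprints left binary; the mixed-type weighting is a
documented choice, configurable by supplying your own matrix). The map is
an exact O(n²) t-SNE (perplexity 30, 400 iterations, early exaggeration),
seeded and deterministic, with coordinates min–max normalized to the unit
square. The buffer radius r = 0.02 is interpreted on those normalized
coordinates because raw t-SNE scale is arbitrary. Disc unions and their
intersection are rasterized at 1024² by default; single-disc area is within
1% of πr² and doubling the resolution moves areas by well under 0.5%. The
map is qualitative — embeddings are not metric — so all assertions about it
are property-based (seeded determinism, blob separation, closed-form disc
geometry), never coordinate values.

## Synthetic libraries and what they do (not) show

`generate_library()` builds molecules by decorating scaffold SMILES
templates (an `R` token marks the substitution slot) from a fixed
substituent menu, so cluster structure is controlled exactly; binding
scores are drawn from a per-cluster Gaussian model (baseline mean
−4.5 kcal/mol, sd 1.2, giving ≈ 10% of molecules past the −6 hit line — a
realistic screening-funnel rate); planting multiplies a cluster's hit odds
at the −6 reference line and redraws scores from the matching truncated
normal, so the marginal score family is preserved. One integer seed drives
a single RNG stream; the same spec and seed reproduce a byte-identical SDF
(the writer pins the program line of each molblock for this reason). The
label-level fast path (`structures = FALSE`) emits cluster and score
columns without chemistry and is what the large simulation studies use.

The generator emulates cluster structure, score distributions and planted
enrichment. It does not emulate the chemistry of a real generative model:
decorations come from a small menu, conformers (when requested) are single
OpenBabel embeddings, and SAscore/QED values in label-level mode are drawn
near-passing rather than computed. Tests passing on these fixtures
demonstrate the statistical and algorithmic contracts — error rates,
sensitivity, invariants, determinism — not performance on real de novo
output. Desk-scale defaults are n ≤ 5,000 molecules; the simulation studies
in the test-suite and acceptance script use 1,000 molecules × 20 clusters
(1,000 null libraries for the type-I study, 200 seeds for sensitivity),
sizes chosen to give stable rate estimates on a single CPU.

## Numerical choices and degenerate inputs

- Fisher: degenerate margins (an empty row or column) define p = 1; the
  two-sided tail uses the standard 1 + 1e−7 relative tolerance when
  comparing point probabilities; everything is computed in `lgamma` space,
  no normal approximation ever.
- Validation is total: unparseable records produce a `parse` failure report
  and land in the rejects sidecar, never an exception; unknown elements,
  implausible formal charges (|q| > 3) and valence overflows (charge
  adjusted; carbon capped at 4) are flagged. Invalid structures are
  discarded and reported, not repaired.
- Canonical SMILES follow one OpenBabel convention fixed at load, so
  duplicate and scaffold identity is stable within a session and across
  machines with the same OpenBabel build.
- Fingerprint hashing uses multiply-add folding modulo 2³¹−1 with products
  bounded inside exact-double range, so bit assignments are identical on
  any platform.
- t-SNE inputs wider than 50 columns are first reduced by PCA; perplexity
  is clamped to (n−1)/3 for tiny inputs.
- The empty scaffold routes to an all-zero fingerprint by convention; two
  all-zero vectors have Tanimoto 1 (identical emptiness).

## Known limitations

- Binding scores are surrogate-scaled: thresholds transfer as conventions,
  not as physical energies; do not compare absolute values against MOE.
- Aromatic ring counting and pharmacophore typing use pragmatic rules
  (SMARTS ring patterns up to 7-membered; sp2 proxies), which can miss
  exotic aromaticity.
- The alert list is a compact subset chosen for the SMARTS dialect
  OpenBabel parses; QED's alert desirability is correspondingly mild.
- Library search is all-pairs and desk-scale; billion-scale search is out
  of scope.
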