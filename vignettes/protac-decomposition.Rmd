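---
title: "Library-driven PROTAC decomposition: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Library-driven PROTAC decomposition: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protacR)
```

## The decomposition model

A PROTAC is modelled as a molecular graph that is an exact union of three
vertex-disjoint induced subgraphs — warhead, linker, E3 ligase ligand —
joined by acyclic single bonds. Decomposition is the inverse problem:
given the parent and two reference libraries, recover every partition of
the parent consistent with that model.

The engine never predicts: it only recognizes. A warhead or E3 candidate
is an *induced* substructure embedding of a library molecule in the
parent — every bond among the matched atoms must be present in the
library fragment and vice versa, so a fragment can never be "almost"
there. Embeddings are enumerated with VF2 on vertex colors
(element, formal charge, aromaticity) and edge colors (bond order, with
aromatic bonds as their own bond class); since VF2 establishes a
monomorphism, an explicit post-filter rejects images that carry chord
bonds. The aromatic bond class is what makes matching independent of the
arbitrary Kekulé alternation a particular SMILES happens to encode.

### The two passes and why they differ

Pass A matches a warhead first; its removal must leave a **single
connected remainder**, in which the E3 ligand is then matched. Pass B is
the mirror image. Only triples that appear identically — same canonical
warhead, same canonical E3, identical canonical linker — in *both*
directions are retained.

The single-remainder gate on the first subtraction is the package's
resolution of a genuinely open design point, and it is load-bearing. If
both passes simply enumerated all disjoint (warhead, E3) placements, the
two directions would provably produce identical candidate sets on a fixed
molecular graph and the consistency check could never fail. With the
gate, the passes become asymmetric in exactly the chemically meaningful
way: a library entry that matches a *central* moiety (so that its removal
disconnects the molecule) kills the triple in one direction but not the
other, and the case is reported as `linker_inconsistent`. The *second*
subtraction is deliberately not gated — removing the second ligand may
split the leftover into several pieces, and such candidates are carried
forward so the single-linker filter (and the `multiple_linker_fragments`
category) can see them; macrocyclic architectures bridged by two
independent chains survive both passes and fail precisely there.

### Filters and failure taxonomy

A consistent candidate becomes a solution only if

1. the linker is one connected fragment with at least one heavy atom
   (linker-less decompositions are not part of the model),
2. heavy atoms are conserved exactly, and
3. SSSR ring counts are conserved exactly. Ring count is computed as the
   circuit rank (bonds − atoms + components) throughout the package.

Conservation is not decorative: for a partition into three connected
parts joined by *k* cut bonds, the parent's circuit rank exceeds the
parts' sum by *k* − 2. Ring conservation therefore holds exactly when the
decomposition uses two cuts — the linear warhead–linker–E3 architecture —
and fails for every looped or macrocyclic placement. This is what the
exhaustive two-cut oracle in the test suite exploits: on parents up to 30
heavy atoms it enumerates all pairs of acyclic single-bond cuts and must
reproduce the engine's solution set exactly.

Failed molecules get exactly one category, assigned by earliest failing
stage: `warhead_not_found` (no warhead-library embedding anywhere), then
`e3_not_found`, then `linker_inconsistent` (embeddings existed but no
triple survived both directions), then `multiple_linker_fragments` (every
consistent candidate had a disconnected linker), then
`count_discrepancy`. The ordering is a design choice — the categories
themselves are standard, but no precedence is canonical — and it is
chosen so that library curation always sees the most actionable cause:
a missing fragment is reported as missing even if downstream symptoms
also occurred. When consistent candidates show mixed violations, the
disconnected-linker label is only used if *all* of them are disconnected;
otherwise the conservation label wins.

### Multiple solutions

When a library contains nested cores (a ligand and its methyl-extended
analogue, say), several chemically plausible boundaries exist. All
filter-passing solutions are reported, deduplicated by the canonical
(warhead, linker, E3) triple and ordered by descending warhead size, then
descending E3 size, then linker SMILES. Pipelines that need a single
answer take the first row (`emit_all_solutions = FALSE` in the batch
driver); the ordering prefers the most specific (largest) ligand
assignment, but no claim is made that it is the chemically "true" one.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_heavy` (libraries) | 3 heavy atoms | smallest admissible library fragment; below this, matches are degenerate (a lone carbon "warhead" would match everywhere) |
| `stereo` | `"ignore"` | `"ignore"` strips stereo descriptors before canonicalization, so enantiomeric fragments share one identity — library sketches frequently omit stereocenters; `"strict"` keeps stereo in the canonical identity used for linker comparison and deduplication |
| `emit_all_solutions` | `TRUE` | batch output policy (all rows vs top-ranked row per degrader) |
| library ordering | size-descending | larger, more specific fragments are tried first; with redundant nested entries this puts the most specific assignment first in the solution order |

Matching itself is constitutional in both stereo modes: the graph carries
no stereo labels, so a `"strict"` run differs only in fragment/linker
identity, not in embedding enumeration.

## The synthetic-data generator

`assemble_protac()` joins standardized fragments with new single bonds at
attachment atoms that have a free valence (carbon or nitrogen with at
least one implicit hydrogen), so heavy-atom and ring conservation hold by
construction and every corpus molecule carries its ground-truth triple.
`random_corpus()` samples triples and sites reproducibly under one seed.
The default pools are small, well-known drug-like chemotypes: fused
azaarene cores of the kind used as kinase hinge binders (quinoline,
aminoquinazoline, benzimidazole, indole), imide/glutarimide cereblon-binder
mimics (including thalidomide itself), and alkyl/PEG/piperazine linkers
with one to eight heavy atoms. Pool sizes (5 warheads × 6 linkers × 5 E3
ligands) and the corpus size of 200 keep exhaustive verification cheap
while exercising every architecture the model admits, including one-atom
linkers and N-linked imides.

What the generator deliberately does *not* emulate: the structural
breadth of real degrader collections (hundreds of distinct ligand
scaffolds), stereochemistry, salts and formulation counter-ions in input
records, tautomeric drift between library and degrader sketches, and
ligands joined by non-single bonds. Passing the round-trip and oracle
suites therefore demonstrates correctness of the *algorithm* under the
three-part model — it does not certify recall on any real-world dataset,
where coverage is dominated by library completeness (the decisive factor
the failure taxonomy is designed to surface).

`adversarial_cases()` complements the corpus with fixed constructions
that hit each failure category: libraries missing one moiety, a
mid-molecule "warhead" (piperazine) whose removal disconnects the parent,
a doubly-bridged macrocycle (disconnected linker), a linker looping back
onto its warhead (ring-count violation with a connected linker), and the
nested-core ambiguity with exactly two valid solutions.

## Descriptors

The linkerology suite reports MW, nC, TPSA, HBD, HBA and Kier's
flexibility index Φ. MW, TPSA, HBD and HBA are taken from OpenBabel's
descriptor implementations (via ChemmineOB): MW is the *average*
molecular weight including implicit hydrogens (not monoisotopic), HBD is
OpenBabel's donor count and HBA its `HBA1` acceptor count. Donor/acceptor
conventions differ across toolkits; the package fixes this pair and group
comparisons remain internally consistent regardless of convention.

Φ is computed in the package from the alpha-modified kappa shape
indices,

Φ = ¹κ_α · ²κ_α / A,  ¹κ_α = (A+α)(A+α−1)²/(¹P+α)²,  ²κ_α = (A+α−1)(A+α−2)²/(²P+α)²,

with A the heavy-atom count, ¹P the bond count, ²P the two-bond-path
count and α the summed Hall–Kier covalent-radius contributions
(hybridization is derived from the bond table: any triple or cumulated
double bond → sp, any double/aromatic bond → sp2, else sp3). On an
unbranched sp3 alkane of A atoms the formula collapses to Φ = A − 1,
which the test suite pins to 1e-9 for A = 3…10. Molecules with fewer
than three heavy atoms have no two-bond path; Φ is reported as 0 there —
a convention, chosen because such fragments have no torsional freedom to
quantify.

## Numerical and degenerate-input choices

* **Identity is canonical SMILES** (OpenBabel), cached aggressively; all
  cross-pass comparison, deduplication and library lookup go through it.
* **Salt handling**: standardization keeps the largest covalently bonded
  component of a multi-component input.
* **Degenerate inputs**: empty SMILES and unparseable strings raise
  structured errors; in batch mode they are exported to the unresolved
  file under an artifact-level `input_error` category rather than dropped,
  so input ids are always conserved across output files.
* **Fragment = parent** is rejected at match time (all three moieties
  must be nonempty).
* **Symmetric embeddings** that cover the same atom set are reported
  once; distinct atom sets yielding the same canonical triple are merged
  at deduplication.
* **Determinism**: libraries are ordered size-descending with
  lexicographic tie-break, match sites by sorted atom tuple, and the
  pipeline holds no hidden state — identical inputs give byte-identical
  outputs, which the batch tests assert literally.

## Problem sizes used in the checks

The shipped verification uses a 200-molecule round-trip corpus, a
50-molecule oracle-equivalence corpus capped at 30 heavy atoms (where
two-cut enumeration is exhaustive), the six adversarial fixtures, and a
25-member shared-warhead/shared-E3 linker series for the descriptor
workflow. These sizes exhaust the fixture pool combinatorics several
times over while keeping the full suite fast enough to run on every
change.

## Known limitations

* Recognition is bounded by the reference libraries: a chemotype absent
  from both libraries is unresolvable by design. The unresolved export
  plus the monotonicity property (adding fragments never removes
  solutions) is the intended curation loop.
* Aromatic-bond classification relies on OpenBabel's aromaticity model;
  exotic ring systems perceived differently in fragment and parent would
  fail to match (none of the shipped chemotypes are affected).
* Linker identity is compared as the bare fragment without
  attachment-point annotation; two solutions differing only in linker
  regiochemistry of attachment are considered identical linkers.
* Degradation-efficacy classes are accepted as user-supplied labels in
  the profiling step, never computed.
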