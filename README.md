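# protacR

Rule-based decomposition of PROTAC degraders into their warhead, linker
and E3 ligase ligand, plus the linker physicochemical descriptor suite
used in linkerology analysis.

## The problem

Proteolysis-targeting chimeras (PROTACs) are heterobifunctional molecules
built from three covalently joined parts: a ligand for the protein of
interest (the *warhead*), an *E3 ligase ligand* that recruits the
ubiquitin-proteasome machinery, and a *linker* joining the two. Systematic
analysis of degrader collections — annotating large datasets, swapping
warheads, studying how linker length, flexibility and polarity drive
degradation efficiency — requires splitting each molecule back into those
three parts. Manual annotation does not scale, and generative ML splitters
can hallucinate atoms that are not in the parent molecule. protacR instead
takes the deterministic route: it matches a degrader against curated
libraries of known warheads and E3 ligands and only ever reports
decompositions whose fragments account, atom for atom, for the entire
parent molecule.

The package is aimed at medicinal and computational chemists working on
targeted protein degradation who need reproducible, library-driven
annotation of degrader structures from SMILES.

## The algorithm

For a degrader *P* and libraries *W* (warheads) and *E* (E3 ligands):

1. **Pass A (warhead first).** Every induced substructure embedding of
   every *w* ∈ *W* in *P* is enumerated (VF2, vertex-colored by
   element/charge/aromaticity, edge-colored by bond order). Matches whose
   removal splits *P* are discarded; in the single connected remainder,
   every *e* ∈ *E* is matched. The leftover atoms form the candidate
   linker *L*.
2. **Pass B (E3 first).** The same procedure starting from *E*.
3. **Bidirectional consistency.** A candidate triple (*w*, *L*, *e*)
   survives only if the identical triple — same canonical warhead, same
   canonical E3, identical canonical linker — is produced in both
   directions.
4. **Structural filters.** A surviving candidate is a solution only if
   (i) the linker is a single connected fragment with ≥ 1 heavy atom,
   (ii) heavy atoms are conserved,
   n(*w*) + n(*L*) + n(*e*) = n(*P*), and
   (iii) SSSR ring counts are conserved (no ring may be cut).
5. **Reporting.** All valid solutions are emitted in a stable order
   (larger warheads first), deduplicated by the canonical triple; the
   final choice between chemically plausible alternative boundaries is
   left to the user. Unsolved cases receive exactly one failure category:
   `warhead_not_found`, `e3_not_found`, `linker_inconsistent`,
   `multiple_linker_fragments` or `count_discrepancy` — so unresolved
   files can drive targeted library expansion.

For linker structure-activity work the package computes the six standard
descriptors: MW (average molecular weight, Da), nC (carbon count), TPSA
(topological polar surface area, Å²), HBD, HBA, and Kier's molecular
flexibility index Φ = ¹κ_α·²κ_α / A computed from the alpha-modified
kappa shape indices.

Cheminformatics plumbing (SMILES parsing, canonicalization, TPSA/MW/HBD/
HBA) is delegated to ChemmineR/ChemmineOB (OpenBabel); subgraph matching
runs on igraph's VF2 with an induced-embedding post-filter.

## Worked example

The toy degrader `c1ccc(nc1)CCCN1CCCCC1` (pyridine–propyl–piperidine)
decomposed against a warhead library that contains both the bare pyridine
core and its methyl-extended analogue — a classic boundary ambiguity:

```r
library(protacR)
wl <- fragment_library(c("c1ccncc1", "Cc1ccccn1"),
                       ids = c("pyridine", "methylpyridine"),
                       role = "warhead")
el <- fragment_library("C1CCNCC1", ids = "piperidine", role = "e3_ligand")
rep <- bidirectional_decompose("c1ccc(nc1)CCCN1CCCCC1", wl, el,
                               protac_id = "P1")
rep
#> <decomp_report> P1  [solved]
#>   C1CCN(CC1)CCCc1ccccn1
#>   solution 1:
#>     warhead [methylpyridine]  Cc1ccccn1
#>     linker        CC
#>     E3      [piperidine]  C1CCCNC1
#>   solution 2:
#>     warhead [pyridine]  c1cccnc1
#>     linker        CCC
#>     E3      [piperidine]  C1CCCNC1
```

Both solutions conserve every heavy atom and ring of the parent; they
differ only in whether the first methylene is assigned to the warhead or
to the linker. Descriptors of the shorter linker:

```r
compute_descriptors(rep$solutions[[1]]$linker_smiles)
#>         mw nC tpsa hbd hba phi n_heavy n_rings
#> 1 30.06904  2    0   0   0   0       2       0
```

Batch work goes through `run_batch()` or the installed command-line
script:

```sh
protacr decompose --input degraders.csv --warheads warheads.smi \
        --e3 e3_ligands.smi --output solved.csv --unresolved unresolved.csv
protacr decompose-one --smiles 'c1ccc(nc1)CCCN1CCCCC1' \
        --warheads warheads.smi --e3 e3_ligands.smi
protacr make-fixtures --outdir fixtures --n 50 --seed 1
```

Synthetic test molecules with known ground truth come from
`random_corpus()` / `assemble_protac()`, and `adversarial_cases()`
provides fixtures engineered to hit each failure category.

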