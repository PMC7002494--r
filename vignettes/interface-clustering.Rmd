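---
title: "Clustering crystal interfaces across crystal forms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering crystal interfaces across crystal forms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalclust)
```

# The model

`xtalclust` operationalizes a simple evolutionary argument: crystal
packing contacts are accidents of one crystallization condition, while
functional interfaces are conserved, so an interface that recurs across
*independent crystal forms* — ideally in *homologous but non-identical*
proteins — is likely biological. Turning that argument into a
computation requires four ingredients, each with explicit rules.

## Lattice expansion and the interaction rule

A deposited asymmetric unit is expanded into the 3×3×3 block of 27 unit
cells: one placement per (chain, space-group operator, cell
translation), each an affine map in the orthogonal frame
(orthogonalization ∘ fractional operator ∘ fractionalization, with the
*a* axis along *x*). Interfaces are enumerated between the identity
asymmetric-unit copies and every placement; by crystal symmetry each
interface class touches the identity copy, so this anchoring loses
nothing, which is also the property the tests assert (the census is
invariant under recentring the lattice on another copy).

Two chains or domains interact iff they have **≥ 10 Cβ–Cβ pairs within
12 Å and ≥ 1 atomic contact within 5 Å, or ≥ 5 atomic contacts within
5 Å**. Glycine (and any residue with an unmodeled side chain)
substitutes Cα for Cβ so the rule stays total. Hydrogens are ignored
everywhere: most X-ray entries lack them, and including them would make
contact counts depend on deposition practice rather than structure.
Domain-level interfaces are *derived from* chain-level contact sets by
the family-defined start/stop positions — they are never recomputed
independently, which guarantees the chain→domain consistency invariant.
Intra-chain domain pairs are enumerated on the identity copies and
flagged `intra_chain`.

Symmetry duplicates are collapsed by a coordinate-free criterion: two
interfaces in one crystal are equivalent iff their residue-level
contact-pair sets map onto each other exactly (Q = 1 under the identity
correspondence), with sides keyed by entity so relabeled symmetry
copies compare equal. The representative is the lexicographically
smallest by (chain id, operator index, shift), making enumeration
deterministic and idempotent.

## Buried surface area

Interface size is half the buried solvent-accessible area,
(SASA_A + SASA_B − SASA_AB)/2, computed by Shrake–Rupley sampling with
a deterministic golden-spiral point set (960 points per atom, probe
1.44 Å, standard van der Waals radii). Chain-level interfaces below
100 Å² and domain-level interfaces below 150 Å² are retained in the
census with a below-threshold flag but excluded from clustering. The
two cutoffs differ deliberately — both figures appear in the protocol
this package implements — and both are configurable
(`min_bsa_chain`, `min_bsa_domain`). The SASA tests compare against the
same construction at 10× point density; agreement is within 2%.

## Correspondence and the Q score

Comparing interfaces of *different* proteins requires mapping residues
to a common coordinate system. Profile-HMM match positions provide it:
each domain annotation carries a residue→match-position map, and a pair
of interfaces is comparable through the HMM iff the model covers at
least 80% of the shorter side (`hmm_cov_min`). Identical sequences fall
back to the sequence-position correspondence. Pairs with neither
correspondence have **undefined Q**; they contribute 0 to linkage
averages, so incomparable interfaces can never drive a merge yet do not
shrink the matrix.

With unit weights the similarity is a Jaccard index over mapped
contact-pair sets: Q = |C₁∩C₂| / |C₁∪C₂|, 1 for an identical
interaction mode, 0 for no shared contacts. A weight hook exists for
non-uniform pair weights, but the default is pure Jaccard because it
reproduces both definitional boundary values exactly and keeps the
score auditable. Homodimer interfaces have no canonical side labels, so
both side-orderings are evaluated and the maximum taken — Q must not
depend on which chain was called A. At chain level, multi-domain
architectures concatenate the per-domain maps in architecture order,
labeling positions (architecture rank, family, match position); this is
an interpretation choice — a single chain-level alignment would be the
alternative — and is isolated behind `build_correspondence()`.

## Clustering

Average-linkage agglomeration: every interface starts as a singleton;
at each step the two clusters with the highest average pairwise Q merge,
as long as that average is ≥ 0.30 (`q_cluster`); ties break toward the
pair whose sorted member labels sort first, making the procedure
deterministic. Because average-linkage merge heights are monotone, this
greedy rule is equivalent to cutting the average-linkage dendrogram of
1 − Q at height 0.70, which is exactly how the tests cross-check it
against `hclust()` on random matrices. Clusters are annotated with the
evidence counts — crystal forms, entries, distinct proteins, minimum
pairwise sequence identity (global alignment, matches over alignment
columns), mean buried area, and the fractions of members present in
author and PISA assemblies.

## Crystal forms

Entries share a crystal form iff they have (1) the same entry-level
architecture signature, (2) the same space group, (3) the same
asymmetric-unit protein stoichiometry, and (4) all six cell parameters
within 1% (per parameter, |x₁−x₂|/max(x₁,x₂) ≤ `cell_tol`). The
signature is the *set* of distinct chain architectures: copy counts
belong to condition (3), and a monomer-ASU entry must share its
signature with the corresponding dimer-ASU entry or the merge rule
below could never apply. The 1% relation is not transitive, so forms
are defined as connected components — deterministic and order-free.
Finally, two forms whose representative interface censuses match
greedily (best Q first) for at least two thirds of the smaller census at
Q ≥ `q_high` are merged to a fixpoint; this collapses the same physical
crystal solved once as a monomer ASU in a screw group and once as an
explicit dimer in P1.

"Highly similar" is quantified as Q ≥ 0.85 (`q_high`): well above the
0.30 cluster threshold, below identity, and configurable; the same
value decides whether a biological assembly *contains* an enumerated
interface.

## Peptides, ligands, nucleic acids

A **peptide** is a polypeptide chain with full polymer length
(including unmodeled residues declared in the entity) strictly below 30;
the boundary is exact and tested at 29/30. The domain–peptide rule
differs from the chain rule in one place: the clauses are joined by
**or** (≥ 10 Cβ pairs within 12 Å *or* ≥ 5 atomic contacts within 5 Å),
so shallow groove binders with no sub-5 Å contact still register. A
peptide touching several chains is assigned to the chain holding ≥ 75%
of its atomic contacts, otherwise all its interfaces are kept. Peptide
interfaces of one family cluster greedily by the (average) number of
shared HMM contact sites, subject to N<sub>hmm</sub> ≥ 3 and
RMSD<sub>pep</sub> ≤ 10 Å. RMSD<sub>pep</sub> is the minimum peptide Cα
RMSD over all *ungapped* sequence alignments (minimum overlap 3, both
peptides N→C) measured after superposing the domains — not the peptides
— on their common HMM positions. Two readings were possible here; the
domain-frame reading is implemented because the clustering intent is
binding-site location: refitting the peptides to each other would let a
helix bound on the opposite face score 0. Gapped alignments are not
scanned; with a 10 Å acceptance tolerance, offsets are sufficient.

**Ligands** are all non-polymer components except water; an interaction
is ≥ 1 atomic contact within 4.5 Å, computed on the asymmetric unit.
Covalent ligands and modified residues count like any other non-polymer.
Per family, ligand instances cluster by average-linkage on the Jaccard
overlap of contacted HMM positions with threshold 0.5
(`ligand_site_jaccard`) — the protocol specifies clustering "by shared
positions" without quantifying the similarity, so a symmetric,
scale-free choice was made and exposed as configuration. **Nucleic
acids** run through the same contact machinery but are evaluated within
the biological assemblies; for each domain instance only the interface
with the most contacted HMM positions is kept (ties: smaller assembly
id, then chain id), with an asymmetric-unit fallback (and warning) when
no assembly exists.

# The synthetic-data generator

`generate_toy_fold()` builds stylized ideal-geometry folds: α-helical
backbone (N, Cα, C, O) with 1.5 Å rise and 100° twist — consecutive
Cα–Cα ≈ 3.8 Å — and Cβ placed radially outward. Sequences are sampled
from the 19 non-glycine residue types so every residue carries a Cβ;
glycine handling is tested separately with hand-built fixtures. The
crystal generator uses a two-helix **hairpin** topology: the designed
C2 dimer forms through the helix-2 face, while lattice packing is
engineered on helix 1 by shrinking exactly one cell direction until a
real packing contact appears (≥ 6 atom pairs within 5 Å, no clash below
3 Å). This mirrors the condition the method exploits in real data —
a conserved dimer plus form-specific packing — and keeps the two
contact classes on structurally distinct faces. With a single helix the
two classes overlap within the 12 Å Cβ reach and their Q hovers at the
clustering threshold; real folds, like the hairpin, have more surface
than interface.

Generator defaults and why:

* `n_res = 40` residues per chain, `d = 9.8` Å inter-axis separation of
  the designed dimer: buries ≈ 190 Å² per side, comfortably above both
  area cutoffs while remaining a "weak-dimer"-sized interface.
* `mutation_rate = 0.25` between homolog forms: pairwise identities of
  ~60–75%, far from identical (so HMM correspondence is genuinely
  exercised) but trivially homologous.
* 3 crystal forms by default, each with its packing contact along a
  different cell direction (x, y, z) — packing interfaces share
  essentially no mapped contact pairs between forms.
* The P2₁ variant places one chain so the screw mate completes the
  designed dimer: the biological interface is absent from the
  asymmetric unit and appears only after lattice expansion — the core
  motivation of the method.
* Identical spec + seed ⇒ bit-identical files; every emitted mmCIF
  re-parses without warnings.

What the generator does **not** emulate: real side-chain packing and
rotamers, solvent, conformational differences between crystal forms
(all homologs share one backbone), experimental noise, missing
residues, and Pfam-style annotation errors. Passing tests therefore
demonstrate the correctness of the rules and the bookkeeping — contact
detection, symmetry handling, correspondence, clustering, evidence
counts — not robustness to coordinate error or annotation noise in real
depositions.

# Numerical choices

* Fractional↔orthogonal conversion follows the standard crystallographic
  convention (a along x, b in the xy plane). Identity placements are
  returned bit-equal, not multiplied through the matrices.
* Distance cutoffs are inclusive (≤), and the tests pin the boundaries
  with exactly representable coordinates (12.0/5.0/4.5 Å).
* Altlocs: the highest-occupancy conformer is kept; ties go to the
  alphabetically first code. Deterministic single-conformer contacts.
* Kabsch superposition via SVD with the determinant correction for
  proper rotations; ≥ 3 common positions required. The test oracle is a
  quaternion-method implementation, agreeing to 1e-6 Å.
* SASA is clamped at zero; the non-negativity of buried area is a
  numerical guarantee, not an assumption.
* Greedy average linkage uses maintained cluster-pair sums, an exact
  (not approximate) evaluation of cross-cluster averages.
* Sequence identity uses Needleman–Wunsch (match 1, mismatch −1, gap
  −2), identity = matches / alignment columns.

Problem sizes in the test-suite: random-fixture contact fuzzing uses
~100 chains of 8–12 residues against a double-loop oracle; the
clustering reference check runs 200 random similarity matrices of up to
50 items against `hclust`; the end-to-end benchmark uses 3 + 1 crystal
forms of 40-residue chains. These sizes exercise every code path while
keeping the default suite fast enough to run routinely.

# Known limitations

* The space-group table covers the common primitive groups the
  generator emits (P1, P2, P2₁, C2, P222, P2₁2₁2, P2₁2₁2₁, P4); any
  other group must carry explicit operator records in the file, which
  deposited mmCIFs normally do.
* Cells are compared as deposited; no Niggli reduction, so equivalent
  cells in non-standard settings count as different crystal forms.
* Clan-level (superfamily) cross-family clustering is not performed;
  clan identifiers are carried as annotation only.
* The weighted-count hook defaults to unit weights; no empirically
  trained weighting is shipped.
* PDB-dialect input reconstructs sequences from modeled residues only
  (the format lacks entity sequences), so the peptide length rule can
  differ from the mmCIF reading for chains with unmodeled termini.
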