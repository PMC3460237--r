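---
title: "Methods: a hierarchical screening funnel for cation-binding pockets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical screening funnel for cation-binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the procedure

Orthosteric ligands of nicotinic acetylcholine receptors and their
water-soluble surrogates (acetylcholine-binding proteins, AChBPs) almost
universally carry a cationic nitrogen that forms a cation-pi interaction
with a conserved binding-pocket tryptophan. `pocketfunnel` implements a
hierarchical in silico screening cascade built around that anchor point:

1. **Library standardization** — counter-ion/solvent removal, deterministic
   protonation of strong bases and deprotonation of strong acids, and
   selection of ligands with at least one cationic center (quaternary or
   protonated nitrogen).
2. **Protein-derived pharmacophore screen** — a query consisting of one
   cationic feature sphere (at the position of the bound reference
   agonist's basic nitrogen, radius 2.5 Å) plus excluded-volume spheres of
   radius 0.8 Å on every heavy atom of the residues within 7.0 Å of the
   bound ligand. Pre-generated conformers are matched rigidly.
3. **Stereoisomer enumeration** — unassigned stereocenters of the
   survivors are expanded combinatorially before docking, because common
   docking programs do not enumerate chirality themselves.
4. **External docking hand-off** — the package exports an SDF and
   re-imports scored poses; docking itself (and its scoring function) is
   deliberately out of scope and treated as an opaque oracle.
5. **Post-docking filters** — poses are kept only if the minimum distance
   from a cationic nitrogen to the reference tryptophan ring (atom CD2 as
   centroid proxy) is at most 5.5 Å, every heavy atom lies inside the
   binding-pocket sphere, and no intra- or intermolecular steric clash is
   present. Hydrogen bonds (e.g. to the tryptophan backbone carbonyl or a
   loop-A tyrosine hydroxyl) are annotated but never required.
6. **Ranking and shortlist** — per-ligand pose cap (3), global sort by
   external score, deterministic tie-breaks; the shortlist replaces manual
   visual inspection with a fully reproducible, annotated table.
7. **Novelty screen** — circular-fingerprint (ECFP-4-class) Tanimoto
   similarity against a user-supplied set of known ligands; candidates at
   or above 0.40 are flagged as chemically known.

The package also implements the structural comparison used to justify the
template choice: global sequence alignment of two ligand-binding-domain
chains, closed-form least-squares (Kabsch) superposition on the matched
Cα pairs, and a per-residue RMSD profile with a 2 Å divergence flag.

# Key parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| excluded-volume radius | 0.8 | Å | smaller than the carbon vdW radius, so the pocket is effectively enlarged to absorb induced-fit effects; because the tolerance is baked into this radius, ligand atoms are treated as points |
| feature radius | 2.5 | Å | allowed displacement of the cationic nitrogen from the reference agonist's basic nitrogen |
| residue shell | 7.0 | Å | any-heavy-atom distance from any bound-ligand heavy atom; all heavy atoms of selected residues become excluded volumes |
| cation-pi cutoff | 5.5 | Å | minimum cationic-N-to-CD2 distance; poses *above* the cutoff are discarded, so a pose at exactly 5.5 Å is kept. CD2 is the default centroid proxy; an option measures to the true six-ring centroid |
| pocket sphere | 10 + 2 | Å | containment radius (the docking-pocket definition, 10 Å around the tryptophan NE1) plus a margin; this operationalizes the visual "outside the binding pocket" judgment |
| clash scale | 0.7 | × vdW sum | a pair closer than 0.7 × (r_i + r_j) is a clash; chosen so ideal bonded geometry never flags 1-4 pairs, with intramolecular checks restricted to pairs ≥ 4 bonds apart |
| H-bond criteria | 3.5 / 120 | Å / deg | donor-acceptor distance and D-H…A angle |
| ECFP threshold | 0.40 | Tanimoto | known/novel boundary for the novelty triage |
| stereo cap | 5 | centers | at most 2⁵ = 32 isomers per compound |

Boundary semantics are uniform: distances exactly equal to a cutoff count
as inside.

# Design decisions

**Protonation by rules, not pKa.** "Strong acid" and "strong base" are
fixed, auditable graph rules (carboxylic/sulfonic/sulfinic/phosphonic
acids and tetrazoles; aliphatic amines that are neither amide- nor
aniline-conjugated; amidines and guanidines; quaternary nitrogens stay
+1). The rule list is an explicit function argument
(`default_charge_rules()`), so users can extend it. Formally positive
nitrogens inside neutral groups (nitro, N-oxide, azide) are excluded from
the cationic-center count. Zwitterions count as cationic when at least
one N⁺ remains. The rules are implemented as R predicates over the
atom/bond graph rather than SMARTS strings because no installed toolkit
exposes SMARTS matching *with atom maps* to R; the semantics are the
same and each rule is independently testable.

**Certified pharmacophore matching.** The matcher enumerates anchor
positions of the cationic nitrogen on a 0.5 Å grid inside the feature
sphere, crossed with a deterministic low-discrepancy rotation grid
(nominally 30°), followed by a greedy clash-count descent. A match is
returned together with its placement, and `verify_placement()` re-checks
that certificate exactly, with no search. Unmatched verdicts on the
bundled fixtures are *provable*: fixture cavities are either roomy enough
that a centered placement trivially fits, or are built so that no
placement can exist (a sealed double-shell wall whose excluded volumes
leave no gap wider than their own radius, with a ligand longer than the
free inner diameter; or a feature sphere fully plugged by volumes). The
independent oracle (`match_linear_oracle`) brute-forces direction ×
anchor grids for the linear rigid fixture ligands and shares no code
with the matcher.

**Conformers.** The default backend embeds one 3D structure per molecule
with a seeded distance-geometry method (RDKit ETKDG via a small bundled
python helper — deterministic under the seed) and then drives every
rotatable bond systematically in 120° steps, discarding rotamers with
1-5+ self-clashes and de-duplicating at 0.5 Å superposed heavy-atom
RMSD. When no python/RDKit is present, OpenBabel's generator is used
instead; it is not seedable, which sacrifices byte-reproducibility but
not correctness. Conformer energies are never computed: geometry is all
the funnel consumes, and force-field minimization is out of scope.

**Stereochemistry is bookkeeping, not CIP.** Stereocenters are detected
as tetrahedral carbons whose four substituent branches have distinct
canonical-refinement signatures; enumeration assigns parity tags
combinatorially (2ᵏ, capped). Meso-compound duplicate elimination and
per-diastereomer 3D feasibility pruning are not implemented — with no
stereo-aware canonical-identity machinery available, expansion counts
are upper bounds for molecules with internal symmetry. The funnel
records pre- and post-expansion counts separately, since this is the only
count-increasing stage.

**Superposition pairing is explicit.** The Cα pairing is always an input;
a helper derives it from a global sequence alignment (BLOSUM62, affine
gaps) taking match states where both chains have a Cα atom. This makes
the main pairing ambiguity of any cross-structure RMSD — *which* residues
correspond — visible and testable instead of burying it in a black box.
The per-residue profile flags pairs at ≥ 2 Å, the conventional divergence
highlight for binding-pocket inspection.

**Hydrogens.** Receptor preparation removes all hetero records and places
polar hydrogens with idealized geometry only (backbone N-H, Ser/Thr/Tyr
hydroxyls oriented toward the nearest acceptor, Trp indole N-H, Asn/Gln
amides). No minimization is performed; hydrogen-bond detection needs only
plausible polar H positions, and heavy-atom geometry is never touched.

**Determinism.** Every stochastic component takes a seed; rotation grids
come from a Halton quaternion sequence; ties break on stable keys.
Manifest files contain no timestamps (wall-clock lines go to the log
stream), so identical config + seed reproduces byte-identical outputs.

# What the synthetic fixtures do and do not show

The fixture generators build spherical-shell cavities with a
tryptophan-like probe group, minimal cationic ligands, planted cation-pi
distances (exact to the SDF coordinate precision, which the generator
quantizes *before* computing its truth table), planted hydrogen-bond
geometries, and a 20-ligand library whose stage-by-stage funnel counts
are known by construction. They validate geometry, filter logic,
bookkeeping, determinism and monotonicity. They do **not** validate
chemical realism: shells are pseudo-atoms, fixture ligands are three-atom
cations, and the sealed-wall construction has no biological counterpart.
Passing these tests therefore shows the machinery is correct, not that
any particular receptor model will enrich actives.

Two further caveats. Circular-fingerprint implementations are not
bit-compatible across software, and hashed fingerprints of very small
symmetric molecules set few bits, which inflates their pairwise Tanimoto
values; reported similarity values should only be compared within one
implementation, which is why the printed hit scores of the original
campaign are shipped as classification inputs rather than recomputed.
Second, the reference binding-domain comparison (chimeric α7/Ls-AChBP
protein, PDB 3SQ6, vs Ls-AChBP, PDB 1UW6; ≈1.7/1.8 Å over ≈204 Cα pairs
per face) requires those public structures, which are not redistributed;
`compare_binding_domains()` performs the full analysis once the user
downloads them (see the README), and the corresponding acceptance test
reports failure rather than silently skipping when they are absent.

# Problem sizes

The bundled test and acceptance workloads use 20 matcher fixtures
(≤ 6-atom rigid ligands, 80-900 excluded volumes), 55 planted poses, a
20-ligand funnel run twice for the byte-identity check, and 100 random
fingerprint pairs: sizes chosen so the full suite exercises every code
path at desk-scale cost while the same code handles library-scale inputs
by iteration.

# Known limitations

* No tautomer enumeration, pKa prediction, partial charges or force-field
  minimization (all deliberately out of scope).
* Stereo enumeration over-counts molecules with internal symmetry and
  does not prune geometrically infeasible fused-ring diastereomers.
* The containment sphere is an operationalization of a visual judgment;
  its center/radius are configurable, not derived.
* `match_conformer` is a certified *search*: a matched verdict is exact
  (certificate re-verified), an unmatched verdict is exhaustive only up
  to the grid resolution. Resolution-doubling stability is part of the
  test suite; pathological near-boundary cases can still flip.
* Multi-feature pharmacophores (aromatic, H-bond features) are not
  supported; the query is one cationic feature plus excluded volumes.
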