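# pocketfunnel

Hierarchical structure-based virtual screening for cation-binding pockets
— the kind of funnel used to find novel ligands of nicotinic
acetylcholine receptors and their soluble AChBP surrogates, where nearly
every agonist anchors a cationic nitrogen against a conserved
binding-pocket tryptophan.

The package provides, as composable R functions with a thin CLI:

* **Structure handling** — PDB/mmCIF reading with altloc resolution,
  receptor preparation (hetero stripping, idealized polar hydrogens),
  pocket extraction by distance shell;
* **Binding-domain comparison** — alignment-derived Cα pairing,
  closed-form least-squares (Kabsch) superposition, per-residue RMSD
  profiles with a 2 Å divergence flag;
* **Ligand preparation** — rule-based standardization (strong acids
  deprotonated, strong bases protonated, counter-ions dropped),
  cationic-center triage, stereoisomer enumeration, deterministic
  conformer generation;
* **Pharmacophore screening** — a protein-derived query of one cationic
  feature sphere (radius 2.5 Å) plus 0.8 Å excluded volumes on all heavy
  atoms of the residues within 7 Å of the bound reference agonist, with a
  certified rigid-placement search (every match carries a re-verifiable
  placement);
* **Post-docking filters** — cation–π distance to the tryptophan ring
  (keep at ≤ 5.5 Å to atom CD2), pocket containment, steric-clash
  rejection, geometric hydrogen-bond annotation (3.5 Å / 120°), ranking
  with per-ligand caps and a deterministic shortlist;
* **Novelty triage** — radius-2 circular fingerprints (ECFP-4 class) and
  Tanimoto similarity against a known-ligand reference set, known/novel
  classification at 0.40;
* **Funnel orchestration** — a config-driven pipeline with a stage
  manifest in which `input = output + logged rejections` holds at every
  stage and identical config + seed reproduces byte-identical outputs;
* **Fixture generators** — synthetic pockets, pose sets and libraries
  with *planted, provable* outcomes, so the whole funnel is testable
  offline.

Docking itself is out of scope by design: the funnel exports an SDF for
an external docking program and re-imports scored poses, treating the
scores as opaque.

## Worked example

```r
library(pocketfunnel)

# a self-contained synthetic campaign: 20-ligand library, sealed toy
# pocket, planted docking poses
fx  <- make_funnel_fixture("funnel_demo", seed = 7)
res <- run_funnel(fx$config)
print(res)
#> FunnelManifest (8 stages):
#>                 stage          unit n_in n_out                           params
#>           standardize       ligands   20    20
#>    cationic_selection       ligands   20    14
#>  pharmacophore_screen       ligands   14    12               spacing=0.5,rot=45
#>     stereo_enumeration stereoisomers   12    18                    max_centers=5
#>        pose_ingestion         poses   20    20
#>          post_filters         poses   20    14 capi<=5.5,contain=10+2,clash=0.7
#>             shortlist         poses   14    10                   top_n=10,cap=3
#>        novelty_screen       ligands    7     5                    threshold=0.4
```

Reading the funnel: of 20 input molecules, 14 carry a cationic nitrogen;
12 of those fit the excluded-volume pharmacophore (the two rigid
oversized cations provably cannot); stereo enumeration expands 12
compounds to 18 stereoisomers (1.50 per compound); all 20 planted poses
load, 14 survive the cation–π/containment/clash filters (exactly the
poses planted at ≤ 5.5 Å), the top 10 by score are shortlisted, and of
the 7 distinct compounds behind them, pyrrolidine — which is itself in
the reference set — is classified as a known chemotype while 5 remain
novel.

The same functions run on real inputs, e.g.:

```r
cmp <- compare_binding_domains("3SQ6.pdb", "1UW6.pdb",
                               chains_ref = c("A", "B"),
                               chains_mob = c("A", "B"))
```

reproduces the chimera-vs-AChBP comparison (≈ 1.7 Å principal face /
≈ 1.8 Å complementary face over ≈ 204 Cα pairs, with all binding-pocket
residues under 2 Å) once the two public PDB entries are downloaded —
they are not redistributed with the package. Place them under
`inst/extdata/` (or set `options(pocketfunnel.structure_dir = ...)`) to
activate the corresponding acceptance test.

A command-line front-end covering the same operations is installed at
`inst/scripts/pocketfunnel` (`compare`, `pharm-build`, `pharm-screen`,
`poses-filter`, `novelty`, `fixtures`, `run`).

## Method documentation

`vignettes/pocketfunnel-methods.Rmd` describes the model and its
assumptions, all tunable parameters with units and defaults, the
provable fixture constructions, numerical choices (boundary semantics,
tie-breaks, seeds) and known limitations.
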