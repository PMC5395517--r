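# pocketmap

Ligand-independent detection, comparison and mapping of potential
small-molecule binding sites on protein structures, in R.

Most structure-based analyses start from a known, ligand-occupied
binding site. `pocketmap` implements the complementary workflow for the
*unliganded* structural proteome:

1. **Detect** cavities geometrically: *alpha spheres* — empty spheres
   tangent to four atoms, the circumspheres of the Delaunay complex of
   protein heavy atoms — filtered to radii in [3, 6] Å and clustered by
   single linkage at 3 Å into candidate pockets (minimum 3 spheres).
2. **Patch** each pocket: the cavity's surface-exposed tangent atoms act
   as a *pseudo-ligand*, and the binding-site patch is every surface
   protein atom within the 0.3 Å *site size* of it (with a bound ligand,
   the patch is instead all surface atoms within 4 Å of the ligand).
   Patches carry shape points (surface-atom centers) and pharmacophore
   pseudocenters of five types: donor, acceptor, anion, cation,
   hydrophobe.
3. **Compare** patches by maximizing atom-centered Gaussian overlap over
   the six rigid degrees of freedom. With Tanimoto-normalized overlaps
   for geometry ("shape") and type-matched pseudocenters ("color"),

   **PatchScore = 3 · T_color + 1 · T_shape ∈ [0, 4]**

   (0 = completely dissimilar, 4 = identical; the symmetric Tanimoto
   makes size matching inherent).
4. **Evaluate** retrieval: ROC/AUROC, enrichment factor at 5%, and
   BEDROC at α = 20, with per-structure true-positive deduplication.
5. **Map** binding-site space: conservation filter (≥ 5 PatchScores
   ≥ 2.0), within-target and global average-linkage clustering, DBSCAN
   (ε = 7, minPts = 10) with noise, cluster-pair link tables
   (highlighted at PatchScore ≥ 2.0), heat-map and Circos-compatible
   exports.

A deterministic synthetic-structure generator (`make_pocket_protein`)
builds toy "pocket proteins" — atom shells with carved,
pharmacophore-lined cavities, placed pseudo-ligands and full ground
truth — so the entire pipeline is testable without downloading any
structure database. An fpocket output-directory parser provides
interoperability with externally detected pockets (conventional Score
threshold 16.8, applied only to parsed fpocket scores).

## Worked example

```r
library(pocketmap)

# a toy protein with one pocket lined by donors, acceptors and hydrophobes
spec <- pocket_spec(center = c(0, 0, 11), mouth_direction = c(0, 0, 1),
                    depth = 8, width = 7,
                    lining_types = c("donor", "acceptor", "hydrophobe"))
pp <- make_pocket_protein(pockets = list(spec), seed = 7)
pp$structure
#> Structure 'synth_s7' with 422 atoms
#>   ligand: 8, protein: 414

# alpha-sphere cavity detection
sp <- compute_alpha_spheres(pp$structure)
sp
#> alpha_spheres: 192 spheres, radius  3.01-5.99 A
cavs <- cluster_alpha_spheres(sp, structure_id = pp$structure$id)
match_cavity_to_ligand(cavs, pp$structure, pp$ligand_atoms[[1]])
#> [1] "synth_s7_cav2"
```

The ligand-matched cavity is the planted pocket; its descriptors and
both patch flavours:

```r
cav <- cavs[[2]]
cavity_descriptors(cav, seed = 1)[c("n_spheres", "mean_radius", "mc_volume")]
#> n=16 spheres, mean radius 3.20 A, Monte-Carlo volume ~413 A^3

surf  <- surface_atoms(pp$structure)
p_cav <- patch_from_cavity(pp$structure, cav, surface = surf)
p_lig <- patch_from_ligand(pp$structure, pp$ligand_atoms[[1]], surface = surf)
p_cav
#> patch 'synth_s7_cav2_patch' (origin: cavity )
#>   16 shape points; 16 pseudocenters ( donor:6 acceptor:6 anion:0 cation:0 hydrophobe:4 )

p_lig
#> patch 'synth_s7_lig' (origin: ligand )
#>   22 shape points; 22 pseudocenters ( donor:8 acceptor:7 anion:0 cation:0 hydrophobe:7 )

align_patches(p_lig, p_cav)
#> patch alignment: PatchScore 3.007 (color 0.739, shape 0.790)
```

A PatchScore of 3.0 between the ligand-defined and the
cavity-defined patch of the *same* pocket (4.0 would be identity)
shows the ligand-independent route recovering the known site. From
many patches, `all_vs_all()` builds the similarity matrix and
`binding_site_map()` + `cluster_link_table()` turn it into clusters
and highlighted links; `write_map_outputs()` exports the heat-map
matrix, Circos karyotype/link files and a JSON summary.

A thin command-line front end with `synth` / `detect` / `patch` /
`compare` / `filter` / `cluster` / `map` / `eval` subcommands is
installed at `inst/cli/pocketmap.R`.

## Package layout

| Stage | File | Key functions |
| --- | --- | --- |
| structures | `R/structures.R` | `read_structure`, `atom_sasa`, `surface_atoms`, `superpose`, `quality_filter` |
| synthetic | `R/synthetic.R` | `make_pocket_protein`, `make_structure_family`, `make_labeled_ranking` |
| cavities | `R/cavities.R` | `compute_alpha_spheres`, `cluster_alpha_spheres`, `cavity_descriptors`, `cavity_score`, `calibrate_score_threshold`, `parse_fpocket_results` |
| patches | `R/patches.R` | `type_pharmacophores`, `patch_from_ligand`, `pseudo_ligand_atoms`, `patch_from_cavity` |
| compare | `R/compare.R` | `gaussian_overlap`, `overlap_tanimoto`, `align_patches`, `patch_score`, `all_vs_all` |
| retrieval | `R/retrieval.R` | `roc_points`, `auroc`, `enrichment_factor`, `bedroc`, `run_retrieval` |
| mapping | `R/mapping.R` | `conservation_filter`, `hierarchical_map`, `dbscan_map`, `binding_site_map`, `cluster_link_table`, `write_map_outputs` |

The methods vignette (`vignettes/binding-site-mapping.Rmd`) documents
the model, its tunable parameters, the numerical choices and the
limits of what the synthetic tests demonstrate.
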