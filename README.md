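# ligandscape

Quantitative tools for ligand-screening campaigns built on docking
output, aimed at medicinal and computational chemists comparing many
closely related ligands against one or more kinase targets.

The package grew out of a screening problem: a library of
polyhalogenated benzimidazole nucleosides (four glycone series — no
glycone, ribose, 2′-deoxyribose, 2′-deoxy-2′,2′-difluoro-ribose —
crossed with ten halogenation patterns at ring positions 4–7) docked
against the CK2α, PIM-1 and RIO1 kinases. It answers three recurring
questions:

1. **Where are the cliffs?** For a ligand pair with structural
   similarity *s* and activities *A₁, A₂*, the Structure–Activity
   Landscape Index is

   SALI = |A₁ − A₂| / (1 − s)

   and its docking analogue, the Structure–Binding Affinity Index, is
   SBAI = |BA₁ − BA₂| / (1 − s) with binding affinities in kcal/mol.
   Large values flag *activity cliffs*: small structural edits with
   outsized effect. The index diverges as *s* → 1, so plots and ranked
   tables carry a truncated copy (default cap 2000). Functions:
   `sali()`, `sbai()`, `pairwise_landscape()`, `detect_cliffs()`,
   `build_graph()` (network-like similarity graphs via igraph),
   `sbai_surface()`.

2. **How do binding modes differ?** A *binding-mode fingerprint* is a
   sparse per-residue (or per-ligand-atom) vector of interaction
   strengths. Two fingerprints P, Q aligned on the union of their keys
   are compared with Manhattan (Σ|pᵢ−qᵢ|), Euclidean (√Σ(pᵢ−qᵢ)²) and
   signed additive (Σ(pᵢ−qᵢ)) distances, and with the root-mean-square
   binding-mode deviation

   RMSD_BM(P, Q) = √( (1/n) Σᵢ (pᵢ − qᵢ)² ).

   Functions: `binding_fingerprint()`, `rmsd_bm()`, `mode_distance()`,
   `rank_keys()`, `build_heatmap()`.

3. **Which contacts and how flexible?** `load_complex()` +
   `detect_hbonds()` / `detect_halogen_bonds()` / `detect_hydrophobic()`
   find noncovalent interactions from geometric criteria (hydrogen bond:
   donor–acceptor ≤ 3.6 Å and D–H⋯A ≥ 120° for the strong class, with a
   weak envelope to 4.1 Å / 90°; halogen bond: X⋯A ≤ 3.8 Å with a
   near-linear C–X⋯A σ-hole angle ≥ 140°; hydrophobic: apolar C⋯C ≤
   4.0 Å). `extract_bfactors()`, `normalize_profile()`,
   `delta_profile()` and `flex_heatmap()` turn B-factor or RMSF profiles
   into per-residue flexibility difference maps.

The docking energy decompositions for the three targets ship with the
package (`load_packaged_tables("ck2a" | "pim1" | "rio1")`), and
synthetic fixture generators (`synth_complex()`, `synth_landscape()`)
plant interaction geometries and affinity cliffs at prescribed
parameters for testing and calibration.

## Worked example

```r
library(ligandscape)

ck2a <- load_packaged_tables("ck2a")       # 40 ligands, energies in kcal/mol
lib  <- enumerate_designed_ligands()       # the same 40 ligands as structures
sim  <- similarity_matrix(lib, measure = "circular")

pairs <- pairwise_landscape(ck2a, sim, cap = 2000)
summary(pairs)
#> landscape pairs: 780
#> similarity range: 0.060..0.815
#> infinite-index pairs: 0
#> top finite index: 5.584

detect_cliffs(pairs, s_min = 0.6, top_fraction = 0.02)
#>                    id_a                    id_b         s d_val    index
#> 1 56-diI-47-diBr_ribose 56-diI-47-diBr_difluoro 0.6034483  1.98 4.993043
#> 2 56-diBr-47-diI_ribose 56-diBr-47-diI_difluoro 0.6034483  1.81 4.564348
```

The top affinity cliffs are ribose→difluoro glycone swaps at fixed
halogenation: among structurally similar pairs, replacing the ribose
with the 2′,2′-difluoro sugar shifts the docking affinity by ~2 kcal/mol
— the same substitution the packaged tables single out by extremum:

```r
series_extremum(ck2a, series = "difluoro", field = "binding_affinity",
                mode = "min")
#> $ligand: "4567-tetraI_difluoro"   $value: -9.59
```

Binding-mode comparison on the energy components:

```r
fps <- energy_fingerprints(ck2a)
rmsd_bm(fps[["4567-tetraBr_deoxyribose"]], fps[["4567-tetraI_difluoro"]])
#> [1] 3.912959
mode_distance(fps[["4567-tetraBr_deoxyribose"]],
              fps[["4567-tetraI_difluoro"]], "additive")
#> [1] -10.8     # negative: the difluoro ligand binds more strongly overall
```

A command-line entry point wrapping the same functions lives at
`inst/cli/ligandscape` (subcommands `profile`, `compare`, `landscape`,
`surface`, `flex`, `simulate`; YAML config via `--config`).

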