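# triazolamer

NMR-restraint-driven conformational analysis of 1,4-disubstituted
1H-1,2,3-triazole **peptidotriazolamers** — hybrid foldamers in which every
second amide bond of a peptide is replaced by a triazole ring, side chains
conserved. The package is aimed at structural chemists and modellers who
want the classical NOE-restrained structure-determination workflow for such
oligomers as tested, reusable, fully deterministic code.

## What it implements

* **Molecule model** — parsing of the field's sequence notation
  (`Boc-Ala-ValΨ[4Tz]Phe-…-OAll`, ASCII aliases `psi[4Tz]`/`~[4Tz]`,
  `d-` prefixes, repeats `(…)n`), a coarse-grained topology with
  triazole-aware backbone torsions (4n: φ = C–N–CA–C4, ψ = N–CA–C4–C5;
  4c: φ = C5–N1–CA–C, ψ = N1–CA–C–N), an exact internal-coordinate builder
  (rigid planar triazole, trans amides), and chirality measurement.
* **ROESY → restraints** — isolated-spin-pair calibration
  r = r_ref·(I_ref/I)^(1/6) and AMBER-style flat-bottom upper-bound
  penalties E = k·max(0, r − r_upper)² with k = 32 kcal·mol⁻¹·Å⁻².
* **Restrained simulated annealing** — single-torsion Metropolis Monte Carlo
  (the desk-scale stand-in for restrained gas-phase MD) over the staged
  protocol 10→600→0 K totalling 900 ps, run as replica campaigns
  (100 parallel runs by default), bit-reproducible under seeds.
* **Iterative restraint pruning** — restraints whose per-replica-minimum
  penalty exceeds 5 kcal/mol are flagged as spectral-interpretation
  artifacts and deactivated until convergence.
* **Trajectory analytics** — Kabsch superposition RMSD (proper rotations
  only), radius of gyration, Ramachandran-style φ/ψ distributions,
  average-linkage hierarchical clustering on backbone RMSD (10 clusters,
  medoid representatives, merging of near-identical clusters), and radial
  distribution functions (0.1 Å bins, bulk-water density normalization).
* **Synthetic data with ground truth** — template conformers (helix,
  extended, twisted-S), two-state trajectory mixtures, r⁻⁶ forward-modelled
  ROESY tables with log-normal noise, ideal-gas RDF inputs, and planted
  contradictory restraints.
* **Pipeline + CLI** — `run_pipeline()` chains everything under a manifest
  with config hash and checksums; `plan_campaign()` enumerates molecule ×
  solvent × replica matrices; `inst/scripts/triazolamer-cli` exposes
  subcommands (`build`, `simulate-data`, `peaks2restraints`, `plan`, `run`,
  `summarize`).

The model is torsion-space only and the stand-in energy is *not* a force
field: green results validate the protocol machinery on synthetic worlds,
not chemistry. See the methods vignette
(`vignettes/triazolamer-methods.Rmd`) for the model, parameter meanings,
design decisions and limitations.

## Worked example

Recover a helical fold from synthetic NOEs:

```r
library(triazolamer)

topo <- parse_sequence("Boc-Ala-ValΨ[4Tz]Phe-LeuΨ[4Tz]Phe-LeuΨ[4Tz]Val-OAll")
topo
#> foldamer_topology: 7 residues, 3 triazole rings, caps Boc/OAll
#>   66 atoms, 68 bonds; backbone selection: 24 atoms (N, C_O, CA, ring_N1, ring_N2, ring_N3)
#>   positions: A1 V4n2 F4c4 L4n5 F4c7 L4n8 V4c10

helix <- template_torsions("helix", topo)
conf  <- build_conformation(topo, helix)
radius_of_gyration(conf)          # compact fold: 6.03 A over the backbone

peaks <- forward_roesy(conf, sigma_log = 0.1, seed = 1)
sum(!peaks$is_ref)                # 30 cross-peaks within the 5 A NOE cutoff

d    <- peaks_to_distances(peaks)
rset <- distances_to_restraints(d[d$role_a != "calibration", ])  # k = 32

out <- refine(topo, rset, default_sa_schedule(steps_per_ps = 25),
              n_replicas = 20, base_seed = 1)
out$converged; out$iterations
#> TRUE, after 1 iteration(s): no restraint exceeded the 5 kcal/mol ceiling

sel  <- backbone_selection(topo)
rmsd <- sapply(out$results, function(r)
  kabsch_superpose(r$conformation$coords[sel, ], conf$coords[sel, ])$rmsd)
min(rmsd)
#> 1.17  — best-replica backbone RMSD to the generating template, in Angstrom

finals <- trajectory(topo, lapply(out$results, `[[`, "conformation"))
cl <- merge_similar_clusters(cluster_frames(finals, n_clusters = 5))
round(cl$populations, 2)
#> 0.95 0.05  — 19 of 20 replicas land in one merged conformational cluster
```

The numbers mean: 30 synthetic NOE upper bounds suffice to fold the extended
chain back to within 1.17 Å (backbone RMSD) of the helical template that
generated them, no restraint is pruned (the set is self-consistent), and the
replica finals collapse into a dominant cluster with 95 % population.

End-to-end, with artifacts written under a manifest:

```r
cfg <- pipeline_config("Boc-Ala-ValΨ[4Tz]Phe-LeuΨ[4Tz]Phe-LeuΨ[4Tz]Val-OAll",
                       seed = 42)
bundle <- run_pipeline(cfg, "out/heptamer")
summarize_pipeline(bundle)   # populations, Table-1-style φ/ψ, RMSD/ROG stats
```

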