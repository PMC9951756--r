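# dietniche

Dietary niche overlap analysis for DNA metabarcoding data.

`dietniche` implements, as a tested and reusable R pipeline, the analysis
chain used to quantify foraging competition between sympatric herbivores
(e.g. free-ranging cattle and sika deer) from fecal plant metabarcodes: from
tagged ~100 bp psbCL amplicon reads, through MOTU count tables, to
relative-read-abundance (RRA) diet profiles, taxonomic and phylogenetic
diversity, niche-overlap statistics with randomization nulls,
PERMANOVA/NMDS ordination, and relative-abundance threshold sensitivity
sweeps. A first-class synthetic-data generator emulates the whole study
design — dual 7-bp sample tags, Dirichlet-multinomial diets, sequencing
errors, cross-contamination and extraction negative controls — so every
stage can be calibrated and validated against known ground truth.

## Who it is for

Molecular ecologists running herbivore (or other consumer) diet
metabarcoding studies who want the standard filtering chain and
niche-overlap statistics in one place, with explicit boundary semantics,
reproducible seeds, and null models whose size has been verified by
simulation.

## The statistics at the core

For species with samples `k = 1..S` and taxa `i = 1..T` with read counts
`n_ik`, the diet profile is the **relative read abundance**

    RRA_i = (1/S) * sum_k ( n_ik / sum_i n_ik ) * 100%

Diet breadth is summarised by Hill numbers `⁰D` (richness), `¹D`
(exponential Shannon), `²D` (inverse Simpson), Pielou's evenness
`J = ln ¹D / ln ⁰D`, and Levins' breadth `B = 1/Σp²` with its standardised
form `B_A = (B−1)/(⁰D−1)`; phylogenetic breadth by abundance-weighted MPD
and MNTD with standardized effect sizes (ses) against a tip-shuffle null.
Overlap between species `j` and `k` uses **Pianka's index**

    O_jk = Σ p_ij p_ik / sqrt( Σ p_ij² · Σ p_ik² )

tested against 10,000 random diets (RA3 row-reshuffle null), and
**Bray–Curtis similarity** `BC_sim = 1 − Σ|p_ij − p_ik| / Σ(p_ij + p_ik)`.
Community-level differences use one-factor PERMANOVA on Bray–Curtis
dissimilarity (pseudo-F by label permutation) and NMDS (Kruskal stress-1
by isotonic-regression majorization).

Upstream, reads pass the conventional filtering chain: pair merging,
mean-quality ≥ 40 filter, **exact** tag+primer demultiplexing,
dereplication, removal of sequences < 80 bp or with dataset-wide count
< 10, obiclean-style denoising (1-edit children at ≤ 0.5× a parent's
count are discarded unless they head their own sample), 100%-identity
taxonomic assignment against a closed reference, and removal of samples
with fewer reads than the negative controls.

## Worked example

```r
library(dietniche)

study <- simulate_study(seed = 42, mean_depth = 800)   # 47 deer + 32 cattle + 7 negatives
tab   <- attach_taxonomy(study$table, study$db)
tab   <- negative_control_filter(tab)$table            # contamination floor
tab   <- apply_threshold(tab, 0.01)                    # 1% working threshold

compute_rra(tab) |> dplyr::arrange(dplyr::desc(rra)) |> head(5)
#>   species   taxon     rra n_samples
#> 1 sika_deer motu001 19.0         47
#> 2 sika_deer motu002 18.0         47
#> 3 sika_deer motu003 11.8         47
#> 4 sika_deer motu004 11.3         47
#> 5 cattle    motu004  9.30        32

overlap_report(tab, n_iter = 10000, seed = 42)
#>   group_j   group_k      o_jk    p_null n_iter  bc_sim resolution
#> 1  cattle sika_deer 0.9137339 9.999e-05  10000 0.75351       motu

diversity_report(tab, tree = study$tree, n_null = 999, seed = 42)
#>     species D0   D1    D2     J   B_A MPD  sesMPD p_MPD   ...
#> 1    cattle 30 19.4 16.27 0.873 0.527 129 -0.0509 0.450
#> 2 sika_deer 24 11.0  8.66 0.754 0.333 124 -0.3462 0.356

d <- bc_dissimilarity_matrix(tab)
permanova(d, n_perm = 999, seed = 42)
#> PERMANOVA: pseudo-F(1,77) = 79.162, R2 = 0.507, p = 0.001 (999 permutations)
nmds(d, seed = 42)
#> NMDS (k = 2): stress = 0.1279, converged, 20 restarts
```

The estimated Pianka overlap (0.914) sits close to the analytic overlap
of the generating mean diets (0.921, in `study$truth$true_overlap`): the
generator's ground truth is what the parameter-recovery tests check
against. `threshold_sweep()` repeats the profile → diversity → overlap
chain over the 0.01%–1% threshold ladder, and `autoplot()` /
`plot_rra()` draw the standard figures. `run_diet_pipeline()` executes
everything above from one validated `pipeline_config()` and writes all
result tables plus a run manifest to a directory.

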