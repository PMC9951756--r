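---
title: "Methods: dietary niche overlap from metabarcoding counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary niche overlap from metabarcoding counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietniche)
```

`dietniche` turns tagged amplicon reads from herbivore feces into diet
profiles and niche-overlap statistics. This vignette is the package's
account of the models behind each stage, the parameters that matter, the
numerical decisions taken where the method leaves room, and what the
synthetic-data tests do and do not establish about real data.

## The generative model behind the synthetic data

The generator is first-class, tested code: it defines the conditions under
which every downstream statistic is validated.

Each non-control sample `k` of species `g` has a true diet
`p_k ~ Dirichlet(alpha_g)` over the reference MOTUs; the species' mean
diet is `alpha_g / sum(alpha_g)`. Read counts are multinomial at a
negative-binomial depth (`mean_depth`, size `depth_dispersion`), with a
`contamination_rate` fraction of each sample's reads drawn from a pooled
background — an equal-weight mixture of the two species' mean diets,
emulating cross-sample carryover. Negative controls receive *only*
background reads at a Poisson `negative_depth`. Reads are
`tag + forward primer + insert + revcomp(reverse primer) + revcomp(tag)`,
with every insert base substituted independently at `error_rate`;
qualities are generated independently of the simulated errors (flat
Phred 40 by default) so that the quality filter and the error model can
be tested separately. A paired mode cuts each merged read into R1/R2
with a fixed overlap to exercise the merge step.

Defaults mirror the study layout this pipeline was built around: 47 sika
deer + 32 cattle fecal samples, 7 extraction negatives, ~30 MOTUs in ~15
plant families, dual 7-bp tags with pairwise Hamming distance at least 3
(each sample twin-tagged), psbCL primers and ~100 bp inserts. The
published read totals only constrain a study-wide sum, not a per-sample
depth law, so the preset's `mean_depth = 1000` with dispersion 5 and
`negative_depth = 30` are the package's own choice of a realistic
mid-depth fecal run with strong per-sample variation; `error_rate =
0.001` and `contamination_rate = 0.02` are typical post-merge point-error
and carryover scales. The species alphas encode a browser-shifted grazer:
both species concentrate on the same dominant dicot families with a rare
tail, cattle with the flatter (more even, broader) profile. The
family-clustered phylogeny option grafts shallow within-family clades
onto a Yule backbone, the topology under which a family-restricted diet
yields negative sesMPD.

The generator deliberately omits chimeras, PCR-cycle amplification bias
and indel sequencing errors (the denoiser still uses an edit distance
that counts indels). Tags and primers are never hit by simulated errors:
the per-read error model applies to the insert, which is what the
published per-read error arithmetic refers to. Consequently, passing the
parameter-recovery tests shows the chain is *self-consistent* — it
cannot show robustness to artefact classes the generator does not
produce.

Two routes produce counts: `simulate_reads()` (read-level) and
`simulate_motu_table()` (direct multinomial shortcut). Both draw counts
through one shared routine that visits samples in manifest order, so
with the same seed the read-level pipeline can be checked for *exact*
count equality against the table-level draw.

## The filtering chain and its boundary semantics

Every boundary is explicit and tested:

* **Merge** (`merge_pairs()`): best ungapped overlap ≥ `min_overlap`,
  score = matches − mismatches, ties to the longer overlap; conflicting
  positions take the higher-quality base, exact quality ties take R1
  (deterministic output); merged qualities are the position-wise
  maximum. Pairs with no overlap at ≥ 75% identity are dropped and
  counted.
* **Quality** (`quality_filter()`): the delegated aligner in the original
  toolchain scores alignments without defining a statistic; here
  "quality < 40 removed" is read as *mean per-base Phred < 40*, exposed
  as `min_score`. The boundary is an inclusive keep (mean exactly 40
  survives).
* **Demultiplex** (`demultiplex()`): tags *and* primers must match
  exactly — one mismatch anywhere unassigns the read. Both the given and
  the reverse-complement orientation are tried. Tags with pairwise
  Hamming ≥ 3 make single-error bleed-through impossible under this
  rule.
* **Length/count** (`length_count_filter()`): "< 80 bp removed" and
  "total < 10 removed" — so 80 bp and a total of exactly 10 survive.
* **Denoise** (`denoise()`): obiclean-style head/internal
  classification. Within each sample, sequence `s` points to a parent
  `t` when `editdist(s, t) ≤ 1` (substitutions *and* indels) and
  `count_s ≤ 0.5 · count_t`; heads (no parent in that sample) survive,
  and a sequence that is a head in *at least one* sample keeps all its
  counts. The cited tool leaves these parameters unstated in the source
  methods; `max_dist = 1`, `ratio = 0.5` and the head-in-≥1-sample rule
  follow that tool's documented semantics and are all exposed.
* **Negative controls** (`negative_control_filter()`): the floor is the
  *maximum* negative-control total — the strictest reading of "fewer
  reads than the negatives" — with the mean available as an option.
  Samples strictly below the floor are removed; negatives never appear
  in the output table.
* **Taxonomy** (`assign_exact()`): 100% identity against a closed
  reference FASTA. A live nucleotide-database BLAST at the 100% criterion
  is, for sequences present in the reference, equivalent in outcome to
  exact matching against that reference; the closed version makes tests
  hermetic. Truncated queries fully contained in a reference also count
  (mini-barcode reads may be clipped), switchable off. Unknown sequences
  are logged with counts and excluded.

## Profiles, thresholds, diversity

`apply_threshold()` zeroes counts whose share of their *sample's* total
is strictly below the threshold — the per-sample convention of the
methodological literature this filter comes from — leaving surviving
counts unrenormalised; a `global` scope is available as a switch. At the
boundary, a taxon at exactly the threshold survives. Thresholds nest:
the survivor set at a larger threshold is a subset of that at a smaller
one, which is what makes richness monotone along the sweep.

`compute_rra()` averages per-sample proportions (zero-total samples are
excluded from `S` with a warning; the source is silent on them) and
multiplies by 100; profiles sum to 100 by construction. The published
formula's inner index is read as the per-MOTU-per-sample count
`n_ik` — the surrounding text confirms the subscript, and the
depth-rescaling invariance test pins the interpretation.

Hill numbers, Pielou's `J` and Levins' `B` are computed on whichever
proportion vector they are given. Two conventions exist for group-level
values: pooled (on the group RRA profile) and per-sample (distribution
across samples). Published tables print single values per species yet
mark between-species significance, which requires per-sample
distributions; `diversity_report()` therefore emits the pooled metrics
plus the per-sample mean of `B_A`, and `compare_sample_diversity()`
carries the Wilcoxon tests. Note that `B = 1/Σp² = ²D` *identically*, so
a table whose `B_A` exceeds its `²D` cannot have computed both from the
same pooled vector; the package emits both conventions and does not try
to reproduce such a value.

Phylogenetic breadth uses abundance-weighted MPD
(`Σ_{i≠j} p_i p_j d_ij / Σ_{i≠j} p_i p_j`) and MNTD. Beware conventions:
some packages normalise weighted MPD by `(Σp)²` instead; the test suite
cross-checks against picante through the explicit `1 − Σp²` conversion
factor. The ses null shuffles tip labels uniformly (the
"taxa.labels"-style null), implemented by permuting index rows of a
precomputed patristic matrix; `ses = (obs − mean_null)/sd_null`, and the
p-value is the lower-tail rank of the observation among observation plus
nulls with ties counted toward the observed tail (conservative), so `p ∈
{1/(n+1), …, 1}` exactly. With a degenerate null (e.g. two taxa),
`ses` is reported missing and `p` from rank alone.

## Overlap and ordination

`pianka_null_test()` defaults to the RA3 algorithm — reshuffle each
row's values across taxa independently — the conventional default for
niche-overlap nulls when the source names only "random diets"; RA1, RA2
and RA4 are behind a flag for sensitivity analysis. The p-value carries
the add-one correction, so it can never be exactly zero and at 10,000
iterations bottoms out just below 10⁻⁴, matching "p < 0.001" reporting
granularity.

`permanova()` implements the one-factor decomposition
(`SS_total = ΣΣ_{k<l} D²/N`, within-group analogue per group, pseudo-F on
`g−1` and `N−g` df) with label permutation; on Euclidean distances of
univariate data it reproduces the classical ANOVA F exactly, which the
tests assert to 10 decimal places — that identity is the implementation's
oracle. One factor only, no strata, matching the single-predictor design.

`nmds()` minimises Kruskal stress-1 by alternating monotone regression
(in-package pool-adjacent-violators) with a Guttman-transform update.
Tie handling is primary (weak) by default — tied dissimilarities may fit
different distances, ties resolved toward the current configuration —
with secondary available; with heavily tied input, primary ties make
near-zero stress trivially attainable, which is the known degeneracy of
that choice, and the classical-scaling first start then decides the
returned geometry. Within a run the recorded stress trace is
non-increasing by construction (an iteration that would increase
stress-1 terminates the run); 20 restarts by default, the first from
classical scaling, the rest random under the run's seed. Stress values
from different datasets are not comparable targets: published stress
figures depend on their data and are not reproduction goals.

## Calibration and problem sizes

The test suite validates the statistics at sizes chosen to keep the full
run around a minute while leaving the Monte-Carlo assertions
well-powered: null-model size checks use 1000 replicates at 199
permutations/iterations (binomial 3-SE band 0.03–0.07 around α = 0.05),
ses-uniformity uses 500 replicates at 199 shuffles with a 10-bin χ²
goodness-of-fit at α = 0.01, and parameter recovery uses exact count
equality on an 18-sample read-level run plus an 80-sample, depth-2000
overlap-convergence check against the generator's analytic mean-diet
overlap within 3 Monte-Carlo SEs.

## Known limitations

* Exact (error-free) tag/primer matching discards every read with a tag
  or primer error; retention rates on real runs will be lower than the
  generator suggests, and company- or run-specific retention differences
  are out of scope.
* The closed-reference assignment cannot produce matches for taxa absent
  from the supplied FASTA; unknowns are logged, not rescued.
* The denoiser is per-sample and single-parent; it does not model
  chimeras or cumulative multi-step error paths.
* The Dirichlet-multinomial generator has no overdispersion beyond the
  Dirichlet layer and no taxon-specific amplification bias, so RRA's
  known quantitative biases on real data (primer mismatch, copy-number
  variation) are invisible to these tests.
* Replicate PCRs are assumed pooled before sequencing; replicate-level
  averaging is a no-op here.
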