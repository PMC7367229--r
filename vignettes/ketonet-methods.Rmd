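---
title: "ketonet: models, synthetic world, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ketonet: models, synthetic world, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ketosis is a metabolic disorder of transition dairy cows, diagnosed by
plasma β-hydroxybutyrate (BHBA) above 1.4 mmol/L in the weeks around
calving. Blood transcriptomes sampled pre- and post-partum from healthy and
ketotic cows give four physiological states (H_Pre, H_Post, K_Pre, K_Post);
plasma biochemistry (BHBA, TC, TG, HDL, LDL, Ca, INS) gives intermediate
phenotypes. Separately, large single-marker GWAS for health traits provide
per-SNP effect estimates `b` and p-values. `ketonet` connects the three
layers: co-expression modules from the transcriptomes, their association
with states and bio-indicators, and their enrichment for GWAS signal —
ending in candidate genes.

## Models and statistics

### Preprocessing

TPM divides each count by gene length in kilobases and scales each sample
to sum 10⁶; it is used only for filtering and reporting. Filtering keeps
genes with TPM strictly above 1 in at least one sample, then requires the
median absolute deviation of log₂(TPM+1) across samples to be strictly
above both 0.01 and the 25% MAD quantile among expression-passing genes
("top 75% of MAD"). Two choices here were genuinely open and are recorded
in the filter report: MAD is computed on log₂(TPM+1) (the scale of an
absolute 0.01 floor is otherwise meaningless for TPM values spanning five
orders of magnitude) and without the 1.4826 normal-consistency constant;
the absolute floor and the quantile rule are combined with AND.

The network stage runs on a variance-stabilizing normalization implemented
as median-of-ratios size factors (geometric-mean reference over genes with
all-positive counts; total-count fallback with a warning) followed by
log₂(x+1). This deliberately replaces a dispersion-fit VST: downstream
statistics consume only correlations, which need approximate — not exact —
homoskedasticity. The returned matrix carries the mean-rank-vs-SD trend
slope before and after so the flattening is inspectable, and the test suite
asserts it shrinks on negative-binomial data.

### Network construction

Unsigned adjacency `a_ij = |cor|^β` (the classical default; the
specification of interest does not state signedness, and the choice is a
parameter). β is the smallest value in 1..20 whose scale-free model fit
reaches R² = 0.8, falling back to 6 with a warning. The fit regresses
log-density of connectivity on log mean connectivity over *quantile* bins
(density = frequency/width): equal-width binning made the R² profile
non-monotone and the selected β jump erratically between 2 and 20 across
seeds of the very same generator, whereas quantile bins give a smooth
profile; the binning method is not specified by any source and is our
numerical choice.

Topological overlap is
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with unit
diagonal, and modules come from average-linkage clustering of `1 − TOM`.

**Module detection** is a deterministic variant of the dynamic hybrid cut,
and the one place implementation overturned the initially planned design.
A single static cut of the dendrogram fails for a reason worth recording:
distinct modules cohere at different heights, and near the top of the tree
chance-correlated "bridge" genes weld separate modules into one branch — on
the standard planted fixture a 0.99-of-maximum cut yielded an adjusted Rand
index of ~0.2. Instead:

1. **Branch seeding.** A merge node becomes a module seed at its *first
   crossing* of `min_module_size` (both children smaller). First-crossing
   nodes are provably disjoint, so seeding is well defined; a
   uniquely-seeded branch absorbs unseeded sisters below the height cap
   (`cut_height` × max height, default 0.99), but two seeded branches are
   never fused here.
2. **Eigengene refinement.** Iteratively, every gene joins the module whose
   eigengene it correlates with most, *provided* |r| > 0.2 **and** the
   correlation is Benjamini–Hochberg significant (q < 0.05) over the
   gene × module grid; modules shrinking below the size floor dissolve.
   The significance gate is essential at n = 24: a bare |r| > 0.2 rule
   admits ~87% of pure-noise genes (null |r| has SD ≈ 0.21), which by
   direct calculation collapses the ARI to ~0.03.
3. **Merging.** Modules whose eigengenes correlate above 0.9 are merged
   greedily (ties broken lexicographically; the larger label survives),
   recomputing eigengenes after each merge. Over-split seeds of one true
   module are collapsed here.

Eigengenes are first right singular vectors of the per-gene z-scored module
submatrix, unit norm over samples, sign-oriented so the mean correlation
with member genes is non-negative; variance explained is d₁²/Σd². Hub genes
require intramodular connectivity kIM > 30 and gene significance
(|cor| with a trait) > 0.2 for at least one trait.

### Module–trait association

States are encoded one-vs-rest as 1/0 indicators (coding was unstated; this
reproduces one association column per state). Pearson r with each eigengene,
`t = r√(n−2)/√(1−r²)` two-sided on n−2 df, and BH FDR pooled across the
full module × trait grid (a single FDR scale across the heat map, not per
trait). Samples are treated as independent; the paired pre/post design is
*not* modeled — the output metadata flags this assumption, and a
mixed-model treatment is a known limitation. Gene-level group comparisons
use Welch's t-test (robust for groups of 4–8).

### GWAS enrichment

`T_sum = Σ b²` over the SNPs falling in a module's gene windows (gene body
±20 kb, 0-based half-open, clipped at zero, merged within module; GWAS
positions are read 1-based and converted). The null rotates the
genome-ordered effect vector over one genome-wide circle (chromosomes
concatenated in sorted name order) by an offset drawn uniformly from
1..m−1, keeping the module's index set fixed — this preserves the local
correlation structure of effects that marker LD induces, which is the point
of the circular scheme; the permuted effect multiset is identical to the
original by construction. Choices made where sources were silent or loose,
all recorded:

* empirical p uses the add-one estimator (1+c)/(1+n_perm) rather than a raw
  proportion, so p = 0 is impossible (a raw proportion is not a valid
  permutation p-value);
* "greater than observed" is implemented as ≥ (conservative, standard);
* one global circle rather than per-chromosome rotation;
* offsets are sampled with replacement, k = 0 excluded; an exhaustive mode
  enumerates all m−1 rotations and the two modes agree within Monte-Carlo
  error (tested);
* a ≥-comparison tolerance of 1e-9·T_obs absorbs floating-point reordering
  (without it, the "module = all SNPs ⇒ p = 1" identity fails);
* the candidate-gene threshold "P < 10e-05" is read as 1e-5 (consistent
  with the stricter usage alongside it) and is configurable.

FDR is pooled over modules × traits; candidates are genes in significant
modules whose top window SNP beats the threshold, with an optional
cross-trait support column (top SNP p < 0.05 in other traits).

### Tissue specificity and set enrichment

The tissue t-statistic is the slope t of a regression of expression on a
+1/−1 code (target tissue vs rest), algebraically the pooled-variance
two-sample t — the equivalence is asserted numerically in the tests. Genes
rank by t per tissue (non-finite t last, ties by gene id); the top
ceil(5%·n) form the tissue-specific set. Module enrichment in those sets —
and in any user-supplied GMT sets, which is how GO-style analysis is served
without bundling a database — is an upper-tail hypergeometric test with BH
FDR over the grid. Covariate correction of the source atlas is out of
scope; the synthetic panel has no batch structure.

### Integration

Across all modules (the leftover "unassigned" module included by default,
matching a 16-modules-including-leftover convention), Pearson correlation
of x = −log₁₀(enrichment empirical p) against y = −log₁₀(association p).
Which quantities the original figure correlated is unstated; −log₁₀ p on
both axes makes both measure evidence strength, and a rank-based variant is
reported alongside (its sign must agree under planted coupling — tested).
The real-data value (r = 0.60) is not claimed or reproduced: it depends on
the study's raw data, and this operation is validated purely by synthetic
recovery.

## The synthetic world

The generator emulates the study design: 24 samples, 6 per state; ~2,000
genes (a desk-scale stand-in for ~13,600 expressed genes) with five planted
modules of 150/120/100/80/60 genes; 20,000 SNPs on 5 chromosomes (vs 2.6M
imputed markers). Defaults state the world once:

* **Latent structure.** Module gene = √ρ·factor + √(1−ρ)·noise with
  ρ = 0.7, so the latent pairwise correlation is exactly ρ (the calibration
  oracle ρ = loading²/(loading²+noise) is asserted in tests). Observed
  log-count correlations are attenuated to ~0.6–0.75 by the count layer.
* **Counts.** Negative binomial, dispersion 0.1; log-normal library sizes
  (CV 0.2) around 3×10⁶ reads — matching real blood RNA-seq depth per gene
  (~25M reads over ~13.6k genes ≈ 1.5k mean count, scaled to 2,000 genes).
  Depth enters through an explicit library-size factor, *not* compositional
  closure: closing each sample to its own rate sum injects an artifactual
  anti-module component into every background gene whenever a large module
  swings (the compositional artifact of extreme differential expression),
  which contaminates the leftover module's eigengene. That artifact is
  real but deliberately out of the stated world.
* **Trait couplings.** M1 is shifted +2.5 latent SD in K_Post and drives a
  BHBA-like indicator (r = 0.7); M2 is shifted −1.5 in K_Post and drives an
  HDL-like indicator positively (r = 0.75) — an HDL-like indicator coupled
  to a module suppressed in post-partum ketosis. Shifts are realized by
  stratified draws (noise standardized within target group and complement)
  and indicator noise is orthogonalized against the factor, so realized
  couplings equal their configured values exactly: at n = 24, raw sampling
  noise in a "configured" correlation has SD ≈ 0.2, which would otherwise
  randomize which module tops which trait and make recovery tests
  meaningless. M2's −1.5 (vs M1's +2.5) keeps the two modules' state
  associations separated by more than estimation noise, so "the driving
  module attains the top |r| for its trait" is a property of the stated
  world rather than a coin flip.
* **GWAS.** b ~ N(0, σ²) with σ = 0.1, inflated ×√4 inside ±20 kb windows
  of enriched modules (M1 and M2 by default — the same modules planted
  transcriptionally, which is what the integration stage is meant to
  recover); p-values from z = b/0.1. The effect-size distribution is our
  construction for testing, not a claim about real GWAS.
* **Tissue panel.** 8 tissues × 5 samples; a disjoint 2% of genes per
  tissue shifted upward in that tissue only (default 3 SD; recovery tests
  use 5 SD for the high-signal case).

What a green test does **not** establish: robustness to batch effects,
paired-sample correlation structure, LD beyond genome-ordered effect
placement, compositional normalization artifacts, isoform-level length
variation (one flat gene model per gene), or anything about the original
study's actual data.

## Numerical and degenerate-input conventions

* Duplicate ids, negative/fractional counts, p ∉ (0,1], start ≥ end are
  hard errors naming the offender; unsorted GWAS input is sorted with a
  logged notice.
* Zero-depth samples and zero-variance genes (post-filter impossible) are
  errors; a constant gene's tissue t is 0, zero residual variance gives a
  signed-infinity sentinel with a warning.
* All greedy tie-breaks (merge order, top-fraction ranking, reassignment)
  are lexicographic, making every stage deterministic given inputs and
  seed; per-cell permutation seeds derive linearly from the base seed in
  (trait, module) sort order.
* Every output table carries `# ketonet_version`, `# config_hash` (FNV-1a
  of the raw config text) and `# seed` header lines; identical seeds give
  byte-identical run directories (tested).

## Known limitations

The paired design is ignored (as in the emulated analysis); the leftover
module's eigengene is a weak, heterogeneous summary; static branch seeding
can still miss a module whose branch never coheres below the height cap
(observed in ~1 of 10 seeds for the weakest 60-gene module, with ARI still
≥ 0.87); the network stage is O(n²)–O(n³) in genes and is not block-wise,
so it is comfortable to ~5k genes, not 30k.
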