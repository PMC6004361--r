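---
title: "Mapping growth loci in a full-sib fish family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping growth loci in a full-sib fish family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpmap)
```

## The problem

A single full-sib family of transgenic common carp shows strongly bimodal
growth: body-weight and body-length histograms separate into a slow- and a
fast-growing subgroup even though all offspring share both parents and the
same transgene integration site. The working hypothesis is that genotypes
segregating from the two (heterozygous) parents at a small number of
"receptor-genome" loci modulate growth. `carpmap` implements the complete
analysis used to find and verify such loci:

1. **Bulked-segregant Fst scan** (`fst_table()`, `fst_scan()`): DNA from
   the ~30 individuals nearest each phenotype peak is pooled and
   sequenced; per-SNP allele frequencies of the two pools are compared
   with a nucleotide-diversity based fixation index.
2. **Candidate annotation** (`annotate_candidates()`): surviving SNPs are
   intersected with exon/promoter features to nominate candidate genes.
3. **Amplicon re-genotyping** (`demux()`, `genotype_samples()`): candidate
   SNPs are PCR-amplified per individual with dual-barcoded primers,
   pooled into one library, demultiplexed by the barcode rule, piled up
   and called as diploid genotypes.
4. **Mixed-model association** (`association_scan()`): each SNP is tested
   against weight and length under a mixed linear model with a
   centered-IBS kinship random effect.
5. **Genotype-effect verification** (`genotype_summary()`,
   `combination_summary()`, `rank_dominant()`): classes and two-locus
   class combinations are summarised by the proportion of carriers above
   a 500 g weight threshold, and "dominant" genotypes are ranked by their
   advantage over the family-wide rate.

A synthetic full-sib family generator (`simulate_family()` and friends)
reproduces the statistical structure each stage assumes, so the whole
pipeline is testable end to end without any external data.

## The Fst statistic

For one SNP and one pool, with read counts $n_A, n_C, n_G, n_T$ and
frequencies $f_N = n_N / \sum n$, per-site diversity is the expected
heterozygosity

$$\Pi = 1 - f_A^2 - f_C^2 - f_G^2 - f_T^2 \in [0, 0.75].$$

With $\Pi_1$, $\Pi_2$ for the two pools,
$\Pi_\text{within} = (\Pi_1 + \Pi_2)/2$ and $\Pi_\text{total}$ the
diversity of the combined frequency vector,

$$F_{st} = \frac{\Pi_\text{total} - \Pi_\text{within}}{\Pi_\text{total}}.$$

Design choices:

* **Frequency pooling.** $\Pi_\text{total}$ uses the *unweighted* mean of
  the two pools' frequency vectors: the bulks are designed equal-sized
  (30 + 30 fish), and the unweighted form treats them symmetrically.
  Read-depth weighting is available via `weighted = TRUE`. By concavity
  of $\Pi$, the unweighted form guarantees $F_{st} \in [0, 1]$.
* **Monomorphic sites** ($\Pi_\text{total} = 0$) give 0/0; they are
  reported as `NA` and excluded from scans rather than set to 0, since
  an uninformative site is not evidence of no differentiation.
* **Filters.** The scan keeps sites with $F_{st} > 0.5$, depth $> 20$
  *in each pool* (the stricter reading of "coverage > 20x": one shallow
  pool already ruins the frequency estimate), and every reported allele
  supported by at least 4 reads in any pool where it appears. A
  variant-caller quality score is not computable from raw counts; the
  read-support filter plus the coverage filter stand in for it.
* SNP-feature overlap is strandless and 1-based inclusive; BED input is
  converted from 0-based half-open coordinates on read. Promoter
  features must be present in the annotation — no default upstream
  window is invented.

As a worked check, pools with allele frequencies 0.9 vs 0.1 (counts
45/5 and 5/45) give $\Pi_1 = \Pi_2 = 0.18$, $\Pi_\text{total} = 0.5$ and
$F_{st} = 0.64$:

```{r fst-worked}
site_fst(c(45, 5, 0, 0), c(5, 45, 0, 0))
```

## Dual-barcode demultiplexing

Each individual's PCR products carry an F barcode on the forward primer
and an R barcode on the reverse primer. Matching uses the 12-mer *key*
formed by bases 9–20 of each barcode (`barcode_key()`). A read pair is
assigned to the unique sample whose F key occurs in one read and whose R
key occurs in the mate, with the key starting within the first 9 read
positions (the barcode sits at the 5' end and its key begins at barcode
position 9, so genuine keys start at read position 9; the window allows
nothing deeper into the read, limiting false internal matches).

* Matching is **exact** — no mismatch tolerance. Tolerant matching would
  mostly manufacture conflicts between near-identical keys.
* Orientation-swapped pairs (F key on read 2) are accepted; sequencers do
  not guarantee which mate carries the forward end.
* Pairs matching two different samples (or two different keys on one
  read) are discarded as `conflicting`, never arbitrated: for genotyping,
  misassignment is worse than loss. Pairs whose (F, R) combination
  belongs to no sample are `unknown-combination`.

The report guarantees conservation: assigned + unassigned = total, and
per-sample counts sum to the assigned total.

## Genotyping without an aligner

Amplicons are short (&le; 290 bp) known sequences, so full read alignment
adds nothing: after stripping the barcode, a read is anchored to its
amplicon by an exact match of the next 20 bases against the amplicon's
primer-landing region, and the base at the target SNP offset is read off
directly. Each read *pair* contributes one observation of the SNP
(forward read preferred, reverse-complement mate otherwise), so depth
counts molecules, not reads.

Diploid calls from the A/C/G/T tallies use three thresholds, all exposed
as arguments (`call_genotype()`): depth &ge; 10 for any call; top-allele
fraction &ge; 0.9 for a homozygote; second-allele fraction inside
[0.25, 0.75] for a heterozygote; anything else is missing (`ambiguous`).
The thresholds are deliberately conservative for ~40x amplicon depth —
at that depth a true heterozygote is missed with probability &lt; 0.005
and a miscall to homozygote is essentially impossible. Sites are then
filtered on minor allele frequency &gt; 0.05 (allele-count basis over
called genotypes, the standard convention) and call rate &gt; 90%.

## Mixed-model association

Per marker the model is

$$y = \mu + \beta \cdot \text{dosage} + g + e, \qquad
  g \sim N(0, \sigma_g^2 K), \quad e \sim N(0, \sigma_e^2 I),$$

with $K$ the centered-IBS kinship: dosages mean-imputed per site,
centered, cross-multiplied and scaled so $\mathrm{mean}(\mathrm{diag}\,K)
= 1$. Variance components are REML-estimated **once** under the null
model ("P3D"): on the eigenbasis of $K$ the restricted likelihood is a
one-dimensional function of the variance ratio
$\lambda = \sigma_e^2/\sigma_g^2$, optimised by Brent search over
$\log\lambda \in [-14, 14]$ with explicit boundary checks (so
$\sigma_g^2 \to 0$ is handled). Each marker is then tested by
generalised least squares with the covariance *shape* fixed and the
residual scale re-estimated, giving an F test on $(1, n-2)$ degrees of
freedom that reduces **exactly** to the ordinary regression F test when
$K = I$ — the module's primary oracle. An optional exact mode
(`exact_reml = TRUE`) re-estimates the variance components per marker.

Other choices: missing dosages are mean-imputed for building $K$ (so the
kinship stays fixed) but the affected individuals are dropped pairwise
from that marker's test; no covariates or principal components are
fitted (a single full-sib family has no population structure beyond the
kinship); weight and length are scanned independently; p values are raw,
with working thresholds 0.05 and 0.1 reported — the verification stage,
not multiplicity arithmetic, is the error control here. Compressed MLM
(clustering individuals to shrink the random effect) is *not*
implemented: with 442 individuals the uncompressed model is tractable,
and compression only approximates it.

## Subgroup splitting and effect summaries

`split_subgroups()` estimates the weight density with a Gaussian kernel
(Silverman's rule-of-thumb bandwidth), keeps local maxima of at least
10% of the tallest peak, and examines consecutive prominent-mode pairs.
The split is made at the *deepest* relative valley, provided that valley
drops below 90% of the flanking peaks; otherwise the distribution is
flagged unimodal (no-split) rather than split arbitrarily. Using the
deepest valley instead of "the two tallest modes" matters here: the
heterozygote and homozygote-advantage classes lie close together and can
form a two-humped fast peak, making the tallest-pair choice unstable
while the slow/fast separation stays by far the deepest valley. The
threshold is then refined to the midpoint of the largest observation gap
between the chosen modes, so every slow individual weighs strictly less
than every fast one. For fewer than 30 fish the KDE is unreliable and
the split falls back to the midpoint of the largest gap in sorted
values. A 2 g wide printed boundary between published subgroup ranges
is, for the record, below the resolution of any density- or gap-based
rule at these sample sizes; the package reproduces the *partition* on
separated data, not a specific 2 g threshold.

Effect summaries count, per genotype class or two-locus class
combination, the carriers with body weight **strictly** above 500 g
(the printed class counts are consistent with either reading of the
threshold; strict was chosen and is used throughout), report the
frequency to 2 decimals, and mean ± sd of weight and length.
`rank_dominant()` orders classes by that frequency (ties by mean weight,
then label) and annotates the percentage-point advantage over the
family-wide rate; classes under 10 carriers are flagged small-sample and
excluded from statistical claims. One-way ANOVA (equal-variance,
`stats::oneway.test`) compares traits across classes; the letter
groupings attached to summaries come from pairwise Welch tests with
Bonferroni correction at 0.01 assembled by insert-and-absorb — the
published tables' exact post-hoc procedure is unstated, so this is a
declared stand-in. Sites are admitted to combination screening when
either trait's association p value is below 0.1 (the union; the source
analysis is ambiguous on which trait's p was meant).

## The synthetic family generator

`simulate_family()` draws a het x het cross: both parents are
heterozygous at every marker (markers are assayed *because* they
segregate), so offspring dosages are sums of two Bernoulli(1/2) gametes
— unlinked 1:2:1 segregation; no genetic map or recombination model is
used because the analysis never uses linkage. Two markers are designated
the causal **major** and **helper** loci. Phenotypes are the mean of the
individual's two-locus class — a free 3x3 table, by default the
published class means (major-locus hom-alt classes near 1 kg, hom-ref
near 290–490 g), so non-additive patterns are expressible — plus
Gaussian noise, floored at 1 (weights are positive).

**Residual noise.** The default residual sd is 50 g for weight and
12 mm for length. This is deliberately smaller than the printed
within-class sds (~450 g): those conflate residual noise with the large
unexplained between-subgroup variance, and a Gaussian residual of that
size makes the family marginal *unimodal*, which contradicts the
clearly separated two-peak structure the entire bulking design rests on
(and the internal requirement that the major-locus class-mean gap,
~500 g, be at least 1.5 residual sds). The generator therefore
prioritises the bimodal family structure and treats the class means as
exact; the cost is that simulated within-class spread is narrower than
observed, so printed per-class sds are emulated only when set
explicitly. Tests that need the published within-class sds (e.g. ANOVA
power at published group sizes) set them explicitly.

Pool counts (`simulate_pool_counts()`) take the `pool_size` individuals
nearest each weight mode ("nearest peak region", operationalised as
smallest |weight − mode|), then draw per site: depth ~
Poisson(`pool_depth` = 40), alt reads ~ Binomial(depth, pooled allele
frequency), with each read substituted to a uniformly random other base
with probability `read_error_rate`. Amplicon reads
(`generate_amplicon_reads()`) are fixed-length 150 bp: barcode +
amplicon prefix (read 1) and barcode + reverse-complement prefix
(read 2), heterozygotes emitting each allele with probability 1/2 per
pair, a configurable fraction of pairs carrying random barcodes
(non-specific amplification; at 0.33 the demultiplexer recovers the
~67% split rate seen in practice), and uniform substitution errors.
Quality strings are constant Q30 placeholders — the simulator models
substitution error directly, not quality. Indels, PCR chemistry,
transgene integration and linkage are all out of scope.

What passing tests on this generator do **not** show: robustness to
skewed or heavy-tailed within-class distributions, to unequal pool DNA
contributions, to indels or primer-site polymorphism, or to population
structure beyond a single full-sib family.

## Problem sizes and numerical choices

The test suite exercises the pipeline at the family's full scale where
that is cheap (442 individuals; 35 amplicons for the demultiplexer round
trip)
and at reduced scale where a full replication would be wasteful: the
end-to-end recovery experiment uses 100 seeded replicates of a
442-offspring family with 200 markers and a 12-site re-genotyping panel
at 20x amplicon depth, and the null-calibration experiment uses
200 seeded null families (h² = 0.3, 48 markers). Eigenvalues of $K$ are
clamped at 0 before REML; GLS on subsets (missing dosages) decomposes
the subset covariance directly. Determinism: every simulation function
consumes an explicit seed from its configuration and restores the RNG
state afterwards; identical configurations give bit-identical output.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, at run
time: the published-class threshold frequencies through
`genotype_summary()` / `combination_summary()`, the worked Fst value,
one full synthetic pipeline run (Fst rank, association rank and
top-class advantage of the planted major locus), the demultiplexer
split rate at a 0.33 non-specific fraction, and the mixed model's
empirical type-I error on null families, writing them as JSON.
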