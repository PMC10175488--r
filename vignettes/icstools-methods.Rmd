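---
title: "Methods: community-state typing, strain tracking and enzymatic profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-state typing, strain tracking and enzymatic profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icstools)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design choices made where
the methodology was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analytical chain

The package works on species-level relative-abundance profiles of infant
gut metagenomes, expressed as **percentages** (0–100) throughout — this
matches how such tables are conventionally printed and avoids a silent
factor-of-100 ambiguity. Samples carry optional metadata: host group
(`HI` healthy urbanized, `PI` preterm/critically ill, `RI` rural), delivery
mode, feeding, antibiotic exposure and age in days.

### Core species

A species is **core** when two prevalence criteria hold simultaneously:

* overall prevalence — percent of samples where its abundance strictly
  exceeds the detection threshold (default 0.05%) — above 10%, and
* *major-player* prevalence — percent of samples in which it ranks among
  the `top_n = 3` most abundant nonzero species — above 3%.

All thresholds are **strict** (`>`), following the defining wording
"higher than"; a taxon at exactly 10.0% prevalence is excluded. Two edge
rules are fixed deliberately: zero-abundance taxa never count toward the
top three even when fewer than three taxa are nonzero, and ties at the
boundary rank are counted *inclusively* (every taxon tied with the third
abundance qualifies), so the statistic cannot depend on taxon identifier
order. The 0.05% detection threshold gates both richness and prevalence;
both are configurable because reasonable pipelines differ on whether
prevalence should be detection-gated at all.

### Community state types

ICSTs are discovered by hierarchical clustering of the core-species
profiles:

* **Distance**: the Pearson-correlation distance `d(i,j) = 1 − r(i,j)`
  between sample profiles over the core species only (range 0–2). A sample
  whose core-species vector has zero variance has no defined correlation
  and is reported by name as an error rather than silently dropped.
* **Linkage**: complete linkage (furthest neighbor). A Ward-type criterion
  (`ward.D2`) is available as a flag; with well-separated states the two
  agree, and complete linkage is kept as the default because its cophenetic
  heights bound the original distances, making the cut heights
  interpretable as worst-case within-cluster dissimilarity.
* **Cut rule**: the tree is cut at the flat partition (candidate cluster
  counts 2 upward) maximizing the **mean silhouette width** on the same
  distances, ties toward fewer clusters. A support-count-maximizing rule
  ("choose the cut with the most clusters above the support threshold") was
  considered and rejected on first principles: any genuine cluster holding
  at least twice the support threshold can be split into two supported
  halves, so that rule strictly prefers over-split partitions and cannot
  return the natural number of states on clean data. Silhouette
  maximization rewards partitions whose clusters are compact relative to
  their separation and is the same criterion used below for enzymatic
  profiles.
* **Support**: after the cut, clusters with fewer members than
  `min_support` are marked `unassigned`. `min_support` accepts an absolute
  count or a fraction of samples; the default fraction 0.0457 is the analog
  of "at least 500 of 10,935 infants", so synthetic runs of any size scale
  consistently. If no cluster reaches support, a single all-sample cluster
  is returned (no supported structure is distinguishable).
* **Naming**: `ICST-` plus the two-letter uppercase genus codes of all taxa
  with within-cluster mean abundance strictly above `dominance = 10`
  percent, joined by `/` in descending mean order. Two species of the same
  genus collapse to one code (two dominant *Prevotella* yield `ICST-PR`,
  not `ICST-PR/PR`). When two *distinct* genera collide on a code within
  one run — *Enterococcus* and *Enterobacter* both give `EN` — the species
  initial is appended (`ENF`, `ENH`); reusing one ambiguous code for
  distinct genera would make downstream grouping by name unsound. A cluster
  with no dominant taxon is named `ICST-NA` with a warning.
* **Health label**: computed from the fraction of cluster members whose
  group metadata reads `PI`, over members with known metadata. Defaults
  `unhealthy_min = 0.60` and `healthy_max = 0.25` were chosen so that every
  published state composition we bundle reproduces its printed label
  (PI fractions of 12–19% → Healthy, 49% → Mixed, 65–87% → Unhealthy); any
  pair of thresholds in (0.49, 0.60] × [0.19, 0.49) does so, and the chosen
  values sit away from the observed fractions on both sides.

Typings are validated by Bray–Curtis PCoA (classical scaling on
double-centered squared dissimilarities; negative eigenvalues are reported,
never silently folded into the explained-variance denominator), PERMANOVA
with label permutations (`p = (1 + #{F* ≥ F})/(1 + n_perm)`, default 1000
permutations, seed explicit, minimum attainable p of `1/(n_perm+1)`), and
one-way ANOVA with Tukey HSD on per-sample richness.

### Strain-level tracking

Strain structure is represented by **population subspecies (PS)**: clusters
of genomes at > 99.8% estimated nucleotide identity.

* **Canonical k-mers** (`k = 23`, odd enforced so canonical form is
  unambiguous; windows containing `N` skipped rather than expanded) make
  all sequence comparisons strand-invariant.
* **Identity estimation** uses the Mash-style transform of the full-set
  Jaccard index, `identity = 100·(1 + ln(2J/(1+J))/k)`, floored at 0 and
  exactly 100 when the sets coincide. At desk scale full sets are used —
  no MinHash sketching — so the estimate is deterministic. At k = 23 a
  substitution rate of 0.002 yields an estimate within ±0.1 of 99.8%
  (checked in the tests), which is what makes 99.8% usable as a
  dereplication threshold.
* **Quality filtering** keeps genomes with completeness > 50% and
  contamination < 1.95% (strict, configurable); records lacking statistics
  pass with a warning because discarding unannotated genomes silently would
  bias the database toward well-curated species.
* **Species validation** keeps a genome when its identity to its claimed
  species' reference exceeds 94%.
* **Dereplication** links genome pairs above 99.8% identity and takes
  single-linkage components as PS; the representative is the longest genome
  (ties by identifier). Single linkage mirrors the transitive "cluster
  genomes above a threshold" reading; the exact criterion used by
  k-mer-based strain tools is not published, so this choice is documented
  rather than asserted as equivalent.
* **Database**: species-specific k-mers are the species union minus every
  other species' union; PS-specific k-mers additionally subtract the other
  PS of the same species. Both disjointness properties are structural and
  asserted in tests. A PS whose specific set is empty is recorded as
  undetectable with a warning instead of failing the build.
* **Detection rule**: a PS is called present in a sample when at least
  `min_fraction = 0.10` of its specific k-mers are observed **and** at
  least `min_kmers = 50` are observed in absolute terms. This rule is the
  package's own (reference strain-tracking tools do not publish their
  thresholds); both knobs are exposed, and detection is monotone — raising
  `min_fraction` can only remove calls. The fraction guards against
  spurious shared-sequence hits, the absolute count against tiny specific
  sets.

Coexistence statistics are computed per species × sample group with the
group size as denominator: the multiplicity distribution `p₁…p₅` (samples
harboring exactly m PS; m ≥ 5 capped into the terminal bin, raw counts also
kept), richness-if-present `Σ m·pₘ / Σ pₘ`, richness-all `Σ m·pₘ / 100`,
and prevalence `Σ pₘ`, with the identity
`richness_all = richness_if_present × prevalence/100` holding by
construction. Top-prevalence PS lists (default five per species, ties by
identifier) feed the exclusivity classification — exclusive to one group,
shared by a subset, or shared by all — over Healthy/Unhealthy/Mixed state
groupings (or HI/PI/RI). Counts analogous to "strains matched" and
"strains with single hit" are emitted as distinct PS detected in the group
and PS detected in exactly one sample; the original definition window is
not published, so these are flagged as inferred.

### Enzymatic profiles

EC-number matrices (samples × EC, rows summing to 1) are clustered with
Bray–Curtis dissimilarity (Pearson distance as a flag) and complete
linkage; candidate cuts k = 2…10 are scored by mean silhouette width and
the maximum wins, ties toward smaller k. The cut-then-score construction is
used rather than k-medoids because it keeps a single clustering tree for
all candidate k. Association uses, per EC with ≥ 10% nonzero prevalence, a
linear model of `log10(x + half the EC's minimum nonzero value)` on cluster
indicators plus covariates, two-sided t-tests per coefficient, and
Benjamini–Hochberg q-values across all EC × cluster tests. The pseudocount
is per-feature so that an EC's zeros enter just below its own detection
floor. Collinear covariates are an error naming the aliased terms;
zero-variance ECs are skipped with a warning. Significant ECs join a
user-editable EC → compound mapping (a 20-entry template ships with the
package; the full curated list of 142 health-relevant compounds is not
reproduced and must be supplied by the user) and compounds are labelled
production- or degradation-enriched by majority among positively associated
ECs. Agreement between metagenomic and metatranscriptomic clusterings is
summarized by the adjusted Rand index on shared samples, with a
single-cluster modality yielding 0 by convention.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised:

* **Communities**: each sample draws from its state's Dirichlet
  distribution. The concentration vector gives each dominant taxon
  `α = c·p/100` (p its target mean percent) and spreads the remainder
  uniformly over the other taxa, so the Dirichlet mean matches the state
  definition exactly and the total concentration `c` (default 60) sets the
  noise level. The eight default state definitions mirror the published
  state compositions: one or two dominant taxa out of the 17 core species
  (45% for single-dominant states, 28/20% for double-dominant ones — above
  the 10% naming threshold with headroom, while leaving a realistic
  non-dominant tail), host-group mixes equal to the printed HI/PI/RI
  percentages, and mixing weights proportional to the printed state sizes.
* **Strain genomes**: one random root, species ancestors mutated at the
  inter-species divergence (default 0.10, comfortably below the 94%
  species boundary), strains mutated at the intra-species divergence.
  Mutations are i.i.d. substitutions — no indels — so pairwise mismatch
  fractions and k-mer retention are analytically predictable (two strains
  at rate d differ per site with probability `2d(1−d) + (2/3)d²`).
* **Reads**: uniform start positions on both strands, per-base substitution
  errors, `round(depth·L/read_length)` reads per genome, Phred+33 constant
  quality. This is deliberately *not* an Illumina error model: no quality
  gradients, indels, adapter or coverage bias. It is adequate for k-mer
  presence detection, which is all the downstream stage consumes.
* **EC matrices**: log-normal abundances; 30% of ECs are informative, each
  elevated by `effect_size` log10 units in one latent cluster; rows
  renormalized. Covariates (age, delivery, feeding, antibiotics) are
  simulated independently of cluster structure, so they are pure nuisance
  terms.

Every generator is a pure function of its specification and seed —
byte-identical output on repeat, no global RNG state leakage.

Passing tests on these data show that the pipeline recovers the structure
it assumes (compositional states, substitution-divergent strains,
log-normal EC clusters) at the stated effect sizes. They do not show
robustness to the things real data add: compositional zero-inflation,
uneven sequencing depth, chimeric or contaminated assemblies,
within-species gene content variation, or batch effects across cohorts.

## Numerical choices and problem sizes

Tolerances: abundance columns must sum to 100 within 1e-6; distance-formula
oracles are checked at 1e-12; the richness identity at 1e-9. Tiny negative
correlations from floating-point rounding are clamped to distance 0.
Degenerate inputs have defined behavior: all-zero sample pairs get
Bray–Curtis 0 with a warning, a constant EC matrix is a "no structure"
error, a support threshold above the sample count returns one cluster with
a warning.

The test suite and acceptance script run the community recovery at n = 800
samples with the eight default states (support fraction 4.6% ≈ 37
samples), strain fixtures at 10–50 kb genomes with 2 species × 2 strains,
read screening at 10× coverage, EC model selection at 80–90 samples × 50–60
features, and PERMANOVA calibration with 200 replicates of 24–48 samples at
99 permutations. These sizes were chosen so the full suite completes in
well under a minute while every statistical check retains enough resolution
(3-SD bands, ±0.03 on a 0.05 type-I rate) to fail on a real defect.

## Known limitations

* ANI is estimated from k-mer Jaccard, not alignment; at divergences beyond
  a few percent the estimate is increasingly approximate (it is used only
  near the 94% and 99.8% thresholds, where it is accurate).
* PS detection is presence/absence; within-sample strain *abundance* is out
  of scope, as is any coverage-aware likelihood scoring.
* The pairwise dereplication is quadratic in genome count — appropriate for
  desk-scale studies, not for tens of thousands of genomes.
* Taxonomic classification, assembly and annotation of reads are upstream
  of this package: abundance tables, genome FASTA and EC matrices are its
  input contracts.
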