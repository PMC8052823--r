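---
title: "Measuring satellite copy number and diversity from k-mers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring satellite copy number and diversity from k-mers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censat)
```

## The problem

Centromeres of most mammals are tandem arrays of satellite repeats — in
the house mouse, a 120-bp minor satellite unit (the CENP-A-binding core
centromere) and a 234-bp major satellite unit (pericentromeric
heterochromatin). These arrays are absent from reference assemblies and
cannot be resolved by read mapping, so neither their size (copy number)
nor their internal sequence heterogeneity is visible to standard
variant-calling workflows. censat implements an assembly-free
alternative: because the frequency of a nucleotide word of length k (a
k-mer) in a shotgun library is proportional to its frequency in the
source genome, satellite abundance and composition can be read off
k-mer statistics alone.

The package estimates, per genome:

* **copy number** of a satellite consensus, from the median normalized
  frequency of the consensus's constituent k-mers;
* **within-genome repeat heterogeneity**, two ways: a *centromere
  diversity index* (CDI; average pairwise differences between reads
  anchored to the same consensus position) and a positional 4 x L
  *polymorphism matrix* built from relaxed-Hamming-distance k-mers;
* **phylogenetic heritability** of those metrics across a panel of
  genomes related by a tree.

## k-mer counting

Reads are decomposed into all length-k windows; windows containing a
non-ACGT character are skipped and tallied rather than error-corrected
(the simplest unbiased handling). Counting is exact — no sketches or
minimizers — because satellite work at desk scale needs faithful counts
of a few hundred thousand query k-mers, not genome-wide cardinality
estimates. Two k values are first-class: k = 15 (fast, used for
scans) and k = 31 (high specificity, used for quantification); any
3 <= k <= 63 is accepted.

K-mers are *canonical* by default: each window is stored as the
lexicographic minimum of itself and its reverse complement. Shotgun
reads sample both strands, so strand-merged counting makes consensus
queries strand-proof; a strand-specific mode (`canonical = FALSE`)
exists for sensitivity analysis because the choice is not forced by the
method.

Satellite consensus units are decomposed *circularly* by default: in a
tandem array the junction between adjacent copies is real genomic
sequence, so the L windows wrapping the junction all occur in the
array. A linear mode (`circular = FALSE`, L - k + 1 windows) is
available. Duplicate canonical k-mers inside a unit (internal
periodicity) are flagged and counted once in downstream queries, so a
self-similar unit does not get double weight.

## GC-bias normalization

PCR efficiency varies with GC content, distorting k-mer counts between
libraries. The correction is fitted per library, never shared, because
the bias is a property of library preparation:

1. sample a panel of k-mers occurring exactly once in a reference
   genome (default 100,000; seeded and reproducible);
2. model the library's observed counts of panel k-mers as a LOESS
   function of GC content (span 0.4, the workflow's standard setting);
3. evaluate the fit at each integer GC level 0..k — the "GC bin" is the
   integer G+C count of the k-mer, giving k + 1 levels, since the
   method needs a prediction exactly at each attainable GC value;
4. normalize any observed count as
   `normalized = log10(observed / predicted)`.

A panel k-mer is single-copy, so `predicted` is the expected count of a
single-copy locus at that GC level, and the normalized value reads
directly as log10 copy number: 0 for single-copy, 2 for a
hundred-copy repeat, 5 for a hundred-thousand-copy satellite.

Numerical choices worth stating:

* Panel k-mers with zero observed count enter the fit as zeros by
  default (they are evidence of low coverage at that GC); an
  exclusion mode exists because the alternative is defensible.
* Predictions are floored at 0.01 counts to guard LOESS undershoot at
  sparse GC extremes, and GC levels outside the panel's observed range
  are filled by nearest-level extrapolation and flagged.
* A zero *query* count becomes a missing value (`NA`), never
  `-Inf`; medians are taken over non-missing values and the missing
  fraction is reported. An estimate with more than 50% missing
  constituent k-mers is flagged below detection.

## Copy number and the variable-k-mer scan

Copy number is `10^median` of the normalized values of the distinct
constituent k-mers of a consensus (median over k-mers, not positions,
so periodic units are not over-weighted). Average per-chromosome array
length is `copies * L / n_chromosomes`; the default `n_chromosomes = 40`
is the house mouse diploid count, where every telocentric chromosome
carries one array. Exact-match k-mer counting deliberately measures the
*consensus-faithful* fraction of an array: in a repeat with per-site
heterogeneity p, a fraction `(1 - p)^k` of copies contributes to each
exact k-mer, so divergent arrays read lower — a known property shared
with the original workflow, and one reason heterogeneity is measured
separately.

The variable-k-mer scan ranks k-mers by the variance (n - 1
denominator) of depth-standardized frequencies across samples, where
the standardizer defaults to `total_read_bases / genome_size`
(2.7 Gb for mouse). The absolute scale of the standardizer is
irrelevant to the ranking — any common rescaling cancels — so the
unstated constant in the original workflow does not affect the top-1000
list the scan reproduces.

Variance partitioning of satellite metrics across design factors
(strain and library; or subspecies, population and individual) uses
sequential (type-I) ANOVA sums of squares via `stats::aov`, reported as
percent of total SS per factor.

## The centromere diversity index

Reads are mapped to each satellite consensus by an exact, ungapped
best-hit scan over all L start positions of the circularised unit and
both orientations. An internal mapper replaces an external aligner
because the diversity index is defined on substitution mismatches at a
fixed anchoring — gapped alignment would change the statistic — and the
workflow explicitly ignores indel contributions. Reads below 80%
identity are unmapped; equal-identity ties between satellites are
ambiguous and dropped; ties among positions break leftmost
(deterministic).

Mapped reads are partitioned by satellite, strand, and start position;
strand partitioning prevents comparing a sequence with its own reverse
complement. Within each cell, a read pair contributes

`d_ij = mismatches * L / overlap`,

i.e. differences rescaled to the repeat-unit length, and the CDI is the
mean over all N eligible pairs across strands and positions. The
rescaled form makes CDI comparable across read lengths and lets it read
as "two random repeat copies differ at ~d of L sites" (d = 17 on the
120-bp unit is ~14% divergence); a raw-mismatch mode is retained
(`rescale = FALSE`) since the alternative convention is plausible.
Pairs overlapping fewer than 30 bp are skipped as uninformative.
Positions with many reads are subsampled to 200 pairs (seeded), keeping
cost O(L x cap); below the cap the exact all-pairs set is used and the
estimate equals a brute-force loop exactly.

Under the generator's independent per-copy substitution model with
per-site rate p, two copies differ at a site with probability
2p(1 - p) (plus a small p^2 term for doubly mutated sites), so the
expected CDI is approximately `2 L p (1 - p)` — the closed form the
simulation tests check against. Per-base sequencing error e adds
approximately `2 L e` for small e.

## The polymorphism matrix

The CDI summarises heterogeneity in one number; the polymorphism matrix
localises it. Observed k-mers within a Hamming distance h of any
consensus window are assigned to the positions they cover: h <= 2 for
k = 15 and h <= 5 for k = 31 (the workflow's standard caps).
"Edit distance" is implemented as substitution-only Hamming distance,
consistent with the workflow ignoring indels.

Matching scans *observed* k-mers against the 2L oriented consensus
windows — never the other direction: the Hamming ball of a 31-mer at
h = 5 has ~41 million members per position and cannot be enumerated. A
lossless pigeonhole prefilter (one of h + 1 disjoint blocks of the
k-mer must occur exactly in the circular consensus or its reverse
complement) prunes non-satellite k-mers before the exact distance scan;
every surviving candidate's distance is verified exactly, so the filter
is a pure speedup.

Each matched k-mer spreads its library frequency over the consensus
positions it covers, oriented to the consensus strand; ties among
equal-distance (position, orientation) assignments split the weight
equally (a winner-take-all mode is the obvious alternative; equal
splitting avoids an arbitrary preference among exactly tied anchors).
Columns are normalized to probabilities summing to one; the
non-consensus fraction of a column is `1 - P(consensus base)`. Sites
with >= 20% non-consensus usage are called variable, and
`motif_report()` extracts the CENP-B box window (positions 62-78 of the
minor satellite, with hotspot positions 75, 78 and 79 flagged; position
75 is critical for CENP-B binding).

## Phylogenetic heritability

For a satellite metric measured across genomes related by a tree, the
phylogenetic covariance matrix G (shared root-to-MRCA path lengths,
from `ape::vcv.phylo`) defines the Brownian-motion expectation of trait
covariance. The model is

`trait ~ Normal(mu * 1, sigma2_phylo * G + sigma2_resid * I)`

fitted by maximum likelihood, and the phylogenetic heritability is
`H2 = sigma2_phylo / (sigma2_phylo + sigma2_resid)`. ML rather than
REML keeps the permutation comparison simple, and with a single mean
parameter the two differ negligibly here. Internally G is rescaled to
unit mean diagonal so both variance components share a scale, and the
likelihood is profiled over the mixing ratio h on [0, 1]: after one
eigendecomposition of G, every h has closed-form GLS mean and variance,
so the 101-point grid search plus local refinement (tolerance 1e-6)
costs O(n) per evaluation. On an ultrametric unit-height tree this
model coincides with the lambda-transform model, which is how the fit
is cross-checked against an independent implementation in the tests.
Non-ultrametric trees (e.g. SNP-based ML trees) are accepted as-is with
no clock rescaling; H2 is invariant to affine transforms of the trait
and to global branch-length rescaling.

Significance uses a permutation null: trait values are shuffled across
tips, H2 re-estimated each time (1000 permutations by default), and
`p = (1 + #{H2_perm >= H2_obs}) / (n_perm + 1)` — one-sided toward
high heritability, the natural alternative, with +1 smoothing.
A property of this statistic worth knowing: under a true null about
half or more of ML fits land exactly on the H2 = 0 boundary, every
permutation then ties with the observed value, and the p-value is 1.
The p-value is therefore *conservative* (valid: P(p <= a) <= a, with
excess mass at 1), not uniform; the package's tests assert exactly
that, plus monotone power as the simulated phylogenetic signal grows.
At n = 32-64 tips the sampling spread of the ML mixing ratio is wide
(sd ~ 0.2 for intermediate truth), which matches an independent
lambda-model implementation replicate-for-replicate; single-genome-set
H2 values should be read with that uncertainty in mind.

## The synthetic-data generator

Every estimator is testable offline against generated data with known
truth:

* `simulate_array()` concatenates `copies` units, mutating each
  position of each copy independently with probability `rate` (scalar
  or per-position), recording every substitution. The i.i.d. model is
  the default because it makes the CDI expectation analytic; a
  shared-variant mode plants population-frequency sites (e.g. a
  50%-frequency CENP-B-box variant) for the polymorphism matrix.
* `simulate_genome()` embeds arrays in a random background at recorded
  coordinates.
* `simulate_reads()` draws uniform fragment starts on both strands and
  keeps each candidate read with probability `gc_bias(read GC)` — a
  thinning model chosen over duplication so expected counts stay
  analytic — then applies i.i.d. per-base substitution errors.
* `scenario_fixtures()` bundles the two reference regimes: an
  *inbred-like* array (2,000 copies, heterogeneity rate 0.02) and a
  *wild-like* array (300 copies, rate 0.10), reproducing the
  qualitative contrast between large homogeneous and small
  heterogeneous centromeres, plus a 32-tip tree with Brownian and
  noise traits.

What the generator does *not* emulate: real mouse genomic background
(transposons, segmental duplications), positionally correlated
mutation, indel polymorphism, paired-end structure, or base-quality
miscalibration. Passing tests therefore demonstrate estimator
correctness under the stated model — unbiased copy-number recovery,
analytic CDI behaviour, exact landscape recovery — not robustness to
every artefact of real libraries; the GC-thinning model in particular
is a deliberate idealisation of amplification bias.

## Problem sizes and defaults

The test-suite and acceptance simulations use 100-kb backgrounds,
20x candidate depth and 100-bp reads, with arrays up to 10,000 copies
(1.2 Mb); panels of 20,000-50,000 unique 15-mers stand in for the
100,000-k-mer default, which a 100-kb background cannot supply. These
sizes keep each estimator's sampling error comfortably inside the
tolerances being asserted (copy-number recovery within 10%, CDI within
15% of its closed form, planted 50% variants within 0.05) while the
whole suite stays desk-sized. All generators and subsampling steps are
seeded; rerunning any stage with the same configuration reproduces its
outputs byte-for-byte.

## Limitations

* Exact-match copy numbers are consensus-referenced: arrays divergent
  from the supplied consensus are undercounted (and visibly so in the
  mapped-read fraction and polymorphism matrix).
* All metrics are genome-wide: the method is agnostic to chromosome of
  origin and cannot see chromosome-specific array differences.
* The CDI anchors both reads of a pair at one consensus position;
  structural rearrangements within arrays (higher-order repeats) are
  outside the model.
* Heritability estimates on small panels carry wide sampling
  uncertainty, and the permutation p-value is conservative by
  construction.
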