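---
title: "Multi-caller CNVR consensus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-caller CNVR consensus: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Short-read CNV callers disagree: read-depth methods see large events at
bin-size resolution, split-read and paired-end methods see small events at
base-pair resolution, and each produces its own false positives. A standard
remedy in population studies is a consensus design — call CNVs per sample
with several tools, merge them into population-level copy number variation
regions (CNVRs), and keep only regions supported by at least two methods and
by enough individuals. `cnvpool` implements that whole chain as reusable,
tested functions: call ingestion, size/chromosome filtering,
reciprocal-overlap deduplication, per-tool CNVR assembly with call-density
trimming, cross-tool consensus, breed-sharing and region-completeness
filters, region-exclusive sets, population structure (classical MDS and
neighbour-joining on a binary presence/absence matrix), QTL and gene-set
over-representation, and ΔΔCt copy number estimation from qPCR triplicates.
A seeded synthetic cohort generator emulates the whole study design so that
every stage can be exercised and measured without any external data.

The cohort layout mirrors a multi-breed minipig resequencing design:
36 samples from nine breeds assigned to three geographic regions (America,
Asia/Oceania, Europe), which is the smallest arity at which the sharing
rules (two animals per breed, all animals of a region) are all non-trivial.

# Coordinates and interval algebra

All internal coordinates are 1-based and fully closed, the native convention
of VCF and GFF3, which are the pipeline's sources. BED output is converted
at the writing boundary (start − 1, half-open) and nowhere else. Two merge
notions are deliberately distinct:

* **Reciprocal overlap** `ov / max(len_a, len_b)` drives *deduplication* of
  pooled per-sample calls: at threshold *f* it is equivalent to requiring
  both intervals to be covered to at least *f* by their intersection.
  Clustering takes the transitive closure (single linkage) of pairs at or
  above the threshold. The closure is order-independent, which a greedy
  sequential merge would not be; each cluster is represented by its span
  `[min start, max end]`.
* **One-bp overlap** drives *region building*: calls sharing at least one
  base merge into candidate regions. Bookended intervals (`end + 1 ==
  start`) share no base and are *not* merged — "overlapping by at least one
  base pair" is read literally.

Whether deduplication should re-test reciprocal overlap against growing
cluster spans iteratively is genuinely open; `cnvpool` uses a single-pass
transitive closure over the original intervals, which is deterministic and
has a clean brute-force oracle.

# Call filtering

Defaults follow the field's conventions for short-read CNV studies: minimum
event size 50 bp (below this, callers are unreliable and the variant class
blurs into indels), maximum 5 Mb (very large calls are dominated by
repetitive or misassembled regions), and autosomes only (hemizygous X
chromosomes in males bias copy number). All three are configurable
(`filter_config()`); removal counts are reported per reason.

# Per-tool CNVRs and density trimming

Within one tool, calls of one type (loss or gain) merging by ≥ 1 bp form a
candidate region. The per-base *support profile* counts how many calls cover
each base; maximal segments supported by fewer than 10% of the region's
contributing calls are removed, which both trims weak flanks and splits
regions at weakly-supported interior segments. The threshold is applied
strictly (`support < 0.10 × n_calls` is removed, ties kept), per the wording
"less than 10%". The per-base reading is a design choice: frequency-based
region summaries differ between implementations, and the per-base rule has
an exact independent oracle (recompute coverage with a plain integer
vector), which the test suite exploits on a thousand random instances.
Trimming never widens a region, and rebuilding CNVRs from their own spans is
a fixed point.

After trimming, loss and gain regions that still overlap by ≥ 1 bp fuse into
a single region typed `both`; sample and call bookkeeping is recomputed
against the fused span, so an individual whose call overlaps the trimmed
region still counts as a carrier.

# Consensus, sharing and exclusivity

Same-type regions from *different* tools combine when they overlap by ≥ 1 bp
(chained, one pass); `both`-typed regions combine with either type, and a
fused consensus region is retyped from its full contributing set. Combined
regions supported by fewer than two distinct tools are discarded. A gain
that meets only a loss has no same-type partner and both are dropped.

An individual *has* a CNVR iff at least one of its filtered calls (any tool,
any type) overlaps the CNVR span by ≥ 1 bp — individuals, not tool-specific
calls, are the unit of sharing. Three sharing rules are provided:

* `per_breed_min2` (default): keep CNVRs supported by ≥ 2 individuals in
  *every* breed. This is the stricter of two plausible readings of "shared
  by at least two individuals from all breeds"; the laxer overall-count
  reading is available as `overall_min`.
* `region_all`: keep CNVRs supported by every animal of one region.
* Singletons (one supporting individual) and doubletons (two) are recorded
  separately and never enter shared sets.

Exclusive CNVRs of a region are its region-complete CNVRs with zero
base-pair overlap against every other region's set; regions are kept or
dropped whole, never trimmed. The three exclusive sets are pairwise
non-overlapping by construction.

# Population structure

The binary matrix marks, per sample and per union locus (reciprocal-overlap
cluster of the pooled calls), whether the sample contributed a call. No
distance metric is canonical for such matrices; `cnvpool` defaults to
Jaccard distance (1 − shared/pooled presences), which ignores shared
absences — appropriate when most loci are absent in most samples — with
simple matching as the alternative. The choice is recorded in the run log.

Classical MDS is the textbook double-centring eigendecomposition; axes with
non-positive eigenvalues are excluded and reported, and each axis's sign is
fixed by making its largest-magnitude coordinate positive so repeated runs
are comparable. Neighbour joining uses the standard Q-criterion with
closed-form branch lengths; ties in Q are broken by the lexicographically
smallest pair of subtree labels, making the topology deterministic. Negative
branch-length estimates (a well-known NJ artefact on non-additive input) are
clamped to zero with the deficit moved to the sister branch, preserving the
pair distance; the count of clamped branches is reported. On additive
matrices the reconstruction is exact to 1e-9, which the tests verify against
random trees, and the implementation is cross-checked against an independent
reference implementation.

# Enrichment

QTL over-representation is tested per trait on QTL *records*: `a` = records
of the trait overlapping ≥ 1 CNVR (1-bp rule), against the complete QTL
table as background. The test is the one-sided (greater) Fisher exact test,
computed as the hypergeometric tail — only over-representation is asked.
Significance is declared at raw p < 0.05 with no multiple-testing
correction, matching common practice for this analysis; a Benjamini-Hochberg
column is emitted alongside for transparency but does not drive the flag.
Gene-set over-representation on local GMT files uses the same hypergeometric
model over a stated gene universe; ortholog mapping and live web services
are out of scope — the gene list and the GMT must share a namespace.

# qPCR copy number

Relative copy number follows the ΔΔCt model anchored at the diploid state:
`ΔCt = mean(Ct_target) − mean(Ct_reference)` over triplicates and
`CN = 2 × 2^(−ΔCt)`, so ΔCt of 0/+1/−1 gives CN 2/1/4 exactly. The CN
standard deviation is propagated in quadrature from the triplicate standard
errors. Measurements with triplicate SD above 0.5 cycles are flagged
unreliable and excluded from verdicts. A predicted loss is *confirmed* below
CN 1.5 and a predicted gain above CN 2.5; these thresholds are package
defaults (no community standard exists) and are configurable.

# The synthetic cohort generator

The generator emulates the *structure* of a multi-breed study, not its
sequences: no reads, no alignment, no LD. Its defaults are the study
conditions under which the package's end-to-end claims are measured:

* genome: three 10-Mb autosomes — large enough to place all truth classes
  disjointly (10-kb spacing), small enough for minute-scale tests;
* cohort: 36 samples, nine breeds (3–5 animals each), three regions;
* truth classes: 12 common-to-all CNVRs (4 of them with extreme copy
  numbers: 0 for losses, ≥ 4 for gains, in every carrier), one
  breed-restricted CNVR per breed, three region-exclusive CNVRs per region,
  six singletons, four doubletons;
* types: 90% losses, reflecting the strong loss bias of short-read CNV
  calling; sizes log-uniform on [200 bp, 1.4 Mb], matching the
  several-orders-of-magnitude spread of real CNVR catalogues;
* tools: four caller profiles (two read-depth-style dialects, two SV-VCF
  dialects), each with detection probability 0.9 per carrier and event,
  breakpoint jitter SD 200 bp (truncated so intervals never invert or leave
  the chromosome), and 0.5 false positives per Mb per sample, drawn outside
  all truth regions.

Annotations are planted with known signal: 70% of truth CNVRs receive a
gene whose three exons cover 60% of the CNVR span (so the ≥ 50% exon rule
fires deterministically); QTL of one designated trait land on common truth
CNVRs with 10:1 odds while all other placements avoid truth regions
entirely, giving the Fisher stage a clean planted positive and a clean
background; one GMT set collects exactly the genes planted on truth CNVRs.
qPCR Ct values are simulated by inverting the ΔΔCt model at the true copy
number with Gaussian noise (SD 0.15 cycles); a true copy number of zero
never amplifies, so an effective floor of 0.05 stands in for it, and two
assays are deliberately discordant (predicted gain over a diploid state) to
exercise the not-confirmed path.

All randomness flows from one 32-bit seed; a fixed configuration yields
byte-identical files, which the determinism tests verify with checksums.

# What the tests do and do not show

Because the generator plants structure directly at the call level, passing
tests demonstrate that the *integration machinery* is correct: planted
common CNVRs surface in the all-breeds shared set, planted exclusives stay
exclusive, common regions never leak into exclusive sets, and the planted
QTL trait is flagged. They do not demonstrate calling accuracy on real
sequencing data — caller error is modelled as independent Bernoulli
detection plus Gaussian breakpoint jitter, which ignores systematic effects
(GC bias, repeat-driven correlated false positives, caller-specific size
biases).

One quantitative limitation is intrinsic and worth stating precisely. With
per-call breakpoint jitter of SD σ, density trimming recovers a region
boundary near the ~10% quantile of the jitter distribution, an error of
roughly 1.3 σ (≈ 250–300 bp at σ = 200) per edge regardless of event size.
A recovered span can therefore reach Jaccard ≥ 0.9 against its planted
truth only for events longer than about `2 × 1.3σ × 0.9/0.1 ≈ 4.7 kb`.
Under the log-uniform size law about a third of planted events are shorter,
so the package reports span-level Jaccard alongside recovery and makes no
claim that sub-5-kb breakpoints are recoverable at 10% precision under
200-bp jitter — no merging strategy could do so from such calls. The
recovery metrics in the acceptance report keep these two notions separate
(`planted_common_recovery_pct` vs `planted_common_jaccard90_pct`).

# Numerical and degenerate-input choices

* All fraction thresholds (reciprocal overlap 0.5, exon overlap 0.5,
  density 0.10) are inclusive for "keep" decisions ("at least"), and the
  density rule removes strictly-below segments.
* An empty CNVR set summarises to zeros and writes header-only tables; a
  Jaccard pair with an empty presence union gets distance 0 with a warning.
* Copy number 2 is rejected as "not a CNV" at classification.
* Chromosome validation happens at ingestion: records on chromosomes
  absent from the genome build are rejected with a warning count, malformed
  records (end before start) are dropped as record-level errors with their
  record numbers, and unsupported SV types (inversions, breakends,
  insertions) are skipped with a counted warning.
* The test problem sizes — three 10-Mb chromosomes, ~40 planted CNVRs,
  ~4,000 calls, 1,000-instance oracle sweeps with n ≤ 15 — were chosen so
  the whole suite runs in minutes on one core while still exercising every
  rule at the study's full 36 × 9 × 3 arity.

# Known limitations

* Genotype-to-copy-number mapping for SV VCFs (diploid `1/1` on a deletion
  ⇒ CN 0, `0/1` ⇒ CN 1) is a declared convention; real callers differ in
  how and whether they report genotypes for duplications.
* Consensus combination runs one transitive pass across the tool sets; it
  does not iterate to a fixed point over its own output spans.
* No amplification-efficiency correction or standard-curve fitting in the
  qPCR model; no bootstrap support on NJ trees; no liftover between genome
  builds; VCF is read, never written.
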