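---
title: "Simulation-driven SV genotyping: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-driven SV genotyping: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(svgenotyper)
```

## The model

`svgenotyper` treats SV genotyping as a supervised classification problem
in which the training data are manufactured on demand. For a putative
sequence-resolved deletion or insertion, the three possible diploid states
(hom-ref, het, hom-alt) each imply a pair of local haplotypes. Sequencing
those haplotypes — with the sample's own read length, base error rate,
insert-size distribution, and coverage — and aligning the simulated reads
the same way the actual reads were aligned yields feature vectors whose
distribution under each zygosity can be learned directly, instead of being
assumed. The genotype of the actual data is then the class its feature
vector is assigned to, and the genotype quality is the Phred-scaled
complement of the winning class probability,
`GQ = min(99, floor(-10 log10(1 - max p)))`.

The central assumption is *matched pipelines*: whatever biases the
genomic context, sequencer, and aligner impose on the evidence, they are
imposed identically on simulated and actual data, so the classifier sees
them in training. This is also the method's main limitation — biases not
reproduced by the simulator (PCR duplicates, index hopping, mapping
artifacts of a different aligner) are invisible to it.

## Sample profile

`estimate_profile()` measures, from the alignments:

- modal read length;
- the insert-size PMF from proper-pair template lengths, truncated at the
  0.05th/99.95th percentiles (protects the PMF against chimeric pairs and
  pairs spanning real SVs);
- mean, per-contig, and per-GC-bin coverage (non-overlapping 100 bp
  windows, GC bin width 0.05 — granularities chosen so that bins stay
  populated on desk-scale genomes; the bin width matters only through the
  DHBFC normalization and the GC acceptance step of the simulator).

`insert_probability()` smooths the PMF additively
(`(count + 1e-6) / (total + 1e-6 K)`) so fragment lengths outside the
observed support keep a small positive probability; without the floor a
single unusual spanning pair would contribute log-probability `-Inf` and
veto an allele outright. `load_profile()` accepts precomputed metrics
(`READ_LENGTH=…`, `INSERT_MEAN=…`, …) and discretizes a normal insert
distribution truncated at ±5 SD.

## Simulator and built-in aligner

`simulate_pairs()` places fragments uniformly along each haplotype
(coverage split equally between haplotypes — the package simulates the
diploid jointly but with independent fragment sets per haplotype), draws
fragment lengths from the insert PMF, reads both ends, and applies uniform
substitution errors at the profile's rate. Qualities are flat; indel
errors are not modeled. The features used downstream are counts, weighted
counts, and depth ratios, all of which are insensitive to this
simplification at the error rates of modern short-read data (~0.1%).

The number of fragments targets the requested coverage in the *interior*
of the simulated window (fragments must fit inside the window, so the
effective placement length is the window minus the mean insert). The
simulation window extends `insert_q99 + depth_flank` beyond the
realignment context so that the depth-feature flanks sit in the coverage
plateau rather than the tapering window edges; otherwise simulated
training rows would carry a systematic DHFFC bias relative to actual,
genome-wide data.

The built-in aligner is truth-aware: each simulated read is placed through
the haplotype-to-reference coordinate map implied by the variant (flank
bases map directly, deletions appear as D CIGAR elements, novel inserted
bases as I elements or soft clips at read ends, fully-novel reads as
unmapped). A plugin hook accepts any function producing an alignment
tibble, so an external aligner can stand in when exact pipeline matching
to a production aligner is wanted. The truth tags (`hap`, `hap_pos`)
stay on every read, which is what makes the aligner itself testable.

## Features

All evidence is extracted by `extract_features()` through one code path
for actual and simulated reads:

- **Realigned allele counts.** Pairs originally mapped within the 99th
  insert percentile of a breakpoint are realigned to both allele contexts.
  A read's score is a read-global/context-local affine-gap alignment in
  log10 units (match `log10(1-e)`, mismatch `log10(e/3)`, gap open −6,
  extend −1); the pair adds the log10 insert probability of the fragment
  length implied on that allele. Assignment requires a log10 margin > 1;
  otherwise the pair is ambiguous and counted in neither allele (the
  ambiguous count is kept as a diagnostic). The realignment context is
  widened by one insert mean plus two read lengths beyond the recruitment
  distance so that recruited mates always lie inside the context — this
  keeps the exact-substring fast path of the C++ scorer effective. The
  scoring constants are package choices, centralized in
  `realign_config()`.
- **Spanning pairs.** For pairs whose mates flank the event, the observed
  reference-frame fragment length `L` is weighted `P(L)` for the reference
  allele and `P(L + SVLEN)` for the alternate (a fragment spanning a
  deletion shrinks, and one spanning an insertion grows, when mapped back
  to the alternate frame); the two weights are normalized per pair.
- **Clipped reads.** Primary alignments with a soft clip of ≥ 4 bp whose
  clip boundary falls within two read lengths of a breakpoint.
- **Depth fold-changes.** Event depth over contig mean (DHFC), over the
  GC-matched bin mean (DHBFC), and over the mean of 1 kb flanks (DHFFC).
  Insertions have no reference width, so their event region is the
  breakpoint ± one read length — wide enough to capture the local pileup
  perturbation an insertion causes. Zero denominators produce `NA`, which
  is excluded from standardization fitting and imputed to the training
  mean at prediction.

## Classifiers

The **single** model is one RBF-kernel SVM per variant type, trained on 1
replicate per variant per zygosity with features standardized to zero mean
and unit variance (the same scaling is reused at prediction). The
hyperparameter sweep over C ∈ {1, 10, 100, 500, 1000, 5000, 10000} and
gamma ∈ {scale, 0.001, 0.0055, 0.01, 0.055, 0.1, 0.55} with 5-fold CV is
available but off by default — default parameters are essentially as
accurate on these features and far cheaper. Training rows can be
restricted to a BED mask.

The **variant** model is one random forest (100 trees, unrestricted
depth) per variant, trained on 100 replicates per zygosity; observations
with any feature more than 5 SD from the class-agnostic mean are dropped
first (a guard against degenerate replicates), falling back to the
unfiltered rows if that would eliminate a class.

Homozygous-reference training rows come, by default, from the actual
alignments at size-matched random null positions (drawn uniformly over the
eligible contig partition, avoiding every variant in the input call set) —
simulated hom-ref data have unrealistically low variance. Purely simulated
hom-ref rows are available via `hom_ref_sim = TRUE`.

The **hybrid** mode routes variants below 1 kb to per-variant classifiers
and larger ones to the single model; the package default (`mode =
"auto"`) is hybrid for deletions and single for insertions. Ties in the
class probabilities resolve in the fixed order hom-ref < het < hom-alt.

## Breakpoint proposals in tandem repeats

A deletion of whole units of a tandem repeat has ambiguous placement.
`detect_repeat_context()` scans periods up to the deletion length,
requiring the deleted sequence plus a window of equal length to be
periodic with ≤ 20% mismatches. The tolerance sits deliberately between
the two regimes the scan encounters: copies of an imperfect repeat differ
from each other at roughly twice the per-copy divergence (a few percent,
with wide sampling variance on the short comparison windows involved),
while a non-periodic offset mismatches at ~75%. A tighter cutoff misses
real periods on ordinarily diverged repeats — and a missed true period is
worse than useless, because the scan then locks onto a multiple of it and
proposes only placements that skip the true one. `propose_alternates()`
shifts the deletion by multiples of the period across the tract; a shifted
placement is accepted while its deleted sequence still resembles the
original (≤ 25% mismatch; this filter only needs to exclude placements
that leave the tract, since the final choice is made from the data).
`select_description()` simulates non-reference replicates for every
candidate, and picks the candidate whose actual feature vector is closest
(z-scored Euclidean distance) to its nearest non-reference class centroid.
The distance uses one realignment axis and one depth axis
(`alt_fraction`, `dhffc`): raw counts scale with the local realized
coverage, so a placement decision should not hinge on whether the sampled
region happens to be a little deeper than the simulation, and the three
depth fold-changes are near-duplicates of a single signal — including all
of them would triple-count the depth axis and let a wrong placement that
mimics a heterozygote of the wrong description outvote the realignment
evidence that actually distinguishes shifted placements.

## Evaluation machinery

`match_variants()` pairs calls with truth within a 2 kb window requiring
70% size similarity (`min|svlen| / max|svlen|`) and 70% sequence
similarity (normalized edit similarity of the deleted/inserted bases),
assigning greedily one-to-one by descending combined similarity — a
deterministic stand-in for heavier matchers. `concordance()` reports the
genotype confusion table, exact and non-reference concordance
(het/hom-alt collapsed), and precision/recall/F1 for the hom-ref vs
non-ref binarization; unmatched non-reference truth counts against recall
and unmatched non-reference calls against precision.
`mendelian()` flags a trio site as a Mendelian error exactly when no pair
of transmitted parental alleles explains the child, categorizing errors
as het de novo, hom de novo, or other; the denominator is sites genotyped
in all three members (optionally after a minimum-trio-GQ filter).
`offset_stratified_concordance()` bins matched pairs by the maximum
breakpoint offset.

## Synthetic fixtures and what they show

`make_reference()` / `plant_sample()` build seeded random genomes
(default GC 0.5) with optional imperfect tandem-repeat tracts (per-base
copy divergence 3% by default — perfect repeats would make unit-shifted
deletion placements exactly equivalent and refinement undecidable),
plant DEL/INS variants of chosen sizes and zygosities with ≥ 5 kb
separation, and sequence the diploid genome-wide with the same simulator
used for replicates. `benchmark_spec()` is the standard end-to-end
sample: 60 unique-context SVs (30 DEL, 30 INS, 60–2,000 bp, 20 per
zygosity) on two 250 kb contigs at 30×, 100 bp reads, 0.1% error —
two contigs keep the per-chromosome normalization honest and 250 kb
keeps the whole suite in CI-scale minutes.

What passing tests on these fixtures shows: the pipeline is internally
consistent (simulated evidence predicts simulated truth), the features
separate zygosities in unique sequence, and the refinement and evaluation
logic behave as specified. What they do not show: performance on real
genomes with repeat landscapes, segmental duplications, mapping biases of
production aligners, PCR artifacts, or non-uniform coverage beyond the GC
model — real-data accuracy must be established against real benchmark
call sets.

## Numerical choices and degenerate inputs

- Seeds: every stochastic step derives its seed deterministically from
  (global seed, variant id, zygosity, replicate index), so runs are
  byte-identical at fixed seed and individual replicates are reproducible
  in isolation.
- Realignment uses an exact-substring fast path, a provably-optimal
  anchored ungapped path (valid when its score beats any gapped
  alternative), and a windowed affine DP around the anchor otherwise (a
  gap longer than |mismatch|·read-length / gap-extend can never pay for
  itself, bounding the optimal alignment's extent); reads with no anchor
  fall back to the full-context DP.
- Variants whose REF allele is >10% N are skipped (simulation over
  assembly gaps is meaningless); variants within one flank of a contig
  edge raise an error asking the caller to clamp the flank.
- Empty inputs return empty-but-typed results (zero counts, `NA` depth
  ratios); a per-variant pipeline failure yields `./.` and the run
  continues.
- Coverage 0 produces a valid empty replicate.

## Problem sizes

The shipped tests and the acceptance script use the 60-SV benchmark
fixture at 30× (≈150,000 reads), 25 simulated replicates per zygosity for
per-variant forests in hybrid mode, 50 replicates for the depth-feature
calibration, 1,000 pairs for the realignment-oracle comparison, 20
tandem-repeat cases for proposal recovery, and 54 variants for the
offset experiment — sizes at which every distributional check has
comfortable statistical power while the whole suite stays in the
minutes range on a single core.
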