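# svgenotyper

Simulation-driven genotyping of structural variants (SVs) in paired-end
short-read sequencing data.

## The problem

Given a set of previously discovered, sequence-resolved deletion and
insertion SVs (a VCF with explicit REF/ALT sequences) and a sample's aligned
reads (BAM), determine each variant's zygosity — homozygous reference
(0/0), heterozygous (0/1), or homozygous alternate (1/1) — with a
Phred-scaled genotype quality. The difficulty is that the observable
evidence for an SV (realigned reads, discordant pairs, depth changes,
soft clips) depends jointly on the variant, its genomic context, the
sequencer, and the alignment pipeline, so no fixed parametric model of
"what a heterozygous deletion looks like" holds across variants.

`svgenotyper` sidesteps the modeling problem by **simulation**: for each
putative SV and each possible genotype it simulates sequencing replicates
matched to the sample (read length, base error rate, insert-size
distribution, coverage), pushes simulated and actual reads through the
*identical* feature-extraction code, and trains a classifier on the
simulated, label-known feature vectors to predict the genotype of the
actual data.

## Method at a glance

For a variant with reference and alternate haplotype contexts and a sample
profile (read length *l*, error rate *e*, insert PMF *P*, coverage *c*):

- **Evidence features** per variant: realigned allele counts and the alt
  fraction (pair score = glocal alignment log10-likelihood of both mates,
  match log10(1−e), mismatch log10(e/3), affine gaps −6/−1, plus
  log10 P(implied fragment length); a pair supports an allele when its
  log10 score margin exceeds 1); insert-probability-weighted spanning-pair
  counts (ref weight P(L), alt weight P(L + SVLEN)); soft-clip counts near
  breakpoints; and depth fold-changes DHFC / DHBFC / DHFFC (event depth
  over chromosome, GC-matched, and flanking-region depth).
- **Training data**: HET and HOM_ALT rows from simulated replicates;
  HOM_REF rows from the *actual* alignments at size-matched random null
  positions (pure hom-ref simulation is unrealistically clean).
- **Classifiers**: a per-sample, per-type RBF-SVM ("single" model; 1
  replicate per variant per zygosity, features standardized, optional
  C/gamma grid search with 5-fold CV) and a per-variant random forest
  ("variant" model; 100 replicates per zygosity, 100 trees, observations
  with any feature >5 SD from the mean excluded). The "hybrid" mode uses
  per-variant classifiers for SVs < 1 kb and the single model above that;
  the default is hybrid for deletions and single for insertions.
- **GQ** = min(99, floor(−10·log10(1 − max class probability))).

Also included: breakpoint-proposal refinement for deletions in tandem
repeats (propose placements shifted by the repeat period, keep the
description whose simulated non-reference evidence is closest to the actual
evidence in z-scored feature space); call-set matching (2 kb window, 70%
size and sequence similarity) with genotype/non-reference concordance;
Mendelian-error analysis for trios; and a fully synthetic fixture
generator (`fixture_spec()` / `plant_sample()`) so the whole pipeline runs
without any external data.

## Worked example

```r
library(svgenotyper)
library(dplyr)

# a synthetic sample: 2 x 60 kb genome, six planted SVs of known zygosity
spec <- fixture_spec(
  contigs = c(chrA = 60000L, chrB = 60000L),
  variants = tibble::tibble(
    svtype   = rep(c("DEL", "INS"), 3),
    size     = c(100L, 150L, 300L, 400L, 700L, 900L),
    zygosity = rep(c("HOM_REF", "HET", "HOM_ALT"), 2),
    context  = "unique", shift = 0L),
  seed = 441)
smp <- plant_sample(spec)

profile <- estimate_profile(smp$reads, smp$genome)
profile
#> <sample_profile>
#>  read length: 100 bp, error rate: 0.001
#>  mean coverage: 29.95x
#>  insert size: 350.8 +/- 76.2 bp (support 100-683)

calls <- genotype_svs(smp$truth, smp$reads, smp$genome, profile,
                      mode = "single", seed = 13)
left_join(calls, select(smp$truth, variant_id, truth = gt), "variant_id") |>
  select(variant_id, gt, truth, gq, mode_used)
#> # A tibble: 6 x 5
#>   variant_id gt    truth    gq mode_used
#> 1 sv001      0/1   0/1       7 single
#> 2 sv002      1/1   1/1       6 single
#> 3 sv003      0/0   0/0       7 single
#> 4 sv004      0/1   0/1       3 single
#> 5 sv005      1/1   1/1       3 single
#> 6 sv006      0/0   0/0       4 single
```

All six planted genotypes are recovered; `gq` is the Phred-scaled
confidence (here modest, as the single model was trained on just 18
simulated observations). `mode = "variant"` builds one random forest per
variant from 100 simulated replicates per zygosity and is slower but more
confident; `mode = "auto"` applies the default hybrid/single routing.

A command-line wrapper with `genotype`, `propose`, `evaluate`, and
`make-fixture` subcommands is installed at `inst/cli/svgenotyper`.

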