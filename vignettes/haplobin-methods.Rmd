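---
title: "haplobin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplobin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplobin)
```

## The problem

Highly heterozygous diploid genomes — outbreeding grasses are the motivating
case, with SNP densities around one per 20 bp — are poorly served both by
reference-based phasing (reference bias suppresses reads from the diverged
haplotype) and by graph-based phasing (haplotype-private sequence that fails
to align produces imbalanced haplomes). A practical middle road is to phase
variants against a haploid assembly, build the two haplotype consensus
sequences, extract the k-mers private to each haplotype, and use those
k-mers — not alignment — to partition long reads or unitigs into haplotype
sets. Short k-mers (21 bp) still match inside highly diverged regions, so
the partition escapes reference bias.

`haplobin` implements the computational stages of that strategy as testable
library functions plus a thin CLI (`exec/haplobin`):

* `hapconsensus` — heterozygous-site selection and haplotype consensus
  construction from a reference plus a phased VCF;
* `kmerlib` — canonical k-mer counting and set subtraction;
* `sortbin` — three-way (hap1 / hap2 / unassigned) classification of reads
  or unitigs;
* `purge` — evidence-based pairing and removal of redundant allelic
  contigs;
* `phaseval` — phasing-quality statistics;
* `hapcompare` — cross-haplome repeat masking and CIGAR-based variation
  decomposition;
* `simdip` — a synthetic diploid generator with complete ground truth, so
  every stage is testable without sequencing data.

## Models and decision rules

**Canonical k-mers.** A k-mer is stored as the lexicographic minimum of
itself and its reverse complement (the convention of KMC/Jellyfish/Meryl).
Internally k-mers are 2-bit encoded with A<C<G<T, so the numeric minimum of
the forward and reverse-complement codes is exactly the lexicographic rule;
the public contract is on strings. Windows containing any non-ACGT symbol
are skipped. Haplotype-specific sets are obtained by *presence/absence*
subtraction — common k-mers are removed from each set regardless of
multiplicity — because specificity is a membership question. No count floor
is applied by default (`min_count = 1`); a floor is exposed for noisy
assemblies.

**Binning rule.** For a sequence, `hits_i` counts every window occurrence
that is a member of specific set *i*, and `score_i = hits_i / |set_i|`
normalizes by set size, compensating unequal divergence between the two
haplotypes (the trio-binning normalization). The larger score wins; exact
ties — including the all-zero case — are conservatively `unassigned`.
Occurrences count multiply because repeated evidence is still evidence. An
optional `min_hits` floor is off by default.

**Consensus construction.** Only heterozygous, biallelic, phased records
with mapping quality ≥ 20 and depth ≥ 10 (both inclusive) are used. Within
each chromosome only the designated chromosome-level phase block is applied
(by default the block with the most sites); sites in small residual blocks
are skipped and counted. SNV-only application is the default because
long-range phasing pipelines primarily phase SNPs; `include_indels = TRUE`
applies anchored indels with a running coordinate offset. The round-trip
validator re-derives hap1-vs-hap2 differences with an alignment-free greedy
walk and compares them to the applied variants after VCF-style
left-normalization.

**Allelic purging.** Contigs are nodes; three parallel evidence lines form
typed edges: merged-interval alignment coverage of the shorter contig
(default threshold 0.7, a Purge-Haplotigs-style convention; the exact value
is not fixed by the method description and is exposed as a parameter),
shared collinear transcripts (strictly more than 5 genes, order preserved
or fully reversed, at most 5 intervening genes between consecutive shared
genes), and shared single-copy markers (at least 1). Any single evidence
type suffices by default (`require_n_evidences` tightens this). Within each
connected component exactly one contig is kept — the longest, ties broken
lexicographically — which resolves multi-way components in one auditable
sweep. Success of a purge is declared iff the duplicated-marker rate is
strictly below 10% and marker loss strictly below 5%.

**Phasing evaluation.** The non-reference allele ratio is computed per
fixed-origin 1 Mb window; the switch-rate estimate is the median over
windows of `min(r, 1 - r)` (folded by default, so the estimate does not
depend on which haplotype matches the reference). Windows without sites are
excluded rather than imputed — switch errors concentrate in low-SNP-density
regions, and imputing empty windows would bias the median. Two phasings are
compared after per-chromosome global orientation (the orientation
minimizing mismatches), so a whole-chromosome flip is not discordance.

**Variation decomposition.** Extended CIGARs (`=`/`X`/`I`/`D`/`S`) are
classified with a 50 bp structural cutoff: `X` runs are SNVs, short `I`/`D`
runs are INDELs, runs ≥ 50 bp are PAVs, and soft-clips are tallied once as
clipped bases with clips ≥ 50 bp additionally counted as PAV events
(without double-counting their bases, so the five base categories always
sum to the total). Identity is matched bases over that total. Ambiguous `M`
operations are rejected with a pointer to `--eqx` alignment; hard-clips are
ignored (none of the supported aligner invocations emit them with bases).
Alignment length for filtering is the query span uniformly. Per-position
cross-haplome coverage assigns each position the source-multiset count of
the canonical k-mer starting there; the trailing k−1 positions (and
positions whose window is interrupted) inherit the last valid start, and N
positions get 0 — the start-position convention of k-mer coverage tools,
made explicit and tested.

## What the simulator emulates — and what it does not

`simulate_diploid()` draws haplotype 1 as uniform random sequence, plants
multicopy repeat arrays (two identical genomic copies per array, array
lengths up to tens of kb), and samples non-overlapping heterozygous
variants: SNVs (default 0.05/bp, one per 20 bp), small indels (< 50 bp) and
PAVs (≥ 50 bp, present in one haplotype and absent from the other).
Haplotype 2 is derived by applying the variants, so the truth set is exact
by construction. Rejection sampling keeps variant footprints disjoint, off
the planted repeats, and gives indel/PAV events a 25 bp clean flank; this
makes the truth recoverable by the alignment-free walk (and is the reason
round-trip tests can demand exactness). SNV placement is otherwise
unrestricted, so SNV counts remain binomial at the configured rate.

Two deliberate idealizations matter when interpreting green tests:

* Planted repeats are *identical* copies kept free of heterozygous
  variation. They model the binning-blind share of a genome — sequence in
  which no haplotype-specific k-mer can exist. The default
  `repeat_fraction = 0.15` with 5–40 kb arrays reproduces the few-percent
  unassigned fraction seen for real ONT reads, and it is why the unassigned
  fraction falls as reads get longer (fewer reads fit inside an array).
  Real repeat landscapes — nested, diverged, het-bearing repeats making up
  most of a grass genome — are *not* emulated; passing tests say nothing
  about k-mer counting at genome scale or about diverged-repeat artifacts.
* Read errors are a flat per-base rate with substitutions : insertions :
  deletions at 60:20:20 (ONT-like at 0.1, HiFi-like at 0.0005); there is no
  homopolymer bias, quality model, or coverage bias. Read lengths are
  log-normal (`read_length_sdlog = 0.3` by default) because only aggregate
  length statistics, not instrument-specific distributions, matter for the
  properties tested.

The mosaic reference (`make_mosaic_reference`) concatenates alternating
haplotype blocks with breakpoints drawn outside variant footprints, so no
block boundary splits an allele; `emit_phased_vcf` re-expresses every
variant against that reference (swapping alleles and genotype orientation
inside haplotype-2 blocks) and can flip each site's phase independently
with a configured switch-error probability, recording every flip.

Heterozygosity presets (`heterozygosity_preset("lp")` at 2.21% and `"lm"`
at 3.49%) scale the SNV rate to the two genotypes the workflow was
developed on.

## Numerical and interface choices

* Coordinates are 0-based half-open internally (BED convention) and
  1-based in VCF records; truth variant positions are 1-based to match the
  VCF they are emitted into.
* `cpp_diff_sequences` resynchronizes with a 20 bp probe accepting ≥ 75%
  agreement — a correct offset disagrees only at nearby substitutions
  (~5%), a wrong offset agrees at random (~25%). Offsets whose probe window
  would be truncated by the sequence end are accepted only on exact
  remainder alignment, which prevents spurious tail matches during the
  indel-length scan. Variant clusters denser than the probe tolerates can
  defeat the walk; that is a limitation of the *validation harness*, not of
  consensus construction.
* Phase-set selection ties (equal spans) break by site count, then by
  smallest PS identifier; purge retention ties break lexicographically —
  all deterministic.
* k ≤ 32 (64-bit encoding); k = 21 for binning, k = 27 for repeat
  coverage.
* CLI outputs are written atomically (temp-then-rename) and each run drops
  a `manifest.json` with its resolved parameters.

## Problem sizes used in the shipped checks

The test-suite simulations use 7 × 1 Mb chromosomes for the binning study
(with 2,500 reads per length class), 1–2 Mb genomes for switch-rate and
discordance recovery (20 replicate seeds), and ≤ 50-contig graphs for
purging — sizes at which every property is measurable in minutes on one
core while the binomial tolerances stay tight. `scripts/acceptance.R`
re-runs the same study at 3 × 1 Mb and prints the headline quantities it
computes.

## Known limitations

* In-memory k-mer hashing only; genome-scale counting should use a
  disk-based counter upstream and import the sets via `read_kmerset()`.
* The purge module consumes evidence tables (PAF, gene placements); it does
  not run aligners, transcript mappers or ortholog detectors.
* `phaseval` evaluates phasings; it does not phase.
* Polyploids are out of scope; everything assumes exactly two haplotypes.
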