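# haplocall

Haplotype-aware two-pass small-variant calling for long-read sequencing data,
at desk scale and fully testable without external datasets.

## The problem

Deep-learning long-read variant callers reach excellent accuracy but are
computationally heavy. A well-established way to keep both speed and accuracy
is a **two-pass design**: a cheap pileup pass first, an expensive
haplotype-aware pass only where it matters.

1. **Pileup pass.** Per-position summary counts nominate candidate sites
   (depth ≥ `min_coverage`, allelic fraction ≥ `min_af`); a classifier
   genotypes each candidate from a windowed count feature.
2. **Intermediate phasing.** High-quality heterozygous SNPs are phased per
   chromosome with a two-stage greedy graph algorithm: local blocks from
   adjacent-by-coverage allele-pairing evidence, then a block-level graph
   joined by longer-range read evidence, then a minimum-error-correction
   (MEC) local refinement.
3. **In-memory haplotagging.** For every chunk, the phased SNPs overlapping
   its flank-extended window define two reference haplotypes HP1/HP2. Each
   read gets support counts N<sub>Hap1</sub>, N<sub>Hap2</sub> (one per
   phased SNP whose read base matches that haplotype's allele) and the tag

   HP = 1 if N<sub>Hap1</sub> > N<sub>Hap2</sub>; 2 if N<sub>Hap1</sub> <
   N<sub>Hap2</sub>; 0 otherwise (including the zero-evidence case).

   No intermediate tagged BAM is written.
4. **Full-alignment pass.** The lowest-quality 70% of pileup variant calls
   plus the lowest-quality 10% of pileup reference calls are refined from a
   haplotype-sorted read × position × channel tensor with three task heads —
   21-genotype (all unordered pairs from {A,C,G,T,Ins,Del}), zygosity, and
   indel length — combined by a joint, compatibility-constrained decision.
5. **Merge and write.** High-confidence pileup calls and full-alignment calls
   are merged, phase-annotated (GT `0|1`/`1|0` + PS) and written as VCF 4.2
   (optionally GVCF with `END`-tagged non-variant blocks).

Everything runs on overlapping genome **chunks** (default 5 Mbp cores) so the
work units are independent and the output is identical for any worker count.

The package ships a seeded **diploid read simulator** (phased SNPs/indels,
lognormal read lengths, per-base substitution/insertion/deletion errors,
analytically constructed alignments — no aligner needed), pluggable
**classifier backends** with a fixture trainer, and an evaluator reporting
precision/recall/F1 over five categories (overall, SNP, Indel, Insertion,
Deletion).

## Worked example

```r
library(haplocall)

# 1. simulate a 200 kb diploid sample at 30x with long-read error rates
cfg   <- simulation_config(length = 2e5, coverage = 30, seed = 42)
truth <- simulate_truth(cfg)
reads <- simulate_reads(truth, cfg)
paths <- write_simulation(truth, reads, "sim")

# 2. train the fixture backends on an independent simulation
tcfg <- simulation_config(length = 2e5, coverage = 30, seed = 11)
tt   <- simulate_truth(tcfg)
bk   <- train_backends_from_simulation(tt, simulate_reads(tt, tcfg),
                                       backend_spec(seed = 7))

# 3. call variants
run <- run_pipeline(pipeline_config(paths$fasta, paths$bam, "out", bk, seed = 42))
run
#> <haplocall run> 380 final calls (2081 candidates) | 1 phase blocks,
#> N50 195912 bp | 97.2% reads haplotagged
#> VCF: out/sample.vcf

# 4. evaluate against the simulated truth
m <- compare_to_truth(read_vcf(run$vcf), truth_calls(truth))
as.data.frame(m)
#>    category  tp fp fn precision recall f1
#> 1   overall 380  0  0         1      1  1
#> 2       SNP 322  0  0         1      1  1
#> 3     Indel  58  0  0         1      1  1
#> 4 Insertion  21  0  0         1      1  1
#> 5  Deletion  37  0  0         1      1  1
autoplot(m)
```

The run object reports 380 final calls from 2081 candidates: the pileup pass
nominated ~2k sites (mostly sequencing-error pileups that the classifier
genotypes as reference), one phase block spans nearly the whole 200 kb
contig, and 97% of reads were assigned a haplotype. At these error rates the
caller recovers the simulated truth exactly; genotype-aware exact matching
gives F1 = 1 in all five categories.

A thin CLI wraps the same functions
(`inst/cli/haplocall call|simulate|evaluate|phase-stats`).

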