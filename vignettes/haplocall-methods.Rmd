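---
title: "haplocall: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplocall: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind the package, the parameters that
matter, the design choices made where the design was genuinely open, and what
the simulator-based tests do and do not demonstrate. Coordinates are 0-based
half-open everywhere inside the package; the single conversion to 1-based
happens when VCF records are written.

## The two-pass calling model

Long-read small-variant calling must separate true variants from a dense
background of sequencing errors (here ~3% of bases). The package implements
the accelerated two-pass architecture used by modern long-read callers:

* a **pileup pass** over per-position summary counts that is cheap enough to
  scan the whole genome, nominates candidate sites, and genotypes the easy
  ones; and
* a **full-alignment pass** that re-examines only the low-confidence sites
  with read-level, haplotype-sorted evidence.

The bridge between the passes is haplotype structure: heterozygous SNPs
called confidently by the first pass are phased, reads are assigned to
haplotypes in memory, and the second pass sees reads grouped by haplotype, so
a true heterozygous variant appears as a clean within-group signal while
random errors do not segregate by haplotype.

### Genome chunking

Contigs are tiled into contiguous chunk cores (default 5 Mbp, advisory range
3–10 Mbp; values outside the range are accepted with a warning because chunk
size is a user-visible throughput/overhead trade-off, not a correctness
parameter). Candidate coordinates are owned by exactly one core. Two
extensions make per-chunk work self-contained:

* `overlap` (default 16 bp) — half the pileup feature window width, so
  feature windows of candidates at core boundaries are complete;
* `flank` (default 100 kb) — haplotagging context, chosen to exceed the
  maximum simulated read length (100 kb truncation) so that every phased SNP
  a chunk-owned read can cover lies inside the chunk's fetch window. This is
  what makes chunked and unchunked runs produce identical haplotags.

When explicit regions of interest are supplied, chunk boundaries are aligned
to the intervals and long regions are subdivided into near-equal cores
(sizes differing by ≤1 bp); regions are never merged across gaps. The last
core per contig may simply be short — redistributing the tail would buy
nothing and complicate the exact-cover contract.

### Pileup pass

Per position the package counts A/C/G/T observations split by strand,
insertion runs (counted once at the anchor base before the run), and
deletions (counted at every deleted reference position). Depth is the number
of reads aligned at the position (base or deletion; insertions do not add
depth). A site becomes a candidate when depth ≥ 4 and some non-reference
class reaches its allelic-fraction floor (0.08 for substitutions, 0.12 for
indels; all CLI-exposed). These permissive defaults give a recall-oriented
first pass: at 30× they admit essentially every true variant plus a few
thousand error sites per Mb, which the classifier then genotypes as
reference.

The pileup feature is a fixed window (W = 33 positions) × 24 channels: the
12 strand-split class counts, a reference one-hot, and a reference-relative
block (reference/alternate counts and fractions). The relative block exists
because the builtin heads are shallow: a linear model cannot represent
"non-reference count" across sites with different reference bases from raw
per-base channels alone, and without it validation accuracy collapses to
memorization. Windows at contig edges are zero-padded.

Genotype classes are {hom-ref, het, hom-alt, multiallelic-het}; genotype
quality is `-10 log10(1 - p_max)` capped at 60.

### Tier routing

The fraction of pileup calls routed to the second pass is implemented as a
calibrated quantile: the lowest-quality `floor(0.7 n)` of variant calls and
the lowest-quality `floor(0.1 n)` of reference calls (candidates genotyped
hom-ref). Floor rounding is the documented convention. A fixed-threshold
strategy is also provided (`tier_split(strategy = "threshold")`) because the
underlying quality cutoffs of the quantile view are not universal constants;
the quantile strategy is the default since it reproduces the intended
routing fractions exactly on any input.

### Phasing

Input: heterozygous, biallelic, single-nucleotide pileup calls with quality
≥ 15 (indels are excluded — indel alleles are noisier and contribute little
linkage information relative to their error rate). Per contig, an allele
graph is built: nodes are het SNPs, and for each read, each co-covered SNP
pair within 200 kb whose bases match ref or alt increments one cell of the
pair's 2×2 pairing-count matrix. Third alleles and deletions are treated as
missing data.

Phasing is a two-stage greedy: stage 1 processes adjacent-by-coverage edges
in descending evidence margin |cis − trans| (ties: leftmost coordinate, then
SNP index) under a parity union-find, accepting an edge unless it
contradicts orientations already fixed in its component; stage 2 aggregates
the remaining longer-range pairing evidence between blocks and re-applies
the same greedy acceptance to join them. A final refinement pass walks each
block with single-SNP flips and suffix flips (the switch-error repair move),
accepting any move that lowers the read-level minimum-error-correction cost,
to a fixpoint. The refinement is incremental (per-fragment mismatch state),
so its cost is proportional to fragment size, not block size squared. On
seeded random instances with ≤8 SNPs and ≤30 reads the greedy+refinement
result attains the exhaustive-search MEC minimum (tested over 200
instances), but the algorithm is a heuristic and global optimality is not
guaranteed in general.

Block labels HP1/HP2 are arbitrary per block (no trio information); the
first SNP of each block is normalized to cis orientation, and everything
downstream is label-symmetric.

### In-memory haplotagging

Per chunk, phased het SNPs in the flank-extended window define allele maps
HP1/HP2. For each read, `count_support` compares the read base at every
covered phased SNP with both alleles; matches increment N<sub>Hap1</sub> or
N<sub>Hap2</sub>; deletions, third alleles, and bases below a quality floor
(default 10) count for neither. The tag is the strict majority: HP = 1 or 2,
and 0 on ties including 0–0. Counting is unweighted — the quality floor is a
guard against raw error bases, not a weighting scheme. Reads whose covered
SNPs span several blocks pool counts across blocks (the assignment rule has
no block term); the per-chunk count of such reads is recorded because label
arbitrariness across blocks can cancel their evidence. No file is written at
any point in this stage.

### Full-alignment pass

For each routed site the feature tensor is D × W × C (defaults 89 reads ×
33 positions × 14 channels: base one-hot, base quality, mapping quality,
strand, haplotype encoding +1/−1/0, inserted length after the position,
deletion flag, reference one-hot). Rows are ordered HP1, HP2, untagged;
within a group by start coordinate and read id. When coverage exceeds D, an
evenly-spaced-by-rank subsample is taken per haplotype group with
largest-remainder allocation, so the tensor is deterministic and group
proportions are preserved. The insertion channel carries the inserted
*length* rather than a 0/1 flag; inserted bases have no reference column of
their own, and a pure flag would make insertion length unlearnable from the
tensor.

Three task heads consume a reduced view of the tensor (per-group
center-column composition, reference-relative fractions, fold-symmetric
terms such as minor-allele fraction and alt·(1−alt), cross-group contrasts,
and window-wide indel profiles). The symmetric terms matter: zygosity
("hom" = hom-ref ∪ hom-alt vs "het") is a middle-versus-extremes decision in
allele fraction and is not linearly separable from raw fractions alone.

The 21-genotype head is trained internally over reference-relative classes
(RR, RX, XX, XY, RI, II, XI, RD, DD, XD, ID with R = reference base,
X/Y = non-reference bases) and its predictions are expanded onto the
concrete 21-class vocabulary per site using the reference and dominant
alternate base. At fixture scale this pooling is what gives every class
enough training support; a concrete-class head starves the indel classes
(2–3 examples each) and visibly loses insertions.

The joint decision selects the argmax of
`p_gt21 × p_zygosity[zygosity(class)]` over classes *compatible* with the
site's observed alleles (the reference pair is always compatible;
lexicographic tie-break), takes quality from the selected class's gt21
probability, and reconstructs concrete alleles: the observed read majority
decides the inserted sequence or deletion run, with the indel-length head
breaking ties among equally supported observations. Deletion calls are
re-anchored to the base before the observed run, which is also why candidate
records at several deleted positions of one run deduplicate to a single VCF
record at merge time (full-alignment records win ties, with a warning).

### Output and evaluation

VCF 4.2 with GT/GQ/DP/AF and PS for phased hets (`0|1` = ref on HP1);
GVCF adds `END`-tagged `<NON_REF>` blocks with a banded minimum GQ derived
from depth and reference support. The evaluator decomposes multiallelic
records, trims shared prefix/suffix bases, strips phase from genotypes, and
then matches exactly on (contig, pos, ref, alt, genotype) within confident
regions; calls outside confident regions are ignored rather than counted as
false positives. Matching is genotype-aware by design — a deliberate,
deterministic simplification relative to haplotype-complex matching, which
means a call with the right allele but wrong zygosity counts as both FP and
FN. Counts are reported for overall/SNP/Indel/Insertion/Deletion with
Indel = Insertion + Deletion by construction.

## The simulator: what it emulates, and what it does not

`simulate_truth` draws a uniform-composition reference and non-overlapping
left-anchored variants: het SNPs (1/1000 bp), hom SNPs (1/2000), het indels
(1/5000, lengths 1–10 geometric), hom indels (1/10000) — densities in the
range expected for a heterozygous human-like diploid genome. Het phase is
uniform. Conflicting draws (within 12 bp) are rejected; a configuration
where more than half the draws conflict is refused. `simulate_reads` draws
lognormal read lengths (median 10 kb), alternates haplotypes, starts
uniformly over the extended interval `[-(len-1), end)` with clipping at
contig bounds — so depth is uniform across the contig and edge variants are
recoverable — and injects per-base substitution (2%), insertion (0.5%) and
deletion (0.5%) errors, defaults chosen to mimic current long-read error
magnitudes. Alignments are constructed analytically from the
haplotype-to-reference coordinate map: simulated CIGARs are exactly right by
construction.

Not emulated: platform-specific error profiles (an optional
homopolymer-bias flag triples indel error density in repeat context but is
off by default for determinism across configurations), mapping errors and
mapping-quality variation, coverage biases (GC, mappability), structural
variants, and alignment ambiguity in repeats. Passing tests therefore
demonstrate the correctness of the machinery — chunking, counting, phasing,
tagging, tensor construction, decision logic, I/O — and the achievable
accuracy under idealized alignments; they do not predict accuracy on real
data, where alignment artifacts dominate the residual error of mature
callers.

## Classifier backends

The inference contract is a pluggable, order-preserving batched classifier
(`batched_predict`): row i of the output always corresponds to row i of the
input for every batch size (default 512) and worker count, and per-batch
working data is released when the batch completes. Two builtin kinds are
provided — a ridge-regularized multinomial linear model (default) and a
small single-hidden-layer network — both deterministic given the spec seed.
Classes with fewer than 3 training examples are dropped from a head (they
can be neither fit nor validated) and are predicted with probability 0; the
explicit missing-class error fires when a caller names required classes that
have no example. Training uses a stratified 80/20 site split; held-out
accuracy is stored on each head and visible via `tidy()`/`glance()`.

The fixture trainer bootstraps in two phases: the pileup head is trained on
truth-labeled pileup features, then the freshly trained pileup stage is run
to reproduce the pipeline's own routing (tier split, phasing, haplotagging),
and the full-alignment heads are trained on truth-labeled tensors of the
routed sites. Training the second pass on its actual operating distribution
matters: the routed set is dominated by low-quality variant calls and
borderline reference calls, not by easy sites.

Model archives embed a format version and a content digest; loading refuses
a mismatch.

## Numerical and degenerate-input choices

* Quality scores are capped at 60 (`-10 log10` of a probability floored at
  1e-6); probability rows are renormalized after prediction and must sum to
  1 within 1e-6.
* Ties are deterministic everywhere: alt alleles by count then
  lexicographically; greedy edges by margin, leftmost coordinate, then
  index; gt21 classes lexicographically; subsampled read rows by evenly
  spaced rank.
* Empty inputs flow through: an empty BAM yields a header-only VCF; empty
  candidate sets, empty phase blocks and zero-read tensors are represented
  explicitly (the all-zero tensor is flagged).
* A failing chunk aborts the run, names the chunk, and removes partial
  output files.
* The N reference base participates in pileup depth but never seeds
  candidates (no defined reference allele).

## Problem sizes used by the tests

The test suite trains its shared backends on a 150 kb / 30× simulation and
evaluates on 100–200 kb fixtures; the end-to-end recovery check runs at
1 Mb / 30× with an independent seed, where the package reaches SNP F1 ≥ 0.99
and indel F1 ≥ 0.90 against the simulated truth (the acceptance script
reproduces this at the same scale). These sizes give every classifier class
hundreds of training examples while keeping the whole suite fast on a single
CPU; accuracy at these scales was indistinguishable from larger training
fixtures in development.

## Known limitations

* Genotype-aware exact matching is stricter than haplotype-complex
  benchmarking; reported F1 on representationally ambiguous indels can be
  pessimistic.
* Pooled cross-block haplotag counting can cancel evidence for reads
  spanning blocks with discordant arbitrary labels; such reads are counted
  and reported per chunk.
* The greedy phaser is a heuristic; MEC optimality is verified empirically
  at small scale, not guaranteed.
* Multiallelic sites involving an indel allele plus a second alternate are
  emitted as the dominant indel het; fully general multiallelic indel
  genotypes are out of scope.
* The builtin heads are shallow models on engineered features; they are the
  fixture stand-in for the pluggable backend contract, not a claim about
  optimal classifier architecture.
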