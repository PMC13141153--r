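#' Collect chunk-specific reference haplotypes
#'
#' Retrieves every phased heterozygous SNP overlapping the chunk's
#' flank-extended fetch window `[fetch_start, fetch_end)` and decodes the two
#' reference haplotype allele maps: at a cis-oriented SNP HP1 carries the ref
#' allele and HP2 the alt; trans is the reverse. SNPs from different phase
#' blocks coexist (block labels are arbitrary per block).
#'
#' @param chunk One chunk row.
#' @param phase_blocks `vc_phase_blocks` for the chunk's contig.
#' @return `vc_chunk_haps`: list with `chunk` and `snps` (tibble `pos`,
#'   `hp1`, `hp2`, `block_id`).
#' @export
collect_chunk_haplotypes <- function(chunk, phase_blocks) {
  pb <- phase_blocks[
    phase_blocks$contig == chunk$contig &
      phase_blocks$pos >= chunk$fetch_start &
      phase_blocks$pos < chunk$fetch_end,
  ]
  cis <- pb$orientation == "cis"
  snps <- tibble(
    pos = pb$pos,
    hp1 = ifelse(cis, pb$ref, pb$alt),
    hp2 = ifelse(cis, pb$alt, pb$ref),
    block_id = pb$block_id
  )
  snps <- snps[order(snps$pos), ]
  structure(list(chunk = chunk, snps = snps), class = "vc_chunk_haps")
}

#' Count haplotype support for one read
#'
#' Iterates the phased SNP positions the read covers over its full span; at
#' each, the read base (via its alignment projection) is compared to the two
#' haplotype alleles: a match with HP1 increments `n_hap1`, with HP2
#' `n_hap2`; deletions, uncovered positions, third alleles, and bases below
#' the quality floor contribute to neither.
#'
#' @param read One read (one-row `vc_reads` or list).
#' @param haps `vc_chunk_haps`.
#' @param min_bq Base-quality floor (default 10; set 0 to disable).
#' @return Named integer vector `c(n_hap1, n_hap2)`.
#' @export
count_support <- function(read, haps, min_bq = 10) {
  if (is_tibble(read)) {
    stopifnot(nrow(read) == 1)
    read <- list(a_qpos = read$a_qpos[[1]], a_rpos = read$a_rpos[[1]],
                 seq = read$seq, qual = read$qual[[1]])
  }
  snps <- haps$snps
  if (nrow(snps) == 0) return(c(n_hap1 = 0L, n_hap2 = 0L))
  idx <- match(snps$pos, read$a_rpos)
  q <- read$a_qpos[idx]
  hasb <- !is.na(idx) & !is.na(q)
  if (!any(hasb)) return(c(n_hap1 = 0L, n_hap2 = 0L))
  base <- substring(read$seq, q[hasb] + 1L, q[hasb] + 1L)
  bq <- read$qual[q[hasb] + 1L]
  base[bq < min_bq] <- NA_character_
  c(
    n_hap1 = sum(base == snps$hp1[hasb], na.rm = TRUE),
    n_hap2 = sum(base == snps$hp2[hasb], na.rm = TRUE)
  )
}

#' Assign a haplotype tag from support counts
#'
#' The piecewise majority rule: HP = 1 if `n_hap1 > n_hap2`, HP = 2 if
#' `n_hap1 < n_hap2`, otherwise HP = 0 (unphased; including the
#' zero-evidence case `n_hap1 = n_hap2 = 0`). Vectorized.
#'
#' @param n_hap1,n_hap2 Non-negative support counts.
#' @return Integer HP tag(s) in {0, 1, 2}.
#' @export
assign_haplotype <- function(n_hap1, n_hap2) {
  if (any(n_hap1 < 0) || any(n_hap2 < 0)) {
    stop_invalid("support counts must be non-negative")
  }
  ifelse(n_hap1 > n_hap2, 1L, ifelse(n_hap1 < n_hap2, 2L, 0L))
}

#' Haplotag a chunk's reads in memory
#'
#' Tags every read by [assign_haplotype()] over [count_support()] and returns
#' the reads sorted by haplotype group (HP 1, then 2, then 0; within a group
#' by `ref_start` then `read_id`), the ordering the full-alignment feature
#' builder consumes. No intermediate files are written. Reads whose covered
#' SNPs span multiple phase blocks pool their counts across blocks; the
#' number of such reads is recorded in `attr(, "cross_block_reads")`.
#'
#' @param reads `vc_reads` fetched for the chunk.
#' @param haps `vc_chunk_haps` from [collect_chunk_haplotypes()].
#' @param min_bq Base-quality floor for support counting (default 10).
#' @return The reads tibble with `hp_tag` set, reordered.
#' @export
haplotag_chunk <- function(reads, haps, min_bq = 10) {
  n <- nrow(reads)
  snps <- haps$snps
  n1 <- integer(n)
  n2 <- integer(n)
  cross <- 0L
  if (n > 0 && nrow(snps) > 0) {
    for (j in seq_len(n)) {
      rp <- reads$a_rpos[[j]]
      idx <- match(snps$pos, rp)
      q <- reads$a_qpos[[j]][idx]
      hasb <- !is.na(idx) & !is.na(q)
      if (!any(hasb)) next
      base <- substring(reads$seq[j], q[hasb] + 1L, q[hasb] + 1L)
      bq <- reads$qual[[j]][q[hasb] + 1L]
      base[bq < min_bq] <- NA_character_
      match1 <- base == snps$hp1[hasb]
      match2 <- base == snps$hp2[hasb]
      n1[j] <- sum(match1, na.rm = TRUE)
      n2[j] <- sum(match2, na.rm = TRUE)
      informative <- (match1 | match2) & !is.na(base)
      if (length(unique(snps$block_id[hasb][informative])) > 1) cross <- cross + 1L
    }
  }
  reads$hp_tag <- assign_haplotype(n1, n2)
  grp <- match(reads$hp_tag, c(1L, 2L, 0L))
  out <- reads[order(grp, reads$ref_start, reads$read_id), ]
  attr(out, "cross_block_reads") <- cross
  out
}

#' Haplotag statistics
#'
#' Percentage of reads assigned to a haplotype (HP != 0) and counts per tag.
#'
#' @param assignments A tagged `vc_reads` tibble (or integer HP vector).
#' @return Tibble with `n_total`, `n_hp1`, `n_hp2`, `n_untagged`,
#'   `tagged_pct`, `empty` (TRUE when the input had no reads; the percentage
#'   is then reported as 0).
#' @export
haplotag_stats <- function(assignments) {
  hp <- if (is.numeric(assignments)) assignments else assignments$hp_tag
  n <- length(hp)
  tibble(
    n_total = n,
    n_hp1 = sum(hp == 1L),
    n_hp2 = sum(hp == 2L),
    n_untagged = sum(hp == 0L),
    tagged_pct = if (n == 0) 0 else 100 * sum(hp != 0L) / n,
    empty = n == 0
  )
}

#' Export haplotagged reads for a whole sample
#'
#' Convenience wrapper around [haplotag_chunk()]: fetches reads per contig,
#' tags them against the supplied phase blocks, and writes an indexed BAM
#' with the `HP` auxiliary tag. Inspection output; not on the calling
#' critical path.
#'
#' @param reference Indexed FASTA path.
#' @param bam Indexed BAM path.
#' @param phase_blocks `vc_phase_blocks` (e.g. from a `vc_run`).
#' @param path Output BAM path.
#' @param min_mapq,min_bq Filters as in the pipeline (defaults 5 and 10).
#' @return The BAM path.
#' @export
export_tagged_bam <- function(reference, bam, phase_blocks, path,
                              min_mapq = 5, min_bq = 10) {
  ref <- reference_source(reference)
  chunks <- partition_genome(ref$contigs, suppressWarnings(chunking_config(
    chunk_size = max(ref$contigs), overlap = 0, flank = 0
  )))
  tagged <- bind_rows(lapply(seq_len(nrow(chunks)), function(i) {
    chunk <- chunks[i, ]
    haplotag_chunk(
      fetch_reads(bam, chunk, min_mapq = min_mapq),
      collect_chunk_haplotypes(chunk, phase_blocks),
      min_bq = min_bq
    )
  }))
  write_tagged_bam(tagged, ref$contigs, path)
}
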