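#' Fetch reads overlapping a chunk's fetch window
#'
#' Returns reads overlapping `[fetch_start, fetch_end)` of the chunk.
#' Unmapped, secondary, duplicate and (by default) supplementary alignments
#' are excluded, as are reads below `min_mapq`. The source may be an indexed
#' BAM path or an in-memory `vc_reads` tibble (e.g. straight from
#' [simulate_reads()]).
#'
#' @param source BAM file path (index required) or a `vc_reads` tibble.
#' @param chunk One chunk row from [partition_genome()].
#' @param min_mapq Minimum mapping quality (default 5).
#' @param include_supplementary Keep supplementary alignments (default FALSE).
#' @return A `vc_reads` tibble (see [simulate_reads()] for columns).
#' @export
fetch_reads <- function(source, chunk, min_mapq = 5, include_supplementary = FALSE) {
  if (is.character(source)) {
    return(fetch_reads_bam(source, chunk, min_mapq, include_supplementary))
  }
  stopifnot(is_tibble(source))
  ends <- map_dbl(source$a_rpos, function(r) {
    if (all(is.na(r))) return(-1)
    max(r, na.rm = TRUE) + 1
  })
  keep <- source$contig == chunk$contig &
    source$ref_start < chunk$fetch_end &
    ends > chunk$fetch_start &
    source$mapq >= min_mapq
  out <- source[keep, ]
  out[order(out$ref_start, out$read_id), ]
}

fetch_reads_bam <- function(path, chunk, min_mapq, include_supplementary) {
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    abort(
      sprintf("BAM index not found for '%s'; create it with Rsamtools::indexBam()", path),
      class = "haplocall_missing_index"
    )
  }
  bf <- Rsamtools::BamFile(path)
  hdr <- Rsamtools::scanBamHeader(bf)
  if (!(chunk$contig %in% names(hdr$targets))) {
    warn(sprintf("contig '%s' absent from '%s'; returning no reads", chunk$contig, path))
    return(empty_reads())
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isDuplicate = FALSE,
    isSupplementaryAlignment = if (include_supplementary) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag, mapqFilter = min_mapq,
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("HP", "XH"),
    which = GenomicRanges::GRanges(
      chunk$contig,
      IRanges::IRanges(chunk$fetch_start + 1, max(chunk$fetch_end, chunk$fetch_start + 1))
    )
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) return(empty_reads())
  pairs <- map2(res$cigar, res$pos - 1L, cigar_to_pairs)
  hp <- res$tag$HP %||% rep(NA_integer_, n)
  xh <- res$tag$XH %||% rep(NA_integer_, n)
  out <- tibble(
    read_id = res$qname,
    contig = chunk$contig,
    ref_start = res$pos - 1L,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(res$mapq),
    hp_tag = as.integer(ifelse(is.na(hp), 0L, hp)),
    truth_hap = as.integer(xh),
    seq = as.character(res$seq),
    qual = lapply(as.character(res$qual), string_to_qual),
    a_qpos = map(pairs, "qpos"),
    a_rpos = map(pairs, "rpos"),
    cigar = res$cigar
  )
  # strict half-open filter: scanBam returns 1-based closed overlaps
  ends <- map_dbl(out$a_rpos, function(r) max(r, na.rm = TRUE) + 1)
  out <- out[out$ref_start < chunk$fetch_end & ends > chunk$fetch_start, ]
  out <- out[order(out$ref_start, out$read_id), ]
  class(out) <- c("vc_reads", class(out))
  out
}

#' Read base aligned to a reference position
#'
#' @param read A single read (one-row `vc_reads` tibble or a list with
#'   `a_qpos`, `a_rpos`, `seq`).
#' @param ref_pos 0-based reference position(s); vectorized.
#' @return Character vector: the aligned base, `"-"` where the position is
#'   deleted in the read, `NA` where the read does not cover it. Insertions
#'   have no reference projection and are never returned.
#' @export
base_at_reference_position <- function(read, ref_pos) {
  if (is_tibble(read)) {
    stopifnot(nrow(read) == 1)
    read <- list(a_qpos = read$a_qpos[[1]], a_rpos = read$a_rpos[[1]], seq = read$seq)
  }
  idx <- match(ref_pos, read$a_rpos)
  q <- read$a_qpos[idx]
  out <- rep(NA_character_, length(ref_pos))
  covered <- !is.na(idx)
  del <- covered & is.na(q)
  has_base <- covered & !is.na(q)
  out[del] <- "-"
  if (any(has_base)) {
    out[has_base] <- substring(read$seq, q[has_base] + 1L, q[has_base] + 1L)
  }
  out
}

#' Read a reference FASTA (indexed)
#'
#' @param path FASTA path; the .fai index is created if missing.
#' @return List with `contigs` (named lengths) and `fetch(contig, start, end)`
#'   returning the uppercase sequence of a 0-based half-open window.
#' @export
reference_source <- function(path) {
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  fa <- Rsamtools::FaFile(path)
  idx <- Rsamtools::scanFaIndex(fa)
  lens <- setNames(GenomicRanges::width(idx), as.character(GenomicRanges::seqnames(idx)))
  list(
    path = path,
    contigs = lens,
    fetch = function(contig, start, end) {
      end <- min(end, lens[[contig]])
      if (end <= start) return("")
      rng <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1, end))
      toupper(as.character(Rsamtools::scanFa(fa, rng)[[1]]))
    }
  )
}

#' Write reads as a coordinate-sorted SAM file
#'
#' The haplotype tag is written as the standard `HP` integer auxiliary tag
#' (omitted when unphased); the simulator's generating haplotype is written as
#' `XH`.
#'
#' @param reads A `vc_reads` tibble.
#' @param contig_lengths Named lengths for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contig_lengths, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths), as.integer(contig_lengths))
  )
  reads <- reads[order(match(reads$contig, names(contig_lengths)), reads$ref_start), ]
  n <- nrow(reads)
  recs <- character(n)
  for (i in seq_len(n)) {
    tags <- character(0)
    if (!is.na(reads$hp_tag[i]) && reads$hp_tag[i] > 0L) {
      tags <- c(tags, sprintf("HP:i:%d", reads$hp_tag[i]))
    }
    if (!is.null(reads$truth_hap) && !is.na(reads$truth_hap[i])) {
      tags <- c(tags, sprintf("XH:i:%d", reads$truth_hap[i]))
    }
    recs[i] <- paste(c(
      reads$read_id[i],
      if (reads$strand[i] == "-") 16L else 0L,
      reads$contig[i],
      reads$ref_start[i] + 1L,
      reads$mapq[i],
      reads$cigar[i],
      "*", 0L, 0L,
      reads$seq[i],
      qual_to_string(reads$qual[[i]]),
      tags
    ), collapse = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Export haplotagged reads as an indexed BAM
#'
#' Convenience inspection output; not on the calling critical path.
#'
#' @param reads Tagged `vc_reads` tibble.
#' @param contig_lengths Named contig lengths.
#' @param path Output BAM path (".bam" appended if missing).
#' @return The BAM path.
#' @export
write_tagged_bam <- function(reads, contig_lengths, path) {
  path <- sub("\\.bam$", "", path)
  sam <- paste0(path, ".sam")
  write_sam(reads, contig_lengths, sam)
  bam <- Rsamtools::asBam(sam, path, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}
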