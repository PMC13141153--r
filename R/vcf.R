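#' Merge high-confidence pileup calls with full-alignment calls
#'
#' Records are sorted by (contig order, position, alleles) and deduplicated
#' on (contig, pos, ref, alt); if a site appears in both sources the
#' full-alignment record wins (with a warning), matching the refinement
#' pass's precedence.
#'
#' @param high_conf_pileup,full_alignment_calls Call tibbles.
#' @param contig_order Optional contig ordering (reference index order).
#' @return Sorted, deduplicated call tibble.
#' @export
merge_calls <- function(high_conf_pileup, full_alignment_calls,
                        contig_order = NULL) {
  all <- bind_rows(full_alignment_calls, high_conf_pileup)
  if (nrow(all) == 0) return(empty_calls())
  key <- paste(all$contig, all$pos, all$ref, all$alt, sep = "\r")
  pref <- order(all$source != "full_alignment", -all$qual)
  all <- all[pref, ]
  key <- key[pref]
  dup <- duplicated(key)
  if (any(dup)) {
    warn(sprintf(
      "%d site(s) present in both tiers; keeping the full-alignment record",
      sum(dup)
    ))
    all <- all[!dup, ]
  }
  contig_order <- contig_order %||% sort(unique(all$contig))
  all[order(match(all$contig, contig_order), all$pos, all$ref, all$alt), ]
}

#' Annotate phased genotypes
#'
#' Heterozygous SNP calls that are members of a phase block get a phased GT
#' (`0|1` for cis orientation, `1|0` for trans) and a PS phase-set field (the
#' block's first member position, 1-based), the convention of common phasing
#' tools.
#'
#' @param calls Call tibble.
#' @param phase_blocks `vc_phase_blocks`.
#' @return The call tibble with `gt`/`ps` updated.
#' @export
annotate_phase <- function(calls, phase_blocks) {
  if (nrow(calls) == 0 || nrow(phase_blocks) == 0) return(calls)
  ps_of_block <- phase_blocks |>
    group_by(.data$contig, .data$block_id) |>
    summarise(ps = min(.data$pos) + 1, .groups = "drop")
  pb <- left_join(phase_blocks, ps_of_block, by = c("contig", "block_id"))
  key_calls <- paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = "\r")
  key_pb <- paste(pb$contig, pb$pos, pb$ref, pb$alt, sep = "\r")
  m <- match(key_calls, key_pb)
  hit <- which(!is.na(m) & calls$gt == "0/1")
  calls$gt[hit] <- ifelse(pb$orientation[m[hit]] == "cis", "0|1", "1|0")
  calls$ps[hit] <- pb$ps[m[hit]]
  calls
}

vcf_header <- function(contig_lengths, sample_name, gvcf = FALSE) {
  c(
    "##fileformat=VCFv4.2",
    "##source=haplocall",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    if (gvcf) "##ALT=<ID=NON_REF,Description=\"Non-variant block\">",
    if (gvcf) "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of non-variant block (1-based, inclusive)\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Calling pass (pileup or full_alignment)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allelic fraction of the first alternate allele\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (first member position of the phase block)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
}

call_record <- function(calls) {
  n <- nrow(calls)
  if (n == 0) return(character(0))
  fmt <- ifelse(is.na(calls$ps), "GT:GQ:DP:AF", "GT:GQ:DP:AF:PS")
  sample <- paste(
    calls$gt,
    ifelse(is.na(calls$gq), ".", calls$gq),
    ifelse(is.na(calls$dp), ".", calls$dp),
    ifelse(is.na(calls$af), ".", sprintf("%.4f", calls$af)),
    sep = ":"
  )
  sample <- ifelse(is.na(calls$ps), sample,
                   paste0(sample, ":", calls$ps))
  info <- ifelse(is.na(calls$source) | calls$source == "truth", ".",
                 paste0("SRC=", calls$source))
  paste(
    calls$contig, format(calls$pos + 1, scientific = FALSE, trim = TRUE),
    ".", calls$ref, calls$alt,
    sprintf("%.2f", calls$qual), "PASS", info, fmt, sample,
    sep = "\t"
  )
}

#' Write calls as VCF 4.2
#'
#' Positions are converted to 1-based at this single point; indels are
#' expected left-anchored with the preceding reference base (the layout the
#' calling passes produce). Refuses unsorted input.
#'
#' @param calls Call tibble (variant records only).
#' @param contig_lengths Named contig lengths for the header.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, contig_lengths, path, sample_name = "sample") {
  check_sorted(calls, names(contig_lengths))
  writeLines(
    c(vcf_header(contig_lengths, sample_name), call_record(calls)),
    path
  )
  invisible(path)
}

check_sorted <- function(calls, contig_order) {
  if (nrow(calls) < 2) return(invisible(TRUE))
  o <- order(match(calls$contig, contig_order), calls$pos)
  if (!identical(o, seq_len(nrow(calls)))) {
    stop_invalid("calls must be coordinate-sorted before writing")
  }
  invisible(TRUE)
}

#' Write calls and non-variant blocks as GVCF
#'
#' Variant records as in [write_vcf()]; between them, non-variant reference
#' blocks are emitted with `END` info, a `<NON_REF>` alternate and the
#' block's minimum genotype quality.
#'
#' @param calls Variant call tibble.
#' @param reference_blocks Tibble `contig`, `start`, `end` (0-based
#'   half-open), `min_gq`, `ref_base` (base at `start`), optional `dp`.
#' @param contig_lengths Named contig lengths.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_gvcf <- function(calls, reference_blocks, contig_lengths, path,
                       sample_name = "sample") {
  check_sorted(calls, names(contig_lengths))
  var_lines <- call_record(calls)
  rb <- reference_blocks
  blk_lines <- if (nrow(rb)) {
    paste(
      rb$contig, format(rb$start + 1, scientific = FALSE, trim = TRUE), ".",
      rb$ref_base, "<NON_REF>", ".", "PASS",
      paste0("END=", format(rb$end, scientific = FALSE, trim = TRUE)),
      "GT:GQ:DP",
      paste("0/0", rb$min_gq, ifelse(is.na(rb$dp), ".", rb$dp), sep = ":"),
      sep = "\t"
    )
  } else character(0)
  keys <- c(
    match(calls$contig, names(contig_lengths)) * 1e10 + calls$pos,
    match(rb$contig, names(contig_lengths)) * 1e10 + rb$start
  )
  lines <- c(var_lines, blk_lines)[order(keys)]
  writeLines(c(vcf_header(contig_lengths, sample_name, gvcf = TRUE), lines), path)
  invisible(path)
}

#' Read a VCF into the package's call layout
#'
#' Parsing is delegated to vcfR; GVCF non-variant blocks (`<NON_REF>` alt)
#' are returned with `is_variant = FALSE`.
#'
#' @param path VCF path.
#' @return Call tibble with 0-based `pos`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_calls())
  gt_field <- function(field) {
    if (nrow(v@gt) == 0) return(rep(NA_character_, nrow(fix)))
    as.character(vcfR::extract.gt(v, element = field)[, 1])
  }
  gt <- gt_field("GT")
  gq <- suppressWarnings(as.integer(gt_field("GQ")))
  dp <- suppressWarnings(as.integer(gt_field("DP")))
  af <- suppressWarnings(as.numeric(gt_field("AF")))
  ps <- suppressWarnings(as.numeric(gt_field("PS")))
  src <- sub("^.*SRC=([^;]+).*$", "\\1", fix$INFO)
  src[!grepl("SRC=", fix$INFO)] <- NA_character_
  out <- tibble(
    contig = fix$CHROM,
    pos = as.numeric(fix$POS) - 1,
    ref = fix$REF,
    alt = fix$ALT,
    gt = gt,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    gq = gq, dp = dp, af = af, ps = ps,
    source = src,
    is_variant = fix$ALT != "<NON_REF>" & !is.na(fix$ALT) & fix$ALT != "."
  )
  out
}
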