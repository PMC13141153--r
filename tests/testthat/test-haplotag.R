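mk_haps <- function(pos, hp1, hp2, block_id = 1L) {
  structure(
    list(
      chunk = NULL,
      snps = tibble::tibble(pos = pos, hp1 = hp1, hp2 = hp2, block_id = block_id)
    ),
    class = "vc_chunk_haps"
  )
}

simple_read <- function(start, seq, qual = 30L) {
  n <- nchar(seq)
  list(
    a_qpos = 0:(n - 1L), a_rpos = start + 0:(n - 1L),
    seq = seq, qual = rep(qual, n)
  )
}

test_that("haplotype assignment follows the piecewise majority rule exactly", {
  for (n1 in 0:10) {
    for (n2 in 0:10) {
      want <- if (n1 > n2) 1L else if (n1 < n2) 2L else 0L
      expect_identical(assign_haplotype(n1, n2), want)
    }
  }
  expect_identical(assign_haplotype(c(3, 1, 2, 0), c(1, 3, 2, 0)),
                   c(1L, 2L, 0L, 0L))
  expect_error(assign_haplotype(-1, 0), class = "haplocall_invalid_input")
})

test_that("support counting compares read bases to both haplotype alleles", {
  haps <- mk_haps(c(2, 5, 8, 11), c("A", "A", "A", "A"), c("C", "C", "C", "C"))
  # matches HP1 at 3 SNPs and HP2 at 1
  r <- simple_read(0, "AAAAACAAAAAA")
  expect_equal(unname(count_support(r, haps)), c(3, 1))
  # read covering no phased SNP
  r0 <- simple_read(100, "AAAA")
  expect_equal(unname(count_support(r0, haps)), c(0, 0))
  # third allele contributes to neither
  rt <- simple_read(0, "TTTTTTTTTTTT")
  expect_equal(unname(count_support(rt, haps)), c(0, 0))
  # bases below the quality floor are skipped
  rq <- simple_read(0, "AAAAAAAAAAAA", qual = 5L)
  expect_equal(unname(count_support(rq, haps, min_bq = 10)), c(0, 0))
  expect_equal(unname(count_support(rq, haps, min_bq = 0)), c(4, 0))
})

test_that("chunk haplotypes decode block orientations over the fetch window", {
  blocks <- tibble::tibble(
    contig = "ctg", pos = c(10, 20, 30), ref = c("A", "G", "T"),
    alt = c("C", "T", "G"), block_id = 1L,
    orientation = c("cis", "trans", "cis")
  )
  chunk <- tibble::tibble(contig = "ctg", core_start = 0, core_end = 25,
                          fetch_start = 0, fetch_end = 30, contig_length = 50)
  haps <- collect_chunk_haplotypes(chunk, blocks)
  expect_equal(haps$snps$pos, c(10, 20))     # 30 == fetch_end is excluded
  expect_equal(haps$snps$hp1, c("A", "T"))   # cis: ref on HP1; trans: alt
  expect_equal(haps$snps$hp2, c("C", "G"))

  none <- collect_chunk_haplotypes(chunk, blocks[0, ])
  expect_equal(nrow(none$snps), 0)
})

test_that("haplotagging orders reads by tag group and writes no files", {
  haps <- mk_haps(c(5), "A", "C")
  reads <- dplyr::bind_rows(
    tibble::tibble(read_id = "u1", contig = "ctg", ref_start = 0L, strand = "+",
                   mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
                   seq = "GGGGGGGGGG", qual = list(rep(30L, 10)),
                   a_qpos = list(0:9), a_rpos = list(0:9), cigar = "10M"),
    tibble::tibble(read_id = "h2", contig = "ctg", ref_start = 1L, strand = "+",
                   mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
                   seq = "CCCCCCCCC", qual = list(rep(30L, 9)),
                   a_qpos = list(0:8), a_rpos = list(1:9), cigar = "9M"),
    tibble::tibble(read_id = "h1", contig = "ctg", ref_start = 2L, strand = "+",
                   mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
                   seq = "AAAAAAAA", qual = list(rep(30L, 8)),
                   a_qpos = list(0:7), a_rpos = list(2:9), cigar = "8M")
  )
  dir <- withr::local_tempdir()
  withr::local_dir(dir)
  before <- list.files(tempdir(), recursive = TRUE)
  tagged <- haplotag_chunk(reads, haps)
  expect_identical(tagged$read_id, c("h1", "h2", "u1"))  # HP1, HP2, then 0
  expect_identical(tagged$hp_tag, c(1L, 2L, 0L))
  expect_equal(length(list.files(dir)), 0)               # in-memory contract
  expect_identical(list.files(tempdir(), recursive = TRUE), before)
})

test_that("swapping HP1/HP2 maps swaps tags 1 and 2 and fixes nothing else", {
  haps <- mk_haps(c(2, 5), c("A", "A"), c("C", "C"))
  swapped <- mk_haps(c(2, 5), c("C", "C"), c("A", "A"))
  reads <- dplyr::bind_rows(
    tibble::tibble(read_id = "a", contig = "ctg", ref_start = 0L, strand = "+",
                   mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
                   seq = "AAAAAAAA", qual = list(rep(30L, 8)),
                   a_qpos = list(0:7), a_rpos = list(0:7), cigar = "8M"),
    tibble::tibble(read_id = "b", contig = "ctg", ref_start = 0L, strand = "+",
                   mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
                   seq = "GGGGGGGG", qual = list(rep(30L, 8)),
                   a_qpos = list(0:7), a_rpos = list(0:7), cigar = "8M")
  )
  t1 <- haplotag_chunk(reads, haps)
  t2 <- haplotag_chunk(reads, swapped)
  m <- match(t1$read_id, t2$read_id)
  expect_identical(t2$hp_tag[m][t1$hp_tag == 1L], 2L)
  expect_identical(t1$hp_tag[t1$read_id == "b"], 0L)
  expect_identical(t2$hp_tag[m][t1$hp_tag == 0L], 0L)
})

test_that("more HP1 evidence never moves a read toward HP2", {
  for (n2 in 0:5) {
    tags <- assign_haplotype(0:10, rep(n2, 11))
    # as n1 grows, tag goes 2 -> 0 -> 1 and never back
    expect_true(all(diff(match(tags, c(2L, 0L, 1L))) >= 0))
  }
})

test_that("haplotag statistics summarize tag fractions", {
  s <- haplotag_stats(c(1L, 1L, 2L, 2L, 2L, 1L, 2L, 1L, 0L, 0L))
  expect_equal(s$tagged_pct, 80)
  expect_equal(s$n_hp1, 4)
  expect_false(s$empty)
  s0 <- haplotag_stats(integer(0))
  expect_equal(s0$tagged_pct, 0)
  expect_true(s0$empty)
  expect_equal(haplotag_stats(rep(0L, 5))$tagged_pct, 0)
})
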