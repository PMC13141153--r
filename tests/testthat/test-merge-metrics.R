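mk_call <- function(pos, ref, alt, gt = "0/1", qual = 50, source = "pileup",
                    contig = "ctg", ps = NA_real_) {
  tibble::tibble(
    contig = contig, pos = pos, ref = ref, alt = alt, gt = gt, qual = qual,
    gq = as.integer(round(qual)), dp = 30L, af = 0.5, ps = ps,
    source = source, is_variant = TRUE
  )
}

test_that("merging sorts, deduplicates and prefers the refinement pass", {
  high <- dplyr::bind_rows(
    mk_call(30, "A", "C"), mk_call(10, "G", "T"), mk_call(50, "T", "TA")
  )
  fa <- dplyr::bind_rows(
    mk_call(20, "C", "G", source = "full_alignment"),
    mk_call(40, "A", "T", source = "full_alignment"),
    mk_call(5, "G", "A", source = "full_alignment"),
    mk_call(60, "CA", "C", source = "full_alignment")
  )
  merged <- merge_calls(high, fa)
  expect_equal(nrow(merged), 7)
  expect_equal(merged$pos, c(5, 10, 20, 30, 40, 50, 60))

  # same site in both tiers: the full-alignment record wins
  dup_high <- mk_call(10, "G", "T", gt = "0/1")
  dup_fa <- mk_call(10, "G", "T", gt = "1/1", source = "full_alignment")
  expect_warning(m2 <- merge_calls(dup_high, dup_fa), "full-alignment")
  expect_equal(nrow(m2), 1)
  expect_equal(m2$gt, "1/1")

  empty <- merge_calls(mk_call(1, "A", "C")[0, ], mk_call(1, "A", "C")[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("VCF output follows 1-based, left-anchored conventions", {
  calls <- dplyr::bind_rows(
    mk_call(9, "A", "C", gt = "0|1", ps = 10),
    mk_call(19, "GAT", "G", gt = "1/1")   # 2 bp deletion anchored at 0-based 19
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, c(ctg = 1000), path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[2], "10")             # 0-based 9 -> POS 10
  expect_equal(f1[10], "0|1:50:30:0.5000:10")
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[c(2, 4, 5)], c("20", "GAT", "G"))

  unsorted <- calls[c(2, 1), ]
  expect_error(write_vcf(unsorted, c(ctg = 1000), path),
               class = "haplocall_invalid_input")
})

test_that("VCF write -> parse round trip is lossless", {
  calls <- dplyr::bind_rows(
    mk_call(9, "A", "C", gt = "0|1", ps = 10),
    mk_call(19, "GAT", "G", gt = "1/1", qual = 60),
    mk_call(25, "T", "TGG", gt = "0/1", source = "full_alignment"),
    mk_call(40, "C", "A,G", gt = "1/2")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, c(ctg = 1000), path)
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$gt, calls$gt)
  expect_equal(back$gq, calls$gq)
  expect_equal(back$dp, calls$dp)
  expect_equal(back$ps, calls$ps)
  expect_equal(back$source, calls$source)
  expect_true(all(back$is_variant))
})

test_that("GVCF emits non-variant blocks with END and survives a round trip", {
  calls <- mk_call(9, "A", "C")
  blocks <- tibble::tibble(
    contig = "ctg", start = c(0, 10), end = c(9, 50),
    min_gq = c(45L, 12L), ref_base = c("G", "T"), dp = c(28L, 30L)
  )
  path <- withr::local_tempfile(fileext = ".g.vcf")
  write_gvcf(calls, blocks, c(ctg = 1000), path)
  back <- read_vcf(path)
  expect_equal(nrow(back), 3)
  expect_equal(sum(back$is_variant), 1)
  blk <- back[!back$is_variant, ]
  expect_equal(blk$pos, c(0, 10))
  lines <- readLines(path)
  expect_true(any(grepl("END=9", lines)))
  expect_true(any(grepl("<NON_REF>", lines, fixed = TRUE)))
  # records interleave in coordinate order
  body <- lines[!startsWith(lines, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 2))
  expect_false(is.unsorted(pos))
})

test_that("phase annotation rewrites genotypes and phase sets", {
  calls <- dplyr::bind_rows(
    mk_call(10, "A", "C"), mk_call(20, "G", "T"), mk_call(30, "T", "TA")
  )
  blocks <- tibble::tibble(
    contig = "ctg", pos = c(10, 20), ref = c("A", "G"), alt = c("C", "T"),
    block_id = 1L, orientation = c("cis", "trans")
  )
  out <- annotate_phase(calls, blocks)
  expect_equal(out$gt, c("0|1", "1|0", "0/1"))
  expect_equal(out$ps, c(11, 11, NA))
})

test_that("metrics reproduce hand-computed precision/recall/F1", {
  truth <- dplyr::bind_rows(lapply(1:10, function(i) mk_call(i * 10, "A", "C")))
  calls <- dplyr::bind_rows(truth[1:9, ], mk_call(999, "G", "T"))
  m <- compare_to_truth(calls, truth)
  ov <- m[m$category == "overall", ]
  expect_equal(ov$tp, 9)
  expect_equal(ov$fp, 1)
  expect_equal(ov$fn, 1)
  expect_equal(ov$precision, 0.9)
  expect_equal(ov$recall, 0.9)
  expect_equal(ov$f1, 0.9)

  empty <- compare_to_truth(truth[0, ], truth[1:5, ])
  ov0 <- empty[empty$category == "overall", ]
  expect_equal(ov0$recall, 0)
  expect_equal(ov0$precision, 0)
  expect_equal(ov0$fn, 5)

  perfect <- compare_to_truth(truth, truth)
  expect_true(all(perfect$f1[perfect$tp > 0] == 1))
})

test_that("genotype-aware matching distinguishes het from hom", {
  truth <- mk_call(10, "A", "C", gt = "0/1")
  wrong_gt <- mk_call(10, "A", "C", gt = "1/1")
  m <- compare_to_truth(wrong_gt, truth)
  ov <- m[m$category == "overall", ]
  expect_equal(ov$tp, 0)
  expect_equal(ov$fp, 1)
  expect_equal(ov$fn, 1)
  # phased vs unphased notation of the same genotype matches
  m2 <- compare_to_truth(mk_call(10, "A", "C", gt = "1|0"), truth)
  expect_equal(m2$tp[m2$category == "overall"], 1)
})

test_that("category counts are additive on randomized inputs", {
  set.seed(99)
  rand_calls <- function(n) {
    type <- sample(1:3, n, replace = TRUE)
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      pos <- i * 20
      switch(type[i],
        mk_call(pos, "A", "C"),
        mk_call(pos, "A", "AGG"),
        mk_call(pos, "ATT", "A")
      )
    }))
  }
  for (rep in 1:5) {
    truth <- rand_calls(40)
    calls <- truth[sample(40, 25), ]
    extra <- rand_calls(10)
    extra$pos <- extra$pos + 7  # guaranteed mismatches
    m <- compare_to_truth(dplyr::bind_rows(calls, extra), truth)
    g <- function(cat, f) m[[f]][m$category == cat]
    for (f in c("tp", "fp", "fn")) {
      expect_equal(g("Indel", f), g("Insertion", f) + g("Deletion", f))
      expect_equal(g("overall", f), g("SNP", f) + g("Indel", f))
    }
    # permutation symmetry
    m2 <- compare_to_truth(dplyr::bind_rows(extra, calls)[sample(35), ], truth)
    expect_equal(as.data.frame(m), as.data.frame(m2))
  }
})

test_that("calls outside confident regions are ignored, not counted FP", {
  truth <- mk_call(10, "A", "C")
  calls <- dplyr::bind_rows(truth, mk_call(500, "G", "T"))
  conf <- tibble::tibble(contig = "ctg", start = 0, end = 100)
  m <- compare_to_truth(calls, truth, conf)
  ov <- m[m$category == "overall", ]
  expect_equal(ov$fp, 0)
  expect_equal(ov$tp, 1)
})

test_that("normalization trims shared bases before matching", {
  # same deletion written with a trailing shared base
  truth <- mk_call(10, "GAT", "G", gt = "1/1")
  padded <- mk_call(10, "GATC", "GC", gt = "1/1")
  m <- compare_to_truth(padded, truth)
  expect_equal(m$tp[m$category == "Deletion"], 1)
  # multiallelic decomposition: a 1/2 site matches its component alleles
  multi <- mk_call(10, "A", "C,G", gt = "1/2")
  comp <- dplyr::bind_rows(mk_call(10, "A", "C"), mk_call(10, "A", "G"))
  m2 <- compare_to_truth(multi, comp)
  expect_equal(m2$tp[m2$category == "overall"], 2)
})

test_that("metrics expose tidy and autoplot views", {
  truth <- dplyr::bind_rows(lapply(1:10, function(i) mk_call(i * 10, "A", "C")))
  m <- compare_to_truth(truth, truth)
  td <- generics::tidy(m)
  expect_true(all(c("category", "metric", "value") %in% names(td)))
  expect_equal(nrow(td), 15)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})
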