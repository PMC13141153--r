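tagged_read <- function(id, start, seq, hp, qual = 30L) {
  n <- nchar(seq)
  tibble::tibble(
    read_id = id, contig = "ctg", ref_start = as.integer(start), strand = "+",
    mapq = 60L, hp_tag = as.integer(hp), truth_hap = NA_integer_,
    seq = seq, qual = list(rep(qual, n)),
    a_qpos = list(0:(n - 1L)), a_rpos = list(as.integer(start + 0:(n - 1L))),
    cigar = paste0(n, "M")
  )
}

mk_candidate <- function(pos, ref = "A", alts = tibble::tibble(class = "C", count = 15L, af = 0.5),
                         ins_obs = NULL, del_obs = NULL) {
  tibble::tibble(
    contig = "ctg", pos = pos, ref_base = ref, depth = 30L,
    alts = list(alts),
    ins_obs = list(ins_obs %||% tibble::tibble(seq = character(0), n = integer(0))),
    del_obs = list(del_obs %||% tibble::tibble(start = integer(0), len = integer(0), n = integer(0)))
  )
}

`%||%` <- rlang::`%||%`

ref60 <- strrep("A", 60)

test_that("tensor rows are grouped by haplotype tag in order 1, 2, 0", {
  reads <- dplyr::bind_rows(
    tagged_read("r1", 0, strrep("A", 40), 1),
    tagged_read("r2", 1, strrep("A", 40), 0),
    tagged_read("r3", 2, strrep("A", 40), 2),
    tagged_read("r4", 3, strrep("A", 40), 1),
    tagged_read("r5", 4, strrep("A", 40), 0)
  )
  f <- build_full_alignment_feature(mk_candidate(20), reads, ref60, 0)
  hp_center <- f$tensor[1:5, 17, 8]
  expect_equal(hp_center, c(1, 1, -1, 0, 0))  # two HP1, one HP2, two HP0
  expect_equal(f$n_reads, 5)
  # determinism
  f2 <- build_full_alignment_feature(mk_candidate(20), reads, ref60, 0)
  expect_identical(f$tensor, f2$tensor)
})

test_that("uncovered candidates produce a flagged all-zero tensor", {
  reads <- tagged_read("r1", 0, strrep("A", 10), 1)
  f <- build_full_alignment_feature(mk_candidate(50), reads, ref60, 0)
  expect_true(f$empty)
  expect_true(all(f$tensor[, , 1:10] == 0))
})

test_that("deep coverage is subsampled deterministically, preserving proportions", {
  set.seed(1)
  reads <- dplyr::bind_rows(lapply(1:200, function(i) {
    tagged_read(sprintf("r%03d", i), sample(0:5, 1), strrep("A", 45),
                c(1L, 2L, 0L)[1 + (i %% 3)])
  }))
  f <- build_full_alignment_feature(mk_candidate(25), reads, ref60, 0, D = 89)
  expect_equal(f$n_reads, 89)
  hp <- f$tensor[, 17, 8]
  # proportions preserved within 1 row (largest remainder over 1/3 each)
  expect_true(abs(sum(hp == 1) - 89 / 3) <= 1)
  expect_true(abs(sum(hp == -1) - 89 / 3) <= 1)
  f2 <- build_full_alignment_feature(mk_candidate(25), reads, ref60, 0, D = 89)
  expect_identical(f$tensor, f2$tensor)
})

test_that("shuffling haplotype tags changes the tensor", {
  reads <- dplyr::bind_rows(
    lapply(1:6, function(i) tagged_read(sprintf("a%d", i), 0, paste0(strrep("A", 20), "C", strrep("A", 19)), 1)),
    lapply(1:6, function(i) tagged_read(sprintf("b%d", i), 0, strrep("A", 40), 2))
  )
  f1 <- build_full_alignment_feature(mk_candidate(20), reads, ref60, 0)
  shuffled <- reads
  shuffled$hp_tag <- rev(shuffled$hp_tag)
  f2 <- build_full_alignment_feature(mk_candidate(20), shuffled, ref60, 0)
  expect_false(identical(f1$tensor, f2$tensor))
})

test_that("full-alignment classification emits all heads, normalized, batch-invariant", {
  bk <- trained_backends()$full_alignment
  reads <- dplyr::bind_rows(
    lapply(1:6, function(i) tagged_read(sprintf("a%d", i), 0, paste0(strrep("A", 20), "C", strrep("A", 19)), 1)),
    lapply(1:6, function(i) tagged_read(sprintf("b%d", i), 0, strrep("A", 40), 2))
  )
  feats <- lapply(c(18, 20, 22), function(p) {
    build_full_alignment_feature(mk_candidate(p), reads, ref60, 0)
  })
  pr <- classify_full_alignment(feats, bk)
  expect_equal(nrow(pr), 3)
  for (i in 1:3) {
    expect_equal(sum(pr$p_gt21[[i]]), 1, tolerance = 1e-6)
    expect_equal(sum(pr$p_zygosity[[i]]), 1, tolerance = 1e-6)
    expect_equal(sum(pr$p_indel_len[[i]]), 1, tolerance = 1e-6)
    expect_equal(length(pr$p_gt21[[i]]), 21)
  }
  expect_equal(nrow(classify_full_alignment(list(), bk)), 0)
  # batch-size invariance
  bk_small <- bk
  bk_small$spec <- backend_spec(batch_size = 1, seed = bk$spec$seed)
  pr2 <- classify_full_alignment(feats, bk_small)
  expect_equal(pr$p_gt21, pr2$p_gt21, tolerance = 1e-12)

  broken <- bk
  broken$heads$zygosity <- NULL
  expect_error(classify_full_alignment(feats, broken),
               class = "haplocall_backend_error")
})

test_that("the joint decision combines heads over compatible classes", {
  conc <- function(vocab, at, p = 0.97) {
    v <- setNames(rep((1 - p) / (length(vocab) - 1), length(vocab)), vocab)
    v[at] <- p
    v
  }
  gtc <- haplocall:::GT21_CLASSES
  lenc <- haplocall:::INDEL_LEN_CLASSES
  # concentrated on (A,C), ref A -> het SNP call
  fc <- joint_decision(
    list(p_gt21 = conc(gtc, "AC"), p_zygosity = c(het = .99, hom = .01),
         p_indel_len = conc(lenc, "0")),
    mk_candidate(20), ref60, 0
  )
  expect_equal(fc$gt, "0/1")
  expect_equal(fc$alt, "C")
  expect_true(fc$is_variant)
  expect_equal(fc$qual, -10 * log10(1 - 0.97), tolerance = 1e-6)

  # concentrated on (A,A), ref A -> reference decision, no variant
  fr <- joint_decision(
    list(p_gt21 = conc(gtc, "AA"), p_zygosity = c(het = .01, hom = .99),
         p_indel_len = conc(lenc, "0")),
    mk_candidate(20), ref60, 0
  )
  expect_false(fr$is_variant)
  expect_equal(fr$gt, "0/0")

  # (Ins,Ins) with length mode +2 and observed 2 bp insertion "AT" -> hom A>AAT
  cand_ins <- mk_candidate(
    20, alts = tibble::tibble(class = "I", count = 28L, af = 0.9),
    ins_obs = tibble::tibble(seq = c("AT", "AT", "G"), n = c(10L, 10L, 1L))
  )
  fi <- joint_decision(
    list(p_gt21 = conc(gtc, "II"), p_zygosity = c(het = .01, hom = .99),
         p_indel_len = conc(lenc, "+2")),
    cand_ins, ref60, 0
  )
  expect_equal(fi$ref, "A")
  expect_equal(fi$alt, "AAT")
  expect_equal(fi$gt, "1/1")

  # zygosity head breaks a near-tie between hom and het classes
  gt_tie <- setNames(rep(0.001, 21), gtc)
  gt_tie["AC"] <- 0.49; gt_tie["CC"] <- 0.51
  gt_tie <- gt_tie / sum(gt_tie)
  ft <- joint_decision(
    list(p_gt21 = gt_tie, p_zygosity = c(het = .9, hom = .1),
         p_indel_len = conc(lenc, "0")),
    mk_candidate(20), ref60, 0
  )
  expect_equal(ft$gt, "0/1")  # het wins after the joint product
})
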