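# hand-built reads over a short contig: perfect matches unless stated
perfect_read <- function(id, start, seq, contig = "ctg") {
  n <- nchar(seq)
  tibble::tibble(
    read_id = id, contig = contig, ref_start = as.integer(start),
    strand = "+", mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
    seq = seq, qual = list(rep(30L, n)),
    a_qpos = list(0:(n - 1L)), a_rpos = list(start + 0:(n - 1L)),
    cigar = paste0(n, "M")
  )
}

test_chunk <- function(len = 100) {
  partition_genome(c(ctg = len), chunking_config(overlap = 0, flank = 0))[1, ]
}

test_that("pileup counts bases, deletions and anchored insertions", {
  ref <- strrep("A", 100)
  reads <- dplyr::bind_rows(lapply(1:10, function(i) {
    perfect_read(sprintf("p%02d", i), 0, strrep("A", 50))
  }))
  cols <- build_pileup(reads, test_chunk(), ref, span = "core")
  expect_equal(cols$depth[cols$ref_pos == 25], 10)
  expect_equal(cols$a_fwd[cols$ref_pos == 25], 10)

  # 6 reads C / 4 reads A at ref A -> alt fraction 0.6
  reads2 <- dplyr::bind_rows(
    lapply(1:6, function(i) perfect_read(sprintf("c%d", i), 0, paste0("AAAAA", "C", "AAAA"))),
    lapply(1:4, function(i) perfect_read(sprintf("a%d", i), 0, strrep("A", 10)))
  )
  cols2 <- build_pileup(reads2, test_chunk(), ref, span = "core")
  at5 <- cols2[cols2$ref_pos == 5, ]
  expect_equal(at5$c_fwd, 6)
  expect_equal((at5$c_fwd + at5$c_rev) / at5$depth, 0.6)

  # a 2 bp deletion spanning position p counts 1 deletion at each deleted spot
  p <- haplocall:::cigar_to_pairs("5M2D5M", 0)
  delread <- perfect_read("d1", 0, strrep("A", 10))
  delread$a_qpos <- list(p$qpos); delread$a_rpos <- list(p$rpos)
  cols3 <- build_pileup(delread, test_chunk(), ref, span = "core")
  expect_equal(cols3$d_fwd[cols3$ref_pos == 5], 1)
  expect_equal(cols3$d_fwd[cols3$ref_pos == 6], 1)

  # insertions count once at the anchor (last aligned base before the run)
  pi <- haplocall:::cigar_to_pairs("5M3I5M", 0)
  insread <- perfect_read("i1", 0, strrep("A", 13))
  insread$a_qpos <- list(pi$qpos); insread$a_rpos <- list(pi$rpos)
  cols4 <- build_pileup(insread, test_chunk(), ref, span = "core")
  expect_equal(cols4$i_fwd[cols4$ref_pos == 4], 1)
  expect_equal(sum(cols4$i_fwd), 1)
})

test_that("candidate selection enforces coverage and allelic-fraction floors", {
  mk_col <- function(depth, alt_cnt, ref = "A", alt = "C") {
    cols <- tibble::tibble(
      contig = "ctg", ref_pos = 10, ref_base = ref, depth = depth,
      a_fwd = depth - alt_cnt, a_rev = 0L, c_fwd = alt_cnt, c_rev = 0L,
      g_fwd = 0L, g_rev = 0L, t_fwd = 0L, t_rev = 0L,
      i_fwd = 0L, i_rev = 0L, d_fwd = 0L, d_rev = 0L
    )
    attr(cols, "window") <- c(0, 100)
    cols
  }
  cfg <- candidate_config(min_coverage = 4, min_af = 0.08, indel_min_af = 0.12)
  expect_equal(nrow(select_candidates(mk_col(20L, 3L), cfg)), 1)   # af 0.15
  expect_equal(nrow(select_candidates(mk_col(3L, 2L), cfg)), 0)    # depth < 4
  expect_equal(nrow(select_candidates(mk_col(20L, 2L), candidate_config(min_af = 0.12))), 0)
})

test_that("candidate selection agrees with a brute-force scan on random pileups", {
  set.seed(31)
  n <- 300
  cnts <- matrix(rpois(n * 6, lambda = c(18, 1, 1, 1, 0.4, 0.4)), ncol = 6, byrow = TRUE)
  ref_idx <- sample(1:4, n, replace = TRUE)
  depth <- as.integer(rowSums(cnts[, 1:4]) + cnts[, 6])
  cols <- tibble::tibble(
    contig = "ctg", ref_pos = seq_len(n) - 1,
    ref_base = c("A", "C", "G", "T")[ref_idx], depth = depth,
    a_fwd = cnts[, 1], a_rev = 0L, c_fwd = cnts[, 2], c_rev = 0L,
    g_fwd = cnts[, 3], g_rev = 0L, t_fwd = cnts[, 4], t_rev = 0L,
    i_fwd = cnts[, 5], i_rev = 0L, d_fwd = cnts[, 6], d_rev = 0L
  )
  attr(cols, "window") <- c(0, n)
  cfg <- candidate_config()
  got <- select_candidates(cols[cols$depth >= 1, ], cfg)
  # brute force: per row, recheck the rule from scratch
  want <- c()
  for (i in seq_len(n)) {
    if (depth[i] < cfg$min_coverage) next
    base_af <- cnts[i, 1:4] / depth[i]
    base_af[ref_idx[i]] <- 0
    indel_af <- cnts[i, 5:6] / depth[i]
    if (any(base_af >= cfg$min_af & cnts[i, 1:4] > 0) ||
        any(indel_af >= cfg$indel_min_af & cnts[i, 5:6] > 0)) {
      want <- c(want, i - 1)
    }
  }
  expect_equal(got$pos, want)
})

test_that("feature windows are centered, zero-padded and deterministic", {
  ref <- strrep("A", 100)
  reads <- dplyr::bind_rows(lapply(1:5, function(i) perfect_read(sprintf("r%d", i), 0, strrep("A", 60))))
  cols <- build_pileup(reads, test_chunk(), ref, span = "core")
  f <- build_pileup_features(cols, 2, W = 33)
  expect_equal(dim(f$matrix), c(33, 24))
  expect_true(all(f$matrix[1:14, ] == 0))  # positions -14..-1 padded
  expect_false(all(f$matrix[15, ] == 0))
  f2 <- build_pileup_features(cols, 2, W = 33)
  expect_identical(f$matrix, f2$matrix)
  # ref-only pileup has zero alt-class counts everywhere
  expect_true(all(f$matrix[, c(3:12)] == 0))
})

test_that("pileup classification is order-preserving, normalized and reproducible", {
  bk <- trained_backends()$pileup
  sim <- eval_sim()
  chunk <- partition_genome(c(chr_sim = sim$cfg$length), chunking_config())[1, ]
  reads <- fetch_reads(sim$reads, chunk)
  cols <- build_pileup(reads, chunk, sim$truth$reference, span = "fetch")
  cands <- select_candidates(cols, candidate_config())
  x <- haplocall:::pileup_feature_batch(cols, cands$pos, cands$depth, W = 33)

  expect_equal(nrow(classify_pileup(x[0, , drop = FALSE], bk)), 0)
  pr <- classify_pileup(x, bk)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_identical(pr, classify_pileup(x, bk))
  # row order follows input order under any batch size
  pr_small <- batched_predict(bk, x, spec = backend_spec(batch_size = 7))
  expect_equal(pr, pr_small, tolerance = 1e-12)
  expect_error(classify_pileup(x, NULL), class = "haplocall_backend_error")
})

test_that("tier routing takes the lowest-quality floor(q*n) variant calls", {
  set.seed(12)
  mk_calls <- function(n_var, n_ref) {
    tibble::tibble(
      contig = "ctg", pos = seq_len(n_var + n_ref),
      qual = runif(n_var + n_ref, 0, 60),
      is_variant = c(rep(TRUE, n_var), rep(FALSE, n_ref))
    )
  }
  calls <- mk_calls(10, 0)
  t <- tier_split(calls, q = 0.7, r = 0.1)
  expect_equal(nrow(t$low_confidence), 7)
  expect_equal(nrow(t$high_confidence), 3)
  expect_true(max(t$low_confidence$qual) <= min(t$high_confidence$qual))

  t0 <- tier_split(calls, q = 0)
  expect_equal(nrow(t0$low_confidence), 0)
  t1 <- tier_split(calls, q = 1)
  expect_equal(nrow(t1$high_confidence), 0)
  expect_error(tier_split(calls, q = 1.5), class = "haplocall_invalid_config")

  for (i in 1:20) {
    nv <- sample(0:50, 1); nr <- sample(0:50, 1)
    tt <- tier_split(mk_calls(nv, nr), q = 0.7, r = 0.1)
    expect_equal(nrow(tt$low_confidence), floor(0.7 * nv))
    expect_equal(nrow(tt$ref_routed), floor(0.1 * nr))
  }

  # threshold strategy uses a fixed quality cutoff
  tc <- tier_split(mk_calls(20, 5), strategy = "threshold", qual_cutoff = 30)
  expect_true(all(tc$low_confidence$qual < 30))
  expect_true(all(tc$high_confidence$qual >= 30))
})

test_that("noiseless 30x reads recover every true variant and nothing else", {
  cfg <- simulation_config(length = 5e4, coverage = 30, seed = 17,
                           sub_rate = 0, ins_rate = 0, del_rate = 0)
  truth <- simulate_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  chunk <- partition_genome(c(chr_sim = cfg$length), chunking_config())[1, ]
  cols <- build_pileup(fetch_reads(reads, chunk), chunk, truth$reference, span = "fetch")
  core <- cols[cols$ref_pos >= chunk$core_start & cols$ref_pos < chunk$core_end, ]
  cands <- select_candidates(core, candidate_config())
  v <- truth$variants
  truth_sites <- unlist(lapply(seq_len(nrow(v)), function(i) {
    if (v$type[i] == "del") v$pos[i] + seq_len(nchar(v$ref[i]) - 1) else v$pos[i]
  }))
  expect_true(all(truth_sites %in% cands$pos))   # every true site selected
  expect_true(all(cands$pos %in% truth_sites))   # and no spurious candidate
  afs <- vapply(cands$alts, function(a) a$af[1], numeric(1))
  # with zero sequencing errors the alt reads all come from the alt haplotype:
  # AF is binomial around 0.5 (het) or exactly 1 (hom); never error-level
  expect_true(all(afs > 0.2))
  hom_sites <- truth$variants$pos[truth$variants$genotype == "hom" &
                                    truth$variants$type == "snp"]
  expect_true(all(afs[cands$pos %in% hom_sites] == 1))
})
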