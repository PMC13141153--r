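# Naive CIGAR walk used as the oracle for the vectorized pair expansion.
naive_pairs <- function(cigar, ref_start) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  q <- 0L; r <- ref_start
  qpos <- integer(0); rpos <- integer(0)
  for (k in seq_along(ops)) {
    for (i in seq_len(lens[k])) {
      if (ops[k] %in% c("M", "=", "X")) {
        qpos <- c(qpos, q); rpos <- c(rpos, r); q <- q + 1L; r <- r + 1L
      } else if (ops[k] == "I") {
        qpos <- c(qpos, q); rpos <- c(rpos, NA_integer_); q <- q + 1L
      } else if (ops[k] == "D") {
        qpos <- c(qpos, NA_integer_); rpos <- c(rpos, r); r <- r + 1L
      } else if (ops[k] == "S") {
        q <- q + 1L
      } else if (ops[k] == "N") {
        r <- r + 1L
      }
    }
  }
  list(qpos = qpos, rpos = rpos)
}

test_that("CIGAR pair expansion matches a naive per-base walk", {
  set.seed(7)
  for (i in 1:30) {
    n_ops <- sample(1:12, 1)
    ops <- sample(c("M", "I", "D"), n_ops, replace = TRUE, prob = c(.7, .15, .15))
    # legal CIGAR: starts/ends with M, no II/DD runs collapse needed
    ops[1] <- "M"; ops[n_ops] <- "M"
    lens <- sample(1:20, n_ops, replace = TRUE)
    cigar <- paste0(lens, ops, collapse = "")
    start <- sample(0:1000, 1)
    got <- haplocall:::cigar_to_pairs(cigar, start)
    want <- naive_pairs(cigar, start)
    expect_identical(got$qpos, want$qpos)
    expect_identical(got$rpos, want$rpos)
  }
  # soft clips consume query but emit no pairs
  got <- haplocall:::cigar_to_pairs("3S4M2S", 100)
  expect_identical(got$qpos, 3:6)
  expect_identical(got$rpos, 100:103)
})

test_that("base_at_reference_position projects matches, deletions and gaps", {
  p <- haplocall:::cigar_to_pairs("10M3D5M", 100)
  read <- list(a_qpos = p$qpos, a_rpos = p$rpos, seq = "ACGTACGTACGTACG")
  expect_equal(base_at_reference_position(read, 105), "C")
  expect_equal(base_at_reference_position(read, 111), "-")  # inside deletion
  expect_true(is.na(base_at_reference_position(read, 99)))
  expect_true(is.na(base_at_reference_position(read, 200)))
  # vectorized
  # 113 maps to query offset 10 ("G" in the read sequence)
  expect_equal(base_at_reference_position(read, c(100, 110, 113)), c("A", "-", "G"))
})

test_that("simulated alignments survive the SAM/BAM round trip bit-exactly", {
  sim <- eval_sim()
  chunk <- partition_genome(c(chr_sim = sim$cfg$length), chunking_config())[1, ]
  from_bam <- fetch_reads(sim$paths$bam, chunk, min_mapq = 0)
  expect_equal(nrow(from_bam), nrow(sim$reads))
  m <- match(sim$reads$read_id, from_bam$read_id)
  expect_false(anyNA(m))
  for (i in seq(1, nrow(sim$reads), by = 37)) {
    expect_identical(from_bam$a_qpos[[m[i]]], sim$reads$a_qpos[[i]])
    expect_identical(from_bam$a_rpos[[m[i]]], sim$reads$a_rpos[[i]])
    expect_identical(from_bam$seq[m[i]], sim$reads$seq[i])
    expect_identical(from_bam$qual[[m[i]]], sim$reads$qual[[i]])
  }
  expect_identical(from_bam$truth_hap[m], sim$reads$truth_hap)
})

test_that("fetch_reads filters by mapping quality and window overlap", {
  sim <- eval_sim()
  chunk <- partition_genome(c(chr_sim = sim$cfg$length),
                            chunking_config(chunk_size = 2e4, overlap = 0, flank = 0))[2, ]
  got <- fetch_reads(sim$paths$bam, chunk)
  ends <- vapply(got$a_rpos, function(r) max(r, na.rm = TRUE) + 1, numeric(1))
  expect_true(all(got$ref_start < chunk$fetch_end & ends > chunk$fetch_start))
  # simulated mapq is 60: a higher floor excludes everything
  none <- fetch_reads(sim$paths$bam, chunk, min_mapq = 61)
  expect_equal(nrow(none), 0)
  # a read spanning the boundary of two adjacent chunks appears in both
  chunks <- partition_genome(c(chr_sim = sim$cfg$length),
                             chunking_config(chunk_size = 2e4, overlap = 0, flank = 0))
  r1 <- fetch_reads(sim$paths$bam, chunks[1, ])
  r2 <- fetch_reads(sim$paths$bam, chunks[2, ])
  spanning <- intersect(r1$read_id, r2$read_id)
  expect_gt(length(spanning), 0)
})

test_that("missing index and absent contig are handled explicitly", {
  sim <- eval_sim()
  chunk <- partition_genome(c(chr_sim = sim$cfg$length), chunking_config())[1, ]
  noidx <- file.path(tempdir(), "noindex.bam")
  file.copy(sim$paths$bam, noidx, overwrite = TRUE)
  expect_error(fetch_reads(noidx, chunk), class = "haplocall_missing_index")

  ghost <- chunk
  ghost$contig <- "chr_ghost"
  expect_warning(res <- fetch_reads(sim$paths$bam, ghost), "absent")
  expect_equal(nrow(res), 0)
})

test_that("tagged reads export the HP auxiliary tag", {
  sim <- eval_sim()
  reads <- sim$reads[1:20, ]
  reads$hp_tag <- rep(c(1L, 2L, 0L, 1L), 5)
  bam <- write_tagged_bam(reads, setNames(sim$cfg$length, "chr_sim"),
                          file.path(tempdir(), "tagged"))
  chunk <- partition_genome(c(chr_sim = sim$cfg$length), chunking_config())[1, ]
  back <- fetch_reads(bam, chunk, min_mapq = 0)
  m <- match(reads$read_id, back$read_id)
  expect_identical(back$hp_tag[m], reads$hp_tag)
})
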