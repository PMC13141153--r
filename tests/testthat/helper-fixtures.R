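# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Backends trained on a 150 kb, 30x simulation; reused across files.
trained_backends <- function() {
  cached("backends", {
    cfg <- simulation_config(length = 1.5e5, coverage = 30, seed = 11)
    truth <- simulate_truth(cfg)
    reads <- simulate_reads(truth, cfg)
    suppressWarnings(
      train_backends_from_simulation(truth, reads, backend_spec(seed = 7))
    )
  })
}

# A small evaluation simulation (independent seed) with files on disk.
eval_sim <- function() {
  cached("eval_sim", {
    cfg <- simulation_config(length = 1e5, coverage = 30, seed = 42)
    truth <- simulate_truth(cfg)
    reads <- simulate_reads(truth, cfg)
    dir <- file.path(tempdir(), "haplocall-eval-sim")
    paths <- write_simulation(truth, reads, dir)
    list(cfg = cfg, truth = truth, reads = reads, paths = paths, dir = dir)
  })
}

run_quiet <- function(config) {
  suppressWarnings(suppressMessages(run_pipeline(config)))
}

# Synthetic single-contig reads from an explicit (reads x SNPs) allele matrix
# (0 = ref A, 1 = alt C, NA inside the span = third allele G); SNP i sits at
# position 10*i so adjacency is unambiguous.
reads_from_allele_matrix <- function(mat) {
  n <- nrow(mat)
  rows <- lapply(seq_len(n), function(r) {
    cov <- which(!is.na(mat[r, ]))
    if (length(cov) == 0) return(NULL)
    span <- min(cov):max(cov)
    pos <- 10L * span
    base <- vapply(span, function(s) {
      if (is.na(mat[r, s])) "G" else if (mat[r, s] == 0) "A" else "C"
    }, character(1))
    list(pos = pos, base = base)
  })
  keep <- which(!vapply(rows, is.null, logical(1)))
  tibble::tibble(
    read_id = sprintf("r%03d", keep),
    contig = "ctg",
    ref_start = vapply(keep, function(r) rows[[r]]$pos[1], integer(1)),
    strand = "+", mapq = 60L, hp_tag = 0L, truth_hap = NA_integer_,
    seq = vapply(keep, function(r) paste(rows[[r]]$base, collapse = ""), character(1)),
    qual = lapply(keep, function(r) rep(30L, length(rows[[r]]$base))),
    a_qpos = lapply(keep, function(r) seq_along(rows[[r]]$pos) - 1L),
    a_rpos = lapply(keep, function(r) rows[[r]]$pos),
    cigar = NA_character_
  )
}

snps_for_matrix <- function(m) {
  tibble::tibble(contig = "ctg", pos = 10L * seq_len(m), ref = "A", alt = "C",
                 qual = 50)
}

# Minimum-error-correction cost of an orientation vector against an allele
# matrix (the brute-force oracle's cost function).
mec_cost_matrix <- function(ori, mat) {
  tot <- 0L
  for (r in seq_len(nrow(mat))) {
    cov <- which(!is.na(mat[r, ]))
    if (!length(cov)) next
    mis <- sum(mat[r, cov] != ori[cov])
    tot <- tot + min(mis, length(cov) - mis)
  }
  tot
}

# Exhaustive MEC minimum over all 2^(m-1) orientation assignments.
mec_brute_force <- function(mat) {
  m <- ncol(mat)
  best <- Inf
  for (k in 0:(2^(m - 1) - 1)) {
    o <- c(0L, as.integer(intToBits(k))[seq_len(m - 1)])
    best <- min(best, mec_cost_matrix(o, mat))
  }
  best
}

# Random diploid phasing instance: m SNPs, n reads drawn from one of two
# haplotypes of a fixed phase, with per-allele error rate.
random_phasing_instance <- function(m, n, err = 0.1) {
  truth <- sample(0:1, m, replace = TRUE)
  mat <- matrix(NA_integer_, n, m)
  for (r in seq_len(n)) {
    a <- sort(sample(seq_len(m), sample(seq_len(min(m, 5)), 1)))
    span <- a[1]:a[length(a)]
    hap <- sample(0:1, 1)
    alle <- if (hap == 0) truth[span] else 1L - truth[span]
    flip <- runif(length(span)) < err
    alle[flip] <- 1L - alle[flip]
    mat[r, span] <- alle
  }
  list(mat = mat, truth = truth)
}

phase_orientation_vector <- function(snps, reads) {
  blocks <- phase_two_stage(build_allele_graph(snps, reads, min_bq = 0))
  ori <- integer(nrow(snps))
  ori[match(blocks$pos, snps$pos)] <- ifelse(blocks$orientation == "cis", 0L, 1L)
  ori
}
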