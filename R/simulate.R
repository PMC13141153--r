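#' Simulation configuration
#'
#' Defines the study conditions for the synthetic diploid fixture: a random
#' reference contig, phased germline variants at configurable densities, and
#' long reads drawn from the two haplotypes with per-base substitution /
#' insertion / deletion sequencing errors. All rates are per bp; the seed
#' fixes every draw.
#'
#' @param length Reference length in bp (default 1e6).
#' @param het_snp_rate,hom_snp_rate Heterozygous / homozygous SNP densities
#'   (defaults 1/1000 and 1/2000 per bp).
#' @param het_indel_rate,hom_indel_rate Indel densities (defaults 1/5000 and
#'   1/10000 per bp); lengths 1-10, geometric.
#' @param indel_geom_p Geometric parameter for germline indel lengths
#'   (default 0.5, mean length 2).
#' @param coverage Mean sequencing depth (default 30).
#' @param read_length_median,read_length_sdlog Lognormal read-length model
#'   (defaults: median 10 kb, sdlog 0.45).
#' @param min_read_length,max_read_length Truncation bounds (300 bp, 100 kb;
#'   the maximum is kept below the default haplotagging flank so chunked and
#'   unchunked runs see identical read context).
#' @param sub_rate,ins_rate,del_rate Per-base sequencing error rates
#'   (defaults 0.02, 0.005, 0.005).
#' @param err_ins_geom_p Geometric parameter for insertion-error lengths
#'   (default 0.7).
#' @param homopolymer_bias If `TRUE`, indel error rates are tripled at bases
#'   repeating their predecessor, mimicking long-read homopolymer noise
#'   (default `FALSE` for test determinism across configurations).
#' @param contig Contig name (default "chr_sim").
#' @param seed Integer seed.
#' @return A list of class `vc_sim_config`.
#' @export
simulation_config <- function(length = 1e6,
                              het_snp_rate = 1 / 1000,
                              hom_snp_rate = 1 / 2000,
                              het_indel_rate = 1 / 5000,
                              hom_indel_rate = 1 / 10000,
                              indel_geom_p = 0.5,
                              coverage = 30,
                              read_length_median = 1e4,
                              read_length_sdlog = 0.45,
                              min_read_length = 300,
                              max_read_length = 1e5,
                              sub_rate = 0.02,
                              ins_rate = 0.005,
                              del_rate = 0.005,
                              err_ins_geom_p = 0.7,
                              homopolymer_bias = FALSE,
                              contig = "chr_sim",
                              seed = 1) {
  rates <- c(het_snp_rate, hom_snp_rate, het_indel_rate, hom_indel_rate,
             sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 1)) stop_invalid("rates must lie in [0, 1]")
  if (coverage < 0) stop_invalid("coverage must be >= 0")
  if (length < 1000) stop_invalid("reference length must be >= 1000")
  structure(as.list(environment()), class = "vc_sim_config")
}

#' Simulate a diploid truth set
#'
#' Draws a uniform-composition reference sequence and non-overlapping phased
#' variants (het/hom SNPs and 1-10 bp indels, left-anchored), then constructs
#' the two haplotype sequences together with coordinate maps back to the
#' reference. Deterministic per seed. Conflicting draws (variants within 12 bp
#' of an accepted one) are rejected; if more than half of all draws conflict
#' the configuration is refused.
#'
#' @param config A [simulation_config()].
#' @return A list of class `vc_truth`: `config`, `contig`, `reference`
#'   (character string), `variants` (tibble: `pos` 0-based anchor, `ref`,
#'   `alt`, `genotype` het/hom, `hap` carrying haplotype, 0 = both, `type`),
#'   and `haplotypes` (per haplotype: `seq` character vector and `refpos`
#'   0-based map, NA over inserted bases).
#' @export
simulate_truth <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- as.integer(config$length)
  ref_vec <- sample(BASES, L, replace = TRUE)

  draw_sites <- function(rate, type, genotype) {
    pos <- which(runif(L) < rate) - 1L
    if (length(pos) == 0) return(NULL)
    tibble(pos = pos, type = type, genotype = genotype)
  }
  sites <- bind_rows(
    draw_sites(config$het_snp_rate, "snp", "het"),
    draw_sites(config$hom_snp_rate, "snp", "hom"),
    draw_sites(config$het_indel_rate, "indel", "het"),
    draw_sites(config$hom_indel_rate, "indel", "hom")
  )
  if (is.null(sites) || nrow(sites) == 0) {
    sites <- tibble(pos = integer(0), type = character(0), genotype = character(0))
  }
  # indel anchors need room for up to 10 deleted bases plus the anchor
  sites <- sites[!(sites$type == "indel" & sites$pos > L - 13), ]
  sites <- sites[order(sites$pos, sites$type), ]
  sites <- sites[!duplicated(sites$pos), ]
  if (nrow(sites) > 1) {
    keep <- logical(nrow(sites))
    last <- -1e18
    for (i in seq_len(nrow(sites))) {
      if (sites$pos[i] - last >= 12) {
        keep[i] <- TRUE
        last <- sites$pos[i]
      }
    }
    n_drop <- sum(!keep)
    if (n_drop > nrow(sites) / 2) {
      stop_invalid(
        "variant rates imply pervasive overlap (%d of %d draws conflicted)",
        n_drop, nrow(sites)
      )
    }
    sites <- sites[keep, ]
  }

  n <- nrow(sites)
  variants <- if (n == 0) {
    tibble(
      pos = integer(0), ref = character(0), alt = character(0),
      genotype = character(0), hap = integer(0), type = character(0)
    )
  } else {
    ref_base <- ref_vec[sites$pos + 1L]
    is_snp <- sites$type == "snp"
    # SNP alt: one of the three other bases, uniform
    shift <- sample(1:3, n, replace = TRUE)
    alt_snp <- BASES[((base_codes(ref_base) - 1L + shift) %% 4L) + 1L]
    is_ins <- !is_snp & runif(n) < 0.5
    ilen <- pmin(1L + rgeom(n, config$indel_geom_p), 10L)
    ref_a <- ref_base
    alt_a <- alt_snp
    type <- ifelse(is_snp, "snp", ifelse(is_ins, "ins", "del"))
    for (i in which(type == "ins")) {
      alt_a[i] <- paste0(ref_base[i],
                         paste(sample(BASES, ilen[i], replace = TRUE), collapse = ""))
      ref_a[i] <- ref_base[i]
    }
    for (i in which(type == "del")) {
      ref_a[i] <- paste(ref_vec[sites$pos[i] + 1L + 0:ilen[i]], collapse = "")
      alt_a[i] <- ref_base[i]
    }
    hap <- ifelse(sites$genotype == "hom", 0L, sample(1:2, n, replace = TRUE))
    tibble(
      pos = sites$pos, ref = ref_a, alt = alt_a,
      genotype = sites$genotype, hap = as.integer(hap), type = type
    )
  }

  haplotypes <- lapply(1:2, function(h) {
    vars <- variants[variants$hap %in% c(0L, h), ]
    build_haplotype(ref_vec, vars)
  })

  structure(
    list(
      config = config, contig = config$contig,
      reference = paste(ref_vec, collapse = ""),
      reference_vec = ref_vec,
      variants = variants, haplotypes = haplotypes
    ),
    class = "vc_truth"
  )
}

# Apply left-anchored variants to the reference, returning the haplotype
# sequence (character vector) and the 0-based reference position of every
# haplotype base (NA for inserted bases).
build_haplotype <- function(ref_vec, vars) {
  L <- length(ref_vec)
  segs_base <- list()
  segs_pos <- list()
  cursor <- 0L
  add <- function(bases, pos) {
    segs_base[[length(segs_base) + 1L]] <<- bases
    segs_pos[[length(segs_pos) + 1L]] <<- pos
  }
  if (nrow(vars) > 0) {
    for (i in seq_len(nrow(vars))) {
      p <- vars$pos[i]
      if (p > cursor) {
        add(ref_vec[(cursor + 1L):p], cursor:(p - 1L))
      }
      if (vars$type[i] == "snp") {
        add(substr(vars$alt[i], 1, 1), p)
        cursor <- p + 1L
      } else if (vars$type[i] == "ins") {
        ins <- strsplit(substr(vars$alt[i], 2, nchar(vars$alt[i])), "")[[1]]
        add(ref_vec[p + 1L], p)
        add(ins, rep(NA_integer_, length(ins)))
        cursor <- p + 1L
      } else {
        dlen <- nchar(vars$ref[i]) - 1L
        add(ref_vec[p + 1L], p)
        cursor <- p + 1L + dlen
      }
    }
  }
  if (cursor < L) add(ref_vec[(cursor + 1L):L], cursor:(L - 1L))
  list(seq = unlist(segs_base), refpos = as.integer(unlist(segs_pos)))
}

#' Simulate error-injected aligned long reads
#'
#' Reads alternate between the two haplotypes, with start positions uniform
#' over the extended interval `[-(len-1), hap_length)` and clipped at contig
#' bounds (yielding uniform depth across the contig). Substitution, insertion
#' and deletion errors are injected per base; alignment records are
#' constructed analytically from the haplotype-to-reference coordinate map,
#' so no external aligner is involved. The generating haplotype is recorded
#' per read.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The same [simulation_config()].
#' @return A `vc_reads` tibble: `read_id`, `contig`, `ref_start`, `strand`,
#'   `mapq`, `hp_tag` (0 until haplotagging), `truth_hap`, `seq`, `qual`
#'   (list of ints), `a_qpos`/`a_rpos` (aligned-pair list columns), `cigar`.
#' @export
simulate_reads <- function(truth, config = truth$config) {
  set.seed(config$seed + 104729L)  # decoupled stream, still seed-determined
  if (config$coverage == 0) return(empty_reads())
  hapL <- vapply(truth$haplotypes, function(h) length(h$seq), integer(1))
  target_bases <- config$coverage * config$length
  meanlog <- log(config$read_length_median)

  lens <- integer(0)
  starts <- integer(0)
  ends <- integer(0)
  haps <- integer(0)
  eff <- numeric(0)
  while (sum(eff) < target_bases) {
    k <- max(64L, ceiling((target_bases - sum(eff)) / config$read_length_median))
    l <- pmin(pmax(round(rlnorm(k, meanlog, config$read_length_sdlog)),
                   config$min_read_length), config$max_read_length)
    h <- rep_len(1:2, k)
    if (length(haps)) h <- ((length(haps) + seq_len(k) - 1L) %% 2L) + 1L
    s <- floor(runif(k, min = -(l - 1), max = hapL[h]))
    e <- pmin(s + l, hapL[h])
    s2 <- pmax(s, 0)
    lens <- c(lens, l); starts <- c(starts, s2); haps <- c(haps, h)
    ends <- c(ends, e)
    eff <- c(eff, e - s2)
  }
  n_keep <- which(cumsum(eff) >= target_bases)[1]
  idx <- seq_len(n_keep)
  starts <- starts[idx]; haps <- haps[idx]; ends <- ends[idx]

  reads <- vector("list", n_keep)
  for (i in idx) {
    h <- truth$haplotypes[[haps[i]]]
    s <- starts[i]
    e <- ends[i]
    if (e - s < config$min_read_length) next
    sl <- (s + 1L):e
    bases <- h$seq[sl]
    rp <- h$refpos[sl]
    r <- inject_errors(bases, rp, config)
    if (length(r$bases) < 30) next
    pr <- pairs_from_refpos(r$bases, r$rp)
    if (is.null(pr)) next
    reads[[i]] <- list(
      ref_start = pr$ref_start, seq = paste(r$bases, collapse = ""),
      a_qpos = pr$qpos, a_rpos = pr$rpos, truth_hap = haps[i],
      n = length(r$bases)
    )
  }
  reads <- reads[!vapply(reads, is.null, logical(1))]
  n <- length(reads)
  if (n == 0) return(empty_reads())
  strand <- sample(c("+", "-"), n, replace = TRUE)
  quals <- lapply(reads, function(r) sample(15:40, r$n, replace = TRUE))
  out <- tibble(
    read_id = sprintf("read_%06d", seq_len(n)),
    contig = truth$contig,
    ref_start = vapply(reads, function(r) r$ref_start, integer(1)),
    strand = strand,
    mapq = 60L,
    hp_tag = 0L,
    truth_hap = vapply(reads, function(r) r$truth_hap, integer(1)),
    seq = vapply(reads, function(r) r$seq, character(1)),
    qual = quals,
    a_qpos = map(reads, "a_qpos"),
    a_rpos = map(reads, "a_rpos"),
    cigar = vapply(reads, function(r) pairs_to_cigar(r$a_qpos, r$a_rpos), character(1))
  )
  out <- out[order(out$ref_start, out$read_id), ]
  class(out) <- c("vc_reads", class(out))
  out
}

empty_reads <- function() {
  out <- tibble(
    read_id = character(0), contig = character(0), ref_start = integer(0),
    strand = character(0), mapq = integer(0), hp_tag = integer(0),
    truth_hap = integer(0), seq = character(0), qual = list(),
    a_qpos = list(), a_rpos = list(), cigar = character(0)
  )
  class(out) <- c("vc_reads", class(out))
  out
}

# Per-base error injection on (bases, refpos) arrays.
inject_errors <- function(bases, rp, config) {
  n <- length(bases)
  del_p <- rep(config$del_rate, n)
  ins_p <- rep(config$ins_rate, n)
  if (isTRUE(config$homopolymer_bias) && n > 1) {
    hp <- c(FALSE, bases[-1] == bases[-n])
    del_p[hp] <- pmin(del_p[hp] * 3, 1)
    ins_p[hp] <- pmin(ins_p[hp] * 3, 1)
  }
  keep <- runif(n) >= del_p
  bases <- bases[keep]; rp <- rp[keep]; ins_p <- ins_p[keep]
  n <- length(bases)
  if (n == 0) return(list(bases = character(0), rp = integer(0)))
  sub <- runif(n) < config$sub_rate
  if (any(sub)) {
    shift <- sample(1:3, sum(sub), replace = TRUE)
    bases[sub] <- BASES[((base_codes(bases[sub]) - 1L + shift) %% 4L) + 1L]
  }
  ia <- which(runif(n) < ins_p)
  if (length(ia)) {
    il <- 1L + rgeom(length(ia), config$err_ins_geom_p)
    newb <- sample(BASES, sum(il), replace = TRUE)
    at <- rep(ia, il)
    within <- sequence(il)
    key <- c(seq_len(n), at + within / (max(il) + 1))
    bases <- c(bases, newb)[order(key)]
    rp <- c(rp, rep(NA_integer_, sum(il)))[order(key)]
  }
  # trim inserted bases at the read edges (no reference anchor)
  ok <- which(!is.na(rp))
  if (length(ok) == 0) return(list(bases = character(0), rp = integer(0)))
  span <- ok[1]:ok[length(ok)]
  list(bases = bases[span], rp = rp[span])
}

# Build aligned pairs from a per-query-base refpos vector (NA = inserted
# base). Deletion rows are interleaved right after the anchoring base.
pairs_from_refpos <- function(bases, rp) {
  n <- length(bases)
  if (n == 0 || all(is.na(rp))) return(NULL)
  qpos <- 0:(n - 1)
  key <- as.numeric(qpos)
  m <- which(!is.na(rp))
  gaps <- diff(rp[m]) - 1L
  gi <- which(gaps > 0)
  if (length(gi)) {
    del_anchor_q <- qpos[m[gi]]
    del_ref_start <- rp[m[gi]] + 1L
    g <- gaps[gi]
    dq <- rep(NA_integer_, sum(g))
    dr <- unlist(lapply(seq_along(gi), function(k) del_ref_start[k] + 0:(g[k] - 1L)))
    dkey <- rep(del_anchor_q, g) + sequence(g) / (max(g) + 1)
    ord <- order(c(key, dkey))
    qpos <- c(qpos, dq)[ord]
    rpos <- c(rp, dr)[ord]
  } else {
    rpos <- rp
  }
  list(qpos = as.integer(qpos), rpos = as.integer(rpos),
       ref_start = as.integer(min(rp, na.rm = TRUE)))
}

#' Write simulated fixtures to disk
#'
#' Emits the reference FASTA (+ .fai index), a coordinate-sorted SAM and its
#' indexed BAM (converted with Rsamtools, no external aligner), the truth VCF,
#' a per-read truth-haplotype table (TSV), and a whole-interval confident-
#' regions BED.
#'
#' @param truth,reads Output of [simulate_truth()] and [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @param sample_name Sample name for the VCF column (default "sim").
#' @return Named list of file paths.
#' @export
write_simulation <- function(truth, reads, dir, sample_name = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(truth$reference)
  fa <- file.path(dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(setNames(truth$reference, truth$contig))
  Biostrings::writeXStringSet(dna, fa)
  Rsamtools::indexFa(fa)

  sam <- file.path(dir, "reads.sam")
  write_sam(reads, setNames(L, truth$contig), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)

  vcf <- file.path(dir, "truth.vcf")
  write_vcf(truth_calls(truth), setNames(L, truth$contig), vcf,
            sample_name = sample_name)

  tsv <- file.path(dir, "truth_reads.tsv")
  readr::write_tsv(
    tibble(read_id = reads$read_id, truth_hap = reads$truth_hap), tsv
  )

  bed <- file.path(dir, "confident.bed")
  writeLines(sprintf("%s\t0\t%d", truth$contig, L), bed)

  list(fasta = fa, sam = sam, bam = bam, truth_vcf = vcf,
       truth_reads = tsv, confident_bed = bed)
}

#' Truth variants as a call tibble
#'
#' Converts a simulated truth set to the `vc_calls` layout used by the merge,
#' VCF and evaluation functions (GT phased as hap1|hap2).
#'
#' @param truth A [simulate_truth()] result.
#' @return A call tibble (`contig`, `pos`, `ref`, `alt`, `gt`, `qual`, ...).
#' @export
truth_calls <- function(truth) {
  v <- truth$variants
  gt <- ifelse(v$genotype == "hom", "1/1", ifelse(v$hap == 1L, "1|0", "0|1"))
  tibble(
    contig = truth$contig, pos = v$pos, ref = v$ref, alt = v$alt,
    gt = gt, qual = 60, gq = 60L, dp = NA_integer_, af = NA_real_,
    ps = NA_integer_, source = "truth", is_variant = TRUE
  )
}
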