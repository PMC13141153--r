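#' Pipeline configuration
#'
#' Bundles every tunable of the two-pass workflow. All referenced paths are
#' validated at construction.
#'
#' @param reference Indexed FASTA path.
#' @param bam Coordinate-sorted indexed BAM path (or an in-memory `vc_reads`
#'   tibble, mainly for tests).
#' @param out_dir Output directory.
#' @param backends Trained `vc_backends` (or a path saved with
#'   [save_backends()]).
#' @param chunking A [chunking_config()].
#' @param candidates A [candidate_config()].
#' @param regions Optional regions of interest (BED path or tibble
#'   `contig`,`start`,`end`).
#' @param contigs Optional contig restriction.
#' @param min_mapq Mapping-quality floor for fetched reads (default 5).
#' @param min_bq Base-quality floor for haplotag support counting (default 10).
#' @param min_phase_qual Quality floor for phasing input SNPs (default 15).
#' @param tier_strategy,low_conf_fraction,ref_call_fraction Routing contract
#'   of [tier_split()] (defaults "quantile", 0.7, 0.1).
#' @param pileup_window Pileup feature width W (default 33).
#' @param fa_depth,fa_window Full-alignment tensor geometry D, W (89, 33).
#' @param max_pair_bp Phasing edge distance cap (default 2e5).
#' @param workers Worker count for chunk-parallel stages (default 1); outputs
#'   are identical for every worker count.
#' @param seed Seed echoed into the report (the calling stages are
#'   deterministic).
#' @param gvcf Also write a GVCF with non-variant blocks (default FALSE).
#' @param sample_name VCF sample name.
#' @return List of class `vc_pipeline_config`.
#' @export
pipeline_config <- function(reference, bam, out_dir, backends,
                            chunking = chunking_config(),
                            candidates = candidate_config(),
                            regions = NULL, contigs = NULL,
                            min_mapq = 5, min_bq = 10, min_phase_qual = 15,
                            tier_strategy = "quantile",
                            low_conf_fraction = 0.7, ref_call_fraction = 0.1,
                            pileup_window = 33, fa_depth = 89, fa_window = 33,
                            max_pair_bp = 2e5,
                            workers = 1, seed = 1, gvcf = FALSE,
                            sample_name = "sample") {
  if (!file.exists(reference)) stop_invalid("reference '%s' not found", reference)
  if (is.character(bam) && !file.exists(bam)) stop_invalid("alignments '%s' not found", bam)
  if (is.character(regions)) {
    if (!file.exists(regions)) stop_invalid("regions file '%s' not found", regions)
    regions <- read_bed(regions)
  }
  if (is.character(backends)) backends <- load_backends(backends)
  structure(as.list(environment()), class = "vc_pipeline_config")
}

log_stage <- function(msg, ...) {
  inform(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(msg, ...)))
}

#' Run the full two-pass calling workflow
#'
#' Per chunk: fetch reads, build the pileup, select and classify candidates.
#' Then per contig: select high-quality het SNPs and phase them. Then per
#' chunk again: haplotag reads in memory, build haplotype-sorted
#' full-alignment tensors for the routed low-confidence sites, classify, and
#' take the joint genotype decision. Finally high-confidence pileup calls and
#' full-alignment calls are merged, phase-annotated and written as VCF (and
#' optionally GVCF). Chunk work units are independent; outputs are identical
#' for any worker count. Any stage error aborts with the failing chunk
#' identified and partial outputs removed.
#'
#' @param config A [pipeline_config()].
#' @return `vc_run`: list with `calls`, `vcf` (path), `gvcf` (path or NULL),
#'   `phase_blocks`, `tag_stats`, `metrics`-ready call tibble and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vc_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(config$out_dir, paste0(config$sample_name, ".vcf"))
  gvcf_path <- file.path(config$out_dir, paste0(config$sample_name, ".g.vcf"))
  on_fail <- function() unlink(c(vcf_path, gvcf_path))

  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  ref <- reference_source(config$reference)
  contig_lengths <- ref$contigs
  if (!is.null(config$contigs)) {
    contig_lengths <- contig_lengths[names(contig_lengths) %in% config$contigs]
  }
  chunks <- if (!is.null(config$regions)) {
    partition_regions(config$regions, config$chunking$chunk_size,
                      config$chunking, contig_lengths)
  } else {
    partition_genome(contig_lengths, config$chunking)
  }
  log_stage("partitioned %d contig(s) into %d chunk(s)",
            length(contig_lengths), nrow(chunks))

  run_chunks <- function(fun) {
    res <- if (config$workers > 1) {
      parallel::mclapply(seq_len(nrow(chunks)), function(i) {
        tryCatch(fun(chunks[i, ]), error = function(e) e)
      }, mc.cores = config$workers)
    } else {
      lapply(seq_len(nrow(chunks)), function(i) {
        tryCatch(fun(chunks[i, ]), error = function(e) e)
      })
    }
    bad <- which(vapply(res, inherits, logical(1), "error"))
    if (length(bad)) {
      on_fail()
      ch <- chunks[bad[1], ]
      abort(sprintf(
        "pipeline failed in chunk %s:%.0f-%.0f: %s",
        ch$contig, ch$core_start, ch$core_end,
        conditionMessage(res[[bad[1]]])
      ), class = "haplocall_pipeline_error")
    }
    res
  }

  # ---- pass 1: pileup calling per chunk -------------------------------
  pileup_stage <- timed("pileup_calling", run_chunks(function(chunk) {
    reads <- fetch_reads(config$bam, chunk, min_mapq = config$min_mapq)
    ref_seq <- ref$fetch(chunk$contig, chunk$fetch_start, chunk$fetch_end)
    columns <- build_pileup(reads, chunk, ref_seq, span = "fetch")
    core <- columns[columns$ref_pos >= chunk$core_start &
                      columns$ref_pos < chunk$core_end, ]
    cands <- select_candidates(core, config$candidates)
    cands <- attach_indel_observations(cands, reads)
    x <- pileup_feature_batch(columns, cands$pos, cands$depth,
                              W = config$pileup_window)
    probs <- classify_pileup(x, config$backends$pileup)
    calls <- pileup_calls(cands, probs)
    calls <- finalize_pileup_calls(calls, ref_seq, chunk$fetch_start)
    ref_blocks <- if (config$gvcf) {
      gvcf_reference_blocks(core, cands$pos)
    } else NULL
    list(calls = calls, n_columns = nrow(core), ref_blocks = ref_blocks)
  }))
  all_calls <- bind_rows(map(pileup_stage, "calls"))
  log_stage("pileup pass: %d candidates, %d variant calls",
            nrow(all_calls), sum(all_calls$is_variant))

  tiers <- tier_split(all_calls, strategy = config$tier_strategy,
                      q = config$low_conf_fraction,
                      r = config$ref_call_fraction)

  # ---- intermediate phasing per contig --------------------------------
  hets <- select_phase_input(all_calls, config$min_phase_qual)
  phase_blocks <- timed("phasing", {
    per_contig <- lapply(names(contig_lengths), function(ctg) {
      h <- hets[hets$contig == ctg, ]
      if (nrow(h) == 0) return(NULL)
      ch <- chunks[chunks$contig == ctg, ]
      # fragments are collected chunk by chunk (owner dedup: a read belongs
      # to the chunk whose core holds its start) so only the small fragment
      # lists, not the reads, accumulate per contig
      frags <- unlist(lapply(seq_len(nrow(ch)), function(i) {
        r <- fetch_reads(config$bam, ch[i, ], min_mapq = config$min_mapq)
        r <- r[r$ref_start >= ch$core_start[i] & r$ref_start < ch$core_end[i], ]
        read_fragments(h, r, min_bq = config$min_bq)
      }), recursive = FALSE)
      graph <- graph_from_fragments(h, frags, max_pair_bp = config$max_pair_bp)
      phase_two_stage(graph)
    })
    pb <- bind_rows(per_contig)
    if (nrow(pb) == 0) {
      pb <- empty_phase_blocks()
    } else {
      # block ids unique across contigs
      pb$block_id <- as.integer(factor(paste(pb$contig, pb$block_id)))
    }
    class(pb) <- unique(c("vc_phase_blocks", class(pb)))
    pb
  })
  log_stage("phasing: %d het SNPs in %d block(s), N50 %.0f bp",
            nrow(phase_blocks), length(unique(phase_blocks$block_id)),
            phase_block_n50(phase_blocks))

  # ---- pass 2: in-memory haplotag + full-alignment refinement ---------
  fa_sites <- bind_rows(tiers$low_confidence, tiers$ref_routed)
  fa_stage <- timed("full_alignment_calling", run_chunks(function(chunk) {
    sites <- fa_sites[fa_sites$contig == chunk$contig &
                        fa_sites$pos >= chunk$core_start &
                        fa_sites$pos < chunk$core_end, ]
    reads <- fetch_reads(config$bam, chunk, min_mapq = config$min_mapq)
    haps <- collect_chunk_haplotypes(chunk, phase_blocks)
    tagged <- haplotag_chunk(reads, haps, min_bq = config$min_bq)
    owner <- tagged$ref_start >= chunk$core_start &
      tagged$ref_start < chunk$core_end
    stats <- haplotag_stats(tagged[owner, ])
    stats$contig <- chunk$contig
    stats$core_start <- chunk$core_start
    calls <- empty_calls()
    if (nrow(sites) > 0) {
      tagged <- precompute_ins_runs(tagged)
      ref_seq <- ref$fetch(chunk$contig, chunk$fetch_start, chunk$fetch_end)
      # reduce each tensor as it is built so only the compact feature rows,
      # never the full D x W x C arrays, are held for the whole chunk
      xmat <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
        reduce_fa_tensor(build_full_alignment_feature(
          sites[i, ], tagged, ref_seq, chunk$fetch_start,
          D = config$fa_depth, W = config$fa_window
        ))
      }))
      preds <- classify_full_alignment(xmat, config$backends$full_alignment)
      calls <- bind_rows(lapply(seq_len(nrow(sites)), function(i) {
        joint_decision(
          list(p_gt21 = preds$p_gt21[[i]], p_zygosity = preds$p_zygosity[[i]],
               p_indel_len = preds$p_indel_len[[i]]),
          sites[i, ], ref_seq, chunk$fetch_start
        )
      }))
    }
    list(calls = calls, stats = stats,
         cross_block = attr(tagged, "cross_block_reads") %||% 0L)
  }))
  fa_calls <- bind_rows(map(fa_stage, "calls"))
  tag_stats <- bind_rows(map(fa_stage, "stats"))
  log_stage("full-alignment pass: %d routed sites, %d variant calls",
            nrow(fa_sites), sum(fa_calls$is_variant))

  # ---- merge, annotate, write -----------------------------------------
  result <- timed("merge_and_write", {
    high_calls <- pileup_tier_calls(tiers$high_confidence)
    merged <- merge_calls(high_calls, fa_calls[fa_calls$is_variant, ],
                          contig_order = names(contig_lengths))
    merged <- annotate_phase(merged, phase_blocks)
    out <- tryCatch({
      write_vcf(merged, contig_lengths, vcf_path,
                sample_name = config$sample_name)
      if (config$gvcf) {
        rb <- bind_rows(map(pileup_stage, "ref_blocks"))
        write_gvcf(merged, rb, contig_lengths, gvcf_path,
                   sample_name = config$sample_name)
      }
      merged
    }, error = function(e) {
      on_fail()
      abort(conditionMessage(e), class = "haplocall_pipeline_error")
    })
    out
  })

  n_var <- sum(all_calls$is_variant)
  report <- list(
    seed = config$seed,
    workers = config$workers,
    n_chunks = nrow(chunks),
    contigs = as.list(contig_lengths),
    stage_seconds = timings,
    n_candidates = nrow(all_calls),
    n_pileup_variant_calls = n_var,
    n_high_confidence = nrow(tiers$high_confidence),
    n_low_confidence = nrow(tiers$low_confidence),
    n_ref_routed = nrow(tiers$ref_routed),
    low_conf_fraction = if (n_var > 0) nrow(tiers$low_confidence) / n_var else NA_real_,
    n_phased_snps = nrow(phase_blocks),
    n_phase_blocks = length(unique(phase_blocks$block_id)),
    phase_block_n50 = phase_block_n50(phase_blocks),
    haplotagged_pct = if (sum(tag_stats$n_total) > 0) {
      100 * sum(tag_stats$n_hp1 + tag_stats$n_hp2) / sum(tag_stats$n_total)
    } else 0,
    cross_block_reads = sum(map_int(fa_stage, "cross_block")),
    n_final_calls = nrow(result),
    calls_by_category = as.list(table(variant_category(
      sub(",.*", "", result$ref), sub(",.*", "", result$alt)
    ))),
    config = list(
      chunk_size = config$chunking$chunk_size,
      overlap = config$chunking$overlap,
      flank = config$chunking$flank,
      min_coverage = config$candidates$min_coverage,
      min_af = config$candidates$min_af,
      indel_min_af = config$candidates$indel_min_af,
      min_mapq = config$min_mapq, min_bq = config$min_bq,
      min_phase_qual = config$min_phase_qual,
      tier_strategy = config$tier_strategy,
      low_conf_fraction = config$low_conf_fraction,
      ref_call_fraction = config$ref_call_fraction
    )
  )

  structure(
    list(
      calls = result, vcf = vcf_path,
      gvcf = if (config$gvcf) gvcf_path else NULL,
      phase_blocks = phase_blocks, tag_stats = tag_stats,
      report = report
    ),
    class = "vc_run"
  )
}

# Reconstruct concrete alleles for pileup variant calls (adds call_pos/ref/
# alt/gt columns; NA where reconstruction is impossible).
finalize_pileup_calls <- function(calls, ref_seq, ref_offset) {
  n <- nrow(calls)
  call_pos <- rep(NA_real_, n)
  call_ref <- rep(NA_character_, n)
  call_alt <- rep(NA_character_, n)
  call_gt <- rep(NA_character_, n)
  for (i in which(calls$is_variant)) {
    a <- calls$alts[[i]]
    pair <- switch(calls$genotype_class[i],
      het = c(calls$ref_base[i], a$class[1]),
      hom = c(a$class[1], a$class[1]),
      multihet = if (nrow(a) >= 2) c(a$class[1], a$class[2]) else c(calls$ref_base[i], a$class[1]),
      NULL
    )
    if (is.null(pair)) next
    fc <- finalize_call(calls[i, ], pair, calls$qual[i], ref_seq, ref_offset,
                        source = "pileup")
    if (is.null(fc)) next
    call_pos[i] <- fc$pos
    call_ref[i] <- fc$ref
    call_alt[i] <- fc$alt
    call_gt[i] <- fc$gt
  }
  calls$call_pos <- call_pos
  calls$call_ref <- call_ref
  calls$call_alt <- call_alt
  calls$call_gt <- call_gt
  calls
}

pileup_tier_calls <- function(tier) {
  ok <- tier[!is.na(tier$call_ref), ]
  if (nrow(ok) == 0) return(empty_calls())
  out <- one_call(
    ok$contig, ok$call_pos, ok$call_ref, ok$call_alt, ok$call_gt,
    ok$qual, ok$depth,
    map_dbl(ok$alts, function(a) a$af[1]),
    source = "pileup"
  )
  dplyr::distinct(out, .data$contig, .data$pos, .data$ref, .data$alt,
                  .keep_all = TRUE)
}

# Banded non-variant blocks for GVCF output: per-position reference genotype
# quality from depth and reference support, grouped into contiguous runs
# within GQ bands [0,20), [20,50), [50,60].
gvcf_reference_blocks <- function(core_columns, candidate_pos) {
  cc <- core_columns[!(core_columns$ref_pos %in% candidate_pos), ]
  if (nrow(cc) == 0) {
    return(tibble(contig = character(0), start = numeric(0), end = numeric(0),
                  min_gq = integer(0), ref_base = character(0), dp = integer(0)))
  }
  ref_idx <- match(cc$ref_base, BASES)
  cnt <- cbind(cc$a_fwd + cc$a_rev, cc$c_fwd + cc$c_rev,
               cc$g_fwd + cc$g_rev, cc$t_fwd + cc$t_rev)
  refn <- ifelse(is.na(ref_idx), 0L, cnt[cbind(seq_len(nrow(cc)), ref_idx)])
  gq <- pmin(60L, as.integer(round(-10 * log10(
    pmax(1e-6, 1 - (refn + 1) / (cc$depth + 2))
  ))))
  band <- findInterval(gq, c(0, 20, 50))
  newblk <- c(TRUE, diff(cc$ref_pos) != 1 | diff(band) != 0)
  blk <- cumsum(newblk)
  cc |>
    mutate(gq = gq, blk = blk) |>
    group_by(.data$blk) |>
    summarise(
      contig = first(.data$contig),
      start = min(.data$ref_pos), end = max(.data$ref_pos) + 1,
      min_gq = min(.data$gq), ref_base = first(.data$ref_base),
      dp = as.integer(round(mean(.data$depth))), .groups = "drop"
    ) |>
    select(-"blk")
}

#' Structured run report
#'
#' Machine-readable summary of a pipeline run: per-stage wall time, candidate
#' counts, tier fractions, haplotag percentage, phase-block N50 and call
#' counts by category.
#'
#' @param run A `vc_run` from [run_pipeline()].
#' @param path Optional path; when given the report is written as JSON.
#' @return The report list, invisibly when written.
#' @export
run_report <- function(run, path = NULL) {
  rep <- run$report
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' @exportS3Method generics::glance
glance.vc_run <- function(x, ...) {
  r <- x$report
  tibble(
    n_candidates = r$n_candidates,
    n_final_calls = r$n_final_calls,
    n_phase_blocks = r$n_phase_blocks,
    phase_block_n50 = r$phase_block_n50,
    haplotagged_pct = r$haplotagged_pct,
    low_conf_fraction = r$low_conf_fraction,
    elapsed_s = sum(unlist(r$stage_seconds))
  )
}

#' @exportS3Method generics::tidy
tidy.vc_run <- function(x, ...) {
  as_tibble(x$calls)
}

#' @export
print.vc_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<haplocall run> %d final calls (%d candidates) | %d phase blocks, N50 %.0f bp | %.1f%% reads haplotagged\nVCF: %s\n",
    r$n_final_calls, r$n_candidates, r$n_phase_blocks, r$phase_block_n50,
    r$haplotagged_pct, x$vcf
  ))
  invisible(x)
}
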