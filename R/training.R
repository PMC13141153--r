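# Truth-derived labels for candidate sites: the pileup genotype class and the
# three full-alignment task labels. Deletion candidates at deleted reference
# positions inherit the labels of the run's variant.
label_candidates <- function(candidates, truth) {
  v <- truth$variants
  n <- nrow(candidates)
  pu <- rep("ref", n)
  gt21 <- paste0(candidates$ref_base, candidates$ref_base)
  zyg <- rep("hom", n)
  ilen <- rep("0", n)
  if (n == 0 || nrow(v) == 0) {
    return(tibble(pileup = pu, gt21 = gt21,
                  gt21_rel = gt21_relative_label(gt21, candidates$ref_base),
                  zygosity = zyg, indel_len = ilen))
  }
  exact <- match(candidates$pos, v$pos)
  # deletion runs: deleted positions are v$pos+1 .. v$pos + (nchar(ref)-1)
  dels <- v[v$type == "del", ]
  for (i in seq_len(n)) {
    vi <- exact[i]
    if (is.na(vi) && nrow(dels) > 0) {
      hit <- which(dels$pos < candidates$pos[i] &
                     candidates$pos[i] <= dels$pos + nchar(dels$ref) - 1)
      if (length(hit)) vi <- which(v$pos == dels$pos[hit[1]] & v$type == "del")[1]
    }
    if (is.na(vi)) next
    b <- candidates$ref_base[i]
    het <- v$genotype[vi] == "het"
    pu[i] <- if (het) "het" else "hom"
    zyg[i] <- if (het) "het" else "hom"
    if (v$type[vi] == "snp") {
      alt <- v$alt[vi]
      gt21[i] <- if (het) gt21_label(b, alt) else paste0(alt, alt)
    } else if (v$type[vi] == "ins") {
      gt21[i] <- if (het) gt21_label(b, "I") else "II"
      ilen[i] <- indel_len_label(nchar(v$alt[vi]) - 1L)
    } else {
      gt21[i] <- if (het) gt21_label(b, "D") else "DD"
      ilen[i] <- indel_len_label(-(nchar(v$ref[vi]) - 1L))
    }
  }
  tibble(pileup = pu, gt21 = gt21,
         gt21_rel = gt21_relative_label(gt21, candidates$ref_base),
         zygosity = zyg, indel_len = ilen)
}

reference_from_truth <- function(truth) {
  L <- nchar(truth$reference)
  list(
    contigs = setNames(L, truth$contig),
    fetch = function(contig, start, end) {
      substr(truth$reference, start + 1, min(end, L))
    }
  )
}

#' Train fixture backends from a labeled simulation
#'
#' Bootstraps the two classifier backends from simulator output: first the
#' pileup genotype head is trained on truth-labeled pileup features; the
#' trained pileup stage is then run to reproduce the exact routing the
#' pipeline uses (tier split, phasing, in-memory haplotagging), and the
#' full-alignment heads are trained on truth-labeled haplotype-sorted
#' tensors of the routed sites. Deterministic given `spec$seed` and the
#' simulation seed.
#'
#' @param truth,reads Output of [simulate_truth()] / [simulate_reads()].
#' @param spec A [backend_spec()].
#' @param candidates A [candidate_config()].
#' @param pileup_window,fa_depth,fa_window Feature geometry (33, 89, 33).
#' @param low_conf_fraction,ref_call_fraction Routing fractions (0.7, 0.1).
#' @param min_phase_qual,min_bq Phasing/haplotagging floors (15, 10).
#' @return A `vc_backends` object with trained `pileup` and `full_alignment`
#'   backends.
#' @export
train_backends_from_simulation <- function(truth, reads,
                                           spec = backend_spec(),
                                           candidates = candidate_config(),
                                           pileup_window = 33,
                                           fa_depth = 89, fa_window = 33,
                                           low_conf_fraction = 0.7,
                                           ref_call_fraction = 0.1,
                                           min_phase_qual = 15, min_bq = 10) {
  ref <- reference_from_truth(truth)
  chunks <- partition_genome(ref$contigs, chunking_config())

  per_chunk <- lapply(seq_len(nrow(chunks)), function(i) {
    chunk <- chunks[i, ]
    rc <- fetch_reads(reads, chunk)
    ref_seq <- ref$fetch(chunk$contig, chunk$fetch_start, chunk$fetch_end)
    columns <- build_pileup(rc, chunk, ref_seq, span = "fetch")
    core <- columns[columns$ref_pos >= chunk$core_start &
                      columns$ref_pos < chunk$core_end, ]
    cands <- select_candidates(core, candidates)
    cands <- attach_indel_observations(cands, rc)
    x <- pileup_feature_batch(columns, cands$pos, cands$depth, W = pileup_window)
    list(chunk = chunk, cands = cands, x = x, columns = columns,
         labels = label_candidates(cands, truth))
  })
  x_pu <- do.call(rbind, map(per_chunk, "x"))
  y_pu <- unlist(map(per_chunk, function(p) p$labels$pileup))
  pu_backend <- train_fixture_models(
    list(pileup = list(x = x_pu, y = y_pu)), spec
  )$pileup

  # reproduce the pipeline's routing with the freshly trained pileup stage
  all_calls <- bind_rows(lapply(per_chunk, function(p) {
    pileup_calls(p$cands, classify_pileup(p$x, pu_backend))
  }))
  tiers <- tier_split(all_calls, q = low_conf_fraction, r = ref_call_fraction)
  fa_sites <- bind_rows(tiers$low_confidence, tiers$ref_routed)

  hets <- select_phase_input(all_calls, min_phase_qual)
  blocks <- if (nrow(hets)) {
    phase_two_stage(build_allele_graph(hets, reads, min_bq = min_bq))
  } else {
    phase_two_stage(build_allele_graph(hets, reads[0, ], min_bq = min_bq))
  }

  fa_parts <- lapply(per_chunk, function(p) {
    chunk <- p$chunk
    sites <- fa_sites[fa_sites$contig == chunk$contig &
                        fa_sites$pos >= chunk$core_start &
                        fa_sites$pos < chunk$core_end, ]
    if (nrow(sites) == 0) return(NULL)
    rc <- fetch_reads(reads, chunk)
    tagged <- haplotag_chunk(rc, collect_chunk_haplotypes(chunk, blocks),
                             min_bq = min_bq)
    tagged <- precompute_ins_runs(tagged)
    ref_seq <- ref$fetch(chunk$contig, chunk$fetch_start, chunk$fetch_end)
    xf <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
      reduce_fa_tensor(build_full_alignment_feature(
        sites[i, ], tagged, ref_seq, chunk$fetch_start,
        D = fa_depth, W = fa_window
      ))
    }))
    lab <- label_candidates(sites, truth)
    list(x = xf, lab = lab)
  })
  fa_parts <- fa_parts[!vapply(fa_parts, is.null, logical(1))]
  x_fa <- do.call(rbind, map(fa_parts, "x"))
  lab_fa <- bind_rows(map(fa_parts, "lab"))

  train_fixture_models(
    list(
      pileup = list(x = x_pu, y = y_pu),
      full_alignment = list(
        x = x_fa, y_gt21 = lab_fa$gt21_rel, y_zygosity = lab_fa$zygosity,
        y_indel_len = lab_fa$indel_len
      )
    ),
    spec
  )
}
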