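# Allele-class vocabularies for the multi-task heads.
GT21_CLASSES <- {
  k <- length(CLASS_LABELS)
  out <- character(0)
  for (i in seq_len(k)) for (j in i:k) {
    out <- c(out, paste0(CLASS_LABELS[i], CLASS_LABELS[j]))
  }
  out  # 21 unordered pairs with replacement from {A,C,G,T,I,D}
}

INDEL_LEN_CLASSES <- c("0", paste0("+", 1:15), ">15", paste0("-", 1:15), "<-15")

ZYGOSITY_CLASSES <- c("het", "hom")

gt21_label <- function(a, b) {
  i <- match(a, CLASS_LABELS)
  j <- match(b, CLASS_LABELS)
  paste0(CLASS_LABELS[min(i, j)], CLASS_LABELS[max(i, j)])
}

indel_len_label <- function(len) {
  ifelse(len == 0, "0",
    ifelse(len > 15, ">15",
      ifelse(len < -15, "<-15",
        ifelse(len > 0, paste0("+", len), as.character(len)))))
}

FA_CHANNELS <- c("A", "C", "G", "T", "bq", "mq", "strand", "hp",
                 "ins_len", "del", "ref_A", "ref_C", "ref_G", "ref_T")

# Reference-relative genotype classes the builtin 21-genotype head is trained
# on: R = reference base, X/Y = first/second non-reference base, I/D =
# insertion/deletion. Pooling sites by relation to the reference (rather than
# by concrete base pair) gives every class enough training support at fixture
# scale; predictions are expanded back onto the concrete 21-class vocabulary
# per site using the reference and dominant alternate base.
GT21_REL_CLASSES <- c("RR", "RX", "XX", "XY", "RI", "II", "XI",
                      "RD", "DD", "XD", "ID")

gt21_relative_label <- function(gt21, ref_base) {
  enc <- function(a, r, alt_seen) {
    if (a == r) "R" else if (a %in% c("I", "D")) a else if (is.na(alt_seen) || a == alt_seen) "X" else "Y"
  }
  vapply(seq_along(gt21), function(i) {
    a <- substring(gt21[i], 1, 1)
    b <- substring(gt21[i], 2, 2)
    e1 <- enc(a, ref_base[i], NA)
    alt_seen <- if (e1 == "X") a else NA
    e2 <- enc(b, ref_base[i], alt_seen)
    lab <- paste0(sort(factor(c(e1, e2), levels = c("R", "X", "Y", "I", "D"))), collapse = "")
    lab
  }, character(1))
}

# Expand relative-class probabilities onto the concrete 21-class vocabulary
# using the reference base and the dominant non-reference base of each
# reduced feature row.
expand_rel_gt21 <- function(rel, x_reduced) {
  n <- nrow(rel)
  out <- matrix(0, nrow = n, ncol = length(GT21_CLASSES),
                dimnames = list(NULL, GT21_CLASSES))
  p <- ncol(x_reduced)
  ref_onehot <- x_reduced[, (p - 3):p, drop = FALSE]
  ga_base <- x_reduced[, (3 * 16 + 2):(3 * 16 + 5), drop = FALSE]
  for (i in seq_len(n)) {
    ri <- which(ref_onehot[i, ] == 1)[1]
    if (is.na(ri)) ri <- which.max(colSums(matrix(ga_base[i, ], 1)))
    bf <- ga_base[i, ]
    bf[ri] <- -1
    xi <- order(-bf, seq_along(bf))[1]
    yi <- order(-bf, seq_along(bf))[2]
    r <- BASES[ri]; xb <- BASES[xi]; yb <- BASES[yi]
    target <- c(
      RR = gt21_label(r, r), RX = gt21_label(r, xb), XX = gt21_label(xb, xb),
      XY = gt21_label(xb, yb), RI = gt21_label(r, "I"), II = "II",
      XI = gt21_label(xb, "I"), RD = gt21_label(r, "D"), DD = "DD",
      XD = gt21_label(xb, "D"), ID = "ID"
    )
    for (cl in colnames(rel)) {
      out[i, target[[cl]]] <- out[i, target[[cl]]] + rel[i, cl]
    }
  }
  out
}

# per-read insertion-run lookup (anchor position -> inserted length), computed
# once per chunk so the feature builder does not rescan alignments per site
precompute_ins_runs <- function(reads) {
  reads$ins_runs <- map(seq_len(nrow(reads)), function(j) {
    rp <- reads$a_rpos[[j]]
    na_r <- is.na(rp)
    if (!any(na_r)) return(NULL)
    r <- rle(na_r)
    endi <- cumsum(r$lengths)
    starti <- endi - r$lengths + 1L
    runs <- which(r$values & starti > 1L)
    if (!length(runs)) return(NULL)
    list(anchor = rp[starti[runs] - 1L], len = r$lengths[runs])
  })
  reads
}

#' Build the full-alignment feature tensor for one candidate
#'
#' A fixed `D x W x C` array: up to `D` read rows ordered by haplotype tag
#' (HP 1, then 2, then 0; within a group by `ref_start` then `read_id`), `W`
#' positions centered on the candidate, and C = 14 channels (read-base
#' one-hot, base quality, mapping quality, strand, haplotype encoding
#' +1/-1/0, inserted length after the position, deletion flag, reference
#' one-hot). When more than `D` reads cover the site a deterministic
#' evenly-spaced-by-rank subsample is taken within each haplotype group,
#' preserving group proportions (largest-remainder allocation, ties in group
#' order 1, 2, 0). If no read covers the candidate the tensor is all-zero and
#' flagged.
#'
#' @param candidate One candidate row (needs `pos`).
#' @param tagged_reads `vc_reads` with `hp_tag` set by [haplotag_chunk()].
#' @param ref_seq Reference sequence of the window backing `ref_offset`.
#' @param ref_offset 0-based position of `ref_seq[1]`.
#' @param D,W Row and width caps (defaults 89 and 33).
#' @return `vc_fa_feature`: list with `tensor` (D x W x 14), `pos`,
#'   `n_reads`, `empty` flag.
#' @export
build_full_alignment_feature <- function(candidate, tagged_reads, ref_seq,
                                         ref_offset, D = 89, W = 33) {
  pos <- if (is.numeric(candidate)) candidate else candidate$pos
  half <- (W - 1L) / 2L
  win <- (pos - half):(pos + half)
  reads <- tagged_reads
  ends <- map_dbl(reads$a_rpos, function(r) max(r, na.rm = TRUE) + 1)
  cov <- which(reads$ref_start <= pos & ends > pos)
  tensor <- array(0, dim = c(D, W, length(FA_CHANNELS)),
                  dimnames = list(NULL, NULL, FA_CHANNELS))
  # reference one-hot is shared across rows
  ref_chars <- substring(ref_seq, win - ref_offset + 1L, win - ref_offset + 1L)
  ref_idx <- match(ref_chars, BASES)
  for (w in which(!is.na(ref_idx))) {
    tensor[, w, 10L + ref_idx[w]] <- 1
  }
  if (length(cov) == 0) {
    return(structure(list(tensor = tensor, pos = pos, n_reads = 0L, empty = TRUE),
                     class = "vc_fa_feature"))
  }
  reads <- reads[cov, ]
  grp <- match(reads$hp_tag, c(1L, 2L, 0L))
  reads <- reads[order(grp, reads$ref_start, reads$read_id), ]
  n <- nrow(reads)
  if (n > D) {
    grp <- match(reads$hp_tag, c(1L, 2L, 0L))
    sizes <- vapply(1:3, function(g) sum(grp == g), integer(1))
    exact <- sizes * D / n
    base <- floor(exact)
    rem <- D - sum(base)
    frac_order <- order(-(exact - base), 1:3)
    add <- integer(3)
    if (rem > 0) add[frac_order[seq_len(rem)]] <- 1L
    take <- base + add
    sel <- unlist(lapply(1:3, function(g) {
      ix <- which(grp == g)
      if (take[g] == 0) return(integer(0))
      ix[ceiling(seq_len(take[g]) * length(ix) / take[g])]
    }))
    reads <- reads[sel, ]
    n <- nrow(reads)
  }
  hp_enc <- c(`1` = 1, `2` = -1, `0` = 0)
  for (r in seq_len(n)) {
    rp <- reads$a_rpos[[r]]
    qp <- reads$a_qpos[[r]]
    idx <- match(win, rp)
    covered <- !is.na(idx)
    if (!any(covered)) next
    q <- qp[idx]
    wcov <- which(covered)
    hasb <- wcov[!is.na(q[wcov])]
    isdel <- wcov[is.na(q[wcov])]
    if (length(hasb)) {
      bidx <- base_codes(substring(reads$seq[r], q[hasb] + 1L, q[hasb] + 1L))
      okb <- !is.na(bidx)
      tensor[cbind(r, hasb[okb], bidx[okb])] <- 1
      tensor[r, hasb, 5] <- reads$qual[[r]][q[hasb] + 1L] / 60
    }
    if (length(isdel)) tensor[r, isdel, 10] <- 1
    tensor[r, wcov, 6] <- reads$mapq[r] / 60
    tensor[r, wcov, 7] <- if (reads$strand[r] == "-") 1 else 0
    tensor[r, wcov, 8] <- hp_enc[[as.character(reads$hp_tag[r])]]
    runs <- if (!is.null(reads$ins_runs)) {
      reads$ins_runs[[r]]
    } else {
      precompute_ins_runs(reads[r, ])$ins_runs[[1]]
    }
    if (!is.null(runs)) {
      im <- match(win, runs$anchor)
      iw <- which(!is.na(im))
      if (length(iw)) tensor[r, iw, 9] <- runs$len[im[iw]] / 10
    }
  }
  structure(list(tensor = tensor, pos = pos, n_reads = n, empty = FALSE),
            class = "vc_fa_feature")
}

# Reduce a D x W x C tensor to the moderate feature vector the builtin heads
# consume: per haplotype group (1, 2, 0, all) center-column composition,
# reference-relative fractions and fold-symmetric terms (minor-allele
# fraction, alt_frac*(1-alt_frac)) that keep heterozygous-vs-homozygous
# decisions linearly accessible; cross-group contrasts; and window-wide
# deletion/insertion profiles.
reduce_fa_tensor <- function(feature) {
  tensor <- if (is.list(feature)) feature$tensor else feature
  D <- dim(tensor)[1]
  W <- dim(tensor)[2]
  cc <- (W + 1L) / 2L
  cover <- tensor[, , 1] + tensor[, , 2] + tensor[, , 3] + tensor[, , 4] +
    tensor[, , 10] > 0
  row_used <- rowSums(cover) > 0
  hp_row <- sign(rowSums(tensor[, , 8, drop = FALSE][, , 1]))
  group_of <- ifelse(hp_row > 0, 1L, ifelse(hp_row < 0, 2L, 3L))
  ref_center <- which(tensor[1, cc, 11:14] == 1)
  stats_for <- function(rows) {
    rows <- rows[cover[rows, cc]]
    if (length(rows) == 0) return(numeric(16))
    base_frac <- c(
      mean(tensor[rows, cc, 1]), mean(tensor[rows, cc, 2]),
      mean(tensor[rows, cc, 3]), mean(tensor[rows, cc, 4])
    )
    ref_frac <- if (length(ref_center)) base_frac[ref_center] else 0
    alt_frac <- if (length(ref_center)) max(base_frac[-ref_center]) else max(base_frac)
    del_frac <- mean(tensor[rows, cc, 10])
    ins_mean <- mean(tensor[rows, cc, 9])
    ins_frac <- mean(tensor[rows, cc, 9] > 0)
    c(
      length(rows) / D,
      base_frac,
      del_frac, ins_mean, ins_frac,
      mean(tensor[rows, cc, 5]),
      ref_frac, alt_frac,
      min(ref_frac, alt_frac), alt_frac * (1 - alt_frac),
      min(del_frac, 1 - del_frac), min(ins_frac, 1 - ins_frac),
      max(tensor[rows, cc, 9])
    )
  }
  used <- which(row_used)
  g1 <- stats_for(used[group_of[used] == 1L])
  g2 <- stats_for(used[group_of[used] == 2L])
  g0 <- stats_for(used[group_of[used] == 3L])
  ga <- stats_for(used)
  # cross-haplotype contrasts: a het site splits cleanly by haplotype group
  contrasts <- c(
    abs(g1[11] - g2[11]),           # alt fraction
    abs(g1[6] - g2[6]),             # deletion fraction
    abs(g1[7] - g2[7]),             # inserted length
    abs(g1[10] - g2[10]),           # ref fraction
    min(g1[1], g2[1])               # weaker haplotype group size
  )
  covn <- pmax(colSums(cover), 1)
  del_profile <- colSums(tensor[, , 10, drop = FALSE][, , 1]) / covn
  ins_profile <- colSums(tensor[, , 9, drop = FALSE][, , 1]) / covn
  c(g1, g2, g0, ga, contrasts, del_profile, ins_profile, tensor[1, cc, 11:14])
}

#' Classify full-alignment feature tensors
#'
#' Applies the three task heads (21-genotype, zygosity, indel length) to a
#' batch of tensors; order-preserving across internal batching, all heads
#' emitted per candidate; distributions padded with zeros to the fixed class
#' vocabularies.
#'
#' @param features List of `vc_fa_feature` tensors (or a pre-reduced matrix).
#' @param model_backend Trained full-alignment backend.
#' @return `vc_fa_predictions` tibble with list-columns `p_gt21`,
#'   `p_zygosity`, `p_indel_len` (named probability vectors).
#' @export
classify_full_alignment <- function(features, model_backend) {
  if (is.null(model_backend$heads) ||
      !all(c("gt21", "zygosity", "indel_len") %in% names(model_backend$heads))) {
    abort("full-alignment backend is missing a task head",
          class = "haplocall_backend_error")
  }
  x <- if (is.matrix(features)) {
    features
  } else {
    do.call(rbind, lapply(features, reduce_fa_tensor))
  }
  if (is.null(x)) x <- matrix(numeric(0), nrow = 0, ncol = 0)
  pr <- batched_predict(model_backend, x)
  if (nrow(x) > 0 && all(colnames(pr$gt21) %in% GT21_REL_CLASSES)) {
    pr$gt21 <- expand_rel_gt21(pr$gt21, x)
  }
  expand <- function(m, vocab) {
    lapply(seq_len(nrow(m)), function(i) {
      v <- setNames(numeric(length(vocab)), vocab)
      v[colnames(m)] <- m[i, ]
      v
    })
  }
  n <- nrow(x)
  out <- tibble(
    p_gt21 = if (n) expand(pr$gt21, GT21_CLASSES) else list(),
    p_zygosity = if (n) expand(pr$zygosity, ZYGOSITY_CLASSES) else list(),
    p_indel_len = if (n) expand(pr$indel_len, INDEL_LEN_CLASSES) else list()
  )
  class(out) <- c("vc_fa_predictions", class(out))
  out
}

empty_calls <- function() {
  tibble(
    contig = character(0), pos = numeric(0), ref = character(0),
    alt = character(0), gt = character(0), qual = numeric(0),
    gq = integer(0), dp = integer(0), af = numeric(0), ps = numeric(0),
    source = character(0), is_variant = logical(0)
  )
}

one_call <- function(contig, pos, ref, alt, gt, qual, dp = NA_integer_,
                     af = NA_real_, source = "pileup", is_variant = TRUE) {
  tibble(
    contig = contig, pos = pos, ref = ref, alt = alt, gt = gt,
    qual = qual, gq = as.integer(round(qual)), dp = as.integer(dp), af = af,
    ps = NA_real_, source = source, is_variant = is_variant
  )
}

# Reconstruct concrete alleles for a candidate given the chosen allele-class
# pair. Returns a one-row call tibble, or NULL when the alleles cannot be
# reconstructed (e.g. an insertion class with no observed inserted sequence).
finalize_call <- function(candidate, class_pair, qual, ref_seq, ref_offset,
                          source, p_indel_len = NULL) {
  ctg <- candidate$contig
  pos <- candidate$pos
  refb <- candidate$ref_base
  dp <- candidate$depth
  c1 <- class_pair[1]
  c2 <- class_pair[2]
  af_of <- function(cls) {
    a <- candidate$alts[[1]]
    i <- match(cls, a$class)
    if (is.na(i)) NA_real_ else a$af[i]
  }
  if (c1 == refb && c2 == refb) {
    return(one_call(ctg, pos, refb, ".", "0/0", qual, dp, 0, source, FALSE))
  }
  # deletion classes move the anchor; resolve them first
  if ("D" %in% class_pair) {
    dob <- candidate$del_obs[[1]]
    if (is.null(dob) || nrow(dob) == 0) return(NULL)
    run <- pick_del_run(dob, p_indel_len)
    anchor <- run$start - 1L
    if (anchor < ref_offset) return(NULL)
    ref_al <- substring(ref_seq, anchor - ref_offset + 1L,
                        anchor - ref_offset + run$len + 1L)
    if (nchar(ref_al) < run$len + 1L) return(NULL)
    alt_al <- substring(ref_al, 1L, 1L)
    gt <- if (c1 == "D" && c2 == "D") "1/1" else "0/1"
    return(one_call(ctg, anchor, ref_al, alt_al, gt, qual, dp, af_of("D"), source))
  }
  if ("I" %in% class_pair) {
    iob <- candidate$ins_obs[[1]]
    if (is.null(iob) || nrow(iob) == 0) return(NULL)
    ins <- pick_ins_seq(iob, p_indel_len)
    alt_al <- paste0(refb, ins)
    gt <- if (c1 == "I" && c2 == "I") "1/1" else "0/1"
    return(one_call(ctg, pos, refb, alt_al, gt, qual, dp, af_of("I"), source))
  }
  # SNV-only pairs
  if (c1 == c2) {
    return(one_call(ctg, pos, refb, c1, "1/1", qual, dp, af_of(c1), source))
  }
  if (c1 == refb || c2 == refb) {
    alt <- if (c1 == refb) c2 else c1
    return(one_call(ctg, pos, refb, alt, "0/1", qual, dp, af_of(alt), source))
  }
  # multiallelic het: two non-reference bases
  one_call(ctg, pos, refb, paste(c1, c2, sep = ","), "1/2", qual, dp,
           af_of(c1), source)
}

# The observed read majority decides the concrete indel allele; the
# indel-length head only breaks ties among equally supported observations.
pick_ins_seq <- function(iob, p_indel_len) {
  top <- iob[iob$n == max(iob$n), ]
  if (nrow(top) > 1 && !is.null(p_indel_len)) {
    pp <- p_indel_len[c(paste0("+", 1:15), ">15")]
    if (sum(pp) > 0) {
      lab <- names(pp)[which.max(pp)]
      want <- if (lab == ">15") 16L else as.integer(sub("\\+", "", lab))
      hit <- top[nchar(top$seq) == want, ]
      if (nrow(hit) > 0) return(hit$seq[1])
    }
  }
  top$seq[1]
}

pick_del_run <- function(dob, p_indel_len) {
  top <- dob[dob$n == max(dob$n), ]
  if (nrow(top) > 1 && !is.null(p_indel_len)) {
    pp <- p_indel_len[c(paste0("-", 1:15), "<-15")]
    if (sum(pp) > 0) {
      lab <- names(pp)[which.max(pp)]
      want <- if (lab == "<-15") 16L else -as.integer(lab)
      hit <- top[top$len == want, ]
      if (nrow(hit) > 0) return(list(start = hit$start[1], len = hit$len[1]))
    }
  }
  list(start = top$start[1], len = top$len[1])
}

#' Joint multi-task genotype decision
#'
#' Combines the three task heads into one call: the genotype is the argmax of
#' `p_gt21 * p_zygosity[zygosity(class)]` over the 21 classes *compatible*
#' with the candidate's observed alleles (reference pair always included),
#' with deterministic lexicographic tie-breaking; the indel-length head
#' resolves insertion/deletion allele lengths; quality is
#' `-10*log10(1 - p_gt21[selected])` capped at 60. A selected reference pair
#' yields a non-variant call.
#'
#' @param pred One row of [classify_full_alignment()] output (list with
#'   `p_gt21`, `p_zygosity`, `p_indel_len`).
#' @param candidate The candidate row (with `alts`, `ins_obs`, `del_obs`).
#' @param ref_seq,ref_offset Backing reference window.
#' @return One-row call tibble (source `"full_alignment"`), or NULL when
#'   allele reconstruction is impossible.
#' @export
joint_decision <- function(pred, candidate, ref_seq, ref_offset) {
  p_gt <- pred$p_gt21
  if (is.list(p_gt) && !is.numeric(p_gt)) p_gt <- p_gt[[1]]
  p_zyg <- pred$p_zygosity
  if (is.list(p_zyg) && !is.numeric(p_zyg)) p_zyg <- p_zyg[[1]]
  p_len <- pred$p_indel_len
  if (is.list(p_len) && !is.numeric(p_len)) p_len <- p_len[[1]]

  refb <- candidate$ref_base
  allowed_classes <- unique(c(refb, candidate$alts[[1]]$class))
  compat <- vapply(GT21_CLASSES, function(cl) {
    a <- substring(cl, 1, 1)
    b <- substring(cl, 2, 2)
    a %in% allowed_classes && b %in% allowed_classes
  }, logical(1))
  zyg_of <- ifelse(substring(GT21_CLASSES, 1, 1) == substring(GT21_CLASSES, 2, 2),
                   "hom", "het")
  score <- p_gt[GT21_CLASSES] * p_zyg[zyg_of]
  score[!compat] <- -Inf
  best <- GT21_CLASSES[which.max(score)]  # which.max: first (lexicographic) tie-break
  qual <- phred_from_prob(1 - p_gt[[best]])
  pair <- c(substring(best, 1, 1), substring(best, 2, 2))
  finalize_call(candidate, pair, qual, ref_seq, ref_offset,
                source = "full_alignment", p_indel_len = p_len)
}
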