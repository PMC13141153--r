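#' Candidate-selection configuration
#'
#' Thresholds for nominating variant candidates from pileup columns. The
#' defaults implement a permissive, recall-oriented first pass: a site becomes
#' a candidate when read depth reaches `min_coverage` and some non-reference
#' observation class reaches the class-appropriate allelic-fraction floor.
#'
#' @param min_coverage Minimum depth (default 4).
#' @param min_af Minimum allelic fraction for SNV alleles (default 0.08).
#' @param indel_min_af Minimum allelic fraction for insertion/deletion
#'   observations (default 0.12).
#' @param max_candidates_per_chunk Cap on candidates per chunk; the
#'   highest-supported candidates are kept (default Inf).
#' @return List of class `vc_candidate_config`.
#' @export
candidate_config <- function(min_coverage = 4, min_af = 0.08,
                             indel_min_af = 0.12,
                             max_candidates_per_chunk = Inf) {
  if (min_af < 0 || min_af > 1 || indel_min_af < 0 || indel_min_af > 1) {
    stop_invalid("allelic-fraction thresholds must lie in [0, 1]")
  }
  if (min_coverage < 1) stop_invalid("min_coverage must be >= 1")
  structure(
    list(
      min_coverage = min_coverage, min_af = min_af,
      indel_min_af = indel_min_af,
      max_candidates_per_chunk = max_candidates_per_chunk
    ),
    class = "vc_candidate_config"
  )
}

PILEUP_COLS <- c(
  "a_fwd", "a_rev", "c_fwd", "c_rev", "g_fwd", "g_rev", "t_fwd", "t_rev",
  "i_fwd", "i_rev", "d_fwd", "d_rev"
)

# Strand-split observation counts over a half-open window. Insertions are
# counted once per insertion run at the anchor position (last aligned base
# before the run); deletions at every deleted reference position.
pileup_count_matrix <- function(reads, wstart, wend) {
  npos <- as.integer(wend - wstart)
  acc_pos <- vector("list", nrow(reads))
  acc_key <- vector("list", nrow(reads))
  for (j in seq_len(nrow(reads))) {
    rp <- reads$a_rpos[[j]]
    qp <- reads$a_qpos[[j]]
    sbit <- if (reads$strand[j] == "-") 1L else 0L
    sc <- strsplit(reads$seq[j], "", fixed = TRUE)[[1]]
    aligned <- !is.na(rp)
    pos <- rp[aligned]
    q <- qp[aligned]
    cls <- ifelse(is.na(q), 6L, base_codes(sc[q + 1L]))
    # insertion anchors
    ins_start <- which(!aligned & !c(FALSE, !aligned[-length(aligned)]))
    ins_start <- ins_start[ins_start > 1L]
    if (length(ins_start)) {
      apos <- rp[ins_start - 1L]
      ok <- !is.na(apos)
      pos <- c(pos, apos[ok])
      cls <- c(cls, rep(5L, sum(ok)))
    }
    inw <- !is.na(cls) & pos >= wstart & pos < wend
    acc_pos[[j]] <- pos[inw]
    acc_key[[j]] <- (cls[inw] - 1L) * 2L + sbit
  }
  pos <- unlist(acc_pos)
  key <- unlist(acc_key)
  if (length(pos) == 0) {
    return(matrix(0L, nrow = npos, ncol = 12L, dimnames = list(NULL, PILEUP_COLS)))
  }
  tab <- tabulate((pos - wstart) * 12L + key + 1L, nbins = npos * 12L)
  matrix(tab, nrow = npos, ncol = 12L, byrow = TRUE,
         dimnames = list(NULL, PILEUP_COLS))
}

#' Build pileup columns for a chunk
#'
#' One row per position with depth >= 1. Depth counts reads aligned (base or
#' deletion) at the position; insertion observations do not add depth.
#'
#' @param reads `vc_reads` fetched for the chunk.
#' @param chunk Chunk row.
#' @param ref_seq Reference sequence of the chunk's fetch window
#'   (`[fetch_start, fetch_end)`), uppercase.
#' @param span `"core"` (default; candidate coordinates are confined to the
#'   core) or `"fetch"` (needed when the columns will also back feature
#'   windows at core boundaries).
#' @return A `vc_pileup` tibble: `contig`, `ref_pos`, `ref_base`, `depth`,
#'   and 12 strand-split class counts. The covered window is kept in
#'   `attr(, "window")`.
#' @export
build_pileup <- function(reads, chunk, ref_seq, span = c("core", "fetch")) {
  span <- match.arg(span)
  wstart <- if (span == "core") chunk$core_start else chunk$fetch_start
  wend <- if (span == "core") chunk$core_end else chunk$fetch_end
  m <- pileup_count_matrix(reads, wstart, wend)
  depth <- as.integer(rowSums(m[, c(1:8, 11:12), drop = FALSE]))
  keep <- which(depth >= 1L)
  offs <- wstart - chunk$fetch_start  # ref_seq starts at fetch_start
  ref_base <- if (length(keep)) substring(ref_seq, offs + keep, offs + keep) else character(0)
  out <- tibble(
    contig = chunk$contig,
    ref_pos = wstart + keep - 1,
    ref_base = ref_base,
    depth = depth[keep]
  )
  out <- dplyr::bind_cols(out, as_tibble(m[keep, , drop = FALSE]))
  attr(out, "window") <- c(wstart, wend)
  class(out) <- c("vc_pileup", class(out))
  out
}

#' Select variant candidates from pileup columns
#'
#' A column yields a candidate iff `depth >= min_coverage` and some
#' non-reference class reaches its allelic-fraction floor. Alt classes are
#' ordered by descending support count, ties broken lexicographically.
#' Columns with an `N` reference base never seed candidates.
#'
#' @param columns A `vc_pileup` tibble (restricted to one chunk core).
#' @param config A [candidate_config()].
#' @return A `vc_candidates` tibble: `contig`, `pos`, `ref_base`, `depth`,
#'   and `alts` (list of tibbles `class`, `count`, `af`).
#' @export
select_candidates <- function(columns, config = candidate_config()) {
  cnt <- cbind(
    A = columns$a_fwd + columns$a_rev,
    C = columns$c_fwd + columns$c_rev,
    G = columns$g_fwd + columns$g_rev,
    T = columns$t_fwd + columns$t_rev,
    I = columns$i_fwd + columns$i_rev,
    D = columns$d_fwd + columns$d_rev
  )
  depth <- columns$depth
  af <- cnt / pmax(depth, 1L)
  ref_idx <- match(columns$ref_base, BASES)  # NA for N
  base_ok <- af[, 1:4, drop = FALSE] >= config$min_af & cnt[, 1:4, drop = FALSE] > 0L
  if (nrow(columns)) {
    base_ok[cbind(seq_len(nrow(columns)), ref_idx)[!is.na(ref_idx), , drop = FALSE]] <- FALSE
  }
  indel_ok <- af[, 5:6, drop = FALSE] >= config$indel_min_af & cnt[, 5:6, drop = FALSE] > 0L
  any_alt <- rowSums(base_ok) + rowSums(indel_ok) > 0
  sel <- which(depth >= config$min_coverage & any_alt & !is.na(ref_idx))
  alts <- map(sel, function(i) {
    ok <- c(base_ok[i, ], indel_ok[i, ])
    cls <- CLASS_LABELS[ok]
    cc <- cnt[i, ok]
    ord <- order(-cc, cls)
    tibble(class = cls[ord], count = as.integer(cc[ord]), af = cc[ord] / depth[i])
  })
  out <- tibble(
    contig = columns$contig[sel],
    pos = columns$ref_pos[sel],
    ref_base = columns$ref_base[sel],
    depth = depth[sel],
    alts = alts
  )
  if (nrow(out) > config$max_candidates_per_chunk) {
    support <- map_int(out$alts, function(a) a$count[1])
    keep <- order(-support, out$pos)[seq_len(config$max_candidates_per_chunk)]
    out <- out[sort(keep), ]
  }
  class(out) <- c("vc_candidates", class(out))
  out
}

# Gather observed insertion sequences and deletion runs from reads at
# candidate positions; attaches `ins_obs` / `del_obs` list-columns.
attach_indel_observations <- function(candidates, reads) {
  need_ins <- map_chr(candidates$alts, function(a) paste(a$class, collapse = "")) |>
    grepl(pattern = "I")
  need_del <- map_chr(candidates$alts, function(a) paste(a$class, collapse = "")) |>
    grepl(pattern = "D")
  ins_all <- list()
  del_all <- list()
  if (any(need_ins) || any(need_del)) {
    for (j in seq_len(nrow(reads))) {
      rp <- reads$a_rpos[[j]]
      qp <- reads$a_qpos[[j]]
      na_r <- is.na(rp)
      if (any(na_r)) {
        r <- rle(na_r)
        endi <- cumsum(r$lengths)
        starti <- endi - r$lengths + 1L
        runs <- which(r$values & starti > 1L)
        if (length(runs)) {
          anch <- rp[starti[runs] - 1L]
          seqs <- substring(reads$seq[j], qp[starti[runs]] + 1L, qp[endi[runs]] + 1L)
          ins_all[[length(ins_all) + 1L]] <- tibble(pos = anch, seq = seqs)
        }
      }
      na_q <- is.na(qp)
      if (any(na_q)) {
        r <- rle(na_q)
        endi <- cumsum(r$lengths)
        starti <- endi - r$lengths + 1L
        runs <- which(r$values)
        if (length(runs)) {
          del_all[[length(del_all) + 1L]] <- tibble(
            start = rp[starti[runs]], len = r$lengths[runs]
          )
        }
      }
    }
  }
  ins_tab <- if (length(ins_all)) {
    bind_rows(ins_all) |> dplyr::count(.data$pos, .data$seq, name = "n")
  } else tibble(pos = integer(0), seq = character(0), n = integer(0))
  del_tab <- if (length(del_all)) {
    bind_rows(del_all) |> dplyr::count(.data$start, .data$len, name = "n")
  } else tibble(start = integer(0), len = integer(0), n = integer(0))

  candidates$ins_obs <- map(seq_len(nrow(candidates)), function(i) {
    if (!need_ins[i]) return(tibble(seq = character(0), n = integer(0)))
    s <- ins_tab[ins_tab$pos == candidates$pos[i], c("seq", "n")]
    s[order(-s$n, s$seq), ]
  })
  candidates$del_obs <- map(seq_len(nrow(candidates)), function(i) {
    if (!need_del[i]) return(tibble(start = integer(0), len = integer(0), n = integer(0)))
    p <- candidates$pos[i]
    s <- del_tab[del_tab$start <= p & p < del_tab$start + del_tab$len, ]
    s[order(-s$n, s$start, s$len), ]
  })
  candidates
}

# Channels per window position backing the pileup features: the 12
# strand-split class counts, a reference one-hot, and a reference-relative
# block (ref/alt counts and fractions) that makes allelic fraction directly
# visible to shallow classifier heads regardless of base identity.
PILEUP_C <- 24L

# Dense (window-position x channel) array from pileup columns. Zero rows
# stand in for positions with no coverage and positions beyond contig ends.
pileup_dense <- function(columns) {
  win <- attr(columns, "window")
  npos <- as.integer(win[2] - win[1])
  m <- matrix(0, nrow = npos, ncol = PILEUP_C)
  if (nrow(columns) == 0) return(m)
  ridx <- as.integer(columns$ref_pos - win[1]) + 1L
  m[ridx, 1:12] <- as.matrix(columns[, PILEUP_COLS])
  ref_idx <- match(columns$ref_base, BASES)
  ok <- !is.na(ref_idx)
  m[cbind(ridx[ok], 12L + ref_idx[ok])] <- 1
  base_cnt <- cbind(
    columns$a_fwd + columns$a_rev, columns$c_fwd + columns$c_rev,
    columns$g_fwd + columns$g_rev, columns$t_fwd + columns$t_rev
  )
  refc <- numeric(nrow(columns))
  refc[ok] <- base_cnt[cbind(which(ok), ref_idx[ok])]
  altc <- base_cnt
  altc[cbind(seq_len(nrow(columns)), ref_idx)[ok, , drop = FALSE]] <- -1L
  alt_sorted <- t(apply(altc, 1, sort, decreasing = TRUE))
  alt_sorted[alt_sorted < 0] <- 0
  ins <- columns$i_fwd + columns$i_rev
  del <- columns$d_fwd + columns$d_rev
  depth <- pmax(columns$depth, 1L)
  m[ridx, 17:24] <- cbind(
    refc, alt_sorted[, 1], alt_sorted[, 2],
    refc / depth, alt_sorted[, 1] / depth, ins / depth, del / depth,
    columns$depth
  )
  m
}

#' Build the pileup feature window for one candidate
#'
#' A fixed `W x 24` matrix centered on the candidate (12 strand-split
#' observation-count channels, a reference one-hot, and a reference-relative
#' block of ref/alt counts and fractions), zero-padded where the window
#' leaves the covered interval, plus the candidate depth.
#'
#' @param columns `vc_pileup` columns covering the chunk's fetch window.
#' @param candidate One candidate row (or a position).
#' @param W Window width in positions (odd; default 33).
#' @return `vc_pileup_feature`: list with `matrix` (W x 24), `depth`, `pos`.
#' @export
build_pileup_features <- function(columns, candidate, W = 33) {
  pos <- if (is.numeric(candidate)) candidate else candidate$pos
  depth <- if (is.numeric(candidate)) NA_integer_ else candidate$depth
  dense <- pileup_dense(columns)
  win <- attr(columns, "window")
  structure(
    list(
      matrix = feature_slice(dense, win[1], pos, W),
      depth = depth, pos = pos
    ),
    class = "vc_pileup_feature"
  )
}

feature_slice <- function(dense, wstart, pos, W) {
  half <- (W - 1L) / 2L
  rows <- (pos - half - wstart + 1):(pos + half - wstart + 1)
  out <- matrix(0, nrow = W, ncol = ncol(dense))
  ok <- rows >= 1 & rows <= nrow(dense)
  out[ok, ] <- dense[rows[ok], , drop = FALSE]
  out
}

# Flattened feature rows (W*16 + 1 columns) for a set of candidates.
pileup_feature_batch <- function(columns, positions, depths, W = 33) {
  dense <- pileup_dense(columns)
  win <- attr(columns, "window")
  n <- length(positions)
  out <- matrix(0, nrow = n, ncol = W * PILEUP_C + 1L)
  for (i in seq_len(n)) {
    out[i, ] <- c(as.numeric(feature_slice(dense, win[1], positions[i], W)),
                  depths[i])
  }
  out
}

# Compact view of flattened pileup feature rows (W x PILEUP_C + depth) for
# the shallow builtin heads: the full center column, the reference-relative
# block of the two neighbor columns on each side, and window-level summaries
# of the alt/ins/del fraction profiles.
reduce_pileup_rows <- function(x) {
  W <- (ncol(x) - 1L) / PILEUP_C
  idx <- function(w, ch) (ch - 1L) * W + w
  ccc <- (W + 1L) / 2L
  center <- x[, idx(ccc, 1:PILEUP_C), drop = FALSE]
  nb <- x[, as.vector(outer((ccc - 2L):(ccc + 2L), 17:24, idx)), drop = FALSE]
  prof <- function(ch) {
    cols <- x[, idx(seq_len(W), ch), drop = FALSE]
    cbind(rowMeans(cols), apply(cols, 1, max))
  }
  cbind(center, nb, prof(21L), prof(22L), prof(23L), x[, ncol(x)])
}

#' Classify pileup feature batches
#'
#' Order-preserving: row i of the output corresponds to row i of `features`
#' regardless of internal batching. Probabilities are normalized per row.
#'
#' @param features Numeric matrix, one flattened pileup feature per row
#'   (see [build_pileup_features()]), or a list of `vc_pileup_feature`s.
#' @param model_backend A trained pileup backend from
#'   [train_fixture_models()].
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   genotype class (`ref`, `het`, `hom`, `multihet`).
#' @export
classify_pileup <- function(features, model_backend) {
  if (is.list(features) && !is.matrix(features)) {
    features <- do.call(rbind, lapply(features, function(f) {
      c(as.numeric(f$matrix), f$depth)
    }))
  }
  if (is.null(model_backend) || is.null(model_backend$head)) {
    abort("pileup backend not initialized; train or load one first",
          class = "haplocall_backend_error")
  }
  batched_predict(model_backend, features)
}

PILEUP_CLASSES <- c("ref", "het", "hom", "multihet")

#' Turn classified candidates into pileup calls
#'
#' Genotype class is the argmax of the classifier probabilities; genotype
#' quality is `-10*log10(1 - p_max)` capped at 60.
#'
#' @param candidates `vc_candidates` (with indel observations attached).
#' @param probs Probability matrix from [classify_pileup()].
#' @return `vc_pileup_calls` tibble adding `probs`, `genotype_class`, `qual`,
#'   `is_variant`.
#' @export
pileup_calls <- function(candidates, probs) {
  stopifnot(nrow(candidates) == nrow(probs))
  cls <- colnames(probs)[max.col(probs, ties.method = "first")]
  pmax_ <- apply(probs, 1, max)
  if (nrow(candidates) == 0) {
    cls <- character(0); pmax_ <- numeric(0)
  }
  out <- candidates
  out$probs <- lapply(seq_len(nrow(probs)), function(i) probs[i, ])
  out$genotype_class <- cls
  out$qual <- phred_from_prob(1 - pmax_)
  out$is_variant <- cls != "ref"
  class(out) <- unique(c("vc_pileup_calls", class(out)))
  out
}

#' Split pileup calls into confidence tiers
#'
#' Routing contract of the two-pass design: the lowest-quality fraction `q`
#' of *variant* calls is marked low-confidence and sent to the full-alignment
#' pass (default 0.7), together with the lowest-quality fraction `r` of
#' *reference* calls (candidates the pileup stage genotyped hom-ref; default
#' 0.1). With `strategy = "threshold"` a fixed quality cutoff is used
#' instead. Counts use floor rounding: exactly `floor(q * n_variant)` variant
#' calls are routed low-confidence.
#'
#' @param calls `vc_pileup_calls`.
#' @param strategy `"quantile"` (default) or `"threshold"`.
#' @param q Low-confidence fraction of variant calls (default 0.7).
#' @param r Routed fraction of reference calls (default 0.1).
#' @param qual_cutoff Quality cutoff for `strategy = "threshold"`.
#' @return List with `high_confidence`, `low_confidence`, `ref_routed`.
#' @export
tier_split <- function(calls, strategy = c("quantile", "threshold"),
                       q = 0.7, r = 0.1, qual_cutoff = 15) {
  strategy <- match.arg(strategy)
  if (q < 0 || q > 1 || r < 0 || r > 1) {
    abort("tier fractions q and r must lie in [0, 1]",
          class = "haplocall_invalid_config")
  }
  var <- calls[calls$is_variant, ]
  refc <- calls[!calls$is_variant, ]
  if (strategy == "quantile") {
    ordv <- order(var$qual, var$contig, var$pos)
    n_low <- floor(q * nrow(var))
    low_idx <- ordv[seq_len(n_low)]
    ordr <- order(refc$qual, refc$contig, refc$pos)
    n_ref <- floor(r * nrow(refc))
    ref_idx <- ordr[seq_len(n_ref)]
  } else {
    low_idx <- which(var$qual < qual_cutoff)
    ref_idx <- which(refc$qual < qual_cutoff)
  }
  list(
    high_confidence = var[setdiff(seq_len(nrow(var)), low_idx), ],
    low_confidence = var[sort(low_idx), ],
    ref_routed = refc[sort(ref_idx), ]
  )
}
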