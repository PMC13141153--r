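#' Select phasing input from pileup calls
#'
#' Keeps heterozygous, biallelic, single-nucleotide calls with genotype
#' quality at or above `min_phase_qual`; indels and homozygous calls are
#' excluded.
#'
#' @param pileup_calls `vc_pileup_calls` (variant calls from the first pass).
#' @param min_phase_qual Quality floor (default 15).
#' @return A `vc_het_snps` tibble: `contig`, `pos`, `ref`, `alt`, `qual`.
#' @export
select_phase_input <- function(pileup_calls, min_phase_qual = 15) {
  keep <- pileup_calls$genotype_class == "het" &
    pileup_calls$qual >= min_phase_qual &
    map_int(pileup_calls$alts, nrow) >= 1 &
    map_chr(pileup_calls$alts, function(a) a$class[1]) %in% BASES
  out <- pileup_calls[keep, ]
  res <- tibble(
    contig = out$contig,
    pos = out$pos,
    ref = out$ref_base,
    alt = map_chr(out$alts, function(a) a$class[1]),
    qual = out$qual
  )
  res <- res[order(res$contig, res$pos), ]
  class(res) <- c("vc_het_snps", class(res))
  res
}

# Per-read SNP fragments: for each read, the indices of covered het SNPs and
# the observed allele code (0 = ref, 1 = alt, NA = deletion/third allele).
read_fragments <- function(het_snps, reads, min_bq = 10) {
  frags <- vector("list", nrow(reads))
  for (j in seq_len(nrow(reads))) {
    rp <- reads$a_rpos[[j]]
    qp <- reads$a_qpos[[j]]
    idx <- match(het_snps$pos, rp)
    cov <- which(!is.na(idx))
    if (length(cov) < 1) next
    q <- qp[idx[cov]]
    base <- rep(NA_character_, length(cov))
    hasb <- !is.na(q)
    if (any(hasb)) {
      base[hasb] <- substring(reads$seq[j], q[hasb] + 1L, q[hasb] + 1L)
      bq <- reads$qual[[j]][q[hasb] + 1L]
      base[hasb][bq < min_bq] <- NA_character_
    }
    allele <- ifelse(base == het_snps$ref[cov], 0L,
                     ifelse(base == het_snps$alt[cov], 1L, NA_integer_))
    ok <- !is.na(allele)
    if (sum(ok) < 1) next
    frags[[j]] <- list(snp = cov[ok], allele = allele[ok])
  }
  frags[!vapply(frags, is.null, logical(1))]
}

#' Build the allele-pairing graph over heterozygous SNPs
#'
#' Nodes are het SNPs in coordinate order. For each read and each pair of
#' SNPs the read covers with a base matching ref or alt (bases matching
#' neither allele, or deleted, contribute nothing), the corresponding cell of
#' the pair's 2x2 pairing-count matrix is incremented. Adjacent-by-coverage
#' pairs drive the stage-1 greedy; longer-range pairs (up to `max_pair_bp`)
#' feed the stage-2 block join. The read fragments ride along for the
#' minimum-error-correction refinement.
#'
#' @param het_snps `vc_het_snps` of one contig.
#' @param reads `vc_reads` of the same contig.
#' @param max_pair_bp Distance cap for edges (default 2e5).
#' @param min_bq Base-quality floor for fragment bases (default 10).
#' @return `vc_allele_graph`: list with `snps`, `edges` (tibble `i`, `j`,
#'   `n00`, `n01`, `n10`, `n11`, `adjacent`), `fragments`.
#' @export
build_allele_graph <- function(het_snps, reads, max_pair_bp = 2e5, min_bq = 10) {
  stopifnot(length(unique(het_snps$contig)) <= 1)
  if (nrow(het_snps) > 0 && nrow(reads) > 0) {
    reads <- reads[reads$contig == het_snps$contig[1], ]
  }
  frags <- read_fragments(het_snps, reads, min_bq = min_bq)
  graph_from_fragments(het_snps, frags, max_pair_bp = max_pair_bp)
}

# Assemble the graph from precomputed fragments; lets callers collect
# fragments chunk by chunk without holding all reads in memory at once.
graph_from_fragments <- function(het_snps, frags, max_pair_bp = 2e5) {
  acc <- new.env(parent = emptyenv())
  bump <- function(i, j, a, b, adjacent) {
    key <- paste0(i, "_", j)
    e <- acc[[key]]
    if (is.null(e)) e <- c(0L, 0L, 0L, 0L, 0L)
    cell <- a * 2L + b + 1L
    e[cell] <- e[cell] + 1L
    if (adjacent) e[5L] <- 1L
    acc[[key]] <- e
  }
  for (f in frags) {
    k <- length(f$snp)
    if (k < 2) next
    for (u in 1:(k - 1)) {
      for (v in (u + 1):k) {
        i <- f$snp[u]; j <- f$snp[v]
        if (het_snps$pos[j] - het_snps$pos[i] > max_pair_bp) break
        bump(i, j, f$allele[u], f$allele[v], adjacent = (v == u + 1L))
      }
    }
  }
  keys <- ls(acc)
  edges <- if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    m <- do.call(rbind, mget(keys, envir = acc))
    rownames(m) <- NULL
    tibble(
      i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
      n00 = m[, 1], n01 = m[, 2], n10 = m[, 3], n11 = m[, 4],
      adjacent = m[, 5] > 0L
    ) |> arrange(.data$i, .data$j)
  } else {
    tibble(i = integer(0), j = integer(0), n00 = integer(0), n01 = integer(0),
           n10 = integer(0), n11 = integer(0), adjacent = logical(0))
  }
  structure(
    list(snps = het_snps, edges = edges, fragments = frags),
    class = "vc_allele_graph"
  )
}

empty_phase_blocks <- function() {
  structure(
    tibble(contig = character(0), pos = numeric(0), ref = character(0),
           alt = character(0), block_id = integer(0), orientation = character(0)),
    class = c("vc_phase_blocks", "tbl_df", "tbl", "data.frame")
  )
}

# weighted union-find with parity (relative orientation to root)
uf_find <- function(uf, x) {
  par <- 0L
  while (uf$parent[x] != x) {
    par <- bitwXor(par, uf$parity[x])
    x <- uf$parent[x]
  }
  list(root = x, parity = par)
}

#' Phase het SNPs with the two-stage greedy graph algorithm
#'
#' Stage 1 processes adjacent-by-coverage edges in descending evidence margin
#' `|cis - trans|` (ties: leftmost coordinate, then SNP index), accepting an
#' edge's implied relative orientation unless it contradicts orientations
#' already fixed in the component; contradictions leave the block split.
#' Stage 2 builds a block-level graph from the remaining longer-range read
#' evidence and re-applies the same greedy acceptance to join blocks. A final
#' refinement pass flips single SNPs and block suffixes while the read-level
#' minimum-error-correction cost decreases. The first SNP of every block is
#' normalized to cis orientation.
#'
#' @param graph `vc_allele_graph` from [build_allele_graph()].
#' @return `vc_phase_blocks` tibble: `contig`, `pos`, `ref`, `alt`,
#'   `block_id`, `orientation` ("cis": ref on HP1 / alt on HP2; "trans":
#'   the reverse).
#' @export
phase_two_stage <- function(graph) {
  snps <- graph$snps
  n <- nrow(snps)
  if (n == 0) {
    return(empty_phase_blocks())
  }
  edges <- graph$edges
  edges$cis <- edges$n00 + edges$n11
  edges$trans <- edges$n01 + edges$n10
  edges$margin <- abs(edges$cis - edges$trans)

  uf <- new.env(parent = emptyenv())
  uf$parent <- seq_len(n)
  uf$parity <- integer(n)

  accept <- function(e_i, e_j, rel) {
    fi <- uf_find(uf, e_i)
    fj <- uf_find(uf, e_j)
    if (fi$root == fj$root) {
      return(bitwXor(fi$parity, fj$parity) == rel)  # consistent?
    }
    # attach the later root under the earlier (deterministic)
    a <- fi; b <- fj
    if (a$root > b$root) { a <- fj; b <- fi; rel <- rel }
    uf$parent[b$root] <- a$root
    uf$parity[b$root] <- bitwXor(bitwXor(a$parity, b$parity), rel)
    TRUE
  }

  greedy_pass <- function(ed) {
    if (nrow(ed) == 0) return(invisible())
    ord <- order(-ed$margin, graph$snps$pos[ed$i], ed$i, ed$j)
    for (k in ord) {
      rel <- if (ed$trans[k] > ed$cis[k]) 1L else 0L
      accept(ed$i[k], ed$j[k], rel)
    }
  }

  # stage 1: local, adjacent-by-coverage evidence
  greedy_pass(edges[edges$adjacent, ])

  # stage 2: block graph from all (incl. long-range) evidence, same greedy
  if (nrow(edges)) {
    roots <- vapply(seq_len(n), function(x) uf_find(uf, x)$root, integer(1))
    if (length(unique(roots[unique(c(edges$i, edges$j))])) > 1) {
      par <- vapply(seq_len(n), function(x) uf_find(uf, x)$parity, integer(1))
      eb <- edges
      eb$bi <- roots[edges$i]
      eb$bj <- roots[edges$j]
      cross <- eb[eb$bi != eb$bj, ]
      if (nrow(cross)) {
        # translate SNP-level pairings into block-relative orientation votes
        flip <- bitwXor(par[cross$i], par[cross$j]) == 1L
        cis_b <- ifelse(flip, cross$trans, cross$cis)
        trans_b <- ifelse(flip, cross$cis, cross$trans)
        lo <- pmin(cross$bi, cross$bj)
        hi <- pmax(cross$bi, cross$bj)
        bg <- tibble(i = lo, j = hi, cis = cis_b, trans = trans_b) |>
          group_by(.data$i, .data$j) |>
          summarise(cis = sum(.data$cis), trans = sum(.data$trans), .groups = "drop")
        bg$margin <- abs(bg$cis - bg$trans)
        greedy_pass(bg)
      }
    }
  }

  roots <- vapply(seq_len(n), function(x) uf_find(uf, x)$root, integer(1))
  ori <- vapply(seq_len(n), function(x) uf_find(uf, x)$parity, integer(1))

  # MEC refinement: single-SNP flips and suffix flips within each block
  ori <- refine_mec(ori, roots, graph$fragments, snps$pos)

  # renumber blocks by first member coordinate; normalize first member to cis
  first_pos <- vapply(split(seq_len(n), roots), function(ix) min(snps$pos[ix]), numeric(1))
  block_order <- names(sort(first_pos))
  block_id <- match(as.character(roots), block_order)
  for (b in unique(block_id)) {
    ix <- which(block_id == b)
    lead <- ix[which.min(snps$pos[ix])]
    if (ori[lead] == 1L) ori[ix] <- 1L - ori[ix]
  }
  out <- tibble(
    contig = snps$contig, pos = snps$pos, ref = snps$ref, alt = snps$alt,
    block_id = block_id,
    orientation = ifelse(ori == 0L, "cis", "trans")
  ) |> arrange(.data$block_id, .data$pos)
  class(out) <- c("vc_phase_blocks", class(out))
  out
}

# Read-level minimum-error-correction cost of an orientation assignment.
# ori[s] = 0 means ref on HP1 at SNP s. A read costs the smaller number of
# allele flips needed to match either haplotype.
mec_cost <- function(ori, fragments) {
  total <- 0L
  for (f in fragments) {
    hp1 <- ori[f$snp]            # allele carried by HP1 at each covered SNP
    mis1 <- sum(f$allele != hp1)
    total <- total + min(mis1, length(f$snp) - mis1)
  }
  total
}

# Local search over orientations, maintaining per-fragment mismatch state so
# each candidate move costs O(fragments touching the flipped SNP). Moves:
# single-SNP flips and block-suffix flips (switch-error repair), iterated to
# a fixpoint. Flipping a whole block is a label swap and cost-neutral, so
# suffixes never start at the first member.
refine_mec <- function(ori, roots, fragments, pos) {
  if (length(fragments) == 0) return(ori)
  nf <- length(fragments)
  size <- vapply(fragments, function(f) length(f$snp), integer(1))
  mis1 <- vapply(fragments, function(f) sum(f$allele != ori[f$snp]), integer(1))
  all_snp <- unlist(lapply(fragments, `[[`, "snp"))
  all_frag <- rep(seq_len(nf), size)
  all_allele <- unlist(lapply(fragments, `[[`, "allele"))
  idx_by_snp <- split(seq_along(all_snp), all_snp)
  fragcost <- function(m, s) pmin(m, s - m)
  cost_total <- sum(fragcost(mis1, size))

  flip_info <- function(s, ori_s, mis1) {
    ii <- idx_by_snp[[as.character(s)]]
    if (is.null(ii)) return(list(delta = 0L, frs = integer(0), newm = integer(0)))
    frs <- all_frag[ii]
    match_now <- all_allele[ii] == ori_s
    newm <- mis1[frs] + ifelse(match_now, 1L, -1L)
    delta <- sum(fragcost(newm, size[frs])) - sum(fragcost(mis1[frs], size[frs]))
    list(delta = delta, frs = frs, newm = newm)
  }

  blocks <- split(seq_along(ori), roots)
  repeat {
    improved <- FALSE
    for (ix in blocks) {
      if (length(ix) < 2) next
      ix <- ix[order(pos[ix])]
      for (s in ix) {
        fi <- flip_info(s, ori[s], mis1)
        if (fi$delta < 0) {
          mis1[fi$frs] <- fi$newm
          ori[s] <- 1L - ori[s]
          cost_total <- cost_total + fi$delta
          improved <- TRUE
        }
      }
      # suffix scan from the right; each step toggles one more SNP
      cand_ori <- ori
      cand_mis1 <- mis1
      cand_cost <- cost_total
      best_cost <- cost_total
      best_k <- NA_integer_
      m <- length(ix)
      for (k in m:2) {
        s <- ix[k]
        fi <- flip_info(s, cand_ori[s], cand_mis1)
        cand_mis1[fi$frs] <- fi$newm
        cand_ori[s] <- 1L - cand_ori[s]
        cand_cost <- cand_cost + fi$delta
        if (cand_cost < best_cost) {
          best_cost <- cand_cost
          best_k <- k
        }
      }
      if (!is.na(best_k)) {
        for (k in m:best_k) {
          s <- ix[k]
          fi <- flip_info(s, ori[s], mis1)
          mis1[fi$frs] <- fi$newm
          ori[s] <- 1L - ori[s]
          cost_total <- cost_total + fi$delta
        }
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ori
}

#' N50 of phase-block spans
#'
#' The largest span s such that blocks with span >= s cover at least half the
#' total spanned length. Span of a block is last member position - first
#' member position + 1.
#'
#' @param blocks `vc_phase_blocks` (or a numeric vector of spans).
#' @return N50 in bp; 0 for empty input.
#' @export
phase_block_n50 <- function(blocks) {
  spans <- if (is.numeric(blocks)) {
    blocks
  } else if (nrow(blocks) == 0) {
    numeric(0)
  } else {
    vapply(split(blocks$pos, blocks$block_id),
           function(p) max(p) - min(p) + 1, numeric(1))
  }
  if (length(spans) == 0) return(0)
  spans <- sort(spans, decreasing = TRUE)
  idx <- which(cumsum(spans) >= sum(spans) / 2)[1]
  spans[idx]
}
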