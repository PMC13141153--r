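# Internal helpers.

phred_from_prob <- function(p_err, cap = 60) {
  q <- -10 * log10(pmax(p_err, 10^(-cap / 10)))
  pmin(q, cap)
}

#' @noRd
stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "haplocall_invalid_input")
}

# Expand a CIGAR string into aligned pairs of query/reference offsets.
# Returns list(qpos, rpos): equal-length integer vectors; qpos is NA over
# deletions, rpos is NA over insertions. Soft/hard clips are excluded from
# the pairs (soft clips still consume query offsets).
cigar_to_pairs <- function(cigar, ref_start) {
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    return(list(qpos = integer(0), rpos = integer(0)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) {
    stop_invalid("malformed CIGAR string '%s'", cigar)
  }
  qcons <- ops %in% c("M", "I", "S", "=", "X")
  rcons <- ops %in% c("M", "D", "N", "=", "X")
  keep <- ops %in% c("M", "I", "D", "=", "X")  # N treated as deletion-like skip? excluded below
  # N (ref skip) consumes reference but produces no pair rows (no deletion call
  # evidence from spliced alignments; long-read DNA data has none in practice).
  pair <- ops %in% c("M", "I", "D", "=", "X")
  q0 <- cumsum(c(0L, lens * qcons))[seq_along(ops)]
  r0 <- ref_start + cumsum(c(0L, lens * rcons))[seq_along(ops)]
  idx <- rep.int(seq_along(ops), lens)
  off <- sequence(lens) - 1L
  sel <- pair[idx]
  idx <- idx[sel]
  off <- off[sel]
  qpos <- ifelse(qcons[idx], q0[idx] + off, NA_integer_)
  rpos <- ifelse(rcons[idx], r0[idx] + off, NA_integer_)
  list(qpos = as.integer(qpos), rpos = as.integer(rpos))
}

# Inverse of cigar_to_pairs for records with no clipping.
pairs_to_cigar <- function(qpos, rpos) {
  if (length(qpos) == 0) return("*")
  op <- ifelse(!is.na(qpos) & !is.na(rpos), "M", ifelse(is.na(rpos), "I", "D"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

qual_to_string <- function(q) {
  intToUtf8(pmin(q, 93L) + 33L)
}

string_to_qual <- function(s) {
  if (is.na(s) || s == "*") return(integer(0))
  utf8ToInt(s) - 33L
}

# Sequence helpers: references are kept as plain uppercase character strings.
seq_window <- function(sequence, start, end) {
  # 0-based half-open window, clamped; positions outside return "N"
  n <- nchar(sequence)
  lo <- max(start, 0L)
  hi <- min(end, n)
  core <- if (hi > lo) substr(sequence, lo + 1L, hi) else ""
  paste0(strrep("N", max(0L, lo - start)), core, strrep("N", max(0L, end - hi)))
}

base_codes <- function(bases) {
  match(bases, BASES)
}

# split x into batches of size at most `size`, preserving order
batch_indices <- function(n, size) {
  if (n == 0) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}
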