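#' Chunking configuration
#'
#' Parameters controlling how contigs (or regions of interest) are partitioned
#' into parallel work units. Each chunk owns a *core* interval; candidate
#' coordinates are confined to the core. For feature completeness at chunk
#' boundaries adjacent chunks overlap by `overlap` bp, and for haplotagging
#' context every chunk is additionally extended by `flank` bp at both ends;
#' the extended interval is the chunk's *fetch* window.
#'
#' @param chunk_size Core size in bp (default 5e6). Values outside
#'   `[min_chunk_size, max_chunk_size]` are accepted with a warning.
#' @param min_chunk_size,max_chunk_size Advisory bounds on `chunk_size`
#'   (defaults 3e6 and 10e6).
#' @param overlap Overlap in bp shared by adjacent fetch windows (default 16,
#'   the half-width of the default pileup feature window).
#' @param flank Flank extension in bp on both ends of the fetch window for
#'   haplotagging context (default 1e5; should exceed the span of
#'   phase-informative reads).
#' @return A list of class `vc_chunking_config`.
#' @export
chunking_config <- function(chunk_size = 5e6, min_chunk_size = 3e6,
                            max_chunk_size = 10e6, overlap = 16,
                            flank = 1e5) {
  chunk_size <- as.numeric(chunk_size)
  if (length(chunk_size) != 1 || is.na(chunk_size) || chunk_size <= 0) {
    stop_invalid("chunk_size must be a single positive number")
  }
  if (overlap < 0 || flank < 0) stop_invalid("overlap and flank must be >= 0")
  if (overlap >= chunk_size) stop_invalid("overlap must be smaller than chunk_size")
  if (chunk_size < min_chunk_size || chunk_size > max_chunk_size) {
    warn(sprintf(
      "chunk_size %.0f is outside the advisory range [%.0f, %.0f]; using it anyway",
      chunk_size, min_chunk_size, max_chunk_size
    ))
  }
  structure(
    list(
      chunk_size = chunk_size, min_chunk_size = min_chunk_size,
      max_chunk_size = max_chunk_size, overlap = overlap, flank = flank
    ),
    class = "vc_chunking_config"
  )
}

new_chunks <- function(contig, core_start, core_end, contig_length, config) {
  ext <- config$overlap + config$flank
  tibble(
    contig = contig,
    core_start = as.numeric(core_start),
    core_end = as.numeric(core_end),
    fetch_start = pmax(core_start - ext, 0),
    fetch_end = pmin(core_end + ext, contig_length),
    contig_length = as.numeric(contig_length)
  )
}

#' Partition a genome into overlapping parallel work units
#'
#' Tiles each contig with contiguous fixed-size chunk cores (the last core per
#' contig may be shorter) and attaches overlap/flank-extended fetch windows
#' clamped to contig bounds. Cores on one contig are pairwise disjoint and
#' their union is exactly `[0, length)`.
#'
#' @param contig_lengths Named numeric vector of contig lengths in bp.
#' @param config A [chunking_config()].
#' @return A tibble with one row per chunk: `contig`, `core_start`, `core_end`,
#'   `fetch_start`, `fetch_end`, `contig_length` (0-based half-open).
#' @examples
#' partition_genome(c(chr1 = 12e6), chunking_config(overlap = 0, flank = 0))
#' @export
partition_genome <- function(contig_lengths, config = chunking_config()) {
  if (length(contig_lengths) == 0) {
    return(new_chunks(character(0), numeric(0), numeric(0), numeric(0), config))
  }
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths)))) {
    stop_invalid("contig_lengths must be a named vector")
  }
  bad <- names(contig_lengths)[is.na(contig_lengths) | contig_lengths <= 0]
  if (length(bad)) {
    stop_invalid("non-positive length for contig '%s'", bad[[1]])
  }
  out <- imap(contig_lengths, function(len, ctg) {
    starts <- seq(0, len - 1, by = config$chunk_size)
    ends <- pmin(starts + config$chunk_size, len)
    new_chunks(ctg, starts, ends, len, config)
  })
  bind_rows(out)
}

#' Partition explicit regions of interest into work units
#'
#' Chunk boundaries are aligned to the supplied intervals: each region longer
#' than `target_size` is subdivided into `ceiling(len / target_size)`
#' near-equal cores (sizes differ by at most 1 bp); regions are never merged
#' across gaps. Output is sorted by (contig, core_start), contigs in order of
#' first appearance in `contig_lengths`.
#'
#' @param regions Tibble/data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param target_size Target core size in bp (defaults to
#'   `config$chunk_size`).
#' @param config A [chunking_config()] (supplies overlap/flank).
#' @param contig_lengths Named vector of contig lengths used for clamping
#'   fetch windows and ordering contigs.
#' @return A chunk tibble as in [partition_genome()].
#' @export
partition_regions <- function(regions, target_size = NULL,
                              config = chunking_config(),
                              contig_lengths = NULL) {
  target_size <- target_size %||% config$chunk_size
  regions <- as_tibble(regions)
  if (any(regions$start >= regions$end)) {
    stop_invalid("inverted or empty interval in regions (start >= end)")
  }
  if (is.null(contig_lengths)) {
    contig_lengths <- setNames(
      vapply(split(regions$end, regions$contig), max, numeric(1)),
      unique(sort(regions$contig))
    )[unique(regions$contig)]
  }
  ctg_order <- names(contig_lengths)
  regions <- merge_intervals(regions)
  regions <- regions[order(match(regions$contig, ctg_order), regions$start), ]
  out <- pmap(regions, function(contig, start, end, ...) {
    len <- end - start
    k <- ceiling(len / target_size)
    # near-equal split: first (len %% k) pieces get one extra bp
    base <- len %/% k
    sizes <- rep(base, k) + c(rep(1, len %% k), rep(0, k - len %% k))
    ends <- start + cumsum(sizes)
    starts <- c(start, head(ends, -1))
    new_chunks(contig, starts, ends, contig_lengths[[contig]], config)
  })
  bind_rows(out)
}

merge_intervals <- function(regions) {
  regions |>
    arrange(.data$contig, .data$start) |>
    group_by(.data$contig) |>
    mutate(grp = cumsum(.data$start > cummax(dplyr::lag(.data$end, default = -Inf)))) |>
    group_by(.data$contig, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("contig", "start", "end")
}

#' Find the chunk owning a genomic position
#'
#' Candidates in overlap zones are emitted only by the chunk whose *core*
#' contains them; this resolves that ownership.
#'
#' @param contig,position Contig name and 0-based coordinate.
#' @param chunks Chunk tibble from [partition_genome()]/[partition_regions()].
#' @return The single owning chunk row (tibble).
#' @export
owner_chunk <- function(contig, position, chunks) {
  hit <- chunks$contig == contig &
    chunks$core_start <= position & position < chunks$core_end
  if (!any(hit)) {
    abort(
      sprintf("position %s:%d is not covered by any chunk core", contig, position),
      class = "haplocall_not_found"
    )
  }
  chunks[which(hit)[1], ]
}

#' Read a BED file of regions of interest
#'
#' Accepts 0-based half-open BED; `track`, `browser` and `#` comment lines are
#' ignored.
#'
#' @param path Path to a BED file.
#' @return Tibble with `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(tibble(contig = character(0), start = numeric(0), end = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    contig = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 2)),
    end = as.numeric(vapply(parts, `[[`, "", 3))
  )
}
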