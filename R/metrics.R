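# Normalize a call record for matching: trim shared suffix then shared prefix
# bases (keeping at least one of each allele), adjusting the position; strip
# phasing from the genotype (0|1 and 1|0 both compare as 0/1).
normalize_records <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  ref <- calls$ref
  alt <- calls$alt
  pos <- calls$pos
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    if (is.na(a) || a %in% c(".", "<NON_REF>") || grepl(",", a)) next
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substring(r, nchar(r)) == substring(a, nchar(a))) {
      r <- substring(r, 1, nchar(r) - 1)
      a <- substring(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 && substring(r, 1, 1) == substring(a, 1, 1)) {
      r <- substring(r, 2)
      a <- substring(a, 2)
      pos[i] <- pos[i] + 1
    }
    ref[i] <- r; alt[i] <- a
  }
  calls$ref <- ref
  calls$alt <- alt
  calls$pos <- pos
  gt <- calls$gt
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  gt[gt == "2/1"] <- "1/2"
  calls$gt <- gt
  calls
}

# Decompose multiallelic records (alt "X,Y", GT 1/2) into biallelic het rows.
decompose_multiallelic <- function(calls) {
  multi <- grepl(",", calls$alt)
  if (!any(multi)) return(calls)
  rest <- calls[!multi, ]
  expanded <- calls[multi, ] |>
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) |>
    tidyr::unnest("alt") |>
    mutate(gt = "0/1")
  bind_rows(rest, expanded)
}

variant_category <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
         ifelse(nchar(alt) > nchar(ref), "Insertion", "Deletion"))
}

METRIC_CATEGORIES <- c("overall", "SNP", "Indel", "Insertion", "Deletion")

#' Compare calls to a truth set
#'
#' Genotype-aware exact matching on (contig, pos, ref, alt, genotype) after
#' normalization (suffix/prefix trimming, phase stripping, multiallelic
#' decomposition), restricted to confident regions when provided. Calls
#' outside the confident regions are ignored rather than counted as false
#' positives. Reports TP/FP/FN and precision/recall/F1 for the five
#' categories overall, SNP, Indel, Insertion and Deletion (Indel counts are
#' the sum of Insertion and Deletion counts).
#'
#' @param calls,truth_calls Call tibbles (variant records; 0-based `pos`).
#' @param confident_regions Optional tibble `contig`, `start`, `end`
#'   (0-based half-open).
#' @return `vc_metrics` tibble: `category`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
compare_to_truth <- function(calls, truth_calls, confident_regions = NULL) {
  prep <- function(x) {
    if (!is.null(x$is_variant)) x <- x[x$is_variant, ]
    x <- decompose_multiallelic(x)
    x <- normalize_records(x)
    x$category <- variant_category(x$ref, x$alt)
    x$key <- paste(x$contig, x$pos, x$ref, x$alt, x$gt, sep = "\r")
    x
  }
  in_conf <- function(x) {
    if (is.null(confident_regions) || nrow(x) == 0) return(rep(TRUE, nrow(x)))
    ok <- logical(nrow(x))
    for (i in seq_len(nrow(confident_regions))) {
      cr <- confident_regions[i, ]
      ok <- ok | (x$contig == cr$contig & x$pos >= cr$start & x$pos < cr$end)
    }
    ok
  }
  c2 <- prep(calls)
  t2 <- prep(truth_calls)
  c2 <- c2[in_conf(c2), ]
  t2 <- t2[in_conf(t2), ]
  tp_keys <- intersect(c2$key, t2$key)
  count_cat <- function(x, keys, keep = TRUE) {
    sel <- if (keep) x$key %in% keys else !(x$key %in% keys)
    table(factor(x$category[sel], levels = c("SNP", "Insertion", "Deletion")))
  }
  tp <- count_cat(t2, tp_keys)
  fn <- count_cat(t2, tp_keys, keep = FALSE)
  fp <- count_cat(c2, tp_keys, keep = FALSE)
  agg <- function(v) {
    c(
      overall = sum(v), SNP = unname(v["SNP"]),
      Indel = unname(v["Insertion"] + v["Deletion"]),
      Insertion = unname(v["Insertion"]), Deletion = unname(v["Deletion"])
    )
  }
  tp <- agg(tp); fp <- agg(fp); fn <- agg(fn)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  out <- tibble(
    category = METRIC_CATEGORIES,
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = unname(precision), recall = unname(recall), f1 = unname(f1)
  )
  class(out) <- c("vc_metrics", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.vc_metrics <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
}

#' @exportS3Method ggplot2::autoplot
autoplot.vc_metrics <- function(object, ...) {
  df <- tidy.vc_metrics(object)
  df$category <- factor(df$category, levels = METRIC_CATEGORIES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Variant-calling performance by category") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.vc_phase_blocks <- function(object, ...) {
  spans <- object |>
    group_by(.data$contig, .data$block_id) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_snps = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(spans, ggplot2::aes(x = .data$start, xend = .data$end,
                                      y = factor(.data$block_id),
                                      yend = factor(.data$block_id))) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::facet_wrap(~contig, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = "phase block",
                  title = sprintf("Phase blocks (N50 = %s bp)",
                                  format(phase_block_n50(object), big.mark = ","))) +
    ggplot2::theme_minimal()
}
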