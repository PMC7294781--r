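#' Call broad enrichment domains by sliding-window Poisson scan
#'
#' A deliberately simple domain caller for broad marks: fixed
#' non-overlapping windows tile each chromosome, the genome-wide mean tag
#' count per window is the Poisson background rate, windows whose upper
#' tail probability falls below `p_threshold` are kept, and significant
#' windows closer than `merge_gap_bp` are merged. Externally produced peak
#' BED files can be substituted anywhere a peak set is consumed.
#'
#' @param tags Tag tibble (`chrom, pos`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window_bp Window size (default 1000).
#' @param p_threshold Poisson upper-tail cutoff per window (default 1e-3).
#' @param merge_gap_bp Merge significant windows within this gap
#'   (default 1000).
#' @param sample_id Label stored on the result.
#' @return A `peak_set` tibble: `chrom, start, end, count, p_value`,
#'   sorted and non-overlapping.
#' @export
call_domains <- function(tags, chrom_sizes, window_bp = 1000,
                         p_threshold = 1e-3, merge_gap_bp = 1000,
                         sample_id = attr(tags, "sample_id") %||% "sample") {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  count = integer(), p_value = numeric())
  if (nrow(tags) == 0) {
    return(structure(empty, sample_id = sample_id,
                     class = c("peak_set", class(empty))))
  }
  windows <- purrr::map_dfr(names(chrom_sizes), function(ch) {
    n_w <- ceiling(chrom_sizes[[ch]] / window_bp)
    tibble(chrom = ch, start = (seq_len(n_w) - 1) * window_bp,
           end = pmin(seq_len(n_w) * window_bp, chrom_sizes[[ch]]))
  })
  windows <- count_tags(tags, windows)
  lambda <- sum(windows$count) / nrow(windows)
  windows$p_value <- ppois(windows$count - 1, lambda, lower.tail = FALSE)
  sig <- filter(windows, .data$p_value < p_threshold)
  if (nrow(sig) == 0) {
    return(structure(empty, sample_id = sample_id,
                     class = c("peak_set", class(empty))))
  }
  gr <- GenomicRanges::reduce(as_granges0(sig), min.gapwidth = merge_gap_bp + 1)
  peaks <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1,
                  end = as.numeric(GenomicRanges::end(gr)))
  hits <- GenomicRanges::findOverlaps(as_granges0(sig), gr)
  peaks$count <- count_tags(tags, peaks)$count
  pmin_by <- tapply(sig$p_value[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), min)
  peaks$p_value <- as.numeric(pmin_by[as.character(seq_len(nrow(peaks)))])
  peaks <- arrange(peaks, .data$chrom, .data$start)
  structure(peaks, sample_id = sample_id,
            class = c("peak_set", class(peaks)))
}

#' Consensus regions supported by at least `min_support` samples
#'
#' Computes per-base sample support (how many distinct samples have a peak
#' covering the base; peaks are merged within each sample first) and keeps
#' maximal runs of bases with support >= `min_support`. A region's
#' `support` is the maximum per-base sample count inside it. The
#' alternative `mode = "union"` instead keeps the union of all peaks that
#' overlap a peak from at least `min_support - 1` other samples, mimicking
#' peak-overlap voting.
#'
#' @param peak_sets List of peak tibbles (`chrom, start, end`), one per
#'   sample.
#' @param min_support Minimum number of supporting samples (default 2).
#' @param mode `"per_base"` (default) or `"union"`.
#' @return Tibble `region_id, chrom, start, end, support`, disjoint and
#'   sorted.
#' @export
consensus_regions <- function(peak_sets, min_support = 2,
                              mode = c("per_base", "union")) {
  mode <- match.arg(mode)
  if (length(peak_sets) < min_support) {
    abort("fewer peak sets than min_support")
  }
  grl <- lapply(peak_sets, function(p) {
    if (nrow(p) == 0) GenomicRanges::GRanges() else
      GenomicRanges::reduce(as_granges0(p))
  })
  all_gr <- Reduce(c, grl)
  if (length(all_gr) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), support = integer()))
  }
  w <- coverage_widths(all_gr)
  cov <- Reduce(`+`, lapply(grl, function(g) {
    g <- GenomicRanges::GRanges(
      seqnames = factor(as.character(GenomicRanges::seqnames(g)),
                        levels = names(w)),
      ranges = IRanges::ranges(g), seqlengths = w)
    GenomicRanges::coverage(g)[names(w)]
  }))
  max_support_in <- function(gr) {
    vapply(seq_along(gr), function(i) {
      v <- cov[[as.character(GenomicRanges::seqnames(gr[i]))]]
      max(IRanges::Views(v, GenomicRanges::start(gr[i]),
                         GenomicRanges::end(gr[i]))[[1]])
    }, 0)
  }
  if (mode == "per_base") {
    keep <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    gr <- GenomicRanges::GRanges(
      seqnames = rep(names(keep), lengths(keep)),
      ranges = unlist(keep, use.names = FALSE))
    if (length(gr) == 0) {
      return(tibble(region_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), support = integer()))
    }
    support <- max_support_in(gr)
  } else {
    # union mode: a peak is kept when peaks of >= min_support distinct
    # samples (itself included) overlap it
    kept <- lapply(seq_along(grl), function(i) {
      g <- grl[[i]]
      if (length(g) == 0) return(GenomicRanges::GRanges())
      n_sup <- rep(1L, length(g))
      for (j in seq_along(grl)[-i]) {
        n_sup <- n_sup + as.integer(IRanges::overlapsAny(g, grl[[j]]))
      }
      g[n_sup >= min_support]
    })
    gr <- GenomicRanges::reduce(Reduce(c, kept))
    if (length(gr) == 0) {
      return(tibble(region_id = character(), chrom = character(),
                    start = numeric(), end = numeric(), support = integer()))
    }
    support <- max_support_in(gr)
  }
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1,
                end = as.numeric(GenomicRanges::end(gr)),
                support = as.integer(support)) |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("cr%04d", row_number())) |>
    select("region_id", "chrom", "start", "end", "support")
  out
}

# common coverage width vector covering every peak
coverage_widths <- function(gr) {
  ends <- tapply(GenomicRanges::end(gr),
                 as.character(GenomicRanges::seqnames(gr)), max)
  setNames(as.integer(ends), names(ends))
}

#' Read / write peaks and regions as BED
#'
#' `read_bed_regions()` reads BED3+ into a region tibble;
#' `write_bed_regions()` writes `chrom, start, end` plus an optional score
#' column (for peak sets, `-log10(p)`; for consensus regions, support).
#'
#' @param path BED file path.
#' @return A region tibble.
#' @export
read_bed_regions <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(bed) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- tibble(chrom = bed[[1]], start = as.numeric(bed[[2]]),
                end = as.numeric(bed[[3]]))
  if (ncol(bed) >= 4) out$name <- bed[[4]]
  if (ncol(bed) >= 5) out$score <- suppressWarnings(as.numeric(bed[[5]]))
  check_intervals(out, path)
}

#' @rdname read_bed_regions
#' @param regions Region tibble.
#' @param score Optional numeric vector for the BED score column.
#' @export
write_bed_regions <- function(regions, path, score = NULL) {
  name <- regions[["region_id"]] %||% regions[["name"]] %||%
    sprintf("r%04d", seq_len(nrow(regions)))
  bed <- tibble(chrom = regions$chrom, start = regions$start,
                end = regions$end, name = name,
                score = score %||% regions[["support"]] %||% 0,
                strand = regions[["strand"]] %||% ".")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
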