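# Internal helpers shared across modules.
#
# All genomic coordinates in user-facing tibbles are 0-based half-open
# ([start, end), BED convention). GRanges (1-based closed) appear only
# transiently inside overlap computations.

# tibble with chrom/start/end (+ optional strand) -> GRanges
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# single-position tags -> width-1 GRanges
tags_granges <- function(tags) {
  GenomicRanges::GRanges(
    seqnames = tags$chrom,
    ranges = IRanges::IRanges(start = tags$pos + 1L, width = 1L)
  )
}

check_intervals <- function(x, what = "regions") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s must have columns chrom, start, end", what))
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$start >= x$end)) {
    abort(sprintf("%s must satisfy 0 <= start < end", what))
  }
  invisible(x)
}

check_sample_sheet <- function(samples) {
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("sample sheet must have columns sample_id and group")
  }
  g <- unique(samples$group)
  if (length(g) != 2) abort("exactly two groups are required")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  invisible(samples)
}

# two group levels in stable order: factor levels if factor, else order of
# first appearance (so the reference group is listed first in the sheet and
# the convention survives TSV round-trips)
group_levels <- function(group) {
  if (is.factor(group)) levels(droplevels(group)) else unique(group)
}

# count table (id column + one column per sample) -> integer matrix
count_matrix <- function(counts, id_col = NULL) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      rownames(counts) <- paste0("row", seq_len(nrow(counts)))
    }
    return(counts)
  }
  counts <- as.data.frame(counts)
  if (is.null(id_col)) {
    id_col <- intersect(c("region_id", "gene_id", "row_id"), names(counts))[1]
    if (is.na(id_col)) id_col <- names(counts)[1]
  }
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- as.character(counts[[id_col]])
  storage.mode(m) <- "double"
  m
}

geometric_mean <- function(x) exp(mean(log(x)))

md5_file <- function(path) unname(tools::md5sum(path))

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
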