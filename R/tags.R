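#' Read, filter and deduplicate sequencing tags
#'
#' Reads single-position tags from a BED file (intervals reduced to their
#' midpoint, or 5' end when `reduce = "five_prime"` and strand is present)
#' or from a SAM/BAM alignment (5' end of the read; requires Rsamtools).
#' Alignment input is filtered on mapping quality (`MAPQ < mapq_min`
#' discarded); plain BED carries no MAPQ so the filter does not apply.
#' Duplicate tags at the same (chrom, pos, strand) are collapsed to one
#' when `dedup = TRUE`.
#'
#' @param path BED6 (or BED3) file, or `.sam`/`.bam` alignment.
#' @param mapq_min Minimum mapping quality kept (default 5).
#' @param dedup Collapse positional duplicates (default TRUE).
#' @param reduce How to reduce an interval to one position: `"midpoint"`
#'   (default for BED) or `"five_prime"` (strand-aware; default for
#'   alignments).
#' @return A `tag_set`: tibble `chrom, pos, strand` with attributes
#'   `sample_id`, `n_raw`, `n_kept`.
#' @export
read_tags <- function(path, mapq_min = 5, dedup = TRUE,
                      reduce = c("auto", "midpoint", "five_prime")) {
  reduce <- match.arg(reduce)
  is_aln <- grepl("\\.(sam|bam)$", path, ignore.case = TRUE)
  if (is_aln) {
    raw <- read_alignment_tags(path, mapq_min,
                               if (reduce == "auto") "five_prime" else reduce)
  } else {
    raw <- read_bed_tags(path, if (reduce == "auto") "midpoint" else reduce)
  }
  tag_set(raw, sample_id = sub("\\.[^.]*$", "", basename(path)),
          dedup = dedup, n_raw = attr(raw, "n_raw") %||% nrow(raw))
}

#' Construct a tag set from a tibble of positions
#'
#' @param tags Tibble `chrom, pos` (optional `strand`).
#' @param sample_id Sample label.
#' @param dedup Collapse duplicates at identical (chrom, pos, strand).
#' @param n_raw Count before filtering (defaults to `nrow(tags)`).
#' @return A `tag_set` tibble.
#' @export
tag_set <- function(tags, sample_id = "sample", dedup = TRUE,
                    n_raw = nrow(tags)) {
  tags <- as_tibble(tags)
  if (!"strand" %in% names(tags)) tags$strand <- "."
  tags <- tags[c("chrom", "pos", "strand")]
  if (dedup) tags <- distinct(tags)
  tags <- arrange(tags, .data$chrom, .data$pos, .data$strand)
  structure(tags, sample_id = sample_id, n_raw = n_raw,
            n_kept = nrow(tags),
            class = c("tag_set", class(tags)))
}

read_bed_tags <- function(path, reduce) {
  bed <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, comment = "#",
                    col_types = readr::cols(.default = "c"), progress = FALSE),
    error = function(e) abort(sprintf("unparseable BED '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (nrow(bed) == 0) {
    out <- tibble(chrom = character(), pos = numeric(), strand = character())
    attr(out, "n_raw") <- 0L
    return(out)
  }
  if (ncol(bed) < 3) abort(sprintf("BED '%s' needs >= 3 columns", path))
  start <- suppressWarnings(as.numeric(bed[[2]]))
  end <- suppressWarnings(as.numeric(bed[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("unparseable BED record at line %d of '%s'",
                                 bad[1], path))
  strand <- if (ncol(bed) >= 6) bed[[6]] else rep(".", nrow(bed))
  strand[!strand %in% c("+", "-")] <- "."
  pos <- if (reduce == "five_prime") {
    ifelse(strand == "-", end - 1, start)
  } else {
    floor((start + end) / 2)
  }
  out <- tibble(chrom = bed[[1]], pos = pos, strand = strand)
  attr(out, "n_raw") <- nrow(out)
  out
}

read_alignment_tags <- function(path, mapq_min, reduce) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Rsamtools is required to read SAM/BAM input")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "mapq", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_raw <- length(a$pos)
  keep <- !is.na(a$mapq) & a$mapq >= mapq_min
  chrom <- as.character(a$rname)[keep]
  pos1 <- a$pos[keep]                      # 1-based leftmost
  strand <- as.character(a$strand)[keep]
  width <- a$qwidth[keep]
  pos <- if (reduce == "midpoint") {
    floor((pos1 - 1 + pos1 - 1 + width) / 2)
  } else {
    ifelse(strand == "-", pos1 - 1 + width - 1, pos1 - 1)
  }
  out <- tibble(chrom = chrom, pos = pos, strand = strand)
  attr(out, "n_raw") <- n_raw
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write tags as BED6
#'
#' @param tags A tag tibble (`chrom, pos, strand`).
#' @param path Output path.
#' @export
write_tags_bed <- function(tags, path) {
  bed <- tibble(chrom = tags$chrom, start = tags$pos, end = tags$pos + 1,
                name = "tag", score = 0,
                strand = ifelse(tags$strand %in% c("+", "-"),
                                tags$strand, "."))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Count tags falling in regions
#'
#' Every tag contributes one count to every region whose half-open interval
#' contains its position; overlapping regions each receive the tag.
#'
#' @param tags Tag tibble (`chrom, pos`).
#' @param regions Region tibble (`chrom, start, end`, any id columns kept).
#' @return `regions` with an added integer `count` column.
#' @export
count_tags <- function(tags, regions) {
  check_intervals(regions, "regions")
  out <- as_tibble(regions)
  if (nrow(tags) == 0 || nrow(regions) == 0) {
    out$count <- integer(nrow(regions))
    return(out)
  }
  out$count <- GenomicRanges::countOverlaps(as_granges0(regions),
                                            tags_granges(tags),
                                            ignore.strand = TRUE)
  out
}

#' Count tags of several samples over one region set
#'
#' @param tag_sets Named list of tag tibbles (one per sample).
#' @param regions Region tibble with a `region_id` column.
#' @return Count tibble: `region_id` plus one integer column per sample.
#' @export
count_tag_matrix <- function(tag_sets, regions) {
  stopifnot(!is.null(names(tag_sets)), "region_id" %in% names(regions))
  cols <- purrr::map(tag_sets, \(t) count_tags(t, regions)$count)
  bind_cols(tibble(region_id = regions$region_id), as_tibble(cols))
}

#' Genomic occupancy proportions of a tag set
#'
#' Classifies every tag with [classify_positions()] and reports the fraction
#' of tags in promoters, gene bodies and intergenic space, plus the split of
#' gene-body tags over CDS, UTR and introns.
#'
#' @param tags Tag tibble.
#' @param index An [annotation_index()].
#' @param promoter_bp Promoter window (default 3000).
#' @return List with tibbles `top_level` (category, n, fraction; fractions
#'   sum to 1) and `gene_body` (fractions of gene-body tags, summing to 1
#'   when any gene-body tag exists).
#' @export
occupancy_proportions <- function(tags, index, promoter_bp = 3000) {
  if (nrow(tags) == 0) abort("empty tag set")
  cls <- classify_positions(index, tags[c("chrom", "pos")], promoter_bp)
  top <- dplyr::case_match(cls$category,
                           c("CDS", "UTR", "intron") ~ "gene_body",
                           "promoter" ~ "promoter",
                           "intergenic" ~ "intergenic")
  top_level <- tibble(category = c("promoter", "gene_body", "intergenic")) |>
    left_join(tibble(category = top) |> dplyr::count(.data$category),
              by = "category") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           fraction = .data$n / sum(.data$n))
  body <- cls$category[top == "gene_body"]
  gene_body <- tibble(category = c("CDS", "UTR", "intron")) |>
    left_join(tibble(category = body) |> dplyr::count(.data$category),
              by = "category") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           fraction = if (length(body)) .data$n / length(body) else NA_real_)
  list(top_level = top_level, gene_body = gene_body)
}

#' Metagene occupancy profile
#'
#' Averages per-bin tag counts across genes over the standardized gene
#' coordinate system produced by [metagene_bins()] (upstream flank -> gene
#' body -> downstream flank, bins oriented 5' to 3').
#'
#' @param tags Tag tibble, or a list of tag tibbles pooled together.
#' @param genes Gene-model tibble or [annotation_index()].
#' @param flank_bp,n_bins Passed to [metagene_bins()].
#' @param normalize `"raw"` (mean counts, default) or `"per_bp"` (mean
#'   count divided by bin width).
#' @param label Optional gene-set label stored on the result.
#' @return An `occupancy_profile` tibble: `bin, mean_count`, with attributes
#'   `n_genes` and `label`.
#' @export
metagene_profile <- function(tags, genes, flank_bp = 5000, n_bins = 100,
                             normalize = c("raw", "per_bp"), label = "custom") {
  normalize <- match.arg(normalize)
  if (is.data.frame(tags)) tags <- list(tags)
  tags <- bind_rows(lapply(tags, \(t) as_tibble(t)[c("chrom", "pos")]))
  chrom_sizes <- NULL
  if (inherits(genes, "annotation_index")) genes <- genes$genes
  if (nrow(genes) == 0) abort("empty gene list")
  bins <- metagene_bins(genes, flank_bp, n_bins)
  bins$count <- if (nrow(tags)) {
    GenomicRanges::countOverlaps(as_granges0(bins), tags_granges(tags),
                                 ignore.strand = TRUE)
  } else 0L
  if (normalize == "per_bp") {
    w <- pmax(bins$end - bins$start, 1)
    bins$count <- bins$count / w
  }
  prof <- bins |>
    group_by(.data$bin) |>
    summarise(mean_count = mean(.data$count), .groups = "drop") |>
    arrange(.data$bin)
  structure(prof, n_genes = length(unique(genes$gene_id)), label = label,
            class = c("occupancy_profile", class(prof)))
}

#' @describeIn metagene_profile Line plot of an occupancy profile.
#' @param object An `occupancy_profile`.
#' @param ... Unused.
#' @export
autoplot.occupancy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "metagene bin (5' → 3')", y = "mean tag count",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}
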