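#' Build an annotation index from gene-model tables
#'
#' The annotation index is the package's central gene-model container: a set
#' of collapsed gene models (one row per gene, outermost TSS/TES across
#' transcripts) plus exon/CDS structure and chromosome sizes. All coordinates
#' are 0-based half-open (BED convention).
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`).
#' @param exons Tibble with `gene_id`, `chrom`, `start`, `end`; overlapping
#'   exons of a gene are merged. Defaults to one exon spanning each gene.
#' @param cds Optional tibble of coding intervals (same columns). Must lie
#'   within exons.
#' @param utr Optional tibble of untranslated exonic intervals. When omitted
#'   it is derived as exon minus CDS.
#' @param chrom_sizes Named vector of chromosome lengths. When omitted, the
#'   maximum annotated end per chromosome is used.
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(genes, exons = NULL, cds = NULL, utr = NULL,
                             chrom_sizes = NULL) {
  check_intervals(genes, "genes")
  if (!all(c("gene_id", "strand") %in% names(genes))) {
    abort("genes must have gene_id and strand columns")
  }
  if (anyDuplicated(genes$gene_id)) abort("gene_id must be unique")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  genes <- as_tibble(genes) |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tes = ifelse(.data$strand == "+", .data$end, .data$start),
      length = .data$end - .data$start
    ) |>
    arrange(.data$chrom, .data$start, .data$gene_id)

  if (is.null(exons)) exons <- genes[c("gene_id", "chrom", "start", "end")]
  exons <- merge_gene_intervals(exons)
  if (is.null(cds)) cds <- exons[0, ]
  cds <- merge_gene_intervals(cds)
  if (is.null(utr)) utr <- setdiff_gene_intervals(exons, cds)
  utr <- merge_gene_intervals(utr)

  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  bad <- genes$end > chrom_sizes[genes$chrom]
  if (any(is.na(bad)) || any(bad)) {
    abort("every gene must fit within its chromosome length")
  }

  structure(
    list(genes = genes, exons = as_tibble(exons), cds = as_tibble(cds),
         utr = as_tibble(utr), chrom_sizes = chrom_sizes),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chrom_sizes)))
  invisible(x)
}

# merge overlapping intervals within each gene
merge_gene_intervals <- function(x) {
  if (is.null(x) || nrow(x) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  check_intervals(x, "intervals")
  x |>
    group_by(.data$gene_id, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(new_run = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                     default = -Inf))) |>
    group_by(.data$gene_id, .data$chrom, .data$new_run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("gene_id", "chrom", "start", "end") |>
    arrange(.data$gene_id, .data$chrom, .data$start)
}

# per-gene interval subtraction (a minus b), both merged beforehand
setdiff_gene_intervals <- function(a, b) {
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  out <- purrr::map_dfr(unique(a$gene_id), function(g) {
    ia <- ga[a$gene_id == g]
    ib <- gb[b$gene_id == g]
    d <- GenomicRanges::setdiff(ia, ib, ignore.strand = TRUE)
    if (length(d) == 0) return(NULL)
    tibble(gene_id = g,
           chrom = as.character(GenomicRanges::seqnames(d)),
           start = GenomicRanges::start(d) - 1,
           end = as.numeric(GenomicRanges::end(d)))
  })
  if (nrow(out) == 0) {
    tibble(gene_id = character(), chrom = character(),
           start = numeric(), end = numeric())
  } else out
}

#' Read a gene annotation from GTF or BED12
#'
#' Multiple transcripts of a gene are collapsed to the outermost TSS/TES with
#' the union of their exons and CDS. GTF input (1-based closed, Ensembl
#' attribute dialect) is converted to the package's 0-based half-open
#' convention on read; BED12 blocks become exons.
#'
#' @param path GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param chrom_sizes Optional named vector or two-column TSV path
#'   (chrom, size).
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return An [annotation_index()].
#' @export
read_annotation <- function(path, chrom_sizes = NULL, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    cs <- readr::read_tsv(chrom_sizes, col_names = c("chrom", "size"),
                          col_types = "cd", progress = FALSE)
    chrom_sizes <- setNames(cs$size, cs$chrom)
  }
  parts <- if (format == "gtf") parse_gtf(path) else parse_bed12(path)
  if (nrow(parts$genes) == 0) abort("annotation contains no genes")
  annotation_index(parts$genes, parts$exons, parts$cds,
                   chrom_sizes = chrom_sizes)
}

parse_gtf <- function(path) {
  cols <- c("chrom", "source", "feature", "start", "end", "score", "strand",
            "frame", "attributes")
  gtf <- tryCatch(
    suppressWarnings(readr::read_tsv(path, col_names = cols, comment = "#",
                                     col_types = "cccddcccc",
                                     progress = FALSE)),
    error = function(e) abort(sprintf("malformed GTF '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(gtf) == 0) abort("annotation contains no genes")
  bad <- which(is.na(gtf$start) | is.na(gtf$end) | !gtf$strand %in% c("+", "-", "."))
  if (length(bad)) abort(sprintf("malformed GTF record at line %d", bad[1]))
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", gtf$attributes)
  if (any(gid == gtf$attributes)) {
    abort(sprintf("GTF line %d lacks a gene_id attribute",
                  which(gid == gtf$attributes)[1]))
  }
  # 1-based closed -> 0-based half-open
  feat <- tibble(gene_id = gid, chrom = gtf$chrom, feature = gtf$feature,
                 start = gtf$start - 1, end = gtf$end, strand = gtf$strand)
  take <- function(kinds) feat |>
    filter(.data$feature %in% kinds) |>
    select("gene_id", "chrom", "start", "end")
  span_feats <- filter(feat, .data$feature %in% c("gene", "transcript", "exon"))
  genes <- span_feats |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  exons <- take("exon")
  if (nrow(exons) == 0) exons <- genes[c("gene_id", "chrom", "start", "end")]
  list(genes = genes, exons = exons, cds = take("CDS"))
}

parse_bed12 <- function(path) {
  bed <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                    comment = "#", progress = FALSE),
    error = function(e) abort(sprintf("malformed BED12 '%s': %s", path, conditionMessage(e)))
  )
  if (ncol(bed) < 12) abort("BED12 requires 12 columns")
  names(bed)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                        "thickStart", "thickEnd", "rgb", "blockCount",
                        "blockSizes", "blockStarts")
  num <- suppressWarnings(vapply(bed$start, as.numeric, 0))
  if (anyNA(num)) abort(sprintf("malformed BED12 record at line %d", which(is.na(num))[1]))
  tx <- bed |>
    mutate(across(c("start", "end", "thickStart", "thickEnd", "blockCount"),
                  as.numeric))
  genes <- tx |>
    group_by(gene_id = .data$name, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  blocks <- tx |>
    mutate(sizes = purrr::map(strsplit(.data$blockSizes, ","), as.numeric),
           offs = purrr::map(strsplit(.data$blockStarts, ","), as.numeric)) |>
    select(gene_id = "name", "chrom", tx_start = "start",
           "thickStart", "thickEnd", "sizes", "offs") |>
    tidyr::unnest(c("sizes", "offs")) |>
    mutate(start = .data$tx_start + .data$offs, end = .data$start + .data$sizes)
  exons <- blocks[c("gene_id", "chrom", "start", "end")]
  # thick region intersected with blocks = coding part
  cds <- blocks |>
    mutate(start = pmax(.data$start, .data$thickStart),
           end = pmin(.data$end, .data$thickEnd)) |>
    filter(.data$start < .data$end) |>
    select("gene_id", "chrom", "start", "end")
  list(genes = genes, exons = exons, cds = cds)
}

#' Promoter regions (fixed window upstream of the TSS)
#'
#' The promoter is the `upstream_bp` window strictly upstream of the TSS:
#' `[tss - upstream_bp, tss)` on the plus strand, `[tss, tss + upstream_bp)`
#' on the minus strand, clipped at chromosome bounds.
#'
#' @param index An [annotation_index()].
#' @param upstream_bp Window size in bp (default 3000).
#' @return Tibble `gene_id, chrom, start, end, strand`.
#' @export
promoter_regions <- function(index, upstream_bp = 3000) {
  stopifnot(inherits(index, "annotation_index"), upstream_bp > 0)
  g <- index$genes
  sizes <- unname(index$chrom_sizes[g$chrom])
  tibble(
    gene_id = g$gene_id, chrom = g$chrom,
    start = pmax(0, ifelse(g$strand == "+", g$tss - upstream_bp, g$tss)),
    end = pmin(sizes, ifelse(g$strand == "+", g$tss, g$tss + upstream_bp)),
    strand = g$strand
  )
}

#' Gene-body regions (TSS to TES)
#'
#' @inheritParams promoter_regions
#' @return Tibble `gene_id, chrom, start, end, strand`.
#' @export
gene_body_regions <- function(index) {
  stopifnot(inherits(index, "annotation_index"))
  index$genes[c("gene_id", "chrom", "start", "end", "strand")]
}

#' Metagene bins over gene structure plus flanks
#'
#' Each gene's span from `flank_bp` upstream of the TSS to `flank_bp`
#' downstream of the TES is divided into `n_bins` contiguous bins of equal
#' width (a remainder of r bp widens the r most 5' bins by 1 bp). Bin 1 is
#' the 5'-most bin in transcription direction, so minus-strand genes are
#' binned right-to-left. Bins running past a chromosome end are clipped and
#' flagged.
#'
#' @param genes Tibble of gene models (needs `gene_id, chrom, start, end,
#'   strand`) or an [annotation_index()].
#' @param flank_bp Flank added on both sides (default 5000).
#' @param n_bins Number of bins (default 100).
#' @param chrom_sizes Optional named vector used for clipping.
#' @return Tibble `gene_id, bin, chrom, start, end, clipped`.
#' @export
metagene_bins <- function(genes, flank_bp = 5000, n_bins = 100,
                          chrom_sizes = NULL) {
  if (inherits(genes, "annotation_index")) {
    chrom_sizes <- genes$chrom_sizes
    genes <- genes$genes
  }
  stopifnot(n_bins >= 1, flank_bp >= 0)
  per_gene <- function(gene_id, chrom, start, end, strand) {
    s0 <- start - flank_bp
    e0 <- end + flank_bp
    len <- e0 - s0
    w <- len %/% n_bins
    r <- len %% n_bins
    widths <- rep(w, n_bins) + c(rep(1, r), rep(0, n_bins - r))
    bounds <- c(0, cumsum(widths))  # transcription coordinates
    if (strand == "+") {
      bs <- s0 + bounds[-length(bounds)]
      be <- s0 + bounds[-1]
    } else {
      bs <- e0 - bounds[-1]
      be <- e0 - bounds[-length(bounds)]
    }
    tibble(gene_id = gene_id, bin = seq_len(n_bins), chrom = chrom,
           start = bs, end = be)
  }
  out <- purrr::pmap_dfr(
    genes[c("gene_id", "chrom", "start", "end", "strand")], per_gene)
  out$clipped <- FALSE
  if (!is.null(chrom_sizes)) {
    hi <- unname(chrom_sizes[out$chrom])
    out$clipped <- out$start < 0 | out$end > hi
    out$start <- pmin(pmax(out$start, 0), hi)
    out$end <- pmin(pmax(out$end, 0), hi)
  }
  out
}

#' Classify genomic positions by gene structure
#'
#' Assigns each position one category among `CDS`, `UTR`, `intron`,
#' `promoter`, `intergenic` under the precedence CDS > UTR > intron >
#' promoter > intergenic, so a base inside any gene body is never called
#' promoter of a neighbouring gene. UTR here means exonic non-coding
#' sequence; intron is gene-body sequence outside exons.
#'
#' @param index An [annotation_index()].
#' @param positions Tibble with columns `chrom`, `pos` (0-based).
#' @param promoter_bp Promoter window (default 3000).
#' @param precedence Category order, strongest first.
#' @return `positions` with an added `category` column.
#' @export
classify_positions <- function(index, positions, promoter_bp = 3000,
                               precedence = c("CDS", "UTR", "intron", "promoter")) {
  stopifnot(inherits(index, "annotation_index"))
  if (!all(positions$chrom %in% names(index$chrom_sizes))) {
    abort("position on unknown chromosome")
  }
  pg <- tags_granges(tibble(chrom = positions$chrom, pos = positions$pos))
  body <- index$genes[c("chrom", "start", "end")]
  cat_sets <- list(
    CDS = index$cds,
    UTR = index$utr,
    intron = body,             # body hit not in exon resolves to intron below
    promoter = promoter_regions(index, promoter_bp)
  )
  category <- rep("intergenic", nrow(positions))
  unassigned <- rep(TRUE, nrow(positions))
  for (cat in precedence) {
    set <- cat_sets[[cat]]
    if (nrow(set) == 0) next
    hit <- IRanges::overlapsAny(pg, as_granges0(set), ignore.strand = TRUE)
    take <- unassigned & hit
    category[take] <- cat
    unassigned <- unassigned & !hit
  }
  mutate(as_tibble(positions), category = category)
}
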