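#' Map differentially marked regions to genes
#'
#' A gene is differentially marked (method 1) when a passing region
#' overlaps its gene body by at least one base; optionally the promoter is
#' included in the footprint. When several regions support one gene, the
#' direction comes from the region with the smallest p-value (ties broken
#' by larger |log2FC|, then lexicographic region id).
#'
#' @param dmr_result Differential table over regions (from
#'   [nb_exact_test()] + [call_differential()], or `tidy()` of a
#'   [diff_test()]); `row_id` must match `regions$region_id`.
#' @param regions Region tibble (`region_id, chrom, start, end`).
#' @param index An [annotation_index()].
#' @param include_promoters Also match regions overlapping promoters
#'   (default FALSE).
#' @param promoter_bp Promoter window when `include_promoters` is TRUE.
#' @return Tibble `gene_id, direction, p_value, log2fc, region_id`,
#'   one row per differentially marked gene.
#' @export
dmrs_to_genes <- function(dmr_result, regions, index,
                          include_promoters = FALSE, promoter_bp = 3000) {
  stopifnot(inherits(index, "annotation_index"))
  pass <- filter(dmr_result, .data$passes)
  footprint <- gene_body_regions(index)
  if (include_promoters) {
    footprint <- bind_rows(footprint, promoter_regions(index, promoter_bp))
  }
  empty <- tibble(gene_id = character(), direction = character(),
                  p_value = numeric(), log2fc = numeric(),
                  region_id = character())
  if (nrow(pass) == 0) return(empty)
  reg <- regions[match(pass$row_id, regions$region_id), ]
  if (anyNA(reg$region_id)) abort("dmr_result row_id not found in regions")
  hits <- GenomicRanges::findOverlaps(as_granges0(reg),
                                      as_granges0(footprint),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  tibble(gene_id = footprint$gene_id[S4Vectors::subjectHits(hits)],
         region_id = reg$region_id[S4Vectors::queryHits(hits)],
         p_value = pass$p_value[S4Vectors::queryHits(hits)],
         log2fc = pass$log2fc[S4Vectors::queryHits(hits)]) |>
    distinct() |>
    arrange(.data$p_value, desc(abs(.data$log2fc)), .data$region_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    select("gene_id", "direction", "p_value", "log2fc", "region_id")
}

# extract the passing-gene table of one diff_test whose rows are genes
passing_genes <- function(fit) {
  tidy(fit) |>
    filter(.data$passes) |>
    select(gene_id = "row_id", "direction", "p_value", "log2fc")
}

#' Differentially marked genes from promoter and gene-body counts
#'
#' Method 2 of differential marking: per-sample tags are counted in each
#' gene's promoter (3 kb upstream of the TSS) and gene body (TSS to TES),
#' and each of the two count matrices is run independently through the
#' full differential chain (TMM, dispersion, exact test, permutation
#' fold-change cutoff).
#'
#' @param tag_sets Named list of per-sample tag tibbles.
#' @param index An [annotation_index()].
#' @param samples Sample sheet tibble (`sample_id, group`); sample ids
#'   must name `tag_sets`.
#' @param promoter_bp Promoter window (default 3000).
#' @param ... Passed to [diff_test()] (alpha, mode, seed, ...).
#' @return List with `promoter` and `body` [diff_test()] fits and
#'   `promoter_genes` / `body_genes` passing-gene tibbles.
#' @export
promoter_genebody_dmgs <- function(tag_sets, index, samples,
                                   promoter_bp = 3000, ...) {
  check_sample_sheet(samples)
  stopifnot(all(samples$sample_id %in% names(tag_sets)))
  tag_sets <- tag_sets[samples$sample_id]
  prom <- promoter_regions(index, promoter_bp) |>
    mutate(region_id = .data$gene_id)
  body <- gene_body_regions(index) |>
    mutate(region_id = .data$gene_id)
  fit_p <- diff_test(count_tag_matrix(tag_sets, prom), samples, ...)
  fit_b <- diff_test(count_tag_matrix(tag_sets, body), samples, ...)
  list(promoter = fit_p, body = fit_b,
       promoter_genes = passing_genes(fit_p),
       body_genes = passing_genes(fit_b))
}

#' Combine the two differential-marking methods
#'
#' Takes the union of the region-overlap gene set (method 1) and the
#' promoter / gene-body gene sets (method 2). Each gene's direction comes
#' from its most significant supporting call (smallest p across methods,
#' ties by larger |log2FC|); genes supported with conflicting directions
#' are flagged.
#'
#' @param method1,method2_promoter,method2_body Tibbles with
#'   `gene_id, direction, p_value, log2fc` (any may be empty).
#' @return Tibble `gene_id, dmg_method1, dmg_method2_promoter,
#'   dmg_method2_body, dmg, dmg_direction, dmg_p, dmg_log2fc,
#'   dmg_conflict`.
#' @export
combine_dmgs <- function(method1, method2_promoter, method2_body) {
  tag <- function(x, lab) if (is.null(x) || nrow(x) == 0) NULL else
    mutate(x, method = lab)
  all_calls <- bind_rows(tag(method1, "method1"),
                         tag(method2_promoter, "promoter"),
                         tag(method2_body, "body"))
  if (is.null(all_calls) || nrow(all_calls) == 0) {
    return(tibble(gene_id = character(), dmg_method1 = logical(),
                  dmg_method2_promoter = logical(),
                  dmg_method2_body = logical(), dmg = logical(),
                  dmg_direction = character(), dmg_p = numeric(),
                  dmg_log2fc = numeric(), dmg_conflict = logical()))
  }
  all_calls |>
    group_by(.data$gene_id) |>
    arrange(.data$p_value, desc(abs(.data$log2fc)), .data$method,
            .by_group = TRUE) |>
    summarise(dmg_method1 = any(.data$method == "method1"),
              dmg_method2_promoter = any(.data$method == "promoter"),
              dmg_method2_body = any(.data$method == "body"),
              dmg = TRUE,
              dmg_direction = first(.data$direction),
              dmg_p = first(.data$p_value),
              dmg_log2fc = first(.data$log2fc),
              dmg_conflict = dplyr::n_distinct(.data$direction) > 1,
              .groups = "drop") |>
    arrange(.data$gene_id)
}

#' Differentially expressed genes
#'
#' Applies the same statistical chain as the histone-mark side (TMM
#' normalization, common dispersion, NB exact test, permutation
#' fold-change cutoff, `p < alpha` and `|log2FC| > cutoff`) to gene-level
#' expression counts. "Up" means higher in the second group (e.g. disease
#' when groups are control/case in factor order).
#'
#' @param rna_counts Count tibble (`gene_id` or `region_id` column +
#'   sample columns).
#' @param samples Sample sheet tibble.
#' @param ... Passed to [diff_test()].
#' @return List with the [diff_test()] `fit` and the `degs` tibble
#'   (`gene_id, direction, p_value, log2fc`).
#' @export
call_degs <- function(rna_counts, samples, ...) {
  fit <- diff_test(rna_counts, samples, ...)
  list(fit = fit, degs = passing_genes(fit))
}

#' Assemble the per-gene call table
#'
#' Joins differential-marking and differential-expression calls over a
#' gene universe into one table, the input of the integration stage.
#'
#' @param gene_ids Character vector: the gene universe.
#' @param dmgs Output of [combine_dmgs()].
#' @param degs DEG tibble (`gene_id, direction, p_value, log2fc`).
#' @return Tibble with one row per gene: membership flags, directions and
#'   supporting statistics of both layers.
#' @export
gene_call_table <- function(gene_ids, dmgs, degs) {
  base <- tibble(gene_id = gene_ids)
  deg_part <- if (is.null(degs) || nrow(degs) == 0) {
    tibble(gene_id = character(), deg_direction = character(),
           deg_p = numeric(), deg_log2fc = numeric())
  } else {
    select(degs, "gene_id", deg_direction = "direction",
           deg_p = "p_value", deg_log2fc = "log2fc")
  }
  base |>
    left_join(dmgs, by = "gene_id") |>
    left_join(deg_part, by = "gene_id") |>
    mutate(across(c("dmg_method1", "dmg_method2_promoter",
                    "dmg_method2_body", "dmg", "dmg_conflict"),
                  \(x) !is.na(x) & x),
           deg = !is.na(.data$deg_direction))
}
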