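#' Divergent (inverse) histone-mark / expression gene sets
#'
#' From a per-gene call table, identifies the common epigenome (genes both
#' differentially marked and differentially expressed) and splits it into
#' the two divergent sets: expression up with mark down, and expression
#' down with mark up. Concordant genes stay in the common set but in
#' neither divergent set.
#'
#' @param calls Tibble from [gene_call_table()] (needs `gene_id, dmg, deg,
#'   dmg_direction, deg_direction`).
#' @return List of class `integration_result`: `up_mrna_down_k9`,
#'   `down_mrna_up_k9`, `inverse_total` (character vectors),
#'   `common_epigenomes`, and the per-gene `evidence` tibble restricted to
#'   the common set.
#' @export
inverse_overlap <- function(calls) {
  common <- filter(calls, .data$dmg & .data$deg)
  up_down <- common |>
    filter(.data$deg_direction == "up" & .data$dmg_direction == "down") |>
    pull("gene_id")
  down_up <- common |>
    filter(.data$deg_direction == "down" & .data$dmg_direction == "up") |>
    pull("gene_id")
  structure(list(up_mrna_down_k9 = up_down, down_mrna_up_k9 = down_up,
                 inverse_total = c(up_down, down_up),
                 common_epigenomes = common$gene_id,
                 evidence = common),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(paste0("integration_result: %d common epigenomes, ",
                     "%d divergent (%d mRNA-up/mark-down, %d mRNA-down/mark-up)\n"),
              length(x$common_epigenomes), length(x$inverse_total),
              length(x$up_mrna_down_k9), length(x$down_mrna_up_k9)))
  invisible(x)
}

#' Expression-stratified metagene occupancy profiles
#'
#' Ranks genes by their average normalized expression across all samples,
#' discards genes shorter than `min_length`, selects the `n_select` most
#' (High) and least (Low) expressed genes, and computes the metagene
#' occupancy profile of each set from the pooled tags. Ties in expression
#' are broken by gene id so the sets are reproducible.
#'
#' @param tag_sets Tag tibble or named list of per-sample tag tibbles
#'   (pooled).
#' @param rna_counts Expression count tibble (`gene_id`/`region_id` +
#'   sample columns).
#' @param index An [annotation_index()].
#' @param n_select Genes per set (default 1000; shrinks with a warning
#'   when fewer qualify).
#' @param min_length Minimum gene length in bp (default 5000).
#' @param factors Optional [tmm_factors()] output used to normalize
#'   expression before ranking (`NULL` = library-size normalization only).
#' @param flank_bp,n_bins,normalize Passed to [metagene_profile()].
#' @return List of class `stratified_profiles`: `high_profile`,
#'   `low_profile`, `high_genes`, `low_genes`.
#' @export
expression_stratified_profiles <- function(tag_sets, rna_counts, index,
                                           n_select = 1000,
                                           min_length = 5000,
                                           factors = NULL, flank_bp = 5000,
                                           n_bins = 100,
                                           normalize = "raw") {
  stopifnot(inherits(index, "annotation_index"))
  m <- count_matrix(rna_counts)
  N <- colSums(m)
  f <- factor_vector(factors, colnames(m))
  cpm <- sweep(m, 2, f * N / mean(f * N), `/`)
  expr <- tibble(gene_id = rownames(m), mean_expr = rowMeans(cpm)) |>
    inner_join(index$genes[c("gene_id", "length")], by = "gene_id") |>
    filter(.data$length >= min_length) |>
    arrange(desc(.data$mean_expr), .data$gene_id)
  if (nrow(expr) == 0) abort("no gene passes the length filter")
  if (nrow(expr) < 2 * n_select) {
    n_select <- floor(nrow(expr) / 2)
    warn(sprintf("fewer qualifying genes than requested; using %d per set",
                 n_select))
  }
  high_ids <- expr$gene_id[seq_len(n_select)]
  low_ids <- expr$gene_id[nrow(expr) + 1 - seq_len(n_select)]
  genes <- index$genes
  high <- metagene_profile(tag_sets, genes[genes$gene_id %in% high_ids, ],
                           flank_bp, n_bins, normalize, label = "high")
  low <- metagene_profile(tag_sets, genes[genes$gene_id %in% low_ids, ],
                          flank_bp, n_bins, normalize, label = "low")
  structure(list(high_profile = high, low_profile = low,
                 high_genes = high_ids, low_genes = low_ids),
            class = "stratified_profiles")
}

#' @rdname expression_stratified_profiles
#' @param object A `stratified_profiles`.
#' @param ... Unused.
#' @export
autoplot.stratified_profiles <- function(object, ...) {
  df <- bind_rows(high = as_tibble(object$high_profile),
                  low = as_tibble(object$low_profile), .id = "set")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_count,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(high = "firebrick",
                                            low = "forestgreen")) +
    ggplot2::labs(x = "metagene bin (5' → 3')", y = "mean tag count",
                  colour = "expression") +
    ggplot2::theme_minimal()
}

#' Rank correlation between histone-mark and expression levels
#'
#' Spearman (default) correlation between per-gene mean normalized mark
#' counts in the chosen region type and per-gene mean normalized
#' expression, over the shared gene universe.
#'
#' @param k9_counts Mark count tibble over genes (promoter or gene-body
#'   counts; `gene_id`/`region_id` + sample columns).
#' @param rna_counts Expression count tibble.
#' @param k9_factors,rna_factors Optional [tmm_factors()] outputs.
#' @param method Correlation method (default `"spearman"`).
#' @return Tibble `estimate, p_value, n_genes, method`.
#' @export
k9_expression_correlation <- function(k9_counts, rna_counts,
                                      k9_factors = NULL, rna_factors = NULL,
                                      method = "spearman") {
  norm_means <- function(counts, factors) {
    m <- count_matrix(counts)
    f <- factor_vector(factors, colnames(m))
    L <- f * colSums(m)
    tibble(gene_id = rownames(m),
           value = rowMeans(sweep(m, 2, mean(L) / L, `*`)))
  }
  k9 <- norm_means(k9_counts, k9_factors)
  rna <- norm_means(rna_counts, rna_factors)
  joint <- inner_join(k9, rna, by = "gene_id", suffix = c("_k9", "_rna"))
  if (nrow(joint) < 10) abort("need >= 10 shared genes")
  if (var(joint$value_k9) == 0 || var(joint$value_rna) == 0) {
    abort("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(cor.test(joint$value_k9, joint$value_rna,
                                  method = method, exact = FALSE))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n_genes = nrow(joint), method = method)
}

#' Hierarchical clustering of paired changes
#'
#' Agglomerative clustering of genes on their (mark change, expression
#' change) vectors with Ward's linkage on Euclidean distances, as used for
#' heat maps of divergent genes.
#'
#' @param changes Tibble with `gene_id` and numeric change columns
#'   (e.g. `delta_k9, delta_rna`).
#' @return List of class `change_clustering`: the `hclust` object,
#'   `leaf_order` (gene ids in dendrogram order) and `newick` string.
#' @export
cluster_changes <- function(changes) {
  stopifnot("gene_id" %in% names(changes))
  x <- as.matrix(changes[setdiff(names(changes), "gene_id")])
  if (nrow(x) < 2) abort("need >= 2 genes to cluster")
  if (anyNA(x)) abort("NA in change values")
  rownames(x) <- changes$gene_id
  hc <- hclust(dist(x), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 newick = ape::write.tree(phy)),
            class = "change_clustering")
}

#' Partition common epigenomes by cell-type marker lists
#'
#' Intersects the common-epigenome gene set with user-supplied marker gene
#' lists (e.g. neurons, astrocytes, oligodendrocytes, microglia,
#' endothelial cells from a published single-cell resource) and splits
#' each intersection by expression direction. A gene on several marker
#' lists appears under each.
#'
#' @param result An [inverse_overlap()] result (or any list with
#'   `common_epigenomes` and an `evidence` tibble carrying
#'   `deg_direction`).
#' @param marker_lists Named list: cell type -> character vector of gene
#'   ids, or a two-column tibble (`celltype, gene_id`).
#' @return Tibble `celltype, n_common, up, down` with list-columns
#'   `up_genes, down_genes`.
#' @export
celltype_partition <- function(result, marker_lists) {
  if (is.data.frame(marker_lists)) {
    marker_lists <- split(marker_lists$gene_id, marker_lists$celltype)
  }
  if (length(marker_lists) == 0) abort("empty marker map")
  ev <- result$evidence
  purrr::imap_dfr(marker_lists, function(markers, type) {
    hit <- filter(ev, .data$gene_id %in% markers)
    up_ids <- hit$gene_id[hit$deg_direction == "up"]
    down_ids <- hit$gene_id[hit$deg_direction == "down"]
    tibble(celltype = type, n_common = nrow(hit),
           up = length(up_ids), down = length(down_ids),
           up_genes = list(up_ids), down_genes = list(down_ids))
  })
}
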