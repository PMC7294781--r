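# brute-force re-derivation of the divergent sets from a call table
inverse_oracle <- function(calls) {
  up_down <- character(); down_up <- character(); common <- character()
  for (i in seq_len(nrow(calls))) {
    if (isTRUE(calls$dmg[i]) && isTRUE(calls$deg[i])) {
      common <- c(common, calls$gene_id[i])
      if (calls$deg_direction[i] == "up" && calls$dmg_direction[i] == "down")
        up_down <- c(up_down, calls$gene_id[i])
      if (calls$deg_direction[i] == "down" && calls$dmg_direction[i] == "up")
        down_up <- c(down_up, calls$gene_id[i])
    }
  }
  list(up = up_down, down = down_up, common = common)
}

test_that("divergent sets match hand enumeration on a 10-gene toy", {
  calls <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    dmg = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    deg = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    dmg_direction = c("down", "up", "up", "up", NA, NA, "down", "up", NA, "down"),
    deg_direction = c("up", "down", NA, "up", "down", NA, "up", "up", "down", NA))
  res <- inverse_overlap(calls)
  # hand evaluation: g01 (deg up, dmg down) and g07 in set (a);
  # g02 in set (b); g04/g08 concordant -> common only
  expect_setequal(res$up_mrna_down_k9, c("g01", "g07"))
  expect_setequal(res$down_mrna_up_k9, "g02")
  expect_setequal(res$common_epigenomes,
                  c("g01", "g02", "g04", "g07", "g08"))
  # invariants
  expect_length(intersect(res$up_mrna_down_k9, res$down_mrna_up_k9), 0)
  expect_true(all(res$inverse_total %in% res$common_epigenomes))
})

test_that("divergent sets equal brute force on randomized call tables", {
  for (seed in 1:10) {
    calls <- random_calls(300, seed = seed)
    res <- inverse_overlap(calls)
    want <- inverse_oracle(calls)
    expect_setequal(res$up_mrna_down_k9, want$up)
    expect_setequal(res$down_mrna_up_k9, want$down)
    expect_setequal(res$common_epigenomes, want$common)
  }
})

test_that("expression strata respect the length filter and tie-breaks", {
  genes <- tibble::tibble(
    gene_id = c("long1", "long2", "long3", "long4", "short"),
    chrom = "chr1",
    start = c(0, 20000, 40000, 60000, 80000) + 5000,
    end = c(0, 20000, 40000, 60000, 80000) + 5000 +
      c(6000, 6000, 6000, 6000, 4999),
    strand = "+")
  idx <- annotation_index(genes, chrom_sizes = c(chr1 = 2e5))
  counts <- tibble::tibble(gene_id = genes$gene_id,
                           s1 = c(100, 90, 10, 5, 1e6),
                           s2 = c(110, 95, 12, 6, 1e6))
  tags <- tibble::tibble(chrom = "chr1", pos = seq(0, 99999, 11))
  got <- expression_stratified_profiles(tags, counts, idx, n_select = 2,
                                        min_length = 5000)
  # the 4999 bp gene is never selected despite extreme expression
  expect_false("short" %in% c(got$high_genes, got$low_genes))
  expect_setequal(got$high_genes, c("long1", "long2"))
  expect_setequal(got$low_genes, c("long3", "long4"))
  expect_equal(nrow(got$high_profile), 100)
  # equal expression everywhere -> selection falls back to gene_id order
  eq <- dplyr::mutate(counts, s1 = 7, s2 = 7)
  g1 <- expression_stratified_profiles(tags, eq, idx, n_select = 2)
  g2 <- expression_stratified_profiles(tags, eq, idx, n_select = 2)
  expect_identical(g1$high_genes, g2$high_genes)
  expect_identical(g1$high_genes, c("long1", "long2"))
})

test_that("inverse level-coupling separates the stratified profiles", {
  cfg <- sim_config(n_genes = 120, chrom_sizes = c(chr1 = 4e6),
                    gene_length_range = c(6000, 20000),
                    expr_mark_coupling = -0.8, seed = 51)
  idx <- simulate_annotation(cfg)
  body <- dplyr::mutate(gene_body_regions(idx), region_id = gene_id)
  chip <- simulate_counts(cfg, body, "chip")
  rna <- simulate_counts(cfg, body, "rna")
  tags <- simulate_tags(cfg, chip$counts, body)
  got <- expression_stratified_profiles(tags, rna$counts, idx,
                                        n_select = 40, min_length = 5000,
                                        normalize = "per_bp")
  body_bins <- 35:66  # interior of the 100-bin metagene
  expect_lt(mean(got$high_profile$mean_count[body_bins]),
            mean(got$low_profile$mean_count[body_bins]))
})

test_that("rank correlation behaves on constructed and null data", {
  k9 <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), s1 = 20:1)
  rna <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), s1 = 1:20)
  perfect <- k9_expression_correlation(k9, rna)
  expect_equal(perfect$estimate, -1)
  expect_error(
    k9_expression_correlation(dplyr::mutate(k9, s1 = 5), rna),
    "constant")
  # null: mostly non-significant small correlations
  ids <- sprintf("h%02d", 1:50)
  hits <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- tibble::tibble(gene_id = ids, s1 = rpois(50, 100))
      b <- tibble::tibble(gene_id = ids, s1 = rpois(50, 100))
    })
    if (k9_expression_correlation(a, b)$p_value < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 2)  # >= 90% of null replicates non-significant
})

test_that("coupled simulations yield a negative mark-expression correlation", {
  cfg <- sim_config(n_genes = 150, chrom_sizes = c(chr1 = 5e6), seed = 52)
  idx <- simulate_annotation(cfg)
  body <- dplyr::mutate(gene_body_regions(idx), region_id = gene_id)
  chip <- simulate_counts(cfg, body, "chip")
  rna <- simulate_counts(cfg, body, "rna")
  got <- k9_expression_correlation(chip$counts, rna$counts)
  expect_lt(got$estimate, -0.3)
  expect_lt(got$p_value, 0.01)
})

test_that("Ward clustering matches the Lance-Williams oracle", {
  # identical points merge at height zero
  same <- tibble::tibble(gene_id = c("a", "b"), d1 = 1, d2 = 2)
  cl <- cluster_changes(same)
  expect_equal(cl$hclust$height, 0)
  # 5-point toy: merge heights equal the independent Ward recursion
  withr::with_seed(61, {
    pts <- tibble::tibble(gene_id = paste0("p", 1:5),
                          d1 = rnorm(5), d2 = rnorm(5))
  })
  cl5 <- cluster_changes(pts)
  x <- as.matrix(pts[, c("d1", "d2")])
  expect_equal(cl5$hclust$height, ward_heights_oracle(x), tolerance = 1e-10)
  # well-separated blocks are recovered by a 2-cut
  blocks <- tibble::tibble(gene_id = paste0("g", 1:20),
                           d1 = rep(c(-5, 5), each = 10) + rnorm(20, sd = 0.1),
                           d2 = rep(c(5, -5), each = 10) + rnorm(20, sd = 0.1))
  clb <- cluster_changes(blocks)
  grp <- stats::cutree(clb$hclust, k = 2)
  expect_equal(length(unique(grp[1:10])), 1)
  expect_equal(length(unique(grp[11:20])), 1)
  expect_true(grp[1] != grp[11])
  # newick export carries every leaf
  expect_true(all(vapply(paste0("g", 1:20), grepl, TRUE, x = clb$newick,
                         fixed = TRUE)))
  expect_error(cluster_changes(dplyr::mutate(same, d1 = NA)), "NA")
})

test_that("cell-type partitions split the common set by direction", {
  calls <- tibble::tibble(
    gene_id = c("n1", "n2", "n3", "a1", "x1"),
    dmg = TRUE, deg = TRUE,
    dmg_direction = c("down", "down", "up", "down", "up"),
    deg_direction = c("up", "up", "down", "up", "down"))
  res <- inverse_overlap(calls)
  markers <- list(neuron = c("n1", "n2", "n3", "absent"),
                  astrocyte = c("a1", "n1"),
                  microglia = "nothing")
  part <- celltype_partition(res, markers)
  neu <- part[part$celltype == "neuron", ]
  expect_equal(c(neu$up, neu$down), c(2, 1))
  expect_setequal(neu$up_genes[[1]], c("n1", "n2"))
  # shared marker appears under both cell types
  ast <- part[part$celltype == "astrocyte", ]
  expect_equal(ast$n_common, 2)
  # disjoint marker list gives an empty partition
  mic <- part[part$celltype == "microglia", ]
  expect_equal(c(mic$n_common, mic$up, mic$down), c(0, 0, 0))
  expect_error(celltype_partition(res, list()), "empty marker")
})
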