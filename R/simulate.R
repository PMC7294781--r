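#' Simulation configuration
#'
#' Collects the parameters of the synthetic two-group epigenome/transcriptome
#' generator. Defaults emulate a desk-scale version of a 6-vs-6 postmortem
#' brain design: negative-binomial counts with dispersion 0.1, mean region
#' count ~100, 10% of genes carrying a histone-mark effect, 15% an
#' expression effect, and half of the smaller effect set inversely coupled
#' (mark up / expression down or vice versa) at |log2FC| = 2.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (two groups).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param gene_length_range Gene lengths are drawn log-uniformly in this
#'   range (bp); the default 2-50 kb yields both genes below and above the
#'   5 kb profile filter.
#' @param library_size_mean Expected total on-region count per sample;
#'   `NULL` means `100 * n_regions` so the average region mean is 100.
#' @param library_size_cv Coefficient of variation of per-sample library
#'   scale factors (lognormal).
#' @param dispersion Negative-binomial dispersion phi (0 = Poisson).
#' @param baseline_logmean_range Per-gene baseline abundance spread: the
#'   range, in log2 units around the common mean, covered by +/- 2 sd of
#'   the latent per-gene abundance; `c(0, 0)` makes all regions equal.
#' @param expr_mark_coupling Correlation in (-1, 1) between a gene's
#'   latent mark abundance and its latent expression abundance (default
#'   -0.6: the repressive-mark case, highly expressed genes carry less
#'   mark).
#' @param frac_chip_effect,frac_rna_effect Fractions of genes with a planted
#'   histone-mark / expression effect.
#' @param frac_inverse_coupled Fraction of the smaller effect set planted
#'   with opposite-sign mark and expression effects.
#' @param effect_log2fc Magnitude of planted effects (log2).
#' @param background_per_bp Genome-wide background tag rate (tags/bp) used
#'   by [simulate_tags()].
#' @param seed Integer seed; every generator draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_per_group = 6,
                       chrom_sizes = c(chr1 = 4e6, chr2 = 4e6),
                       gene_length_range = c(2000, 50000),
                       library_size_mean = NULL, library_size_cv = 0.2,
                       dispersion = 0.1,
                       baseline_logmean_range = c(-1.5, 1.5),
                       expr_mark_coupling = -0.6,
                       frac_chip_effect = 0.10, frac_rna_effect = 0.15,
                       frac_inverse_coupled = 0.5, effect_log2fc = 2,
                       background_per_bp = 0, seed = 1) {
  stopifnot(n_genes >= 1, n_per_group >= 2, dispersion >= 0,
            all(c(frac_chip_effect, frac_rna_effect, frac_inverse_coupled)
                >= 0),
            all(c(frac_chip_effect, frac_rna_effect, frac_inverse_coupled)
                <= 1),
            effect_log2fc >= 0, library_size_cv >= 0,
            abs(expr_mark_coupling) <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic sub-seed per stage so stages are independently reproducible
sub_seed <- function(seed, stage) {
  (seed * 1009L + match(stage, c("annotation", "truth", "chip", "rna",
                                 "tags", "latent")) * 7919L) %% .Machine$integer.max
}

# latent per-gene log-abundance, shared between layers so the mark level
# can be coupled to the expression level; keyed by sorted gene id
latent_abundance <- function(config, gene_ids) {
  sug <- sort(unique(gene_ids))
  z <- withr::with_seed(sub_seed(config$seed, "latent"),
                        stats::rnorm(length(sug)))
  setNames(z, sug)
}

#' Simulate a toy genome annotation
#'
#' Places `n_genes` non-overlapping genes (random strand, log-uniform
#' lengths) along the configured chromosomes with enough spacing for 3 kb
#' promoters and 5 kb profile flanks. Each gene gets 1-5 exons anchored at
#' the gene ends and a CDS occupying the inner part of its exons.
#'
#' @param config A [sim_config()].
#' @return An [annotation_index()].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, "annotation"), {
    lr <- log(config$gene_length_range)
    lens <- round(exp(runif(config$n_genes, lr[1], lr[2])))
    gaps <- round(runif(config$n_genes, 9000, 16000))
    chroms <- names(config$chrom_sizes)
    gene_rows <- vector("list", config$n_genes)
    ci <- 1; cursor <- 5000
    for (i in seq_len(config$n_genes)) {
      if (cursor + lens[i] + 5000 > config$chrom_sizes[ci]) {
        ci <- ci + 1; cursor <- 5000
        if (ci > length(chroms)) {
          abort("chromosomes too small for the requested number of genes")
        }
      }
      gene_rows[[i]] <- tibble(
        gene_id = sprintf("g%04d", i), chrom = chroms[ci],
        start = cursor, end = cursor + lens[i],
        strand = sample(c("+", "-"), 1))
      cursor <- cursor + lens[i] + gaps[i]
    }
    genes <- bind_rows(gene_rows)
    exons <- purrr::pmap_dfr(genes, function(gene_id, chrom, start, end, strand) {
      len <- end - start
      n_ex <- sample(1:5, 1)
      if (n_ex == 1 || len < 400 * n_ex) {
        return(tibble(gene_id = gene_id, chrom = chrom, start = start, end = end))
      }
      # n_ex exon blocks separated by introns; first/last anchored at gene ends
      cuts <- sort(sample(seq(start + 100, end - 100, by = 50),
                          2 * (n_ex - 1), replace = FALSE))
      bounds <- c(start, cuts, end)
      idx <- seq(1, length(bounds) - 1, by = 2)
      tibble(gene_id = gene_id, chrom = chrom,
             start = bounds[idx], end = bounds[idx + 1])
    })
    # CDS: trim 20% of exonic bp from each end of the exon chain
    cds <- exons |>
      group_by(.data$gene_id) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(exlen = .data$end - .data$start,
             cum0 = cumsum(dplyr::lag(.data$exlen, default = 0)),
             total = sum(.data$exlen),
             lo = 0.2 * .data$total, hi = 0.8 * .data$total,
             cs = .data$start + pmax(0, .data$lo - .data$cum0),
             ce = .data$start + pmin(.data$exlen, .data$hi - .data$cum0)) |>
      ungroup() |>
      filter(.data$cs < .data$ce) |>
      mutate(start = floor(.data$cs), end = ceiling(.data$ce)) |>
      select("gene_id", "chrom", "start", "end")
    annotation_index(genes, exons, cds, chrom_sizes = config$chrom_sizes)
  })
}

#' Plant ground-truth effects per gene
#'
#' Partitions genes into an inversely coupled set (opposite-sign mark and
#' expression effects), mark-only and expression-only sets, all disjoint;
#' remaining genes are null. Truth flags are computed from the planted
#' values, so `is_inverse_truth` always implies opposite nonzero signs.
#'
#' @param config A [sim_config()].
#' @param gene_ids Gene identifiers to plant over.
#' @return Tibble `gene_id, chip_log2fc, rna_log2fc, is_dmg_truth,
#'   is_deg_truth, is_inverse_truth`.
#' @export
simulate_truth <- function(config, gene_ids) {
  n <- length(gene_ids)
  withr::with_seed(sub_seed(config$seed, "truth"), {
    n_chip <- round(config$frac_chip_effect * n)
    n_rna <- round(config$frac_rna_effect * n)
    n_inv <- round(config$frac_inverse_coupled * min(n_chip, n_rna))
    ids <- sample(gene_ids)
    inv <- ids[seq_len(n_inv)]
    chip_only <- ids[n_inv + seq_len(n_chip - n_inv)]
    rna_only <- ids[n_chip + seq_len(n_rna - n_inv)]
    d <- config$effect_log2fc
    chip_fc <- setNames(rep(0, n), gene_ids)
    rna_fc <- setNames(rep(0, n), gene_ids)
    inv_sign <- sample(c(-1, 1), n_inv, replace = TRUE)
    chip_fc[inv] <- inv_sign * d
    rna_fc[inv] <- -inv_sign * d
    chip_fc[chip_only] <- sample(c(-1, 1), length(chip_only), TRUE) * d
    rna_fc[rna_only] <- sample(c(-1, 1), length(rna_only), TRUE) * d
    tibble(
      gene_id = gene_ids,
      chip_log2fc = unname(chip_fc[gene_ids]),
      rna_log2fc = unname(rna_fc[gene_ids]),
      is_dmg_truth = chip_fc[gene_ids] != 0,
      is_deg_truth = rna_fc[gene_ids] != 0,
      is_inverse_truth = chip_fc[gene_ids] * rna_fc[gene_ids] < 0
    )
  })
}

#' Simulate a two-group count matrix over regions
#'
#' Counts are drawn NB(mean = s_k * mu_g * 2^(+/- delta_g / 2), dispersion
#' phi): the planted log2 effect delta_g is split as opposite half-effects
#' between the groups so overall abundance stays comparable. Group B carries
#' the positive half, so delta_g > 0 means higher in group B.
#'
#' @param config A [sim_config()].
#' @param regions Tibble of regions with `region_id` and (for planted
#'   effects) a `gene_id` column; regions without a gene are null.
#' @param layer `"chip"` or `"rna"` — selects which truth column drives the
#'   planted effect and the RNG stream.
#' @param truth Truth table from [simulate_truth()]; `NULL` plants nothing.
#' @return List with `counts` (tibble: region_id + one column per sample),
#'   `samples` (sample sheet tibble) and `truth`.
#' @export
simulate_counts <- function(config, regions, layer = c("chip", "rna"),
                            truth = NULL) {
  layer <- match.arg(layer)
  stopifnot(inherits(config, "sim_config"))
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions, region_id = .data$gene_id)
  }
  n_reg <- nrow(regions)
  n <- 2 * config$n_per_group
  samples <- tibble(
    sample_id = c(sprintf("C%d", seq_len(config$n_per_group)),
                  sprintf("A%d", seq_len(config$n_per_group))),
    group = rep(c("control", "case"), each = config$n_per_group)
  )
  delta <- rep(0, n_reg)
  if (!is.null(truth) && "gene_id" %in% names(regions)) {
    fc_col <- if (layer == "chip") "chip_log2fc" else "rna_log2fc"
    m <- match(regions$gene_id, truth$gene_id)
    delta <- ifelse(is.na(m), 0, truth[[fc_col]][m])
  }
  withr::with_seed(sub_seed(config$seed, layer), {
    lsm <- config$library_size_mean
    if (is.null(lsm)) lsm <- 100 * n_reg
    spread_sd <- diff(range(config$baseline_logmean_range)) / 4
    x <- if ("gene_id" %in% names(regions) && !anyNA(regions$gene_id)) {
      # per-gene abundance; the mark layer is coupled to the latent
      # expression abundance with correlation expr_mark_coupling
      sug <- sort(unique(regions$gene_id))
      z <- latent_abundance(config, sug)
      e <- setNames(stats::rnorm(length(sug)), sug)
      rho <- if (layer == "chip") config$expr_mark_coupling else 1
      unname((rho * z + sqrt(1 - rho^2) * e)[regions$gene_id])
    } else {
      stats::rnorm(n_reg)
    }
    w <- 2^(x * spread_sd)
    mu_g <- w / sum(w) * lsm
    cv <- config$library_size_cv
    sdlog <- sqrt(log(1 + cv^2))
    s_k <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    half <- outer(delta / 2, ifelse(samples$group == "case", 1, -1))
    mu <- (mu_g %o% s_k) * 2^half
    counts <- if (config$dispersion > 0) {
      matrix(rnbinom(n_reg * n, size = 1 / config$dispersion, mu = mu),
             n_reg, n)
    } else {
      matrix(rpois(n_reg * n, mu), n_reg, n)
    }
    out <- as_tibble(setNames(as.data.frame(counts), samples$sample_id))
    out <- bind_cols(tibble(region_id = regions$region_id), out)
    list(counts = out, samples = samples, truth = truth)
  })
}

#' Simulate per-base tags consistent with a count matrix
#'
#' For every region x sample cell, places exactly that many single-base tags
#' uniformly at random within the region, plus optional uniform genome-wide
#' background at `config$background_per_bp` tags per bp. Re-counting the
#' tags in the generating regions reproduces the count matrix exactly when
#' the background rate is zero.
#'
#' @param config A [sim_config()].
#' @param counts Count tibble (`region_id` + sample columns) as produced by
#'   [simulate_counts()].
#' @param regions Region tibble with `region_id, chrom, start, end`.
#' @return Named list of per-sample tag tibbles
#'   (`chrom, pos, strand`), sorted by position.
#' @export
simulate_tags <- function(config, counts, regions) {
  check_intervals(regions, "regions")
  m <- count_matrix(counts, "region_id")
  regions <- regions[match(rownames(m), regions$region_id), ]
  withr::with_seed(sub_seed(config$seed, "tags"), {
    lapply(setNames(colnames(m), colnames(m)), function(s) {
      k <- m[, s]
      pos <- floor(runif(sum(k),
                         rep(regions$start, k), rep(regions$end, k)))
      tags <- tibble(chrom = rep(regions$chrom, k), pos = pos)
      if (config$background_per_bp > 0) {
        nbg <- rpois(length(config$chrom_sizes),
                     config$background_per_bp * config$chrom_sizes)
        bg <- tibble(
          chrom = rep(names(config$chrom_sizes), nbg),
          pos = floor(runif(sum(nbg), 0,
                            rep(config$chrom_sizes, nbg))))
        tags <- bind_rows(tags, bg)
      }
      tags |>
        mutate(strand = ".") |>
        arrange(.data$chrom, .data$pos)
    })
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes one simulated study: BED12 annotation + chromosome sizes,
#' per-sample tag BED files (from promoter+gene-body mark counts), RNA count
#' matrix, ChIP promoter/body count matrices, truth table, sample sheet,
#' the realized configuration (JSON) and a manifest with md5 checksums.
#' Identical configurations produce byte-identical trees.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- simulate_annotation(config)
  truth <- simulate_truth(config, index$genes$gene_id)

  prom <- promoter_regions(index) |>
    mutate(region_id = paste0(.data$gene_id, ":prom"))
  body <- gene_body_regions(index) |>
    mutate(region_id = paste0(.data$gene_id, ":body"))
  chip_regions <- bind_rows(prom, body)
  chip <- simulate_counts(config, chip_regions, "chip", truth)
  rna <- simulate_counts(config, gene_body_regions(index), "rna", truth)
  tags <- simulate_tags(config, chip$counts, chip_regions)

  write_annotation_bed12(index, file.path(dir, "annotation.bed"))
  readr::write_tsv(tibble(chrom = names(index$chrom_sizes),
                          size = unname(index$chrom_sizes)),
                   file.path(dir, "chrom_sizes.tsv"), col_names = FALSE,
                   progress = FALSE)
  for (s in names(tags)) {
    write_tags_bed(tags[[s]], file.path(dir, sprintf("tags_%s.bed", s)))
  }
  write_tsv_plain(chip$counts, file.path(dir, "chip_counts.tsv"))
  write_tsv_plain(rna$counts, file.path(dir, "rna_counts.tsv"))
  write_tsv_plain(truth, file.path(dir, "truth.tsv"))
  write_tsv_plain(rna$samples, file.path(dir, "samples.tsv"))
  cfg <- config
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- tibble(file = files,
                     md5 = unname(vapply(file.path(dir, files), md5_file, "")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_annotation_bed12 <- function(index, path) {
  ex <- index$exons |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(blockCount = n(),
              blockSizes = paste0(.data$end - .data$start, collapse = ","),
              blockStarts = paste0(.data$start - min(.data$start),
                                   collapse = ","),
              .groups = "drop")
  cds <- index$cds |>
    group_by(.data$gene_id) |>
    summarise(thickStart = min(.data$start), thickEnd = max(.data$end),
              .groups = "drop")
  g <- index$genes |>
    left_join(ex, by = "gene_id") |>
    left_join(cds, by = "gene_id") |>
    mutate(thickStart = ifelse(is.na(.data$thickStart), .data$start,
                               .data$thickStart),
           thickEnd = ifelse(is.na(.data$thickEnd), .data$start,
                             .data$thickEnd))
  bed <- tibble(chrom = g$chrom, start = g$start, end = g$end,
                name = g$gene_id, score = 0, strand = g$strand,
                thickStart = g$thickStart, thickEnd = g$thickEnd,
                rgb = "0,0,0", blockCount = g$blockCount,
                blockSizes = g$blockSizes, blockStarts = g$blockStarts)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
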