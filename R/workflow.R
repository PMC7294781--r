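#' Workflow parameters
#'
#' All tunable parameters of the end-to-end analysis, with the package
#' defaults: 3 kb promoters, 5 kb metagene flanks and 100 bins, 1000-gene
#' expression strata with a 5 kb length filter, p < .05 with a 1000-round
#' permutation fold-change cutoff at the 10th percentile (literal mode),
#' 1 kb scan windows at Poisson p < 1e-3 and >= 2-sample consensus.
#'
#' @param alpha Significance level on raw p-values.
#' @param n_permutations,percentile,mode,prior_count See
#'   [permutation_fc_cutoff()].
#' @param dispersion `"moments"`, `"profile"`, or a numeric phi.
#' @param promoter_bp,flank_bp,n_bins,n_select,min_length Region and
#'   profile geometry.
#' @param window_bp,p_threshold,merge_gap_bp,min_support Domain calling
#'   and consensus.
#' @param seed Integer seed governing the permutation draws.
#' @return A named list of class `workflow_params`.
#' @export
workflow_params <- function(alpha = 0.05, n_permutations = 1000,
                            percentile = 0.10, mode = "literal",
                            prior_count = 0.5, dispersion = "moments",
                            promoter_bp = 3000, flank_bp = 5000,
                            n_bins = 100, n_select = 1000,
                            min_length = 5000, window_bp = 1000,
                            p_threshold = 1e-3, merge_gap_bp = 1000,
                            min_support = 2, seed = 1) {
  structure(as.list(environment()), class = "workflow_params")
}

#' Read workflow parameters from a YAML file
#'
#' Values in the file override the defaults; arguments passed in `...`
#' override the file (precedence: call > file > defaults).
#'
#' @param path YAML file whose keys are [workflow_params()] names.
#' @param ... Overrides.
#' @return A `workflow_params` list.
#' @export
read_workflow_params <- function(path = NULL, ...) {
  p <- workflow_params()
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    bad <- setdiff(names(y), names(p))
    if (length(bad)) abort(sprintf("unknown parameter '%s'", bad[1]))
    p[names(y)] <- y
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) abort(sprintf("unknown parameter '%s'", bad[1]))
  p[names(dots)] <- dots
  structure(p, class = "workflow_params")
}

params_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(params), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full integrative workflow
#'
#' Executes every stage in dependency order on a dataset directory laid
#' out as written by [simulate_dataset()] (BED12 annotation, chromosome
#' sizes, per-sample tag BEDs, RNA count matrix, sample sheet): domain
#' calling per sample, >= 2-sample consensus regions, differential marking
#' of consensus regions (method 1, mapped to genes by overlap), of
#' promoters and gene bodies (method 2), the DMG union, DEG calling, the
#' divergent-gene integration, mark/expression correlation,
#' expression-stratified metagene profiles, and Ward clustering of the
#' divergent genes' changes. All result tables are written as TSV (plus
#' BED and Newick where appropriate) together with a metadata JSON
#' carrying the parameter hash and per-file checksums. Identical inputs,
#' parameters and seed give byte-identical outputs.
#'
#' @param input_dir Dataset directory.
#' @param output_dir Results directory (created).
#' @param params A [workflow_params()] list.
#' @param markers Optional cell-type marker lists for
#'   [celltype_partition()] (named list or `celltype, gene_id` tibble).
#' @param resume When TRUE, a stage whose output files already exist is
#'   loaded from disk instead of recomputed, so deleting an intermediate
#'   regenerates only it and its dependents.
#' @return Invisibly, a list with the main result tables.
#' @export
run_workflow <- function(input_dir, output_dir, params = workflow_params(),
                         markers = NULL, resume = FALSE) {
  stopifnot(inherits(params, "workflow_params"))
  for (f in c("annotation.bed", "samples.tsv", "rna_counts.tsv")) {
    if (!file.exists(file.path(input_dir, f))) {
      abort(sprintf("missing input file '%s'", f))
    }
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  have <- function(...) all(file.exists(out(...)))

  index <- read_annotation(file.path(input_dir, "annotation.bed"),
                           chrom_sizes = file.path(input_dir, "chrom_sizes.tsv"))
  samples <- readr::read_tsv(file.path(input_dir, "samples.tsv"),
                             col_types = "cc", progress = FALSE)
  check_sample_sheet(samples)
  rna_counts <- readr::read_tsv(file.path(input_dir, "rna_counts.tsv"),
                                col_types = readr::cols(
                                  region_id = "c", .default = "d"),
                                progress = FALSE)
  tag_files <- file.path(input_dir, sprintf("tags_%s.bed", samples$sample_id))
  if (!all(file.exists(tag_files))) abort("missing tag BED for a sample")
  tag_sets <- setNames(lapply(tag_files, read_tags), samples$sample_id)

  diff_args <- list(alpha = params$alpha, dispersion = params$dispersion,
                    n_permutations = params$n_permutations,
                    percentile = params$percentile, mode = params$mode,
                    prior_count = params$prior_count)

  # stage: per-sample domain calling
  peak_files <- sprintf("peaks_%s.bed", samples$sample_id)
  if (resume && have(peak_files)) {
    peak_sets <- setNames(lapply(out(peak_files), read_bed_regions),
                          samples$sample_id)
  } else {
    peak_sets <- lapply(tag_sets, call_domains,
                        chrom_sizes = index$chrom_sizes,
                        window_bp = params$window_bp,
                        p_threshold = params$p_threshold,
                        merge_gap_bp = params$merge_gap_bp)
    for (s in samples$sample_id) {
      ps <- peak_sets[[s]]
      write_bed_regions(ps, out(sprintf("peaks_%s.bed", s)),
                        score = round(-log10(pmax(ps$p_value, 1e-300)), 3))
    }
  }

  # stage: consensus regions
  if (resume && have("consensus_regions.bed")) {
    consensus <- read_bed_regions(out("consensus_regions.bed")) |>
      rename(region_id = "name", support = "score")
  } else {
    consensus <- consensus_regions(peak_sets,
                                   min_support = params$min_support)
    write_bed_regions(consensus, out("consensus_regions.bed"))
  }

  # stage: differential marking and expression
  diff_files <- c("dmr_table.tsv", "promoter_table.tsv", "body_table.tsv",
                  "deg_table.tsv", "stats_summary.tsv", "norm_factors.tsv")
  if (resume && have(diff_files)) {
    dmr_table <- readr::read_tsv(out("dmr_table.tsv"),
                                 col_types = readr::cols(
                                   row_id = "c", direction = "c",
                                   passes = "l", .default = "d"),
                                 progress = FALSE)
    prom_table <- readr::read_tsv(out("promoter_table.tsv"),
                                  col_types = readr::cols(
                                    row_id = "c", direction = "c",
                                    passes = "l", .default = "d"),
                                  progress = FALSE)
    body_table <- readr::read_tsv(out("body_table.tsv"),
                                  col_types = readr::cols(
                                    row_id = "c", direction = "c",
                                    passes = "l", .default = "d"),
                                  progress = FALSE)
    deg_table <- readr::read_tsv(out("deg_table.tsv"),
                                 col_types = readr::cols(
                                   row_id = "c", direction = "c",
                                   passes = "l", .default = "d"),
                                 progress = FALSE)
    stats_summary <- readr::read_tsv(out("stats_summary.tsv"),
                                     progress = FALSE,
                                     col_types = readr::cols())
  } else {
    fits <- list()
    if (nrow(consensus) > 0) {
      chip_counts <- count_tag_matrix(tag_sets, consensus)
      fits$dmr <- do.call(diff_test, c(list(chip_counts, samples,
                                            seed = params$seed), diff_args))
      dmr_table <- tidy(fits$dmr)
    } else {
      dmr_table <- call_differential(
        tibble(row_id = character(), log2fc = numeric(),
               p_value = numeric(), mean_A = numeric(), mean_B = numeric()))
    }
    m2 <- do.call(promoter_genebody_dmgs,
                  c(list(tag_sets, index, samples,
                         promoter_bp = params$promoter_bp,
                         seed = params$seed + 1L), diff_args))
    fits$promoter <- m2$promoter
    fits$body <- m2$body
    prom_table <- tidy(m2$promoter)
    body_table <- tidy(m2$body)
    deg <- do.call(call_degs, c(list(rna_counts, samples,
                                     seed = params$seed + 2L), diff_args))
    fits$deg <- deg$fit
    deg_table <- tidy(deg$fit)
    stats_summary <- purrr::imap_dfr(fits, \(f, nm) mutate(glance(f),
                                                           layer = nm,
                                                           .before = 1))
    norm_factors <- purrr::imap_dfr(fits, \(f, nm) mutate(f$factors,
                                                          layer = nm,
                                                          .before = 1))
    write_tsv_plain(norm_factors, out("norm_factors.tsv"))
    write_tsv_plain(dmr_table, out("dmr_table.tsv"))
    write_tsv_plain(prom_table, out("promoter_table.tsv"))
    write_tsv_plain(body_table, out("body_table.tsv"))
    write_tsv_plain(deg_table, out("deg_table.tsv"))
    write_tsv_plain(stats_summary, out("stats_summary.tsv"))
  }

  # stage: gene-level calls
  pass_tbl <- function(tbl) tbl |>
    filter(.data$passes) |>
    select(gene_id = "row_id", "direction", "p_value", "log2fc")
  if (resume && have("gene_calls.tsv")) {
    calls <- readr::read_tsv(out("gene_calls.tsv"),
                             col_types = readr::cols(
                               gene_id = "c", dmg_direction = "c",
                               deg_direction = "c", region_id = "c",
                               dmg_method1 = "l", dmg_method2_promoter = "l",
                               dmg_method2_body = "l", dmg = "l",
                               deg = "l", dmg_conflict = "l",
                               .default = "d"),
                             progress = FALSE)
  } else {
    method1 <- dmrs_to_genes(dmr_table, consensus, index)
    dmgs <- combine_dmgs(method1, pass_tbl(prom_table), pass_tbl(body_table))
    calls <- gene_call_table(index$genes$gene_id, dmgs, pass_tbl(deg_table))
    write_tsv_plain(calls, out("gene_calls.tsv"))
  }

  # per-sample genomic occupancy of the mark
  occupancy <- purrr::imap_dfr(tag_sets, function(t, s) {
    oc <- occupancy_proportions(t, index, params$promoter_bp)
    bind_rows(mutate(oc$top_level, level = "genome"),
              mutate(oc$gene_body, level = "gene_body")) |>
      mutate(sample_id = s, .before = 1)
  })
  write_tsv_plain(occupancy, out("occupancy.tsv"))

  # stage: integration
  integ <- inverse_overlap(calls)
  inverse_tbl <- bind_rows(
    tibble(gene_id = integ$up_mrna_down_k9, set = "up_mrna_down_k9"),
    tibble(gene_id = integ$down_mrna_up_k9, set = "down_mrna_up_k9"))
  write_tsv_plain(inverse_tbl, out("inverse_sets.tsv"))
  write_tsv_plain(integ$evidence, out("common_epigenomes.tsv"))

  body_regions <- gene_body_regions(index) |>
    mutate(region_id = .data$gene_id)
  body_counts <- count_tag_matrix(tag_sets, body_regions)
  corr <- k9_expression_correlation(body_counts, rna_counts,
                                    k9_factors = tmm_factors(body_counts),
                                    rna_factors = tmm_factors(rna_counts))
  write_tsv_plain(corr, out("correlation.tsv"))

  strat <- withr::with_options(list(warn = -1), expression_stratified_profiles(
    tag_sets, rna_counts, index, n_select = params$n_select,
    min_length = params$min_length, flank_bp = params$flank_bp,
    n_bins = params$n_bins))
  prof_tbl <- bind_rows(high = as_tibble(strat$high_profile),
                        low = as_tibble(strat$low_profile), .id = "set")
  write_tsv_plain(prof_tbl, out("stratified_profiles.tsv"))

  if (length(integ$inverse_total) >= 2) {
    ch <- integ$evidence |>
      filter(.data$gene_id %in% integ$inverse_total) |>
      select("gene_id", delta_k9 = "dmg_log2fc", delta_rna = "deg_log2fc")
    clust <- cluster_changes(ch)
    writeLines(clust$newick, out("divergent_dendrogram.nwk"))
  } else clust <- NULL

  celltypes <- NULL
  if (!is.null(markers)) {
    celltypes <- celltype_partition(integ, markers)
    write_tsv_plain(select(celltypes, -"up_genes", -"down_genes"),
                    out("celltype_partition.tsv"))
  }

  files <- sort(setdiff(list.files(output_dir), "metadata.json"))
  meta <- list(
    params = unclass(params),
    params_hash = params_hash(params),
    n_samples = nrow(samples),
    groups = as.list(table(samples$group)),
    files = lapply(setNames(files, files),
                   \(f) md5_file(file.path(output_dir, f))))
  jsonlite::write_json(meta, out("metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(index = index, samples = samples, consensus = consensus,
                 dmr_table = dmr_table, promoter_table = prom_table,
                 body_table = body_table, deg_table = deg_table,
                 gene_calls = calls, integration = integ,
                 correlation = corr, profiles = strat, occupancy = occupancy,
                 clustering = clust, celltypes = celltypes,
                 stats_summary = stats_summary))
}
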