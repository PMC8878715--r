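#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated
#' object: the fixed hexamer trim, the 40-nt per-mate coverage minimum,
#' the 95% V-identity floor, the 8-nt exact-match floor for D calls, the
#' UM mutation threshold, the DE thresholds (|log2FC| >= 2, FDR <= 0.05),
#' the frequency-shift screen settings and the alignment scoring.
#'
#' @param hexamer_trim_len,min_read_cov,min_v_identity,min_d_match
#'   Extraction/annotation thresholds (defaults 6, 40, 95, 8).
#' @param um_threshold UM mutation threshold (default 0).
#' @param fc_threshold,fdr_threshold DE thresholds (defaults 2, 0.05).
#' @param alpha,min_shift Frequency-shift screen settings (0.05, 0.01).
#' @param scoring An [align_scoring()] scheme.
#' @param loci Ig locus intervals (default [ig_loci()]).
#' @param seed Master seed for the synthetic stages.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(hexamer_trim_len = 6L, min_read_cov = 40L,
                            min_v_identity = 95, min_d_match = 8L,
                            um_threshold = 0L, fc_threshold = 2,
                            fdr_threshold = 0.05, alpha = 0.05,
                            min_shift = 0.01, scoring = align_scoring(),
                            loci = ig_loci(), seed = 1L) {
  assert_scalar_count(hexamer_trim_len, "hexamer_trim_len")
  assert_scalar_count(min_read_cov, "min_read_cov")
  assert_probability(min_v_identity, "min_v_identity", 0, 100)
  assert_scalar_count(min_d_match, "min_d_match")
  assert_scalar_count(um_threshold, "um_threshold", min = 0L)
  assert_probability(fdr_threshold, "fdr_threshold")
  assert_probability(alpha, "alpha")
  assert_probability(min_shift, "min_shift")
  if (!is.numeric(fc_threshold) || fc_threshold < 0) {
    abort("`fc_threshold` must be a non-negative number",
          class = "bcellrepseq_argument_error")
  }
  stopifnot(inherits(scoring, "align_scoring"))
  structure(
    list(hexamer_trim_len = as.integer(hexamer_trim_len),
         min_read_cov = as.integer(min_read_cov),
         min_v_identity = min_v_identity,
         min_d_match = as.integer(min_d_match),
         um_threshold = as.integer(um_threshold),
         fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
         alpha = alpha, min_shift = min_shift,
         scoring = scoring, loci = loci, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Hash of the semantic content of a config
#' @param config A `pipeline_config`.
#' @return Character hash; changes iff any field changes.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the all-synthetic demonstration pipeline
#'
#' Executes every stage end to end on simulated data: germline reference,
#' mixed UM/M population, paired reads placed in SAM, locus-pair
#' extraction, hexamer trim, VDJ annotation + filtering, repertoire
#' summaries, and the count-matrix side (TMM, NB test, BH, DE calls,
#' biotype classification, Ig-locus annotation). Writes TSV outputs and a
#' `manifest.json` with the config hash and seeds; reruns with the same
#' config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_cells,frac_mutated,shm_rate,depth_per_cell Population settings
#'   for the demonstration.
#' @param n_genes Genes in the simulated count matrix.
#' @return Invisibly, a list with the in-memory results (`calls`,
#'   `repertoire`, `de`, `biotypes`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("bcr_"),
                         n_cells = 100L, frac_mutated = 0.5, shm_rate = 0.04,
                         depth_per_cell = 2L, n_genes = 500L) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ref <- generate_germline_reference(5, 4, 3, seed = seed)
  pop <- simulate_population(ref, n_cells, frac_mutated, shm_rate,
                             seed = seed + 1L)
  reads <- simulate_paired_reads(pop, depth_per_cell = depth_per_cell,
                                 add_hexamer = TRUE, seed = seed + 2L)
  sam <- simulate_sam(reads, ref, decoy_fraction = 0.1, seed = seed + 3L)
  sam_path <- file.path(out_dir, "simulated.sam")
  write_sam(sam, sam_path)

  locus <- locus_interval(ref$igh_contig_name, 0, nchar(ref$contig_seq),
                          name = "IGH")
  pairs <- read_sam(sam_path) |>
    extract_locus_pairs(locus) |>
    trim_hexamer(config$hexamer_trim_len)
  calls <- annotate_pairs(pairs, ref, scoring = config$scoring,
                          min_d_match = config$min_d_match,
                          min_read_cov = config$min_read_cov)
  split_calls <- filter_calls(calls, config$min_v_identity)
  passing <- split_calls$passing
  write_airr_tsv(calls, file.path(out_dir, "vdj_calls.tsv"))

  repsum <- tibble(
    unique_vdj = unique_vdj_count(passing)
  )
  repsum <- bind_cols(repsum, mutation_status(passing, config$um_threshold))
  utils::write.table(repsum, file.path(out_dir, "repertoire_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sim <- simulate_count_matrix(n_genes, de_fraction = 0.1,
                               logfc_magnitude = 3, dispersion = 0.1,
                               ig_locus_fraction = 0.01,
                               loci = config$loci, seed = seed + 4L)
  de <- de_table(sim$counts, sim$samples$timepoint,
                 fc_threshold = config$fc_threshold,
                 fdr_threshold = config$fdr_threshold)
  utils::write.table(de, file.path(out_dir, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  de_genes <- sim$genes[sim$genes$gene_id %in% de$gene_id[de$is_de], ,
                        drop = FALSE]
  bios <- classify_biotypes(de_genes)
  utils::write.table(tidy(bios), file.path(out_dir, "biotype_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ig_ann <- annotate_ig_locus(de_genes, config$loci)
  utils::write.table(ig_ann, file.path(out_dir, "ig_locus_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "bcellrepseq",
    version = as.character(utils::packageVersion("bcellrepseq")),
    config_hash = config_hash(config),
    seed = seed,
    n_pairs = nrow(pairs),
    n_passing_calls = nrow(passing)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, repertoire = repsum, de = de,
                 biotypes = bios, out_dir = out_dir))
}
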