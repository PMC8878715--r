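#' Default biotype mixture for count simulation
#'
#' GENCODE-style biotype strings with proportions loosely modeled on a
#' whole-transcriptome differential-expression table from activated human
#' B cells: mostly protein-coding, a substantial long-non-coding component,
#' pseudogenes, Ig genes and miscellaneous small RNAs.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_biotype_mix <- function() {
  c(protein_coding = 0.64,
    antisense = 0.085, lincRNA = 0.06, lncRNA = 0.04, miRNA = 0.01,
    snRNA = 0.01,
    processed_pseudogene = 0.067,
    IG_V_gene = 0.03, IG_C_gene = 0.012, IG_V_pseudogene = 0.01,
    misc_RNA = 0.036)
}

#' Simulate a negative-binomial count matrix with known DE truth
#'
#' Generates a genes x samples integer count matrix over `n_groups` time
#' points with `n_reps` replicates each. Per-gene baseline means are
#' log-normal; a `de_fraction` of genes receives a monotone group effect of
#' total magnitude `logfc_magnitude` (log2, random sign; half the effect at
#' the middle time point), and counts are drawn NB with common dispersion
#' `dispersion` (variance mu + mu^2 * dispersion). Library sizes vary
#' log-normally around 1. Every gene gets a GENCODE-style biotype drawn
#' from `biotype_mix` and synthetic coordinates; a configurable fraction is
#' placed inside the configured Ig locus intervals.
#'
#' @param n_genes Number of genes.
#' @param biotype_mix Named proportions over biotype strings (sums to 1).
#' @param n_groups,n_reps Time points and replicates per time point.
#' @param de_fraction Fraction of genes that are truly differential.
#' @param logfc_magnitude Absolute log2 effect between first and last group.
#' @param dispersion NB dispersion (> 0); values near 0 approach Poisson.
#' @param lib_sd Log-normal sd of per-sample library-size factors (0 gives
#'   equal effective library sizes).
#' @param ig_locus_fraction Fraction of genes placed inside Ig loci.
#' @param loci Ig locus intervals as from [ig_loci()].
#' @param seed Integer seed.
#'
#' @return List of class `count_sim`: `counts` (integer matrix), `genes`
#'   (tibble: `gene_id`, `biotype`, `contig`, `start`, `end`), `samples`
#'   (tibble: `sample_id`, `timepoint`, `donor_id`), `truth` (list:
#'   `de_genes`, `logfc_truth` tibble, `dispersion`, `library_sizes`).
#' @export
simulate_count_matrix <- function(n_genes, biotype_mix = default_biotype_mix(),
                                  n_groups = 3L, n_reps = 3L,
                                  de_fraction = 0.1, logfc_magnitude = 2,
                                  dispersion = 0.1, lib_sd = 0.15,
                                  ig_locus_fraction = 0,
                                  loci = ig_loci(), seed = 1L) {
  assert_scalar_count(n_genes, "n_genes")
  assert_probability(de_fraction, "de_fraction")
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0) {
    abort("`dispersion` must be a single positive number",
          class = "bcellrepseq_argument_error")
  }
  if (abs(sum(biotype_mix) - 1) > 1e-9) {
    abort("`biotype_mix` proportions must sum to 1",
          class = "bcellrepseq_argument_error")
  }
  assert_probability(ig_locus_fraction, "ig_locus_fraction")

  with_seed(seed, {
    n_samples <- n_groups * n_reps
    tp_levels <- if (n_groups == 3L) c("D0", "D4", "D10") else
      paste0("G", seq_len(n_groups))
    samples <- tibble(
      sample_id = paste0(rep(tp_levels, each = n_reps), "_r", seq_len(n_reps)),
      timepoint = factor(rep(tp_levels, each = n_reps), levels = tp_levels),
      donor_id = paste0("donor", rep(seq_len(n_reps), times = n_groups))
    )

    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    base_mu <- exp(rnorm(n_genes, log(100), 1.2))
    n_de <- as.integer(round(n_genes * de_fraction))
    de_idx <- if (n_de > 0L) sort(sample.int(n_genes, n_de)) else integer(0)
    sign <- rep(0, n_genes)
    sign[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
    # monotone effect: 0 at first group, half at middle, full at last
    grade <- seq(0, 1, length.out = n_groups)
    lfc_gene <- sign * logfc_magnitude

    lib <- exp(rnorm(n_samples, 0, lib_sd))
    mu <- outer(base_mu, rep(1, n_samples))
    for (s in seq_len(n_samples)) {
      g <- as.integer(samples$timepoint)[s]
      mu[, s] <- base_mu * 2^(lfc_gene * grade[g]) * lib[s]
    }
    counts <- matrix(
      rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
      nrow = n_genes,
      dimnames = list(gene_id, samples$sample_id)
    )

    biotype <- sample(names(biotype_mix), n_genes, replace = TRUE,
                      prob = biotype_mix)
    n_ig <- as.integer(round(n_genes * ig_locus_fraction))
    in_ig <- sample.int(n_genes, n_ig)
    contig <- sample(paste0("chr", 1:22), n_genes, replace = TRUE)
    gstart <- floor(runif(n_genes, 0, 2e8))
    glen <- pmax(200L, floor(rexp_len(n_genes)))
    if (n_ig > 0L) {
      li <- sample.int(nrow(loci), n_ig, replace = TRUE)
      contig[in_ig] <- loci$contig[li]
      gstart[in_ig] <- floor(runif(n_ig, loci$start[li],
                                   loci$end[li] - glen[in_ig]))
    }
    genes <- tibble(gene_id = gene_id, biotype = biotype, contig = contig,
                    start = as.numeric(gstart),
                    end = as.numeric(gstart + glen))

    logfc_truth <- tibble(
      gene_id = gene_id,
      lfc_mid_vs_first = lfc_gene * grade[max(1L, (n_groups + 1L) %/% 2L)],
      lfc_last_vs_first = lfc_gene
    )
    structure(
      list(counts = counts, genes = genes, samples = samples,
           truth = list(de_genes = gene_id[de_idx],
                        logfc_truth = logfc_truth,
                        dispersion = dispersion,
                        library_sizes = colSums(counts))),
      class = "count_sim"
    )
  })
}

rexp_len <- function(n) stats::rexp(n, rate = 1 / 20000)

#' @export
print.count_sim <- function(x, ...) {
  cat(sprintf("<count_sim> %d genes x %d samples; %d truth-DE genes\n",
              nrow(x$counts), ncol(x$counts), length(x$truth$de_genes)))
  invisible(x)
}
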