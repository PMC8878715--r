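#' Default biotype mapping table
#'
#' Maps GENCODE-style biotype strings to the five reporting categories
#' (non-Ig protein coding, Ig related, ncRNA, pseudogene, miscellaneous
#' RNA) and, within ncRNA, to subcategories (antisense, lincRNA, other
#' lncRNA, miRNA, other). Editable: pass any tibble with the same columns
#' to [classify_biotypes()].
#'
#' @return Tibble with columns `biotype`, `category`, `subcategory`.
#' @export
biotype_mapping <- function() {
  tribble(
    ~biotype, ~category, ~subcategory,
    "protein_coding", "non_Ig_protein_coding", NA,
    "IG_V_gene", "Ig_related", NA,
    "IG_D_gene", "Ig_related", NA,
    "IG_J_gene", "Ig_related", NA,
    "IG_C_gene", "Ig_related", NA,
    "IG_V_pseudogene", "Ig_related", NA,
    "IG_C_pseudogene", "Ig_related", NA,
    "IG_J_pseudogene", "Ig_related", NA,
    "IG_pseudogene", "Ig_related", NA,
    "antisense", "ncRNA", "antisense",
    "lincRNA", "ncRNA", "lincRNA",
    "lncRNA", "ncRNA", "other_lncRNA",
    "sense_intronic", "ncRNA", "other_lncRNA",
    "sense_overlapping", "ncRNA", "other_lncRNA",
    "bidirectional_promoter_lncRNA", "ncRNA", "other_lncRNA",
    "3prime_overlapping_ncRNA", "ncRNA", "other_lncRNA",
    "macro_lncRNA", "ncRNA", "other_lncRNA",
    "miRNA", "ncRNA", "miRNA",
    "snRNA", "ncRNA", "other",
    "snoRNA", "ncRNA", "other",
    "scaRNA", "ncRNA", "other",
    "processed_pseudogene", "pseudogene", NA,
    "unprocessed_pseudogene", "pseudogene", NA,
    "transcribed_processed_pseudogene", "pseudogene", NA,
    "transcribed_unprocessed_pseudogene", "pseudogene", NA,
    "unitary_pseudogene", "pseudogene", NA,
    "polymorphic_pseudogene", "pseudogene", NA,
    "pseudogene", "pseudogene", NA,
    "misc_RNA", "misc_RNA", NA,
    "rRNA", "misc_RNA", NA,
    "ribozyme", "misc_RNA", NA,
    "TEC", "misc_RNA", NA,
    "processed_transcript", "misc_RNA", NA
  )
}

BIOTYPE_CATEGORIES <- c("non_Ig_protein_coding", "Ig_related", "ncRNA",
                        "pseudogene", "misc_RNA")
NCRNA_SUBCATEGORIES <- c("antisense", "lincRNA", "other_lncRNA", "miRNA",
                         "other")

#' Classify differentially expressed transcripts by biotype
#'
#' Maps each gene's biotype string to one of five categories and tallies
#' counts and percentages (1 decimal) over the input set; ncRNA genes are
#' additionally broken down into subcategories with percentages of the
#' ncRNA total. Biotype strings not in the mapping are routed to
#' `misc_RNA` with a warning (generic fallbacks `*_pseudogene` to
#' pseudogene and `IG_*` to Ig_related are tried first).
#'
#' @param de_gene_annotations Tibble with at least a `biotype` column
#'   (typically the annotation rows of the DE gene set).
#' @param mapping Mapping table as from [biotype_mapping()].
#' @return Object of class `biotype_summary`: list with `categories`
#'   (tibble: `category`, `count`, `percent`), `ncrna` (tibble:
#'   `subcategory`, `count`, `percent` of ncRNA), and `n_total`.
#' @export
classify_biotypes <- function(de_gene_annotations,
                              mapping = biotype_mapping()) {
  bt <- de_gene_annotations$biotype
  if (is.null(bt)) {
    abort("`de_gene_annotations` must have a `biotype` column",
          class = "bcellrepseq_argument_error")
  }
  n_total <- length(bt)
  i <- match(bt, mapping$biotype)
  category <- mapping$category[i]
  subcategory <- mapping$subcategory[i]
  miss <- is.na(category)
  if (any(miss)) {
    ig <- miss & grepl("^IG_", bt)
    pseudo <- miss & !ig & grepl("_pseudogene$", bt)
    category[ig] <- "Ig_related"
    category[pseudo] <- "pseudogene"
    unknown <- unique(bt[miss & !ig & !pseudo])
    if (length(unknown) > 0L) {
      warn(sprintf("unknown biotype(s) routed to misc_RNA: %s",
                   paste(unknown, collapse = ", ")))
      category[miss & !ig & !pseudo] <- "misc_RNA"
    }
  }
  cat_tab <- tibble(category = factor(category, BIOTYPE_CATEGORIES)) |>
    count(category, .drop = FALSE, name = "count") |>
    mutate(category = as.character(category),
           percent = if (n_total > 0) round(100 * count / n_total, 1)
                     else NA_real_)
  nc <- subcategory[!is.na(category) & category == "ncRNA"]
  n_nc <- length(nc)
  nc_tab <- tibble(subcategory = factor(nc, NCRNA_SUBCATEGORIES)) |>
    count(subcategory, .drop = FALSE, name = "count") |>
    mutate(subcategory = as.character(subcategory),
           percent = if (n_nc > 0) round(100 * count / n_nc, 1)
                     else NA_real_)
  structure(list(categories = cat_tab, ncrna = nc_tab, n_total = n_total),
            class = "biotype_summary")
}

#' @export
print.biotype_summary <- function(x, ...) {
  cat(sprintf("<biotype_summary> %d transcripts\n", x$n_total))
  print(x$categories)
  if (any(x$ncrna$count > 0)) {
    cat("ncRNA breakdown (% of ncRNA):\n")
    print(x$ncrna)
  }
  invisible(x)
}

#' @rdname classify_biotypes
#' @param x A `biotype_summary`.
#' @param ... Unused.
#' @export
tidy.biotype_summary <- function(x, ...) {
  bind_rows(
    mutate(x$categories, level = "category", .before = 1) |>
      rename(group = "category"),
    mutate(x$ncrna, level = "ncRNA_subcategory", .before = 1) |>
      rename(group = "subcategory")
  )
}

#' Annotate genes for Ig-locus overlap
#'
#' Flags genes whose interval (0-based half-open) intersects any of the
#' configured immunoglobulin locus intervals (IGH on chr14, IGK on chr2,
#' IGL on chr22 by default); overlap is computed with IRanges. Genes on
#' contigs absent from the locus set are `FALSE`.
#'
#' @param gene_annotations Tibble with `gene_id`, `contig`, `start`, `end`.
#' @param loci Locus tibble as from [ig_loci()].
#' @return The input with `in_ig_locus` (logical) and `ig_locus` (locus
#'   name or `NA`) columns appended.
#' @export
annotate_ig_locus <- function(gene_annotations, loci = ig_loci()) {
  g <- gene_annotations
  stopifnot(all(c("contig", "start", "end") %in% names(g)))
  g$in_ig_locus <- FALSE
  g$ig_locus <- NA_character_
  for (k in seq_len(nrow(loci))) {
    on <- which(g$contig == loci$contig[k])
    if (length(on) == 0L) next
    # half-open to closed: [start, end) becomes [start + 1, end] 1-based
    q <- IRanges::IRanges(start = g$start[on] + 1, end = g$end[on])
    s <- IRanges::IRanges(start = loci$start[k] + 1, end = loci$end[k])
    hit <- IRanges::overlapsAny(q, s)
    g$in_ig_locus[on[hit]] <- TRUE
    g$ig_locus[on[hit]] <- ifelse(is.na(g$ig_locus[on[hit]]),
                                  loci$locus[k], g$ig_locus[on[hit]])
  }
  g
}
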