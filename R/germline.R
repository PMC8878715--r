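#' Generate a synthetic germline V/D/J reference
#'
#' Builds a random but reproducible set of germline IGH segments (variable,
#' diversity and joining) together with a synthetic IGH contig on which each
#' segment occupies a non-overlapping interval, and a short constant-region
#' stub appended downstream of rearranged transcripts. Segment lengths follow
#' the characteristic ranges of the human IGH locus: V 250--320 nt, D 10--37
#' nt, J 40--65 nt.
#'
#' @param n_v,n_d,n_j Number of V, D and J segments (each >= 1).
#' @param seed Integer seed; the reference is a pure function of the
#'   arguments and the seed.
#' @param const_len Length in nt of the constant-region stub (default 60).
#' @param spacer_len Length in nt of the random spacer separating segments on
#'   the synthetic contig (default 50).
#'
#' @return An object of class `germline_reference`: a list with
#'   `segments` (tibble: `name`, `locus_class`, `sequence`), `igh_contig_name`,
#'   `contig_seq`, `offsets` (tibble: `name`, `start`, `end`; 0-based
#'   half-open intervals on the contig), `const_seq` and `decoy_contig_name`.
#' @examples
#' ref <- generate_germline_reference(5, 3, 2, seed = 1)
#' ref$segments
#' @export
generate_germline_reference <- function(n_v, n_d, n_j, seed,
                                        const_len = 60L, spacer_len = 50L) {
  assert_scalar_count(n_v, "n_v")
  assert_scalar_count(n_d, "n_d")
  assert_scalar_count(n_j, "n_j")
  assert_scalar_count(const_len, "const_len", min = 10L)
  with_seed(seed, {
    seg <- tibble(
      name = c(sprintf("IGHV1-%d", seq_len(n_v)),
               sprintf("IGHD1-%d", seq_len(n_d)),
               sprintf("IGHJ%d", seq_len(n_j))),
      locus_class = rep(c("V", "D", "J"), c(n_v, n_d, n_j)),
      length = c(sample(250:320, n_v, replace = TRUE),
                 sample(10:37, n_d, replace = TRUE),
                 sample(40:65, n_j, replace = TRUE))
    )
    seg$sequence <- vapply(seg$length, random_dna, character(1))
    seg$length <- NULL

    # lay segments on a synthetic contig with random spacers
    pieces <- character(0)
    starts <- integer(nrow(seg))
    pos <- 0L
    for (i in seq_len(nrow(seg))) {
      sp <- random_dna(spacer_len)
      pieces <- c(pieces, sp, seg$sequence[i])
      pos <- pos + spacer_len
      starts[i] <- pos
      pos <- pos + nchar(seg$sequence[i])
    }
    pieces <- c(pieces, random_dna(spacer_len))
    structure(
      list(
        segments = seg,
        igh_contig_name = "igh_synth",
        decoy_contig_name = "decoy_synth",
        contig_seq = paste(pieces, collapse = ""),
        offsets = tibble(name = seg$name, start = starts,
                         end = starts + nchar(seg$sequence)),
        const_seq = random_dna(const_len)
      ),
      class = "germline_reference"
    )
  })
}

#' @export
print.germline_reference <- function(x, ...) {
  cls <- table(x$segments$locus_class)
  cat(sprintf(
    "<germline_reference> %d V / %d D / %d J segments on contig '%s' (%d nt)\n",
    cls[["V"]], cls[["D"]], cls[["J"]], x$igh_contig_name, nchar(x$contig_seq)
  ))
  invisible(x)
}

segments_by_class <- function(ref, class) {
  ref$segments[ref$segments$locus_class == class, , drop = FALSE]
}

#' Write germline segments to FASTA
#'
#' @param ref A `germline_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$segments$sequence)
  names(x) <- ref$segments$name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read germline segments from FASTA
#'
#' Accepts the simulator's own FASTA output or any IMGT-style germline FASTA
#' whose record names contain IGHV/IGHD/IGHJ gene names; locus class is
#' inferred from the name.
#'
#' @param path FASTA file of germline segments.
#' @return A tibble with `name`, `locus_class`, `sequence`.
#' @export
read_germline_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  cls <- dplyr::case_when(
    grepl("^IG.V", nm) ~ "V",
    grepl("^IG.D", nm) ~ "D",
    grepl("^IG.J", nm) ~ "J",
    .default = NA_character_
  )
  if (anyNA(cls)) {
    abort("cannot infer locus class (V/D/J) from FASTA record names",
          class = "bcellrepseq_parse_error")
  }
  tibble(name = nm, locus_class = cls, sequence = unname(as.character(x)))
}
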