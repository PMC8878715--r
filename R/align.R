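#' Alignment scoring scheme
#'
#' Scoring for the local (Smith-Waterman-style) alignments used to annotate
#' reads against germline segments. Gap semantics: a gap of length L costs
#' `|gap_open| + (L - 1) * |gap_extend|` (the first gapped position pays the
#' opening cost). `N` never matches anything, including another `N`.
#'
#' @param match Match reward (> 0).
#' @param mismatch,gap_open,gap_extend Penalties (< 0).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                          gap_extend = -1L) {
  if (match <= 0 || mismatch >= 0 || gap_open >= 0 || gap_extend >= 0) {
    abort("match must be > 0 and all penalties < 0",
          class = "bcellrepseq_argument_error")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_scoring")
}

substitution_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(as.numeric(scoring$mismatch), 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch # N never matches
  m
}

# Biostrings charges gapOpening + L*gapExtension for a gap of length L;
# our convention (first position gap_open, then gap_extend) maps to:
biostrings_gap <- function(scoring) {
  list(opening = abs(scoring$gap_open) - abs(scoring$gap_extend),
       extension = abs(scoring$gap_extend))
}

#' Locally align a read against one germline segment
#'
#' Optimal local alignment under [align_scoring()]; identity is computed
#' over aligned columns with gap columns counted as non-matching.
#'
#' @param read_seq,segment_seq Non-empty ACGTN strings.
#' @param scoring An [align_scoring()] scheme.
#' @return One-row tibble (a segment hit): `score`, `identity` (percent),
#'   `n_match`, `aligned_len` (columns, gaps included), `read_start`,
#'   `read_end`, `seg_start`, `seg_end` (0-based half-open),
#'   `longest_match_run` and `mismatch_positions` (list column of 0-based
#'   segment coordinates of substitution and gap columns).
#' @examples
#' seg <- strrep("ACGT", 20)
#' local_align(substr(seg, 11, 40), seg)
#' @export
local_align <- function(read_seq, segment_seq, scoring = align_scoring()) {
  if (length(read_seq) != 1L || length(segment_seq) != 1L ||
      !nzchar(read_seq) || !nzchar(segment_seq)) {
    abort("sequences must be single non-empty strings",
          class = "bcellrepseq_argument_error")
  }
  aln <- pairwise_local(read_seq, segment_seq, scoring)
  hit <- hit_table(aln, 1L)
  pg <- as.character(Biostrings::alignedPattern(aln))
  sg <- as.character(Biostrings::alignedSubject(aln))
  hit$longest_match_run <- longest_match_run(
    Biostrings::compareStrings(pg, sg)
  )
  hit$mismatch_positions <- list(
    mismatch_positions_one(pg, sg, hit$seg_start)
  )
  hit$seq_idx <- NULL
  hit
}

pairwise_local <- function(reads, segment_seq, scoring) {
  gp <- biostrings_gap(scoring)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads),
    Biostrings::DNAString(segment_seq),
    type = "local",
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = gp$opening, gapExtension = gp$extension
  )
}

# cheap vectorized accessors only (no gapped-string construction)
hit_table <- function(aln, n) {
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  gap_cols <- unname(ind@insertion[, "WidthSum"] + ind@deletion[, "WidthSum"])
  cols <- nm + nmm + gap_cols
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  tibble(
    seq_idx = seq_len(n),
    score = as.numeric(Biostrings::score(aln)),
    n_match = as.integer(nm),
    aligned_len = as.integer(cols),
    identity = ifelse(cols > 0, 100 * nm / cols, 0),
    read_start = IRanges::start(p) - 1L,
    read_end = IRanges::end(p),
    seg_start = IRanges::start(s) - 1L,
    seg_end = IRanges::end(s)
  )
}

# align many reads against one segment; returns one row per read
align_batch <- function(reads, segment_seq, scoring = align_scoring()) {
  aln <- pairwise_local(reads, segment_seq, scoring)
  hit_table(aln, length(reads))
}

# does each read contain a contiguous exact match of >= k nt to `segment`?
# (Aho-Corasick over the segment's k-mers; the D-evidence floor)
has_exact_kmer <- function(reads, segment_seq, k) {
  L <- nchar(segment_seq)
  if (L < k) return(rep(FALSE, length(reads)))
  kmers <- unique(substring(segment_seq, seq_len(L - k + 1L),
                            seq_len(L - k + 1L) + k - 1L))
  pd <- Biostrings::PDict(kmers)
  cnt <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(reads))
  colSums(cnt) > 0L
}

# longest run of match columns in a compareStrings() string
# (match columns display the base; any other symbol is a non-match column)
longest_match_run <- function(cmp) {
  pieces <- strsplit(cmp, "[^ACGT]+")
  map_int(pieces, function(p) {
    if (length(p) == 0L) 0L else max(nchar(p))
  })
}

# 0-based segment coordinates of non-match columns, from the gapped pattern
# and subject strings. Substitution and deletion (gap in read) columns
# consume a segment coordinate; insertion columns (gap in segment) do not
# and are attributed to the previous segment coordinate.
mismatch_positions_one <- function(pat_gapped, sub_gapped, seg_start0) {
  pc <- strsplit(pat_gapped, "", fixed = TRUE)[[1]]
  sc <- strsplit(sub_gapped, "", fixed = TRUE)[[1]]
  pos <- integer(0)
  coord <- seg_start0
  for (i in seq_along(pc)) {
    if (sc[i] == "-") { # insertion in read
      pos <- c(pos, max(coord - 1L, seg_start0))
    } else if (pc[i] == "-" || pc[i] != sc[i] ||
               (pc[i] == "N" && sc[i] == "N")) {
      pos <- c(pos, coord)
      coord <- coord + 1L
    } else {
      coord <- coord + 1L
    }
  }
  unique(pos)
}
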