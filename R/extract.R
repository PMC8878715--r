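#' Default Ig locus intervals (GRCh38)
#'
#' The heavy (IGH, chr14), kappa (IGK, chr2) and lambda (IGL, chr22) locus
#' intervals on GRCh38, 0-based half-open. Shipped as an editable TSV in
#' `inst/extdata/ig_loci_grch38.tsv`; override by passing any tibble with
#' the same columns.
#'
#' @param path Optional TSV with columns `locus`, `contig`, `start`, `end`.
#' @return Tibble with columns `locus`, `contig`, `start`, `end`.
#' @export
ig_loci <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ig_loci_grch38.tsv",
                                package = "bcellrepseq")
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_tibble(out)
}

#' Define a single locus interval
#'
#' @param contig Contig/chromosome name.
#' @param start,end 0-based half-open interval (`start < end`).
#' @param name Locus name (e.g. "IGH").
#' @return One-row tibble with `locus`, `contig`, `start`, `end`.
#' @export
locus_interval <- function(contig, start, end, name = "IGH") {
  if (!(is.numeric(start) && is.numeric(end) && start < end)) {
    abort("locus interval requires start < end",
          class = "bcellrepseq_argument_error")
  }
  tibble(locus = name, contig = contig, start = as.numeric(start),
         end = as.numeric(end))
}

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Read a SAM file into a tibble of alignment records
#'
#' Parses SAM text (header optional) into one row per record. Positions are
#' converted to the package's internal 0-based half-open convention
#' (`pos0`); unmapped records carry `pos0 = NA` as the sentinel. FLAG bits
#' are unpacked into logical columns.
#'
#' @param path Path to a SAM text file.
#' @return Tibble with the 11 mandatory SAM columns plus `pos0`,
#'   `is_paired`, `is_unmapped`, `is_reverse`, `is_first_mate`,
#'   `is_secondary`, `is_supplementary`, and `ref_width` (reference span
#'   from the CIGAR; 0 for unmapped).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("SAM file not found: %s", path),
          class = "bcellrepseq_argument_error")
  }
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (length(body_idx) == 0L) {
    return(empty_sam_tibble())
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- body_idx[which(nf < 11L)[1]]
    abort(sprintf("malformed SAM record at line %d: %d of 11 mandatory columns",
                  bad, nf[which(nf < 11L)[1]]),
          class = "bcellrepseq_parse_error")
  }
  m <- vapply(fields, function(f) f[1:11], character(11))
  out <- as_tibble(setNames(as.list(as.data.frame(t(m),
                                                  stringsAsFactors = FALSE)),
                            SAM_COLS))
  flag <- suppressWarnings(as.integer(out$flag))
  pos <- suppressWarnings(as.integer(out$pos))
  if (anyNA(flag) || anyNA(pos)) {
    bad <- body_idx[which(is.na(flag) | is.na(pos))[1]]
    abort(sprintf("malformed SAM record at line %d: non-numeric FLAG or POS", bad),
          class = "bcellrepseq_parse_error")
  }
  out$flag <- flag
  out$pos <- pos
  out$is_paired <- bitwAnd(flag, 0x1) > 0L
  out$is_unmapped <- bitwAnd(flag, 0x4) > 0L
  out$is_reverse <- bitwAnd(flag, 0x10) > 0L
  out$is_first_mate <- bitwAnd(flag, 0x40) > 0L
  out$is_secondary <- bitwAnd(flag, 0x100) > 0L
  out$is_supplementary <- bitwAnd(flag, 0x800) > 0L
  out$pos0 <- ifelse(out$is_unmapped | out$pos == 0L, NA_integer_, out$pos - 1L)
  out$ref_width <- ifelse(is.na(out$pos0), 0L, cigar_ref_width(out$cigar))
  out
}

empty_sam_tibble <- function() {
  out <- as_tibble(setNames(rep(list(character(0)), 11L), SAM_COLS))
  out$flag <- integer(0); out$pos <- integer(0)
  for (nm in c("is_paired", "is_unmapped", "is_reverse", "is_first_mate",
               "is_secondary", "is_supplementary")) out[[nm]] <- logical(0)
  out$pos0 <- integer(0); out$ref_width <- integer(0)
  out
}

# reference span consumed by a CIGAR: M/D/N/=/X count, I/S/H/P do not
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks), nchar(toks))
    len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract read pairs overlapping a locus
#'
#' Keeps a pair if and only if at least one mate's reference span (computed
#' from POS and CIGAR; 0-based half-open) intersects the locus interval;
#' when kept, *both* mates are emitted, including an unmapped mate rescued
#' alongside its mapped partner. Secondary (0x100) and supplementary
#' (0x800) alignments are ignored.
#'
#' @param records Alignment tibble from [read_sam()].
#' @param locus One-row locus tibble, e.g. from [locus_interval()].
#' @return Tibble of read pairs: `pair_id`, `mate1_seq`, `mate2_seq`,
#'   `mate1_trimmed`, `mate2_trimmed` (both `FALSE`).
#' @export
extract_locus_pairs <- function(records, locus) {
  stopifnot(all(c("contig", "start", "end") %in% names(locus)))
  prim <- filter(records, !is_secondary, !is_supplementary)
  tally <- table(prim$qname)
  if (any(tally > 2L)) {
    abort(sprintf("qname '%s' has more than 2 primary records",
                  names(tally)[which(tally > 2L)[1]]),
          class = "bcellrepseq_ambiguity_error")
  }
  hit <- !is.na(prim$pos0) &
    prim$rname == locus$contig[1] &
    prim$pos0 < locus$end[1] &
    (prim$pos0 + prim$ref_width) > locus$start[1]
  keep_qnames <- unique(prim$qname[hit])
  kept <- prim[prim$qname %in% keep_qnames, , drop = FALSE]

  # read as sequenced: undo the aligner's reverse-complement storage
  oriented <- ifelse(kept$is_reverse & kept$seq != "*",
                     revcomp(kept$seq), kept$seq)
  kept$oriented_seq <- oriented
  m1 <- kept[kept$is_first_mate | !kept$is_paired, c("qname", "oriented_seq")]
  m2 <- kept[kept$is_paired & !kept$is_first_mate, c("qname", "oriented_seq")]
  out <- inner_join(
    rename(m1, mate1_seq = "oriented_seq"),
    rename(m2, mate2_seq = "oriented_seq"),
    by = "qname"
  )
  orphan <- setdiff(keep_qnames, out$qname)
  if (length(orphan) > 0L) {
    warn(sprintf("%d kept qname(s) lacked a complete mate pair and were dropped",
                 length(orphan)))
  }
  out <- rename(out, pair_id = "qname")
  out$mate1_trimmed <- FALSE
  out$mate2_trimmed <- FALSE
  arrange(as_tibble(out), pair_id)
}

#' Trim random-hexamer bases from both mates
#'
#' Random-hexamer priming corrupts the first bases of each read; the
#' standard remedy is a fixed-length hard clip. Removes the first
#' `hexamer_len` bases of each mate exactly once; a second call is a no-op
#' with a warning (guarded by the `mate*_trimmed` flags).
#'
#' @param pairs Pair tibble from [extract_locus_pairs()].
#' @param hexamer_len Bases to clip from each mate 5' end (default 6).
#' @return The pair tibble with trimmed sequences and trimmed flags set.
#' @export
trim_hexamer <- function(pairs, hexamer_len = 6L) {
  assert_scalar_count(hexamer_len, "hexamer_len")
  if (nrow(pairs) == 0L) return(pairs)
  if (all(pairs$mate1_trimmed) && all(pairs$mate2_trimmed)) {
    warn("pairs already hexamer-trimmed; returning unchanged")
    return(pairs)
  }
  if (any(nchar(pairs$mate1_seq) <= hexamer_len) ||
      any(nchar(pairs$mate2_seq) <= hexamer_len)) {
    abort(sprintf("mate shorter than %d nt cannot be hexamer-trimmed",
                  hexamer_len + 1L),
          class = "bcellrepseq_degenerate_read_error")
  }
  mutate(
    pairs,
    mate1_seq = ifelse(mate1_trimmed, mate1_seq,
                       substr(mate1_seq, hexamer_len + 1L, nchar(mate1_seq))),
    mate2_seq = ifelse(mate2_trimmed, mate2_seq,
                       substr(mate2_seq, hexamer_len + 1L, nchar(mate2_seq))),
    mate1_trimmed = TRUE,
    mate2_trimmed = TRUE
  )
}
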