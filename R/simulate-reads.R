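#' Simulate paired-end reads from a cell population
#'
#' Draws `depth_per_cell` fragments per cell (length N(frag_mean, frag_sd),
#' clamped to \[read_len, transcript length\]; start uniform), and sequences
#' both fragment ends in the FR convention: mate 1 reads the fragment 5' end
#' forward, mate 2 reads the 3' end and is reported reverse-complemented.
#' Sequencing error is an independent per-base substitution at `error_rate`
#' (no indels). When `add_hexamer = TRUE` the first 6 nt of each raw mate
#' are replaced by a random 6-mer, emulating random-hexamer priming
#' artifacts and motivating the fixed 6-nt trim downstream.
#'
#' The returned tibble doubles as the truth table: per pair it records the
#' source cell, its segments and mutation status, each mate's covered
#' interval on the V portion (0-based half-open transcript coordinates) and
#' the number of planted mutations inside that interval.
#'
#' @param pop Population tibble from [simulate_population()].
#' @param read_len Read length in nt (>= 50; default 100 for 100x2 layouts).
#' @param frag_mean,frag_sd Fragment length distribution in nt.
#' @param depth_per_cell Read pairs drawn per cell.
#' @param error_rate Per-base substitution error probability.
#' @param add_hexamer Replace the first 6 nt of each mate with a random 6-mer?
#' @param seed Integer seed.
#'
#' @return Tibble of class `read_pairs`, one row per pair: `pair_id`,
#'   `cell_id`, `mate1_seq`, `mate2_seq`, `frag_start`, `frag_len`,
#'   `mate1_tstart`, `mate2_tstart` (0-based transcript starts),
#'   `mate1_v_cov`, `mate2_v_cov` (nt of V portion covered),
#'   `mate1_mut`, `mate2_mut` (planted mutations in the covered V interval),
#'   plus truth columns `v_name`, `d_name`, `j_name`, `is_mutated_lineage`.
#' @export
simulate_paired_reads <- function(pop, read_len = 100L, frag_mean = 250,
                                  frag_sd = 30, depth_per_cell = 2L,
                                  error_rate = 0, add_hexamer = FALSE,
                                  seed = 1L) {
  if (nrow(pop) == 0L) {
    abort("empty population", class = "bcellrepseq_argument_error")
  }
  assert_scalar_count(read_len, "read_len", min = 50L)
  assert_scalar_count(depth_per_cell, "depth_per_cell")
  assert_probability(error_rate, "error_rate")

  with_seed(seed, {
    idx <- rep(seq_len(nrow(pop)), each = depth_per_cell)
    n <- length(idx)
    tlen <- nchar(pop$transcript_seq)[idx]
    flen <- pmin(pmax(round(rnorm(n, frag_mean, frag_sd)), read_len), tlen)
    fstart <- floor(runif(n) * (tlen - flen + 1L)) # 0-based

    m1_start <- fstart
    m2_start <- fstart + flen - read_len
    tx <- pop$transcript_seq[idx]
    m1 <- substr(tx, m1_start + 1L, m1_start + read_len)
    m2_fwd <- substr(tx, m2_start + 1L, m2_start + read_len)
    m2 <- revcomp(m2_fwd)

    if (error_rate > 0) {
      m1 <- vapply(m1, add_seq_errors, character(1), error_rate, USE.NAMES = FALSE)
      m2 <- vapply(m2, add_seq_errors, character(1), error_rate, USE.NAMES = FALSE)
    }
    if (isTRUE(add_hexamer)) {
      m1 <- paste0(vapply(seq_len(n), function(i) random_dna(6L), character(1)),
                   substr(m1, 7L, read_len))
      m2 <- paste0(vapply(seq_len(n), function(i) random_dna(6L), character(1)),
                   substr(m2, 7L, read_len))
    }

    vlen <- pop$v_portion_len[idx]
    cov <- function(s) pmax(0L, pmin(s + read_len, vlen) - pmax(s, 0L))
    muts_in <- function(s) {
      lo <- pmax(s, 0L); hi <- pmin(s + read_len, vlen)
      map_int(seq_len(n), function(i) {
        p <- pop$shm_positions[[idx[i]]]
        sum(p >= lo[i] & p < hi[i])
      })
    }

    out <- tibble(
      pair_id = sprintf("pair%05d", seq_len(n)),
      cell_id = pop$cell_id[idx],
      mate1_seq = m1, mate2_seq = m2,
      frag_start = as.integer(fstart), frag_len = as.integer(flen),
      mate1_tstart = as.integer(m1_start), mate2_tstart = as.integer(m2_start),
      mate1_v_cov = as.integer(cov(m1_start)),
      mate2_v_cov = as.integer(cov(m2_start)),
      mate1_mut = muts_in(m1_start), mate2_mut = muts_in(m2_start),
      v_name = pop$v_name[idx], d_name = pop$d_name[idx],
      j_name = pop$j_name[idx],
      is_mutated_lineage = pop$is_mutated_lineage[idx]
    )
    class(out) <- c("read_pairs", class(out))
    out
  })
}

add_seq_errors <- function(seq, rate) {
  hits <- which(runif(nchar(seq)) < rate)
  substitute_bases(seq, hits)
}

#' Write simulated read pairs as a FASTQ pair
#'
#' @param reads A `read_pairs` tibble.
#' @param prefix Output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` with constant quality "I".
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (k in 1:2) {
    seqs <- if (k == 1) reads$mate1_seq else reads$mate2_seq
    qual <- strrep("I", nchar(seqs))
    writeLines(
      as.vector(rbind(paste0("@", reads$pair_id, "/", k), seqs, "+", qual)),
      paths[k]
    )
  }
  invisible(paths)
}

#' Place simulated read pairs in a minimal SAM file
#'
#' Emits a valid minimal SAM text: an `@SQ` header for the synthetic IGH
#' contig plus one decoy contig, and one properly flag-paired record per
#' mate. Pairs are positioned on the IGH contig at the coordinate of their
#' source V segment shifted by the mate's offset in the transcript (clamped
#' to the contig); a configurable fraction of pairs is placed on the decoy
#' contig instead, and a further fraction has only mate 2 moved to the
#' decoy (exercising the rule that a pair is rescued when either mate
#' overlaps the locus).
#'
#' @param reads A `read_pairs` tibble.
#' @param ref The `germline_reference` the population was simulated from.
#' @param decoy_fraction Fraction of pairs with both mates on the decoy.
#' @param mate_split_fraction Fraction of pairs with mate 1 on IGH and
#'   mate 2 on the decoy.
#' @param seed Integer seed for assigning pairs to contigs.
#' @return Character vector of SAM lines (header first).
#' @export
simulate_sam <- function(reads, ref, decoy_fraction = 0,
                         mate_split_fraction = 0, seed = 1L) {
  stopifnot(inherits(ref, "germline_reference"))
  assert_probability(decoy_fraction, "decoy_fraction")
  assert_probability(mate_split_fraction, "mate_split_fraction")
  need <- c("pair_id", "mate1_seq", "mate2_seq", "v_name",
            "mate1_tstart", "mate2_tstart")
  if (!all(need %in% names(reads))) {
    abort("reads lack truth columns required for SAM placement",
          class = "bcellrepseq_internal_error")
  }
  contig_len <- nchar(ref$contig_seq)
  decoy_len <- 10000L
  n <- nrow(reads)
  read_len1 <- nchar(reads$mate1_seq)
  read_len2 <- nchar(reads$mate2_seq)

  with_seed(seed, {
    u <- runif(n)
    on_decoy <- u < decoy_fraction
    split <- !on_decoy & u < decoy_fraction + mate_split_fraction

    v_start <- ref$offsets$start[match(reads$v_name, ref$offsets$name)]
    pos1 <- pmin(pmax(v_start + reads$mate1_tstart + 1L, 1L),
                 contig_len - read_len1 + 1L)
    pos2 <- pmin(pmax(v_start + reads$mate2_tstart + 1L, 1L),
                 contig_len - read_len2 + 1L)

    rname1 <- ifelse(on_decoy, ref$decoy_contig_name, ref$igh_contig_name)
    rname2 <- ifelse(on_decoy | split, ref$decoy_contig_name, ref$igh_contig_name)
    dpos1 <- pmin(pos1, decoy_len - read_len1)
    dpos2 <- pmin(pos2, decoy_len - read_len2)
    pos1 <- ifelse(rname1 == ref$decoy_contig_name, dpos1, pos1)
    pos2 <- ifelse(rname2 == ref$decoy_contig_name, dpos2, pos2)

    # FLAG: paired + proper + mate-reverse + first (99); paired + proper +
    # reverse + last (147). SEQ for a reverse-strand record is stored
    # reverse-complemented by convention, which mate 2 already is.
    rec1 <- paste(reads$pair_id, 99L, rname1, pos1, 60L,
                  paste0(read_len1, "M"), ifelse(rname2 == rname1, "=", rname2),
                  pos2, 0L, reads$mate1_seq, strrep("I", read_len1),
                  sep = "\t")
    rec2 <- paste(reads$pair_id, 147L, rname2, pos2, 60L,
                  paste0(read_len2, "M"), ifelse(rname1 == rname2, "=", rname1),
                  pos1, 0L, reads$mate2_seq, strrep("I", read_len2),
                  sep = "\t")
    c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", ref$igh_contig_name, contig_len),
      sprintf("@SQ\tSN:%s\tLN:%d", ref$decoy_contig_name, decoy_len),
      as.vector(rbind(rec1, rec2))
    )
  })
}

#' Write SAM lines to a file
#' @param sam_lines Character vector from [simulate_sam()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam_lines, path) {
  writeLines(sam_lines, path)
  invisible(path)
}
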