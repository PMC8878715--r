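#' Annotate one mate against a germline reference
#'
#' Aligns the read (both strands) against every V, D and J segment, picks
#' the read's orientation from the best-scoring hit overall, ranks hits
#' per class by (score, identity, name), discards D hits lacking a
#' contiguous exact match of at least `min_d_match` nt (junctional
#' trimming leaves D remnants of only a handful of bases, so without this
#' floor spurious D hits dominate), and marks a class confident only when
#' its top score strictly exceeds the runner-up.
#'
#' @param read_seq Read sequence (>= 20 nt, ACGTN).
#' @param ref A `germline_reference` (or a segments tibble with `name`,
#'   `locus_class`, `sequence`).
#' @param scoring An [align_scoring()] scheme.
#' @param min_d_match Minimum contiguous exact match for a D hit (nt).
#' @param min_vj_score Minimum alignment score for a V or J hit to count as
#'   evidence (default 20, roughly 20 matched bases). Without this floor,
#'   short spurious local alignments on reads that do not actually cover a
#'   class would regularly be "confident" and poison the pair collapse.
#' @return A `mate_annotation`: list with `hits` (ranked tibble), `strand`,
#'   `confident` (named list V/D/J, `NA` when not confident),
#'   `covered_len` (nt of read covered by the top hit of any class) and
#'   `v_stats` (n_match / aligned_len of the top V hit).
#' @export
annotate_mate <- function(read_seq, ref, scoring = align_scoring(),
                          min_d_match = 8L, min_vj_score = 20L) {
  if (nchar(read_seq) < 20L) {
    abort("read must be at least 20 nt", class = "bcellrepseq_argument_error")
  }
  segs <- if (inherits(ref, "germline_reference")) ref$segments else ref
  hits <- align_all_segments(c(read_seq, revcomp(read_seq)),
                             c("+", "-"), segs, scoring, min_d_match)
  ann <- summarize_mate(hits[order(hits$seq_idx), , drop = FALSE],
                        min_vj_score)
  ann$read_seq <- read_seq
  structure(ann, class = "mate_annotation")
}

# align seqs (with per-seq strand labels) against every segment; D rows
# carry the exact-k-mer evidence flag used as the D floor
align_all_segments <- function(seqs, strands, segs, scoring,
                               min_d_match = 8L) {
  res <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    h <- align_batch(seqs, segs$sequence[i], scoring)
    h$segment_name <- segs$name[i]
    h$locus_class <- segs$locus_class[i]
    h$strand <- strands[h$seq_idx]
    h$d_evidence <- if (segs$locus_class[i] == "D") {
      has_exact_kmer(seqs, segs$sequence[i], min_d_match)[h$seq_idx]
    } else {
      TRUE
    }
    res[[i]] <- h
  }
  bind_rows(res)
}

# reduce one mate's hit table (both strands, all segments) to its
# annotation: orientation choice, per-class ranking, D floors, confidence.
# D hits must carry exact-k-mer evidence and, when the mate also shows V
# and/or J, must lie in the junction window between the V end and the J
# start in read coordinates (spurious short D matches inside the V or the
# constant region are not biologically interpretable as a D call).
summarize_mate <- function(hits, min_vj_score = 20L, junction_pad = 3L) {
  best <- which.max(hits$score)
  strand <- hits$strand[best]
  h <- hits[hits$strand == strand, , drop = FALSE]
  h <- h[h$d_evidence, , drop = FALSE]
  h <- h[!(h$locus_class %in% c("V", "J") & h$score < min_vj_score), ,
         drop = FALSE]
  h <- h[order(h$locus_class, -h$score, -h$identity, h$segment_name), ,
         drop = FALSE]

  is_d <- h$locus_class == "D"
  if (any(is_d)) {
    hv <- h[h$locus_class == "V", , drop = FALSE]
    hj <- h[h$locus_class == "J", , drop = FALSE]
    lo <- if (nrow(hv) > 0L) hv$read_end[1] - junction_pad else -Inf
    hi <- if (nrow(hj) > 0L) hj$read_start[1] + junction_pad else Inf
    in_window <- h$read_start >= lo & h$read_end <= hi
    h <- h[!is_d | in_window, , drop = FALSE]
  }

  confident <- list(V = NA_character_, D = NA_character_, J = NA_character_)
  v_stats <- list(name = NA_character_, n_match = NA_integer_,
                  aligned_len = NA_integer_)
  cover <- matrix(numeric(0), ncol = 2)
  for (cl in c("V", "D", "J")) {
    hc <- h[h$locus_class == cl, , drop = FALSE]
    if (nrow(hc) == 0L) next
    if (nrow(hc) == 1L || hc$score[1] > hc$score[2]) {
      confident[[cl]] <- hc$segment_name[1]
    }
    cover <- rbind(cover, c(hc$read_start[1], hc$read_end[1]))
    if (cl == "V") {
      v_stats <- list(name = hc$segment_name[1], n_match = hc$n_match[1],
                      aligned_len = hc$aligned_len[1])
    }
  }
  list(hits = as_tibble(h), strand = strand, confident = confident,
       covered_len = interval_union_len(cover), v_stats = v_stats)
}

# total length of a union of half-open intervals given as a 2-column matrix
interval_union_len <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0L
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- iv[i, 1]; cur_e <- iv[i, 2]
    } else {
      cur_e <- max(cur_e, iv[i, 2])
    }
  }
  as.integer(total + (cur_e - cur_s))
}

#' Collapse two mate annotations into a single VDJ call
#'
#' Applies the pair-level rules: a minimum aligned coverage of
#' `min_read_cov` nt for *each* mate (else `SHORT_READ`); per class, the
#' union of the two mates' confident genes (two different confident genes
#' give `AMBIGUOUS_<class>`, none gives `INCOMPLETE`); V identity is pooled
#' as 100 * total V matches / total V aligned columns over the mates whose
#' confident V is the call's V gene, and those mates' per-read V mutation
#' counts (non-match V columns, gaps included) are recorded.
#'
#' @param a1,a2 `mate_annotation` objects for mates 1 and 2 of one pair.
#' @param min_read_cov Minimum aligned coverage per mate (nt, default 40).
#' @param pair_id Optional pair identifier carried into the call.
#' @return One-row tibble (a VDJ call): `pair_id`, `v_call`, `d_call`,
#'   `j_call`, `v_identity`, `per_read_v_mutations` (list column),
#'   `v_mutations` (pooled), `passed_filters`, `fail_reasons` (list
#'   column).
#' @export
collapse_pair <- function(a1, a2, min_read_cov = 40L, pair_id = NA_character_) {
  stopifnot(inherits(a1, "mate_annotation"), inherits(a2, "mate_annotation"))
  collapse_from_summaries(
    pair_id = pair_id,
    conf1 = a1$confident, conf2 = a2$confident,
    cov1 = a1$covered_len, cov2 = a2$covered_len,
    v1 = a1$v_stats, v2 = a2$v_stats,
    min_read_cov = min_read_cov
  )
}

collapse_from_summaries <- function(pair_id, conf1, conf2, cov1, cov2,
                                    v1, v2, min_read_cov) {
  fail <- character(0)
  if (cov1 < min_read_cov || cov2 < min_read_cov) fail <- c(fail, "SHORT_READ")

  genes <- list(V = NA_character_, D = NA_character_, J = NA_character_)
  for (cl in c("V", "D", "J")) {
    g <- unique(stats::na.omit(c(conf1[[cl]], conf2[[cl]])))
    if (length(g) > 1L) {
      fail <- c(fail, paste0("AMBIGUOUS_", cl))
    } else if (length(g) == 0L) {
      if (!("INCOMPLETE" %in% fail)) fail <- c(fail, "INCOMPLETE")
    } else {
      genes[[cl]] <- g
    }
  }

  # a mate contributes V identity/mutations iff it covers the call's V
  # gene (its top V hit is that gene), whether or not the hit was uniquely
  # confident on that mate alone
  v_gene <- genes$V
  contrib <- list()
  if (!is.na(v_gene)) {
    if (identical(v1$name, v_gene)) contrib <- c(contrib, list(v1))
    if (identical(v2$name, v_gene)) contrib <- c(contrib, list(v2))
  }
  if (length(contrib) > 0L) {
    nm <- sum(vapply(contrib, `[[`, integer(1), "n_match"))
    al <- sum(vapply(contrib, `[[`, integer(1), "aligned_len"))
    v_identity <- 100 * nm / al
    per_read <- vapply(contrib, function(v) v$aligned_len - v$n_match,
                       integer(1))
  } else {
    v_identity <- NA_real_
    per_read <- integer(0)
  }

  tibble(
    pair_id = pair_id,
    v_call = genes$V, d_call = genes$D, j_call = genes$J,
    v_identity = v_identity,
    per_read_v_mutations = list(per_read),
    v_mutations = if (length(per_read)) sum(per_read) else NA_integer_,
    passed_filters = length(fail) == 0L,
    fail_reasons = list(fail)
  )
}

#' Annotate and collapse all read pairs (batch pipeline)
#'
#' Vectorized equivalent of [annotate_mate()] + [collapse_pair()] over a
#' pair tibble: every mate of every pair is aligned (both strands) against
#' every germline segment, mates are summarized, and pairs are collapsed
#' into VDJ calls. Results are identical to calling the per-read functions
#' pair by pair.
#'
#' @param pairs Pair tibble with `pair_id`, `mate1_seq`, `mate2_seq` (e.g.
#'   from [extract_locus_pairs()] / [trim_hexamer()]).
#' @inheritParams annotate_mate
#' @inheritParams collapse_pair
#' @return Tibble of VDJ calls, one row per pair (see [collapse_pair()]).
#' @export
annotate_pairs <- function(pairs, ref, scoring = align_scoring(),
                           min_d_match = 8L, min_read_cov = 40L,
                           min_vj_score = 20L) {
  stopifnot(all(c("pair_id", "mate1_seq", "mate2_seq") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(tibble(
      pair_id = character(0), v_call = character(0), d_call = character(0),
      j_call = character(0), v_identity = numeric(0),
      per_read_v_mutations = list(), v_mutations = integer(0),
      passed_filters = logical(0), fail_reasons = list()
    ))
  }
  segs <- if (inherits(ref, "germline_reference")) ref$segments else ref
  n <- nrow(pairs)
  mate_seq <- c(pairs$mate1_seq, pairs$mate2_seq) # mate index = position
  all_seqs <- c(mate_seq, revcomp(mate_seq))
  strands <- rep(c("+", "-"), each = 2L * n)
  mate_of <- rep(seq_len(2L * n), times = 2L)

  hits <- align_all_segments(all_seqs, strands, segs, scoring, min_d_match)
  hits$mate_idx <- mate_of[hits$seq_idx]

  df <- as.data.frame(hits[, c("mate_idx", "strand", "segment_name",
                               "locus_class", "score", "identity", "n_match",
                               "aligned_len", "read_start", "read_end",
                               "d_evidence")])
  summaries <- lapply(split(df, df$mate_idx), summarize_mate,
                      min_vj_score = min_vj_score)
  # split() orders by the numeric-as-character key; restore mate order
  summaries <- summaries[order(as.integer(names(summaries)))]

  calls <- vector("list", n)
  for (i in seq_len(n)) {
    s1 <- summaries[[i]]
    s2 <- summaries[[i + n]]
    calls[[i]] <- collapse_from_summaries(
      pair_id = pairs$pair_id[i],
      conf1 = s1$confident, conf2 = s2$confident,
      cov1 = s1$covered_len, cov2 = s2$covered_len,
      v1 = s1$v_stats, v2 = s2$v_stats,
      min_read_cov = min_read_cov
    )
  }
  bind_rows(calls)
}

#' Apply the V-identity filter to collapsed calls
#'
#' Appends `LOW_V_IDENTITY` to calls whose pooled V identity falls below
#' `min_v_identity` percent; the threshold is inclusive (a call at exactly
#' 95.0 passes). Calls without a V identity (no confident V) are left to
#' their existing fail reasons.
#'
#' @param calls Call tibble from [annotate_pairs()] / [collapse_pair()].
#' @param min_v_identity Minimum V identity in percent (default 95).
#' @return List with `passing` and `failing` call tibbles.
#' @export
filter_calls <- function(calls, min_v_identity = 95) {
  assert_probability(min_v_identity, "min_v_identity", 0, 100)
  low <- !is.na(calls$v_identity) & calls$v_identity < min_v_identity
  calls$fail_reasons <- map2(calls$fail_reasons, low, function(fr, l) {
    if (l) c(fr, "LOW_V_IDENTITY") else fr
  })
  calls$passed_filters <- lengths(calls$fail_reasons) == 0L
  list(passing = calls[calls$passed_filters, , drop = FALSE],
       failing = calls[!calls$passed_filters, , drop = FALSE])
}

#' Per-read V-region mutation counts of a call
#'
#' For each mate that contributed V coverage to the call (its confident V
#' is the call's V gene), the mutation count is the number of non-matching
#' aligned V columns -- substitutions and gap columns both count. Mates
#' without V coverage are omitted, not counted as zero.
#'
#' @param call A one-row call tibble.
#' @return Integer vector of per-read counts (length 0--2).
#' @export
count_v_mutations <- function(call) {
  if (is.na(call$v_call)) {
    abort("call has no confident V gene", class = "bcellrepseq_state_error")
  }
  call$per_read_v_mutations[[1]]
}

#' Write calls as an AIRR-style rearrangement TSV
#'
#' @param calls Call tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(calls, path) {
  out <- tibble(
    sequence_id = calls$pair_id,
    v_call = calls$v_call, d_call = calls$d_call, j_call = calls$j_call,
    v_identity = calls$v_identity,
    v_mutations = calls$v_mutations,
    pass = calls$passed_filters,
    fail_reasons = map_chr(calls$fail_reasons, paste, collapse = ";")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
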