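ref <- generate_germline_reference(4, 3, 2, seed = 42)
pop <- simulate_population(ref, 10, frac_mutated = 0.5, shm_rate = 0.03,
                           seed = 42)
reads <- simulate_paired_reads(pop, depth_per_cell = 2, seed = 42)
igh_locus <- locus_interval(ref$igh_contig_name, 0, nchar(ref$contig_seq),
                            name = "IGH")

# hand-rolled SAM line builder for edge-case fixtures
sam_line <- function(qname, flag, rname, pos, cigar, seq,
                     rnext = "=", pnext = 1) {
  paste(qname, flag, rname, pos, 60, cigar, rnext, pnext, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
sam_header <- c("@HD\tVN:1.6\tSO:unsorted",
                "@SQ\tSN:chrT\tLN:100000",
                "@SQ\tSN:chrD\tLN:100000")

test_that("read_sam parses records in order with unmapped sentinels", {
  f <- tempfile(fileext = ".sam")
  lines <- c(sam_header,
             sam_line("q1", 99, "chrT", 500, "100M", strrep("A", 100)),
             sam_line("q1", 147, "chrT", 700, "100M", strrep("C", 100)),
             sam_line("q2", 69, "chrT", 900, "*", strrep("G", 100)))
  writeLines(lines, f)
  rec <- read_sam(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$qname, c("q1", "q1", "q2"))
  expect_equal(rec$pos0[1], 499)
  expect_true(rec$is_unmapped[3])
  expect_true(is.na(rec$pos0[3]))
  expect_equal(rec$ref_width[1:2], c(100L, 100L))
})

test_that("truncated records give a parse error naming the line", {
  f <- tempfile(fileext = ".sam")
  writeLines(c(sam_header, "q1\t99\tchrT\t500\t60\t100M\t=\t700"), f)
  expect_error(read_sam(f), "line 4", class = "bcellrepseq_parse_error")
})

test_that("CIGAR reference widths follow M/D/N consumption", {
  f <- tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               sam_line("q1", 0, "chrT", 100, "50M10D20M", strrep("A", 70)),
               sam_line("q2", 0, "chrT", 100, "30M5I30M", strrep("A", 65)),
               sam_line("q3", 0, "chrT", 100, "10S50M", strrep("A", 60))), f)
  rec <- read_sam(f)
  expect_equal(rec$ref_width, c(80L, 60L, 50L))
})

test_that("pairs are kept iff either mate overlaps the locus, and kept whole", {
  sam_all <- simulate_sam(reads, ref, decoy_fraction = 0, seed = 1)
  sam_none <- simulate_sam(reads, ref, decoy_fraction = 1, seed = 1)
  sam_split <- simulate_sam(reads, ref, decoy_fraction = 0,
                            mate_split_fraction = 1, seed = 1)
  fa <- tempfile(); fn <- tempfile(); fs <- tempfile()
  write_sam(sam_all, fa); write_sam(sam_none, fn); write_sam(sam_split, fs)

  kept_all <- extract_locus_pairs(read_sam(fa), igh_locus)
  expect_equal(sort(kept_all$pair_id), sort(reads$pair_id))

  expect_equal(nrow(extract_locus_pairs(read_sam(fn), igh_locus)), 0)

  # one mate on the decoy: the pair is still rescued in full
  kept_split <- extract_locus_pairs(read_sam(fs), igh_locus)
  expect_equal(sort(kept_split$pair_id), sort(reads$pair_id))
  expect_true(all(nzchar(kept_split$mate2_seq)))
})

test_that("half-open abutment at the locus boundary is not an overlap", {
  f <- tempfile(fileext = ".sam")
  # locus [500, 600): spans [400,500) and [600,700) must both be dropped,
  # [499,599) and [599,699) kept
  writeLines(c(sam_header,
               sam_line("qa", 99, "chrT", 401, "100M", strrep("A", 100)),
               sam_line("qa", 147, "chrT", 601, "100M", strrep("A", 100)),
               sam_line("qb", 99, "chrT", 500, "100M", strrep("C", 100)),
               sam_line("qb", 147, "chrT", 600, "100M", strrep("C", 100))), f)
  loc <- locus_interval("chrT", 500, 600)
  kept <- extract_locus_pairs(read_sam(f), loc)
  expect_equal(kept$pair_id, "qb")
})

test_that("extraction agrees with a brute-force oracle and ignores order", {
  sam <- simulate_sam(reads, ref, decoy_fraction = 0.4, seed = 9)
  f <- tempfile(); write_sam(sam, f)
  rec <- read_sam(f)
  kept <- extract_locus_pairs(rec, igh_locus)

  # oracle: nested loop over records
  keep_q <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (!is.na(rec$pos0[i]) && rec$rname[i] == igh_locus$contig &&
        overlaps_oracle(rec$pos0[i], rec$pos0[i] + rec$ref_width[i],
                        igh_locus$start, igh_locus$end)) {
      keep_q <- union(keep_q, rec$qname[i])
    }
  }
  expect_setequal(kept$pair_id, keep_q)

  # order invariance
  shuf <- rec[sample(nrow(rec)), ]
  kept2 <- extract_locus_pairs(shuf, igh_locus)
  expect_identical(kept, kept2)

  # pair completeness: both mates present and non-empty
  expect_true(all(nzchar(kept$mate1_seq) & nzchar(kept$mate2_seq)))
})

test_that("more than two primary records for a qname is an error", {
  f <- tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               sam_line("q1", 99, "chrT", 100, "50M", strrep("A", 50)),
               sam_line("q1", 147, "chrT", 200, "50M", strrep("A", 50)),
               sam_line("q1", 0, "chrT", 300, "50M", strrep("A", 50))), f)
  expect_error(extract_locus_pairs(read_sam(f), locus_interval("chrT", 0, 1000)),
               class = "bcellrepseq_ambiguity_error")
})

test_that("secondary and supplementary alignments are skipped", {
  f <- tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               sam_line("q1", 99, "chrT", 100, "50M", strrep("A", 50)),
               sam_line("q1", 147, "chrT", 200, "50M", strrep("C", 50)),
               sam_line("q1", 99 + 256, "chrT", 300, "50M", strrep("A", 50)),
               sam_line("q1", 147 + 2048, "chrT", 400, "50M", strrep("C", 50))), f)
  kept <- extract_locus_pairs(read_sam(f), locus_interval("chrT", 0, 1000))
  expect_equal(nrow(kept), 1)
})

test_that("hexamer trimming removes exactly six bases exactly once", {
  pairs <- tibble::tibble(pair_id = "p1",
                          mate1_seq = strrep("ACGTT", 20),
                          mate2_seq = strrep("TGCAA", 20),
                          mate1_trimmed = FALSE, mate2_trimmed = FALSE)
  t1 <- trim_hexamer(pairs)
  expect_equal(nchar(t1$mate1_seq), 94)
  expect_identical(t1$mate1_seq, substr(pairs$mate1_seq, 7, 100))
  expect_true(t1$mate1_trimmed && t1$mate2_trimmed)
  expect_warning(t2 <- trim_hexamer(t1), "already")
  expect_identical(t2, t1)
  short <- tibble::tibble(pair_id = "p2", mate1_seq = "ACGTAC",
                          mate2_seq = strrep("A", 20),
                          mate1_trimmed = FALSE, mate2_trimmed = FALSE)
  expect_error(trim_hexamer(short), class = "bcellrepseq_degenerate_read_error")
})
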