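ref <- tiny_ref()
segs <- ref$segments
seg_seq <- function(nm) segs$sequence[match(nm, segs$name)]

# a clean rearranged transcript from known pieces (no trimming, no SHM)
v1 <- seg_seq("IGHV1-1"); d1 <- seg_seq("IGHD1-1"); j1 <- seg_seq("IGHJ1")
transcript <- paste0(v1, d1, j1, ref$const_seq)

test_that("a read wholly inside a unique V is confidently V-annotated", {
  read <- substr(v1, 50, 149)
  ann <- annotate_mate(read, ref)
  expect_s3_class(ann, "mate_annotation")
  expect_identical(ann$confident$V, "IGHV1-1")
  expect_true(is.na(ann$confident$D))
  expect_true(is.na(ann$confident$J))
  expect_equal(ann$covered_len, 100)
  expect_identical(ann$strand, "+")
})

test_that("reverse-complemented reads are annotated identically", {
  read <- substr(v1, 50, 149)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  ann <- annotate_mate(rc, ref)
  expect_identical(ann$confident$V, "IGHV1-1")
  expect_identical(ann$strand, "-")
})

test_that("two identical segments under different names are never confident", {
  dup <- ref
  dup$segments <- tibble::add_row(segs,
                                  name = "IGHV1-9", locus_class = "V",
                                  sequence = seg_seq("IGHV1-1"))
  ann <- annotate_mate(substr(v1, 1, 80), dup)
  expect_true(is.na(ann$confident$V))
})

test_that("junction-spanning mates recover V, D and J", {
  # mate covering V tail + D + J head
  read <- substr(transcript, nchar(v1) - 59, nchar(v1) + nchar(d1) + 40)
  ann <- annotate_mate(read, ref)
  expect_identical(ann$confident$V, "IGHV1-1")
  expect_identical(ann$confident$D, "IGHD1-1")
  expect_identical(ann$confident$J, "IGHJ1")
})

test_that("annotation is invariant to segment table order", {
  read <- substr(transcript, nchar(v1) - 59, nchar(v1) + nchar(d1) + 40)
  perm <- ref
  perm$segments <- segs[c(4, 2, 6, 1, 3, 5), ]
  a <- annotate_mate(read, ref)
  b <- annotate_mate(read, perm)
  expect_identical(a$confident, b$confident)
  expect_identical(a$covered_len, b$covered_len)
})

test_that("pair collapse applies the 40-nt coverage rule per mate", {
  long_mate <- annotate_mate(substr(v1, 1, 100), ref)
  short_mate <- annotate_mate(substr(v1, 101, 139), ref) # 39 nt
  call <- collapse_pair(long_mate, short_mate, pair_id = "p1")
  expect_true("SHORT_READ" %in% call$fail_reasons[[1]])
  expect_false(call$passed_filters)

  ok_mate <- annotate_mate(substr(v1, 101, 140), ref) # 40 nt
  call2 <- collapse_pair(long_mate, ok_mate, pair_id = "p2")
  expect_false("SHORT_READ" %in% call2$fail_reasons[[1]])
})

test_that("conflicting confident genes give an ambiguity failure", {
  m1 <- annotate_mate(substr(seg_seq("IGHV1-1"), 1, 100), ref)
  m2 <- annotate_mate(substr(seg_seq("IGHV1-2"), 1, 100), ref)
  call <- collapse_pair(m1, m2)
  expect_true("AMBIGUOUS_V" %in% call$fail_reasons[[1]])
})

test_that("complementary mates collapse into a complete passing call", {
  m1 <- annotate_mate(substr(transcript, nchar(v1) - 69,
                             nchar(v1) + nchar(d1) + 10), ref) # V + D
  m2 <- annotate_mate(substr(transcript, nchar(v1) + nchar(d1) - 5,
                             nchar(v1) + nchar(d1) + 44), ref) # D tail + J
  call <- collapse_pair(m1, m2, pair_id = "p3")
  expect_identical(call$v_call, "IGHV1-1")
  expect_identical(call$d_call, "IGHD1-1")
  expect_identical(call$j_call, "IGHJ1")
  expect_true(call$passed_filters)
  expect_equal(call$v_identity, 100)
})

test_that("V identity filtering is inclusive at the 95% boundary", {
  fake_call <- function(vid) {
    tibble::tibble(pair_id = "x", v_call = "IGHV1-1", d_call = "IGHD1-1",
                   j_call = "IGHJ1", v_identity = vid,
                   per_read_v_mutations = list(0L), v_mutations = 0L,
                   passed_filters = TRUE, fail_reasons = list(character(0)))
  }
  res <- filter_calls(dplyr::bind_rows(fake_call(94.9), fake_call(95.0),
                                       fake_call(100)))
  expect_equal(nrow(res$passing), 2)
  expect_equal(nrow(res$failing), 1)
  expect_true("LOW_V_IDENTITY" %in% res$failing$fail_reasons[[1]])
})

test_that("planted V mutations are counted per read, uncovered mates omitted", {
  # mutate 3 interior bases of the V portion within mate 1's window
  v_read <- substr(v1, 41, 140)
  chars <- strsplit(v_read, "")[[1]]
  for (p in c(20, 50, 80)) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  m1 <- annotate_mate(paste(chars, collapse = ""), ref)
  m2 <- annotate_mate(substr(transcript, nchar(v1) + nchar(d1) - 7,
                             nchar(v1) + nchar(d1) + 42), ref) # D+J only
  call <- collapse_pair(m1, m2)
  expect_identical(call$v_call, "IGHV1-1")
  expect_equal(count_v_mutations(call), 3L) # one contributing mate only
  expect_equal(call$v_mutations, 3L)
  expect_equal(call$v_identity, 97)

  no_v <- collapse_pair(m2, m2)
  expect_error(count_v_mutations(no_v), class = "bcellrepseq_state_error")
})

test_that("batch annotation equals per-pair annotate + collapse", {
  set.seed(42)
  pop <- simulate_population(ref, 6, frac_mutated = 0.5, shm_rate = 0.05,
                             seed = 7)
  reads <- simulate_paired_reads(pop, depth_per_cell = 1, seed = 7)
  batch <- annotate_pairs(reads, ref)
  for (i in seq_len(nrow(reads))) {
    m1 <- annotate_mate(reads$mate1_seq[i], ref)
    m2 <- annotate_mate(reads$mate2_seq[i], ref)
    single <- collapse_pair(m1, m2, pair_id = reads$pair_id[i])
    expect_equal(batch[i, ], single)
  }
})

test_that("error-free simulated pairs recover truth segments", {
  set.seed(43)
  pop <- simulate_population(ref, 40, frac_mutated = 0, seed = 13)
  reads <- simulate_paired_reads(pop, depth_per_cell = 2, seed = 13)
  calls <- filter_calls(annotate_pairs(reads, ref))$passing
  expect_gt(nrow(calls), 10)
  tr <- reads[match(calls$pair_id, reads$pair_id), ]
  expect_true(all(calls$v_call == tr$v_name))
  expect_true(all(calls$d_call == tr$d_name))
  expect_true(all(calls$j_call == tr$j_name))
  expect_true(all(calls$v_identity == 100))
  expect_true(all(calls$v_mutations == 0))
})
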