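make_calls <- function(combos, sample_id = "s1", timepoint = "D0",
                       donor_id = "donor1", v_mutations = 0L) {
  tibble::tibble(
    pair_id = sprintf("p%03d", seq_len(nrow(combos))),
    v_call = combos[[1]], d_call = combos[[2]], j_call = combos[[3]],
    v_identity = 100, v_mutations = v_mutations,
    passed_filters = TRUE,
    sample_id = sample_id, timepoint = timepoint, donor_id = donor_id
  )
}

test_that("unique VDJ combinations are counted over distinct tuples", {
  combos <- tibble::tibble(
    v = c("V1", "V1", "V2"), d = c("D1", "D1", "D1"), j = c("J1", "J1", "J2")
  )
  calls <- make_calls(combos)
  expect_equal(unique_vdj_count(calls), 2)
  expect_equal(unique_vdj_count(calls[sample(nrow(calls)), ]), 2)
  expect_warning(n0 <- unique_vdj_count(calls[0, ]), "empty")
  expect_equal(n0, 0)
})

test_that("unique count is monotone under added calls", {
  set.seed(5)
  combos <- tibble::tibble(
    v = sample(paste0("V", 1:6), 60, TRUE),
    d = sample(paste0("D", 1:3), 60, TRUE),
    j = sample(paste0("J", 1:3), 60, TRUE)
  )
  calls <- make_calls(combos)
  counts <- vapply(seq(10, 60, 10),
                   function(k) unique_vdj_count(calls[1:k, ]), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mutation status partitions calls and reports percentages", {
  calls <- make_calls(
    tibble::tibble(v = paste0("V", 1:10), d = "D1", j = "J1"),
    v_mutations = c(rep(0L, 3), rep(4L, 6), NA)
  )
  ms <- mutation_status(calls)
  expect_equal(ms$n_um, 3)
  expect_equal(ms$n_m, 6)
  expect_equal(ms$n_excluded, 1)
  expect_equal(ms$pct_um, round(100 * 3 / 9, 1))
  expect_equal(ms$n_um + ms$n_m + ms$n_excluded, nrow(calls))
  # a huge threshold makes everything unmutated
  expect_equal(mutation_status(calls, threshold_mutations = 1000L)$pct_um, 100)
})

test_that("frequency tables normalize within sample and complete zeros", {
  calls <- make_calls(tibble::tibble(
    v = rep(c("V1", "V2", "V3", "V4"), each = 5),
    d = "D1", j = "J1"
  ))
  tab <- frequency_table(calls)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$freq == 0.25))

  # two samples with different combinations: zeros are completed
  calls2 <- dplyr::bind_rows(
    calls,
    make_calls(tibble::tibble(v = "V9", d = "D1", j = "J1"),
               sample_id = "s2", donor_id = "donor2")
  )
  tab2 <- frequency_table(calls2)
  sums <- tapply(tab2$freq, tab2$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(tab2$freq[tab2$sample_id == "s2" & tab2$v_call == "V1"], 0)

  # brute-force tally oracle on a 20-call fixture
  manual <- table(paste(calls$v_call, calls$d_call, calls$j_call))
  expect_equal(sort(unname(tab$n)), sort(as.vector(manual)))
})

make_timecourse <- function(freqs_by_donor) {
  # freqs_by_donor: list(donor -> list(D0 = named freq vec, D10 = ...))
  rows <- list()
  for (don in names(freqs_by_donor)) {
    for (tp in names(freqs_by_donor[[don]])) {
      f <- freqs_by_donor[[don]][[tp]]
      rows[[paste(don, tp)]] <- tibble::tibble(
        sample_id = paste0(don, "_", tp), timepoint = tp, donor_id = don,
        v_call = names(f), d_call = "D1", j_call = "J1",
        n = NA_integer_, freq = unname(f)
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("identical frequency profiles are never flagged", {
  f <- c(A = 0.5, B = 0.3, C = 0.2)
  tab <- make_timecourse(list(
    donor1 = list(D0 = f, D10 = f),
    donor2 = list(D0 = f, D10 = f),
    donor3 = list(D0 = f, D10 = f)
  ))
  res <- frequency_shift_test(tab)
  expect_true(all(res$mean_delta == 0))
  expect_false(any(res$flagged))
})

test_that("a consistent 5-point expansion is flagged, and alpha = 0 silences it", {
  base <- c(A = 0.30, B = 0.30, C = 0.40, X = 0)
  shifted <- function(j) {
    f <- c(A = 0.28 + j, B = 0.29 - j, C = 0.38, X = 0.05)
    f / sum(f)
  }
  tab <- make_timecourse(list(
    donor1 = list(D0 = base, D10 = shifted(0.001)),
    donor2 = list(D0 = base, D10 = shifted(-0.002)),
    donor3 = list(D0 = base, D10 = shifted(0.002))
  ))
  res <- frequency_shift_test(tab)
  expect_true(res$flagged[res$v_call == "X"])
  res0 <- frequency_shift_test(tab, alpha = 0)
  x0 <- res0[res0$v_call == "X", ]
  expect_true(is.na(x0$p_value) || !x0$flagged)
})

test_that("p-values match stats::t.test to near machine precision", {
  set.seed(11)
  f0 <- c(A = 0.4, B = 0.35, C = 0.25)
  jitter <- function() {
    f <- abs(f0 + rnorm(3, 0, 0.03))
    setNames(f / sum(f), names(f0))
  }
  donors <- list(
    donor1 = list(D0 = jitter(), D10 = jitter()),
    donor2 = list(D0 = jitter(), D10 = jitter()),
    donor3 = list(D0 = jitter(), D10 = jitter())
  )
  tab <- make_timecourse(donors)
  res <- frequency_shift_test(tab)
  for (combo in res$v_call) {
    d <- vapply(donors, function(x) x$D10[combo] - x$D0[combo], numeric(1))
    ref_p <- stats::t.test(d)$p.value
    expect_equal(res$p_value[res$v_call == combo], ref_p, tolerance = 1e-10)
  }
})

test_that("fewer than two donors is an error", {
  f <- c(A = 1)
  tab <- make_timecourse(list(donor1 = list(D0 = f, D10 = f)))
  expect_error(frequency_shift_test(tab),
               class = "bcellrepseq_insufficient_replication_error")
})
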