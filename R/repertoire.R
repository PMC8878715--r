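#' Count unique VDJ combinations in a repertoire
#'
#' The number of distinct (v_call, d_call, j_call) tuples among passing
#' calls -- the transcript-level repertoire breadth statistic. Calls, not
#' cells, are the counting unit: bulk RNA-seq cannot resolve cells, so two
#' transcripts with the same combination count once.
#'
#' @param calls Call tibble (passing calls).
#' @return Integer count (0 with a warning for an empty repertoire).
#' @export
unique_vdj_count <- function(calls) {
  if (nrow(calls) == 0L) {
    warn("empty repertoire: unique VDJ count is 0")
    return(0L)
  }
  nrow(distinct(calls, v_call, d_call, j_call))
}

#' Summarize somatic-mutation status of a repertoire
#'
#' A call is unmutated (UM) when its pooled V-region mutation count is at
#' most `threshold_mutations` (default 0: any detected V mutation makes the
#' call mutated). Naive B cells are typically UM, memory-derived cells M;
#' an alternative convention in the CLL literature uses 98% germline
#' identity, which corresponds to a non-zero threshold here. Calls without
#' mutation data are excluded and tallied.
#'
#' @param calls Call tibble with `v_mutations`.
#' @param threshold_mutations Maximum pooled V mutations for UM status.
#' @return One-row tibble: `n_um`, `n_m`, `n_excluded`, `pct_um`, `pct_m`
#'   (percent, 1 decimal), `threshold_mutations`.
#' @export
mutation_status <- function(calls, threshold_mutations = 0L) {
  has <- !is.na(calls$v_mutations)
  n_excluded <- sum(!has)
  m <- calls$v_mutations[has]
  n_um <- sum(m <= threshold_mutations)
  n_m <- sum(m > threshold_mutations)
  total <- n_um + n_m
  tibble(
    n_um = n_um, n_m = n_m, n_excluded = n_excluded,
    pct_um = if (total > 0) round(100 * n_um / total, 1) else NA_real_,
    pct_m = if (total > 0) round(100 * n_m / total, 1) else NA_real_,
    threshold_mutations = threshold_mutations
  )
}

#' Per-sample relative frequencies of VDJ combinations
#'
#' Tallies each (v_call, d_call, j_call) combination within each sample and
#' normalizes to relative frequency; combinations observed in any sample
#' but absent from another are completed with frequency 0 so samples are
#' directly comparable.
#'
#' @param calls Call tibble with `sample_id`, `timepoint`, `donor_id`,
#'   `v_call`, `d_call`, `j_call`.
#' @return Long tibble: one row per sample x combination with `n` and
#'   `freq`; per-sample frequencies sum to 1.
#' @export
frequency_table <- function(calls) {
  need <- c("sample_id", "timepoint", "donor_id", "v_call", "d_call", "j_call")
  stopifnot(all(need %in% names(calls)))
  meta <- distinct(calls, sample_id, timepoint, donor_id)
  tab <- calls |>
    count(sample_id, v_call, d_call, j_call, name = "n") |>
    tidyr::complete(sample_id,
                    tidyr::nesting(v_call, d_call, j_call),
                    fill = list(n = 0L)) |>
    group_by(sample_id) |>
    mutate(freq = n / sum(n)) |>
    ungroup() |>
    left_join(meta, by = "sample_id") |>
    relocate(sample_id, timepoint, donor_id)
  tab
}

#' Test VDJ combination frequency shifts between two time points
#'
#' For each combination, a paired t-test across donors on the difference in
#' relative frequency between the two time points. A combination is
#' flagged as shifted only when the test is significant at `alpha` *and*
#' the mean absolute shift exceeds `min_shift` (default 1 percentage point
#' of repertoire share, i.e. 0.01). Combinations with zero variance across
#' donor pairs get `p = NA` and are flagged on the mean shift alone.
#' Combinations present in neither time point of any donor are dropped.
#'
#' @param freq_table Output of [frequency_table()].
#' @param from,to Time point labels to compare (default D0 to D10).
#' @param alpha Significance level.
#' @param min_shift Minimum absolute mean frequency change to flag.
#' @param p_adjust `"none"` (default; the screen is descriptive) or `"BH"`.
#' @return Tibble per combination: `v_call`, `d_call`, `j_call`,
#'   `mean_delta`, `p_value`, `flagged`, `n_pairs`.
#' @export
frequency_shift_test <- function(freq_table, from = "D0", to = "D10",
                                 alpha = 0.05, min_shift = 0.01,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  wide <- freq_table |>
    filter(timepoint %in% c(from, to)) |>
    select(donor_id, timepoint, v_call, d_call, j_call, freq) |>
    tidyr::pivot_wider(names_from = timepoint, values_from = freq,
                       values_fill = 0)
  if (!(from %in% names(wide)) || !(to %in% names(wide))) {
    abort("both time points must be present in the frequency table",
          class = "bcellrepseq_argument_error")
  }
  n_donors <- length(unique(wide$donor_id))
  if (n_donors < 2L) {
    abort("paired frequency-shift test needs at least 2 donors",
          class = "bcellrepseq_insufficient_replication_error")
  }
  out <- wide |>
    mutate(delta = .data[[to]] - .data[[from]]) |>
    group_by(v_call, d_call, j_call) |>
    summarize(
      mean_delta = mean(delta),
      sd_delta = sd(delta),
      n_pairs = dplyr::n(),
      any_obs = any(.data[[from]] > 0 | .data[[to]] > 0),
      .groups = "drop"
    ) |>
    filter(any_obs) |>
    select(-any_obs)
  out <- out |>
    mutate(
      p_value = ifelse(
        sd_delta > 0,
        2 * pt(-abs(mean_delta / (sd_delta / sqrt(n_pairs))), df = n_pairs - 1),
        NA_real_
      )
    )
  if (p_adjust == "BH") out$p_value <- p.adjust(out$p_value, method = "BH")
  out |>
    mutate(flagged = ifelse(
      is.na(p_value),
      abs(mean_delta) > min_shift,
      p_value < alpha & abs(mean_delta) > min_shift
    )) |>
    select(-sd_delta)
}
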