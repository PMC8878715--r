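# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# Affine-gap local alignment score by explicit Gotoh dynamic programming.
# Conventions mirror the documented align_scoring() semantics: a gap of
# length L costs |gap_open| + (L - 1) * |gap_extend|; N never matches.
sw_score_oracle <- function(a, b, match = 1, mismatch = -2,
                            gap_open = -4, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  open <- abs(gap_open); ext <- abs(gap_extend)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (moving along b)
  F <- matrix(-Inf, n + 1, m + 1) # gap in b (moving along a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force Benjamini-Hochberg step-up (definition, not p.adjust):
# q_(i) = min_{k >= i} min(1, m * p_(k) / k)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  for (i in (m - 1):1) {
    if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# half-open interval intersection by definition
overlaps_oracle <- function(s1, e1, s2, e2) {
  max(s1, s2) < min(e1, e2)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A tiny deterministic germline reference with hand-chosen sequences that
# are pairwise very dissimilar, for construction-style annotation tests.
tiny_ref <- function() {
  set.seed(991)
  segs <- tibble::tibble(
    name = c("IGHV1-1", "IGHV1-2", "IGHD1-1", "IGHD1-2", "IGHJ1", "IGHJ2"),
    locus_class = c("V", "V", "D", "D", "J", "J"),
    sequence = c(random_seq(260), random_seq(280),
                 random_seq(20), random_seq(24),
                 random_seq(50), random_seq(48))
  )
  ref <- generate_germline_reference(1, 1, 1, seed = 1)
  ref$segments <- segs
  ref$offsets <- tibble::tibble(
    name = segs$name,
    start = cumsum(c(0, head(nchar(segs$sequence) + 50, -1))) + 50,
    end = cumsum(c(0, head(nchar(segs$sequence) + 50, -1))) + 50 +
      nchar(segs$sequence)
  )
  ref$contig_seq <- paste(c(rbind(replicate(6, random_seq(50)),
                                  segs$sequence), random_seq(50)),
                          collapse = "")
  ref
}

# independent re-implementation of the pair-collapse filter rules for the
# filter-rule oracle: takes per-mate confident gene lists, coverages and
# pooled V stats, returns the fail-reason set
collapse_rules_oracle <- function(conf1, conf2, cov1, cov2,
                                  v_match_total, v_cols_total,
                                  min_read_cov = 40, min_v_identity = 95) {
  fails <- character(0)
  if (min(cov1, cov2) < min_read_cov) fails <- c(fails, "SHORT_READ")
  for (cl in c("V", "D", "J")) {
    g <- unique(c(conf1[[cl]], conf2[[cl]]))
    g <- g[!is.na(g)]
    if (length(g) > 1) fails <- c(fails, paste0("AMBIGUOUS_", cl))
    if (length(g) == 0) fails <- union(fails, "INCOMPLETE")
  }
  if (v_cols_total > 0 && 100 * v_match_total / v_cols_total < min_v_identity) {
    fails <- c(fails, "LOW_V_IDENTITY")
  }
  sort(unique(fails))
}
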