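# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitute each selected position with a different base, uniformly
substitute_bases <- function(seq, positions1) {
  if (length(positions1) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions1) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "bcellrepseq_argument_error")
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, name, lower = 0, upper = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lower, upper),
          class = "bcellrepseq_argument_error")
  }
  invisible(as.numeric(x))
}
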