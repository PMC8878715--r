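#' Negative-binomial time-course test
#'
#' A per-gene likelihood-ratio test of a group-means negative-binomial
#' model against an intercept-only model, with effective library sizes as
#' offsets. Dispersion is estimated per gene by a bias-corrected method of
#' moments from within-group residual variation and shrunk strongly toward
#' a pooled (abundance-weighted) common dispersion, then held fixed while
#' both models are fitted as NB GLMs; the statistic is referred to a
#' chi-square with (groups - 1) degrees of freedom. All-zero genes get
#' p = 1 by convention. The pooled ratio estimator is the shrinkage
#' target because, at two or three replicates per group, the per-gene
#' moment estimates are so noisy that their median is biased low and
#' would make the test anti-conservative.
#'
#' This is intentionally a transparent stand-in for quasi-likelihood
#' F-test machinery: it tests the same "any change across time points"
#' hypothesis, but makes no claim of replicating any specific package's
#' gene lists.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Factor (or coercible) of length `ncol(counts)` with the
#'   time point of each sample; needs >= 2 replicates per group.
#' @param norm_factors Optional per-sample normalization factors
#'   (default [tmm_factors()]).
#' @param shrink_weight Weight on the pooled common dispersion in the
#'   shrinkage (0 = raw per-gene, 1 = fully common); default 0.8.
#' @return Object of class `nb_timecourse`: a tibble with `gene_id`,
#'   `p_value` and `dispersion`, with the group labels and shrinkage
#'   settings stored as attributes.
#' @export
nb_timecourse_test <- function(counts, groups, norm_factors = NULL,
                               shrink_weight = 0.8) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(counts)) {
    abort("`groups` must have one label per sample column",
          class = "bcellrepseq_argument_error")
  }
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    abort("need >= 2 groups with >= 2 replicates each",
          class = "bcellrepseq_argument_error")
  }
  norm_factors <- norm_factors %||% tmm_factors(counts)
  eff <- colSums(counts) * norm_factors
  off <- log(eff / exp(mean(log(eff))))

  disp <- shrunk_dispersion(counts, groups, off, shrink_weight)
  df_test <- nlevels(groups) - 1L
  n_genes <- nrow(counts)
  p <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) {
      p[g] <- 1
      next
    }
    p[g] <- nb_lrt_one(y, groups, off, disp[g], df_test)
  }
  out <- tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(n_genes)),
    p_value = p,
    dispersion = disp
  )
  structure(out, class = c("nb_timecourse", class(out)),
            groups = groups, shrink_weight = shrink_weight)
}

# bias-corrected method-of-moments NB dispersion per gene on
# offset-normalized counts, shrunk toward a pooled common dispersion;
# floored to keep theta finite
shrunk_dispersion <- function(counts, groups, off, shrink_weight) {
  norm <- sweep(counts, 2, exp(off), `/`)
  lev <- levels(groups)
  n <- ncol(norm)
  mu <- matrix(0, nrow(norm), n)
  ss <- rep(0, nrow(norm))
  for (l in lev) {
    j <- which(groups == l)
    m <- rowMeans(norm[, j, drop = FALSE])
    mu[, j] <- m
    ss <- ss + rowSums((norm[, j, drop = FALSE] - m)^2)
  }
  s2 <- ss / (n - length(lev))
  mbar <- rowMeans(mu)
  keep <- mbar > 0
  common <- max(sum(s2[keep] - mbar[keep]) / sum(mbar[keep]^2), 1e-4)
  # mbar^2 overstates mu^2 by Var(mbar) ~ s2/n; correct, with a floor
  denom <- pmax(mbar^2 - s2 / n, 0.25 * mbar^2)
  raw <- (s2 - mbar) / denom
  raw[!is.finite(raw)] <- common
  pmax((1 - shrink_weight) * raw + shrink_weight * common, 1e-4)
}

nb_lrt_one <- function(y, groups, off, phi, df_test) {
  fam <- MASS::negative.binomial(theta = 1 / phi)
  f1 <- try(stats::glm(y ~ groups + offset(off), family = fam),
            silent = TRUE)
  f0 <- try(stats::glm(y ~ 1 + offset(off), family = fam), silent = TRUE)
  if (inherits(f1, "try-error") || inherits(f0, "try-error")) {
    return(NA_real_)
  }
  stat <- max(0, f0$deviance - f1$deviance)
  pchisq(stat, df = df_test, lower.tail = FALSE)
}

#' @export
print.nb_timecourse <- function(x, ...) {
  cat(sprintf("<nb_timecourse> %d genes, %d groups\n",
              nrow(x), nlevels(attr(x, "groups"))))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname nb_timecourse_test
#' @param x An `nb_timecourse` object.
#' @param ... Unused.
#' @export
tidy.nb_timecourse <- function(x, ...) {
  out <- as_tibble(x)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' @rdname nb_timecourse_test
#' @export
glance.nb_timecourse <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_groups = nlevels(attr(x, "groups")),
    median_dispersion = median(x$dispersion),
    n_sig_fdr05 = sum(bh_fdr(x$p_value) <= 0.05, na.rm = TRUE)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (the standard BH
#' procedure as implemented in [stats::p.adjust()]), with input
#' validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted values, elementwise >= input and <= 1.
#' @export
bh_fdr <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) {
    abort("p-values must lie in [0, 1]", class = "bcellrepseq_argument_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differential expression from fold changes and FDR
#'
#' A gene is differentially expressed when the largest absolute log2 fold
#' change over the contrasts reaches `fc_threshold` *and* its FDR is at
#' most `fdr_threshold`; both boundaries are inclusive. The magnitude
#' criterion is two-sided: strong down-regulation qualifies just as
#' up-regulation does.
#'
#' @param log2fc Numeric vector or matrix (genes x contrasts) of log2 fold
#'   changes.
#' @param fdr FDR vector aligned with the rows of `log2fc`.
#' @param fc_threshold Minimum |log2 FC| (default 2).
#' @param fdr_threshold Maximum FDR (default 0.05).
#' @return Logical vector of DE flags.
#' @export
call_de <- function(log2fc, fdr, fc_threshold = 2, fdr_threshold = 0.05) {
  lfc <- as.matrix(log2fc)
  if (nrow(lfc) != length(fdr)) {
    abort("log2fc rows and fdr must align", class = "bcellrepseq_argument_error")
  }
  max_abs <- apply(abs(lfc), 1, max, na.rm = TRUE)
  as.vector(max_abs >= fc_threshold & !is.na(fdr) & fdr <= fdr_threshold)
}

#' Full differential-expression table for a three-time-point design
#'
#' Convenience wrapper chaining [tmm_factors()], [pseudo_counts()],
#' [nb_timecourse_test()], [bh_fdr()] and [call_de()]. Log2 fold changes
#' per contrast are computed from group-mean pseudo-counts with a prior
#' count of 0.5.
#'
#' @inheritParams nb_timecourse_test
#' @param fc_threshold,fdr_threshold Thresholds for [call_de()].
#' @param prior_count Added to group-mean pseudo-counts before log2.
#' @return Tibble: `gene_id`, one `log2fc_*` column per contrast,
#'   `p_value`, `fdr`, `is_de`.
#' @export
de_table <- function(counts, groups, fc_threshold = 2, fdr_threshold = 0.05,
                     prior_count = 0.5) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  factors <- tmm_factors(counts)
  pc <- pseudo_counts(counts, factors)
  lev <- levels(groups)
  gm <- vapply(lev, function(l) {
    rowMeans(pc[, groups == l, drop = FALSE])
  }, numeric(nrow(pc)))
  contrasts <- utils::combn(seq_along(lev), 2)
  lfc <- apply(contrasts, 2, function(ct) {
    log2((gm[, ct[2]] + prior_count) / (gm[, ct[1]] + prior_count))
  })
  colnames(lfc) <- apply(contrasts, 2, function(ct) {
    paste0("log2fc_", lev[ct[2]], "_vs_", lev[ct[1]])
  })
  fit <- nb_timecourse_test(counts, groups, norm_factors = factors)
  fdr <- bh_fdr(fit$p_value)
  out <- tibble(gene_id = fit$gene_id)
  out <- bind_cols(out, as_tibble(lfc))
  out$p_value <- fit$p_value
  out$fdr <- fdr
  out$is_de <- call_de(lfc, fdr, fc_threshold, fdr_threshold)
  out
}
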