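#' Pearson correlation with leave-one-out outlier correction
#'
#' With few dozen patient samples a single aberrant measurement can dominate
#' a Pearson coefficient. The coefficient is therefore re-estimated n times,
#' leaving out one sample at a time; a sample whose removal shifts the
#' coefficient by two or more standard deviations (of the n leave-one-out
#' replicates) from their mean is flagged as an outlier, and the final
#' coefficient is recomputed once on the remaining samples. The p-value comes
#' from the exact t transform of the corrected coefficient at its effective
#' sample size.
#'
#' When the leave-one-out replicates have (numerically) zero spread, e.g. on
#' perfectly linear data, no sample is flagged. If every sample were flagged the correction is
#' refused: the raw coefficient is returned with `refused = TRUE`.
#'
#' @param x,y numeric vectors over the same samples, length >= 5.
#' @param sample_ids optional sample identifiers (defaults to `S1..Sn`).
#' @param mirna_id,gene_id identifiers carried into the result.
#' @param pvalue_method `"t"` (default) for the exact t transform, or
#'   `"permutation"` for a two-sided permutation p-value on the corrected
#'   coefficient (the outlier correction is re-applied to every permuted
#'   pairing), for symmetry with the antagonism scan.
#' @param n_permutations permutation rounds when
#'   `pvalue_method = "permutation"`.
#' @return a one-row data frame: `mirna_id`, `gene_id`, `r` (corrected),
#'   `r_raw`, `pvalue`, `n_effective`, `n_outliers`, `outlier_samples`
#'   (comma-joined), `refused`.
#' @export
loo_corrected_pearson <- function(x, y, sample_ids = NULL,
                                  mirna_id = "miRNA", gene_id = "gene",
                                  pvalue_method = c("t", "permutation"),
                                  n_permutations = 200) {
  pvalue_method <- match.arg(pvalue_method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 5) stop("leave-one-out correction needs n >= 5", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate input: constant vector", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  r_raw <- cor(x, y)
  r_loo <- vapply(seq_len(n), function(k) cor(x[-k], y[-k]), numeric(1))
  s <- sd(r_loo)
  # coefficients live on [-1, 1]; spread below 1e-12 is numerically zero
  # (e.g. perfectly linear data), in which case no sample is an outlier
  out <- if (is.finite(s) && s > 1e-12) {
    abs(r_loo - mean(r_loo)) >= 2 * s
  } else {
    rep(FALSE, n)
  }
  refused <- FALSE
  if (all(out)) {
    warning("all samples flagged as outliers; returning the raw coefficient",
            call. = FALSE)
    refused <- TRUE
    out <- rep(FALSE, n)
  }
  keep <- !out
  r <- if (any(out)) cor(x[keep], y[keep]) else r_raw
  n_eff <- sum(keep)
  pv <- if (pvalue_method == "t") {
    pearson_pvalue(r, n_eff)
  } else {
    r_perm <- vapply(seq_len(n_permutations), function(m) {
      loo_r_only(x, y[sample.int(n)])
    }, numeric(1))
    (1 + sum(abs(r_perm) >= abs(r))) / (1 + n_permutations)
  }
  data.frame(
    mirna_id = as.character(mirna_id), gene_id = as.character(gene_id),
    r = r, r_raw = r_raw, pvalue = pv,
    n_effective = n_eff, n_outliers = sum(out),
    outlier_samples = paste(sample_ids[out], collapse = ","),
    refused = refused, stringsAsFactors = FALSE
  )
}

# the corrected coefficient alone (no p-value), for permutation nulls
loo_r_only <- function(x, y) {
  n <- length(x)
  r_raw <- cor(x, y)
  r_loo <- vapply(seq_len(n), function(k) cor(x[-k], y[-k]), numeric(1))
  s <- sd(r_loo)
  out <- if (is.finite(s) && s > 1e-12) {
    abs(r_loo - mean(r_loo)) >= 2 * s
  } else {
    rep(FALSE, n)
  }
  if (all(out) || !any(out)) return(r_raw)
  cor(x[!out], y[!out])
}

# two-sided p from the t transform of a Pearson coefficient
pearson_pvalue <- function(r, n) {
  if (n < 3) return(NA_real_)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

#' Correlation baseline over every miRNA x gene pair
#'
#' Scores all pairs with [loo_corrected_pearson()] and attaches
#' Benjamini-Hochberg adjusted q-values. The coefficient's sign is retained so
#' callers can restrict to the negatively correlated component, the part of
#' the correlation network comparable to antagonism-based silencing links.
#'
#' @param expr a [paired_expression_set()].
#' @param fdr_q FDR threshold for the `significant` flag (default 0.1).
#' @param sign one of `"both"` (default), `"negative"`, `"positive"`; rows
#'   with the excluded sign are dropped after scoring.
#' @param p_threshold optional raw p-value cutoff; when given it replaces the
#'   FDR rule for the `significant` flag (useful to size-match networks
#'   across methods).
#' @return data frame, one row per retained pair, columns as in
#'   [loo_corrected_pearson()] plus `qvalue`, `significant`.
#' @export
correlation_scan <- function(expr, fdr_q = 0.1,
                             sign = c("both", "negative", "positive"),
                             p_threshold = NULL) {
  stopifnot(inherits(expr, "paired_expression_set"))
  sign <- match.arg(sign)
  mi <- drop_constant_rows(expr$mirna, "miRNA")
  mg <- drop_constant_rows(expr$mrna, "mRNA")
  rows <- vector("list", nrow(mi) * nrow(mg))
  k <- 0L
  for (i in seq_len(nrow(mi))) {
    for (j in seq_len(nrow(mg))) {
      k <- k + 1L
      rows[[k]] <- loo_corrected_pearson(
        mi[i, ], mg[j, ], sample_ids = expr$sample_ids,
        mirna_id = rownames(mi)[i], gene_id = rownames(mg)[j])
    }
  }
  out <- do.call(rbind, rows)
  out$qvalue <- bh_adjust(out$pvalue)
  out$significant <- if (is.null(p_threshold)) {
    out$qvalue <= fdr_q
  } else {
    out$pvalue <= p_threshold
  }
  if (sign == "negative") out <- out[out$r < 0, , drop = FALSE]
  if (sign == "positive") out <- out[out$r > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
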