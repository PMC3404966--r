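#' Standardize an expression vector to z-scores
#'
#' Centers and scales a feature's expression across samples using the sample
#' mean and the (n - 1)-denominator standard deviation, so that miRNA and mRNA
#' intensities measured on different platforms become comparable before the
#' antagonism scan.
#'
#' @param v numeric vector of expression values, length at least 3.
#' @return numeric vector with mean 0 and unit standard deviation, in the
#'   input order.
#' @export
zscore <- function(v) {
  if (!is.numeric(v) || length(v) < 3) {
    stop("zscore() needs a numeric vector of length >= 3", call. = FALSE)
  }
  if (anyNA(v) || !all(is.finite(v))) {
    stop("zscore() input contains missing or non-finite values", call. = FALSE)
  }
  s <- sd(v)
  if (s == 0) {
    stop("degenerate input: vector is constant across samples", call. = FALSE)
  }
  (v - mean(v)) / s
}

#' Bundle a z-scored miRNA/mRNA expression pair
#'
#' @param x numeric vector, miRNA expression (z-scored unless `standardize`).
#' @param y numeric vector, mRNA expression, same samples in the same order.
#' @param mirna_id,gene_id feature identifiers carried through to results.
#' @param standardize if `TRUE` (default) apply [zscore()] to both vectors.
#' @return an object of class `standardized_pair` with elements `x`, `y`,
#'   `n`, `mirna_id`, `gene_id`.
#' @export
standardized_pair <- function(x, y, mirna_id = "miRNA", gene_id = "gene",
                              standardize = TRUE) {
  if (length(x) != length(y)) {
    stop("x and y must have the same number of samples", call. = FALSE)
  }
  if (standardize) {
    x <- zscore(x)
    y <- zscore(y)
  } else if (length(x) < 3) {
    stop("a pair needs at least 3 samples", call. = FALSE)
  }
  structure(
    list(x = x, y = y, n = length(x),
         mirna_id = as.character(mirna_id), gene_id = as.character(gene_id)),
    class = "standardized_pair"
  )
}

#' @export
print.standardized_pair <- function(x, ...) {
  cat(sprintf("standardized_pair: %s ~ %s over %d samples\n",
              x$mirna_id, x$gene_id, x$n))
  invisible(x)
}

as_pair <- function(pair) {
  if (inherits(pair, "standardized_pair")) return(pair)
  if (is.list(pair) && !is.null(pair$x) && !is.null(pair$y)) {
    return(standardized_pair(pair$x, pair$y, standardize = FALSE))
  }
  stop("expected a standardized_pair or a list with x and y", call. = FALSE)
}

#' Fraction of samples below the anti-diagonal line x + y = b
#'
#' The building block of the antagonism statistic: the proportion of samples
#' whose summed (z-scored) miRNA and mRNA expression falls strictly below the
#' line with intercept `b`. As a function of `b` this is the left-continuous
#' empirical CDF of the sums.
#'
#' @param pair a `standardized_pair` (or list with `x`, `y`).
#' @param b intercept of the anti-diagonal line; finite scalar.
#' @return the fraction `#\{i : x_i + y_i < b\} / n`, in `[0, 1]`.
#' @export
fraction_below <- function(pair, b) {
  pair <- as_pair(pair)
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b)) {
    stop("b must be a single finite number", call. = FALSE)
  }
  mean(pair$x + pair$y < b)
}

#' Antagonism statistic from precomputed sum pools
#'
#' Deterministic core of the antagonism coefficient: the supremum over
#' intercepts b of the difference between the observed below-line fraction and
#' the shuffle-null below-line fraction. Both arguments are pools of
#' x + y sums. The supremum over all real b of the strict-below difference is
#' attained just above an observed breakpoint (between observed breakpoints
#' the observed CDF is flat while the null CDF cannot decrease) and equals the
#' maximum over observed sum values v of
#' `mean(obs_sums <= v) - mean(null_sums <= v)`; ties resolve to the smallest
#' such v, reported as `best_intercept`.
#'
#' @param obs_sums numeric vector of observed pairing sums `x_i + y_i`.
#' @param null_sums numeric vector pooling the sums of all null re-pairings.
#' @return list with `coefficient` (in `[0, 1]`: at the largest observed sum
#'   both CDFs reach 1, so the maximum is never negative) and
#'   `best_intercept` (the smallest maximizing breakpoint, on the z-score sum
#'   scale).
#' @export
antagonism_stat <- function(obs_sums, null_sums) {
  stopifnot(is.numeric(obs_sums), is.numeric(null_sums),
            length(obs_sums) >= 1, length(null_sums) >= 1)
  antag_stat_cpp(as.numeric(obs_sums), as.numeric(null_sums))
}

#' Antagonism coefficient of a miRNA/mRNA expression pair
#'
#' Measures how strongly the joint expression avoids the high/high corner.
#' The observed below-line CDF of `x_i + y_i` is compared with its mean under
#' `n_null_shuffles` uniform random re-pairings of the two vectors (value
#' multisets preserved, association destroyed; shuffling one vector against
#' the other draws the same null as shuffling both). The coefficient is the
#' maximal excess over an exhaustive candidate set: every breakpoint at which
#' the difference of the two step functions can peak.
#'
#' Randomness is taken from R's global RNG; call [set.seed()] beforehand for
#' reproducibility. Every permutation is drawn exactly as base
#' [sample.int()] would draw it, so results can be replayed in plain R.
#'
#' @param pair a `standardized_pair`.
#' @param n_null_shuffles number of null re-pairings averaged into the
#'   reference CDF (default 100).
#' @return list with `coefficient` and `best_intercept`.
#' @export
antagonism_coefficient <- function(pair, n_null_shuffles = 100) {
  pair <- as_pair(pair)
  if (!is.numeric(n_null_shuffles) || n_null_shuffles < 1) {
    stop("n_null_shuffles must be at least 1", call. = FALSE)
  }
  antag_coef_cpp(pair$x, pair$y, as.integer(n_null_shuffles))
}

#' Permutation p-value of the antagonism coefficient
#'
#' The observed coefficient is ranked within coefficients recomputed on
#' `n_permutations` random re-pairings of the mRNA vector against the miRNA
#' vector, each scored with its own fresh shuffle null. The p-value uses
#' add-one smoothing, `(1 + r) / (1 + M)` with `r` the number of null
#' coefficients at least as large as the observed one, so it is bounded below
#' by `1 / (M + 1)` and never exactly zero.
#'
#' @inheritParams antagonism_coefficient
#' @param n_permutations number of permutation rounds `M` (default 1000).
#' @return a one-row data frame (a pair score) with columns `mirna_id`,
#'   `gene_id`, `coefficient`, `best_intercept`, `pvalue`, `n_permutations`,
#'   `n_null_shuffles`.
#' @export
antagonism_pvalue <- function(pair, n_permutations = 1000,
                              n_null_shuffles = 100) {
  pair <- as_pair(pair)
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop("n_permutations must be at least 1", call. = FALSE)
  }
  if (!is.numeric(n_null_shuffles) || n_null_shuffles < 1) {
    stop("n_null_shuffles must be at least 1", call. = FALSE)
  }
  res <- antag_pvalue_cpp(pair$x, pair$y,
                          as.integer(n_permutations),
                          as.integer(n_null_shuffles))
  data.frame(
    mirna_id = pair$mirna_id,
    gene_id = pair$gene_id,
    coefficient = res$coefficient,
    best_intercept = res$best_intercept,
    pvalue = res$pvalue,
    n_permutations = as.integer(n_permutations),
    n_null_shuffles = as.integer(n_null_shuffles),
    stringsAsFactors = FALSE
  )
}

#' Scan every miRNA x gene pair for the antagonism pattern
#'
#' Z-scores each feature across samples, scores all pairs with
#' [antagonism_pvalue()], and attaches Benjamini-Hochberg adjusted q-values
#' over the full pair family. Each pair consumes an RNG stream derived from
#' `seed` and its (row, column) position, so results do not depend on
#' evaluation order and any single pair can be re-run in isolation.
#'
#' Features that are constant across samples cannot be z-scored and are
#' dropped with a message before scanning.
#'
#' @param expr a [paired_expression_set()].
#' @param n_permutations,n_null_shuffles permutation parameters per pair.
#' @param seed integer master seed.
#' @param fdr_q FDR threshold used to set the `significant` flag
#'   (default 0.02).
#' @param progress_every log a progress message every this many pairs
#'   (`Inf` disables logging).
#' @return data frame with one row per (miRNA, gene) pair: `mirna_id`,
#'   `gene_id`, `coefficient`, `best_intercept`, `pvalue`, `qvalue`,
#'   `significant`.
#' @export
scan_all_pairs <- function(expr, n_permutations = 1000, n_null_shuffles = 100,
                           seed = 1, fdr_q = 0.02, progress_every = Inf) {
  stopifnot(inherits(expr, "paired_expression_set"))
  mi <- drop_constant_rows(expr$mirna, "miRNA")
  mg <- drop_constant_rows(expr$mrna, "mRNA")
  if (nrow(mi) == 0 || nrow(mg) == 0) {
    stop("schema error: an expression matrix has no usable features",
         call. = FALSE)
  }
  mi_z <- t(apply(mi, 1, zscore))
  mg_z <- t(apply(mg, 1, zscore))
  total <- nrow(mi_z) * nrow(mg_z)
  rows <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(mi_z))) {
    for (j in seq_len(nrow(mg_z))) {
      k <- k + 1L
      set.seed(derive_seed(seed, i, j))
      pair <- standardized_pair(mi_z[i, ], mg_z[j, ],
                                mirna_id = rownames(mi_z)[i],
                                gene_id = rownames(mg_z)[j],
                                standardize = FALSE)
      rows[[k]] <- antagonism_pvalue(pair, n_permutations, n_null_shuffles)
      if (k %% progress_every == 0) {
        message(sprintf("scanned %d / %d pairs", k, total))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$n_permutations <- NULL
  out$n_null_shuffles <- NULL
  out$qvalue <- bh_adjust(out$pvalue)
  out$significant <- out$qvalue <= fdr_q
  out
}

drop_constant_rows <- function(mat, what) {
  if (is.null(mat) || nrow(mat) == 0) {
    stop(sprintf("schema error: empty %s matrix", what), call. = FALSE)
  }
  sds <- apply(mat, 1, sd)
  bad <- sds == 0
  if (any(bad)) {
    message(sprintf("dropping %d constant %s feature(s)", sum(bad), what))
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}
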