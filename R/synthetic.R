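#' Simulate a triangular expression-like miRNA/mRNA pair
#'
#' Generates the synthetic substrate used to characterize the antagonism
#' detector: `n_samples` points on the unit square of which a fixed count
#' `round(noise_fraction * n_samples)` are "noise" points drawn uniformly
#' from the upper triangle `x + y > 1` and the rest are "signal" points drawn
#' uniformly from the lower triangle `x + y <= 1`. With `null_mode = TRUE`
#' the triangular structure is destroyed and all points are uniform on the
#' whole square (for calibration of the null distribution of p-values).
#'
#' Sampling is by rejection from the unit square, which is exactly uniform on
#' each triangle. The noise count is fixed per dataset (not Bernoulli per
#' point), so the stated fraction holds exactly in every draw.
#'
#' @param n_samples number of samples (>= 2).
#' @param noise_fraction fraction of points violating the triangle, in
#'   `[0, 0.5]`.
#' @param seed integer seed; the draw is fully determined by it.
#' @param null_mode if `TRUE`, ignore `noise_fraction` and draw uniformly on
#'   the unit square.
#' @return an object of class `synthetic_pair`: list with `x`, `y`,
#'   `n_samples`, `noise_fraction`, `seed`, `null_mode`.
#' @export
simulate_pair <- function(n_samples, noise_fraction = 0, seed = 1,
                          null_mode = FALSE) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 2 ||
      n_samples != round(n_samples)) {
    stop("n_samples must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(noise_fraction) || length(noise_fraction) != 1 ||
      !is.finite(noise_fraction) || noise_fraction < 0 ||
      noise_fraction > 0.5) {
    stop("noise_fraction must be a finite number in [0, 0.5]", call. = FALSE)
  }
  n <- as.integer(n_samples)
  set.seed(as.integer(seed))
  if (null_mode) {
    x <- runif(n)
    y <- runif(n)
  } else {
    n_noise <- as.integer(round(noise_fraction * n))
    sig <- draw_triangle(n - n_noise, upper = FALSE)
    noi <- draw_triangle(n_noise, upper = TRUE)
    x <- c(sig$x, noi$x)
    y <- c(sig$y, noi$y)
  }
  structure(
    list(x = x, y = y, n_samples = n,
         noise_fraction = if (null_mode) NA_real_ else noise_fraction,
         seed = as.integer(seed), null_mode = null_mode),
    class = c("synthetic_pair", "list")
  )
}

# rejection sampling: uniform on the lower (x+y<=1) or upper (x+y>1) triangle
draw_triangle <- function(n, upper = FALSE) {
  x <- numeric(n)
  y <- numeric(n)
  got <- 0L
  while (got < n) {
    need <- n - got
    # expect ~50% acceptance; draw with some headroom
    m <- max(16L, ceiling(need * 2.5))
    u <- runif(m)
    v <- runif(m)
    keep <- if (upper) u + v > 1 else u + v <= 1
    take <- min(need, sum(keep))
    if (take > 0) {
      idx <- which(keep)[seq_len(take)]
      x[got + seq_len(take)] <- u[idx]
      y[got + seq_len(take)] <- v[idx]
      got <- got + take
    }
  }
  list(x = x, y = y)
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "synthetic_pair: n = %d, noise fraction = %s, seed = %d%s\n",
    x$n_samples,
    if (is.na(x$noise_fraction)) "-" else format(x$noise_fraction),
    x$seed, if (isTRUE(x$null_mode)) " (null mode: uniform square)" else ""))
  invisible(x)
}

#' Write a simulated pair to TSV
#'
#' @param pair a `synthetic_pair`.
#' @param path output file; columns `sample_id`, `x`, `y` with header.
#' @return `path`, invisibly.
#' @export
write_pair_tsv <- function(pair, path) {
  stopifnot(inherits(pair, "synthetic_pair"))
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(pair$n_samples)),
                   x = pair$x, y = pair$y)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Power benchmark of the antagonism detector on simulated data
#'
#' For every (sample size, noise level) cell, simulates `n_datasets`
#' triangular pairs, scores each with the antagonism permutation test after
#' the same z-score transform applied to real data, and records the mean
#' permutation p-value. This reproduces the detector's operating
#' characteristic: mean p-value falls with sample size and rises with noise.
#'
#' Each dataset consumes an independent RNG stream derived from
#' `(seed, cell index, replicate index)`, so any cell can be recomputed in
#' isolation and results do not depend on cell order. A dataset whose scoring
#' fails marks its whole cell `NA` rather than being silently averaged.
#'
#' @param sample_sizes integer vector of sample counts per dataset.
#' @param noise_levels numeric vector of noise fractions in `[0, 0.5]`.
#' @param n_datasets simulated datasets per cell.
#' @param n_permutations permutation rounds per dataset score.
#' @param n_null_shuffles shuffle-null size inside each coefficient.
#' @param seed integer master seed.
#' @return an object of class `benchmark_grid`: list with `mean_pvalue`
#'   (matrix, rows = sample sizes, cols = noise levels), `pvalues` (list of
#'   per-cell p-value vectors), and the grid parameters.
#' @export
run_benchmark <- function(sample_sizes, noise_levels, n_datasets = 100,
                          n_permutations = 500, n_null_shuffles = 100,
                          seed = 1) {
  stopifnot(length(sample_sizes) >= 1, all(sample_sizes >= 2),
            length(noise_levels) >= 1,
            all(noise_levels >= 0 & noise_levels <= 0.5),
            n_datasets >= 1, n_permutations >= 1)
  grid <- matrix(NA_real_, nrow = length(sample_sizes),
                 ncol = length(noise_levels),
                 dimnames = list(paste0("n", sample_sizes),
                                 paste0("noise", noise_levels)))
  cells <- vector("list", length(sample_sizes) * length(noise_levels))
  cell_idx <- 0L
  for (i in seq_along(sample_sizes)) {
    for (j in seq_along(noise_levels)) {
      cell_idx <- cell_idx + 1L
      pv <- rep(NA_real_, n_datasets)
      ok <- TRUE
      for (r in seq_len(n_datasets)) {
        res <- tryCatch({
          sp <- simulate_pair(sample_sizes[i], noise_levels[j],
                              seed = derive_seed(seed, cell_idx, r, 1))
          pair <- standardized_pair(sp$x, sp$y)
          set.seed(derive_seed(seed, cell_idx, r, 2))
          antagonism_pvalue(pair, n_permutations, n_null_shuffles)$pvalue
        }, error = function(e) {
          warning(sprintf("cell (n=%d, noise=%g) replicate %d failed: %s",
                          sample_sizes[i], noise_levels[j], r,
                          conditionMessage(e)), call. = FALSE)
          NA_real_
        })
        if (is.na(res)) ok <- FALSE
        pv[r] <- res
      }
      cells[[cell_idx]] <- pv
      grid[i, j] <- if (ok) mean(pv) else NA_real_
    }
  }
  structure(
    list(mean_pvalue = grid, pvalues = cells,
         sample_sizes = sample_sizes, noise_levels = noise_levels,
         n_datasets = n_datasets, n_permutations = n_permutations,
         n_null_shuffles = n_null_shuffles, seed = seed),
    class = "benchmark_grid"
  )
}

#' @export
print.benchmark_grid <- function(x, ...) {
  cat(sprintf("benchmark_grid: %d x %d cells, %d datasets/cell, M = %d\n",
              nrow(x$mean_pvalue), ncol(x$mean_pvalue), x$n_datasets,
              x$n_permutations))
  print(round(x$mean_pvalue, 4))
  invisible(x)
}

#' Write a benchmark grid to TSV (long format)
#'
#' @param grid a `benchmark_grid`.
#' @param path output file; columns `n_samples`, `noise_fraction`,
#'   `mean_pvalue`.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "benchmark_grid"))
  df <- expand.grid(n_samples = grid$sample_sizes,
                    noise_fraction = grid$noise_levels)
  df$mean_pvalue <- as.vector(grid$mean_pvalue)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Line plot of mean p-value against sample size, one line per noise level
#'
#' @param grid a `benchmark_grid`.
#' @return a ggplot object.
#' @export
plot_benchmark <- function(grid) {
  stopifnot(inherits(grid, "benchmark_grid"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_benchmark() needs the ggplot2 package", call. = FALSE)
  }
  df <- expand.grid(n_samples = grid$sample_sizes,
                    noise_fraction = grid$noise_levels)
  df$mean_pvalue <- as.vector(grid$mean_pvalue)
  df$noise <- factor(df$noise_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_samples, y = .data$mean_pvalue,
                                   colour = .data$noise)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(x = "samples per dataset", y = "mean permutation p-value",
                  colour = "noise fraction") +
    ggplot2::theme_minimal()
}
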