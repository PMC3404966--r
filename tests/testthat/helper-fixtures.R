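# programmatic fixtures shared across test files

# expression matrices with named features/samples, i.i.d. Gaussian rows
make_expr <- function(n_features, n_samples, prefix, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_features * n_samples), nrow = n_features,
              dimnames = list(paste0(prefix, seq_len(n_features)),
                              paste0("S", seq_len(n_samples))))
  m
}

# paired set with an antagonistic (triangular) pair planted at (mi1, g1)
make_planted_set <- function(n_mirna, n_gene, n_samples, seed,
                             noise_fraction = 0) {
  mi <- make_expr(n_mirna, n_samples, "mi", seed)
  mg <- make_expr(n_gene, n_samples, "g", seed + 1000)
  sp <- simulate_pair(n_samples, noise_fraction, seed = seed + 2000)
  mi[1, ] <- sp$x
  mg[1, ] <- sp$y
  paired_expression_set(mi, mg)
}

# write a small expression TSV and return its path
write_expr_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# write a FASTA file from a named character vector
write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(mapply(function(id, s) c(paste0(">", id), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# pure-R replay of the C++ coefficient: same RNG stream (sample.int), then
# brute-force double loop over the union-of-all-sums candidate set
r_oracle_coefficient <- function(x, y, n_null_shuffles) {
  n <- length(x)
  nulls <- c()
  for (s in seq_len(n_null_shuffles)) {
    p <- sample.int(n)
    nulls <- c(nulls, x + y[p])
  }
  obs <- x + y
  cand <- sort(unique(c(obs, nulls)))
  diffs <- vapply(cand, function(v) mean(obs <= v) - mean(nulls <= v),
                  numeric(1))
  obs_cand <- sort(unique(obs))
  d_obs <- vapply(obs_cand, function(v) mean(obs <= v) - mean(nulls <= v),
                  numeric(1))
  list(A_union = max(diffs), A = max(d_obs),
       b_star = obs_cand[which.max(d_obs)], null_sums = nulls)
}

# brute-force BH step-up definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# naive sliding-window seed count (regex-free)
naive_count <- function(utr, patterns) {
  k <- nchar(patterns[1])
  n <- nchar(utr)
  if (n < k) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1)) {
    if (substr(utr, i, i + k - 1) %in% patterns) hits <- hits + 1L
  }
  hits
}

# closed-form hypergeometric upper tail via binomial coefficients
hyper_tail_brute <- function(ov, K, N, m) {
  i <- ov:min(K, m)
  sum(choose(K, i) * choose(N - K, m - i)) / choose(N, m)
}
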