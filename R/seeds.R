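#' Seed-match strings of a mature miRNA
#'
#' Derives, from the first eight 5' nucleotides of a mature miRNA sequence,
#' the DNA-alphabet strings whose presence in a 3'UTR constitutes a seed
#' match: the reverse complement of every contiguous window of length 6, 7
#' and 8 inside that seed region (k = 6: positions 1-6, 2-7, 3-8; k = 7:
#' 1-7, 2-8; k = 8: 1-8).
#'
#' The seed region starts at position 1 by default; `offset = 1` shifts it to
#' positions 2-9 for the canonical seed-theory convention that discounts the
#' first nucleotide.
#'
#' @param mature_sequence mature miRNA sequence, RNA alphabet (`T` is
#'   tolerated and read as `U`), length >= 8 + offset.
#' @param mirna_id identifier carried into the catalog.
#' @param offset 0-based shift of the eight-nucleotide seed region
#'   (default 0).
#' @return an object of class `seed_catalog`: list with `mirna_id`,
#'   `mature_sequence`, and `matches`, a list mapping `"6"`, `"7"`, `"8"` to
#'   character vectors of unique match strings in the `ACGT` alphabet.
#' @export
extract_seed_matches <- function(mature_sequence, mirna_id = "miRNA",
                                 offset = 0) {
  stopifnot(length(mature_sequence) == 1, is.character(mature_sequence),
            offset >= 0, offset == round(offset))
  seq_u <- chartr("tT", "uU", mature_sequence)
  seq_u <- toupper(seq_u)
  if (nchar(seq_u) < 8 + offset) {
    stop(sprintf("mature sequence shorter than %d nt", 8 + offset),
         call. = FALSE)
  }
  if (grepl("[^ACGU]", seq_u)) {
    stop("illegal character in mature miRNA sequence (alphabet ACGU)",
         call. = FALSE)
  }
  region <- substr(seq_u, 1 + offset, 8 + offset)
  region_dna <- chartr("U", "T", region)
  matches <- lapply(c(`6` = 6L, `7` = 7L, `8` = 8L), function(k) {
    starts <- seq_len(8 - k + 1)
    unique(vapply(starts, function(s) {
      win <- substr(region_dna, s, s + k - 1)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    }, character(1)))
  })
  structure(
    list(mirna_id = as.character(mirna_id), mature_sequence = seq_u,
         matches = matches),
    class = "seed_catalog"
  )
}

#' @export
print.seed_catalog <- function(x, ...) {
  cat(sprintf("seed_catalog for %s (%s...)\n", x$mirna_id,
              substr(x$mature_sequence, 1, 8)))
  for (k in names(x$matches)) {
    cat(sprintf("  %s-mers: %s\n", k, paste(x$matches[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Count seed matches of one miRNA in one 3'UTR
#'
#' Total number of occurrences, overlapping included, of every length-k match
#' string of the catalog in the UTR (sliding window, step 1). Counting uses
#' `Biostrings::countPattern`, which reports overlapping hits.
#'
#' @param utr_sequence 3'UTR sequence, DNA alphabet (`U` tolerated, read as
#'   `T`); an empty string counts 0.
#' @param catalog a `seed_catalog`.
#' @param k seed length, one of 6, 7, 8.
#' @return non-negative integer count.
#' @export
count_matches <- function(utr_sequence, catalog, k) {
  stopifnot(inherits(catalog, "seed_catalog"), k %in% c(6, 7, 8),
            length(utr_sequence) == 1, is.character(utr_sequence))
  utr <- toupper(chartr("uU", "tT", utr_sequence))
  if (nchar(utr) == 0) return(0L)
  subject <- Biostrings::DNAString(utr)
  pats <- catalog$matches[[as.character(k)]]
  sum(vapply(pats, function(p) {
    Biostrings::countPattern(p, subject)
  }, integer(1)))
}

#' Seed enrichment of predicted targets against miRNA-label shuffles
#'
#' Tests whether the 3'UTRs of antagonism-predicted targets carry more seed
#' matches for their predicted miRNAs than expected by chance. The observed
#' statistic is the total match count over all predicted pairs, per seed
#' length k in \{6, 7, 8\}. The null preserves each target's 3'UTR (hence
#' nucleotide composition and length) and the per-miRNA link counts: the
#' assignment of miRNA labels to the target multiset is randomly permuted
#' `n_shuffles` times (unbiased Fisher-Yates via [sample()]), and the real
#' count is referred to a normal distribution with the mean and standard
#' deviation of the shuffled counts (one-sided, enrichment).
#'
#' @param edges edge table of predicted pairs (`mirna_id`, `gene_id`).
#' @param utr_db named character vector (or `DNAStringSet`) of 3'UTR
#'   sequences keyed by gene id; for duplicated gene ids the longest isoform
#'   is used (with a message).
#' @param mature_db named character vector (or `XStringSet`) of mature miRNA
#'   sequences keyed by miRNA id.
#' @param n_shuffles number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param offset seed-region offset, see [extract_seed_matches()].
#' @return data frame with one row per k: `k`, `observed_count`, `null_mean`,
#'   `null_sd`, `zscore`, `pvalue`, `n_shuffles`, `degenerate` (`TRUE` when
#'   the statistic is permutation-invariant, `null_sd == 0`).
#' @export
seed_enrichment <- function(edges, utr_db, mature_db, n_shuffles = 1000,
                            seed = 1, offset = 0) {
  if (!is.numeric(n_shuffles) || n_shuffles < 1) {
    stop("n_shuffles must be at least 1", call. = FALSE)
  }
  utr_db <- as_named_seqs(utr_db, "uT")
  mature_db <- as_named_seqs(mature_db, "mature")
  utr_db <- dedupe_longest(utr_db)
  stopifnot(is.data.frame(edges), nrow(edges) >= 1)
  has_seq <- edges$mirna_id %in% names(mature_db)
  if (!all(has_seq)) {
    stop(sprintf("%d edge(s) reference miRNAs without a mature sequence",
                 sum(!has_seq)), call. = FALSE)
  }
  has_utr <- edges$gene_id %in% names(utr_db)
  if (!all(has_utr)) {
    message(sprintf("dropping %d edge(s) whose gene lacks a 3'UTR",
                    sum(!has_utr)))
    edges <- edges[has_utr, , drop = FALSE]
  }
  if (nrow(edges) == 0) stop("no edges left after UTR matching", call. = FALSE)
  mirnas <- unique(edges$mirna_id)
  if (length(mirnas) < 2) {
    stop("label permutation needs at least 2 distinct miRNAs", call. = FALSE)
  }
  genes <- unique(edges$gene_id)
  catalogs <- lapply(setNames(mirnas, mirnas), function(m) {
    extract_seed_matches(mature_db[[m]], mirna_id = m, offset = offset)
  })
  # per-k count matrix over the distinct (miRNA, gene) combinations; both the
  # observed and every shuffled statistic are sums of its entries
  ks <- c(6L, 7L, 8L)
  count_mat <- lapply(setNames(ks, ks), function(k) {
    m <- matrix(0L, nrow = length(mirnas), ncol = length(genes),
                dimnames = list(mirnas, genes))
    for (mi in mirnas) {
      for (g in genes) {
        m[mi, g] <- count_matches(utr_db[[g]], catalogs[[mi]], k)
      }
    }
    m
  })
  mi_idx <- match(edges$mirna_id, mirnas)
  g_idx <- match(edges$gene_id, genes)
  set.seed(as.integer(seed))
  perms <- replicate(n_shuffles, sample.int(nrow(edges)), simplify = FALSE)
  rows <- lapply(ks, function(k) {
    cm <- count_mat[[as.character(k)]]
    obs <- sum(cm[cbind(mi_idx, g_idx)])
    null_counts <- vapply(perms, function(p) {
      sum(cm[cbind(mi_idx[p], g_idx)])
    }, numeric(1))
    mu <- mean(null_counts)
    s <- sd(null_counts)
    degenerate <- !is.finite(s) || s == 0
    z <- if (degenerate) NA_real_ else (obs - mu) / s
    pv <- if (degenerate) 1 else pnorm(z, lower.tail = FALSE)
    data.frame(k = k, observed_count = obs, null_mean = mu, null_sd = s,
               zscore = z, pvalue = pv, n_shuffles = as.integer(n_shuffles),
               degenerate = degenerate)
  })
  do.call(rbind, rows)
}

as_named_seqs <- function(db, what) {
  if (methods::is(db, "XStringSet")) db <- as.character(db)
  if (!is.character(db) || is.null(names(db)) || any(names(db) == "")) {
    stop(sprintf("%s sequences must be a named character vector or XStringSet",
                 what), call. = FALSE)
  }
  db
}

dedupe_longest <- function(db) {
  if (!anyDuplicated(names(db))) return(db)
  message(sprintf("%d gene(s) with multiple UTR isoforms: keeping the longest",
                  sum(duplicated(names(db)))))
  ord <- order(names(db), -nchar(db))
  db <- db[ord]
  db[!duplicated(names(db))]
}
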