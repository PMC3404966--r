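#' Hypergeometric gene-set enrichment of one target set
#'
#' Upper-tail hypergeometric test of the overlap between a miRNA's predicted
#' target set and each annotation category, within the universe of genes that
#' entered the scan. Categories are intersected with the universe before
#' testing; the target set must be a subset of the universe.
#'
#' @param target_set character vector of predicted target gene ids.
#' @param annotation named list mapping category id to gene id vectors.
#' @param universe character vector: all genes the scan could have predicted.
#' @param p_threshold significance flag threshold on the raw p-value
#'   (default 0.001). No multiple-testing correction is applied here; the
#'   pipeline's negative control is a label-shuffle randomization instead.
#' @param mirna_id identifier carried into the rows.
#' @return data frame with one row per (non-empty) category: `mirna_id`,
#'   `category_id`, `overlap`, `set_size`, `category_size`, `universe_size`,
#'   `pvalue`, `significant`.
#' @export
hypergeom_enrich <- function(target_set, annotation, universe,
                             p_threshold = 0.001, mirna_id = NA_character_) {
  universe <- unique(as.character(universe))
  target_set <- unique(as.character(target_set))
  if (!all(target_set %in% universe)) {
    stop("target_set must be a subset of the universe", call. = FALSE)
  }
  if (length(target_set) == 0) {
    warning("empty target set: no enrichment computed", call. = FALSE)
    return(data.frame(mirna_id = character(), category_id = character(),
                      overlap = integer(), set_size = integer(),
                      category_size = integer(), universe_size = integer(),
                      pvalue = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  m <- length(target_set)
  rows <- lapply(names(annotation), function(cat_id) {
    cat_genes <- intersect(unique(annotation[[cat_id]]), universe)
    K <- length(cat_genes)
    if (K == 0) return(NULL)
    ov <- length(intersect(target_set, cat_genes))
    pv <- phyper(ov - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(mirna_id = mirna_id, category_id = cat_id, overlap = ov,
               set_size = m, category_size = K, universe_size = N,
               pvalue = pv, significant = pv <= p_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no annotation category intersects the universe", call. = FALSE)
    out <- hypergeom_enrich(character(0), annotation, universe,
                            p_threshold, mirna_id)
  }
  rownames(out) <- NULL
  out
}

#' Per-miRNA target sets from an edge table
#'
#' @param edges edge table (`mirna_id`, `gene_id`).
#' @return named list mapping miRNA id to its predicted target gene ids.
#' @export
target_sets <- function(edges) {
  if (nrow(edges) == 0) return(setNames(list(), character(0)))
  lapply(split(edges$gene_id, edges$mirna_id), unique)
}

#' Target sets supported by both expression pattern and seed occurrence
#'
#' Intersects the expression-based prediction with sequence evidence: a gene
#' stays in a miRNA's target set only if the pair is a network edge AND the
#' gene's 3'UTR carries at least one seed match (any k) for that miRNA.
#'
#' @param edges edge table (`mirna_id`, `gene_id`).
#' @param seed_hits data frame with `mirna_id`, `gene_id`, `has_seed`
#'   (logical), e.g. built from [count_matches()] over the edge list.
#' @return named list mapping miRNA id to the restricted target set (possibly
#'   empty; miRNAs with no surviving target are kept as empty sets).
#' @export
combined_target_sets <- function(edges, seed_hits) {
  stopifnot(all(c("mirna_id", "gene_id", "has_seed") %in% names(seed_hits)))
  if (nrow(edges) == 0) return(setNames(list(), character(0)))
  hit_key <- pair_key(seed_hits$mirna_id[seed_hits$has_seed],
                      seed_hits$gene_id[seed_hits$has_seed])
  keep <- pair_key(edges$mirna_id, edges$gene_id) %in% hit_key
  sets <- lapply(split(edges$gene_id[keep],
                       factor(edges$mirna_id[keep],
                              levels = unique(edges$mirna_id))),
                 unique)
  sets
}

#' Enrichment of every miRNA's target set
#'
#' @param edges edge table.
#' @param annotation named list of category gene sets.
#' @param universe scan universe of gene ids.
#' @param p_threshold raw p-value threshold for the significance flag.
#' @param min_set_size skip miRNAs with fewer predicted targets (default 1).
#' @return data frame of [hypergeom_enrich()] rows over all miRNAs.
#' @export
mirna_target_enrichment <- function(edges, annotation, universe,
                                    p_threshold = 0.001, min_set_size = 1) {
  sets <- target_sets(edges)
  rows <- lapply(names(sets), function(m) {
    if (length(sets[[m]]) < min_set_size) return(NULL)
    hypergeom_enrich(sets[[m]], annotation, universe, p_threshold,
                     mirna_id = m)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- hypergeom_enrich(character(0), annotation, universe, p_threshold)
  }
  out
}

#' Label-shuffle negative control for the GO-style enrichment
#'
#' Re-runs the per-miRNA enrichment on networks in which the target node
#' labels are randomly permuted while every miRNA keeps its connectivity,
#' and reports how often categories reach the real-data threshold. With a
#' sound test, almost no category should stay significant on shuffled
#' networks.
#'
#' @param edges edge table of the real network.
#' @param annotation named list of category gene sets.
#' @param universe scan universe of gene ids.
#' @param n_rounds number of shuffle rounds (>= 1).
#' @param p_threshold the threshold used on the real data.
#' @param seed integer seed.
#' @return list with `null_pvalues` (all p-values pooled over rounds),
#'   `frac_significant` (per-round fraction of tests at or below the
#'   threshold), and `n_rounds`.
#' @export
randomized_go_control <- function(edges, annotation, universe, n_rounds = 100,
                                  p_threshold = 0.001, seed = 1) {
  if (!is.numeric(n_rounds) || n_rounds < 1) {
    stop("n_rounds must be at least 1", call. = FALSE)
  }
  stopifnot(nrow(edges) >= 1)
  set.seed(as.integer(seed))
  frac <- numeric(n_rounds)
  pooled <- vector("list", n_rounds)
  gene_pool <- unique(as.character(universe))
  for (r in seq_len(n_rounds)) {
    shuf <- edges
    # relabel target nodes: a random injection of the network's gene labels
    # into the universe keeps each miRNA's degree and the label multiset size
    old <- unique(edges$gene_id)
    new <- sample(gene_pool, length(old))
    shuf$gene_id <- new[match(edges$gene_id, old)]
    res <- mirna_target_enrichment(shuf, annotation, universe, p_threshold)
    pooled[[r]] <- res$pvalue
    frac[r] <- if (nrow(res) == 0) 0 else mean(res$pvalue <= p_threshold)
  }
  list(null_pvalues = unlist(pooled), frac_significant = frac,
       n_rounds = as.integer(n_rounds))
}
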