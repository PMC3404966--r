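#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over a family of p-values. Delegates to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("pvalues must be numbers in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Assemble the significant-link edge table
#'
#' Edges of the bipartite miRNA-gene network are exactly the scored pairs
#' whose BH q-value does not exceed the FDR threshold.
#'
#' @param scores data frame from [scan_all_pairs()] or [correlation_scan()]
#'   (needs `mirna_id`, `gene_id`, `pvalue`, `qvalue` and a score column
#'   named `coefficient` or `r`).
#' @param q_threshold FDR threshold (default 0.02).
#' @return an `edge_table` data frame: `mirna_id`, `gene_id`, `score`,
#'   `pvalue`, `qvalue`, with attribute `q_threshold`.
#' @export
build_network <- function(scores, q_threshold = 0.02) {
  stopifnot(is.data.frame(scores),
            all(c("mirna_id", "gene_id", "pvalue", "qvalue") %in%
                  names(scores)))
  score_col <- if ("coefficient" %in% names(scores)) "coefficient" else "r"
  if (!score_col %in% names(scores)) {
    stop("scores need a 'coefficient' or 'r' column", call. = FALSE)
  }
  if (anyDuplicated(scores[c("mirna_id", "gene_id")])) {
    stop("duplicate (mirna_id, gene_id) rows in scores", call. = FALSE)
  }
  keep <- scores$qvalue <= q_threshold
  out <- data.frame(mirna_id = scores$mirna_id[keep],
                    gene_id = scores$gene_id[keep],
                    score = scores[[score_col]][keep],
                    pvalue = scores$pvalue[keep],
                    qvalue = scores$qvalue[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Per-node connectivity of an edge table
#'
#' @param edges an edge table (data frame with `mirna_id`, `gene_id`).
#' @return data frame `node_id`, `node_class` (`"miRNA"` or `"gene"`),
#'   `k` (edge count).
#' @export
node_connectivity <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    return(data.frame(node_id = character(), node_class = character(),
                      k = integer(), stringsAsFactors = FALSE))
  }
  km <- table(edges$mirna_id)
  kg <- table(edges$gene_id)
  data.frame(
    node_id = c(names(km), names(kg)),
    node_class = c(rep("miRNA", length(km)), rep("gene", length(kg))),
    k = as.integer(c(km, kg)),
    stringsAsFactors = FALSE
  )
}

#' Hub detection calibrated on a randomized-data network
#'
#' A node is a hub when its connectivity exceeds a cutoff derived from the
#' connectivity distribution of a network rebuilt by the same pipeline on
#' sample-shuffled expression data. miRNA hubs and target (gene) hubs are
#' called separately, each against the randomized distribution of its own
#' class. Two cutoff rules are available: `"max75"` (default), 0.75 times the
#' maximal connectivity seen in the randomized network, and `"percentile75"`,
#' the 75th percentile of the randomized connectivity distribution.
#'
#' @param edges edge table of the real network.
#' @param randomized_edges edge table built by the identical pipeline on
#'   sample-shuffled data at the same threshold.
#' @param rule cutoff rule, `"max75"` or `"percentile75"`.
#' @return a `hub_table` data frame: `node_id`, `node_class`, `k`, `is_hub`,
#'   `cutoff_used`.
#' @export
detect_hubs <- function(edges, randomized_edges,
                        rule = c("max75", "percentile75")) {
  rule <- match.arg(rule)
  kc <- node_connectivity(edges)
  if (nrow(kc) == 0) {
    out <- cbind(kc, is_hub = logical(), cutoff_used = numeric())
    class(out) <- c("hub_table", "data.frame")
    return(out)
  }
  kr <- node_connectivity(randomized_edges)
  if (nrow(kr) == 0) {
    warning("empty randomized network: cutoff 0, every connected node is a hub",
            call. = FALSE)
  }
  cutoff_for <- function(cls) {
    kk <- kr$k[kr$node_class == cls]
    if (length(kk) == 0) return(0)
    if (rule == "max75") 0.75 * max(kk) else unname(quantile(kk, 0.75))
  }
  cut_mi <- cutoff_for("miRNA")
  cut_ge <- cutoff_for("gene")
  kc$cutoff_used <- ifelse(kc$node_class == "miRNA", cut_mi, cut_ge)
  kc$is_hub <- kc$k > kc$cutoff_used
  kc <- kc[c("node_id", "node_class", "k", "is_hub", "cutoff_used")]
  class(kc) <- c("hub_table", "data.frame")
  kc
}

#' Deterministic 1-based ranking of scored pairs
#'
#' Orders pairs by increasing p-value, breaking ties by decreasing absolute
#' score and then lexicographically by (mirna_id, gene_id), so two runs over
#' the same scores always yield the same ranking.
#'
#' @param scores data frame with `mirna_id`, `gene_id`, `pvalue` and a score
#'   column (`coefficient` or `r`).
#' @return `scores` with a `rank` column, sorted by rank.
#' @export
rank_predictions <- function(scores) {
  score_col <- if ("coefficient" %in% names(scores)) "coefficient" else "r"
  o <- order(scores$pvalue, -abs(scores[[score_col]]),
             scores$mirna_id, scores$gene_id)
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

pair_key <- function(mirna_id, gene_id) paste(mirna_id, gene_id, sep = "\r")

#' Merge ranked prediction lists by best rank
#'
#' Combines several methods or datasets by keeping, for each (miRNA, gene)
#' pair, its minimum rank across lists, then re-ranking (ties broken by
#' pair id) so the merged list is again a 1-based unique ranking.
#'
#' @param rank_tables list of data frames with `mirna_id`, `gene_id`, `rank`.
#' @return data frame `mirna_id`, `gene_id`, `best_rank`, `rank`.
#' @export
merge_ranks <- function(rank_tables) {
  stopifnot(is.list(rank_tables), length(rank_tables) >= 1)
  all_df <- do.call(rbind, lapply(rank_tables, function(d) {
    d[c("mirna_id", "gene_id", "rank")]
  }))
  key <- pair_key(all_df$mirna_id, all_df$gene_id)
  best <- tapply(all_df$rank, key, min)
  first <- !duplicated(key)
  out <- data.frame(mirna_id = all_df$mirna_id[first],
                    gene_id = all_df$gene_id[first],
                    stringsAsFactors = FALSE)
  out$best_rank <- as.numeric(best[pair_key(out$mirna_id, out$gene_id)])
  o <- order(out$best_rank, out$mirna_id, out$gene_id)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cumulative-hit curve of a ranked prediction list against known targets
#'
#' For each rank r, counts how many experimentally validated (truth) pairs
#' appear among the top r predictions, the evaluation used to compare the
#' antagonism detector with the correlation baseline. Truth pairs absent from
#' the prediction universe can never be hit and are reported via a message.
#'
#' @param ranked data frame with `mirna_id`, `gene_id`, `rank` (1-based,
#'   unique).
#' @param truth_pairs data frame with `mirna_id`, `gene_id` of validated
#'   interactions.
#' @return data frame `rank`, `hits` (non-decreasing), one row per rank.
#' @export
rank_evaluation <- function(ranked, truth_pairs) {
  stopifnot(is.data.frame(ranked),
            all(c("mirna_id", "gene_id", "rank") %in% names(ranked)),
            all(c("mirna_id", "gene_id") %in% names(truth_pairs)))
  if (anyDuplicated(ranked$rank) || any(ranked$rank != round(ranked$rank))) {
    stop("ranks must be unique integers", call. = FALSE)
  }
  tkey <- unique(pair_key(truth_pairs$mirna_id, truth_pairs$gene_id))
  pkey <- pair_key(ranked$mirna_id, ranked$gene_id)
  missing <- setdiff(tkey, pkey)
  if (length(missing) > 0) {
    message(sprintf(
      "%d truth pair(s) absent from the prediction universe (never hit)",
      length(missing)))
  }
  o <- order(ranked$rank)
  hit <- pkey[o] %in% tkey
  data.frame(rank = ranked$rank[o], hits = cumsum(hit))
}

#' Write an edge table in SIF format for graph viewers
#'
#' @param edges edge table.
#' @param path output file; lines `mirna_id  targets  gene_id`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- sprintf("%s\ttargets\t%s", edges$mirna_id, edges$gene_id)
  writeLines(lines, path)
  invisible(path)
}
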