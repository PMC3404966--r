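#' Run the full antagonism-detection pipeline
#'
#' Executes, from normalized expression matrices on disk to result tables:
#' IQR filtering, the antagonism scan with BH adjustment, network assembly,
#' hub detection against a sample-shuffled randomized network, and (when
#' sequence / annotation inputs are supplied) seed enrichment and gene-set
#' enrichment with its shuffle control. A JSON manifest recording seeds,
#' parameters, package version and per-stage counts is written alongside the
#' tables. Any stage error aborts the run, names the stage, and removes
#' partial outputs.
#'
#' @param config named list with entries:
#'   \describe{
#'     \item{mirna, mrna}{paths to expression TSVs (required).}
#'     \item{out_dir}{output directory (required; created if absent).}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{n_permutations, n_null_shuffles}{scan parameters (defaults 1000,
#'       100).}
#'     \item{fdr_q}{FDR threshold for edges (default 0.02).}
#'     \item{iqr_filter}{apply the IQR variance filter (default `TRUE`).}
#'     \item{floor_quantile}{optional low-abundance floor quantile.}
#'     \item{hub_rule}{`"max75"` (default) or `"percentile75"`.}
#'     \item{utr_fasta, mature_fasta}{optional FASTA paths; both needed for
#'       the seed stage, otherwise it is skipped with a message.}
#'     \item{annotation}{optional GMT/TSV path; absent skips the GO stage.}
#'     \item{seed_shuffles}{seed-enrichment shuffles (default 1000).}
#'     \item{go_threshold}{raw p threshold for the GO stage (default 0.001).}
#'     \item{go_rounds}{GO shuffle-control rounds (default 100).}
#'   }
#' @return named list of written file paths, invisibly.
#' @export
run_full_pipeline <- function(config) {
  req <- c("mirna", "mrna", "out_dir")
  if (!all(req %in% names(config))) {
    stop("config needs at least: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(list(
    seed = 1L, n_permutations = 1000L, n_null_shuffles = 100L,
    fdr_q = 0.02, iqr_filter = TRUE, floor_quantile = NULL,
    hub_rule = "max75", utr_fasta = NULL, mature_fasta = NULL,
    annotation = NULL, seed_shuffles = 1000L, go_threshold = 0.001,
    go_rounds = 100L), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "load"
  counts <- list()
  res <- tryCatch({
    expr <- read_paired_expression(cfg$mirna, cfg$mrna)

    stage <- "filter"
    if (isTRUE(cfg$iqr_filter)) {
      mi <- iqr_filter(expr$mirna, cfg$floor_quantile)
      mg <- iqr_filter(expr$mrna, cfg$floor_quantile)
      expr <- paired_expression_set(mi, mg)
    }
    counts$mirnas_kept <- nrow(expr$mirna)
    counts$genes_kept <- nrow(expr$mrna)
    message(sprintf("filter: %d miRNAs, %d genes retained",
                    nrow(expr$mirna), nrow(expr$mrna)))

    stage <- "scan"
    scores <- scan_all_pairs(expr, cfg$n_permutations, cfg$n_null_shuffles,
                             seed = derive_seed(cfg$seed, 1),
                             fdr_q = cfg$fdr_q)
    counts$pairs_scored <- nrow(scores)
    emit(scores, "pairs.tsv")

    stage <- "network"
    edges <- build_network(scores, cfg$fdr_q)
    counts$edges <- nrow(edges)
    message(sprintf("network: %d significant edges at FDR %.3g",
                    nrow(edges), cfg$fdr_q))
    emit(edges, "edges.tsv")

    stage <- "hubs"
    shuffled <- shuffle_samples(expr, seed = derive_seed(cfg$seed, 2))
    rand_scores <- scan_all_pairs(shuffled, cfg$n_permutations,
                                  cfg$n_null_shuffles,
                                  seed = derive_seed(cfg$seed, 3),
                                  fdr_q = cfg$fdr_q)
    rand_edges <- build_network(rand_scores, cfg$fdr_q)
    hubs <- detect_hubs(edges, rand_edges, rule = cfg$hub_rule)
    counts$hubs <- sum(hubs$is_hub)
    message(sprintf("hubs: %d of %d connected nodes", sum(hubs$is_hub),
                    nrow(hubs)))
    emit(hubs, "hubs.tsv")

    stage <- "seeds"
    if (!is.null(cfg$utr_fasta) && !is.null(cfg$mature_fasta) &&
        nrow(edges) > 0) {
      utr_db <- read_fasta_seqs(cfg$utr_fasta, "DNA")
      mature_db <- read_fasta_seqs(cfg$mature_fasta, "RNA")
      se <- seed_enrichment(edges, utr_db, mature_db,
                            n_shuffles = cfg$seed_shuffles,
                            seed = derive_seed(cfg$seed, 4))
      emit(se, "seed_enrichment.tsv")
    } else {
      message("seeds: stage skipped (no UTR/mature FASTA or no edges)")
    }

    stage <- "enrichment"
    if (!is.null(cfg$annotation) && nrow(edges) > 0) {
      ann <- read_annotation(cfg$annotation)
      universe <- rownames(expr$mrna)
      go <- mirna_target_enrichment(edges, ann, universe, cfg$go_threshold)
      emit(go, "go_enrichment.tsv")
      ctrl <- randomized_go_control(edges, ann, universe, cfg$go_rounds,
                                    cfg$go_threshold,
                                    seed = derive_seed(cfg$seed, 5))
      emit(data.frame(round = seq_along(ctrl$frac_significant),
                      frac_significant = ctrl$frac_significant),
           "go_control.tsv")
    } else {
      message("enrichment: stage skipped (no annotation or no edges)")
    }

    stage <- "manifest"
    manifest <- list(
      package = "mirantag",
      version = as.character(utils::packageVersion("mirantag")),
      seed = cfg$seed,
      parameters = cfg[setdiff(names(cfg), c("mirna", "mrna", "out_dir"))],
      inputs = cfg[intersect(names(cfg),
                             c("mirna", "mrna", "utr_fasta", "mature_fasta",
                               "annotation"))],
      counts = counts,
      outputs = basename(written)
    )
    mp <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    written <- c(written, mp)
    setNames(as.list(written), basename(written))
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Shuffle the sample assignment of a paired expression set
#'
#' Randomizes the coupling between miRNA and mRNA measurements by permuting
#' the sample order of the mRNA matrix (labels kept), the randomization used
#' to calibrate hub cutoffs.
#'
#' @param expr a [paired_expression_set()].
#' @param seed integer seed.
#' @return a new `paired_expression_set` with the association destroyed.
#' @export
shuffle_samples <- function(expr, seed = 1) {
  stopifnot(inherits(expr, "paired_expression_set"))
  set.seed(as.integer(seed))
  p <- sample.int(length(expr$sample_ids))
  mrna <- expr$mrna[, p, drop = FALSE]
  colnames(mrna) <- expr$sample_ids
  paired_expression_set(expr$mirna, mrna)
}
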