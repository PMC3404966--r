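#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of feature
#' identifiers and a numeric body. Duplicate feature rows are collapsed by
#' their mean with a warning; rows containing missing values are dropped with
#' a message; any non-numeric cell aborts with the offending row and column
#' named.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, features in rows (unique rownames), samples in
#'   columns.
#' @export
read_expression <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) {
    stop("expression file needs a feature column plus at least one sample",
         call. = FALSE)
  }
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- !is.na(body) & body != "" & toupper(body) != "NA" & is.na(num)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "parse error in %s: non-numeric value '%s' at feature '%s', sample '%s'",
      path, body[w[1], w[2]], ids[w[1]], colnames(body)[w[2]]), call. = FALSE)
  }
  rownames(num) <- ids
  if (anyDuplicated(ids)) {
    warning(sprintf("collapsing %d duplicate feature id(s) by mean",
                    sum(duplicated(ids))), call. = FALSE)
    num <- do.call(rbind, lapply(split(seq_along(ids), ids), function(ix) {
      colMeans(num[ix, , drop = FALSE])
    }))
    num <- num[unique(ids), , drop = FALSE]
  }
  has_na <- apply(num, 1, anyNA)
  if (any(has_na)) {
    message(sprintf("dropping %d feature(s) with missing values",
                    sum(has_na)))
    num <- num[!has_na, , drop = FALSE]
  }
  num
}

#' Couple miRNA and mRNA expression matrices over the same samples
#'
#' The antagonism scan needs expression of every miRNA and every transcript
#' measured in the same samples. Both matrices must carry identical sample
#' identifiers in identical order; anything else is a schema error caught
#' before any computation.
#'
#' @param mirna numeric matrix, miRNAs x samples.
#' @param mrna numeric matrix, genes x samples.
#' @return an object of class `paired_expression_set` with elements `mirna`,
#'   `mrna`, `sample_ids`.
#' @export
paired_expression_set <- function(mirna, mrna) {
  stopifnot(is.matrix(mirna), is.matrix(mrna),
            is.numeric(mirna), is.numeric(mrna))
  if (is.null(colnames(mirna)) || is.null(colnames(mrna))) {
    stop("schema error: both matrices need sample ids as column names",
         call. = FALSE)
  }
  if (!identical(colnames(mirna), colnames(mrna))) {
    stop("schema error: sample ids differ (or differ in order) between the miRNA and mRNA matrices",
         call. = FALSE)
  }
  if (anyNA(mirna) || anyNA(mrna)) {
    stop("schema error: matrices must be free of missing values", call. = FALSE)
  }
  structure(list(mirna = mirna, mrna = mrna, sample_ids = colnames(mirna)),
            class = "paired_expression_set")
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat(sprintf("paired_expression_set: %d miRNAs x %d genes over %d samples\n",
              nrow(x$mirna), nrow(x$mrna), length(x$sample_ids)))
  invisible(x)
}

#' Read coupled miRNA and mRNA expression files
#'
#' @param mirna_path,mrna_path TSV files as accepted by [read_expression()].
#' @return a [paired_expression_set()].
#' @export
read_paired_expression <- function(mirna_path, mrna_path) {
  paired_expression_set(read_expression(mirna_path),
                        read_expression(mrna_path))
}

#' Variance filter by interquartile range
#'
#' Keeps features whose across-sample IQR strictly exceeds the median IQR of
#' all features, discarding the low-variation half whose apparent associations
#' would be dominated by noise. Optionally a low-abundance floor is applied
#' first: features whose median expression falls below the given quantile of
#' all feature medians are removed.
#'
#' @param mat numeric matrix, features x samples (>= 2 features, >= 2
#'   samples).
#' @param floor_quantile optional abundance floor in `(0, 1)`; `NULL`
#'   (default) disables it.
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
iqr_filter <- function(mat, floor_quantile = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2) {
    stop("IQR is undefined on a single sample", call. = FALSE)
  }
  if (nrow(mat) < 2) {
    stop("iqr_filter() needs at least 2 features", call. = FALSE)
  }
  if (!is.null(floor_quantile)) {
    med <- apply(mat, 1, median)
    mat <- mat[med >= quantile(med, floor_quantile), , drop = FALSE]
  }
  iqrs <- apply(mat, 1, IQR)
  keep <- iqrs > median(iqrs)
  if (!any(keep)) {
    warning("no feature exceeds the median IQR; returning an empty matrix",
            call. = FALSE)
  }
  mat[keep, , drop = FALSE]
}

#' Read gene-set annotations (GMT or two-column TSV)
#'
#' A `.gmt` file is parsed with `fgsea::gmtPathways()`; any other extension is
#' read as a headerless two-column table `category<TAB>gene`.
#'
#' @param path annotation file.
#' @return named list mapping category id to a character vector of gene ids.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    if (!requireNamespace("fgsea", quietly = TRUE)) {
      stop("reading GMT files needs the fgsea package", call. = FALSE)
    }
    return(fgsea::gmtPathways(path))
  }
  df <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(df) < 2) {
    stop("two-column annotation expected: category<TAB>gene", call. = FALSE)
  }
  lapply(split(df[[2]], df[[1]]), unique)
}

#' Read named sequences from FASTA
#'
#' Thin wrapper over Biostrings returning plain named character vectors, the
#' sequence form the seed-analysis functions accept. Headers are truncated at
#' the first whitespace to match expression-matrix identifiers.
#'
#' @param path FASTA file.
#' @param type `"RNA"` for mature miRNA sequences, `"DNA"` for 3'UTRs.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path, type = c("DNA", "RNA")) {
  type <- match.arg(type)
  # mature miRNA files in the wild mix T and U; read loosely and let the
  # seed extractor normalize and validate the alphabet
  set <- if (type == "RNA") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
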