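# Validated containers. These are deliberately thin: plain base-R matrices
# and data frames with naming conventions, checked on entry.

#' Validate (and coerce to) an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix of normalized,
#' log-scale expression with unique gene rownames and unique sample colnames
#' and no missing values.
#'
#' @param x numeric matrix (or object coercible to one) with dimnames.
#' @param what label used in error messages.
#' @return the validated matrix.
#' @export
as_expression_matrix <- function(x, what = "expression matrix") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(what, ": values must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, ": missing or non-finite values are not allowed", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, ": gene rownames and sample colnames are required", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(what, ": duplicated gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicated sample ids", call. = FALSE)
  x
}

#' Construct a prior matrix
#'
#' A prior matrix P is a (sparse) genes x TFs matrix of prior TF-gene
#' evidence. ATAC/motif-derived priors are binary (0/1); signed priors
#' (e.g. from knockout experiments) carry entries in \{-1, 0, +1\} or real
#' scores.
#'
#' @param entries matrix or Matrix, genes in rows, TFs in columns.
#' @param gene_ids,tf_ids optional dimnames (taken from \code{entries} if
#'   absent).
#' @param source_tag character label recording the evidence source.
#' @return a \code{\link[Matrix]{sparseMatrix}} (dgCMatrix) with dimnames and
#'   a \code{source_tag} attribute.
#' @export
prior_matrix <- function(entries, gene_ids = rownames(entries),
                         tf_ids = colnames(entries), source_tag = "prior") {
  if (is.null(gene_ids) || is.null(tf_ids))
    stop("prior matrix: gene and TF ids are required", call. = FALSE)
  if (anyDuplicated(gene_ids) || anyDuplicated(tf_ids))
    stop("prior matrix: duplicated gene or TF ids", call. = FALSE)
  P <- methods::as(methods::as(Matrix::Matrix(entries, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (nrow(P) != length(gene_ids) || ncol(P) != length(tf_ids))
    stop("prior matrix: dimensions do not match id lists", call. = FALSE)
  dimnames(P) <- list(gene_ids, tf_ids)
  attr(P, "source_tag") <- source_tag
  P
}

#' Validate a genomic feature set
#'
#' Records of (chrom, start, end, id, strand, score) with 0-based half-open
#' coordinates (BED convention) and start < end.
#'
#' @param df data frame with at least chrom, start, end columns.
#' @param what label for error messages.
#' @return data frame with columns chrom, start, end, id, strand, score.
#' @export
genomic_features <- function(df, what = "feature set") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, ": columns chrom, start, end are required", call. = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop(what, ": non-integer coordinates", call. = FALSE)
  if (any(df$start < 0)) stop(what, ": negative start coordinate", call. = FALSE)
  if (any(df$end <= df$start))
    stop(what, ": malformed interval (end <= start)", call. = FALSE)
  if (is.null(df$id)) df$id <- paste0(df$chrom, ":", df$start, "-", df$end)
  df$id <- as.character(df$id)
  if (is.null(df$strand)) df$strand <- "."
  if (!all(df$strand %in% c("+", "-", ".")))
    stop(what, ": unknown strand symbol", call. = FALSE)
  if (is.null(df$score)) df$score <- NA_real_
  df[, c("chrom", "start", "end", "id", "strand", "score")]
}

# GRanges from a 0-based half-open feature set, optionally widened by
# `window` on both sides. A shared seqlevels universe keeps overlap
# queries between two sets quiet even when their chromosomes differ.
.features_to_granges <- function(df, window = 0L, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels %||% unique(df$chrom)),
    ranges = IRanges::IRanges(start = df$start + 1L - window,
                              end = df$end + window),
    id = df$id)
}
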