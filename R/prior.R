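# Prior-network construction from chromatin accessibility peaks, motif
# occurrences and gene annotations, plus merging of priors from several
# evidence sources.

#' Associate accessibility peaks with nearby genes
#'
#' A peak is associated with a gene iff the peak interval overlaps the gene
#' body extended by \code{window_bp} on both sides (default +/- 10 kb), on
#' the same chromosome. Strand is ignored. A peak may map to several genes;
#' unmapped peaks are dropped.
#'
#' @param peaks,genes feature data frames (0-based half-open; see
#'   \code{\link{genomic_features}}).
#' @param window_bp window in bp added to both sides of the gene body.
#' @return named list mapping peak id to a character vector of gene ids.
#' @export
associate_peaks_to_genes <- function(peaks, genes, window_bp = 10000L) {
  stopifnot(window_bp >= 0)
  peaks <- genomic_features(peaks, "peaks")
  if (nrow(genes) == 0L) {
    warning("associate_peaks_to_genes: empty gene set")
    return(structure(list(), names = character(0)))
  }
  genes <- genomic_features(genes, "genes")
  chroms <- union(peaks$chrom, genes$chrom)
  pg <- .features_to_granges(peaks, seqlevels = chroms)
  gg <- .features_to_granges(genes, window = as.integer(window_bp),
                             seqlevels = chroms)
  ov <- GenomicRanges::findOverlaps(pg, gg)
  if (!length(ov)) return(structure(list(), names = character(0)))
  split(genes$id[S4Vectors::subjectHits(ov)],
        factor(peaks$id[S4Vectors::queryHits(ov)],
               levels = unique(peaks$id[S4Vectors::queryHits(ov)]))) |>
    lapply(unique)
}

#' Build a binary motif prior matrix
#'
#' P[g, k] = 1 iff at least one occurrence of TF k's motif with raw p-value
#' below \code{p_threshold} lies in a peak associated with gene g. Hits are
#' assigned to peaks by interval overlap (a hit overlapping two peaks counts
#' for both); alternatively hits may carry a \code{peak_id} column.
#'
#' @param hits motif hit table (see \code{\link{read_motif_hits}}).
#' @param peak_gene_map mapping from \code{\link{associate_peaks_to_genes}}.
#' @param peaks peak feature data frame (required unless hits carry
#'   \code{peak_id}).
#' @param p_threshold strict upper bound on the raw motif p-value.
#' @param gene_ids,tf_ids optional universes fixing the matrix dimensions.
#' @return binary sparse prior matrix (genes x TFs).
#' @export
build_motif_prior <- function(hits, peak_gene_map, peaks = NULL,
                              p_threshold = 1e-5,
                              gene_ids = NULL, tf_ids = NULL) {
  hits <- hits[hits$p_value < p_threshold, , drop = FALSE]
  if (is.null(hits$peak_id)) {
    if (is.null(peaks))
      stop("build_motif_prior: peaks required when hits lack peak_id",
           call. = FALSE)
    peaks <- genomic_features(peaks, "peaks")
    chroms <- union(hits$chrom, peaks$chrom)
    hg <- GenomicRanges::GRanges(factor(hits$chrom, levels = chroms),
                                 IRanges::IRanges(hits$start + 1L, hits$end))
    ov <- GenomicRanges::findOverlaps(hg, .features_to_granges(peaks,
                                                               seqlevels = chroms))
    tf <- hits$tf_id[S4Vectors::queryHits(ov)]
    pk <- peaks$id[S4Vectors::subjectHits(ov)]
  } else {
    tf <- hits$tf_id; pk <- as.character(hits$peak_id)
  }
  keep <- pk %in% names(peak_gene_map)
  tf <- tf[keep]; pk <- pk[keep]
  gl <- if (length(pk)) peak_gene_map[pk] else list()
  pairs <- if (length(gl))
    data.frame(tf = rep(tf, lengths(gl)), gene = unlist(gl, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(tf = character(0), gene = character(0))
  if (is.null(gene_ids))
    gene_ids <- sort(unique(unlist(peak_gene_map, use.names = FALSE)))
  if (is.null(tf_ids)) tf_ids <- sort(unique(hits$tf_id))
  pairs <- unique(pairs[pairs$gene %in% gene_ids & pairs$tf %in% tf_ids, ])
  if (!nrow(pairs))
    warning("build_motif_prior: no motif hits pass the threshold; ",
            "prior is all-zero")
  P <- Matrix::sparseMatrix(i = match(pairs$gene, gene_ids),
                            j = match(pairs$tf, tf_ids), x = 1,
                            dims = c(length(gene_ids), length(tf_ids)),
                            dimnames = list(gene_ids, tf_ids))
  prior_matrix(P, source_tag = "atac_motif")
}

#' Merge prior matrices from several evidence sources
#'
#' The gene/TF universe of the result is the union across sources.
#' \code{union_binary} sets an entry to 1 iff it is nonzero in any source.
#' \code{signed_override} takes the sign from the highest-precedence source
#' (earlier in the list = higher precedence) with a nonzero entry, magnitude
#' 1; sign conflicts are resolved by precedence and counted in a message.
#'
#' @param priors list of prior matrices.
#' @param mode \code{"union_binary"} or \code{"signed_override"}.
#' @return merged sparse prior matrix.
#' @export
merge_priors <- function(priors, mode = c("union_binary", "signed_override")) {
  mode <- match.arg(mode)
  stopifnot(length(priors) >= 1L)
  genes <- sort(unique(unlist(lapply(priors, rownames))))
  tfs <- sort(unique(unlist(lapply(priors, colnames))))
  expand <- function(P) {
    M <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(genes), length(tfs)),
                              dimnames = list(genes, tfs))
    M[rownames(P), colnames(P)] <- methods::as(P, "CsparseMatrix")
    M
  }
  mats <- lapply(priors, expand)
  if (mode == "union_binary") {
    supp <- Reduce(`+`, lapply(mats, function(M) abs(Matrix::drop0(M))))
    out <- supp
    out@x <- rep(1, length(out@x))
    return(prior_matrix(out, source_tag = "merged_union"))
  }
  # signed_override: apply lowest precedence first, overwrite with higher
  res <- mats[[length(mats)]]
  res@x <- sign(res@x)
  conflicts <- 0L
  for (k in rev(seq_len(length(mats) - 1L))) {
    M <- Matrix::drop0(mats[[k]])
    tr <- Matrix::summary(methods::as(M, "TsparseMatrix"))
    if (!nrow(tr)) next
    old <- res[cbind(tr$i, tr$j)]
    newsign <- sign(tr$x)
    conflicts <- conflicts + sum(old != 0 & old != newsign)
    res[cbind(tr$i, tr$j)] <- newsign
  }
  if (conflicts > 0L)
    message("merge_priors: ", conflicts,
            " sign conflict(s) resolved by source precedence")
  prior_matrix(Matrix::drop0(res), source_tag = "merged_signed")
}

#' Select differentially expressed genes
#'
#' Retains genes with \code{fdr < fdr_max} and \code{|log2 fold change| >
#' lfc_min} (both strict). Used to pick both target genes and, applied to
#' the TF universe, potential regulators.
#'
#' @param de data frame with columns gene_id, log2_fold_change, fdr.
#' @param fdr_max FDR bound (default 10\%).
#' @param lfc_min strict lower bound on |log2 FC| (default log2(1.5)).
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(de, fdr_max = 0.10, lfc_min = log2(1.5)) {
  stopifnot(all(c("gene_id", "log2_fold_change", "fdr") %in% names(de)))
  if (any(de$fdr < 0 | de$fdr > 1))
    stop("select_genes: fdr outside [0, 1]", call. = FALSE)
  sel <- de$gene_id[de$fdr < fdr_max & abs(de$log2_fold_change) > lfc_min]
  if (!length(sel)) warning("select_genes: no genes pass the filters")
  as.character(sel)
}
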