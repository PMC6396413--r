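# Partial correlations between a gene and its selected TFs, and the
# stability + partial-correlation edge ranking.

#' Partial correlation of a gene with each of its selected TFs
#'
#' Computes the partial correlation between the gene's expression and each
#' TF's activity conditioning on the remaining selected TFs, via the
#' inverse of the joint correlation matrix. A single-TF model reduces to
#' the plain Pearson correlation. A singular correlation matrix is handled
#' by a ridge-regularized inverse (epsilon added to the diagonal) with a
#' warning.
#'
#' @param x_gene expression vector over samples.
#' @param A_selected activities of the selected TFs (TFs x samples).
#' @param ridge_eps ridge added to the diagonal on singularity.
#' @return named vector of partial correlations, one per selected TF.
#' @export
compute_partial_correlations <- function(x_gene, A_selected,
                                         ridge_eps = 1e-6) {
  A_selected <- matrix(A_selected, ncol = length(x_gene),
                       dimnames = if (is.matrix(A_selected))
                         dimnames(A_selected) else NULL)
  k <- nrow(A_selected)
  if (k == 0L) stop("compute_partial_correlations: empty TF set", call. = FALSE)
  if (k == 1L) {
    r <- stats::cor(x_gene, A_selected[1L, ])
    return(stats::setNames(r, rownames(A_selected)))
  }
  n <- length(x_gene)
  if (n <= k + 1L)
    warning("compute_partial_correlations: sample count does not exceed ",
            "TF set size + 1; estimates are unstable")
  C <- stats::cor(cbind(x_gene, t(A_selected)))
  Om <- tryCatch(solve(C), error = function(e) {
    warning("compute_partial_correlations: singular correlation matrix; ",
            "using ridge-regularized inverse (eps = ", ridge_eps, ")")
    solve(C + diag(ridge_eps, nrow(C)))
  })
  pc <- -Om[1L, -1L] / sqrt(Om[1L, 1L] * diag(Om)[-1L])
  stats::setNames(pmin(1, pmax(-1, pc)), rownames(A_selected))
}

#' Rank edges by stability count plus partial correlation
#'
#' Confidence(i, k) = NonzeroSubsamples(i, k) + |pcorr(i, k)|: the integer
#' subsample count dominates and |pcorr| < 1 acts as a tie-breaker. A
#' normalized confidence (count + |pcorr|) / (n_subsamples + 1) is emitted
#' alongside for cross-network comparability. Edges with zero count are
#' excluded; the sign is the sign of the partial correlation.
#'
#' @param counts named TFs x genes integer matrix of nonzero-subsample
#'   counts at the selected lambda.
#' @param pcorrs named TFs x genes numeric matrix of partial correlations
#'   (entries only needed where counts > 0).
#' @param n_subsamples subsample count used for the stability run.
#' @param prior_mask optional logical genes x TFs matrix flagging
#'   prior-supported edges.
#' @return ranked network (class \code{trn_network}).
#' @export
rank_edges <- function(counts, pcorrs, n_subsamples, prior_mask = NULL) {
  sel <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(sel)) {
    empty <- data.frame(regulator = character(0), target = character(0),
                        sign = character(0), confidence = numeric(0),
                        confidence_norm = numeric(0),
                        nonzero_subsamples = integer(0),
                        partial_correlation = numeric(0),
                        in_prior = logical(0), stringsAsFactors = FALSE)
    return(new_trn_network(empty, n_subsamples = n_subsamples))
  }
  tf <- rownames(counts)[sel[, 1L]]
  gene <- colnames(counts)[sel[, 2L]]
  cnt <- counts[sel]
  pc <- pcorrs[sel]
  pc[is.na(pc)] <- 0
  inp <- if (is.null(prior_mask)) rep(FALSE, length(tf))
         else prior_mask[cbind(gene, tf)]
  edges <- data.frame(
    regulator = tf, target = gene,
    sign = ifelse(pc >= 0, "+", "-"),
    confidence = cnt + abs(pc),
    confidence_norm = (cnt + abs(pc)) / (n_subsamples + 1),
    nonzero_subsamples = as.integer(cnt),
    partial_correlation = pc,
    in_prior = inp, stringsAsFactors = FALSE)
  edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  new_trn_network(edges, n_subsamples = n_subsamples)
}
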