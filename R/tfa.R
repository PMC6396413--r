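# Transcription factor activity (TFA) estimation: either the TF's own mRNA
# or the least-squares inversion of the prior, X = P A, solved by the
# minimum-norm pseudoinverse.

.zscore_rows <- function(m, warn_constant = TRUE) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero) && warn_constant)
    warning("constant rows set to all-zero activity: ",
            paste(rownames(m)[zero], collapse = ", "))
  sdv[zero] <- 1
  out <- (m - mu) / sdv
  out[zero, ] <- 0
  out
}

#' TF activities from TF mRNA
#'
#' Uses each TF's own expression row, z-scored across samples, as its
#' activity estimate.
#'
#' @param expr expression matrix (genes x samples) containing the TFs.
#' @param tf_ids TFs to extract.
#' @return TFs x samples activity matrix with a \code{method} attribute
#'   (\code{"mrna"} per TF).
#' @export
tfa_from_mrna <- function(expr, tf_ids) {
  expr <- as_expression_matrix(expr)
  miss <- setdiff(tf_ids, rownames(expr))
  if (length(miss))
    stop("tfa_from_mrna: TF(s) absent from expression: ",
         paste(miss, collapse = ", "), call. = FALSE)
  A <- .zscore_rows(expr[tf_ids, , drop = FALSE])
  attr(A, "method") <- stats::setNames(rep("mrna", length(tf_ids)), tf_ids)
  A
}

# Minimum-norm least-squares solve via SVD pseudoinverse.
.pinv_solve <- function(P, X) {
  s <- svd(P)
  tol <- max(dim(P)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) stop("prior has numerically zero column space", call. = FALSE)
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * (t(s$u[, pos, drop = FALSE]) %*% X))
}

#' TF activities by least-squares inversion of the prior
#'
#' Solves X = P A for A in the least-squares sense on the genes that carry
#' at least one prior edge, using the minimum-norm (pseudoinverse) solution;
#' signed prior entries are used as-is. TFs whose prior column is all zero
#' fall back to their mRNA (\code{\link{tfa_from_mrna}}) and are tagged
#' \code{"mrna"}. All activity rows are then z-scored across samples.
#'
#' @param expr expression matrix (genes x samples).
#' @param P prior matrix (genes x TFs); rownames must be gene ids present in
#'   \code{expr} for the solve.
#' @param standardize z-score activity rows across samples (default TRUE);
#'   set FALSE to obtain the raw least-squares solution.
#' @return TFs x samples activity matrix with per-TF \code{method} attribute.
#' @export
tfa_from_prior <- function(expr, P, standardize = TRUE) {
  expr <- as_expression_matrix(expr)
  P <- methods::as(P, "CsparseMatrix")
  if (all(P@x == 0) || length(P@x) == 0L)
    stop("tfa_from_prior: prior is all-zero; use tfa_from_mrna instead",
         call. = FALSE)
  genes <- intersect(rownames(P)[Matrix::rowSums(P != 0) > 0], rownames(expr))
  if (!length(genes))
    stop("tfa_from_prior: no prior genes present in the expression matrix",
         call. = FALSE)
  tf_ids <- colnames(P)
  nonzero_col <- Matrix::colSums(P[genes, , drop = FALSE] != 0) > 0
  A <- matrix(0, nrow = length(tf_ids), ncol = ncol(expr),
              dimnames = list(tf_ids, colnames(expr)))
  if (any(nonzero_col)) {
    Psub <- as.matrix(P[genes, nonzero_col, drop = FALSE])
    A[nonzero_col, ] <- .pinv_solve(Psub, expr[genes, , drop = FALSE])
  }
  method <- stats::setNames(ifelse(nonzero_col, "prior_based", "mrna"), tf_ids)
  fallback <- tf_ids[!nonzero_col]
  if (length(fallback)) {
    miss <- setdiff(fallback, rownames(expr))
    if (length(miss))
      stop("tfa_from_prior: TF(s) without prior targets and absent from ",
           "expression: ", paste(miss, collapse = ", "), call. = FALSE)
    A[fallback, ] <- expr[fallback, , drop = FALSE]
  }
  if (standardize) A <- .zscore_rows(A)
  attr(A, "method") <- method
  A
}
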