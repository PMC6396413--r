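# Weighted LASSO building blocks: the single-gene solver, the null
# regularization level and the penalty scheme carrying prior reinforcement.

#' Solve one gene's weighted LASSO
#'
#' Minimises \eqn{\|x - A^T b\|_2^2 + \sum_k penalties_k |b_k|} by cyclic
#' coordinate descent on the Gram matrix. Predictors with per-coefficient
#' penalties allow prior reinforcement (penalty \code{bias * lambda} for
#' prior-supported TFs, \code{lambda} otherwise).
#'
#' @param x_gene numeric vector over samples (mean-centered expression of
#'   one gene).
#' @param A TFs x samples activity matrix (rows standardized).
#' @param penalties positive penalty per TF; an infinite penalty excludes a
#'   TF.
#' @return named coefficient vector over TFs.
#' @export
solve_weighted_lasso <- function(x_gene, A, penalties) {
  A <- as.matrix(A)
  if (!all(is.finite(x_gene)) || !all(is.finite(A)))
    stop("solve_weighted_lasso: non-finite inputs", call. = FALSE)
  if (length(penalties) != nrow(A))
    stop("solve_weighted_lasso: one penalty per TF required", call. = FALSE)
  if (any(penalties < 0))
    stop("solve_weighted_lasso: penalties must be non-negative", call. = FALSE)
  X <- t(A)
  gram <- crossprod(X)
  zerovar <- diag(gram) == 0
  if (any(zerovar)) {
    warning("solve_weighted_lasso: zero-variance predictor(s) dropped: ",
            paste(rownames(A)[zerovar], collapse = ", "))
  }
  b <- .lasso_path_single(gram, crossprod(X, x_gene), as.numeric(penalties),
                          1.0)[, 1L]
  names(b) <- rownames(A)
  b
}

# Smallest uniform-lambda level at which every coefficient of every gene is
# zero: max over genes i and TFs k of |2 a_k' x_i| / pf_ik, where pf is the
# per-entry penalty factor (bias on prior-supported entries, 1 otherwise,
# Inf on excluded self-edges).
.lambda_max <- function(Xc, A, pf) {
  z <- abs(2 * (A %*% t(Xc)))   # TFs x genes
  max(z / pf)
}

#' Build a descending log-spaced lambda grid
#'
#' @param lambda_max largest grid value (the null threshold).
#' @param n_lambda number of grid points.
#' @param min_ratio smallest grid value as a fraction of \code{lambda_max}.
#' @return strictly decreasing positive numeric vector.
#' @export
build_lambda_grid <- function(lambda_max, n_lambda = 25L, min_ratio = 1e-3) {
  stopifnot(lambda_max > 0, n_lambda >= 2L, min_ratio > 0, min_ratio < 1)
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = n_lambda))
}

#' Penalty scheme for prior-reinforced LASSO
#'
#' Per-entry penalties are \code{bias * lambda} where the prior mask is
#' true and \code{lambda} elsewhere; \code{bias} in [0, 1] with 1 = no
#' reinforcement, smaller = stronger reinforcement.
#'
#' @param lambda_grid strictly decreasing positive grid.
#' @param bias reinforcement multiplier in [0, 1].
#' @param prior_mask logical genes x TFs matrix (TRUE where the prior
#'   supports the interaction).
#' @return object of class \code{penalty_scheme}.
#' @export
penalty_scheme <- function(lambda_grid, bias, prior_mask) {
  if (any(diff(lambda_grid) >= 0) || any(lambda_grid <= 0))
    stop("penalty_scheme: lambda grid must be strictly decreasing and positive",
         call. = FALSE)
  if (length(bias) != 1L || bias < 0 || bias > 1)
    stop("penalty_scheme: bias must be a single value in [0, 1]", call. = FALSE)
  structure(list(lambda_grid = lambda_grid, bias = bias,
                 prior_mask = prior_mask),
            class = "penalty_scheme")
}

# genes x TFs penalty-factor matrix for a scheme; excluded entries (e.g.
# self-edges) get +Inf and are never selected.
.penalty_factors <- function(prior_mask, bias, exclude = NULL) {
  pf <- matrix(1, nrow = nrow(prior_mask), ncol = ncol(prior_mask),
               dimnames = dimnames(prior_mask))
  pf[prior_mask] <- bias
  if (!is.null(exclude)) pf[exclude] <- Inf
  pf
}
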