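# The core estimator: per-gene weighted LASSO with prior-reduced penalties,
# StARS lambda selection, and stability + partial-correlation edge ranking.

#' Infer a transcriptional regulatory network (mLASSO-StARS)
#'
#' Fits, for every target gene, a sparse linear model of mean-centered
#' expression on standardized TF activities with per-coefficient LASSO
#' penalties: \code{lambda} for TF-gene pairs without prior evidence and
#' \code{bias * lambda} (bias in (0, 1]) for prior-supported pairs, so a
#' smaller bias reinforces the prior. One network-level lambda is chosen by
#' StARS: average edge-selection instability across subsamples, monotonized,
#' compared to \code{instability_cutoff}. Gene models are then refit on the
#' full data at the selected lambda, partial correlations are computed on
#' each gene's selected TF set, and edges are ranked by
#' \code{NonzeroSubsamples + |pcorr|}. Self-edges (a gene regressed on its
#' own mRNA/activity) are excluded.
#'
#' @param expr genes x samples expression matrix (normalized, log scale).
#' @param activities TFs x samples activity matrix (see
#'   \code{\link{tfa_from_mrna}}, \code{\link{tfa_from_prior}}).
#' @param prior optional genes x TFs prior matrix; nonzero entries mark
#'   prior support. NULL means no prior (all penalties equal).
#' @param targets target gene ids (must be rows of \code{expr}).
#' @param regulators candidate TF ids (must be rows of \code{activities}).
#' @param bias prior reinforcement multiplier in (0, 1]; 1 = none,
#'   0.5 = moderate, 0.25 = high.
#' @param instability_cutoff StARS average instability cutoff (default 0.05).
#' @param n_lambda,lambda_min_ratio grid of \code{n_lambda} log-spaced
#'   values from the null threshold down to \code{lambda_min_ratio} times it.
#' @param n_subsamples,subsample_frac StARS subsampling: \code{n_subsamples}
#'   draws of \code{floor(subsample_frac * n)} samples without replacement.
#' @param seed RNG seed for the subsample draw; the full run is reproducible
#'   given (data, grid, seed, n_subsamples).
#' @return object of class \code{trn}: the ranked \code{$network}, refit
#'   \code{$coefficients} (sparse genes x TFs, on the centered/standardized
#'   scale), the lambda grid with raw and monotonized instabilities, the
#'   selected lambda, and the centering/scaling needed for prediction.
#' @seealso \code{\link{trim_network}}, \code{\link{max_combine}},
#'   \code{\link{precision_recall}}, \code{\link{predict_out_of_sample}}
#' @export
mlasso_stars <- function(expr, activities, prior = NULL,
                         targets = rownames(expr),
                         regulators = rownames(activities),
                         bias = 0.5, instability_cutoff = 0.05,
                         n_lambda = 25L, lambda_min_ratio = 1e-3,
                         n_subsamples = 50L, subsample_frac = 0.63,
                         seed = 42L) {
  cl <- match.call()
  expr <- as_expression_matrix(expr)
  if (!all(targets %in% rownames(expr)))
    stop("mlasso_stars: targets absent from expression matrix", call. = FALSE)
  if (!all(regulators %in% rownames(activities)))
    stop("mlasso_stars: regulators absent from activity matrix", call. = FALSE)
  if (!identical(colnames(expr), colnames(activities)))
    stop("mlasso_stars: expression and activity sample ids differ",
         call. = FALSE)
  if (bias <= 0 || bias > 1)
    stop("mlasso_stars: bias must lie in (0, 1]", call. = FALSE)

  X <- expr[targets, , drop = FALSE]
  x_center <- rowMeans(X)
  Xc <- X - x_center
  Araw <- activities[regulators, , drop = FALSE]
  a_center <- rowMeans(Araw)
  a_scale <- apply(Araw, 1L, stats::sd)
  a_scale[a_scale == 0] <- 1
  A <- (Araw - a_center) / a_scale

  mask <- matrix(FALSE, length(targets), length(regulators),
                 dimnames = list(targets, regulators))
  if (!is.null(prior)) {
    g <- intersect(targets, rownames(prior))
    k <- intersect(regulators, colnames(prior))
    if (length(g) && length(k))
      mask[g, k] <- as.matrix(prior[g, k, drop = FALSE] != 0)
  }
  self <- outer(regulators, targets, `==`)               # TFs x genes
  pf_tg <- t(.penalty_factors(mask, bias))               # TFs x genes
  pf_tg[self] <- Inf

  lmax <- max(abs(2 * (A %*% t(Xc))) / pf_tg)
  if (!is.finite(lmax) || lmax <= 0)
    stop("mlasso_stars: degenerate data (null lambda threshold is ",
         lmax, ")", call. = FALSE)
  grid <- build_lambda_grid(lmax, n_lambda, lambda_min_ratio)

  cand <- !self
  # the lambda path stops once the running-max instability exceeds the
  # cutoff: the monotonized selection below is unaffected (it only uses
  # the curve up to the first exceedance)
  stab <- .stars_core(Xc, A, pf_tg, cand, grid, n_subsamples,
                      subsample_frac, seed, stop_cutoff = instability_cutoff)
  stab <- structure(stab, class = "stars_instability")
  done <- stab$computed
  sel <- select_lambda(stab$instability[done], grid[done],
                       cutoff = instability_cutoff)
  mono <- rep(NA_real_, length(grid))
  mono[done] <- sel$monotonized
  sel$monotonized <- mono

  # full-data refit at lambda* defines each gene's selected TF set
  Xs <- t(A)
  B <- .lasso_multi_fit(crossprod(Xs), crossprod(Xs, t(Xc)), pf_tg,
                        sel$lambda)                      # TFs x genes
  dimnames(B) <- list(regulators, targets)

  counts <- stab$counts[, , sel$index]
  if (is.null(dim(counts)))
    counts <- matrix(counts, length(regulators), length(targets),
                     dimnames = list(regulators, targets))
  pcorrs <- matrix(NA_real_, length(regulators), length(targets),
                   dimnames = list(regulators, targets))
  for (gi in seq_along(targets)) {
    cand_tfs <- which(counts[, gi] > 0)
    if (!length(cand_tfs)) next
    support <- which(B[, gi] != 0)
    if (length(support)) {
      pcorrs[support, gi] <- suppressWarnings(
        compute_partial_correlations(Xc[gi, ], A[support, , drop = FALSE]))
    }
    # edges stable across subsamples but outside the refit support:
    # condition each on the refit-selected set
    for (k in setdiff(cand_tfs, support)) {
      set <- sort(c(support, k))
      pc <- suppressWarnings(
        compute_partial_correlations(Xc[gi, ], A[set, , drop = FALSE]))
      pcorrs[k, gi] <- pc[match(k, set)]
    }
  }
  net <- rank_edges(counts, pcorrs, n_subsamples, prior_mask = mask)

  structure(list(
    network = net,
    coefficients = methods::as(Matrix::Matrix(t(B), sparse = TRUE),
                               "CsparseMatrix"),
    lambda_grid = grid,
    instability = stab$instability,
    monotonized = sel$monotonized,
    lambda = sel$lambda,
    lambda_index = sel$index,
    instability_cutoff = instability_cutoff,
    bias = bias,
    n_subsamples = n_subsamples,
    subsample_frac = subsample_frac,
    seed = seed,
    targets = targets,
    regulators = regulators,
    x_center = x_center,
    a_center = a_center,
    a_scale = a_scale,
    activities = A,
    prior_mask = mask,
    call = cl), class = "trn")
}

#' @export
print.trn <- function(x, ...) {
  cat("mLASSO-StARS transcriptional regulatory network\n")
  cat(sprintf("  %d target genes, %d candidate TFs, bias = %g\n",
              length(x$targets), length(x$regulators), x$bias))
  cat(sprintf("  lambda* = %.4g (instability %.4f at cutoff %.2f)\n",
              x$lambda, x$monotonized[x$lambda_index], x$instability_cutoff))
  cat(sprintf("  %d edges (%d subsamples); %.1f%% prior-supported\n",
              nrow(x$network), x$n_subsamples,
              if (nrow(x$network)) 100 * mean(x$network$in_prior) else 0))
  invisible(x)
}

#' @export
summary.trn <- function(object, ...) {
  net <- object$network
  deg <- table(factor(net$regulator, levels = object$regulators))
  structure(list(
    n_edges = nrow(net),
    n_targets = length(unique(net$target)),
    n_regulators = sum(deg > 0),
    model_size = nrow(net) / max(1L, length(unique(net$target))),
    sign_ratio = sum(net$sign == "+") / max(1L, sum(net$sign == "-")),
    prior_fraction = if (nrow(net)) mean(net$in_prior) else NA_real_,
    top_tfs = head(sort(deg, decreasing = TRUE), 10L),
    lambda = object$lambda,
    instability = object$monotonized[object$lambda_index],
    bias = object$bias), class = "summary.trn")
}

#' @export
print.summary.trn <- function(x, ...) {
  cat("Ranked TRN summary\n")
  cat(sprintf("  edges: %d across %d targets (%.2f TFs/gene), %d active TFs\n",
              x$n_edges, x$n_targets, x$model_size, x$n_regulators))
  cat(sprintf("  positive:negative sign ratio %.2f; prior-supported %.1f%%\n",
              x$sign_ratio, 100 * x$prior_fraction))
  cat(sprintf("  lambda* = %.4g at instability %.4f (bias %g)\n",
              x$lambda, x$instability, x$bias))
  cat("  highest-degree TFs:\n")
  print(x$top_tfs)
  invisible(x)
}

#' @export
coef.trn <- function(object, ...) object$coefficients

#' Predict expression from a fitted TRN
#'
#' Applies the refit coefficients to new TF activities: activities are
#' standardized by the training means/sds and predictions are re-centered
#' by the training gene means.
#'
#' @param object a \code{trn} fit.
#' @param newactivities TFs x samples matrix on the same scale as the
#'   training activities (defaults to the training activities).
#' @param ... unused.
#' @return genes x samples matrix of predicted expression.
#' @export
predict.trn <- function(object, newactivities = NULL, ...) {
  if (is.null(newactivities))
    An <- object$activities
  else {
    An <- (as.matrix(newactivities)[object$regulators, , drop = FALSE] -
             object$a_center) / object$a_scale
  }
  as.matrix(object$coefficients %*% An) + object$x_center
}

#' @export
fitted.trn <- function(object, ...) predict.trn(object)

#' @export
residuals.trn <- function(object, expr = NULL, ...) {
  fit <- fitted.trn(object)
  if (is.null(expr))
    stop("residuals.trn: supply the training expression matrix via expr=",
         call. = FALSE)
  as_expression_matrix(expr)[object$targets, colnames(fit), drop = FALSE] - fit
}

#' Simulate expression replicates from a fitted TRN
#'
#' Draws Gaussian noise around the fitted values with per-gene residual
#' standard deviations estimated from the training fit.
#'
#' @param object a \code{trn} fit.
#' @param nsim number of replicate matrices.
#' @param seed optional RNG seed.
#' @param expr training expression matrix (needed for residual scale).
#' @param ... unused.
#' @return list of \code{nsim} genes x samples matrices.
#' @export
simulate.trn <- function(object, nsim = 1, seed = NULL, expr = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- residuals.trn(object, expr = expr)
  sdg <- apply(res, 1L, stats::sd)
  fit <- fitted.trn(object)
  lapply(seq_len(nsim), function(i)
    fit + matrix(stats::rnorm(length(fit), sd = rep(sdg, ncol(fit))),
                 nrow = nrow(fit)))
}

#' Plot the StARS instability curve of a fitted TRN
#'
#' @param x a \code{trn} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.trn <- function(x, ...) {
  plot(log10(x$lambda_grid), x$instability, type = "b", pch = 16,
       xlab = expression(log[10](lambda)),
       ylab = "average edge instability", ...)
  graphics::lines(log10(x$lambda_grid), x$monotonized, lty = 2, col = "grey40")
  graphics::abline(h = x$instability_cutoff, col = "red3", lty = 3)
  graphics::abline(v = log10(x$lambda), col = "blue3", lty = 3)
  invisible(x)
}
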