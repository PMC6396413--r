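# StARS: estimate edge-selection instability across subsamples along the
# lambda path, and select the smallest lambda whose (monotonized) average
# instability stays below the cutoff.

# Draw subsample index sets reproducibly without disturbing the caller's RNG.
.draw_subsamples <- function(n, n_subsamples, subsample_frac, seed) {
  ns <- floor(subsample_frac * n)
  if (ns < 3L)
    stop("too few samples for subsampling (floor(frac * n) < 3)",
         call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_subsamples), function(i) sample.int(n, ns))
}

# Core instability engine on prepared matrices:
#   Xc    genes x samples, rows mean-centered
#   A     TFs x samples, rows standardized
#   pf    TFs x genes penalty factors (Inf = excluded edge)
#   cand  TFs x genes logical candidate mask (instability average)
# Iterates the lambda path outermost with per-subsample warm starts. When
# stop_cutoff is given, the path stops once the running-max instability
# exceeds it: the monotonized selection rule only depends on the prefix up
# to the first exceedance, so the selected lambda (and all counts at and
# above it) are unchanged.
.stars_core <- function(Xc, A, pf, cand, lambda_grid, n_subsamples,
                        subsample_frac, seed, stop_cutoff = NULL) {
  n <- ncol(Xc)
  subs <- .draw_subsamples(n, n_subsamples, subsample_frac, seed)
  p <- nrow(A); g <- nrow(Xc); nl <- length(lambda_grid)
  grams <- vector("list", n_subsamples)
  xtys <- vector("list", n_subsamples)
  for (s in seq_len(n_subsamples)) {
    Xs <- t(A[, subs[[s]], drop = FALSE])      # samples x TFs
    grams[[s]] <- crossprod(Xs)
    xtys[[s]] <- crossprod(Xs, t(Xc[, subs[[s]], drop = FALSE]))
  }
  states <- rep(list(matrix(0, p, g)), n_subsamples)
  counts <- array(0L, dim = c(p, g, nl))
  inst <- rep(NA_real_, nl)
  runmax <- 0
  computed <- nl
  for (l in seq_len(nl)) {
    cnt <- matrix(0L, p, g)
    for (s in seq_len(n_subsamples)) {
      states[[s]] <- .lasso_multi_fit_warm(grams[[s]], xtys[[s]], pf,
                                           lambda_grid[l], states[[s]])
      cnt <- cnt + (states[[s]] != 0)
    }
    counts[, , l] <- cnt
    theta <- cnt / n_subsamples
    inst[l] <- mean((2 * theta * (1 - theta))[cand])
    runmax <- max(runmax, inst[l])
    if (!is.null(stop_cutoff) && runmax > stop_cutoff) {
      computed <- l
      break
    }
  }
  dimnames(counts) <- list(rownames(A), rownames(Xc), NULL)
  list(lambda_grid = lambda_grid, instability = inst, counts = counts,
       n_subsamples = n_subsamples, subsample_size = floor(subsample_frac * n),
       seed = seed, computed = seq_len(computed))
}

#' Estimate StARS edge instabilities along a lambda path
#'
#' For each lambda, all gene models are fit on each subsample (samples drawn
#' without replacement, size \code{floor(subsample_frac * n)}), nonzero
#' selections per candidate TF-gene edge are counted, and the average edge
#' instability \eqn{2 \hat\theta (1 - \hat\theta)} over all candidates is
#' returned. Deterministic given \code{seed}.
#'
#' @param expr genes x samples expression matrix of target genes (rows are
#'   mean-centered internally).
#' @param A TFs x samples activity matrix (rows z-scored internally).
#' @param scheme a \code{\link{penalty_scheme}}.
#' @param n_subsamples number of subsamples (>= 2).
#' @param subsample_frac fraction of samples per subsample, in (0, 1).
#' @param seed RNG seed for the subsample draw.
#' @param exclude_self exclude gene-on-own-activity edges (matched by id).
#' @return object of class \code{stars_instability}: lambda grid, average
#'   instability per lambda, per-edge nonzero counts (TFs x genes x lambda),
#'   subsample count/size and seed.
#' @export
estimate_instability <- function(expr, A, scheme, n_subsamples = 50L,
                                 subsample_frac = 0.63, seed = 42L,
                                 exclude_self = TRUE) {
  stopifnot(inherits(scheme, "penalty_scheme"), n_subsamples >= 2L,
            subsample_frac > 0, subsample_frac < 1)
  Xc <- expr - rowMeans(expr)
  Az <- .zscore_rows(A, warn_constant = FALSE)
  self <- if (exclude_self) outer(rownames(Az), rownames(Xc), `==`) else NULL
  pf <- t(.penalty_factors(scheme$prior_mask, scheme$bias))   # TFs x genes
  if (!is.null(self)) pf[self] <- Inf
  cand <- matrix(TRUE, nrow(Az), nrow(Xc))
  if (!is.null(self)) cand[self] <- FALSE
  res <- .stars_core(Xc, Az, pf, cand, scheme$lambda_grid, n_subsamples,
                     subsample_frac, seed)
  structure(res, class = "stars_instability")
}

#' Select lambda from a StARS instability curve
#'
#' The instability curve is monotonized by a running maximum from the
#' largest lambda downward, and the smallest lambda whose monotonized
#' instability does not exceed \code{cutoff} is returned. If no lambda
#' qualifies, the largest grid value is returned with a warning.
#'
#' @param stability a \code{stars_instability} object, or a numeric vector
#'   of per-lambda instabilities (lambda descending).
#' @param lambda_grid required when \code{stability} is a bare vector.
#' @param cutoff average instability cutoff (default 0.05).
#' @return list with \code{lambda}, grid \code{index}, and the
#'   \code{monotonized} curve.
#' @export
select_lambda <- function(stability, lambda_grid = NULL, cutoff = 0.05) {
  if (inherits(stability, "stars_instability")) {
    lambda_grid <- stability$lambda_grid
    inst <- stability$instability
  } else inst <- as.numeric(stability)
  stopifnot(!is.null(lambda_grid), length(lambda_grid) == length(inst),
            all(diff(lambda_grid) < 0))
  mono <- cummax(inst)
  ok <- which(mono <= cutoff)
  if (!length(ok)) {
    warning("select_lambda: no lambda meets the instability cutoff; ",
            "returning the largest grid value")
    idx <- 1L
  } else idx <- max(ok)
  list(lambda = lambda_grid[idx], index = idx, monotonized = mono)
}
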