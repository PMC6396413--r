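# Synthetic ground-truth TRNs, activities, expression, noisy priors and
# gold standards, so the whole pipeline is testable without external data.
# The generative model mirrors the inference model: expression is a sparse
# signed linear combination of latent TF activities plus Gaussian noise,
# and TF mRNA tracks activity with a per-TF fidelity (fidelity near 0
# emulates post-translationally regulated TFs).

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a sparse signed ground-truth TRN
#'
#' Each gene is assigned Poisson(\code{tfs_per_gene_mean})-many distinct
#' regulators (at least 1, at most \code{n_tfs}) with signed effect sizes
#' drawn uniformly from +/- \code{effect_size_range}.
#'
#' @param n_genes,n_tfs network dimensions.
#' @param tfs_per_gene_mean mean regulators per gene (must be <
#'   \code{n_tfs}).
#' @param effect_size_range length-2 vector of |effect| bounds.
#' @param seed RNG seed (reproducible given seed).
#' @return sparse signed genes x TFs effect matrix \code{B_true} with gene
#'   ids \code{g0001...} and TF ids \code{TF01...}.
#' @export
simulate_trn <- function(n_genes, n_tfs, tfs_per_gene_mean = 3,
                         effect_size_range = c(0.25, 1.5), seed = 1L) {
  if (tfs_per_gene_mean >= n_tfs)
    stop("simulate_trn: tfs_per_gene_mean must be smaller than n_tfs",
         call. = FALSE)
  stopifnot(n_genes >= 1, n_tfs >= 2, length(effect_size_range) == 2L,
            all(effect_size_range > 0))
  gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  tf_ids <- sprintf("TF%0*d", nchar(n_tfs), seq_len(n_tfs))
  .with_seed(seed, {
    kk <- pmin(n_tfs, pmax(1L, stats::rpois(n_genes, tfs_per_gene_mean)))
    ii <- rep(seq_len(n_genes), kk)
    jj <- unlist(lapply(kk, function(k) sample.int(n_tfs, k)))
    eff <- stats::runif(length(ii), effect_size_range[1L],
                        effect_size_range[2L]) *
      sample(c(-1, 1), length(ii), replace = TRUE)
    Matrix::sparseMatrix(i = ii, j = jj, x = eff,
                         dims = c(n_genes, n_tfs),
                         dimnames = list(gene_ids, tf_ids))
  })
}

#' Simulate expression and TF mRNA from a ground-truth TRN
#'
#' Latent activities are standard normal per TF and sample; gene
#' expression is \code{B_true \%*\% A_true} plus Gaussian noise; TF mRNA is
#' \code{fidelity * activity + sqrt(1 - fidelity^2) * noise} per TF, so
#' fidelity 1 makes mRNA a perfect activity proxy and fidelity 0 an
#' uninformative one.
#'
#' @param B_true sparse genes x TFs effect matrix from
#'   \code{\link{simulate_trn}}.
#' @param n_samples number of samples.
#' @param noise_sd sd of additive expression noise.
#' @param mrna_fidelity scalar or per-TF vector in [0, 1].
#' @param seed RNG seed.
#' @return list with \code{genes} (genes x samples expression),
#'   \code{tf_mrna} (TFs x samples), \code{activities} (true TFs x
#'   samples), and the inputs \code{noise_sd}, \code{mrna_fidelity},
#'   \code{seed}.
#' @export
simulate_expression <- function(B_true, n_samples, noise_sd = 0.25,
                                mrna_fidelity = 0.75, seed = 1L) {
  n_tfs <- ncol(B_true); n_genes <- nrow(B_true)
  fid <- rep_len(mrna_fidelity, n_tfs)
  stopifnot(all(fid >= 0 & fid <= 1), noise_sd >= 0, n_samples >= 2)
  sample_ids <- sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))
  .with_seed(seed, {
    A <- matrix(stats::rnorm(n_tfs * n_samples), n_tfs, n_samples,
                dimnames = list(colnames(B_true), sample_ids))
    X <- as.matrix(B_true %*% A) +
      matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
             n_genes, n_samples)
    dimnames(X) <- list(rownames(B_true), sample_ids)
    mrna <- fid * A + sqrt(1 - fid^2) *
      matrix(stats::rnorm(n_tfs * n_samples), n_tfs, n_samples)
    dimnames(mrna) <- dimnames(A)
    list(genes = X, tf_mrna = mrna, activities = A, noise_sd = noise_sd,
         mrna_fidelity = stats::setNames(fid, colnames(B_true)),
         seed = seed)
  })
}

#' Corrupt a ground-truth network into a noisy binary prior
#'
#' True edges are dropped independently with probability
#' \code{false_neg_rate}; false edges are added by drawing a
#' Binomial(|true edges|, \code{false_pos_rate}) number of distinct
#' non-edges uniformly.
#'
#' @param B_true sparse signed effect matrix.
#' @param false_pos_rate,false_neg_rate corruption rates in [0, 1).
#' @param seed RNG seed.
#' @return binary sparse prior matrix (genes x TFs).
#' @export
corrupt_prior <- function(B_true, false_pos_rate = 0.25,
                          false_neg_rate = 0.25, seed = 1L) {
  stopifnot(false_pos_rate >= 0, false_pos_rate < 1,
            false_neg_rate >= 0, false_neg_rate <= 1)
  tr <- Matrix::summary(methods::as(B_true, "TsparseMatrix"))
  n_true <- nrow(tr)
  .with_seed(seed, {
    keep <- stats::runif(n_true) >= false_neg_rate
    lin_true <- (tr$j - 1L) * nrow(B_true) + tr$i
    n_fp <- stats::rbinom(1L, n_true, false_pos_rate)
    lin_non <- setdiff(seq_len(prod(dim(B_true))), lin_true)
    fp <- if (n_fp > 0L) sample(lin_non, min(n_fp, length(lin_non))) else
      integer(0)
    lin <- c(lin_true[keep], fp)
    P <- Matrix::sparseMatrix(
      i = ((lin - 1L) %% nrow(B_true)) + 1L,
      j = ((lin - 1L) %/% nrow(B_true)) + 1L,
      x = 1, dims = dim(B_true), dimnames = dimnames(B_true))
    prior_matrix(P, source_tag = "synthetic_corrupted")
  })
}

#' Gold standard from a random TF subset of the truth
#'
#' Emulates a gold standard restricted to the TFs probed experimentally:
#' the signed true edges of a random subset of TFs, scored by |effect|.
#'
#' @param B_true sparse signed effect matrix.
#' @param fraction_tfs fraction of TFs in (0, 1] to include.
#' @param seed RNG seed.
#' @return \code{gold_standard} data frame; the gene universe is all genes
#'   of \code{B_true}, the TF universe the selected subset.
#' @export
make_gold_standard <- function(B_true, fraction_tfs = 1, seed = 1L) {
  stopifnot(fraction_tfs > 0, fraction_tfs <= 1)
  n_tfs <- ncol(B_true)
  sel <- .with_seed(seed,
    sort(sample.int(n_tfs, max(1L, round(fraction_tfs * n_tfs)))))
  tr <- Matrix::summary(methods::as(B_true, "TsparseMatrix"))
  tr <- tr[tr$j %in% sel, , drop = FALSE]
  edges <- data.frame(regulator = colnames(B_true)[tr$j],
                      target = rownames(B_true)[tr$i],
                      score = abs(tr$x),
                      sign = ifelse(tr$x >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  load_gold_standard(edges, provenance = "other", cutoff = 0,
                     gene_universe = rownames(B_true),
                     tf_universe = colnames(B_true)[sel])
}
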