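# Post-processing of ranked networks: trimming to a target model size and
# combining networks across TFA methods or priors.

#' Trim a ranked network to a target model size
#'
#' Keeps the top \code{floor(n_target_genes * avg_tfs_per_gene)} edges
#' globally by confidence (ties broken by |partial correlation|, then
#' lexicographically by regulator and target for determinism).
#'
#' @param net ranked network (or \code{trn} fit).
#' @param n_target_genes number of target genes defining the budget.
#' @param avg_tfs_per_gene desired average TFs per gene (default 15).
#' @return trimmed ranked network.
#' @export
trim_network <- function(net, n_target_genes, avg_tfs_per_gene = 15) {
  stopifnot(avg_tfs_per_gene > 0, n_target_genes >= 0)
  net <- as_trn_network(net)
  budget <- floor(n_target_genes * avg_tfs_per_gene)
  if (budget >= nrow(net)) {
    if (budget > nrow(net))
      warning("trim_network: requested ", budget, " edges but only ",
              nrow(net), " available; returning all")
    return(net)
  }
  ord <- order(-net$confidence, -abs(net$partial_correlation),
               net$regulator, net$target)
  new_trn_network(net[ord[seq_len(budget)], , drop = FALSE],
                  n_subsamples = attr(net, "n_subsamples"))
}

.combine_check <- function(nets, normalize) {
  stopifnot(length(nets) >= 1L)
  nets <- lapply(nets, as_trn_network)
  ns <- vapply(nets, attr, integer(1), which = "n_subsamples")
  if (length(unique(ns)) > 1L && !normalize)
    stop("combine: networks have different subsample counts; ",
         "set normalize = TRUE to compare normalized confidences",
         call. = FALSE)
  nets
}

#' Combine ranked networks by maximum edge confidence
#'
#' The edge set is the union across networks; each edge keeps the fields
#' (sign, partial correlation, counts) of the contributing network that
#' achieves the maximum confidence, and \code{in_prior} is OR-ed.
#'
#' @param nets list of ranked networks (same \code{n_subsamples}, unless
#'   \code{normalize}).
#' @param normalize compare \code{confidence_norm} instead of raw
#'   confidence (required when subsample counts differ).
#' @return combined ranked network.
#' @export
max_combine <- function(nets, normalize = FALSE) {
  nets <- .combine_check(nets, normalize)
  all <- do.call(rbind, lapply(nets, as.data.frame))
  key <- paste(all$regulator, all$target, sep = "\r")
  score <- if (normalize) all$confidence_norm else all$confidence
  # deterministic winner: highest score, then |pcorr|, then first network
  ord <- order(key, -score, -abs(all$partial_correlation))
  all <- all[ord, , drop = FALSE]
  key <- key[ord]
  prior_any <- tapply(all$in_prior, key, any)
  win <- all[!duplicated(key), , drop = FALSE]
  win$in_prior <- as.logical(prior_any[paste(win$regulator, win$target,
                                             sep = "\r")])
  if (normalize) win$confidence <- win$confidence_norm
  ns <- attr(nets[[1L]], "n_subsamples")
  new_trn_network(win, n_subsamples = ns)
}

#' Combine ranked networks by mean rank
#'
#' Each edge receives the mean of its per-network ranks (rank 1 = highest
#' confidence; an edge missing from a network gets rank |edges| + 1 there)
#' and the result is re-ranked ascending by mean rank. The reported
#' confidence is \code{1 / mean_rank} so that the usual descending-
#' confidence order matches the ascending mean-rank order.
#'
#' @inheritParams max_combine
#' @return combined ranked network with a \code{mean_rank} attribute column.
#' @export
rank_combine <- function(nets, normalize = FALSE) {
  nets <- .combine_check(nets, normalize)
  keys <- lapply(nets, function(n) paste(n$regulator, n$target, sep = "\r"))
  ranks <- lapply(nets, function(n)
    rank(-n$confidence, ties.method = "average"))
  univ <- unique(unlist(keys))
  R <- vapply(seq_along(nets), function(i) {
    r <- rep(nrow(nets[[i]]) + 1, length(univ))
    m <- match(keys[[i]], univ)
    r[m] <- ranks[[i]]
    r
  }, numeric(length(univ)))
  mean_rank <- rowMeans(as.matrix(R))
  # carry fields from the best-ranked contributing network
  best <- max_combine(nets, normalize = length(unique(vapply(
    nets, attr, integer(1), "n_subsamples"))) > 1L)
  bkey <- paste(best$regulator, best$target, sep = "\r")
  out <- as.data.frame(best)[match(univ, bkey), , drop = FALSE]
  out$mean_rank <- mean_rank
  out$confidence <- 1 / mean_rank
  out$confidence_norm <- 1 / mean_rank
  out$mean_rank <- NULL
  net <- new_trn_network(out, n_subsamples = attr(best, "n_subsamples"))
  net$mean_rank <- 1 / net$confidence
  net
}
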