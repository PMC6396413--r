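# The ranked-network container: a data frame of signed TF->gene edges with
# stability counts, partial correlations and confidences, ordered by
# descending confidence.

#' Construct a ranked network
#'
#' @param edges data frame with columns regulator, target, sign,
#'   confidence, confidence_norm, nonzero_subsamples, partial_correlation,
#'   in_prior.
#' @param n_subsamples number of StARS subsamples the counts refer to.
#' @return data frame of class \code{trn_network}.
#' @export
new_trn_network <- function(edges, n_subsamples) {
  need <- c("regulator", "target", "sign", "confidence", "confidence_norm",
            "nonzero_subsamples", "partial_correlation", "in_prior")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("ranked network: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(edges$regulator == edges$target))
    stop("ranked network: self-edges are not allowed", call. = FALSE)
  if (any(abs(edges$partial_correlation) > 1 + 1e-12))
    stop("ranked network: |partial correlation| > 1", call. = FALSE)
  edges <- as.data.frame(edges[, need], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$confidence, -abs(edges$partial_correlation),
                       edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, n_subsamples = as.integer(n_subsamples),
            class = c("trn_network", "data.frame"))
}

#' Coerce to a ranked network
#' @param x a \code{trn_network}, a \code{trn} fit, or a data frame with the
#'   required columns.
#' @export
as_trn_network <- function(x) {
  if (inherits(x, "trn")) return(x$network)
  if (inherits(x, "trn_network")) return(x)
  new_trn_network(x, n_subsamples = if (!is.null(attr(x, "n_subsamples")))
    attr(x, "n_subsamples") else if (nrow(x)) max(x$nonzero_subsamples) else NA)
}

#' @export
print.trn_network <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked TRN: %d edges, %d regulators, %d target genes (%d subsamples)\n",
              nrow(x), length(unique(x$regulator)), length(unique(x$target)),
              attr(x, "n_subsamples")))
  if (nrow(x)) print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more edges\n", sep = "")
  invisible(x)
}
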