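# Benchmarking inferred networks: precision-recall / AUPR against gold
# standards (global and per TF) and out-of-sample expression prediction.

#' Load (filter) a gold standard edge set
#'
#' Retains edges with |score| >= cutoff. Default cutoffs follow the
#' provenance of the reference data: 0.75 for KO, 0.75 for ChIP and 1.5
#' for combined KO + ChIP networks.
#'
#' @param edges data frame with columns regulator, target and score (and
#'   optionally sign; otherwise the sign of the score is used).
#' @param provenance one of \code{"KO"}, \code{"ChIP"}, \code{"KO_ChIP"},
#'   \code{"other"}.
#' @param cutoff score cutoff; defaults by provenance as above (0 for
#'   \code{"other"}).
#' @param gene_universe,tf_universe optional evaluation universes the
#'   retained edges are restricted to (and which define the possible-edge
#'   space for random AUPR).
#' @return data frame of class \code{gold_standard} with attributes
#'   \code{cutoff}, \code{provenance}, \code{gene_universe},
#'   \code{tf_universe}.
#' @export
load_gold_standard <- function(edges, provenance = c("KO", "ChIP", "KO_ChIP",
                                                     "other"),
                               cutoff = NULL, gene_universe = NULL,
                               tf_universe = NULL) {
  provenance <- match.arg(provenance)
  if (is.null(cutoff))
    cutoff <- switch(provenance, KO = 0.75, ChIP = 0.75, KO_ChIP = 1.5,
                     other = 0)
  if (is.null(edges$score)) edges$score <- 1
  if (!is.numeric(edges$score)) stop("gold standard: non-numeric scores",
                                     call. = FALSE)
  gs <- edges[abs(edges$score) >= cutoff, , drop = FALSE]
  if (is.null(gs$sign)) gs$sign <- ifelse(gs$score >= 0, "+", "-")
  if (!is.null(gene_universe)) gs <- gs[gs$target %in% gene_universe, ]
  if (!is.null(tf_universe)) gs <- gs[gs$regulator %in% tf_universe, ]
  if (!nrow(gs))
    stop("load_gold_standard: no edges retained after cutoff ", cutoff,
         call. = FALSE)
  gs <- unique(gs[, c("regulator", "target", "score", "sign")])
  rownames(gs) <- NULL
  structure(gs, cutoff = cutoff, provenance = provenance,
            gene_universe = if (is.null(gene_universe)) unique(gs$target)
                            else gene_universe,
            tf_universe = if (is.null(tf_universe)) unique(gs$regulator)
                          else tf_universe,
            class = c("gold_standard", "data.frame"))
}

# Precision/recall step curve with tie-block averaging and trapezoidal
# AUPR. `labels` are 0/1 in ranked order; `scores` break the ranking into
# tie blocks (equal scores). Returns boundary points and the area.
.pr_area <- function(labels, scores, n_positives) {
  if (!length(labels) || n_positives == 0)
    return(list(curve = data.frame(rank = integer(0), recall = numeric(0),
                                   precision = numeric(0)), aupr = 0))
  blocks <- cumsum(!duplicated(scores))
  endrank <- cumsum(as.integer(table(blocks)))
  tp <- cumsum(labels)[endrank]
  prec <- tp / endrank
  rec <- tp / n_positives
  # prepend recall 0 at the first block's precision
  r0 <- c(0, rec); p0 <- c(prec[1L], prec)
  aupr <- sum(diff(r0) * (utils::head(p0, -1L) + p0[-1L]) / 2)
  list(curve = data.frame(rank = endrank, recall = rec, precision = prec),
       aupr = aupr)
}

#' Precision-recall of a ranked network against a gold standard
#'
#' Evaluation is restricted to the gold standard's TF x gene universe:
#' network edges whose regulator is a GS TF and whose target lies in the
#' GS-assessable gene universe, traversed in descending confidence. Ties
#' in confidence are handled by averaging over the tied block; AUPR is the
#' trapezoidal integral of precision over recall.
#'
#' @param net ranked network (or \code{trn} fit).
#' @param gs gold standard from \code{\link{load_gold_standard}} (or any
#'   data frame with regulator/target and optional universe attributes).
#' @return list with \code{curve}, \code{aupr}, \code{random_aupr},
#'   \code{n_positives}, \code{n_candidates}.
#' @export
precision_recall <- function(net, gs) {
  net <- as_trn_network(net)
  tfs <- unique(attr(gs, "tf_universe") %||% gs$regulator)
  genes <- unique(attr(gs, "gene_universe") %||% gs$target)
  if (!any(net$regulator %in% tfs))
    stop("precision_recall: gold standard TFs disjoint from the network",
         call. = FALSE)
  sub <- net[net$regulator %in% tfs & net$target %in% genes, , drop = FALSE]
  gs_keys <- paste(gs$regulator, gs$target, sep = "\r")
  labels <- as.integer(paste(sub$regulator, sub$target, sep = "\r") %in%
                         gs_keys)
  pr <- .pr_area(labels, sub$confidence, length(gs_keys))
  c(pr, list(random_aupr = length(gs_keys) / (length(tfs) * length(genes)),
             n_positives = length(gs_keys),
             n_candidates = length(tfs) * length(genes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-ranking AUPR baseline
#'
#' The expected AUPR of a random ranking equals the edge density of the
#' gold standard: |GS edges| / (n_tfs * n_genes).
#'
#' @param gs gold standard (optional if \code{n_edges} given).
#' @param n_tfs,n_genes dimensions of the possible-edge space (taken from
#'   the GS universes when omitted).
#' @param n_edges number of gold standard edges (default \code{nrow(gs)}).
#' @return the density ratio.
#' @export
random_aupr <- function(gs = NULL, n_tfs = NULL, n_genes = NULL,
                        n_edges = NULL) {
  if (!is.null(gs)) {
    n_edges <- n_edges %||% nrow(gs)
    n_tfs <- n_tfs %||% length(unique(attr(gs, "tf_universe") %||%
                                        gs$regulator))
    n_genes <- n_genes %||% length(unique(attr(gs, "gene_universe") %||%
                                            gs$target))
  }
  stopifnot(n_tfs > 0, n_genes > 0, n_edges >= 0)
  n_edges / (n_tfs * n_genes)
}

#' Per-TF AUPR against a gold standard
#'
#' Precision-recall is computed within each TF's candidate-gene column and
#' compared (log2 fold change) to that TF's random AUPR, its GS degree
#' divided by the assessable gene count. TFs without GS targets are
#' skipped with a message.
#'
#' @inheritParams precision_recall
#' @return data frame (tf, n_gs_targets, aupr, random_aupr, log2_fc).
#' @export
per_tf_aupr <- function(net, gs) {
  net <- as_trn_network(net)
  genes <- unique(attr(gs, "gene_universe") %||% gs$target)
  tfs <- unique(attr(gs, "tf_universe") %||% gs$regulator)
  out <- lapply(tfs, function(tf) {
    pos <- unique(gs$target[gs$regulator == tf])
    pos <- intersect(pos, genes)
    if (!length(pos)) {
      message("per_tf_aupr: skipping ", tf, " (no gold standard targets)")
      return(NULL)
    }
    sub <- net[net$regulator == tf & net$target %in% genes, , drop = FALSE]
    pr <- .pr_area(as.integer(sub$target %in% pos), sub$confidence,
                   length(pos))
    rnd <- length(pos) / length(genes)
    data.frame(tf = tf, n_gs_targets = length(pos), aupr = pr$aupr,
               random_aupr = rnd, log2_fc = log2(pr$aupr / rnd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Out-of-sample expression prediction from a ranked network
#'
#' For each confidence cutoff: every gene's TF set is taken from the
#' network's edges at or above the cutoff; centered training expression is
#' regressed (OLS) on training activities standardized by the training
#' means/sds; test expression is predicted with the same training
#' normalization. SSE_pred is compared to the null SSE about the training
#' gene mean, giving R2_pred = 1 - SSE_pred / SSE_null (per gene and pooled
#' over genes). Genes whose TF set reaches the training sample count are
#' skipped with a warning; zero-training-variance TFs are dropped per gene.
#'
#' @param net ranked network (inferred from training data only).
#' @param expr_train,expr_test genes x samples expression (disjoint sample
#'   sets).
#' @param activities_train,activities_test TFs x samples activities.
#' @param confidence_cutoffs numeric vector of cutoffs (edges with
#'   confidence >= cutoff are used).
#' @param genes evaluation genes (default: network targets present in both
#'   expression matrices).
#' @return object of class \code{prediction_report}: data frame
#'   \code{$summary} (cutoff, model_size, r2_pred_pooled, r2_pred_mean)
#'   and list \code{$per_gene} of per-gene tables.
#' @export
predict_out_of_sample <- function(net, expr_train, expr_test,
                                  activities_train, activities_test,
                                  confidence_cutoffs = 0,
                                  genes = NULL) {
  net <- as_trn_network(net)
  if (length(intersect(colnames(expr_train), colnames(expr_test))))
    stop("predict_out_of_sample: train/test samples overlap", call. = FALSE)
  if (is.null(genes))
    genes <- intersect(intersect(unique(net$target), rownames(expr_train)),
                       rownames(expr_test))
  tf_ok <- intersect(rownames(activities_train), rownames(activities_test))
  amu <- rowMeans(activities_train)
  asd <- apply(activities_train, 1L, stats::sd)
  per_gene <- list(); summ <- list()
  for (ci in seq_along(confidence_cutoffs)) {
    cutoff <- confidence_cutoffs[ci]
    sel <- net[net$confidence >= cutoff & net$regulator %in% tf_ok, ,
               drop = FALSE]
    sets <- split(sel$regulator, factor(sel$target, levels = genes))
    skipped <- character(0)
    rows <- vector("list", length(genes))
    sizes <- numeric(length(genes))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      tfs <- setdiff(unique(sets[[g]]), g)   # no self-prediction
      tfs <- tfs[asd[tfs] > 0]
      xtr <- expr_train[g, ]; xte <- expr_test[g, ]
      mu <- mean(xtr)
      sse_null <- sum((xte - mu)^2)
      if (length(tfs) >= ncol(expr_train)) {
        skipped <- c(skipped, g)
        rows[[gi]] <- data.frame(gene = g, n_tfs = length(tfs),
                                 sse_pred = NA_real_, sse_null = sse_null,
                                 r2_pred = NA_real_)
        sizes[gi] <- length(tfs)
        next
      }
      if (!length(tfs)) {
        pred <- rep(mu, length(xte))
      } else {
        Ztr <- t((activities_train[tfs, , drop = FALSE] - amu[tfs]) /
                   asd[tfs])
        Zte <- t((activities_test[tfs, , drop = FALSE] - amu[tfs]) /
                   asd[tfs])
        beta <- stats::lm.fit(Ztr, xtr - mu)$coefficients
        beta[is.na(beta)] <- 0
        pred <- drop(Zte %*% beta) + mu
      }
      sse_pred <- sum((xte - pred)^2)
      rows[[gi]] <- data.frame(gene = g, n_tfs = length(tfs),
                               sse_pred = sse_pred, sse_null = sse_null,
                               r2_pred = 1 - sse_pred / sse_null)
      sizes[gi] <- length(tfs)
    }
    if (length(skipped))
      warning("predict_out_of_sample: skipped ", length(skipped),
              " gene(s) with TF sets reaching the training sample count")
    tab <- do.call(rbind, rows)
    ok <- !is.na(tab$sse_pred)
    summ[[ci]] <- data.frame(
      cutoff = cutoff,
      model_size = mean(sizes),
      r2_pred_pooled = 1 - sum(tab$sse_pred[ok]) / sum(tab$sse_null[ok]),
      r2_pred_mean = mean(tab$r2_pred[ok]))
    per_gene[[ci]] <- tab
  }
  structure(list(summary = do.call(rbind, summ), per_gene = per_gene,
                 cutoffs = confidence_cutoffs),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Out-of-sample prediction report\n")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Network quality metrics as a function of model size
#'
#' Sweeps a confidence-cutoff grid, reporting the mean TFs/gene, pooled
#' out-of-sample R2_pred and (when a gold standard is given) precision and
#' recall of the thresholded network.
#'
#' @inheritParams predict_out_of_sample
#' @param cutoff_grid confidence cutoffs to sweep.
#' @param gs optional gold standard for precision/recall.
#' @return data frame (cutoff, model_size, r2_pred_pooled, precision,
#'   recall).
#' @export
model_size_sweep <- function(net, expr_train, expr_test, activities_train,
                             activities_test, cutoff_grid, gs = NULL,
                             genes = NULL) {
  net <- as_trn_network(net)
  rep_ <- predict_out_of_sample(net, expr_train, expr_test,
                                activities_train, activities_test,
                                confidence_cutoffs = cutoff_grid,
                                genes = genes)
  out <- rep_$summary
  out$precision <- NA_real_; out$recall <- NA_real_
  if (!is.null(gs)) {
    tfs <- unique(attr(gs, "tf_universe") %||% gs$regulator)
    genes_gs <- unique(attr(gs, "gene_universe") %||% gs$target)
    keys <- paste(gs$regulator, gs$target, sep = "\r")
    for (i in seq_along(cutoff_grid)) {
      sub <- net[net$confidence >= cutoff_grid[i] & net$regulator %in% tfs &
                   net$target %in% genes_gs, , drop = FALSE]
      tp <- sum(paste(sub$regulator, sub$target, sep = "\r") %in% keys)
      out$precision[i] <- if (nrow(sub)) tp / nrow(sub) else NA_real_
      out$recall[i] <- tp / length(keys)
    }
  }
  out
}
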