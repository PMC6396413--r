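# Interrogation of a final network: de novo core regulators, TF-TF target
# overlap modules, GWAS gene-set enrichment and centrality.

# Upper-tail hypergeometric p-value: P(overlap >= q) drawing k from a
# universe with m successes.
.hyper_p <- function(q, m, n, k) stats::phyper(q - 1, m, n, k,
                                               lower.tail = FALSE)

#' De novo core regulators by signed target enrichment
#'
#' A TF is a core regulator of a condition if its positive targets are
#' enriched in the condition's up-regulated genes, or its negative targets
#' in the down-regulated genes, at the given FDR (hypergeometric upper
#' tail, Benjamini-Hochberg corrected per direction).
#'
#' @param net signed ranked network (or \code{trn} fit).
#' @param up_genes,down_genes condition-responsive gene sets (subsets of
#'   the universe).
#' @param universe evaluation universe (default: network target genes).
#' @param fdr BH threshold (default 1\%).
#' @return data frame (tf, direction, n_targets, overlap, p, fdr_adj,
#'   core).
#' @export
core_tf_enrichment <- function(net, up_genes, down_genes, universe = NULL,
                               fdr = 0.01) {
  net <- as_trn_network(net)
  universe <- unique(universe %||% net$target)
  up_genes <- intersect(unique(up_genes), universe)
  down_genes <- intersect(unique(down_genes), universe)
  tfs <- unique(net$regulator)
  one_dir <- function(sgn, set, label) {
    rows <- lapply(tfs, function(tf) {
      targ <- intersect(unique(
        net$target[net$regulator == tf & net$sign == sgn]), universe)
      if (!length(targ)) return(NULL)   # no signed targets of this sign
      q <- length(intersect(targ, set))
      data.frame(tf = tf, direction = label, n_targets = length(targ),
                 overlap = q,
                 p = .hyper_p(q, length(set),
                              length(universe) - length(set), length(targ)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) return(NULL)
    tab$fdr_adj <- stats::p.adjust(tab$p, method = "BH")
    tab
  }
  out <- rbind(one_dir("+", up_genes, "activator_of_up"),
               one_dir("-", down_genes, "repressor_of_down"))
  if (is.null(out)) stop("core_tf_enrichment: no signed targets to test",
                         call. = FALSE)
  out$core <- out$fdr_adj <= fdr
  rownames(out) <- NULL
  out
}

#' Normalized TF-TF shared-target overlap matrix
#'
#' After excluding edges with |partial correlation| below \code{pcorr_min}
#' and TFs with fewer than \code{min_targets} remaining targets of the
#' requested sign, overlap(i, j) = |targets_i intersect targets_j| /
#' min(|targets_i|, |targets_j|); symmetric with unit diagonal.
#'
#' @param net signed ranked network.
#' @param sign \code{"positive"} or \code{"negative"} target edges.
#' @param min_targets minimum targets per TF (default 20).
#' @param pcorr_min minimum |partial correlation| per edge (default 0.01).
#' @param normalization \code{"min"} (default) or \code{"jaccard"}.
#' @return symmetric TF x TF matrix in [0, 1].
#' @export
tf_module_overlap <- function(net, sign = c("positive", "negative"),
                              min_targets = 20L, pcorr_min = 0.01,
                              normalization = c("min", "jaccard")) {
  sign <- match.arg(sign); normalization <- match.arg(normalization)
  net <- as_trn_network(net)
  sgn <- if (sign == "positive") "+" else "-"
  sub <- net[net$sign == sgn & abs(net$partial_correlation) >= pcorr_min, ]
  sets <- split(sub$target, sub$regulator)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) >= min_targets]
  if (length(sets) < 2L)
    stop("tf_module_overlap: fewer than 2 TFs survive the filters",
         call. = FALSE)
  sets <- sets[order(names(sets))]
  k <- length(sets)
  M <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in i:k) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    denom <- if (normalization == "min")
      min(lengths(sets)[c(i, j)])
    else length(union(sets[[i]], sets[[j]]))
    M[i, j] <- M[j, i] <- inter / denom
  }
  M
}

#' Cluster TFs into modules from an overlap matrix
#'
#' Average-linkage hierarchical clustering on distance 1 - overlap, with
#' deterministic input ordering by TF id. Modules of size >= 2 are
#' reported.
#'
#' @param overlap symmetric TF x TF overlap matrix in [0, 1].
#' @param k number of clusters, or
#' @param h dendrogram cut height (one of \code{k}, \code{h} required).
#' @return list with \code{assignments} (named integer vector),
#'   \code{modules} (list of TF id vectors, size >= 2) and the
#'   \code{hclust} tree.
#' @export
cluster_tf_modules <- function(overlap, k = NULL, h = NULL) {
  stopifnot(isSymmetric(unname(overlap)), !is.null(k) || !is.null(h))
  ord <- order(rownames(overlap))
  overlap <- overlap[ord, ord]
  tree <- stats::hclust(stats::as.dist(1 - overlap), method = "average")
  assign <- stats::cutree(tree, k = k, h = h)
  tab <- table(assign)
  keep <- as.integer(names(tab)[tab >= 2L])
  modules <- lapply(keep, function(m) sort(names(assign)[assign == m]))
  list(assignments = assign, modules = modules, tree = tree)
}

#' Map SNPs to their nearest gene within a window
#'
#' @param snp_table data frame (snp_id, chrom, pos, phenotype, optionally
#'   mapped_gene which is used directly when present).
#' @param gene_annotations feature data frame of gene bodies (0-based
#'   half-open).
#' @param window_bp maximum SNP-to-gene-body distance (default 1 Mbp);
#'   SNPs farther from every gene stay unmapped.
#' @return the SNP table with a \code{mapped_gene} column (NA = unmapped).
#' @export
map_snps_to_genes <- function(snp_table, gene_annotations,
                              window_bp = 1e6) {
  if (!is.null(snp_table$mapped_gene)) return(snp_table)
  genes <- genomic_features(gene_annotations, "genes")
  chroms <- union(snp_table$chrom, genes$chrom)
  sg <- GenomicRanges::GRanges(factor(snp_table$chrom, levels = chroms),
                               IRanges::IRanges(snp_table$pos + 1L,
                                                snp_table$pos + 1L))
  gg <- .features_to_granges(genes, seqlevels = chroms)
  near <- GenomicRanges::distanceToNearest(sg, gg)
  mapped <- rep(NA_character_, nrow(snp_table))
  hit <- S4Vectors::queryHits(near)
  ok <- S4Vectors::mcols(near)$distance <= window_bp
  mapped[hit[ok]] <- genes$id[S4Vectors::subjectHits(near)[ok]]
  snp_table$mapped_gene <- mapped
  snp_table
}

#' TF-target enrichment in GWAS phenotype gene sets
#'
#' Phenotype sets (from \code{gene_sets}, or built from a SNP table by
#' nearest-gene mapping within \code{window_bp}) with at least
#' \code{min_set} genes are tested against the targets of every TF with at
#' least \code{min_targets} targets, using the hypergeometric upper tail on
#' the network's target-gene universe, with Benjamini-Hochberg correction
#' across all tested pairs.
#'
#' @param net ranked network.
#' @param gene_sets named list of phenotype gene sets (e.g. from
#'   \code{\link{read_gmt}}).
#' @param snp_table,gene_annotations alternative input: SNP-phenotype table
#'   mapped to nearest genes (see \code{\link{map_snps_to_genes}}).
#' @param min_set minimum genes per phenotype set (default 5).
#' @param min_targets minimum targets per TF (default 5).
#' @param fdr BH threshold (default 10\%).
#' @param window_bp SNP-to-gene window (default 1 Mbp).
#' @return data frame (tf, phenotype, n_targets, set_size, overlap, p,
#'   fdr_adj, significant).
#' @export
gwas_enrichment <- function(net, gene_sets = NULL, snp_table = NULL,
                            gene_annotations = NULL, min_set = 5L,
                            min_targets = 5L, fdr = 0.10, window_bp = 1e6) {
  net <- as_trn_network(net)
  if (is.null(gene_sets)) {
    if (is.null(snp_table))
      stop("gwas_enrichment: supply gene_sets or a snp_table", call. = FALSE)
    snp_table <- map_snps_to_genes(snp_table, gene_annotations, window_bp)
    mapped <- snp_table[!is.na(snp_table$mapped_gene), , drop = FALSE]
    gene_sets <- lapply(split(mapped$mapped_gene, mapped$phenotype), unique)
  }
  gene_sets <- gene_sets[vapply(gene_sets, length, 1L) >= min_set]
  universe <- unique(net$target)
  targets <- lapply(split(net$target, net$regulator), unique)
  targets <- targets[lengths(targets) >= min_targets]
  if (!length(gene_sets) || !length(targets))
    stop("gwas_enrichment: no testable TF-phenotype pairs", call. = FALSE)
  rows <- list()
  for (tf in names(targets)) for (ph in names(gene_sets)) {
    set <- intersect(gene_sets[[ph]], universe)
    q <- length(intersect(targets[[tf]], set))
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, phenotype = ph, n_targets = length(targets[[tf]]),
      set_size = length(set), overlap = q,
      p = .hyper_p(q, length(set), length(universe) - length(set),
                   length(targets[[tf]])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr_adj <= fdr
  out[order(out$p), ]
}

#' Degree and betweenness centrality of TFs in a TRN
#'
#' The network is a directed TF -> gene graph (TFs may themselves be
#' targets). Normalized out-degree is a TF's target count divided by the
#' total number of target genes in the (sub)network. Betweenness is the
#' fraction of shortest TF -> target paths that pass through the TF as an
#' intermediate node: paths of length 1 admit no intermediate and are
#' excluded from the denominator, multiple shortest paths for a pair split
#' fractionally. With \code{restrict_genes} the induced subnetwork on
#' those genes and their regulators is analysed instead.
#'
#' @param net ranked network.
#' @param restrict_genes optional gene subset (e.g. disease genes).
#' @param tf_universe optional TF universe; TFs without edges in the
#'   (sub)network are reported with degree and betweenness 0.
#' @return data frame (tf, n_targets, out_degree_normalized, betweenness).
#' @export
centrality <- function(net, restrict_genes = NULL, tf_universe = NULL) {
  net <- as_trn_network(net)
  edges <- as.data.frame(net)[, c("regulator", "target")]
  if (!is.null(restrict_genes)) {
    regs <- unique(edges$regulator[edges$target %in% restrict_genes])
    nodes <- union(restrict_genes, regs)
    edges <- edges[edges$regulator %in% nodes & edges$target %in% nodes, ]
  }
  if (!nrow(edges)) stop("centrality: empty (sub)network", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  tfs <- sort(unique(edges$regulator))
  target_genes <- unique(edges$target)
  deg <- vapply(tfs, function(tf)
    length(unique(edges$target[edges$regulator == tf])), 1L)
  # enumerate shortest TF -> target paths with >= 1 intermediate
  btw <- stats::setNames(numeric(length(tfs)), tfs)
  denom <- 0L
  vnames <- igraph::V(g)$name
  for (s in tfs) {
    d <- igraph::distances(g, v = s, mode = "out")[1L, ]
    reach <- vnames[is.finite(d) & d >= 2 & vnames %in% target_genes]
    reach <- setdiff(reach, s)
    if (!length(reach)) next
    for (t in reach) {
      ap <- igraph::all_shortest_paths(g, from = s, to = t,
                                       mode = "out")$vpaths
      denom <- denom + 1L
      sigma <- length(ap)
      for (p in ap) {
        mids <- setdiff(names(p), c(s, t))
        mids <- intersect(mids, tfs)
        if (length(mids)) btw[mids] <- btw[mids] + 1 / sigma
      }
    }
  }
  if (denom > 0L) btw <- btw / denom
  out <- data.frame(tf = tfs, n_targets = as.integer(deg),
                    out_degree_normalized = deg / length(target_genes),
                    betweenness = as.numeric(btw),
                    stringsAsFactors = FALSE, row.names = NULL)
  extra <- setdiff(tf_universe, tfs)
  if (length(extra))
    out <- rbind(out, data.frame(tf = sort(extra), n_targets = 0L,
                                 out_degree_normalized = 0,
                                 betweenness = 0, stringsAsFactors = FALSE))
  out
}
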