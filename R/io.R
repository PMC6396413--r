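# Readers and writers for the external formats the pipeline touches.
# All genomic coordinates are converted to 0-based half-open on read:
# BED is consumed as-is, FIMO and GTF (1-based inclusive) are shifted.

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column
#' (genes as rows). Set \code{transpose = TRUE} for samples-as-rows files.
#'
#' @param path file path.
#' @param transpose if TRUE, the file has samples as rows and is transposed
#'   on read.
#' @return validated numeric genes x samples matrix.
#' @export
read_expression <- function(path, transpose = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("read_expression: duplicated gene id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    stop("read_expression: non-numeric values in column(s): ",
         paste(names(vals)[!num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  as_expression_matrix(m)
}

#' Write an expression matrix to TSV (genes as rows)
#' @param x expression matrix.
#' @param path output path.
#' @param id_col header for the gene-id column.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  x <- as_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic features
#'
#' BED 3+ columns; coordinates are kept 0-based half-open.
#'
#' @param path BED file.
#' @return feature data frame (see \code{\link{genomic_features}}).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("read_bed: need at least 3 columns", call. = FALSE)
  df <- data.frame(chrom = as.character(tab[[1L]]), start = tab[[2L]],
                   end = tab[[3L]], stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) df$id <- as.character(tab[[4L]])
  if (ncol(tab) >= 5L) df$score <- suppressWarnings(as.numeric(tab[[5L]]))
  if (ncol(tab) >= 6L) df$strand <- as.character(tab[[6L]])
  genomic_features(df, what = "BED")
}

#' Read gene records from a GTF file
#'
#' Extracts gene bodies (feature type \code{gene}, or all rows if no gene
#' records are present) with ids parsed from the \code{gene_id} attribute.
#' GTF 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GTF file.
#' @return feature data frame.
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9L)) stop("read_gtf_genes: malformed GTF", call. = FALSE)
  feat <- vapply(parts, `[[`, "", 3L)
  keep <- if (any(feat == "gene")) feat == "gene" else rep(TRUE, length(feat))
  parts <- parts[keep]
  attrs <- vapply(parts, `[[`, "", 9L)
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?;?.*', "\\1", attrs)
  genomic_features(data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(parts, `[[`, "", 5L)),
    id = gid,
    strand = vapply(parts, `[[`, "", 7L),
    stringsAsFactors = FALSE), what = "GTF")
}

#' Read a FIMO-style motif occurrence table
#'
#' Expects a TSV with columns motif_id (or \code{#pattern name}),
#' sequence_name, start, stop, strand, score, p-value. FIMO's 1-based
#' inclusive coordinates are converted to 0-based half-open.
#'
#' @param path FIMO TSV.
#' @return data frame with columns tf_id, chrom, start, end, strand, score,
#'   p_value.
#' @export
read_motif_hits <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(tab))))
  nm <- sub("^_+|_+$", "", nm)
  names(tab) <- nm
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (!length(hit)) stop("read_motif_hits: missing column (one of ",
                           paste(cands, collapse = "/"), ")", call. = FALSE)
    tab[[hit[1L]]]
  }
  hits <- data.frame(
    tf_id = as.character(pick(c("motif_id", "pattern_name", "tf_id"))),
    chrom = as.character(pick(c("sequence_name", "chrom", "seqnames"))),
    start = as.integer(pick("start")) - 1L,
    end = as.integer(pick(c("stop", "end"))),
    strand = as.character(pick("strand")),
    score = as.numeric(pick("score")),
    p_value = as.numeric(pick(c("p_value", "p.value", "pvalue"))),
    stringsAsFactors = FALSE)
  if (any(hits$end <= hits$start))
    stop("read_motif_hits: malformed interval (end <= start)", call. = FALSE)
  if (!all(hits$strand %in% c("+", "-", ".")))
    stop("read_motif_hits: unknown strand symbol", call. = FALSE)
  if (any(hits$p_value <= 0 | hits$p_value > 1))
    stop("read_motif_hits: p_value outside (0, 1]", call. = FALSE)
  hits
}

#' Read gene sets from a GMT file
#' @param path GMT file (name, description, genes... per tab-separated line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("read_gmt: each line needs name, description and >= 1 gene",
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Read a TF-gene edge table from TSV
#'
#' The first two columns are taken as regulator and target (headers
#' regulator/target or tf/gene are recognised); optional \code{score} and
#' \code{sign} columns are carried along.
#'
#' @param path TSV file.
#' @return data frame with columns regulator, target and optionally score,
#'   sign.
#' @export
read_edge_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  reg <- match(TRUE, nm %in% c("regulator", "tf", "tf_id", "source"))
  tgt <- match(TRUE, nm %in% c("target", "gene", "gene_id"))
  if (is.na(reg)) reg <- 1L
  if (is.na(tgt)) tgt <- setdiff(seq_len(ncol(tab)), reg)[1L]
  out <- data.frame(regulator = as.character(tab[[reg]]),
                    target = as.character(tab[[tgt]]),
                    stringsAsFactors = FALSE)
  if ("score" %in% nm) out$score <- as.numeric(tab[[match("score", nm)]])
  if ("sign" %in% nm) out$sign <- as.character(tab[[match("sign", nm)]])
  out
}

#' Read/write a prior matrix as TSV
#'
#' Triplet format has header \code{regulator  target  value}; dense format
#' is a genes x TFs table with gene ids in the first column.
#'
#' @param path TSV file.
#' @return sparse prior matrix.
#' @export
read_prior <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  if (all(c("regulator", "target") %in% nm)) {
    reg <- as.character(tab[[match("regulator", nm)]])
    tgt <- as.character(tab[[match("target", nm)]])
    val <- if ("value" %in% nm) as.numeric(tab[[match("value", nm)]]) else 1
    genes <- sort(unique(tgt)); tfs <- sort(unique(reg))
    P <- Matrix::sparseMatrix(i = match(tgt, genes), j = match(reg, tfs),
                              x = val, dims = c(length(genes), length(tfs)),
                              dimnames = list(genes, tfs))
    prior_matrix(P)
  } else {
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- ids
    prior_matrix(m)
  }
}

#' @rdname read_prior
#' @param P prior matrix.
#' @param format \code{"triplet"} (sparse, default) or \code{"dense"}.
#' @export
write_prior <- function(P, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(gene_id = rownames(P), as.matrix(P),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tr <- Matrix::summary(methods::as(P, "TsparseMatrix"))
    df <- data.frame(regulator = colnames(P)[tr$j],
                     target = rownames(P)[tr$i], value = tr$x,
                     stringsAsFactors = FALSE)
    df <- df[order(df$regulator, df$target), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a ranked network to TSV
#'
#' Columns: regulator, target, sign, confidence, confidence_norm,
#' nonzero_subsamples, partial_correlation, in_prior; rows sorted by
#' descending confidence.
#'
#' @param network ranked network data frame (class \code{trn_network}) or a
#'   \code{trn} fit.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  net <- as_trn_network(network)
  net <- net[order(-net$confidence, -abs(net$partial_correlation),
                   net$regulator, net$target), , drop = FALSE]
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked network written by \code{write_network}
#' @param path TSV file.
#' @param n_subsamples subsample count to attach (taken from the largest
#'   nonzero_subsamples value if missing).
#' @return ranked network data frame.
#' @export
read_network <- function(path, n_subsamples = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  tab$regulator <- as.character(tab$regulator)
  tab$target <- as.character(tab$target)
  tab$sign <- as.character(tab$sign)
  if (is.null(n_subsamples))
    n_subsamples <- if (nrow(tab)) max(tab$nonzero_subsamples) else NA_integer_
  new_trn_network(tab, n_subsamples = n_subsamples)
}
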