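test_that("core-TF enrichment matches exact hypergeometric tails", {
  # TF with all 10 positive targets inside a 20-gene up-set, universe 100
  universe <- paste0("g", 1:100)
  up <- paste0("g", 1:20)
  edges <- data.frame(
    regulator = "TF1", target = paste0("g", 1:10), sign = "+",
    confidence = 50.5, confidence_norm = 0.99, nonzero_subsamples = 50L,
    partial_correlation = 0.5, in_prior = FALSE)
  # pad the network so the universe is the full 100 genes
  pad <- data.frame(
    regulator = "TF2", target = universe, sign = "-",
    confidence = 10.1, confidence_norm = 0.2, nonzero_subsamples = 10L,
    partial_correlation = -0.1, in_prior = FALSE)
  net <- new_trn_network(rbind(edges, pad), 50L)
  tab <- core_tf_enrichment(net, up_genes = up, down_genes = character(0),
                            universe = universe)
  p_tf1 <- tab$p[tab$tf == "TF1" & tab$direction == "activator_of_up"]
  expect_equal(p_tf1, hyper_tail_oracle(10, 20, 100, 10) /
                 1)  # overlap 10 of 10 draws
  expect_equal(p_tf1, phyper(9, 20, 80, 10, lower.tail = FALSE))
  expect_true(tab$core[tab$tf == "TF1" & tab$direction == "activator_of_up"])

  # zero overlap is never core
  down <- paste0("g", 90:100)
  tab2 <- core_tf_enrichment(net, up_genes = character(0),
                             down_genes = down, universe = universe)
  r <- tab2[tab2$tf == "TF2" & tab2$direction == "repressor_of_down", ]
  expect_equal(r$overlap, 11L)
  # TF2 targets everything, so the overlap is certain: p = 1
  expect_equal(r$p, 1)
})

test_that("hypergeometric p-values agree with enumeration (universe <= 30)", {
  set.seed(101)
  for (rep in 1:20) {
    N <- sample(10:30, 1)
    m <- sample(1:(N - 1), 1)
    k <- sample(1:(N - 1), 1)
    q <- sample(0:min(m, k), 1)
    expect_equal(priorTRN:::.hyper_p(q, m, N - m, k),
                 hyper_tail_oracle(q, m, N, k), tolerance = 1e-12)
  }
})

test_that("BH thresholding never rejects beyond the step-up bound", {
  set.seed(102)
  p <- c(runif(30)^3, runif(20))
  adj <- p.adjust(p, "BH")
  q <- 0.1
  rej <- adj <= q
  if (any(rej)) {
    m <- length(p)
    ranks <- rank(p, ties.method = "max")
    expect_true(all(p[rej] <= q * max(ranks[rej]) / m))
  }
})

test_that("TF-TF overlap applies the filters and min-normalization", {
  # sets of sizes 20 and 40 sharing 10 -> 10/20 = 0.5
  e1 <- data.frame(regulator = "TF1", target = paste0("g", 1:20))
  e2 <- data.frame(regulator = "TF2", target = paste0("g", 11:50))
  e3 <- data.frame(regulator = "TF3", target = paste0("g", 1:20))   # = TF1
  e4 <- data.frame(regulator = "TF4", target = paste0("g", 60:79))  # disjoint
  e5 <- data.frame(regulator = "TF5", target = paste0("g", 1:5))    # too few
  edges <- rbind(e1, e2, e3, e4, e5)
  edges$sign <- "+"; edges$confidence <- 30.5
  edges$confidence_norm <- 0.6; edges$nonzero_subsamples <- 30L
  edges$partial_correlation <- 0.5; edges$in_prior <- FALSE
  # one weak-pcorr edge that must be excluded before counting
  edges$partial_correlation[edges$regulator == "TF2" &
                              edges$target == "g11"] <- 0.005
  net <- new_trn_network(edges, 50L)
  M <- tf_module_overlap(net, "positive", min_targets = 20)
  expect_false("TF5" %in% rownames(M))   # < 20 targets
  # TF2 keeps 39 >= 20 targets after the pcorr filter, so it stays;
  # shared targets with TF1 are g12..g20 after the filter: 9/20
  expect_equal(M["TF1", "TF2"], 9 / 20)
  expect_equal(M["TF1", "TF3"], 1)       # identical sets
  expect_equal(M["TF1", "TF4"], 0)       # disjoint
  expect_true(isSymmetric(unname(M)))
  expect_equal(unname(diag(M)), rep(1, nrow(M)))
  expect_true(all(M >= 0 & M <= 1))
  # without the weak edge the toy matches 10/20 exactly
  edges$partial_correlation <- 0.5
  M2 <- tf_module_overlap(new_trn_network(edges, 50L), "positive", 20)
  expect_equal(M2["TF1", "TF2"], 0.5)
  expect_error(tf_module_overlap(net, "negative"), "fewer than 2")
})

test_that("module clustering finds block structure deterministically", {
  tfs <- c("TFa", "TFb", "TFc", "TFd")
  M <- diag(4); dimnames(M) <- list(tfs, tfs)
  M[1, 2] <- M[2, 1] <- 0.9
  M[3, 4] <- M[4, 3] <- 0.8
  cl <- cluster_tf_modules(M, k = 2)
  expect_length(cl$modules, 2L)
  expect_true(list(c("TFa", "TFb")) %in% cl$modules ||
                identical(sort(cl$modules[[1]]), c("TFa", "TFb")) ||
                identical(sort(cl$modules[[2]]), c("TFa", "TFb")))
  # permuting input order leaves the assignment unchanged
  perm <- c(3, 1, 4, 2)
  cl2 <- cluster_tf_modules(M[perm, perm], k = 2)
  expect_equal(cl2$assignments[tfs], cl$assignments[tfs])
  # cut height 0.5 on a hand-built matrix: within-block distances 0.1/0.2
  # merge below 0.5, across-block distance 1 stays split
  cl3 <- cluster_tf_modules(M, h = 0.5)
  expect_equal(unname(cl3$assignments["TFa"]),
               unname(cl3$assignments["TFb"]))
  expect_false(cl3$assignments["TFa"] == cl3$assignments["TFc"])
})

test_that("SNPs map to the nearest gene within 1 Mbp only", {
  genes <- genomic_features(data.frame(
    chrom = "chr1", start = c(1e6, 8e6), end = c(1.1e6, 8.1e6),
    id = c("geneA", "geneB")))
  snps <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                     chrom = "chr1",
                     pos = c(1.05e6, 1.9e6, 4.5e6),
                     phenotype = "pheno1", stringsAsFactors = FALSE)
  mapped <- map_snps_to_genes(snps, genes, window_bp = 1e6)
  expect_equal(mapped$mapped_gene, c("geneA", "geneA", NA))
  # rs3 sits ~3.4 Mbp and ~3.5 Mbp from the genes: beyond the 1 Mbp bound
})

test_that("GWAS enrichment filters sets and TFs, then applies BH", {
  universe <- paste0("g", 1:30)
  net <- new_trn_network(data.frame(
    regulator = rep(c("TF1", "TF2"), c(10, 4)),
    target = c(paste0("g", 1:10), paste0("g", 1:4)),
    sign = "+", confidence = 30.5, confidence_norm = 0.6,
    nonzero_subsamples = 30L, partial_correlation = 0.5,
    in_prior = FALSE), 50L)
  pad <- new_trn_network(data.frame(
    regulator = "TF3", target = universe, sign = "+", confidence = 10.1,
    confidence_norm = 0.2, nonzero_subsamples = 10L,
    partial_correlation = 0.1, in_prior = FALSE), 50L)
  full <- max_combine(list(net, pad))
  sets <- list(ph_big = paste0("g", 1:8),        # 8 genes, retained
               ph_small = paste0("g", 1:4))      # 4 genes, dropped
  tab <- gwas_enrichment(full, gene_sets = sets, min_set = 5,
                         min_targets = 5)
  expect_false(any(tab$phenotype == "ph_small"))
  expect_false(any(tab$tf == "TF2"))    # only 4 targets
  r <- tab[tab$tf == "TF1" & tab$phenotype == "ph_big", ]
  # combinatorial oracle: overlap 8 of TF1's 10 targets from a set of 8
  # in a 30-gene universe
  expect_equal(r$p, hyper_tail_oracle(8, 8, 30, 10), tolerance = 1e-12)
  expect_equal(r$overlap, 8L)
  expect_error(gwas_enrichment(full, gene_sets = list(a = "g1"),
                               min_set = 5), "no testable")
})

test_that("centrality separates local degree from path betweenness", {
  # star graph: TF -> 5 genes
  star <- new_trn_network(data.frame(
    regulator = "TF1", target = paste0("g", 1:5), sign = "+",
    confidence = 20.5, confidence_norm = 0.4, nonzero_subsamples = 20L,
    partial_correlation = 0.5, in_prior = FALSE), 50L)
  cs <- centrality(star)
  expect_equal(cs$out_degree_normalized[cs$tf == "TF1"], 1)
  expect_equal(cs$betweenness[cs$tf == "TF1"], 0)

  # chain TF1 -> TF2 -> g: TF2 is the sole intermediate on the only
  # multi-step shortest path
  chain <- new_trn_network(data.frame(
    regulator = c("TF1", "TF2"), target = c("TF2", "gX"), sign = "+",
    confidence = 20.5, confidence_norm = 0.4, nonzero_subsamples = 20L,
    partial_correlation = 0.5, in_prior = FALSE), 50L)
  cc <- centrality(chain)
  expect_equal(cc$betweenness[cc$tf == "TF2"], 1)
  expect_equal(cc$betweenness[cc$tf == "TF1"], 0)

  # disconnected TF via explicit universe
  cu <- centrality(star, tf_universe = c("TF1", "TFiso"))
  expect_equal(cu$out_degree_normalized[cu$tf == "TFiso"], 0)
  expect_equal(cu$betweenness[cu$tf == "TFiso"], 0)

  # restriction to a gene subset recomputes on the induced subnetwork
  mix <- new_trn_network(data.frame(
    regulator = c("TF1", "TF1", "TF2"),
    target = c("gA", "gB", "gB"), sign = "+",
    confidence = 20.5, confidence_norm = 0.4, nonzero_subsamples = 20L,
    partial_correlation = 0.5, in_prior = FALSE), 50L)
  cr <- centrality(mix, restrict_genes = "gA")
  expect_equal(cr$tf, "TF1")
  expect_equal(cr$out_degree_normalized, 1)
  expect_error(centrality(mix, restrict_genes = "gZ"), "empty")
})
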