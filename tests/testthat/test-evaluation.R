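toy_gs <- function() {
  load_gold_standard(data.frame(
    regulator = c("TF1", "TF1", "TF2"),
    target = c("gA", "gB", "gC"),
    score = c(2, -1.8, 1.6), stringsAsFactors = FALSE),
    provenance = "other", cutoff = 0,
    gene_universe = c("gA", "gB", "gC", "gD"),
    tf_universe = c("TF1", "TF2"))
}

test_that("gold-standard cutoffs follow provenance defaults", {
  edges <- data.frame(regulator = c("TF1", "TF1", "TF2", "TF2", "TF3"),
                      target = paste0("g", 1:5),
                      score = c(1.4, 1.6, -2.0, 0.7, 0.76))
  # combined KO+ChIP cutoff 1.5 drops the 1.4 edge
  gs <- load_gold_standard(edges, "KO_ChIP")
  expect_equal(attr(gs, "cutoff"), 1.5)
  expect_false(any(gs$target == "g1"))
  expect_equal(sort(gs$target), c("g2", "g3"))
  # KO cutoff 0.75: hand filter keeps |score| >= 0.75
  gs_ko <- load_gold_standard(edges, "KO")
  expect_equal(sort(gs_ko$target), c("g1", "g2", "g3", "g5"))
  # cutoff 0 keeps everything
  expect_equal(nrow(load_gold_standard(edges, "KO", cutoff = 0)), 5L)
  # signs derive from score signs
  expect_equal(gs$sign[gs$target == "g3"], "-")
  expect_error(load_gold_standard(edges, "KO", cutoff = 10), "no edges")
})

test_that("precision-recall matches brute-force step curves", {
  gs <- toy_gs()
  # perfect ranking: all GS edges first -> AUPR 1
  perfect <- new_trn_network(data.frame(
    regulator = c("TF1", "TF1", "TF2", "TF2"),
    target = c("gA", "gB", "gC", "gD"),
    sign = "+", confidence = c(50, 49, 48, 1), confidence_norm = 0.5,
    nonzero_subsamples = c(50L, 49L, 48L, 1L),
    partial_correlation = 0.1, in_prior = FALSE), 50L)
  expect_equal(precision_recall(perfect, gs)$aupr, 1)

  # 4 candidates, positives ranked 1st and 3rd: brute-force enumeration
  mixed <- new_trn_network(data.frame(
    regulator = c("TF1", "TF2", "TF1", "TF2"),
    target = c("gA", "gD", "gB", "gA"),
    sign = "+", confidence = c(50, 40, 30, 20), confidence_norm = 0.5,
    nonzero_subsamples = c(50L, 40L, 30L, 20L),
    partial_correlation = 0.1, in_prior = FALSE), 50L)
  # positives among candidates: TF1->gA (rank 1), TF1->gB (rank 3);
  # TF2->gC is never retrieved (recall tops out at 2/3)
  labels <- c(1, 0, 1, 0)
  expect_equal(precision_recall(mixed, gs)$aupr,
               aupr_oracle(labels, c(50, 40, 30, 20), 3))

  # reversing the ranking gives the minimal AUPR for this composition
  rev_net <- mixed
  rev_net$confidence <- rev(rev_net$confidence)
  rev_net <- new_trn_network(rev_net, 50L)
  a_rev <- precision_recall(rev_net, gs)$aupr
  expect_equal(a_rev, aupr_oracle(rev(labels), c(50, 40, 30, 20), 3))
  expect_lt(a_rev, precision_recall(mixed, gs)$aupr)

  # precision at rank 1 is 0 or 1; recall never decreases
  curve <- precision_recall(mixed, gs)$curve
  expect_true(curve$precision[1] %in% c(0, 1))
  expect_true(all(diff(curve$recall) >= 0))

  # disjoint TF universes are an error
  empty <- new_trn_network(perfect[0, , drop = FALSE], 50L)
  lone <- new_trn_network(data.frame(
    regulator = "TFX", target = "gA", sign = "+", confidence = 1,
    confidence_norm = 0.1, nonzero_subsamples = 1L,
    partial_correlation = 0.1, in_prior = FALSE), 50L)
  expect_error(precision_recall(lone, gs), "disjoint")
})

test_that("random AUPR equals the gold-standard edge density", {
  expect_equal(random_aupr(n_edges = 8875, n_tfs = 25, n_genes = 3578),
               8875 / 89450)
  expect_equal(round(random_aupr(n_edges = 8875, n_tfs = 25,
                                 n_genes = 3578), 4), 0.0992)
  gs <- toy_gs()
  expect_equal(random_aupr(gs), 3 / (2 * 4))
  # complete GS -> 1; empty -> 0
  expect_equal(random_aupr(n_edges = 8, n_tfs = 2, n_genes = 4), 1)
  expect_equal(random_aupr(n_edges = 0, n_tfs = 2, n_genes = 4), 0)
})

test_that("random rankings converge to the density (permutation law)", {
  set.seed(91)
  tfs <- paste0("TF", 1:5); genes <- sprintf("g%02d", 1:20)
  univ <- expand.grid(regulator = tfs, target = genes,
                      stringsAsFactors = FALSE)
  pos_idx <- sample.int(nrow(univ), 25)
  gs <- load_gold_standard(
    data.frame(regulator = univ$regulator[pos_idx],
               target = univ$target[pos_idx], score = 1),
    provenance = "other", gene_universe = genes, tf_universe = tfs)
  auprs <- replicate(200, {
    conf <- sample(seq_len(nrow(univ))) + 0.5
    net <- new_trn_network(data.frame(
      regulator = univ$regulator, target = univ$target, sign = "+",
      confidence = conf, confidence_norm = conf / 101,
      nonzero_subsamples = as.integer(conf), partial_correlation = 0.1,
      in_prior = FALSE), 100L)
    precision_recall(net, gs)$aupr
  })
  dens <- random_aupr(gs)
  expect_equal(dens, 25 / 100)
  se <- sd(auprs) / sqrt(length(auprs))
  expect_lt(abs(mean(auprs) - dens), 3 * se + 0.01)
})

test_that("per-TF AUPR isolates each TF's candidate column", {
  gs <- toy_gs()
  net <- new_trn_network(data.frame(
    regulator = c("TF1", "TF1", "TF1", "TF2", "TF2"),
    target = c("gA", "gB", "gC", "gC", "gD"),
    sign = "+", confidence = c(50, 49, 10, 50, 9), confidence_norm = 0.5,
    nonzero_subsamples = c(50L, 49L, 10L, 50L, 9L),
    partial_correlation = 0.1, in_prior = FALSE), 50L)
  tab <- per_tf_aupr(net, gs)
  # TF1: both GS targets occupy the top ranks -> AUPR 1,
  # log2 fc = -log2(density) with density 2/4
  r1 <- tab[tab$tf == "TF1", ]
  expect_equal(r1$aupr, 1)
  expect_equal(r1$log2_fc, -log2(2 / 4))
  # TF2: single GS target gC ranked first -> AUPR 1
  expect_equal(tab$aupr[tab$tf == "TF2"], 1)
  # brute-force per-column check on a shuffled ranking
  net2 <- net
  net2$confidence <- c(10, 50, 49, 9, 50)
  net2 <- new_trn_network(net2, 50L)
  tab2 <- per_tf_aupr(net2, gs)
  sub <- net2[net2$regulator == "TF1", ]
  lab <- as.integer(sub$target %in% c("gA", "gB"))
  expect_equal(tab2$aupr[tab2$tf == "TF1"],
               aupr_oracle(lab, sub$confidence, 2))
})

test_that("out-of-sample prediction satisfies the R2 identities", {
  set.seed(92)
  n_tr <- 12; n_te <- 6
  A_tr <- matrix(rnorm(2 * n_tr), 2, n_tr,
                 dimnames = list(c("TF1", "TF2"), paste0("tr", 1:n_tr)))
  A_te <- matrix(rnorm(2 * n_te), 2, n_te,
                 dimnames = list(c("TF1", "TF2"), paste0("te", 1:n_te)))
  x_tr <- 1.5 * A_tr["TF1", ] + rnorm(n_tr, sd = 0.1)
  x_te <- 1.5 * A_te["TF1", ] + rnorm(n_te, sd = 0.1)
  expr_tr <- matrix(x_tr, 1, dimnames = list("gA", colnames(A_tr)))
  expr_te <- matrix(x_te, 1, dimnames = list("gA", colnames(A_te)))
  net <- new_trn_network(data.frame(
    regulator = "TF1", target = "gA", sign = "+", confidence = 50.5,
    confidence_norm = 0.99, nonzero_subsamples = 50L,
    partial_correlation = 0.9, in_prior = TRUE), 50L)

  # empty TF set (cutoff above max confidence): prediction = training mean
  rep0 <- predict_out_of_sample(net, expr_tr, expr_te, A_tr, A_te,
                                confidence_cutoffs = 100)
  expect_equal(rep0$summary$r2_pred_pooled, 0)
  expect_equal(rep0$summary$model_size, 0)

  # hand-computed SSE terms for the 1-gene/1-TF model
  rep1 <- predict_out_of_sample(net, expr_tr, expr_te, A_tr, A_te,
                                confidence_cutoffs = 0)
  z_tr <- (A_tr["TF1", ] - mean(A_tr["TF1", ])) / sd(A_tr["TF1", ])
  z_te <- (A_te["TF1", ] - mean(A_tr["TF1", ])) / sd(A_tr["TF1", ])
  beta <- sum(z_tr * (x_tr - mean(x_tr))) / sum(z_tr^2)
  pred <- beta * z_te + mean(x_tr)
  expect_equal(rep1$per_gene[[1]]$sse_pred, sum((x_te - pred)^2))
  expect_equal(rep1$per_gene[[1]]$sse_null, sum((x_te - mean(x_tr))^2))
  expect_equal(rep1$summary$r2_pred_pooled,
               1 - sum((x_te - pred)^2) / sum((x_te - mean(x_tr))^2))
  expect_lte(rep1$summary$r2_pred_pooled, 1)

  # test = train with an interpolating model: R2 = 1 (needs disjoint ids)
  A_te2 <- A_tr; colnames(A_te2) <- paste0("te", 1:n_tr)
  expr_te2 <- expr_tr; colnames(expr_te2) <- colnames(A_te2)
  x_exact <- 2 * A_tr["TF1", ] - 1 * A_tr["TF2", ]
  expr_tr3 <- matrix(x_exact, 1, dimnames = list("gA", colnames(A_tr)))
  expr_te3 <- matrix(x_exact, 1, dimnames = list("gA", colnames(A_te2)))
  net2 <- new_trn_network(rbind(as.data.frame(net), data.frame(
    regulator = "TF2", target = "gA", sign = "-", confidence = 49.5,
    confidence_norm = 0.97, nonzero_subsamples = 49L,
    partial_correlation = -0.9, in_prior = TRUE)), 50L)
  rep2 <- predict_out_of_sample(net2, expr_tr3, expr_te3, A_tr, A_te2,
                                confidence_cutoffs = 0)
  expect_equal(rep2$summary$r2_pred_pooled, 1, tolerance = 1e-10)

  # overlapping train/test is rejected
  expect_error(predict_out_of_sample(net, expr_tr, expr_tr, A_tr, A_tr),
               "overlap")
})

test_that("model-size sweep is monotone in the cutoff", {
  out <- fit_small(noise = 0.3, n_samples = 50)
  sim_te <- simulate_expression(out$B, 20, noise_sd = 0.3,
                                mrna_fidelity = 1, seed = 77)
  colnames(sim_te$genes) <- paste0("t", 1:20)
  colnames(sim_te$tf_mrna) <- paste0("t", 1:20)
  A_tr <- tfa_from_mrna(out$sim$tf_mrna, colnames(out$B))
  A_te <- tfa_from_mrna(sim_te$tf_mrna, colnames(out$B))
  gs <- make_gold_standard(out$B, 1, seed = 1)
  cuts <- c(0, 10, 20, 45, 1000)
  tab <- model_size_sweep(out$fit, out$sim$genes, sim_te$genes,
                          A_tr, A_te, cutoff_grid = cuts, gs = gs)
  expect_true(all(diff(tab$model_size) <= 0))
  expect_equal(tab$model_size[length(cuts)], 0)
  expect_equal(tab$r2_pred_pooled[length(cuts)], 0)
  expect_true(all(diff(tab$recall) <= 0))
  # per-cutoff recomputation oracle for one interior cutoff
  rep_i <- predict_out_of_sample(out$fit, out$sim$genes, sim_te$genes,
                                 A_tr, A_te, confidence_cutoffs = 20)
  expect_equal(tab$r2_pred_pooled[3], rep_i$summary$r2_pred_pooled)
})
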