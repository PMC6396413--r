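# Small fixtures built in code, shared across test files.

# genes x samples matrix with ids
toy_expr <- function(n_genes = 6, n_samples = 8, seed = 11) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

# standardized activity matrix
toy_activities <- function(n_tfs = 4, n_samples = 8, seed = 12) {
  set.seed(seed)
  A <- matrix(rnorm(n_tfs * n_samples), n_tfs, n_samples,
              dimnames = list(paste0("TF", seq_len(n_tfs)),
                              paste0("s", seq_len(n_samples))))
  t(scale(t(A)))
}

# hand-built ranked network
toy_network <- function() {
  new_trn_network(data.frame(
    regulator = c("TF1", "TF1", "TF2", "TF2", "TF3", "TF3", "TF1"),
    target = c("gA", "gB", "gA", "gC", "gB", "gD", "gD"),
    sign = c("+", "-", "+", "+", "-", "+", "+"),
    confidence = c(50.9, 48.2, 50.1, 30.5, 22.8, 12.3, 5.4),
    confidence_norm = c(50.9, 48.2, 50.1, 30.5, 22.8, 12.3, 5.4) / 51,
    nonzero_subsamples = c(50L, 48L, 50L, 30L, 22L, 12L, 5L),
    partial_correlation = c(0.9, -0.2, 0.1, 0.5, -0.8, 0.3, 0.4),
    in_prior = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE), n_subsamples = 50L)
}

# small end-to-end fit on noiseless-ish synthetic data
fit_small <- function(bias = 0.5, prior = NULL, seed = 7, noise = 0,
                      n_genes = 30, n_tfs = 6, n_samples = 40,
                      fidelity = 1, sim_seed = 3) {
  B <- simulate_trn(n_genes, n_tfs, 2, c(1, 2), seed = sim_seed)
  sim <- simulate_expression(B, n_samples, noise_sd = noise,
                             mrna_fidelity = fidelity, seed = sim_seed + 1)
  A <- tfa_from_mrna(sim$tf_mrna, colnames(B))
  list(B = B, sim = sim,
       fit = mlasso_stars(sim$genes, A, prior = prior, bias = bias,
                          n_subsamples = 20, seed = seed))
}

# brute-force AUPR oracle: step curve at each rank with tie-block
# averaging, trapezoid over recall, recall-0 point at the first block's
# precision
aupr_oracle <- function(labels, scores, n_pos) {
  stopifnot(length(labels) == length(scores))
  if (!length(labels) || n_pos == 0) return(0)
  blocks <- cumsum(!duplicated(scores))
  last <- cumsum(tabulate(blocks))
  tp <- cumsum(labels)[last]
  prec <- tp / last
  rec <- tp / n_pos
  r <- c(0, rec); p <- c(prec[1], prec)
  sum(diff(r) * (p[-length(p)] + p[-1]) / 2)
}

# exact hypergeometric upper-tail by enumeration (universe <= ~30)
hyper_tail_oracle <- function(q, set_size, universe_size, draw) {
  support <- max(0, draw - (universe_size - set_size)):min(draw, set_size)
  probs <- choose(set_size, support) *
    choose(universe_size - set_size, draw - support) /
    choose(universe_size, draw)
  sum(probs[support >= q])
}
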