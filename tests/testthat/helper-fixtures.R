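# random positive expression matrix with named dims
random_expr <- function(p, n, seed = NULL, tissue = "SAT", base = 100,
                        sd = 1, normalized = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(base + rnorm(p * n, sd = sd), p, n,
              dimnames = list(sprintf("p%03d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  expression_matrix(v, tissue = tissue, normalized = normalized)
}

# mark a raw matrix as normalized without changing values (for unit tests
# of stages that only require the flag)
as_normalized <- function(x) {
  expression_matrix(x$values, tissue = x$tissue, normalized = TRUE)
}

# strip the normalized flag so normalization can be applied again
as_normalized_raw <- function(x) {
  expression_matrix(x$values, tissue = x$tissue, normalized = FALSE)
}

# independent quantile-normalization oracle: sort each column, average,
# put back by rank (no ties assumed)
qn_oracle <- function(v) {
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) ref[rank(col)])
  dimnames(out) <- dimnames(v)
  out
}

# random clustering instance mixing planted blocks and noise; small sample
# counts make spurious high correlations common enough to exercise merges
random_instance <- function(seed, max_probes = 50, n_samples = 12) {
  set.seed(seed)
  n_block <- sample(0:3, 1)
  blocks <- if (n_block) lapply(seq_len(n_block), function(i)
    module_spec(sample(2:6, 1), runif(1, 0.7, 1))) else list()
  n_bg <- sample(3:(max_probes - sum(vapply(blocks, `[[`, integer(1),
                                            "n_probes"))), 1)
  d <- cohort_design(n_samples = n_samples, n_background_probes = n_bg,
                     modules = blocks, noise_sd = runif(1, 0.3, 1),
                     trait_missing_rate = 0)
  as_normalized(generate_cohort(d, seed = seed)$sat)
}

# brute-force hypergeometric upper tail by enumerating all draws of size
# n_b from a universe of size N containing the n_a marked elements
hyper_tail_enum <- function(k, n_a, n_b, N) {
  draws <- utils::combn(N, n_b)
  mean(colSums(draws <= n_a) >= k)
}
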