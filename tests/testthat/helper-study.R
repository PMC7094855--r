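# shared helpers for building small studies and null inputs

# a small quick study config for pipeline-level tests
small_config <- function(seed = 42L, n_genes = 300L, ...) {
  study_config(n_genes = n_genes, n_terms = 10L, term_size = 15L,
               n_enriched_terms = 0L, seed = seed, ...)
}

# gene-by-array matrix with no group structure (global null)
null_value_matrix <- function(n_genes, n_arrays = 16L, sd = 1) {
  matrix(rnorm(n_genes * n_arrays, sd = sd), nrow = n_genes,
         dimnames = list(sprintf("g%05d", seq_len(n_genes)), NULL))
}

# lognormal fold-change table: strict orderings almost surely
random_fc_table <- function(n_genes, sdlog = 1) {
  data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
             FC_t6 = rlnorm(n_genes, 0, sdlog),
             FC_t12 = rlnorm(n_genes, 0, sdlog),
             FC_t24 = rlnorm(n_genes, 0, sdlog),
             stringsAsFactors = FALSE)
}

# chi-square distances between row profiles (independent CA oracle)
chisq_row_distances <- function(m) {
  P <- m / sum(m)
  r <- rowSums(P)
  cc <- colSums(P)
  prof <- P / r
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((prof[i, ] - prof[j, ])^2 / cc))
  d
}
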